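#' Resampled mean CV at one sample size
#'
#' Draws `replicates` samples of size `k` from a pool (with replacement by
#' default), applies every estimator to each draw, and returns the mean
#' and standard error of the estimates.  All eight estimators are computed
#' from the same draws, so comparisons between estimators are paired and
#' their bias differences carry much less Monte-Carlo noise.
#'
#' Degenerate draws (sd = 0) contribute a CV of 0 and are counted.
#' Replicates where the `cv3` correction leaves its domain are dropped
#' from the `cv3`/`cv5`/`cv7` means and counted; if they exceed 1% of
#' replicates the run aborts with diagnostics.
#'
#' @param pool a `"trait_pool"` or numeric vector.
#' @param k sample size per replicate (4 <= k; k <= pool size when
#'   `replace = FALSE`).
#' @param replicates number of resampled draws (>= 2; the stated
#'   evaluation world uses 9,999).
#' @param replace draw with replacement (default, matching the evaluation
#'   design) or without (used by the exhaustive-enumeration oracle).
#' @return A data.frame with one row per estimator: `estimator`,
#'   `mean_cv`, `se`, `n_ok`; attributes `n_degenerate`, `n_cv3_domain`,
#'   `n_cv4_clamped`.
#' @export
resample_cv <- function(pool, k, replicates = 9999L, replace = TRUE) {
  x <- if (inherits(pool, "trait_pool")) pool$values else
    check_trait_sample(pool, min_n = 2L, what = "pool")
  k <- as.integer(k)
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("replicates must be >= 2", call. = FALSE)
  if (k < 2L) stop("sample size k must be >= 2", call. = FALSE)
  # k in 2..3 serves the exhaustive-enumeration oracle; estimators whose
  # moment requirements exceed k come back NA there.
  if (!replace && k > length(x))
    stop("k exceeds pool size for without-replacement sampling",
         call. = FALSE)
  if (replace) {
    idx <- sample.int(length(x), k * replicates, replace = TRUE)
    m <- matrix(x[idx], nrow = k)
  } else {
    m <- vapply(seq_len(replicates),
                function(i) x[sample.int(length(x), k)], numeric(k))
  }
  summarise_cv_matrix(cv_matrix(m), replicates)
}

summarise_cv_matrix <- function(est, replicates) {
  bad3 <- attr(est, "n_cv3_domain")
  if (bad3 / replicates >= 0.01)
    stop(sprintf(
      "cv3 correction out of domain in %d/%d replicates (>= 1%%); %s",
      bad3, replicates,
      "the pool is too extreme for the skewness correction at this k"),
      call. = FALSE)
  mean_cv <- colMeans(est, na.rm = TRUE)
  n_ok <- colSums(!is.na(est))
  sds <- apply(est, 2, sd, na.rm = TRUE)
  out <- data.frame(estimator = colnames(est), mean_cv = mean_cv,
                    se = sds / sqrt(n_ok), n_ok = n_ok,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_degenerate") <- attr(est, "n_degenerate")
  attr(out, "n_cv3_domain") <- bad3
  attr(out, "n_cv4_clamped") <- attr(est, "n_cv4_clamped")
  out
}

#' Bias profile of the CV estimators across sample sizes
#'
#' For each sample size k in `grid`, resamples the pool and records, per
#' estimator: the mean CV, its standard error, the bias
#' `B(i,k) = mean_cv - cv_true`, and the proportional bias
#' `PB(i,k) = B(i,k) / cv_true`.  Total bias summaries per estimator are
#' attached: `tpb = sum_k |PB(i,k)|` (the headline, comparable across
#' pools) and `tab = sum_k |B(i,k)|` (the absolute-scale variant).
#'
#' The transform is fitted on and applied to the entire pool before any
#' resampling ([transform_pool()]); `cv_true` is the plug-in CV of the
#' transformed pool.
#'
#' @inheritParams resample_cv
#' @param grid ordered integer vector of sample sizes; default
#'   `seq(10, 400, by = 5)`.  Values must be >= 4 and (without
#'   replacement) <= pool size.
#' @param transform normalization applied pool-wide first; see
#'   [fit_transform()].
#' @param estimators which estimators to report: integers 1:8 or names
#'   `"cv1"`...`"cv8"`.
#' @return A data.frame of class `"bias_profile"` with columns
#'   `estimator`, `k`, `mean_cv`, `se`, `bias`, `pb`; attributes
#'   `cv_true`, `transform`, `replicates`, `tpb`, `tab`,
#'   `n_degenerate`, `n_cv3_domain`, `n_cv4_clamped`.
#' @examples
#' set.seed(1)
#' pool <- simulate_pool(pool_config(4, 10, n_base = 2000, n_extreme = 100))
#' bp <- bias_profile(pool, grid = c(10, 20, 40), replicates = 499)
#' head(bp)
#' attr(bp, "tpb")
#' @export
bias_profile <- function(pool, grid = seq(10L, 400L, by = 5L),
                         replicates = 9999L,
                         transform = c("raw", "log", "cuberoot", "minmax"),
                         estimators = 1:8, replace = TRUE) {
  transform <- match.arg(transform)
  est_names <- normalize_estimators(estimators)
  if (!inherits(pool, "trait_pool")) pool <- empirical_pool(pool)
  grid <- validate_grid(grid, length(pool$values), replace)
  tpool <- if (transform == "raw") pool else transform_pool(pool, transform)
  cv_true <- tpool$cv_true
  if (cv_true == 0) stop("PB undefined: reference CV of the pool is 0",
                         call. = FALSE)
  counts <- c(n_degenerate = 0L, n_cv3_domain = 0L, n_cv4_clamped = 0L)
  rows <- vector("list", length(grid))
  for (j in seq_along(grid)) {
    rs <- resample_cv(tpool, grid[j], replicates, replace = replace)
    counts <- counts + c(attr(rs, "n_degenerate"), attr(rs, "n_cv3_domain"),
                         attr(rs, "n_cv4_clamped"))
    rs <- rs[rs$estimator %in% est_names, ]
    rows[[j]] <- data.frame(estimator = rs$estimator, k = grid[j],
                            mean_cv = rs$mean_cv, se = rs$se,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$bias <- out$mean_cv - cv_true
  out$pb <- out$bias / cv_true
  out <- out[order(match(out$estimator, est_names), out$k), ]
  rownames(out) <- NULL
  attr(out, "cv_true") <- cv_true
  attr(out, "transform") <- transform
  attr(out, "replicates") <- replicates
  attr(out, "tpb") <- vapply(split(abs(out$pb), out$estimator), sum, 0)[est_names]
  attr(out, "tab") <- vapply(split(abs(out$bias), out$estimator), sum, 0)[est_names]
  for (nm in names(counts)) attr(out, nm) <- unname(counts[nm])
  class(out) <- c("bias_profile", "data.frame")
  out
}

normalize_estimators <- function(estimators) {
  if (is.numeric(estimators)) {
    if (!all(estimators %in% 1:8)) stop("estimators must be in 1..8",
                                        call. = FALSE)
    return(paste0("cv", sort(unique(as.integer(estimators)))))
  }
  est <- as.character(estimators)
  ok <- paste0("cv", 1:8)
  if (!all(est %in% ok))
    stop("unknown estimator(s): ", paste(setdiff(est, ok), collapse = ", "),
         call. = FALSE)
  ok[ok %in% est]
}

validate_grid <- function(grid, pool_size, replace = TRUE) {
  grid <- as.integer(grid)
  if (length(grid) == 0L) stop("empty sample-size grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("sample-size grid must be strictly increasing", call. = FALSE)
  if (grid[1] < 4L) stop("sample-size grid minimum must be >= 4",
                         call. = FALSE)
  if (!replace && max(grid) > pool_size)
    stop("sample-size grid exceeds pool size", call. = FALSE)
  grid
}

#' Minimum sample size for a stated accuracy band
#'
#' The minimum sample size k_min of an estimator is the smallest tested k
#' whose proportional bias lies within the accuracy band.  Under the
#' default `"sustained"` rule the band must also hold at every larger
#' tested k, which is robust to Monte-Carlo noise making a curve dip into
#' the band and leave it again; `"first"` takes the raw first crossing.
#'
#' @param profile a [bias_profile()].
#' @param accuracy half-width of the proportional-bias band (default 0.05,
#'   i.e. plus or minus 5%).
#' @param rule `"sustained"` (default) or `"first"`.
#' @return A data.frame of class `"min_sample_report"` with one row per
#'   estimator: `estimator`, `transform`, `accuracy`, `k_min`, `reached`.
#'   `k_min` is `NA` (and `reached` FALSE) when the band is never attained
#'   at the tested sizes.
#' @examples
#' set.seed(1)
#' pool <- simulate_pool(pool_config(4, 10, n_base = 2000, n_extreme = 100))
#' bp <- bias_profile(pool, grid = seq(10, 50, 10), replicates = 499)
#' min_sample_size(bp)
#' @export
min_sample_size <- function(profile, accuracy = 0.05,
                            rule = c("sustained", "first")) {
  rule <- match.arg(rule)
  stopifnot(inherits(profile, "bias_profile"))
  if (nrow(profile) == 0L) stop("empty bias profile", call. = FALSE)
  stopifnot(is.numeric(accuracy), accuracy > 0)
  res <- lapply(split(profile, profile$estimator), function(d) {
    d <- d[order(d$k), ]
    ok <- abs(d$pb) <= accuracy
    hit <- if (rule == "sustained") rev(cumprod(rev(ok))) == 1 else ok
    if (any(hit)) c(k_min = d$k[which(hit)[1]], reached = 1) else
      c(k_min = NA_real_, reached = 0)
  })
  out <- data.frame(estimator = names(res),
                    transform = attr(profile, "transform"),
                    accuracy = accuracy,
                    k_min = vapply(res, `[`, 0, "k_min"),
                    reached = vapply(res, `[`, 0, "reached") == 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(match(out$estimator, paste0("cv", 1:8))), ]
  rownames(out) <- NULL
  class(out) <- c("min_sample_report", "data.frame")
  out
}

#' Full factorial bias evaluation
#'
#' Sweeps pools x transforms x sample sizes, reporting per-k bias rows,
#' per-estimator total bias, and minimum sample sizes, in long format.
#' Input can be a list of `"trait_pool"` objects (simulated or empirical)
#' or a long-format trait table (columns species, trait, value), whose
#' species x trait groups become empirical pools.
#'
#' Groups smaller than the grid minimum are skipped with a warning; for
#' larger groups the grid is truncated at the group size.  Within one pool
#' and sample size the same draws are reused across transforms (indices
#' are drawn once), so transform comparisons are paired.
#'
#' @param pools list of `"trait_pool"` objects, a single `"trait_pool"`,
#'   or a data.frame with columns species, trait, value.
#' @inheritParams bias_profile
#' @param transforms character vector of normalization kinds.
#' @param accuracy accuracy band for the k_min report.
#' @param rule k_min rule, see [min_sample_size()].
#' @return list with data.frames `bias` (pool, transform, estimator, k,
#'   mean_cv, se, bias, pb), `tpb` (pool, transform, estimator, tpb, tab)
#'   and `kmin` (pool, transform, estimator, accuracy, k_min, reached),
#'   plus `skipped` (labels of groups too small to evaluate).
#' @export
evaluate_matrix <- function(pools, estimators = 1:8, transforms = "raw",
                            grid = seq(10L, 400L, by = 5L),
                            replicates = 9999L, accuracy = 0.05,
                            rule = c("sustained", "first")) {
  rule <- match.arg(rule)
  est_names <- normalize_estimators(estimators)
  transforms <- vapply(transforms, function(tr)
    match.arg(tr, transform_kinds()), "")
  pools <- as_pool_list(pools)
  grid <- validate_grid(grid, max(vapply(pools, function(p)
    length(p$values), 0L)))

  bias_rows <- list(); tpb_rows <- list(); kmin_rows <- list()
  skipped <- character(0)
  for (pname in names(pools)) {
    pool <- pools[[pname]]
    npool <- length(pool$values)
    pgrid <- grid[grid <= npool]
    if (length(pgrid) == 0L) {
      warning(sprintf("skipping '%s': %d values < grid minimum %d",
                      pname, npool, grid[1]))
      skipped <- c(skipped, pname)
      next
    }
    # one index draw per (pool, k), shared across transforms
    idx <- lapply(pgrid, function(k)
      matrix(sample.int(npool, k * replicates, replace = TRUE), nrow = k))
    names(idx) <- as.character(pgrid)
    for (tr in transforms) {
      tpool <- if (tr == "raw") pool else transform_pool(pool, tr)
      cv_true <- tpool$cv_true
      if (cv_true == 0) stop(sprintf("PB undefined: cv_true = 0 for '%s' (%s)",
                                     pname, tr), call. = FALSE)
      rows <- lapply(pgrid, function(k) {
        m <- matrix(tpool$values[idx[[as.character(k)]]], nrow = k)
        rs <- summarise_cv_matrix(cv_matrix(m), replicates)
        rs <- rs[rs$estimator %in% est_names, ]
        data.frame(pool = pname, transform = tr, estimator = rs$estimator,
                   k = k, mean_cv = rs$mean_cv, se = rs$se,
                   stringsAsFactors = FALSE)
      })
      b <- do.call(rbind, rows)
      b$bias <- b$mean_cv - cv_true
      b$pb <- b$bias / cv_true
      bias_rows[[paste(pname, tr)]] <- b
      tpb_rows[[paste(pname, tr)]] <- data.frame(
        pool = pname, transform = tr, estimator = est_names,
        tpb = vapply(split(abs(b$pb), b$estimator), sum, 0)[est_names],
        tab = vapply(split(abs(b$bias), b$estimator), sum, 0)[est_names],
        cv_true = cv_true, stringsAsFactors = FALSE)
      km <- lapply(split(b, b$estimator), function(d) {
        d <- d[order(d$k), ]
        ok <- abs(d$pb) <= accuracy
        hit <- if (rule == "sustained") rev(cumprod(rev(ok))) == 1 else ok
        if (any(hit)) d$k[which(hit)[1]] else NA_real_
      })
      kmin_rows[[paste(pname, tr)]] <- data.frame(
        pool = pname, transform = tr, estimator = est_names,
        accuracy = accuracy,
        k_min = unlist(km)[est_names],
        reached = !is.na(unlist(km)[est_names]),
        stringsAsFactors = FALSE)
    }
  }
  flatten <- function(l) {
    if (length(l) == 0L) return(data.frame())
    out <- do.call(rbind, l); rownames(out) <- NULL; out
  }
  list(bias = flatten(bias_rows), tpb = flatten(tpb_rows),
       kmin = flatten(kmin_rows), skipped = skipped)
}

# Coerce evaluate_matrix() input to a named list of trait pools.
as_pool_list <- function(pools) {
  if (inherits(pools, "trait_pool")) pools <- list(pools)
  if (is.data.frame(pools)) {
    tab <- validate_trait_table(pools)
    groups <- split(tab$value, interaction(tab$species, tab$trait,
                                           drop = TRUE, sep = ":"))
    pools <- lapply(names(groups), function(g)
      empirical_pool(groups[[g]], label = g))
    names(pools) <- names(groups)
    return(pools)
  }
  if (!is.list(pools) || !all(vapply(pools, inherits, TRUE, "trait_pool")))
    stop("pools must be trait_pool objects or a species/trait/value table",
         call. = FALSE)
  if (is.null(names(pools)) || any(names(pools) == ""))
    names(pools) <- sprintf("pool%03d", seq_along(pools))
  pools
}
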