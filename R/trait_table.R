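#' Read a long-format trait table
#'
#' Expects a CSV or TSV file with header columns `species`, `trait`,
#' `value` (any order, case-insensitive; extra columns are kept).  The
#' separator is taken from the file extension (`.tsv`/`.tab` = tab,
#' otherwise comma) unless given.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) infers from the extension.
#' @return A data.frame of class `"trait_table"` with lower-cased
#'   `species`, `trait`, `value` columns; attribute `group_sizes` holds
#'   the per species x trait counts.
#' @export
read_trait_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  for (col in c("species", "trait", "value"))
    if (!col %in% names(raw)) stop("missing column: ", col, call. = FALSE)
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(val) | !is.finite(val))
  if (length(bad) > 0L)
    stop("non-numeric or non-finite value(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE) # +1 for header
  raw$value <- val
  validate_trait_table(raw)
}

validate_trait_table <- function(tab) {
  names(tab) <- tolower(names(tab))
  for (col in c("species", "trait", "value"))
    if (!col %in% names(tab)) stop("missing column: ", col, call. = FALSE)
  if (nrow(tab) == 0L) stop("empty trait table", call. = FALSE)
  if (!is.numeric(tab$value) || anyNA(tab$value) || any(!is.finite(tab$value)))
    stop("trait values must be finite numerics", call. = FALSE)
  sizes <- table(interaction(tab$species, tab$trait, drop = TRUE, sep = ":"))
  attr(tab, "group_sizes") <- sizes
  class(tab) <- unique(c("trait_table", class(tab)))
  tab
}

#' Per-group CV estimates for a trait table
#'
#' Applies the requested estimators to every species x trait group under
#' every requested normalization.  Groups with fewer than 4 values (the
#' kurtosis minimum) are skipped with a warning.  Non-positive values in a
#' group are flagged before a log transform is attempted.
#'
#' @param tab a [read_trait_table()] result or any data.frame with
#'   species, trait, value columns.
#' @param estimators integers 1:8 or names `"cv1"`...`"cv8"`.
#' @param transforms character vector of normalization kinds
#'   (see [fit_transform()]).
#' @return data.frame with one row per (species, trait, transform,
#'   estimator): estimate, n, and the group moments on the transformed
#'   scale (mean, sd, skewness, kurtosis).
#' @export
estimate_traits <- function(tab, estimators = 1:8, transforms = "raw") {
  tab <- validate_trait_table(tab)
  est_names <- normalize_estimators(estimators)
  transforms <- vapply(transforms, function(tr)
    match.arg(tr, transform_kinds()), "")
  key <- interaction(tab$species, tab$trait, drop = TRUE, sep = ":")
  rows <- list()
  for (g in levels(key)) {
    d <- tab[key == g, ]
    if (nrow(d) < 4L) {
      warning(sprintf("skipping '%s': n = %d < 4", g, nrow(d)))
      next
    }
    for (tr in transforms) {
      if (tr == "log" && any(d$value <= 0))
        warning(sprintf("'%s' has non-positive values; log uses the +1 shift",
                        g))
      y <- trait_transform(d$value, tr)
      es <- estimate_cv(as.numeric(y))
      keep <- es$estimates[est_names]
      rows[[paste(g, tr)]] <- data.frame(
        species = d$species[1], trait = d$trait[1], transform = tr,
        estimator = est_names, estimate = unname(keep), n = es$n,
        mean = es$moments$mean, sd = es$moments$sd,
        skewness = es$moments$skewness, kurtosis = es$moments$kurtosis,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no group had enough values to estimate",
                               call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write evaluation reports to disk
#'
#' Writes the long-format outputs of [evaluate_matrix()] (or compatible
#' data.frames) as CSV files with stable column order and full double
#' precision, plus a JSON summary, a YAML echo of the run configuration,
#' and a plain-text log.  Missing parent directories are created.
#'
#' @param results list with any of `bias`, `tpb`, `kmin` data.frames (and
#'   optionally `skipped`), or a single data.frame written as
#'   `<prefix>estimates.csv`.
#' @param out_prefix path prefix, e.g. `"out/run1_"`.
#' @param config optional list echoed to `<prefix>config.yaml`.
#' @param log_lines optional character vector appended to the log.
#' @return (invisibly) character vector of the files written.
#' @export
write_reports <- function(results, out_prefix, config = NULL,
                          log_lines = character(0)) {
  dir <- dirname(paste0(out_prefix, "x"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    f <- paste0(out_prefix, name, ".csv")
    write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  if (is.data.frame(results)) {
    emit(results, "estimates")
    results <- list()
  } else {
    stopifnot(is.list(results))
    for (name in intersect(c("bias", "tpb", "kmin", "estimates"),
                           names(results)))
      if (is.data.frame(results[[name]]) && nrow(results[[name]]) > 0)
        emit(results[[name]], name)
  }
  summary <- list(
    files = basename(written),
    n_rows = lapply(setNames(written, basename(written)),
                    function(f) nrow(read.csv(f, nrows = 1))),
    skipped = if (!is.null(results$skipped)) results$skipped else character(0))
  jf <- paste0(out_prefix, "summary.json")
  jsonlite::write_json(summary, jf, auto_unbox = TRUE, digits = NA)
  written <- c(written, jf)
  if (!is.null(config)) {
    cf <- paste0(out_prefix, "config.yaml")
    yaml::write_yaml(config, cf)
    written <- c(written, cf)
  }
  lf <- paste0(out_prefix, "run.log")
  writeLines(c(sprintf("itvcv run: %d file(s) written", length(written)),
               if (length(summary$skipped))
                 paste("skipped:", summary$skipped),
               log_lines), lf)
  written <- c(written, lf)
  invisible(written)
}
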