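#' Configuration for a simulated trait pool
#'
#' A trait pool emulates the population of trait values of one species:
#' a strictly positive, right-skewed bulk (gamma distributed) plus a small
#' fraction of extreme large values, as seen in large empirical trait
#' datasets (about 4.8% of values beyond mean + 3 sd).
#'
#' Defaults are the stated simulation world: 9,520 gamma draws with shape
#' `beta1 ~ U(1, 10)` and scale `beta2 ~ U(5, 30)` (trait units), plus 480
#' extremes whose excess over the threshold mean + 3 sd is exponential
#' with rate `lambda = 1` per trait unit, giving a 4.8% contamination
#' fraction in a pool of 10,000.  `lambda` is interpreted on the raw trait
#' scale (mean excess of 1 trait unit) and does not scale with `beta2`.
#'
#' @param shape gamma shape parameter beta1 (dimensionless).
#' @param scale gamma scale parameter beta2 (trait units).
#' @param n_base number of gamma draws (>= 2).
#' @param n_extreme number of extreme large values (>= 0).
#' @param lambda rate of the exponential excess of extremes over the
#'   threshold (1 / trait units).
#' @return An object of class `"pool_config"`.
#' @seealso [draw_pool_config()], [simulate_pool()]
#' @export
pool_config <- function(shape, scale, n_base = 9520L, n_extreme = 480L,
                        lambda = 1) {
  stopifnot(is.numeric(shape), length(shape) == 1L, shape > 0,
            is.numeric(scale), length(scale) == 1L, scale > 0,
            is.numeric(lambda), length(lambda) == 1L, lambda > 0)
  n_base <- as.integer(n_base)
  n_extreme <- as.integer(n_extreme)
  if (n_base < 2L) stop("n_base must be >= 2", call. = FALSE)
  if (n_extreme < 0L) stop("n_extreme must be >= 0", call. = FALSE)
  structure(list(shape = shape, scale = scale, n_base = n_base,
                 n_extreme = n_extreme, lambda = lambda),
            class = "pool_config")
}

#' Draw a random pool configuration
#'
#' Shape ~ U(1, 10), scale ~ U(5, 30); counts and lambda at their
#' defaults.  Uses the current RNG state, so seed with [set.seed()] for
#' reproducibility.
#'
#' @inheritParams pool_config
#' @return A `"pool_config"`.
#' @export
draw_pool_config <- function(n_base = 9520L, n_extreme = 480L, lambda = 1) {
  pool_config(shape = runif(1, 1, 10), scale = runif(1, 5, 30),
              n_base = n_base, n_extreme = n_extreme, lambda = lambda)
}

#' @export
print.pool_config <- function(x, ...) {
  cat(sprintf(
    "pool_config: gamma(shape %.4g, scale %.4g), %d base + %d extremes, lambda %.4g\n",
    x$shape, x$scale, x$n_base, x$n_extreme, x$lambda))
  invisible(x)
}

#' Generate the gamma bulk of a trait pool
#'
#' @param config a [pool_config()].
#' @return numeric vector of `config$n_base` positive gamma draws.
#' @export
generate_base_pool <- function(config) {
  stopifnot(inherits(config, "pool_config"))
  rgamma(config$n_base, shape = config$shape, scale = config$scale)
}

#' Contaminate a base pool with extreme large values
#'
#' Appends `config$n_extreme` values of `t + Exp(rate = lambda)` where
#' `t = mean(base) + 3 * sd(base)` is the extreme-value threshold, then
#' shuffles the pool so positional sampling cannot bias draws, and
#' recomputes the pool's reference CV on the full contaminated pool.
#'
#' By default the threshold uses the moments of the base (pre-contamination)
#' values - the extremes do not exist yet when the threshold is formed.
#' `threshold_on = "pool"` instead iterates the threshold on the
#' contaminated pool's own moments (a post-hoc reading): the threshold is
#' recomputed from base + extremes and the extremes redrawn until the
#' threshold stabilises.
#'
#' @param base numeric vector of base trait values (non-degenerate when
#'   `n_extreme > 0`).
#' @param config a [pool_config()].
#' @param threshold_on `"base"` (default) or `"pool"`.
#' @return A `"trait_pool"`: list with `values`, `cv_true`, `config`,
#'   `transform` (an identity [fit_transform()] spec) and `threshold`.
#' @export
add_extremes <- function(base, config, threshold_on = c("base", "pool")) {
  stopifnot(inherits(config, "pool_config"))
  threshold_on <- match.arg(threshold_on)
  base <- check_trait_sample(base, min_n = 2L, what = "pool")
  if (config$n_extreme > 0L && sd(base) <= 0)
    stop("cannot place extremes on a degenerate base pool", call. = FALSE)
  thr <- mean(base) + 3 * sd(base)
  if (config$n_extreme > 0L) {
    ext <- thr + rexp(config$n_extreme, rate = config$lambda)
    if (threshold_on == "pool") {
      # fixed-point iteration on the contaminated pool's own moments
      for (i in 1:20) {
        pool <- c(base, ext)
        thr2 <- mean(pool) + 3 * sd(pool)
        if (abs(thr2 - thr) < 1e-8 * max(1, thr)) break
        thr <- thr2
        ext <- thr + rexp(config$n_extreme, rate = config$lambda)
      }
    }
    values <- sample(c(base, ext))
  } else {
    values <- sample(base)
  }
  new_trait_pool(values, config = config, threshold = thr)
}

new_trait_pool <- function(values, config, threshold = NA_real_,
                           transform = fit_transform(values, "raw")) {
  pool <- structure(
    list(values = values, cv_true = NA_real_, config = config,
         transform = transform, threshold = threshold),
    class = "trait_pool")
  pool$cv_true <- pool_true_cv(pool)
  pool
}

#' Simulate one contaminated trait pool
#'
#' Convenience wrapper: [generate_base_pool()] then [add_extremes()].
#'
#' @inheritParams add_extremes
#' @param config a [pool_config()]; drawn via [draw_pool_config()] when
#'   missing.
#' @return A `"trait_pool"`.
#' @examples
#' set.seed(1)
#' pool <- simulate_pool()
#' length(pool$values)  # 10000
#' pool$cv_true
#' @export
simulate_pool <- function(config = draw_pool_config(),
                          threshold_on = c("base", "pool")) {
  add_extremes(generate_base_pool(config), config,
               threshold_on = match.arg(threshold_on))
}

#' Simulate an ensemble of trait pools
#'
#' Each pool gets its own configuration drawn by [draw_pool_config()].
#'
#' @param n_pools number of pools (the stated evaluation world uses 200).
#' @inheritParams pool_config
#' @return list of `"trait_pool"` objects.
#' @export
simulate_pools <- function(n_pools = 200L, n_base = 9520L, n_extreme = 480L,
                           lambda = 1) {
  lapply(seq_len(n_pools), function(i)
    simulate_pool(draw_pool_config(n_base = n_base, n_extreme = n_extreme,
                                   lambda = lambda)))
}

#' Reference (population) CV of a pool
#'
#' The pool's reference CV is the plug-in CV over all pool values, on the
#' pool's current transform scale.  For simulated pools this is computed
#' empirically from the full contaminated pool (not the analytic gamma
#' CV), because contamination changes the population CV; for empirical
#' pools it is the plug-in CV over all measured individuals.
#'
#' @param pool a `"trait_pool"` (or plain numeric vector).
#' @return dimensionless reference CV.
#' @export
pool_true_cv <- function(pool) {
  x <- if (inherits(pool, "trait_pool")) pool$values else pool
  cv1(x)
}

#' Build a trait pool from observed values
#'
#' Tags the pool as empirical; its reference CV is the plug-in CV over all
#' supplied individuals.
#'
#' @param values numeric vector of all measured trait values.
#' @param label identifier (e.g. "species x trait").
#' @return A `"trait_pool"` whose `config` is the tag `"empirical"`.
#' @export
empirical_pool <- function(values, label = "empirical") {
  values <- check_trait_sample(values, min_n = 2L, what = "pool")
  pool <- structure(
    list(values = values, cv_true = NA_real_,
         config = structure(list(label = label), class = "empirical_tag"),
         transform = fit_transform(values, "raw"), threshold = NA_real_),
    class = "trait_pool")
  pool$cv_true <- pool_true_cv(pool)
  pool
}

#' Apply a normalization to a whole pool
#'
#' Fits the transform on the entire pool, transforms every value, and
#' recomputes the reference CV on the transformed scale.  Downstream
#' resampling then draws from the transformed pool, so estimates and
#' reference live on the same scale.
#'
#' @param pool a `"trait_pool"`.
#' @param kind see [fit_transform()].
#' @return A new `"trait_pool"` on the transformed scale.
#' @export
transform_pool <- function(pool, kind = c("raw", "log", "cuberoot", "minmax")) {
  stopifnot(inherits(pool, "trait_pool"))
  kind <- match.arg(kind)
  spec <- fit_transform(pool$values, kind)
  out <- pool
  out$values <- apply_transform(spec, pool$values)
  out$transform <- spec
  out$cv_true <- pool_true_cv(out)
  out
}

#' @export
print.trait_pool <- function(x, ...) {
  src <- if (inherits(x$config, "empirical_tag"))
    paste0("empirical (", x$config$label, ")")
  else sprintf("simulated gamma(%.3g, %.3g) + %d extremes",
               x$config$shape, x$config$scale, x$config$n_extreme)
  cat(sprintf("trait_pool: %d values, %s, transform %s, cv_true %.4f\n",
              length(x$values), src, x$transform$kind, x$cv_true))
  invisible(x)
}
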