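#' Sample moments of a trait sample
#'
#' Computes the mean, standard deviation, skewness and excess kurtosis of a
#' vector of trait measurements.  These are the ingredients of the
#' bias-corrected CV estimators ([cv3()], [cv4()]).
#'
#' Conventions (they matter for the estimators downstream):
#' \itemize{
#'   \item `sd` uses the n-1 (sample) denominator.  The small-sample bias
#'     corrections implemented here are derived for the sample sd.
#'   \item `skewness` and `kurtosis` are the plug-in moment coefficients
#'     g1 = m3 / m2^(3/2) and g2 = m4 / m2^2 - 3, with central moments
#'     mk = sum((x - mean(x))^k) / n.  Kurtosis is reported in the excess
#'     convention: a normal sample has kurtosis near 0.
#' }
#'
#' A degenerate sample (sd = 0) gets skewness and kurtosis 0 and
#' `degenerate = TRUE` instead of an error, so batch pipelines do not abort
#' on constant traits.
#'
#' @param x numeric vector of trait measurements; at least 2 finite values.
#' @return An object of class `"moment_set"`: a list with elements `mean`,
#'   `sd`, `skewness`, `kurtosis` (excess), `n`, and `degenerate`.
#' @examples
#' trait_moments(c(2, 4, 4, 4, 5, 5, 7, 9))
#' @export
trait_moments <- function(x) {
  x <- check_trait_sample(x, min_n = 2L)
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  m2 <- mean(xc^2)
  sdv <- sqrt(m2 * n / (n - 1))
  degenerate <- m2 <= 0
  if (degenerate) {
    g1 <- 0
    g2 <- 0
  } else {
    g1 <- mean(xc^3) / m2^1.5
    g2 <- mean(xc^4) / m2^2 - 3
  }
  structure(
    list(mean = mu, sd = sdv, skewness = g1, kurtosis = g2, n = n,
         degenerate = degenerate),
    class = "moment_set"
  )
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf(
    "moments (n = %d%s): mean %.6g, sd %.6g, skewness %.4g, excess kurtosis %.4g\n",
    x$n, if (x$degenerate) ", degenerate" else "", x$mean, x$sd,
    x$skewness, x$kurtosis))
  invisible(x)
}

# Validate a trait sample vector; returns it stripped of attributes.
check_trait_sample <- function(x, min_n = 2L, what = "sample") {
  if (!is.numeric(x)) stop("trait ", what, " must be numeric", call. = FALSE)
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("trait ", what, " contains non-finite values", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("insufficient sample: n = %d < %d", length(x), min_n),
         call. = FALSE)
  x
}
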