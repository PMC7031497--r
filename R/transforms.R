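#' Data normalizations for trait vectors
#'
#' Fits one of the three normalizations used in ITV studies (or the
#' identity) on a trait vector and applies it.  A fitted
#' `"transform_spec"` freezes the data-dependent parameters (the log shift
#' decision, the min-max reference minimum/maximum) so that the same
#' mapping can be re-applied to subsamples without re-deriving them; in
#' pool-based evaluation the transform is fitted on, and applied to, the
#' entire pool before any resampling, so the reference CV and the
#' resampled estimates live on the same scale.
#'
#' Kinds:
#' \describe{
#'   \item{`raw`}{identity.}
#'   \item{`log`}{natural logarithm; if any value of the vector is below
#'     1, 1 is first added to \emph{all} values of that vector
#'     (`shift_applied` records this).  Values must be positive (or above
#'     -1 when the shift triggers).}
#'   \item{`cuberoot`}{elementwise x^(1/3); values must be >= 0.}
#'   \item{`minmax`}{(x - x_min) / x_max, with x_min and x_max frozen from
#'     the fitted vector.  Note the denominator is x_max, not the range
#'     x_max - x_min; set `minmax_range = TRUE` for the conventional
#'     range denominator.}
#' }
#'
#' All transforms are monotone non-decreasing, so ranks are preserved.
#'
#' @param x numeric trait vector to fit on (and, for [trait_transform()],
#'   to transform).
#' @param kind one of `"raw"`, `"log"`, `"cuberoot"`, `"minmax"`.
#' @param minmax_range logical; use the conventional
#'   (x - x_min)/(x_max - x_min) instead of the default x_max denominator.
#' @return `fit_transform()` returns a `"transform_spec"`;
#'   `apply_transform()` returns the transformed numeric vector;
#'   `trait_transform()` returns the transformed vector with the fitted
#'   spec attached as attribute `"spec"`.
#' @examples
#' trait_transform(c(0.5, 2), "log")      # shift rule triggers
#' trait_transform(c(2, 4, 10), "minmax") # 0, 0.2, 0.8
#' @export
fit_transform <- function(x, kind = c("raw", "log", "cuberoot", "minmax"),
                          minmax_range = FALSE) {
  kind <- match.arg(kind)
  x <- check_trait_sample(x, min_n = 1L, what = "vector")
  spec <- list(kind = kind, shift_applied = FALSE,
               reference_min = NA_real_, reference_max = NA_real_,
               range_denominator = isTRUE(minmax_range))
  if (kind == "log") {
    spec$shift_applied <- min(x) < 1
    lo <- if (spec$shift_applied) min(x) + 1 else min(x)
    if (lo <= 0)
      stop("log domain: values must be positive (or > -1 with the shift rule)",
           call. = FALSE)
  } else if (kind == "cuberoot") {
    if (min(x) < 0)
      stop("cube root requires non-negative trait values", call. = FALSE)
  } else if (kind == "minmax") {
    spec$reference_min <- min(x)
    spec$reference_max <- max(x)
    denom <- if (spec$range_denominator)
      spec$reference_max - spec$reference_min else spec$reference_max
    if (denom <= 0) stop("min-max undefined: denominator <= 0", call. = FALSE)
  }
  class(spec) <- "transform_spec"
  spec
}

#' @rdname fit_transform
#' @param spec a fitted `"transform_spec"`.
#' @export
apply_transform <- function(spec, x) {
  stopifnot(inherits(spec, "transform_spec"))
  x <- check_trait_sample(x, min_n = 1L, what = "vector")
  switch(spec$kind,
    raw = x,
    log = {
      y <- if (spec$shift_applied) x + 1 else x
      if (min(y) <= 0)
        stop("log domain: non-positive value under the fitted shift",
             call. = FALSE)
      log(y)
    },
    cuberoot = {
      if (min(x) < 0)
        stop("cube root requires non-negative trait values", call. = FALSE)
      x^(1 / 3)
    },
    minmax = {
      denom <- if (spec$range_denominator)
        spec$reference_max - spec$reference_min else spec$reference_max
      (x - spec$reference_min) / denom
    }
  )
}

#' @rdname fit_transform
#' @export
trait_transform <- function(x, kind = c("raw", "log", "cuberoot", "minmax"),
                            minmax_range = FALSE) {
  spec <- fit_transform(x, kind, minmax_range = minmax_range)
  out <- apply_transform(spec, x)
  attr(out, "spec") <- spec
  out
}

#' @export
print.transform_spec <- function(x, ...) {
  extra <- switch(x$kind,
    log = sprintf(" (shift_applied = %s)", x$shift_applied),
    minmax = sprintf(" (min = %.6g, max = %.6g, denominator = %s)",
                     x$reference_min, x$reference_max,
                     if (x$range_denominator) "range" else "max"),
    "")
  cat(sprintf("transform_spec: %s%s\n", x$kind, extra))
  invisible(x)
}

#' @rdname fit_transform
#' @export
transform_kinds <- function() c("raw", "log", "cuberoot", "minmax")
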