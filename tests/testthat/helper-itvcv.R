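# Independent oracles and small fixtures, built in code.

# Direct-summation moments, written deliberately unlike the package path
# (explicit loops over sums, no shared helpers).
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  ss2 <- ss3 <- ss4 <- 0
  for (v in x) {
    d <- v - mu
    ss2 <- ss2 + d^2; ss3 <- ss3 + d^3; ss4 <- ss4 + d^4
  }
  m2 <- ss2 / n
  list(mean = mu,
       sd = sqrt(ss2 / (n - 1)),
       skewness = if (m2 > 0) (ss3 / n) / m2^1.5 else 0,
       kurtosis = if (m2 > 0) (ss4 / n) / m2^2 - 3 else 0)
}

# Estimator formulas recomputed from oracle moments (direct substitution).
oracle_cv <- function(x) {
  n <- length(x)
  m <- oracle_moments(x)
  v1 <- m$sd / m$mean
  v2 <- v1 + v1 / (4 * n)
  v3 <- v1 / (1 - (v1 / n) * (3 * v1 - 2 * m$skewness))
  v4 <- v1 - v1^3 / n + v1 / (4 * n) + v1^2 * m$skewness / (2 * n) +
    v1 * m$kurtosis / (8 * n)
  c(cv1 = v1, cv2 = v2, cv3 = v3, cv4 = max(v4, 0),
    cv5 = (v3 + max(v4, 0)) / 2, cv6 = (v2 + max(v4, 0)) / 2,
    cv7 = sqrt(v3 * max(v4, 0)), cv8 = sqrt(v2 * max(v4, 0)))
}

# A small simulated pool for fast evaluation tests.
small_pool <- function(shape = 4, scale = 10, n_base = 2000, n_extreme = 100) {
  simulate_pool(pool_config(shape, scale, n_base = n_base,
                            n_extreme = n_extreme))
}

# Hand-built bias_profile for rule tests (bypasses resampling).
fake_profile <- function(k, pb, estimator = "cv1", transform = "raw") {
  df <- data.frame(estimator = estimator, k = k,
                   mean_cv = NA_real_, se = NA_real_,
                   bias = NA_real_, pb = pb, stringsAsFactors = FALSE)
  attr(df, "cv_true") <- 1
  attr(df, "transform") <- transform
  class(df) <- c("bias_profile", "data.frame")
  df
}

# Tiny well-formed trait table.
demo_table <- function() {
  data.frame(
    species = rep(c("quercus", "fagus"), each = 6),
    trait = "sla",
    value = c(12.1, 9.8, 14.2, 11.0, 10.5, 13.3,
              22.5, 19.1, 25.2, 21.0, 20.4, 23.9))
}
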