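test_that("resampling handles degenerate and exhaustive edge cases", {
  const <- empirical_pool(rep(5, 40))
  rs <- resample_cv(const, k = 10, replicates = 50)
  expect_equal(rs$mean_cv[rs$estimator == "cv1"], 0)
  expect_equal(rs$se[rs$estimator == "cv1"], 0)
  expect_equal(attr(rs, "n_degenerate"), 50)

  set.seed(8)
  pool <- empirical_pool(rgamma(60, 4, scale = 10))
  # k = pool size without replacement: every draw is the whole pool
  rs2 <- resample_cv(pool, k = 60, replicates = 20, replace = FALSE)
  expect_equal(rs2$mean_cv[rs2$estimator == "cv1"], pool$cv_true)
  expect_equal(rs2$se[rs2$estimator == "cv1"], 0)

  set.seed(15); a <- resample_cv(pool, 10, 200)
  set.seed(15); b <- resample_cv(pool, 10, 200)
  expect_identical(a, b)

  expect_error(resample_cv(pool, k = 100, replicates = 10, replace = FALSE),
               "exceeds pool size")
  expect_error(resample_cv(pool, k = 10, replicates = 1), "replicates")
})

test_that("expected cv1 at k = 2 matches exhaustive pair enumeration", {
  pool_vals <- c(3.1, 4.7, 5.0, 6.2, 7.9, 8.4, 10.3, 12.5)
  pairs <- utils::combn(pool_vals, 2)
  exact <- mean(apply(pairs, 2, function(p) sd(p) / mean(p)))
  set.seed(201)
  rs <- resample_cv(pool_vals, k = 2, replicates = 1e5, replace = FALSE)
  row <- rs[rs$estimator == "cv1", ]
  expect_lt(abs(row$mean_cv - exact), 3 * row$se)
})

test_that("bias profile fields satisfy their defining identities", {
  set.seed(9)
  pool <- small_pool()
  bp <- bias_profile(pool, grid = c(10, 20, 40), replicates = 499,
                     estimators = c(1, 2, 4))
  expect_s3_class(bp, "bias_profile")
  expect_equal(nrow(bp), 9)
  expect_equal(bp$bias, bp$mean_cv - attr(bp, "cv_true"))
  expect_equal(bp$pb, bp$bias / attr(bp, "cv_true"))
  expect_true(all(bp$se > 0))
  tpb <- attr(bp, "tpb")
  expect_equal(unname(tpb["cv1"]),
               sum(abs(bp$pb[bp$estimator == "cv1"])))
  expect_gte(min(tpb), 0)
  # transform is fitted pool-wide before resampling
  bpl <- bias_profile(pool, grid = c(10, 20), replicates = 199,
                      transform = "log", estimators = 4)
  lp <- transform_pool(pool, "log")
  expect_equal(attr(bpl, "cv_true"), lp$cv_true)
})

test_that("min_sample_size applies the sustained and first-crossing rules", {
  prof <- fake_profile(k = c(10, 15, 20, 25, 30, 35),
                       pb = c(0.08, 0.04, 0.06, 0.03, 0.02, 0.01))
  expect_equal(min_sample_size(prof)$k_min, 25)  # sustained
  expect_equal(min_sample_size(prof, rule = "first")$k_min, 15)
  # widening the band never increases k_min
  expect_lte(min_sample_size(prof, accuracy = 0.10)$k_min,
             min_sample_size(prof, accuracy = 0.05)$k_min)
  # never attained -> NA + flag
  never <- fake_profile(k = c(10, 20), pb = c(0.5, 0.4))
  expect_true(is.na(min_sample_size(never)$k_min))
  expect_false(min_sample_size(never)$reached)
  # a perfect estimator reaches the band at the grid minimum
  perfect <- fake_profile(k = c(10, 20, 30), pb = c(0, 0, 0))
  expect_equal(min_sample_size(perfect)$k_min, 10)
})

test_that("evaluate_matrix sweeps the full factorial with stable cardinality", {
  set.seed(12)
  pools <- list(small_pool(3, 8, 600, 30), small_pool(6, 20, 600, 30))
  res <- evaluate_matrix(pools, estimators = c(1, 4),
                         transforms = c("raw", "log"),
                         grid = seq(10, 50, 10), replicates = 99)
  expect_equal(nrow(res$bias), 2 * 2 * 2 * 5)
  expect_equal(nrow(res$tpb), 2 * 2 * 2)
  expect_equal(nrow(res$kmin), 2 * 2 * 2)
  expect_named(res$tpb, c("pool", "transform", "estimator", "tpb", "tab",
                          "cv_true"))
  # small groups are skipped with a warning, not dropped silently
  tab <- demo_table()
  tab <- rbind(tab, data.frame(species = "tiny", trait = "sla",
                               value = c(1, 2, 3)))
  expect_warning(
    res2 <- evaluate_matrix(tab, estimators = 1, grid = c(4, 6),
                            replicates = 49),
    "skipping")
  expect_equal(res2$skipped, "tiny:sla")
  expect_setequal(unique(res2$bias$pool), c("quercus:sla", "fagus:sla"))
})

test_that("cv1 underestimates at small k and its bias shrinks with k", {
  set.seed(14)
  pools <- replicate(3, small_pool(), simplify = FALSE)
  for (pool in pools) {
    bp <- bias_profile(pool, grid = c(10, 20, 50, 100, 200), replicates = 999,
                       estimators = 1)
    pb <- bp$pb[order(bp$k)]
    expect_true(all(pb[1:3] < 0))          # k <= 50: underestimation
    expect_lt(abs(pb[5]), abs(pb[1]))      # |PB| decreases with k
  }
})

test_that("k_min of cv4 never exceeds k_min of cv1 on simulated pools", {
  set.seed(16)
  for (i in 1:3) {
    pool <- simulate_pool()
    bp <- bias_profile(pool, grid = seq(10, 100, 10), replicates = 999,
                       estimators = c(1, 4))
    km <- min_sample_size(bp)
    k1 <- km$k_min[km$estimator == "cv1"]
    k4 <- km$k_min[km$estimator == "cv4"]
    if (is.na(k1)) k1 <- Inf
    if (is.na(k4)) k4 <- Inf
    expect_lte(k4, k1)
  }
})
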