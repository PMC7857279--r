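test_that("degenerate components have zero variance and covariance", {
  rel <- data.frame(F = rgamma(30, 4), MS = rep(1, 30),
                    STE = rgamma(30, 4), SFE = rgamma(30, 4),
                    mRS = rgamma(30, 4))
  vp <- decompose_variance(rel)
  expect_equal(unname(vp$variances["MS"]), 0)
  expect_equal(unname(vp$covariances["F:MS"]), 0)
  expect_equal(unname(vp$covariances["MS:STE"]), 0)

  rel$SFE[1:29] <- NA
  expect_warning(vp2 <- decompose_variance(rel), "fewer than 2")
  expect_true(is.na(vp2$variances["SFE"]))
})

test_that("sum identity holds for small-CV multiplicative components", {
  # oracle: direct Monte Carlo of the product at n = 1e5; in the small-CV
  # limit Var(product of mean-1 factors) ~ sum of variances + 2 sum of
  # covariances
  set.seed(42)
  n <- 1e5
  rel <- data.frame(F = rnorm(n, 1, 0.05), MS = rnorm(n, 1, 0.04),
                    STE = rnorm(n, 1, 0.05), SFE = rnorm(n, 1, 0.03))
  rel$mRS <- rel$F * rel$MS * rel$STE * rel$SFE
  rel[] <- lapply(rel, relativize)
  vp <- decompose_variance(rel)
  expect_lt(abs(vp$var_mrs - vp$model_total) / vp$var_mrs, 0.05)
})

test_that("binomial error variance: closed form, toy values, Monte-Carlo
           agreement", {
  # all shares at 0 or 1: no binomial noise
  agg <- manual_aggregates(m_t = c(10, 10), m_f = c(10, 10),
                           s_t = c(20, 20), s_f = c(20, 0),
                           o_t = c(12, 12), o_f = c(12, 0))
  expect_equal(as.numeric(binomial_error_variance(agg, "STE")), 0)

  # 4 replicates, s_t = 20, p = 0.5, MS = 1: proportion variance
  # p(1-p)/n = 0.0125, propagated through MS = 1 and relativization by
  # mean 0.5 gives 0.0125 / 0.25 = 0.05
  agg <- manual_aggregates(m_t = rep(10, 4), m_f = rep(10, 4),
                           s_t = rep(20, 4), s_f = rep(10, 4),
                           o_t = rep(12, 4), o_f = rep(6, 4))
  closed <- binomial_error_variance(agg, "STE", method = "closed_form")
  # 0.05 plus the O(1/k) relativization correction 3 M^2 / (k mu^4)
  expect_equal(as.numeric(closed), 0.05 + 3 * 0.0125^2 / (4 * 0.5^4))
  mc <- binomial_error_variance(agg, "STE", method = "monte_carlo",
                                draws = 1e5, seed = 3)
  expect_lt(abs(as.numeric(mc) - as.numeric(closed)),
            3 * attr(mc, "mc_se"))

  expect_error(binomial_error_variance(agg, "F"), "should be one of")
})

test_that("closed-form error variance decreases in the denominators", {
  set.seed(5)
  agg <- manual_aggregates(m_t = rep(20, 12), m_f = rbinom(12, 20, 0.5) + 1,
                           s_t = 20 + rpois(12, 10),
                           s_f = 10, o_t = 10 + rpois(12, 5), o_f = 4)
  e1 <- as.numeric(binomial_error_variance(agg, "STE"))
  agg2 <- agg
  agg2$s_t <- 2L * agg$s_t
  agg2$s_f <- 2L * agg$s_f  # same p-hat, doubled n
  e2 <- as.numeric(binomial_error_variance(agg2, "STE"))
  expect_lte(e2, e1 / 2 + 1e-12)
})

test_that("bootstrap_statistic: degenerate CI, determinism, CLT width", {
  d <- data.frame(replicate_id = 1:50, value = 3)
  b <- bootstrap_statistic(function(df) mean(df$value), d,
                           bootstrap_config(iterations = 50, seed = 1))
  expect_equal(unname(b$ci[1, ]), c(3, 3))

  set.seed(99)
  d2 <- data.frame(replicate_id = 1:150, value = rnorm(150))
  cfg <- bootstrap_config(iterations = 10000, seed = 42)
  b1 <- bootstrap_statistic(function(df) mean(df$value), d2, cfg)
  b2 <- bootstrap_statistic(function(df) mean(df$value), d2, cfg)
  expect_identical(b1$draws, b2$draws)  # same seed, bit-identical
  width <- diff(b1$ci[1, ])
  # oracle: CLT interval width 2 * 1.96 * sd/sqrt(150)
  expected <- 2 * 1.96 * stats::sd(d2$value) / sqrt(150)
  expect_lt(abs(width - expected) / expected, 0.10)
})

test_that("bootstrap resampling unit is the whole replicate", {
  sim <- small_sim(seed = 31, n_focals = 10)
  res <- resample_replicates(sim$data, rep("F001", 3))
  expect_equal(nrow(res$groups), 9L)           # 3 copies x 3 groups
  expect_equal(length(unique(res$groups$replicate_id)), 3L)
  expect_equal(nrow(res$recipients), 36L)
  # each copy carries the full set of its recipients
  expect_true(all(table(res$recipients$replicate_id) == 12L))
})

test_that("signed-difference test: self-comparison gives p = 1", {
  d <- impute_total_sperm(small_sim(seed = 32)$data)
  st <- signed_difference_test(d, "MS", "MS",
                               config = bootstrap_config(iterations = 100,
                                                         seed = 2))
  expect_equal(st$p_value, 1)
  expect_true(all(st$diffs == 0))
})

test_that("signed-difference machinery detects a 4:1 variance ratio and is
           calibrated under the null", {
  # power: var(A) = 4 var(B), independent Gaussians, n = 150 (scaled-down
  # replication count; the underlying power at B = 300 is near 1)
  runs <- 30
  rej <- 0
  set.seed(7)
  for (r in seq_len(runs)) {
    df <- data.frame(replicate_id = 1:150, A = rnorm(150, 0, 2),
                     B = rnorm(150, 0, 1))
    boot <- bootstrap_statistic(
      function(d) c(vA = stats::var(d$A), vB = stats::var(d$B)), df,
      bootstrap_config(iterations = 300, seed = 1000 + r))
    p <- repsel:::signed_p_value(boot$draws[, 1] - boot$draws[, 2], 300)
    rej <- rej + (p < 0.01)
  }
  expect_gte(rej, 0.9 * runs)

  # null calibration: two iid copies, p approximately uniform
  runs <- 60
  ps <- numeric(runs)
  set.seed(8)
  for (r in seq_len(runs)) {
    df <- data.frame(replicate_id = 1:150, A = rnorm(150), B = rnorm(150))
    boot <- bootstrap_statistic(
      function(d) c(vA = stats::var(d$A), vB = stats::var(d$B)), df,
      bootstrap_config(iterations = 200, seed = 2000 + r))
    ps[r] <- repsel:::signed_p_value(boot$draws[, 1] - boot$draws[, 2], 200)
  }
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("full decomposition: percentages sum to 100 and bootstrap is
           seeded", {
  d <- impute_total_sperm(small_sim(seed = 33, n_focals = 60)$data)
  cfg <- bootstrap_config(iterations = 120, seed = 11)
  dec <- decompose_dataset(d, cfg)
  expect_equal(sum(dec$terms$pct), 100, tolerance = 1e-9)
  expect_equal(nrow(dec$terms), 4 + 2 + 6)
  dec2 <- decompose_dataset(d, cfg)
  expect_identical(dec$terms, dec2$terms)
  # CIs ordered
  expect_true(all(dec$terms$pct_lo <= dec$terms$pct_hi))
  expect_true(all(dec$terms$pct_lo - 1e-9 <= dec$terms$pct))
})
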