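# Helper: long table with a given among/within variance split.
make_icc_table <- function(n_focals, n_groups, va, ve, seed = 1,
                           mu = 10) {
  set.seed(seed)
  id <- rep(sprintf("f%04d", seq_len(n_focals)), each = n_groups)
  a <- rep(rnorm(n_focals, 0, sqrt(va)), each = n_groups)
  data.frame(replicate_id = id,
             batch = rep(rep(1:5, length.out = n_focals), each = n_groups),
             group_label = rep(LETTERS[2:(1 + n_groups)], n_focals),
             component = "MS",
             value = mu + a + rnorm(n_focals * n_groups, 0, sqrt(ve)),
             stringsAsFactors = FALSE)
}

test_that("identical within-focal values give R = 1; zero variance errors", {
  tab <- data.frame(replicate_id = rep(letters[1:6], each = 3),
                    value = rep(c(1, 2, 3, 4, 5, 6), each = 3))
  r <- estimate_repeatability(tab, bootstrap_config(iterations = 50, seed = 1),
                              compute_p = FALSE)
  expect_equal(r$R, 1, tolerance = 1e-6)
  tab$value <- 5
  expect_error(estimate_repeatability(tab), "no variance to partition")
})

test_that("profiled REML matches lme4 on unbalanced data within 1e-6", {
  tab <- make_icc_table(60, 3, va = 0.4, ve = 0.6, seed = 4)
  tab <- tab[-c(3, 7, 12, 50, 51), ]  # unbalance: some focals lose values
  cfg <- bootstrap_config(iterations = 20, seed = 2)
  fast <- estimate_repeatability(tab, cfg, compute_p = FALSE)
  lmm <- estimate_repeatability(tab, cfg, engine = "lmm", compute_p = FALSE)
  expect_equal(fast$R, lmm$R, tolerance = 1e-6)
  expect_equal(fast$var_among, lmm$var_among, tolerance = 1e-6)
  expect_equal(fast$var_resid, lmm$var_resid, tolerance = 1e-6)
})

test_that("balanced-data REML repeatability equals the one-way ANOVA ICC", {
  tab <- make_icc_table(150, 3, va = 0.4, ve = 0.6, seed = 11)
  cfg <- bootstrap_config(iterations = 500, seed = 3)
  r <- estimate_repeatability(tab, cfg, compute_p = FALSE)
  av <- estimate_repeatability(tab, cfg, engine = "anova", compute_p = FALSE)
  expect_equal(r$R, av$R, tolerance = 1e-6)
  # recovers the generative ratio 0.4 within its bootstrap CI
  expect_true(r$ci[1] <= 0.4 && 0.4 <= r$ci[2])
  # CI contained in [0, 1]
  expect_true(all(r$draws >= 0 & r$draws <= 1))
  # significance: strong among-focal variance
  expect_lt(estimate_repeatability(tab, cfg)$p_value, 1e-6)
})

test_that("R is invariant to positive rescaling", {
  tab <- make_icc_table(40, 3, va = 0.3, ve = 0.7, seed = 5)
  cfg <- bootstrap_config(iterations = 10, seed = 1)
  r1 <- estimate_repeatability(tab, cfg, compute_p = FALSE)$R
  tab$value <- tab$value * 37.5
  r2 <- estimate_repeatability(tab, cfg, compute_p = FALSE)$R
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("permuting values across focals destroys repeatability", {
  tab <- make_icc_table(100, 3, va = 0.5, ve = 0.5, seed = 6)
  set.seed(7)
  rs <- replicate(100, {
    perm <- tab
    perm$value <- sample(perm$value)
    st <- repsel:::oneway_stats(perm$value, perm$replicate_id)
    repsel:::icc_from_stats(st$n, st$sum, st$ss, engine = "reml")$R
  })
  expect_lt(mean(rs), 0.05)
})

test_that("boundary-corrected LRT is conservative under the null and
           powerful under the alternative", {
  set.seed(8)
  ps_null <- replicate(60, {
    tab <- make_icc_table(60, 3, va = 0, ve = 1, seed = sample.int(1e6, 1))
    st <- repsel:::oneway_stats(tab$value, tab$replicate_id)
    repsel:::icc_lrt(st$n, st$sum, st$ss)
  })
  expect_lte(mean(ps_null < 0.05), 0.10)  # near-nominal size
  ps_alt <- replicate(20, {
    tab <- make_icc_table(60, 3, va = 0.5, ve = 0.5,
                          seed = sample.int(1e6, 1))
    st <- repsel:::oneway_stats(tab$value, tab$replicate_id)
    repsel:::icc_lrt(st$n, st$sum, st$ss)
  })
  expect_gte(mean(ps_alt < 0.001), 0.95)
})

test_that("trend model is calibrated under the null and detects a batch
           effect", {
  # null: no group or batch structure; p for the group effect ~ uniform
  set.seed(9)
  ps <- replicate(40, {
    tab <- make_icc_table(60, 3, va = 0.3, ve = 0.7,
                          seed = sample.int(1e6, 1))
    fit_trend_model(tab)$terms$p_value[1]
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)

  # additive batch effects with SD = 1 SD of the data
  set.seed(10)
  hits <- replicate(20, {
    tab <- make_icc_table(60, 3, va = 0.3, ve = 0.7,
                          seed = sample.int(1e6, 1))
    shift <- rnorm(5, 0, stats::sd(tab$value))
    tab$value <- tab$value + shift[tab$batch]
    fit_trend_model(tab)$terms$p_value[2] < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("trend model errors on rank-deficient designs", {
  tab <- make_icc_table(30, 3, va = 0.3, ve = 0.7, seed = 12)
  tab$batch <- 1L
  expect_error(fit_trend_model(tab), "at least 2")
  # batch perfectly confounded with group
  tab2 <- make_icc_table(30, 3, va = 0.3, ve = 0.7, seed = 13)
  tab2$batch <- match(tab2$group_label, c("B", "C", "D"))
  expect_error(fit_trend_model(tab2), "aliased|rank-deficient")
})

test_that("estimate_repeatability handles the pipeline's long tables", {
  d <- impute_total_sperm(small_sim(seed = 41, n_focals = 60)$data)
  gc <- compute_components_per_group(d)
  long <- do.call(rbind, lapply(c("F", "MS", "STE", "SFE", "mRS"),
                                function(cl) transform_component(gc, cl)))
  r <- estimate_repeatability(long, bootstrap_config(iterations = 100,
                                                     seed = 3),
                              component = "STE")
  expect_equal(r$component, "STE")
  expect_true(r$R >= 0 && r$R <= 1)
  expect_true(all(r$ci >= 0 & r$ci <= 1))
  expect_equal(r$n_replicates, 60L)
})
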