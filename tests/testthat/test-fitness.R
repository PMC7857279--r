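test_that("imputation fills egg-masked totals with the observed mean", {
  tc <- toy_counts()
  # two observable totals (10, 30); every other recipient is egg-masked
  tc$recipients$focal_sperm <- 2L
  tc$recipients$total_sperm <- c(10L, 30L, rep(NA, 22))
  tc$recipients$egg_in_antrum <- c(FALSE, FALSE, rep(TRUE, 22))
  d <- repsel_data(tc$groups, tc$recipients)
  imp <- impute_total_sperm(d)
  expect_equal(attr(imp, "imputation")$value, 20)
  expect_true(all(imp$recipients$total_sperm[-(1:2)] == 20))
  expect_true(all(imp$recipients$sperm_imputed[-(1:2)]))
  expect_false(any(imp$recipients$sperm_imputed[1:2]))
})

test_that("imputation is a no-op without egg-masked recipients and never
           touches focal sperm", {
  d <- toy_data()
  imp <- impute_total_sperm(d)
  expect_equal(imp$recipients$total_sperm, d$recipients$total_sperm)
  expect_equal(attr(imp, "imputation")$n_imputed, 0L)

  sim <- small_sim(seed = 12)
  imp2 <- impute_total_sperm(sim$data)
  expect_equal(sum(imp2$recipients$focal_sperm),
               sum(sim$data$recipients$focal_sperm))
  expect_false(anyNA(imp2$recipients$total_sperm))
})

test_that("imputed totals are raised to the focal count when needed", {
  tc <- toy_counts()
  tc$recipients$total_sperm <- c(2L, 2L, rep(NA, 22))
  tc$recipients$egg_in_antrum <- c(FALSE, FALSE, rep(TRUE, 22))
  tc$recipients$focal_sperm <- c(1L, 1L, rep(5L, 22))
  d <- repsel_data(tc$groups, tc$recipients)
  imp <- impute_total_sperm(d)  # mean = 2 < focal 5
  expect_true(all(imp$recipients$total_sperm[-(1:2)] == 5L))
  expect_equal(attr(imp, "imputation")$n_raised, 22L)
  expect_error(impute_total_sperm(
    repsel_data(tc$groups,
                transform(tc$recipients,
                          total_sperm = NA_integer_, focal_sperm = 0L,
                          egg_in_antrum = TRUE))),
    "no recipient with observable total sperm")
})

test_that("fitness components follow their ratio definitions", {
  agg <- manual_aggregates(m_t = 10, m_f = 4, s_t = 20, s_f = 8,
                           o_t = 12, o_f = 6)
  comp <- compute_components(agg)
  expect_equal(comp$MS, 0.4)
  expect_equal(comp$STE, 1.0)
  expect_equal(comp$SFE, 1.25)
  expect_equal(comp[["F"]], 12)
  expect_equal(comp$mRS, 6)
  expect_equal(comp[["F"]] * comp$MS * comp$STE * comp$SFE, comp$mRS)

  # monopoly: focal takes everything
  mono <- compute_components(manual_aggregates(20, 20, 30, 30, 15, 15))
  expect_equal(mono$MS, 1); expect_equal(mono$STE, 1)
  expect_equal(mono$SFE, 1); expect_equal(mono$mRS, mono[["F"]])

  # focal never mates: zero MS, derived components undefined
  none <- compute_components(manual_aggregates(10, 0, 20, 0, 12, 0))
  expect_equal(none$MS, 0)
  expect_true(is.na(none$STE) && is.na(none$SFE))
  expect_equal(none$mRS, 0)

  expect_warning(compute_components(manual_aggregates(0, 0, 5, 0, 5, 0)),
                 "no matings")
})

test_that("per-group components guard divisions and match pooled definitions", {
  d <- toy_data()
  gc <- compute_components_per_group(d)
  expect_equal(nrow(gc), 6L)
  w1b <- gc[gc$replicate_id == "W1" & gc$group_label == "B", ]
  expect_equal(w1b$MS, 0.4)            # 4/10
  expect_equal(w1b$STE, (8 / 20) / 0.4)
  # all-zero offspring group: F = 0 and SFE missing
  tc <- toy_counts()
  zero <- tc$recipients$replicate_id == "W1" & tc$recipients$group_label == "B"
  tc$recipients$total_offspring[zero] <- 0L
  tc$recipients$focal_offspring[zero] <- 0L
  gc2 <- compute_components_per_group(repsel_data(tc$groups, tc$recipients))
  row <- gc2[gc2$replicate_id == "W1" & gc2$group_label == "B", ]
  expect_equal(row[["F"]], 0)
  expect_true(is.na(row$SFE))
})

test_that("multiplicative identity holds on every simulated replicate", {
  for (seed in c(21, 22)) {
    d <- impute_total_sperm(small_sim(seed = seed, n_focals = 60)$data)
    comp <- compute_components(aggregate_replicates(d))
    ok <- stats::complete.cases(comp[c("F", "MS", "STE", "SFE")])
    prod <- comp[["F"]][ok] * comp$MS[ok] * comp$STE[ok] * comp$SFE[ok]
    expect_true(all(abs(prod - comp$mRS[ok]) <=
                      1e-12 * pmax(comp$mRS[ok], 1)))
  }
})

test_that("relativize rescales to mean one and preserves structure", {
  expect_equal(relativize(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(relativize(c(7, 7, 7)), c(1, 1, 1))
  expect_equal(relativize(c(0, 0, 6)), c(0, 0, 3))
  expect_equal(relativize(c(2, NA, 4)), c(2 / 3, NA, 4 / 3))
  expect_error(relativize(c(NA_real_, NA_real_)), "all-missing")
  expect_error(relativize(c(-1, 1)), "not positive")

  # scale invariance
  x <- rgamma(50, 2)
  expect_equal(relativize(3.7 * x), relativize(x))

  rel <- relativize_components(compute_components(
    aggregate_replicates(impute_total_sperm(small_sim(seed = 23)$data))))
  for (cl in c("F", "MS", "STE", "SFE", "mRS"))
    expect_equal(mean(rel[[cl]], na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("per-group transformations match their closed forms", {
  gc <- data.frame(replicate_id = c("a", "a", "b"), batch = 1L,
                   group_label = c("B", "C", "B"),
                   F = c(0.5, 3.5, 8.5), MS = c(0.2, 0.4, 0.6),
                   STE = c(0, 1, 4), SFE = c(0, 9, 99),
                   mRS = c(0, 4, 16), stringsAsFactors = FALSE)
  expect_equal(transform_component(gc, "SFE")$value, c(0, 1, 2))
  expect_equal(transform_component(gc, "F")$value, c(0.5, 1, 1.5))
  expect_equal(transform_component(gc, "MS")$value, c(0.5, 1, 1.5))
  ste <- transform_component(gc, "STE")
  expect_equal(nrow(ste), 3L)   # STE = 0 kept, not treated as missing
  expect_equal(ste$value[1], 0)
  expect_equal(mean(transform_component(gc, "mRS")$value), 1)
  gc$SFE[2] <- NA
  expect_equal(nrow(transform_component(gc, "SFE")), 2L)
})
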