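# The repeatable opportunity for selection: I_R = R x I.
#
# I is the (uncorrected) variance of a relativized component, expressed as a
# percentage of the model-predicted total variance in relative male
# reproductive success; R is the component's repeatability across mating
# groups. The product is the portion of the opportunity for selection that
# is consistent across independent mating contexts, i.e. attributable to
# deterministic (selectable) differences among focals rather than chance.
# Inside the joint bootstrap the uncorrected variance is used (subtracting
# the binomial sampling error there would bias I_R downward); the displayed
# I column is error-corrected.

#' Joint bootstrap of variance and repeatability: the I_R table
#'
#' In each of B iterations, resamples whole replicates with replacement and
#' recomputes, per component, (i) the uncorrected variance as a percentage
#' of the model total, (ii) the repeatability of the transformed per-group
#' values, and (iii) their product I_R. Reports bootstrap means, plug-in
#' values and percentile CIs, plus pairwise signed-difference p-values for
#' the corrected variances (I) and for I_R, derived from the same draws.
#'
#' @param x a `repsel_data` object (sperm totals imputed on the fly if
#'   needed).
#' @param config a [bootstrap_config()].
#' @param icc_engine `"reml"` (default; profiled REML, identical estimator
#'   to [estimate_repeatability()]) or `"anova"` (fast method of moments,
#'   for very large B).
#' @param error_method method for the sampling-error terms of the displayed
#'   I column.
#' @return list of class `repsel_ir` with elements `table` (one row per
#'   component: `I_pct` corrected, `I_total_pct` uncorrected, `R`, `IR_mean`,
#'   `IR_plugin`, and CIs), `R_mrs` (+ CI), `p_I` and `p_IR` (symmetric
#'   pairwise p-value matrices), `n_failed`, `config`.
#' @export
compute_ir <- function(x, config = bootstrap_config(),
                       icc_engine = c("reml", "anova"),
                       error_method = "closed_form") {
  icc_engine <- match.arg(icc_engine)
  if (anyNA(x$recipients$total_sperm)) x <- impute_total_sperm(x)
  prep <- ir_prepare(x)
  point <- ir_eval(prep, seq_len(prep$n_rep), need_r = TRUE,
                   icc_engine = icc_engine, error_method = error_method)
  if (is.null(point)) stop("I_R undefined on the full data", call. = FALSE)
  boot <- ir_bootstrap(prep, config, need_r = TRUE,
                       icc_engine = icc_engine, error_method = error_method)
  if (boot$n_failed > 0.1 * boot$B)
    stop(sprintf("%d of %d bootstrap iterations failed", boot$n_failed,
                 boot$B), call. = FALSE)

  lv <- config$level
  ir_d <- extract_draws(boot, "ir", COMPONENTS)
  raw_d <- extract_draws(boot, "pct_raw", COMPONENTS)
  corr_d <- extract_draws(boot, "pct_corr", COMPONENTS)
  r_d <- extract_draws(boot, "R", c(COMPONENTS, "mRS"))
  ci2 <- function(m) t(apply(m, 2, percentile_ci, level = lv))

  ir_ci <- ci2(ir_d); raw_ci <- ci2(raw_d); corr_ci <- ci2(corr_d)
  r_ci <- ci2(r_d)
  tab <- data.frame(
    component = COMPONENTS,
    I_pct = as.numeric(point$pct_corr),
    I_lo = corr_ci[, 1], I_hi = corr_ci[, 2],
    I_total_pct = as.numeric(point$pct_raw),
    I_total_lo = raw_ci[, 1], I_total_hi = raw_ci[, 2],
    R = as.numeric(point$R[COMPONENTS]),
    R_lo = r_ci[seq_along(COMPONENTS), 1],
    R_hi = r_ci[seq_along(COMPONENTS), 2],
    IR_plugin = as.numeric(point$ir),
    IR_mean = colMeans(ir_d, na.rm = TRUE),
    IR_lo = ir_ci[, 1], IR_hi = ir_ci[, 2],
    stringsAsFactors = FALSE)

  pair_p <- function(draw_mat) {
    p <- matrix(NA_real_, 4, 4, dimnames = list(COMPONENTS, COMPONENTS))
    for (i in 1:3) for (j in (i + 1):4) {
      p[i, j] <- p[j, i] <-
        signed_p_value(draw_mat[, i] - draw_mat[, j], boot$B)
    }
    diag(p) <- 1
    p
  }

  structure(list(table = tab,
                 R_mrs = as.numeric(point$R["mRS"]),
                 R_mrs_ci = r_ci[5, ],
                 p_I = pair_p(corr_d), p_IR = pair_p(ir_d),
                 draws = list(IR = ir_d, I_total = raw_d, I = corr_d,
                              R = r_d),
                 n_failed = boot$n_failed, config = config,
                 icc_engine = icc_engine),
            class = "repsel_ir")
}

#' @export
print.repsel_ir <- function(x, ...) {
  cat(sprintf("Repeatable opportunity for selection (B = %d, %d failed)\n",
              x$config$iterations, x$n_failed))
  tab <- x$table
  cat(sprintf("  %-5s I = %4.1f%% [%4.1f-%4.1f]  R = %.2f [%.2f-%.2f]  I_R = %4.1f%% [%4.1f-%4.1f]\n",
              paste0(tab$component, "*"), tab$I_pct, tab$I_lo, tab$I_hi,
              tab$R, tab$R_lo, tab$R_hi, tab$IR_mean, tab$IR_lo, tab$IR_hi),
      sep = "")
  cat(sprintf("  repeatability of mRS*: %.2f [%.2f-%.2f]\n", x$R_mrs,
              x$R_mrs_ci[1], x$R_mrs_ci[2]))
  invisible(x)
}

#' Write the I_R report to disk
#'
#' Emits the component table as CSV and, together with the decomposition, a
#' JSON report; the numbers in the two formats are identical. Optionally
#' draws a stacked summary figure (total variance bar per component with the
#' repeatable portion shaded).
#'
#' @param ir a `repsel_ir` object from [compute_ir()].
#' @param decomposition optional `repsel_decomposition` from [decompose_dataset()].
#' @param prefix output path prefix; writes `<prefix>.csv`, `<prefix>.json`
#'   and (if `plot = TRUE`) `<prefix>.png`.
#' @param plot draw the stacked-bar figure (default `FALSE`).
#' @return invisibly, the list written to JSON.
#' @export
render_report <- function(ir, decomposition = NULL, prefix = "ir_report",
                          plot = FALSE) {
  tab <- ir$table
  utils::write.csv(tab, paste0(prefix, ".csv"), row.names = FALSE)
  payload <- list(table = tab,
                  R_mrs = ir$R_mrs, R_mrs_ci = ir$R_mrs_ci,
                  p_I = ir$p_I, p_IR = ir$p_IR)
  if (!is.null(decomposition)) {
    payload$decomposition <- list(
      terms = decomposition$terms,
      var_mrs = decomposition$var_mrs,
      var_mrs_ci = decomposition$var_mrs_ci,
      model_total = decomposition$model_total)
  }
  jsonlite::write_json(payload, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  if (plot) {
    grDevices::png(paste0(prefix, ".png"), width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    mids <- graphics::barplot(tab$I_total_pct, names.arg = paste0(tab$component, "*"),
                              col = "white", ylab = "% of variance in mRS*",
                              ylim = c(0, max(tab$I_total_hi) * 1.1))
    graphics::barplot(tab$IR_mean, col = "grey60", add = TRUE, axes = FALSE)
    graphics::arrows(mids, tab$I_total_lo, mids, tab$I_total_hi,
                     angle = 90, code = 3, length = 0.05)
    graphics::legend("topleft", fill = c("white", "grey60"),
                     legend = c("total variance (I)", "repeatable (I_R)"))
  }
  invisible(payload)
}
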