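# Repeatability (intraclass correlation) of per-group fitness values.
#
# The model is the one-way Gaussian random-intercept LMM
#   y_ij = mu + a_i + e_ij,  a_i ~ N(0, va), e_ij ~ N(0, ve),
# fitted by REML on the unbalanced table (each focal contributes 1-3
# per-group values); R = va / (va + ve). Because the model has a single
# grouping factor and no covariates, REML can be profiled down to a
# one-dimensional optimization over gamma = va/ve, which this file
# implements directly (engine "reml"); lme4::lmer is retained as an
# independent route (engine "lmm") and a method-of-moments one-way ANOVA
# ICC as a fast alternative (engine "anova").

#' Transformations applied to per-group fitness values
#'
#' Variance-stabilizing transforms chosen from LMM residual diagnostics:
#' `sqrt(mRS)`, `sqrt(F + 0.5)`, `sqrt(STE)`, `log10(SFE + 1)`; mating
#' success (`MS`) is left untransformed.
#'
#' @param x numeric vector of raw per-group values.
#' @param component one of `"mRS"`, `"F"`, `"MS"`, `"STE"`, `"SFE"`.
#' @return transformed vector.
#' @export
transform_values <- function(x, component) {
  switch(component,
         mRS = sqrt(x),
         F   = sqrt(x + 0.5),
         MS  = x,
         STE = sqrt(x),
         SFE = log10(x + 1),
         stop("unknown component: ", component, call. = FALSE))
}

#' Build the long table of transformed, relativized per-group values
#'
#' Applies the component's transformation (see [transform_values()]) to each
#' per-group value, drops missing values (a group in which the component
#' could not be estimated contributes no row), then divides by the grand
#' mean so the transformed component has mean 1. Relativization does not
#' change the intraclass correlation (R is scale invariant) but puts all
#' components on a common scale.
#'
#' @param group_components data.frame from [compute_components_per_group()].
#' @param component component label (`"mRS"`, `"F"`, `"MS"`, `"STE"`, `"SFE"`).
#' @return data.frame `replicate_id`, `batch`, `group_label`, `component`,
#'   `value`.
#' @export
transform_component <- function(group_components, component) {
  v <- transform_values(group_components[[component]], component)
  keep <- !is.na(v)
  out <- data.frame(replicate_id = group_components$replicate_id[keep],
                    batch = group_components$batch[keep],
                    group_label = group_components$group_label[keep],
                    component = component,
                    value = v[keep],
                    stringsAsFactors = FALSE)
  out$value <- relativize(out$value)
  out
}

# Per-focal sufficient statistics (size, sum, within sum of squares):
# everything the one-way ICC needs, so bootstrap resamples of whole focals
# reduce to row indexing.
oneway_stats <- function(value, id) {
  keep <- !is.na(value)
  value <- value[keep]; id <- id[keep]
  f <- factor(id, levels = unique(id))
  n <- as.vector(tapply(value, f, length))
  s <- as.vector(tapply(value, f, sum))
  ss <- as.vector(tapply(value, f, function(v) sum((v - mean(v))^2)))
  data.frame(replicate_id = levels(f), n = n, sum = s, ss = ss,
             stringsAsFactors = FALSE)
}

# Profiled REML criterion for gamma = va/ve (up to a constant).
reml_profile <- function(gamma, n, ybar, ssw, N) {
  w <- n / (1 + gamma * n)
  mu <- sum(w * ybar) / sum(w)
  Q <- ssw + sum(w * (ybar - mu)^2)
  (N - 1) * log(Q) + sum(log1p(gamma * n)) + log(sum(w))
}

ml_profile <- function(gamma, n, ybar, ssw, N) {
  w <- n / (1 + gamma * n)
  mu <- sum(w * ybar) / sum(w)
  Q <- ssw + sum(w * (ybar - mu)^2)
  N * log(Q) + sum(log1p(gamma * n))
}

icc_from_stats <- function(n, s, ss, engine = c("reml", "anova", "ml")) {
  engine <- match.arg(engine)
  k <- length(n); N <- sum(n)
  if (k < 2L || all(n == 1L))
    return(list(R = NA_real_, var_among = NA_real_, var_resid = NA_real_))
  ybar <- s / n
  ssw <- sum(ss)
  if (engine == "anova") {
    gm <- sum(s) / N
    msb <- sum(n * (ybar - gm)^2) / (k - 1)
    if (N - k <= 0) return(list(R = NA_real_, var_among = NA_real_,
                                var_resid = NA_real_))
    msw <- ssw / (N - k)
    n0 <- (N - sum(n^2) / N) / (k - 1)
    va <- max((msb - msw) / n0, 0)
    tot <- va + msw
    if (tot <= 0) return(list(R = NA_real_, var_among = 0, var_resid = msw))
    return(list(R = va / tot, var_among = va, var_resid = msw))
  }
  obj <- if (engine == "reml") reml_profile else ml_profile
  fn <- function(u) obj(exp(u), n, ybar, ssw, N)
  # total sum of squares about the GLS mean at gamma = 0
  mu0 <- sum(s) / N
  Q0 <- ssw + sum(n * (ybar - mu0)^2)
  if (Q0 <= 0) return(list(R = NA_real_, var_among = NA_real_,
                           var_resid = NA_real_))
  opt <- stats::optimize(fn, interval = c(-25, 25), tol = 1e-10)
  f0 <- obj(0, n, ybar, ssw, N)
  if (f0 <= opt$objective) {
    gamma <- 0; val <- f0
  } else {
    gamma <- exp(opt$minimum); val <- opt$objective
  }
  w <- n / (1 + gamma * n)
  mu <- sum(w * ybar) / sum(w)
  Q <- ssw + sum(w * (ybar - mu)^2)
  ve <- Q / if (engine == "reml") (N - 1) else N
  va <- gamma * ve
  list(R = gamma / (1 + gamma), var_among = va, var_resid = ve,
       objective = val, gamma = gamma, Q = Q)
}

# Boundary-corrected likelihood-ratio test of va = 0 (ML refits).
icc_lrt <- function(n, s, ss) {
  N <- sum(n)
  fit <- icc_from_stats(n, s, ss, engine = "ml")
  if (is.na(fit$R)) return(NA_real_)
  ybar <- s / n
  dev1 <- ml_profile(fit$gamma, n, ybar, sum(ss), N)
  dev0 <- ml_profile(0, n, ybar, sum(ss), N)
  lr <- dev0 - dev1
  if (lr <= 1e-10) return(1)
  0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Estimate repeatability of a fitness component across mating groups
#'
#' Fits the Gaussian random-intercept model `value ~ 1 + (1 | replicate_id)`
#' by REML on the (possibly unbalanced) long table and reports
#' `R = va / (va + ve)` with a nonparametric bootstrap percentile CI
#' (resampling whole focals) and a boundary-corrected likelihood-ratio
#' p-value for `va = 0` (ML refits, p halved for the one-sided boundary).
#' Negative variance estimates are truncated at zero by construction.
#'
#' @param table long data.frame from [transform_component()] (or any table
#'   with `replicate_id` and `value` columns); if it carries several
#'   components, pass `component` to select one.
#' @param config a [bootstrap_config()].
#' @param component optional component label to filter `table` on.
#' @param engine `"reml"` (fast profiled REML, default), `"lmm"`
#'   (lme4::lmer, independent route) or `"anova"` (one-way method of
#'   moments).
#' @param compute_p run the likelihood-ratio test (default `TRUE`).
#' @return list of class `repsel_repeatability`: `component`, `R`,
#'   `var_among`, `var_resid`, `ci`, `p_value`, `n_replicates`, `n_values`,
#'   `engine`, `draws` (bootstrap replicates of R).
#' @export
estimate_repeatability <- function(table, config = bootstrap_config(),
                                   component = NULL,
                                   engine = c("reml", "lmm", "anova"),
                                   compute_p = TRUE) {
  engine <- match.arg(engine)
  if (!is.null(component) && "component" %in% names(table))
    table <- table[table$component == component, , drop = FALSE]
  comp <- component %||% (if ("component" %in% names(table))
    unique(table$component)[1] else NA_character_)
  if (!nrow(table)) stop("empty table", call. = FALSE)
  st <- oneway_stats(table$value, table$replicate_id)
  if (nrow(st) < 2L)
    stop("need at least 2 replicates with values", call. = FALSE)
  if (stats::var(table$value) <= 0)
    stop("no variance to partition", call. = FALSE)

  point <- if (engine == "lmm") icc_lmer(table) else
    icc_from_stats(st$n, st$sum, st$ss,
                   engine = if (engine == "anova") "anova" else "reml")

  B <- config$iterations
  m <- config$resample_size %||% nrow(st)
  set.seed(derive_seed(config$seed, 101L))
  draws <- vapply(seq_len(B), function(b) {
    idx <- sample.int(nrow(st), m, replace = TRUE)
    icc_from_stats(st$n[idx], st$sum[idx], st$ss[idx],
                   engine = if (engine == "anova") "anova" else "reml")$R
  }, numeric(1))
  ci <- percentile_ci(draws, config$level)
  p <- if (compute_p) icc_lrt(st$n, st$sum, st$ss) else NA_real_

  structure(list(component = comp, R = point$R,
                 var_among = point$var_among, var_resid = point$var_resid,
                 ci = ci, p_value = p,
                 n_replicates = nrow(st), n_values = sum(st$n),
                 engine = engine, draws = draws),
            class = "repsel_repeatability")
}

#' @export
print.repsel_repeatability <- function(x, ...) {
  cat(sprintf("Repeatability of %s: R = %.3f [%.3f-%.3f], p = %.3g (%s, n = %d focals, %d values)\n",
              x$component, x$R, x$ci[1], x$ci[2], x$p_value, x$engine,
              x$n_replicates, x$n_values))
  invisible(x)
}

# lme4 route, used as an independent cross-check of the profiled REML.
icc_lmer <- function(table) {
  fit <- lme4::lmer(value ~ 1 + (1 | replicate_id), data = table,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  va <- vc$vcov[vc$grp == "replicate_id"]
  ve <- vc$vcov[vc$grp == "Residual"]
  list(R = va / (va + ve), var_among = va, var_resid = ve)
}

#' Test for trends across mating groups and experimental batches
#'
#' Fits `value ~ group_label * batch + (1 | replicate_id)` and reports
#' likelihood-ratio tests (maximum-likelihood refits) for the interaction and
#' for each main effect dropped from the additive model. A consistent trend
#' across groups would violate the steady-state assumption behind the
#' repeatability design; a batch effect flags environmental heterogeneity.
#'
#' @param table long data.frame from [transform_component()].
#' @return list of class `repsel_trend`: `component`, `terms` (data.frame
#'   with `term`, `df`, `chisq`, `p_value`), `ranef_variance`, `method`.
#' @export
fit_trend_model <- function(table) {
  table$group_label <- factor(table$group_label)
  table$batch <- factor(table$batch)
  if (nlevels(table$group_label) < 2L || nlevels(table$batch) < 2L)
    stop("need at least 2 mating groups and 2 batches", call. = FALSE)
  mm <- stats::model.matrix(~ group_label * batch, table)
  if (qr(mm)$rank < ncol(mm)) {
    ali <- colnames(mm)[-seq_len(qr(mm)$rank)]
    stop("rank-deficient design; aliased term(s): ",
         paste(ali, collapse = ", "), call. = FALSE)
  }
  ctl <- lme4::lmerControl(check.conv.singular = "ignore")
  full <- lme4::lmer(value ~ group_label * batch + (1 | replicate_id),
                     data = table, REML = FALSE, control = ctl)
  addi <- lme4::lmer(value ~ group_label + batch + (1 | replicate_id),
                     data = table, REML = FALSE, control = ctl)
  no_g <- lme4::lmer(value ~ batch + (1 | replicate_id),
                     data = table, REML = FALSE, control = ctl)
  no_b <- lme4::lmer(value ~ group_label + (1 | replicate_id),
                     data = table, REML = FALSE, control = ctl)
  lrt <- function(small, big) {
    df <- attr(stats::logLik(big), "df") - attr(stats::logLik(small), "df")
    ch <- max(0, 2 * (as.numeric(stats::logLik(big)) -
                        as.numeric(stats::logLik(small))))
    c(df = df, chisq = ch, p = stats::pchisq(ch, df, lower.tail = FALSE))
  }
  res <- rbind(`group_label` = lrt(no_g, addi),
               `batch` = lrt(no_b, addi),
               `group_label:batch` = lrt(addi, full))
  terms <- data.frame(term = rownames(res), df = res[, "df"],
                      chisq = res[, "chisq"], p_value = res[, "p"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(full))
  structure(list(component = if ("component" %in% names(table))
    unique(table$component)[1] else NA_character_,
    terms = terms,
    ranef_variance = vc$vcov[vc$grp == "replicate_id"],
    method = "likelihood-ratio tests, ML refits"),
    class = "repsel_trend")
}

#' @export
print.repsel_trend <- function(x, ...) {
  cat("Trend model for", x$component, "(", x$method, ")\n")
  print(x$terms, row.names = FALSE)
  invisible(x)
}
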