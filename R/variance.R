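# Variance decomposition of relative male reproductive success, binomial
# sampling-error correction, bootstrap CIs and signed-difference tests.
#
# With all components relativized to mean 1, the multiplicative model is
# approximately additive, so
#   Var(mRS*) ~ sum_c Var(c*) + 2 * sum_{c<d} Cov(c*, d*),
# the classic opportunity-for-selection partition. Percentages are expressed
# relative to the model-predicted total (the sum of all variance, covariance
# and sampling-error terms), the only convention under which the printed
# parts add to 100%.

COMPONENT_PAIRS <- utils::combn(COMPONENTS, 2)

#' Bootstrap configuration
#'
#' @param iterations number of bootstrap iterations B (default 10,000).
#' @param resample_size replicates drawn per iteration (default: the number
#'   of replicates in the data).
#' @param seed integer root seed; all derived streams are deterministic in it.
#' @param level confidence level for percentile intervals (default 0.95).
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(iterations = 10000L, resample_size = NULL,
                             seed = 1L, level = 0.95) {
  stopifnot(iterations >= 1, is.null(resample_size) || resample_size >= 1,
            level > 0, level < 1)
  structure(list(iterations = as.integer(iterations),
                 resample_size = resample_size,
                 seed = as.integer(seed), level = level),
            class = "bootstrap_config")
}

#' Point-estimate variance decomposition of relativized components
#'
#' Computes the variance of each relativized component, the six pairwise
#' covariances (pairwise-complete replicates), the observed variance of
#' relative male reproductive success and the model-predicted total
#' (sum of variances plus twice the covariances).
#'
#' @param relcomp data.frame of relativized components (`F`, `MS`, `STE`,
#'   `SFE`, `mRS`), e.g. from [relativize_components()].
#' @return list of class `repsel_varpart`: `variances` (named, 4),
#'   `covariances` (named `"A:B"`, 6), `var_mrs`, `model_total`, `n_used`
#'   (replicates per term). Terms with fewer than 2 usable replicates are
#'   `NA` with a warning.
#' @export
decompose_variance <- function(relcomp) {
  vars <- vapply(COMPONENTS, function(cl) {
    v <- relcomp[[cl]]
    if (sum(!is.na(v)) < 2L) return(NA_real_)
    stats::var(v, na.rm = TRUE)
  }, numeric(1))
  covs <- apply(COMPONENT_PAIRS, 2, function(pr) {
    a <- relcomp[[pr[1]]]; b <- relcomp[[pr[2]]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2L) return(NA_real_)
    stats::cov(a[ok], b[ok])
  })
  names(covs) <- apply(COMPONENT_PAIRS, 2, paste, collapse = ":")
  if (anyNA(c(vars, covs)))
    warning("term(s) with fewer than 2 usable replicates set to NA")
  var_mrs <- if (sum(!is.na(relcomp$mRS)) >= 2L)
    stats::var(relcomp$mRS, na.rm = TRUE) else NA_real_
  n_used <- vapply(COMPONENTS, function(cl) sum(!is.na(relcomp[[cl]])),
                   integer(1))
  structure(list(variances = vars, covariances = covs, var_mrs = var_mrs,
                 model_total = sum(vars) + 2 * sum(covs), n_used = n_used),
            class = "repsel_varpart")
}

# Closed-form (delta method) expected sampling-error variance of a
# relativized derived component. For each usable replicate the underlying
# binomial proportion p = succ/n has variance v = p(1-p)/n; the component is
# x = p/denom with noise variance v_x = v/denom^2, and the relativized value
# is x* = x/mean(x). Independent mean-zero noise inflates the (k-1)-divisor
# sample variance of x exactly by mean(v_x); propagating through the noisy
# relativization mean to second order gives
#   E = M/mu^2 + 3 M (A + M) / (k mu^4) - 2 C / mu^3
# with M = mean(v_x), mu = mean(x), A = var(x), and
# C = 2 sum((x - mu) v_x) / (k (k-1)). The correction terms are O(1/k) and
# matter only for very small replicate sets.
error_closed_form <- function(succ, n, denom) {
  p <- succ / n
  x <- p / denom
  vx <- p * (1 - p) / n / denom^2
  k <- length(x)
  mu <- mean(x)
  A <- stats::var(x)
  M <- mean(vx)
  C <- 2 * sum((x - mu) * vx) / (k * (k - 1))
  M / mu^2 + 3 * M * (A + M) / (k * mu^4) - 2 * C / mu^3
}

#' Expected binomial sampling-error variance of a derived component
#'
#' The derived components are ratios of estimated proportions (focal sperm
#' share for `STE`, focal offspring share for `SFE`); counting a finite
#' number of sperm/offspring adds spurious variance that would inflate the
#' opportunity for selection. This estimates the expected inflation, either
#' by the delta method (`closed_form`) or by redrawing the focal counts from
#' their fitted binomials and measuring the extra across-replicate variance
#' (`monte_carlo`). `F` and `MS` carry no correction.
#'
#' @param aggregates data.frame from [aggregate_replicates()].
#' @param component `"STE"` or `"SFE"`.
#' @param method `"closed_form"` (default) or `"monte_carlo"`.
#' @param draws Monte-Carlo repetitions (default 1000).
#' @param seed integer seed for the Monte-Carlo route.
#' @return expected error variance (on the relativized-component scale), with
#'   attribute `"n_used"`.
#' @export
binomial_error_variance <- function(aggregates,
                                    component = c("STE", "SFE"),
                                    method = c("closed_form", "monte_carlo"),
                                    draws = 1000L, seed = 1L) {
  component <- match.arg(component)
  method <- match.arg(method)
  a <- aggregates
  if (component == "STE") {
    ok <- a$m_f > 0 & a$s_t > 0
    succ <- a$s_f[ok]; n <- a$s_t[ok]; denom <- (a$m_f / a$m_t)[ok]
  } else {
    ss <- ifelse(a$s_t > 0, a$s_f / a$s_t, NA_real_)
    ok <- a$s_f > 0 & a$o_t > 0 & !is.na(ss)
    succ <- a$o_f[ok]; n <- a$o_t[ok]; denom <- ss[ok]
  }
  if (sum(ok) < 2L)
    stop("fewer than 2 replicates with a defined ", component, call. = FALSE)
  if (method == "closed_form") {
    out <- error_closed_form(succ, n, denom)
    mc_se <- NA_real_
  } else {
    p <- succ / n
    x_obs <- (p / denom)
    v_obs <- stats::var(x_obs / mean(x_obs))
    set.seed(derive_seed(seed, 202L))
    vs <- vapply(seq_len(draws), function(d) {
      sf <- stats::rbinom(length(n), n, p)
      x <- (sf / n) / denom
      m <- mean(x)
      if (m <= 0) return(NA_real_)
      stats::var(x / m)
    }, numeric(1))
    out <- mean(vs, na.rm = TRUE) - v_obs
    mc_se <- stats::sd(vs, na.rm = TRUE) / sqrt(sum(!is.na(vs)))
  }
  structure(out, n_used = sum(ok), mc_se = mc_se)
}

# ---- shared bootstrap core -------------------------------------------------
#
# Precomputes everything resampling-invariant: the per-replicate aggregate
# counts and, per component, the per-focal sufficient statistics of the
# transformed per-group values (R is scale invariant, so the relativization
# step can be skipped inside iterations).

ir_prepare <- function(x) {
  agg <- aggregate_replicates(x)
  gc <- compute_components_per_group(x)
  comps <- c(COMPONENTS, "mRS")
  stats_list <- lapply(comps, function(cl) {
    tv <- transform_values(gc[[cl]], cl)
    st <- oneway_stats(tv, gc$replicate_id)
    # align to agg rows; focals with no usable value get n = 0
    idx <- match(agg$replicate_id, st$replicate_id)
    data.frame(n = ifelse(is.na(idx), 0L, st$n[idx]),
               sum = ifelse(is.na(idx), 0, st$sum[idx]),
               ss = ifelse(is.na(idx), 0, st$ss[idx]))
  })
  names(stats_list) <- comps
  list(agg = agg, stats = stats_list, n_rep = nrow(agg))
}

# One iteration's statistics on a replicate index vector.
ir_eval <- function(prep, idx, need_r = TRUE,
                    icc_engine = "reml", error_method = "closed_form") {
  a <- prep$agg[idx, , drop = FALSE]
  comp <- component_row(a$m_t, a$m_f, a$s_t, a$s_f, a$o_t, a$o_f)
  rel <- comp
  for (cl in c(COMPONENTS, "mRS")) {
    m <- mean(rel[[cl]], na.rm = TRUE)
    if (!is.finite(m) || m <= 0) return(NULL)
    rel[[cl]] <- rel[[cl]] / m
  }
  vp <- suppressWarnings(decompose_variance(rel))
  if (anyNA(vp$variances)) return(NULL)
  err <- c(F = 0, MS = 0,
           STE = as.numeric(binomial_error_variance(a, "STE",
                                                    method = error_method)),
           SFE = as.numeric(binomial_error_variance(a, "SFE",
                                                    method = error_method)))
  total <- vp$model_total
  pct_raw <- 100 * vp$variances / total
  pct_err <- 100 * err / total
  pct_corr <- pct_raw - pct_err
  pct_cov <- 100 * 2 * vp$covariances / total
  out <- list(pct_raw = pct_raw, pct_corr = pct_corr, pct_err = pct_err,
              pct_cov = pct_cov, variances = vp$variances,
              corrected = pmax(vp$variances - err, 0),
              covariances = vp$covariances, errors = err,
              var_mrs = vp$var_mrs, model_total = total)
  if (need_r) {
    R <- vapply(c(COMPONENTS, "mRS"), function(cl) {
      st <- prep$stats[[cl]][idx, , drop = FALSE]
      st <- st[st$n > 0L, , drop = FALSE]
      icc_from_stats(st$n, st$sum, st$ss,
                     engine = if (icc_engine == "anova") "anova" else "reml")$R
    }, numeric(1))
    out$R <- R
    out$ir <- R[COMPONENTS] * pct_raw
  }
  out
}

ir_bootstrap <- function(prep, config, need_r = TRUE, icc_engine = "reml",
                         error_method = "closed_form") {
  B <- config$iterations
  m <- config$resample_size %||% prep$n_rep
  set.seed(derive_seed(config$seed, 303L))
  idx_mat <- matrix(sample.int(prep$n_rep, B * m, replace = TRUE), nrow = B)
  draws <- vector("list", B)
  for (b in seq_len(B))
    draws[[b]] <- ir_eval(prep, idx_mat[b, ], need_r, icc_engine,
                          error_method)
  failed <- vapply(draws, is.null, logical(1))
  list(draws = draws[!failed], n_failed = sum(failed), B = B)
}

extract_draws <- function(boot, field, names) {
  t(vapply(boot$draws, function(d) as.numeric(d[[field]][names]),
           numeric(length(names))))
}

#' Bootstrap a statistic over whole replicates
#'
#' Generic percentile bootstrap in which the resampling unit is the whole
#' replicate: every row sharing a `replicate_id` moves together, and
#' resampled copies of the same replicate are treated as distinct. The same
#' seed always yields bit-identical draws.
#'
#' @param statistic function taking a resampled object and returning a
#'   numeric scalar or named vector.
#' @param data a `repsel_data` object or any data.frame with a
#'   `replicate_id` column.
#' @param config a [bootstrap_config()].
#' @return list of class `repsel_bootstrap`: `point` (statistic on the full
#'   data), `ci` (matrix, one row per element), `draws` (B x p matrix),
#'   `n_failed`.
#' @export
bootstrap_statistic <- function(statistic, data, config = bootstrap_config()) {
  ids <- if (inherits(data, "repsel_data"))
    unique(data$groups$replicate_id) else unique(data$replicate_id)
  n <- length(ids)
  m <- config$resample_size %||% n
  point <- statistic(data)
  p <- length(point)
  cache <- make_resample_cache(data)
  set.seed(derive_seed(config$seed, 404L))
  draws <- matrix(NA_real_, config$iterations, p,
                  dimnames = list(NULL, names(point)))
  for (b in seq_len(config$iterations)) {
    take <- sample(ids, m, replace = TRUE)
    res <- tryCatch(statistic(cached_resample(cache, take)),
                    error = function(e) rep(NA_real_, p))
    draws[b, ] <- as.numeric(res)
  }
  bad <- colMeans(is.na(draws))
  if (any(bad > 0.5))
    stop(sprintf("statistic undefined on %.0f%% of resamples",
                 100 * max(bad)), call. = FALSE)
  ci <- t(apply(draws, 2, percentile_ci, level = config$level))
  structure(list(point = point, ci = ci, draws = draws,
                 n_failed = sum(apply(is.na(draws), 1, any))),
            class = "repsel_bootstrap")
}

# Precomputed row indices per replicate id, so each bootstrap iteration is a
# single indexed subset rather than a per-id scan.
make_resample_cache <- function(data) {
  idx_of <- function(df) split(seq_len(nrow(df)), df$replicate_id)
  if (inherits(data, "repsel_data")) {
    list(rd = TRUE, data = data, g = idx_of(data$groups),
         r = idx_of(data$recipients),
         p = if (!is.null(data$penetrance)) idx_of(data$penetrance))
  } else {
    list(rd = FALSE, data = data, i = idx_of(data))
  }
}

cached_resample <- function(cache, ids) {
  copy <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  new_id <- paste0(ids, "#", copy)
  build <- function(df, map) {
    rows <- map[as.character(ids)]
    out <- df[unlist(rows, use.names = FALSE), , drop = FALSE]
    out$replicate_id <- rep(new_id, lengths(rows))
    rownames(out) <- NULL
    out
  }
  if (cache$rd) {
    repsel_data(build(cache$data$groups, cache$g),
                build(cache$data$recipients, cache$r),
                if (!is.null(cache$p)) build(cache$data$penetrance, cache$p),
                validate = FALSE)
  } else {
    build(cache$data, cache$i)
  }
}

#' Materialize a replicate-level resample
#'
#' Builds the dataset corresponding to a with-replacement draw of replicate
#' ids; the i-th copy of a duplicated replicate gets the id suffix `"#i"` so
#' copies remain distinct grouping units.
#'
#' @param data a `repsel_data` or a data.frame with a `replicate_id` column.
#' @param ids character/numeric vector of drawn replicate ids (duplicates
#'   allowed).
#' @return object of the same type as `data`.
#' @export
resample_replicates <- function(data, ids) {
  copy <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  new_id <- paste0(ids, "#", copy)
  take_df <- function(df) {
    pieces <- lapply(seq_along(ids), function(i) {
      rows <- df[df$replicate_id == ids[i], , drop = FALSE]
      rows$replicate_id <- new_id[i]
      rows
    })
    do.call(rbind, pieces)
  }
  if (inherits(data, "repsel_data")) {
    repsel_data(take_df(data$groups), take_df(data$recipients),
                if (!is.null(data$penetrance)) take_df(data$penetrance),
                validate = FALSE)
  } else {
    take_df(data)
  }
}

signed_p_value <- function(diffs, B) {
  diffs <- diffs[is.finite(diffs)]
  if (!length(diffs)) return(NA_real_)
  pos <- sum(diffs > 0) + 0.5 * sum(diffs == 0)
  neg <- sum(diffs < 0) + 0.5 * sum(diffs == 0)
  p <- 2 * min(pos, neg) / length(diffs)
  min(max(p, 2 / B), 1)
}

#' Bootstrap signed-difference test between two components
#'
#' In each iteration, resamples whole replicates, computes the target
#' quantity for both components on the same resample, and records the sign
#' of the difference; the two-tailed p-value is twice the smaller sign
#' frequency, ties split equally, floored at `2/B`.
#'
#' @param x a `repsel_data` object (imputed; see [impute_total_sperm()]).
#' @param compA,compB component labels among `"F"`, `"MS"`, `"STE"`, `"SFE"`.
#' @param target `"variance"` (error-corrected variance, as a percentage of
#'   the model total) or `"repeatable_variance"` (the repeatable opportunity
#'   for selection, R x uncorrected percentage).
#' @param config a [bootstrap_config()].
#' @param icc_engine ICC engine used when `target = "repeatable_variance"`.
#' @return list of class `repsel_signed_test`: `p_value`, `diffs`,
#'   `n_failed`, `target`.
#' @export
signed_difference_test <- function(x, compA, compB,
                                   target = c("variance",
                                              "repeatable_variance"),
                                   config = bootstrap_config(),
                                   icc_engine = "reml") {
  target <- match.arg(target)
  stopifnot(compA %in% COMPONENTS, compB %in% COMPONENTS)
  prep <- ir_prepare(x)
  boot <- ir_bootstrap(prep, config, need_r = target == "repeatable_variance",
                       icc_engine = icc_engine)
  if (boot$n_failed > 0.5 * boot$B)
    stop(sprintf("target undefined on %d of %d resamples", boot$n_failed,
                 boot$B), call. = FALSE)
  field <- if (target == "variance") "pct_corr" else "ir"
  vals <- extract_draws(boot, field, c(compA, compB))
  diffs <- vals[, 1] - vals[, 2]
  structure(list(p_value = signed_p_value(diffs, boot$B), diffs = diffs,
                 n_failed = boot$n_failed, target = target,
                 comparison = c(compA, compB)),
            class = "repsel_signed_test")
}

#' Full variance decomposition with bootstrap confidence intervals
#'
#' Runs the complete decomposition pipeline on a validated dataset: imputes
#' sperm totals if needed, pools counts per replicate, computes and
#' relativizes the components, decomposes the variance, estimates the
#' binomial sampling-error terms, and attaches bootstrap percentile CIs to
#' every term (errors re-estimated inside each iteration, corrected
#' variances clipped at zero).
#'
#' @param x a `repsel_data` object.
#' @param config a [bootstrap_config()].
#' @param error_method `"closed_form"` (default) or `"monte_carlo"`.
#' @return list of class `repsel_decomposition` with elements `terms` (a
#'   data.frame of every term: value, percentage, CIs), `var_mrs`,
#'   `model_total`, `n_replicates`, `n_failed`.
#' @export
decompose_dataset <- function(x, config = bootstrap_config(),
                      error_method = "closed_form") {
  if (anyNA(x$recipients$total_sperm)) x <- impute_total_sperm(x)
  prep <- ir_prepare(x)
  point <- ir_eval(prep, seq_len(prep$n_rep), need_r = FALSE,
                   error_method = error_method)
  if (is.null(point)) stop("decomposition undefined on the full data",
                           call. = FALSE)
  boot <- ir_bootstrap(prep, config, need_r = FALSE,
                       error_method = error_method)

  term_tbl <- function(names, value, pct, field_v, field_p) {
    v_d <- extract_draws(boot, field_v, names)
    p_d <- extract_draws(boot, field_p, names)
    data.frame(term = names, value = as.numeric(value),
               pct = as.numeric(pct),
               value_lo = apply(v_d, 2, function(z) percentile_ci(z, config$level)[1]),
               value_hi = apply(v_d, 2, function(z) percentile_ci(z, config$level)[2]),
               pct_lo = apply(p_d, 2, function(z) percentile_ci(z, config$level)[1]),
               pct_hi = apply(p_d, 2, function(z) percentile_ci(z, config$level)[2]),
               stringsAsFactors = FALSE)
  }
  if (any(point$variances - point$errors < 0))
    warning("corrected variance went negative and was clipped at 0 ",
            "(percentage terms are left unclipped so they sum to 100)")
  vt <- term_tbl(COMPONENTS, point$corrected, point$pct_corr,
                 "corrected", "pct_corr")
  vt$type <- "variance_corrected"
  et <- term_tbl(c("STE", "SFE"), point$errors[c("STE", "SFE")],
                 point$pct_err[c("STE", "SFE")], "errors", "pct_err")
  et$type <- "sampling_error"
  ct <- term_tbl(names(point$covariances), 2 * point$covariances,
                 point$pct_cov, "covariances", "pct_cov")
  ct$value_lo <- 2 * ct$value_lo; ct$value_hi <- 2 * ct$value_hi
  ct$type <- "covariance_x2"
  terms <- rbind(vt, et, ct)

  mrs_d <- vapply(boot$draws, function(d) d$var_mrs, numeric(1))
  tot_d <- vapply(boot$draws, function(d) d$model_total, numeric(1))
  structure(list(terms = terms, var_mrs = point$var_mrs,
                 var_mrs_ci = percentile_ci(mrs_d, config$level),
                 model_total = point$model_total,
                 model_total_ci = percentile_ci(tot_d, config$level),
                 raw_variances = point$variances,
                 pct_raw = point$pct_raw,
                 n_replicates = prep$n_rep, n_failed = boot$n_failed,
                 config = config),
            class = "repsel_decomposition")
}

#' @export
print.repsel_decomposition <- function(x, digits = 3, ...) {
  cat(sprintf("Variance decomposition over %d replicates\n", x$n_replicates))
  cat(sprintf("  observed Var(mRS*) = %.*g [%.*g-%.*g]; model total = %.*g\n",
              digits, x$var_mrs, digits, x$var_mrs_ci[1], digits,
              x$var_mrs_ci[2], digits, x$model_total))
  tt <- x$terms
  tt$pct <- round(tt$pct, 1)
  print(tt[c("term", "type", "value", "pct", "pct_lo", "pct_hi")],
        row.names = FALSE, digits = digits)
  invisible(x)
}
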