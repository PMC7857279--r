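# Sperm-count imputation, the four multiplicative fitness components,
# and relativization.
#
# Male reproductive success factorizes as
#   mRS = F x MS x STE x SFE
# with F = total offspring of all partners, MS = focal matings / total
# matings, STE = (focal sperm share) / MS, SFE = (focal offspring share) /
# (focal sperm share). The identity holds exactly whenever all terms are
# defined.

COMPONENTS <- c("F", "MS", "STE", "SFE")

#' Impute unobservable total sperm counts
#'
#' Total stored sperm cannot be counted in a recipient whose antrum holds an
#' egg (the egg hides unlabelled sperm); those recipients carry
#' `total_sperm = NA` with `egg_in_antrum = TRUE`. Each such recipient
#' receives the mean observed total over all countable recipients in the
#' dataset (rounded to the nearest integer by default, for count semantics).
#' If the imputed total falls below the recipient's observed focal sperm
#' count, it is raised to that count.
#'
#' @param x a `repsel_data` object.
#' @param fallback_mean value to use when no recipient has an observable
#'   total (default `NULL`: error in that case).
#' @param round_mean round the imputation value to the nearest integer
#'   (default `TRUE`).
#' @return `x` with all `total_sperm` filled in; the recipients table gains a
#'   logical `sperm_imputed` column, and the attribute `"imputation"` records
#'   the value used, the number of imputed recipients and the number raised
#'   to the focal count.
#' @export
impute_total_sperm <- function(x, fallback_mean = NULL, round_mean = TRUE) {
  r <- x$recipients
  obs <- !is.na(r$total_sperm)
  need <- !obs
  if (!any(need)) {
    r$sperm_imputed <- FALSE
    x$recipients <- r
    attr(x, "imputation") <- list(value = NA_real_, n_imputed = 0L,
                                  n_raised = 0L)
    return(x)
  }
  if (any(obs)) {
    m <- mean(r$total_sperm[obs])
  } else if (!is.null(fallback_mean)) {
    m <- fallback_mean
  } else {
    stop("no recipient with observable total sperm and no fallback_mean",
         call. = FALSE)
  }
  if (round_mean) m <- round(m)
  imp <- pmax(m, r$focal_sperm[need])
  n_raised <- sum(imp > m)
  r$total_sperm[need] <- imp
  r$sperm_imputed <- need
  x$recipients <- r
  attr(x, "imputation") <- list(value = m, n_imputed = sum(need),
                                n_raised = n_raised)
  x
}

component_row <- function(m_t, m_f, s_t, s_f, o_t, o_f) {
  MS <- ifelse(m_t > 0, m_f / m_t, NA_real_)
  ss <- ifelse(s_t > 0, s_f / s_t, NA_real_)
  os <- ifelse(o_t > 0, o_f / o_t, NA_real_)
  STE <- ifelse(m_f > 0 & s_t > 0, ss / MS, NA_real_)
  SFE <- ifelse(s_f > 0 & o_t > 0 & !is.na(ss), os / ss, NA_real_)
  data.frame(F = o_t, MS = MS, STE = STE, SFE = SFE, mRS = o_f)
}

#' Compute fitness components from replicate-pooled counts
#'
#' @param aggregates data.frame from [aggregate_replicates()].
#' @return data.frame with one row per replicate: `replicate_id`, `batch`,
#'   `F`, `MS`, `STE`, `SFE`, `mRS`. `STE` is missing when the focal never
#'   mated or no sperm was stored; `SFE` when the focal transferred no sperm
#'   or no offspring were produced.
#' @export
compute_components <- function(aggregates) {
  if (any(aggregates$m_t == 0))
    warning("replicate(s) with no matings observed: MS set to missing")
  cbind(aggregates[c("replicate_id", "batch")],
        component_row(aggregates$m_t, aggregates$m_f, aggregates$s_t,
                      aggregates$s_f, aggregates$o_t, aggregates$o_f))
}

#' Compute fitness components for each replicate x mating group
#'
#' Same definitions as [compute_components()] but on single-group counts;
#' these per-group values are the unit of the repeatability analysis.
#'
#' @param x a `repsel_data` object with imputed sperm totals.
#' @return data.frame with one row per replicate x group: `replicate_id`,
#'   `batch`, `group_label`, `F`, `MS`, `STE`, `SFE`, `mRS`.
#' @export
compute_components_per_group <- function(x) {
  if (anyNA(x$recipients$total_sperm))
    stop("total_sperm contains missing values; run impute_total_sperm() first",
         call. = FALSE)
  g <- x$groups; r <- x$recipients
  key <- paste(g$replicate_id, g$group_label, sep = "\r")
  rkey <- factor(paste(r$replicate_id, r$group_label, sep = "\r"),
                 levels = key)
  sum_by <- function(v) {
    out <- as.vector(tapply(v, rkey, sum))
    out[is.na(out)] <- 0
    out
  }
  cbind(g[c("replicate_id", "batch", "group_label")],
        component_row(g$total_matings, g$focal_matings,
                      sum_by(r$total_sperm), sum_by(r$focal_sperm),
                      sum_by(r$total_offspring), sum_by(r$focal_offspring)))
}

#' Relativize a fitness vector to mean 1
#'
#' Divides by the mean of the non-missing entries, so that variances are
#' comparable across components (Crow's standardized variance). Missing
#' entries stay missing.
#'
#' @param x numeric vector, possibly with `NA`s.
#' @return `x / mean(x, na.rm = TRUE)`.
#' @export
relativize <- function(x) {
  if (all(is.na(x))) stop("cannot relativize an all-missing vector",
                          call. = FALSE)
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("cannot relativize: mean of non-missing values is not positive",
         call. = FALSE)
  x / m
}

#' Relativize all fitness components of a component table
#'
#' @param components data.frame from [compute_components()].
#' @return the same data.frame with `F`, `MS`, `STE`, `SFE`, `mRS` each
#'   divided by its mean; attribute `"means"` stores the means used.
#' @export
relativize_components <- function(components) {
  cols <- c(COMPONENTS, "mRS")
  means <- vapply(cols, function(cl) mean(components[[cl]], na.rm = TRUE),
                  numeric(1))
  for (cl in cols) components[[cl]] <- components[[cl]] / means[[cl]]
  attr(components, "means") <- means
  components
}
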