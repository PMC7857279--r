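# Generative simulator of the sequential mating-group design.
#
# Each focal i carries latent quality effects a_i (mating, log rate scale),
# b_i (sperm transfer, log-odds scale) and c_i (fertilization, log-odds
# scale); each focal x group adds independent group-level noise on the same
# scales. Observation layers are Poisson (dyadic copulation counts, sperm
# pools, offspring) and binomial (focal shares), so focal counts can never
# exceed totals by construction. Increasing a latent SD relative to its
# group-level noise raises the generative repeatability of the matching
# component; setting all latent SDs to zero yields a world where every
# apparent difference among focals is stochastic.

#' Simulation configuration
#'
#' Defaults emulate the scale of the empirical design: 150 focals x 3
#' groups x 4 partners in 8 batches, dyadic copulation rate such that a
#' 5-worm group accumulates ~58 copulations per 3-h trial, ~21 stored sperm
#' and ~5.8 offspring per partner, and a 40% chance that a recipient holds
#' an egg (masking its total sperm count). Latent and group-noise SDs
#' default to values calibrated (by large-sample simulation, see the
#' methods vignette) to give repeatabilities of roughly 0.4 / 0.5 / 0.2 for
#' mating success, sperm-transfer efficiency and sperm fertilizing
#' efficiency.
#'
#' @param n_focals number of focals (replicates).
#' @param n_groups mating groups per focal.
#' @param n_partners partners per group.
#' @param n_batches experimental batches (focals assigned in balanced order).
#' @param lambda dyadic copulation rate per trial (each of the 10 dyads of a
#'   5-worm group).
#' @param sigma_ms,sigma_ste,sigma_sfe focal latent SDs (log / log-odds
#'   scale).
#' @param tau_ms,tau_ste,tau_sfe group-level noise SDs (same scales).
#' @param sperm_pool_mean mean total stored sperm per recipient.
#' @param mu_f mean offspring per recipient.
#' @param batch_sd SD of the batch effect on fecundity (log scale).
#' @param egg_prob probability a recipient holds an egg in the antrum.
#' @param penetrance GFP-marker penetrance used in the screen.
#' @param penetrance_screened offspring screened per focal.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_focals = 150L, n_groups = 3L,
                              n_partners = 4L, n_batches = 8L,
                              lambda = 5.8,
                              sigma_ms = 0.33, sigma_ste = 0.51,
                              sigma_sfe = 0.44,
                              tau_ms = 0.30, tau_ste = 0.45,
                              tau_sfe = 0.55,
                              sperm_pool_mean = 21, mu_f = 5.8,
                              batch_sd = 0.07, egg_prob = 0.406,
                              penetrance = 1, penetrance_screened = 48L,
                              seed = 1L) {
  cfg <- list(n_focals = as.integer(n_focals), n_groups = as.integer(n_groups),
              n_partners = as.integer(n_partners),
              n_batches = as.integer(n_batches), lambda = lambda,
              sigma_ms = sigma_ms, sigma_ste = sigma_ste,
              sigma_sfe = sigma_sfe, tau_ms = tau_ms, tau_ste = tau_ste,
              tau_sfe = tau_sfe, sperm_pool_mean = sperm_pool_mean,
              mu_f = mu_f, batch_sd = batch_sd, egg_prob = egg_prob,
              penetrance = penetrance,
              penetrance_screened = as.integer(penetrance_screened),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_focals >= 1, n_groups >= 1, n_partners >= 1, n_batches >= 1,
              lambda >= 0, sigma_ms >= 0, sigma_ste >= 0, sigma_sfe >= 0,
              tau_ms >= 0, tau_ste >= 0, tau_sfe >= 0,
              sperm_pool_mean > 0, mu_f > 0, batch_sd >= 0,
              egg_prob >= 0, egg_prob <= 1, penetrance >= 0, penetrance <= 1)
  })
  structure(cfg, class = "simulation_config")
}

qlogis_clamped <- function(p, eps = 1e-6) {
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' Simulate a mating-group dataset
#'
#' Draws a full dataset under the generative model described in
#' [simulation_config()]: latent focal effects, group-level noise, dyadic
#' Poisson copulation counts (partner-partner dyads dilute the focal's
#' mating share), binomial focal sperm and offspring shares chained through
#' the realized shares of the previous episode, egg-in-antrum masking of
#' total sperm counts, and a GFP-penetrance screen. The same seed yields a
#' bit-identical dataset.
#'
#' @param config a [simulation_config()].
#' @return list of class `repsel_sim`: `data` (a validated [repsel_data]),
#'   `truth` (data.frame of per-focal latent effects plus the config).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  cfg <- config
  set.seed(cfg$seed)
  nf <- cfg$n_focals; ng <- cfg$n_groups; np <- cfg$n_partners
  ids <- sprintf("F%03d", seq_len(nf))
  batch <- rep(seq_len(cfg$n_batches), length.out = nf)
  a <- stats::rnorm(nf, 0, cfg$sigma_ms)
  b <- stats::rnorm(nf, 0, cfg$sigma_ste)
  cc <- stats::rnorm(nf, 0, cfg$sigma_sfe)
  batch_eff <- stats::rnorm(cfg$n_batches, 0, cfg$batch_sd)

  labels <- LETTERS[seq(2, 1 + ng)]           # B, C, D, ...
  n_dyads_pp <- np * (np - 1) / 2             # partner-partner dyads
  rows <- expand.grid(gi = seq_len(ng), fi = seq_len(nf))
  fi <- rows$fi; gi <- rows$gi
  nrw <- nrow(rows)

  eps <- stats::rnorm(nrw, 0, cfg$tau_ms)
  eta <- stats::rnorm(nrw, 0, cfg$tau_ste)
  nu <- stats::rnorm(nrw, 0, cfg$tau_sfe)

  pp_m <- stats::rpois(nrw, n_dyads_pp * cfg$lambda)
  foc_m <- stats::rpois(nrw, np * cfg$lambda * exp(a[fi] + eps))
  tot_m <- pp_m + foc_m
  share_m <- ifelse(tot_m > 0, foc_m / tot_m, 0)

  groups <- data.frame(replicate_id = ids[fi], batch = batch[fi],
                       group_label = labels[gi], total_matings = tot_m,
                       focal_matings = foc_m, stringsAsFactors = FALSE)

  # recipients: np per focal x group
  ridx <- rep(seq_len(nrw), each = np)
  rec_no <- rep(seq_len(np), times = nrw)
  s_tot <- stats::rpois(nrw * np, cfg$sperm_pool_mean)
  p_s <- ifelse(foc_m[ridx] > 0,
                stats::plogis(qlogis_clamped(share_m[ridx]) +
                                b[fi[ridx]] + eta[ridx]), 0)
  s_foc <- stats::rbinom(nrw * np, s_tot, p_s)
  o_tot <- stats::rpois(nrw * np, cfg$mu_f * exp(batch_eff[batch[fi[ridx]]]))
  share_s <- ifelse(s_tot > 0, s_foc / s_tot, 0)
  p_o <- ifelse(s_foc > 0,
                stats::plogis(qlogis_clamped(share_s) +
                                cc[fi[ridx]] + nu[ridx]), 0)
  o_foc <- stats::rbinom(nrw * np, o_tot, p_o)
  egg <- stats::runif(nrw * np) < cfg$egg_prob

  recipients <- data.frame(
    replicate_id = ids[fi[ridx]], group_label = labels[gi[ridx]],
    recipient_index = rec_no,
    total_sperm = ifelse(egg, NA_integer_, s_tot),
    focal_sperm = s_foc, egg_in_antrum = egg,
    total_offspring = o_tot, focal_offspring = o_foc,
    stringsAsFactors = FALSE)

  screened <- rep(cfg$penetrance_screened, nf)
  penetrance <- data.frame(
    replicate_id = ids, offspring_screened = screened,
    gfp_positive = stats::rbinom(nf, screened, cfg$penetrance),
    stringsAsFactors = FALSE)

  truth <- data.frame(replicate_id = ids, batch = batch,
                      a = a, b = b, c = cc, stringsAsFactors = FALSE)
  structure(list(data = repsel_data(groups, recipients, penetrance),
                 truth = list(effects = truth, batch_effects = batch_eff,
                              masked_total_sperm = s_tot[egg],
                              config = cfg)),
            class = "repsel_sim")
}

#' Operational true repeatability of a configuration
#'
#' The generative repeatability of each component is defined operationally
#' as the large-sample intraclass correlation of the transformed per-group
#' values under the generative model (including egg masking and sperm
#' imputation, i.e. exactly what the estimation pipeline sees), obtained by
#' brute-force simulation rather than closed-form algebra.
#'
#' @param config a [simulation_config()].
#' @param n_focals_large number of focals in the brute-force run
#'   (default 20,000).
#' @param seed seed for the brute-force run.
#' @return named numeric vector of R for `F`, `MS`, `STE`, `SFE`, `mRS`.
#' @export
true_repeatability <- function(config, n_focals_large = 20000L,
                               seed = 999L) {
  big <- config
  big$n_focals <- as.integer(n_focals_large)
  big$seed <- as.integer(seed)
  sim <- simulate_dataset(big)
  d <- impute_total_sperm(sim$data)
  gc <- compute_components_per_group(d)
  vapply(c(COMPONENTS, "mRS"), function(cl) {
    tv <- transform_values(gc[[cl]], cl)
    st <- oneway_stats(tv, gc$replicate_id)
    icc_from_stats(st$n, st$sum, st$ss, engine = "anova")$R
  }, numeric(1))
}

#' Parameter-recovery experiment over a grid of configurations
#'
#' For each configuration, simulates `n_sims` datasets, runs the estimation
#' pipeline, and compares the estimated repeatability of each component with
#' the configuration's operational truth (see [true_repeatability()]):
#' bias, RMSE and, optionally, coverage of bootstrap CIs for R and whether
#' the I_R interval covers zero. Pipeline errors in a cell are recorded,
#' not fatal.
#'
#' @param configs list of [simulation_config()] objects.
#' @param n_sims simulated datasets per configuration.
#' @param compute_ci also run [compute_ir()] per simulation to get CIs
#'   (slower); controlled by `ci_iterations`.
#' @param ci_iterations bootstrap iterations for the per-simulation CIs.
#' @param icc_engine ICC engine for the per-simulation estimates.
#' @param truth_n focals used for the brute-force truth.
#' @param seed root seed.
#' @return list of class `repsel_recovery`: `summary` (per config x
#'   component: truth, mean estimate, bias, rmse, CI coverage, I_R-covers-0
#'   rate), `errors` (count per config), `n_sims`.
#' @export
recovery_experiment <- function(configs, n_sims = 100L, compute_ci = FALSE,
                                ci_iterations = 200L,
                                icc_engine = "reml", truth_n = 20000L,
                                seed = 1L) {
  if (!length(configs)) stop("empty configuration grid", call. = FALSE)
  comps <- c(COMPONENTS, "mRS")
  out <- list(); errors <- integer(length(configs))
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    truth <- true_repeatability(cfg, n_focals_large = truth_n,
                                seed = derive_seed(seed, 7000L + ci))
    est <- matrix(NA_real_, n_sims, length(comps),
                  dimnames = list(NULL, comps))
    cover <- matrix(NA, n_sims, length(comps), dimnames = list(NULL, comps))
    ir_zero <- matrix(NA, n_sims, length(COMPONENTS),
                      dimnames = list(NULL, COMPONENTS))
    for (s in seq_len(n_sims)) {
      cfg_s <- cfg
      cfg_s$seed <- derive_seed(seed, ci * 100000L + s)
      res <- tryCatch({
        sim <- simulate_dataset(cfg_s)
        d <- impute_total_sperm(sim$data)
        gc <- compute_components_per_group(d)
        r_hat <- vapply(comps, function(cl) {
          tv <- transform_values(gc[[cl]], cl)
          st <- oneway_stats(tv, gc$replicate_id)
          icc_from_stats(st$n, st$sum, st$ss,
                         engine = if (icc_engine == "anova") "anova"
                         else "reml")$R
        }, numeric(1))
        ir <- NULL
        if (compute_ci) {
          ir <- compute_ir(d, bootstrap_config(iterations = ci_iterations,
                                               seed = cfg_s$seed),
                           icc_engine = icc_engine)
        }
        list(r_hat = r_hat, ir = ir)
      }, error = function(e) NULL)
      if (is.null(res)) { errors[ci] <- errors[ci] + 1L; next }
      est[s, ] <- res$r_hat
      if (!is.null(res$ir)) {
        ir_zero[s, ] <- res$ir$table$IR_lo <= 1e-9
        rci <- res$ir$table[, c("R_lo", "R_hi")]
        cover[s, COMPONENTS] <- truth[COMPONENTS] >= rci$R_lo &
          truth[COMPONENTS] <= rci$R_hi
      }
      NULL
    }
    out[[ci]] <- data.frame(
      config = ci, component = comps, truth_R = truth[comps],
      mean_R = colMeans(est, na.rm = TRUE),
      bias = colMeans(est, na.rm = TRUE) - truth[comps],
      rmse = sqrt(colMeans(sweep(est, 2, truth[comps])^2, na.rm = TRUE)),
      ci_coverage = colMeans(cover, na.rm = TRUE),
      ir_covers_zero = c(colMeans(ir_zero, na.rm = TRUE),
                         NA)[seq_along(comps)],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(summary = do.call(rbind, out), errors = errors,
                 n_sims = n_sims),
            class = "repsel_recovery")
}
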