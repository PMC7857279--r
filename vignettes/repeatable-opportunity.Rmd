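---
title: "Decomposing and weighting the opportunity for selection by its repeatability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing and weighting the opportunity for selection by its repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The opportunity for selection, *I* — the variance in relative fitness — is an
upper bound on how strongly selection can act on any trait. When male
reproductive success is measured in mating groups, *I* can be partitioned into
multiplicative pre- and postcopulatory fitness components; but a large *I*
does not prove strong selection, because part of the variance in individual
success is pure chance (who happened to meet whom, which sperm happened to
fertilize). `repsel` implements a design that separates the two: each focal
individual is measured in several *independent* mating groups, the
consistency of its success across groups is quantified as a repeatability
*R* (an intraclass correlation), and the deterministic — i.e. potentially
selectable — share of each component's variance is reported as the
*repeatable opportunity for selection*,

$$ I_R = R \times I. $$

The motivating system is a transparent, simultaneously hermaphroditic
flatworm in which a dominant GFP transgene makes a focal's sperm and
offspring identifiable inside its partners, so that even the cryptic
postcopulatory episodes are observable. Nothing in the code is specific to
that organism: any replicated mating-group design with count data fits the
schema.

## The multiplicative model

For each focal (a *replicate*), counts are summed over its mating groups:
total and focal matings ($m_t, m_f$), total and focal stored sperm
($s_t, s_f$), total and focal offspring ($o_t, o_f$). The fitness components
are

* partner fecundity $F = o_t$,
* mating success $MS = m_f / m_t$,
* sperm-transfer efficiency $STE = (s_f/s_t) / MS$,
* sperm fertilizing efficiency $SFE = (o_f/o_t) / (s_f/s_t)$,

so that male reproductive success factorizes exactly:
$mRS = F \times MS \times STE \times SFE = o_f$. A component whose
denominator is zero (a focal that never mated, or transferred no sperm) is
*missing*, not zero; every later stage uses the values that exist, which
mirrors the unbalanced bookkeeping of real datasets.

Each component is relativized (divided by its mean across replicates), and
for mean-one factors that are not too variable

$$ \operatorname{Var}(mRS^*) \approx \sum_c \operatorname{Var}(c^*) +
   2 \sum_{c<d} \operatorname{Cov}(c^*, d^*). $$

`decompose_dataset()` reports each term both absolutely and as a percentage. The
percentage denominator is the **model-predicted total** (all variances +
doubled covariances), not the observed $\operatorname{Var}(mRS^*)$: only
under that convention do the printed parts sum to exactly 100%. The
observed $\operatorname{Var}(mRS^*)$ is reported alongside so the quality of
the additive approximation is visible (skewed components make the model
total exceed the observed variance).

### Binomial sampling error

$STE$ and $SFE$ are built from *estimated* proportions ($s_f/s_t$ with
denominator $s_t$; $o_f/o_t$ with denominator $o_t$), so counting finitely
many sperm or offspring inflates their variance even if every focal had
identical true shares. The expected inflation is estimated and subtracted.
Two estimators are provided and must agree:

* **closed form** (default): per replicate the proportion variance is
  $\hat p(1-\hat p)/n$; propagated through the ratio and the relativization
  by the delta method. The implementation carries the $O(1/k)$ second-order
  terms of the noisy relativization mean ($k$ = number of replicates), which
  matter only for very small datasets but let the closed form agree with the
  Monte-Carlo oracle to its standard error even at $k = 4$.
* **Monte Carlo**: redraw focal counts from
  $\operatorname{Binomial}(n, \hat p)$, recompute the relativized component,
  and average the extra across-replicate variance over many redraws.

No correction is applied to $F^*$ or $MS^*$. Corrected variances are clipped
at zero (with a warning) on the absolute scale; percentage terms are left
unclipped so the 100% identity is preserved.

## Repeatability

Per-group component values are first transformed
($\sqrt{mRS}$, $\sqrt{F + 0.5}$, $\sqrt{STE}$, $\log_{10}(SFE+1)$; $MS$ is
deliberately untransformed — no transformation is part of the model for it),
then relativized to mean 1 (this does not change $R$, which is scale
invariant, but keeps components comparable). The model is the one-way
Gaussian random-intercept LMM fitted by REML; $R = \sigma^2_{\alpha} /
(\sigma^2_{\alpha} + \sigma^2_{\varepsilon})$.

Because the model has a single grouping factor and no covariates, the REML
criterion can be profiled to a one-dimensional optimization over
$\gamma = \sigma^2_\alpha / \sigma^2_\varepsilon$ using only per-focal
sufficient statistics (size, sum, within-group sum of squares). This is the
default engine; it is numerically identical to `lme4::lmer` (tested to
1e-6) and fast enough to be refitted inside every bootstrap iteration, which
keeps the estimator *the same* inside and outside the bootstrap. `lme4`
remains available as an independent cross-check (`engine = "lmm"`), and a
method-of-moments one-way ANOVA ICC (`engine = "anova"`) as a cheap
alternative for very large bootstrap counts.

Inference:

* **CI**: nonparametric bootstrap resampling whole focals (the same
  resampling unit as everywhere else in the pipeline), percentile interval.
  A parametric bootstrap is *not* used; the nonparametric choice keeps one
  consistent resampling unit across the package.
* **Significance**: likelihood-ratio test of the random intercept with ML
  refits, p halved for the one-degree boundary. This construction is this
  package's documented choice; it is standard, but no claim is made that it
  reproduces any particular other implementation bit for bit.

`fit_trend_model()` checks the design assumptions: value ~ mating group ×
batch with a random intercept per focal, term-wise likelihood-ratio tests
(ML refits, method recorded in the output). A consistent group trend would
undermine the steady-state premise of the repeatability design.

## Combining: the joint bootstrap

`compute_ir()` resamples whole replicates (default 10,000 iterations,
resample size = number of replicates), and inside each iteration recomputes
(i) the relativized components and their variance percentages and (ii) the
repeatability of each component, then records $I_R = R \times I$. Two
conventions follow the design:

* Inside the product, $I$ is the **uncorrected** (total) variance share:
  subtracting the binomial error there would bias $I_R$ downward. The
  displayed $I$ column is error-corrected; both are reported.
* The error terms and the percentage denominator are recomputed within each
  iteration, as are the relativization means.

Whether the reported point estimate should be the bootstrap mean or the
plug-in product is ambiguous in general; both are returned (`IR_mean`,
`IR_plugin`) and the plug-in satisfies $I_R = R \times I_{total}$ exactly.
Pairwise comparisons use the signed-difference test: the difference of the
two statistics is computed on the *same* resample in each iteration, and the
two-tailed p-value is twice the smaller sign frequency, with ties split
equally between signs and a floor of $2/B$. The self-comparison therefore
yields exactly p = 1.

Iterations on which a statistic is undefined (e.g. a resample where a
component has fewer than two usable replicates) are dropped and counted;
more than 10% failures aborts with an error.

## The synthetic world

`simulate_dataset()` generates data with the statistical structure the
analysis assumes, so that every stage — and parameter recovery — is testable
without any field data. Per focal $i$: latent effects $a_i \sim N(0,
\sigma_{MS}^2)$ (log rate), $b_i \sim N(0, \sigma_{STE}^2)$ and $c_i \sim
N(0, \sigma_{SFE}^2)$ (log odds). Per focal × group, independent noise on
the same scales. Observation layers:

* each of the 10 dyads of a 5-worm group copulates
  $\sim \operatorname{Poisson}(\lambda)$, the 4 focal dyads with rate
  multiplied by $e^{a_i + \varepsilon_{ig}}$ — partner–partner matings are
  simulated because mating success is focal matings over *all* copulations;
* per partner, stored sperm $\sim \operatorname{Poisson}(21)$, focal share
  $\sim \operatorname{Binomial}$ with success probability
  $\operatorname{logit}^{-1}(\operatorname{logit}(\text{mating share}) +
  b_i + \eta_{ig})$;
* per partner, offspring $\sim \operatorname{Poisson}(\mu_F e^{\beta_b})$
  with batch effects $\beta_b \sim N(0, \sigma_{batch}^2)$, focal offspring
  binomial through the realized sperm share shifted by $c_i + \nu_{ig}$;
* recipients hold an egg with probability 0.406, which masks their total
  sperm count (the imputation path of the pipeline).

Latent effects act on log/log-odds scales so all counts remain valid and
focal counts can never exceed totals by construction.

**Default values are the stated world, chosen once.** Design-shaped
quantities (150 focals × 3 groups × 4 partners, 8 batches) follow the
empirical design; the rate-like defaults ($\lambda = 5.8$, 21 sperm, 5.8
offspring per recipient, egg probability 0.406) reproduce the reported
grand totals per trial/recipient. The latent and noise SDs
($\sigma_{MS}, \tau_{MS}, \sigma_{STE}, \tau_{STE}, \sigma_{SFE},
\tau_{SFE}, \sigma_{batch}$ = 0.33, 0.30, 0.51, 0.45, 0.44, 0.55, 0.07)
were calibrated **once**, by large-sample simulation (20,000 focals),
so that the operational repeatabilities of the transformed components are
approximately 0.03 (F), 0.40 (MS), 0.47 (STE), 0.22 (SFE) and 0.33 (mRS) —
the magnitudes reported for this kind of data. Two auxiliary stated worlds
used in the recovery tests were calibrated the same way: a
pure-stochasticity world (all $\sigma = 0$, no batch effects; true $R = 0$
for every component) and a 3:1 variance-ratio world
($\sigma_{MS} = 0.275$, no batch effects; the true variance of relativized
mating success is 3.0× that of partner fecundity, checked at 80,000
focals over several seeds).

"True" repeatability under the generative model is defined *operationally*
(`true_repeatability()`): the large-sample ICC of the transformed per-group
component, including egg masking and imputation — i.e. what an infinite
version of the estimation pipeline would see — obtained by brute-force
simulation rather than closed-form algebra, which would be easy to get
subtly wrong for these chained nonlinear layers.

What the generator does **not** emulate: behavioral dynamics (mating order,
sperm displacement mechanics, partner-choice or genotype × genotype
interactions), overdispersion beyond Poisson/binomial, and any correlation
between latent effects across components. A green recovery test therefore
establishes that the estimators recover the parameters of *this* structure,
not that the model is a complete description of real mating groups.

## Numerical choices and degenerate inputs

* All randomness flows from one root seed through `derive_seed()`; the same
  seed gives bit-identical datasets, draws and reports.
* Percentile CIs use `stats::quantile` type 7; REML profiling uses
  `optimize` on $\log \gamma \in [-25, 25]$ with tolerance 1e-10 and an
  explicit boundary comparison at $\gamma = 0$ (negative variance estimates
  are thereby truncated at zero, and perfect repeatability lands at the
  upper interval end, $R = 1$ to well below 1e-6).
* Sperm imputation uses the dataset-wide mean of observable totals, rounded
  to the nearest integer for count semantics (`round_mean = FALSE` gives
  the unrounded mean); an imputed total below the recipient's observed
  focal count is raised to that count and flagged. Whether the original
  analyses recomputed the mean per batch is unknown; dataset-wide is the
  documented default.
* The penetrance filter defaults to `min_fraction = 0.90`,
  `require_offspring = TRUE`, inferred from the reported exclusions
  (a 47% focal and a no-offspring focal excluded, 90–100% focals kept); no
  per-offspring correction is applied to retained focals.
* Missing mating groups (a failed recording) reduce a replicate's sums, they
  do not drop the replicate; per-component sample sizes are tracked
  throughout.
* A replicate table can also arrive with per-group sperm sums instead of
  per-recipient counts: encode each group as a single pseudo-recipient row;
  the pipeline is agnostic to the recipient granularity as long as the
  totals are right (imputation is bypassed when no totals are missing).

## Known limitations

* The additive variance identity is an approximation; for strongly skewed
  components the model total can exceed the observed
  $\operatorname{Var}(mRS^*)$ noticeably. Both numbers are always reported.
* The delta-method error correction assumes independent binomial noise
  given the observed proportions; overdispersed counting noise would be
  underestimated.
* Bootstrap percentile CIs for $R$ near 0 (or 1) are boundary-limited, and
  the LRT p-value relies on the asymptotic half-chi-square; for very small
  datasets both are approximate.
* The reproduction of the published table requires the original deposited
  dataset, which is not redistributable with the package; the corresponding
  acceptance tests fail (they do not skip) when it is absent. Every other
  guarantee is established on data generated in code.
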