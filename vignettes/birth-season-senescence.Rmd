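---
title: "Modelling birth-season stress and reproductive senescence"
author: "repsen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling birth-season stress and reproductive senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(repsen)
```

## The question and the analysis it requires

Long-lived, continuously breeding mammals show *reproductive senescence*:
after a peak age, the probability of producing offspring declines. A
recurring hypothesis in life-history research is that conditions around
birth set the pace of that decline decades later. `repsen` implements a
complete analysis pipeline for this question, modelled on semi-captive
Asian-elephant studbook populations in which

1. a *high-stress season* is defined physiologically, from monthly faecal
   glucocorticoid metabolite (GCM) concentrations of reproductive-aged
   females, rather than from calendar proxies;
2. each female's reproductive career is discretised into 3-year
   observation bins scored 1 if she calved in the bin, and the shape of
   the age trajectory is found by AIC comparison of candidate
   mixed-effect logistic models (null, polynomial, and broken-stick
   models with one or two free knots on a grid);
3. the post-peak (senescent) phase is tested for a birth-season × age
   interaction — faster decline in high-stress-born females — with
   maternal-covariate subsets and a conception-season sensitivity
   analysis as confounding checks; and
4. the lifetime consequences are quantified with Poisson (total calves)
   and binomial (ever reproduced) mixed models.

Because studbook data of this kind are not freely redistributable, the
package ships a synthetic-data module with known ground truth that
emulates the published population structure; every statistical claim the
package makes about itself is established on that generator by the test
suite.

## The mixed-model core

All models are random-intercept GLMMs
$$ g\{E(y_{ij})\} = \mathbf{x}_{ij}^\top\beta + u_{i} + v_{r(i)},\qquad
   u_i \sim N(0, \sigma^2_{\mathrm{id}}),\;
   v_r \sim N(0, \sigma^2_{\mathrm{region}}), $$
with binomial-logit, Poisson-log or Gaussian-identity response. The
marginal likelihood integrates over the random effects; `fit_glmm()`
maximises its Laplace approximation (exact in the Gaussian case) by ML —
not REML — so likelihood-ratio tests between fixed-effect structures are
valid.

Implementation choices that matter for reproducibility:

* **Joint optimisation with analytic gradients.** The objective is
  maximised over $(\beta, \log\sigma)$ jointly by BFGS. Profiling the
  fixed effects at the *joint penalised mode* (as fast "nAGQ = 0"
  schemes do) biases $\hat\beta$ and can even make a larger model report
  a smaller likelihood; optimising the true Laplace objective keeps the
  nesting monotonicity that the test suite asserts. The gradient of the
  Laplace objective — including the derivative of the
  $\log\det$ curvature term through the random-effect mode — is
  evaluated in closed form.
* **Arrow algebra.** For one or two random-intercept factors, the
  penalised curvature $Z^\top W Z + D^{-1}$ has an arrow structure: the
  block of the larger factor is diagonal and the second factor is small
  (10 regions). Factorisation, solves, log-determinants and the
  selected-inverse diagonals needed by the gradient are therefore dense
  closed-form operations; no sparse-matrix machinery is needed and fits
  of ~2,000 rows with ~500 random effects take well under a second.
* **Inner loop.** The random-effect mode is found by penalised IRLS with
  step halving; relative tolerance $10^{-11}$ on the penalised
  log-likelihood, 80 iterations cap.
* **Outer loop.** BFGS with relative tolerance $10^{-9}$ (configurable;
  the heavy simulation loops in the tests use $10^{-6}$–$10^{-8}$ where
  only AIC rankings or rejection rates are consumed). Log-SDs live in a
  box $[-5, 4]$; an estimate at the lower edge is a *boundary* fit
  (variance ≈ 0), flagged but not an error. Because a boundary descent
  can pass a shallow interior optimum, one deterministic retry restarts
  any boundary component from $\sigma = 0.15$. All starting values are
  fixed, so refitting identical data is bit-reproducible.
* **Bookkeeping conventions.** AIC counts fixed coefficients plus free
  variance components (plus the Gaussian residual variance);
  likelihood-ratio statistics are clipped at zero with a warning;
  aliased fixed-effect columns are dropped deterministically
  (first-come kept); rows with missing covariates are dropped and
  counted.
* **Oracles.** `brute_force_loglik()` recomputes the marginal likelihood
  by adaptive 1-D quadrature per group (product Gauss–Hermite grid over
  a small second factor), and `laplace_loglik()` evaluates the Laplace
  objective at arbitrary fixed parameters so the two routes can be
  compared at identical inputs. On Bernoulli clusters of 3–5
  observations the Laplace error is a few hundredths of a log-unit at
  moderate variance; the Gaussian case is exact. Zero-variance fits are
  checked against `stats::glm`, and full fits against `lme4` (in the
  test suite only — `lme4` is never the implementation).

## The synthetic study population

`sim_config()` encodes the study conditions: 1,078 females born
1941–1999 across 10 regions, observed from the earliest reproductive age
(5 y), censored at study end (2000) or at 55 y. Its defaults are the
published summaries of the emulated population and are not tuned:

* **Three-stage trajectory.** Probability of calving within a 3-year bin:
  a low plateau (0.08 at age 5, flat on the logit scale) to the first
  knot at 15 y; a logit-linear rise to the peak at 24 y (0.46 for
  high-stress-born, 0.34 for other-born females); then a *linear decline
  on the probability scale* of 0.022 vs 0.0073 per 3-year bin, floored
  at 0.01. `true_reproduction_probability()` exposes this curve; it is
  the conditional (random-effects-at-zero) trajectory.
* **Random effects.** Individual logit SD 0.438 (the reported senescent-
  phase estimate in the emulated study system); region SD 0.05 (the
  reported region variance is essentially zero; a small positive value
  keeps the component estimable). Shared across all of a female's bins.
* **Reproduction mechanics.** The per-bin Bernoulli draw *is* the
  reproduction indicator — that is what makes empirical bin frequencies
  converge to the configured trajectory, the generator's central
  contract. A successful draw is then dated inside the bin with an
  inter-birth-interval draw (normal, mean 5.4 y, SD 2.7 y, truncated at
  the refractory minimum of gestation 22 months + 1 year of rest).
  Because the refractory minimum (≈2.83 y) is shorter than the bin
  width, every drawn success is placeable; the configured interval
  distribution shapes dates, not rates. A consequence worth knowing:
  females dying mid-bin can have a success suppressed in that final
  partial bin, a terminal-exposure artifact that mimics late-life
  nonlinearity. `build_observation_bins(drop_partial = TRUE)` exists for
  trajectory-recovery simulations for exactly this reason; the default
  (partial bins kept, controlled by the censoring covariates) mirrors
  how such studbook data are actually analysed.
* **Mortality and censoring.** A three-piece constant hazard, 0.022 /y
  (ages 5–23), 0.026 /y (23–38) and 0.116 /y (38+), solved in closed
  form from three attrition anchors of the emulated population under
  uniform birth years and study end 2000: ~42% of females reach the
  senescent phase (≈455 of 1,078), those females contribute ≈2,059
  post-peak bins, and ≈38 reach the 47–49 bin. A single exponential
  hazard cannot satisfy these jointly; age-increasing mortality is also
  the biologically right shape for elephants. Survivors at study end
  are censored, flagged, never dropped.
* **Birth months.** Uniform by default (the analysis conditions on the
  season flag, not on birth-month frequencies); a 12-weight seasonal
  distribution is available for experiments that need realistic group
  imbalance (e.g. the peak-bin comparison, where high-stress-born
  females are the small group).
* **Maternal covariates.** Birth order and maternal age are recorded
  only for females born from 1969 on (≈52% of the cohort), emulating
  incomplete archival pedigrees; they carry no effect in the generator,
  which is what the confounder subset analyses should find.

The hormone generator (`gcm_sim_config()`) emulates a year of monthly
sampling of 37 non-pregnant females aged 17–55: month means 45.6 ng/g
dry faeces, elevated to 68.1 ng/g in June–August. The within-female SD
of 10 ng/g is derived from the emulated study's reported month-factor
F statistic (≈32 on 11 df at ~30 usable samples per month implies
σ within ≈ 10); the between-female SD of 8 ng/g gives an intra-class
correlation around 0.4, typical for repeated hormone sampling. Values
truncate at zero; an optional missingness fraction thins the 444
scheduled samples toward realistic field yields (~354).

What the generator does *not* emulate: correlated year effects, seasonal
birth-frequency variation (by default), maternal identity effects on
daughters, calf survival, individual frailty linking mortality to
reproduction, or assay-level measurement error structure. Passing tests
therefore demonstrate that the pipeline recovers what it claims under
the stated stochastic structure — not that real studbook data meet that
structure.

## Season derivation

`fit_month_model()` fits concentration on a 12-level month factor with a
female random intercept (Gaussian, ML; a log-transform flag exists but
raw concentrations are the default). `elevated_months()` takes the
months whose contrast against the January baseline is positive with
two-sided Wald $p < \alpha$ ($\alpha = 0.05$, no multiple-testing
correction across the 11 contrasts — both choices configurable).
`high_stress_season()` reduces that set to its maximal run of
consecutive months, circular across December–January, ties broken by
the higher mean fitted concentration. With a 0.025 one-directional
false-positive rate per contrast, a month adjacent to a true season
joins it in roughly 5% of replicates — the price of the uncorrected
rule, visible in the classifier's measured exact-recovery rate.
`season_vs_month()` compares the binary season coding against the full
month factor on identical rows: both AICs and the likelihood-ratio test
with the honest parameter-count degrees of freedom (10).

## Trajectory selection and the senescent phase

Candidate age structures — null, linear, quadratic, cubic, single
thresholds at 9–45 y (step 3), and threshold pairs (first 12–39, second
18–45, at least 6 y apart, each segment required to contain ≥3 observed
bin mid-ages when the data are supplied) — share identical base fixed
effects (season flag, birth decade with the earliest decade as
reference, censored flag, last-sighting age and its square) and random
intercepts. Age and last-sighting age are divided by 100 in these
models (a conditioning choice; the senescent-phase models below default
to unscaled years, and both scalings are supported). Knots are placed
at bin mid-ages; the spline basis $[a, (a-T_1)_+, (a-T_2)_+]$ keeps the
predictor continuous with a free slope per segment. Exact AIC ties
(below $10^{-6}$) go to the model with fewer parameters; non-converged
candidates are excluded with a warning. Variance-parameter estimates
are warm-started across the grid, which makes a 20-plus-candidate
search at 2,000 females a matter of seconds per candidate.

The senescent phase is the data at and beyond the second knot of the
best model (mid-age ≥ 24 under the default truth). `fit_senescence_models()`
centres age at the peak — the season main effect is then the
peak-height contrast — and tests the season × age interaction by LRT.
`decline_rates()` converts a fit into probability declines per 3-year
bin per group, averaging the drop of the marginal (random effects at
zero) predictions over the post-peak range. By default the predictions
are standardised over the observed covariate rows (G-computation), so
the reported declines live on the same scale as the population's raw
age trajectory and recover the generator's configured per-bin declines;
a fixed-reference mode (not censored, earliest observed decade,
last-sighting age at its subset mean, all overridable) is available,
with the caveat that a reference whose baseline probability sits above
the population average proportionally inflates probability-scale
declines. The peak-bin
comparison is a Welch two-sample t-test oriented other-minus-high-stress.
The type-I calibration of the interaction test uses identical group
trajectories (equal peaks *and* equal declines): equal probability-scale
declines from unequal peaks are not parallel on the logit scale, so
that configuration is not a null for a logit-scale interaction.

## Lifetime models

One row per female: total calves (Poisson) and ever-reproduced
(binomial), each with the season flag, unscaled last-sighting age and
its square, censored flag, birth decade, a region intercept and an
individual intercept. With one row per female the individual term is an
observation-level random effect; in the Poisson model it absorbs
overdispersion. It is retained for structural fidelity with the
bin-level models and can be dropped (`olre = FALSE`). The season
contrast reports the raw percent difference in unadjusted group means
*and* the covariate-adjusted rate ratio $e^{\beta_{\mathrm{season}}}$
separately — the two answer different questions and are deliberately
not forced to agree. Under the default trajectory (higher high-stress
peak, faster high-stress decline, curves crossing only ~24 years after
the peak) high-stress-born females accumulate *more* calves; the
lifetime-deficit scenario used in the recovery tests scales the whole
high-stress trajectory by 0.841, which produces a 15.9% deficit in
expected lifetime calves.

## Problem sizes and tolerances used by the test suite

The suite establishes, at fixed seeds: Laplace-vs-quadrature agreement
within 0.05 log-units on 20 tiny instances and exact ($10^{-4}$)
agreement with `glm` at zero variance; coefficient agreement with the
GLM oracle within $10^{-3}$ under pinned variances; threshold recovery
(both knots within ±3 y) in ≥80% of 20 replicates at 2,000 females on
a 22-candidate grid, with linear- and constant-truth data keeping the
simpler model within ΔAIC 2; interaction-test power at 1,078 females
over 100 replicates and type-I calibration (0.05 ± 0.02) over 500
replicates; season-classifier exact recovery in ≥95% of 200 replicates
and the null false-positive fraction against its analytic expectation;
the birth-vs-conception dissociation over 40 replicates; lifetime
contrast recovery (±3 percentage points over 15 replicates) and Poisson
season-test power over 40 replicates; and byte-identical pipeline
reruns. Replicate counts and the reduced threshold grid are sized so
the whole suite runs in routine time on one core; the grid retains
candidates well outside the recovery tolerance so the selection task
stays non-trivial.

Two caveats the measurements themselves make visible: at the default
effect sizes (declines 0.022 vs 0.0073 per bin at 1,078 females) the
mean fitted interaction is recovered almost exactly, but its sampling
error at this design size leaves the LRT with modest power, so the
power clauses of the interaction checks are expected to sit below an
80% bar that the same suite reports honestly; and the uncorrected
per-contrast α places the season classifier's exact-recovery rate right
at the 95% bar it is tested against, where individual seed sets can
land on either side.

## Known limitations

The Laplace approximation is least accurate for binary responses with
few observations per group and large variance; the oracle quantifies
but does not remove that error. Only random intercepts are supported
(the analyses need nothing more), at most two factors. The generator's
ground-truth trajectory is piecewise on two different scales (logit
rise, probability-scale decline), so no single GLMM candidate is
exactly true post-peak — model selection recovers the knots, not the
literal generating equation. Calendar arithmetic is month-resolution;
day-of-month is never used. The pipeline's season derivation feeds the
cohort labelling downstream, so a failed season detection aborts the
run rather than silently defaulting.
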