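# repsen — birth-season stress and reproductive senescence

`repsen` is an R package for a question from life-history biology: do
individuals born under physiologically stressful conditions age faster
reproductively? It implements, end to end, the analysis design used for
semi-captive Asian elephant (*Elephas maximus*) studbook populations,
where a "high-stress" season can be defined from faecal glucocorticoid
metabolite (GCM) measurements of reproductive-aged females and each
female's calving record spans decades. It is aimed at researchers who
analyse longitudinal reproduction records of long-lived mammals and at
methodologists who want a tested, self-contained reference
implementation of the broken-stick mixed-model senescence analysis.

## What it computes

1. **High-stress season.** A Gaussian random-intercept model of monthly
   GCM concentration, $y_{im} = \mu + \alpha_m + u_i + \varepsilon_{im}$,
   fitted by ML; the season is the maximal run of consecutive calendar
   months significantly above the January baseline
   (`fit_month_model()`, `elevated_months()`, `high_stress_season()`),
   plus an AIC/LRT comparison of season vs month codings
   (`season_vs_month()`).
2. **Age trajectory of reproduction.** Each female's record becomes
   3-year observation bins scored 1 if she calved
   (`build_observation_bins()`, `attach_covariates()`). Candidate
   binomial GLMMs
   $\mathrm{logit}\,P(y_{ij}=1) = f(a_{ij}) + \mathbf{x}_{ij}^\top\beta + u_i + v_{r(i)}$
   differ only in the age term $f$: null, polynomials, and continuous
   linear splines $[a, (a-T_1)_+, (a-T_2)_+]$ with knots on a grid;
   `select_trajectory()` ranks them by AIC.
3. **Senescence-phase test.** On bins past the peak knot,
   `fit_senescence_models()` tests the birth-season × age interaction by
   likelihood ratio, with maternal-covariate subsets
   (`subset_effect_models()`), a conception-season sensitivity analysis
   (`conception_sensitivity()`), probability-scale decline rates
   (`decline_rates()`) and a peak-bin comparison
   (`peak_probability_test()`).
4. **Lifetime fitness.** Poisson (total calves) and binomial (ever
   reproduced) GLMMs with the season contrast
   (`fit_lifetime_models()`, `season_contrast()`).

The GLMM engine (`fit_glmm()`) is part of the package: Laplace-
approximate ML with analytic gradients and closed-form "arrow" algebra
for one or two random-intercept factors, validated in the test suite
against a brute-force quadrature oracle (`brute_force_loglik()`),
against `stats::glm` at zero variance, and against `lme4`.

Because studbook data of this kind are not redistributable, the package
includes a first-class synthetic-data module (`sim_config()`,
`simulate_population()`, `gcm_sim_config()`, `simulate_gcm()`) whose
defaults encode the published structure of the emulated population
(1,078 females born 1941–1999, three-stage trajectory with knots at 15
and 24 y, peak bin probabilities 0.46 vs 0.34, post-peak declines 0.022
vs 0.0073 per bin, GCM months at 45.6 vs 68.1 ng/g). See the vignette
`vignettes/birth-season-senescence.Rmd` for every modelling and
calibration decision.

## Worked example

```r
library(repsen)

config <- pipeline_config(out_dir = "run1", seed = 1)
res <- run_pipeline(config)
#> stage gcm_season: 444 samples, season = 6,7,8
#> stage cohort_builder: 1078 females, 6849 bin rows
#> stage age_trajectory: best model thr(15,24)
#> stage senescence: interaction chi^2 = 6.621 (p = 0.01008)
#> stage lifetime: raw season contrast +20.9%
```

Reading the output: the hormone model recovers June–August as the
high-stress season; the AIC search over 71 candidate age structures
picks the two-threshold broken stick with knots at 15 and 24 years
(`res$selection$table` holds the full ranking); in the senescent phase
the birth-season × age interaction is negative with likelihood-ratio
χ²₁ = 6.62 (p = 0.010), i.e. high-stress-born females decline faster —
with standardised per-bin probability declines

```r
res$declines$high_stress * 100   # 3.95  (% per 3-year bin)
res$declines$other * 100         # 1.48
```

These marginal declines sit above the generating values (2.2 and 0.73)
for two visible reasons: final partial bins clipped by mid-bin deaths
add a decline component in both groups, and this particular draw's
interaction happens to be steep (its χ² of 6.62 is in the upper tail
for the configured effect size). Complete-exposure analyses in the
test suite recover the configured declines. The peak-bin means are 0.487
(high-stress-born) vs 0.348 (other), Welch t = −2.64. Under the default
trajectory the high-stress-born group accumulates *more* lifetime
calves (+20.9% here) because its higher peak outweighs its faster
decline over observed lifespans; the lifetime-deficit scenario used in
the acceptance checks scales the whole high-stress trajectory down
instead. All stage outputs are also written to `run1/` as CSV/JSON, and
reruns with the same seed are byte-identical.

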