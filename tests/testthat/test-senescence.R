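test_that("senescence model guards its preconditions", {
  sen <- make_senescent_table(n_females = 300, seed = 41)
  pop <- simulate_population(sim_config(n_females = 100, seed = 41))
  pop_tab_full <- attach_covariates(build_observation_bins(pop), pop)
  ## full (unsubset) table must be rejected
  expect_error(fit_senescence_models(pop_tab_full), "pre-senescent")
  ## single season group present
  one <- sen[sen$high_stress_born == 0, ]
  expect_error(fit_senescence_models(one), "one")
  expect_error(fit_senescence_models(sen[0, ]), "empty")
})

test_that("interaction fit and LRT behave on simulated senescent data", {
  sen <- make_senescent_table(n_females = 600, seed = 43)
  sf <- fit_senescence_models(sen)
  expect_s3_class(sf$fit, "glmm_fit")
  ## interaction model nests the reduced one
  expect_gte(sf$fit$logLik, sf$fit_no_interaction$logLik - 1e-6)
  expect_equal(sf$interaction_lrt$df, 1L)
  ## coefficient names follow the Table-style layout
  expect_true("high_stress_born:age_c" %in% names(coef(sf$fit)))
  expect_true(all(c("id", "region") %in% sf$fit$varcomp$group))
})

test_that("decline rates reproduce constructed anchors and flat fits", {
  sen <- make_senescent_table(n_females = 600, seed = 47)
  sf <- fit_senescence_models(sen)
  ## constructed coefficients: marginal predictions 0.340 at 24 and
  ## 0.3327 at 27 give a decline of exactly 0.0073 for that group
  fake <- sf
  beta <- coef(sf$fit) * 0
  beta["(Intercept)"] <- qlogis(0.340)
  beta["age_c"] <- (qlogis(0.3327) - qlogis(0.340)) / 3
  fake$fit$coefficients <- beta
  d1 <- decline_rates(fake, from_age = 24, to_age = 27)
  expect_equal(d1$other, 0.340 - 0.3327, tolerance = 1e-10)
  ## flat fit: zero age and interaction coefficients -> zero decline
  flat <- sf
  beta0 <- coef(sf$fit) * 0
  beta0["(Intercept)"] <- qlogis(0.3)
  flat$fit$coefficients <- beta0
  dflat <- decline_rates(flat)
  expect_equal(dflat$high_stress, 0, tolerance = 1e-12)
  expect_equal(dflat$other, 0, tolerance = 1e-12)
  ## invariance to the decade reference-level coding: refitting with a
  ## releveled decade factor leaves the declines unchanged when the
  ## prediction covariates are held at the same values
  ref_dec <- levels(droplevels(factor(sen$birth_decade)))[1]
  sen_rl <- sen
  sen_rl$birth_decade <- stats::relevel(droplevels(factor(sen$birth_decade)),
                                        ref = levels(droplevels(factor(sen$birth_decade)))[2])
  sf_rl <- fit_senescence_models(sen_rl)
  d_a <- decline_rates(sf, ref = list(birth_decade = ref_dec))
  d_b <- decline_rates(sf_rl, ref = list(birth_decade = ref_dec))
  expect_lt(abs(d_a$high_stress - d_b$high_stress), 1e-5)
  expect_lt(abs(d_a$other - d_b$other), 1e-5)
  expect_error(decline_rates(sf, from_age = 30, to_age = 30), "degenerate")
})

test_that("standardised decline rates recover the generating per-bin declines", {
  ## complete-exposure bins: terminal mid-bin mortality clipping would
  ## otherwise add a spurious decline component in both groups
  decs <- sapply(1:5, function(r) {
    sen <- make_senescent_table(n_females = 1078, seed = 300 + r,
                                drop_partial = TRUE)
    sf <- fit_senescence_models(sen)
    dr <- decline_rates(sf)
    c(hs = dr$high_stress, other = dr$other)
  })
  expect_lt(abs(mean(decs["hs", ]) - 0.022), 0.01)
  expect_lt(abs(mean(decs["other", ]) - 0.0073), 0.005)
})

test_that("maternal-covariate subset models report the documented LRTs", {
  sen <- make_senescent_table(n_females = 800, seed = 53)
  for (mode in c("birth_order", "maternal_age")) {
    sub <- subset_effect_models(sen, mode)
    expect_equal(sub$covariate_lrt$df, 1L)
    expect_equal(sub$covariate_season_lrt$df, 1L)
    expect_equal(sub$interaction_lrt$df, 1L)
    ## the generator attaches no effect to either covariate: LRT should
    ## be unremarkable (not an assertion of exact calibration here)
    expect_gte(sub$covariate_lrt$p_value, 0)
    expect_lt(sub$n_rows, nrow(sen))
  }
  ## 100% missing covariate errors with its name
  sen2 <- sen
  sen2$birth_order_flag <- NA_integer_
  expect_error(subset_effect_models(sen2, "birth_order"),
               "birth_order_flag")
  sen3 <- sen
  sen3$maternal_age[!is.na(sen3$maternal_age)] <- 25
  expect_error(subset_effect_models(sen3, "maternal_age"), "constant")
})

test_that("conception-season sensitivity runs the same machinery on the shifted flag", {
  sen <- make_senescent_table(n_females = 600, seed = 59)
  cs <- conception_sensitivity(sen)
  expect_equal(cs$season_var, "high_stress_conceived")
  expect_equal(cs$interaction_lrt$df, 1L)
  sen0 <- sen
  sen0$high_stress_conceived <- 0L
  expect_error(conception_sensitivity(sen0), "one")
})

test_that("peak-bin test compares groups with Welch orientation", {
  sen <- make_senescent_table(n_females = 800, seed = 61)
  pt <- peak_probability_test(sen)
  expect_equal(pt$n_high_stress + pt$n_other,
               sum(sen$bin_mid_age == 24))
  ## orientation: other minus high-stress (negative t when HS higher)
  manual <- t.test(sen$reproduced[sen$bin_mid_age == 24 &
                                    sen$high_stress_born == 0],
                   sen$reproduced[sen$bin_mid_age == 24 &
                                    sen$high_stress_born == 1])
  expect_equal(pt$t_statistic, unname(manual$statistic))
  expect_equal(pt$p_value, manual$p.value)
  ## identical outcomes: t = 0, p = 1
  same <- sen[sen$bin_mid_age == 24, ][1:10, ]
  same$reproduced <- 1L
  same$high_stress_born <- rep(c(0L, 1L), 5)
  pt0 <- peak_probability_test(same)
  expect_equal(pt0$t_statistic, 0)
  expect_equal(pt0$p_value, 1)
  ## one group empty
  empty <- sen[sen$bin_mid_age == 24 & sen$high_stress_born == 0, ]
  expect_error(peak_probability_test(empty), "per season group")
})
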