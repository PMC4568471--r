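test_that("empty and invalid configurations are handled", {
  cfg <- sim_config(n_females = 0)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop), 0L)
  expect_setequal(names(pop),
                  c("id", "birth_year", "birth_month", "region", "mother_id",
                    "birth_order_flag", "maternal_age", "last_seen_age",
                    "censored_flag", "calving_ages"))
  expect_error(sim_config(thresholds = c(24, 15)), "T1 < T2")
  expect_error(sim_config(peak_prob = c(high_stress = 1.2, other = 0.3)),
               "probabilities")
  expect_error(sim_config(sd_id = -1), "non-negative")
  expect_error(sim_config(gestation_months = 0), "gestation")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_females = 120, seed = 7)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  attr(p1, "truth") <- attr(p2, "truth") <- NULL
  expect_identical(p1, p2)
  g1 <- simulate_gcm(gcm_sim_config(seed = 7))
  g2 <- simulate_gcm(gcm_sim_config(seed = 7))
  expect_identical(g1, g2)
  ## different seed gives different draws
  p3 <- simulate_population(sim_config(n_females = 120, seed = 8))
  expect_false(identical(p1$birth_month, p3$birth_month))
})

test_that("true trajectory hits its anchors, is continuous, and declines as configured", {
  cfg <- sim_config()
  T1 <- cfg$thresholds[1]; T2 <- cfg$thresholds[2]
  ## peak anchor by construction
  expect_equal(true_reproduction_probability(cfg, T2, 1), 0.46)
  expect_equal(true_reproduction_probability(cfg, T2, 0), 0.34)
  ## post-peak decline per 3-year bin equals the configured group rates
  expect_equal(true_reproduction_probability(cfg, 27, 1) -
                 true_reproduction_probability(cfg, 24, 1), -0.022,
               tolerance = 1e-12)
  expect_equal(true_reproduction_probability(cfg, 27, 0) -
                 true_reproduction_probability(cfg, 24, 0), -0.0073,
               tolerance = 1e-12)
  ## continuity at both thresholds
  for (tt in c(T1, T2)) for (g in 0:1) {
    expect_equal(true_reproduction_probability(cfg, tt - 1e-9, g),
                 true_reproduction_probability(cfg, tt + 1e-9, g),
                 tolerance = 1e-6)
  }
  ## monotone: non-decreasing on [T1, T2], non-increasing after T2
  ages_up <- seq(T1, T2, by = 0.5)
  ages_dn <- seq(T2, 50, by = 0.5)
  for (g in 0:1) {
    expect_true(all(diff(true_reproduction_probability(cfg, ages_up, g)) >= 0))
    expect_true(all(diff(true_reproduction_probability(cfg, ages_dn, g)) <= 0))
  }
  expect_error(true_reproduction_probability(cfg, 3, 0), "age")
})

test_that("equalised groups produce indistinguishable post-peak rates", {
  cfg <- sim_config(n_females = 5000, seed = 1,
                    peak_prob = c(high_stress = 0.34, other = 0.34),
                    post_peak_decline = c(high_stress = 0.0073,
                                          other = 0.0073))
  pop <- simulate_population(cfg)
  bins <- attach_covariates(build_observation_bins(pop), pop)
  post <- bins[bins$bin_mid_age >= 24, ]
  m1 <- mean(post$reproduced[post$high_stress_born == 1])
  m0 <- mean(post$reproduced[post$high_stress_born == 0])
  se <- sqrt(m1 * (1 - m1) / sum(post$high_stress_born == 1) +
               m0 * (1 - m0) / sum(post$high_stress_born == 0))
  expect_lt(abs(m1 - m0), 2 * se)
})

test_that("per-bin reproduction frequency converges to the true trajectory", {
  ## no-attrition configuration so every bin is fully observed
  cfg <- sim_config(n_females = 20000, hazard = c(0, 0, 0),
                    study_end_year = 2100, max_age = 50, seed = 9)
  pop <- simulate_population(cfg)
  bins <- attach_covariates(build_observation_bins(pop), pop)
  for (g in 0:1) {
    sel <- bins$high_stress_born == g & bins$bin_start_age <= 47
    emp <- tapply(bins$reproduced[sel], bins$bin_mid_age[sel], mean)
    tru <- true_reproduction_probability(cfg, as.numeric(names(emp)), g)
    expect_lt(max(abs(emp - tru)), 0.02)
  }
})

test_that("life-history invariants hold: calving bounds and refractory gaps", {
  cfg <- sim_config(n_females = 800, seed = 13)
  pop <- simulate_population(cfg)
  refract <- cfg$gestation_months / 12 + 1
  for (i in seq_len(nrow(pop))) {
    a <- pop$calving_ages[[i]]
    if (!length(a)) next
    expect_true(all(a >= cfg$min_reproduction_age))
    expect_true(all(a <= pop$last_seen_age[i]))
    if (length(a) > 1) expect_true(all(diff(a) >= refract - 1e-3))
  }
  ## censoring flag consistent with study end
  age_at_end <- pmin(cfg$study_end_year - pop$birth_year, cfg$max_age)
  expect_true(all(pop$last_seen_age[pop$censored_flag == 0] <=
                    pmax(age_at_end[pop$censored_flag == 0],
                         cfg$min_reproduction_age) + 1e-9))
})

test_that("attrition matches the calibrated population profile", {
  cfg <- sim_config(n_females = 1078, seed = 42)
  pop <- simulate_population(cfg)
  bins <- attach_covariates(build_observation_bins(pop), pop)
  sen <- senescent_subset(bins)
  ## anchors: ~455 females reach the senescent phase, ~2,059 post-peak
  ## rows, ~38 females reach the 47-49 bin (generous Monte-Carlo bands)
  expect_gt(length(unique(sen$id)), 395)
  expect_lt(length(unique(sen$id)), 515)
  expect_gt(nrow(sen), 1750)
  expect_lt(nrow(sen), 2450)
  n_last <- sum(bins$bin_start_age == 47)
  expect_gt(n_last, 15)
  expect_lt(n_last, 65)
})

test_that("hormone simulator respects its configuration", {
  ## full grid with fixed seed
  g <- simulate_gcm(gcm_sim_config(seed = 5))
  expect_equal(nrow(g), 37L * 12L)
  expect_true(all(g$concentration_ng_g >= 0))
  expect_true(all(g$age >= 17 & g$age <= 55))
  ## optional missingness thins towards the field sample count
  gm <- simulate_gcm(gcm_sim_config(missing_fraction = 90 / 444, seed = 5))
  expect_lt(nrow(gm), 444)
  expect_gt(nrow(gm), 270)
  ## noise-free case: every June value exactly the elevated mean
  g0 <- simulate_gcm(gcm_sim_config(sd_within = 0, sd_between_female = 0,
                                    seed = 2))
  expect_true(all(g0$concentration_ng_g[g0$month == 6] == 68.1))
  expect_true(all(g0$concentration_ng_g[g0$month == 1] == 45.6))
  ## null configuration: no elevated months at all
  gn <- simulate_gcm(gcm_sim_config(elevated_months = integer(0),
                                    sd_within = 0, sd_between_female = 0,
                                    seed = 2))
  expect_true(all(gn$concentration_ng_g == 45.6))
  ## grand mean within 3 SEs of the configured mixture mean (pooled over
  ## several independent simulations to keep the check stable)
  pooled <- unlist(lapply(31:35, function(s)
    simulate_gcm(gcm_sim_config(seed = s))$concentration_ng_g))
  mix <- (3 * 68.1 + 9 * 45.6) / 12
  se <- sqrt(10^2 / length(pooled) + 8^2 / (5 * 37))
  expect_lt(abs(mean(pooled) - mix), 3 * se)
  expect_error(gcm_sim_config(sd_within = -1), "non-negative")
})
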