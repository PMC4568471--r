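test_that("birth-season labelling follows the month set", {
  expect_equal(label_birth_season(7, 6:8), 1L)
  expect_equal(label_birth_season(5, 6:8), 0L)
  expect_equal(label_birth_season(1:12, integer(0)), rep(0L, 12))
  expect_equal(label_birth_season(c(6, 8, 9), 6:8), c(1L, 1L, 0L))
  expect_error(label_birth_season(13, 6:8), "month")
  expect_error(label_birth_season(0, 6:8), "month")
})

test_that("conception date arithmetic is exact and invertible", {
  expect_equal(conception_date(1990, 4), data.frame(year = 1988, month = 6))
  expect_equal(conception_date(1990, 3), data.frame(year = 1988, month = 5))
  ## composition with the season flag: born April -> conceived June
  cd <- conception_date(1990, 4)
  expect_equal(label_birth_season(cd$month, 6:8), 1L)
  ## round trip over every month and several gestations
  grid <- expand.grid(y = c(1941, 1999), m = 1:12, g = c(12, 22, 24))
  cd <- conception_date(grid$y, grid$m, grid$g)
  back <- cd$year * 12 + (cd$month - 1) + grid$g
  expect_equal(back %/% 12, grid$y)
  expect_equal(back %% 12 + 1, grid$m)
})

test_that("observation bins follow the 3-year binning rule", {
  rec <- data.frame(id = 1L, birth_year = 1950L, birth_month = 3L,
                    region = factor("R01"), mother_id = NA_integer_,
                    birth_order_flag = NA_integer_,
                    maternal_age = NA_real_, last_seen_age = 20,
                    censored_flag = 1L)
  rec$calving_ages <- list(c(9, 19))
  bins <- build_observation_bins(rec)
  expect_equal(nrow(bins), 6L)          # starts 5, 8, 11, 14, 17, 20
  expect_equal(bins$bin_start_age, seq(5, 20, 3))
  expect_equal(bins$bin_mid_age, bins$bin_start_age + 1)
  expect_equal(bins$reproduced, c(0L, 1L, 0L, 0L, 1L, 0L))
  ## two calvings in one bin still score 1
  rec$calving_ages <- list(c(9, 10))
  bins2 <- build_observation_bins(rec)
  expect_equal(sum(bins2$reproduced), 1L)
  ## boundary: last seen at the first bin start
  rec$last_seen_age <- 5
  rec$calving_ages <- list(numeric(0))
  expect_equal(nrow(build_observation_bins(rec)), 1L)
  ## calving before the observation window errors
  rec$last_seen_age <- 20
  rec$calving_ages <- list(3)
  expect_error(build_observation_bins(rec), "outside")
})

test_that("bin partition covers the observed life with no overlap", {
  pop <- simulate_population(sim_config(n_females = 150, seed = 17))
  bins <- build_observation_bins(pop)
  counts <- table(bins$id)
  expected <- floor((pop$last_seen_age - 5) / 3) + 1
  expect_equal(as.integer(counts[as.character(pop$id)]),
               as.integer(expected), ignore_attr = TRUE)
  ## reproduced bins never exceed calvings; equal without same-bin doubles
  nb <- tapply(bins$reproduced, bins$id, sum)
  ncalv <- vapply(pop$calving_ages, length, integer(1))
  expect_true(all(nb[as.character(pop$id)] <= ncalv))
  same_bin <- vapply(pop$calving_ages, function(a) {
    k <- (floor(a) - 5) %/% 3
    any(duplicated(k))
  }, logical(1))
  expect_equal(as.integer(nb[as.character(pop$id)])[!same_bin],
               ncalv[!same_bin])
})

test_that("covariates are attached with the documented conventions", {
  pop <- simulate_population(sim_config(n_females = 200, seed = 19))
  pop$birth_year[1] <- 1963L
  bins <- build_observation_bins(pop)
  tab <- attach_covariates(bins, pop, season_months = 6:8)
  expect_equal(as.character(tab$birth_decade[tab$id == 1][1]), "1960s")
  ## age scaled by 100
  expect_equal(tab$age_scaled, tab$bin_mid_age / 100)
  row24 <- tab[tab$bin_mid_age == 24, ][1, ]
  expect_equal(row24$age_scaled, 0.24)
  ## decades ordered with the earliest as reference
  expect_equal(levels(tab$birth_decade)[1], "1940s")
  ## season flags agree with direct labelling
  i <- match(tab$id, pop$id)
  expect_equal(tab$high_stress_born, label_birth_season(pop$birth_month[i], 6:8))
  cm <- conception_date(pop$birth_year[i], pop$birth_month[i])$month
  expect_equal(tab$high_stress_conceived, label_birth_season(cm, 6:8))
  ## rows with missing maternal covariates are retained for main models
  expect_true(anyNA(tab$maternal_age))
  ## unscaled option
  tab2 <- attach_covariates(bins, pop, scale_age = FALSE)
  expect_equal(tab2$age_scaled, tab2$bin_mid_age)
})

test_that("senescent subset retains only post-peak bins", {
  pop <- simulate_population(sim_config(n_females = 300, seed = 23))
  tab <- attach_covariates(build_observation_bins(pop), pop)
  sen <- senescent_subset(tab)
  expect_true(all(sen$bin_mid_age >= 24))
  expect_setequal(unique(sen$bin_mid_age),
                  intersect(unique(tab$bin_mid_age),
                            seq(24, max(tab$bin_mid_age), 3)))
  expect_warning(senescent_subset(tab[tab$bin_mid_age < 24, ]), "empty")
})

test_that("individual and bin tables round-trip through CSV", {
  pop <- simulate_population(sim_config(n_females = 60, seed = 29))
  f <- tempfile(fileext = ".csv")
  write_individuals_csv(pop, f)
  back <- read_individuals_csv(f)
  expect_equal(back$id, pop$id)
  expect_equal(back$last_seen_age, pop$last_seen_age)
  expect_equal(back$calving_ages, pop$calving_ages)
  expect_equal(as.character(back$region), as.character(pop$region))
  tab <- attach_covariates(build_observation_bins(pop), pop)
  f2 <- tempfile(fileext = ".csv")
  write_bins_csv(tab, f2)
  back2 <- read_bins_csv(f2)
  expect_equal(back2$reproduced, tab$reproduced)
  expect_equal(back2$age_scaled, tab$age_scaled)
  expect_equal(as.character(back2$birth_decade),
               as.character(tab$birth_decade))
  unlink(c(f, f2))
})
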