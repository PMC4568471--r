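## Synthetic life-history and hormone data with known ground truth.
## The generator emulates a semi-captive timber-elephant study population:
## ~1,078 females born 1941-1999 in 10 regions, observed from the earliest
## reproductive age (5 y) in 3-year bins, with a three-stage age-specific
## reproduction trajectory (low plateau to T1 = 15, rise to a peak at
## T2 = 24, then senescent decline) that differs between females born in
## the physiologically defined high-stress season and the rest.

#' Configuration for the life-history simulator
#'
#' Defaults are the study conditions the package emulates: 1,078 females
#' born 1941-1999 in 10 regions; age thresholds 15 and 24 y; peak
#' three-year reproduction probability 0.46 (high-stress-born) vs 0.34
#' (other-born); post-peak decline of 0.022 vs 0.0073 in probability per
#' 3-year bin; 22-month gestation; inter-birth interval 5.4 +/- 2.7 y;
#' individual logit SD 0.438. Mortality is a 3-piece constant hazard
#' (0.022 /y at ages 5-23, 0.026 /y at 23-38, 0.116 /y after 38) solved in
#' closed form from the population's attrition profile: of 1,078 females,
#' about 455 reach the senescent phase (age bin starting at 23) and about
#' 38 reach the 47-49 bin, given uniform birth years and study end 2000.
#'
#' @param n_females number of females to simulate.
#' @param birth_year_range inclusive integer range of birth years.
#' @param thresholds ages `c(T1, T2)` of the trajectory knots (years).
#' @param p_start three-year reproduction probability at age bin 5-7;
#'   scalar or `c(high_stress, other)`.
#' @param slope_pre logit slope per year below T1; scalar or per-group.
#' @param peak_prob probability at the peak bin (mid-age T2), per group
#'   `c(high_stress, other)`.
#' @param post_peak_decline decline in probability per 3-year bin after the
#'   peak, per group `c(high_stress, other)`.
#' @param season_months calendar months of the high-stress season.
#' @param gestation_months gestation length (months).
#' @param mean_ibi,sd_ibi inter-birth interval distribution (years); draws
#'   are truncated below at the refractory minimum (gestation + 1 y rest).
#' @param n_regions number of regions (random-intercept levels).
#' @param sd_id,sd_region SDs of the individual and region random
#'   intercepts on the logit scale.
#' @param hazard,hazard_breaks piecewise-constant mortality hazard per year
#'   from age 5, changing at the break ages.
#' @param study_end_year females alive in this year are censored.
#' @param max_age observation cap (years); survivors are censored there.
#' @param birth_month_weights optional length-12 positive weights for a
#'   seasonal birth-month distribution (default uniform).
#' @param min_reproduction_age earliest possible calving age (years).
#' @param floor_prob lower floor of the declining trajectory.
#' @param covar_known_from birth year from which maternal covariates
#'   (birth order, maternal age) are recorded; earlier records have them
#'   missing, emulating incomplete archival pedigree data.
#' @param seed master seed; all draws derive from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_females = 1078L,
                       birth_year_range = c(1941L, 1999L),
                       thresholds = c(15, 24),
                       p_start = 0.08,
                       slope_pre = 0,
                       peak_prob = c(high_stress = 0.46, other = 0.34),
                       post_peak_decline = c(high_stress = 0.022,
                                             other = 0.0073),
                       season_months = 6:8,
                       gestation_months = 22L,
                       mean_ibi = 5.4, sd_ibi = 2.7,
                       n_regions = 10L,
                       sd_id = 0.438, sd_region = 0.05,
                       hazard = c(0.022, 0.026, 0.116),
                       hazard_breaks = c(23, 38),
                       study_end_year = 2000L,
                       max_age = 55,
                       birth_month_weights = NULL,
                       min_reproduction_age = 5,
                       floor_prob = 0.01,
                       covar_known_from = 1969L,
                       seed = 1L) {
  as_group_pair <- function(x, what) {
    if (length(x) == 1L) x <- c(high_stress = unname(x), other = unname(x))
    if (is.null(names(x)) && length(x) == 2L)
      names(x) <- c("high_stress", "other")
    if (!setequal(names(x), c("high_stress", "other")))
      stop_repsen(what, " must be scalar or named c(high_stress=, other=)")
    x[c("high_stress", "other")]
  }
  cfg <- list(
    n_females = as.integer(n_females),
    birth_year_range = as.integer(birth_year_range),
    thresholds = as.numeric(thresholds),
    p_start = as_group_pair(p_start, "p_start"),
    slope_pre = as_group_pair(slope_pre, "slope_pre"),
    peak_prob = as_group_pair(peak_prob, "peak_prob"),
    post_peak_decline = as_group_pair(post_peak_decline, "post_peak_decline"),
    season_months = as.integer(season_months),
    gestation_months = as.integer(gestation_months),
    mean_ibi = mean_ibi, sd_ibi = sd_ibi,
    n_regions = as.integer(n_regions),
    sd_id = sd_id, sd_region = sd_region,
    hazard = hazard, hazard_breaks = hazard_breaks,
    study_end_year = as.integer(study_end_year),
    max_age = max_age,
    birth_month_weights = birth_month_weights,
    min_reproduction_age = min_reproduction_age,
    floor_prob = floor_prob,
    covar_known_from = as.integer(covar_known_from),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_females < 0L) stop_repsen("n_females must be non-negative")
  if (cfg$thresholds[1] >= cfg$thresholds[2])
    stop_repsen("thresholds must satisfy T1 < T2")
  probs <- c(cfg$p_start, cfg$peak_prob, cfg$floor_prob)
  if (any(probs <= 0 | probs >= 1))
    stop_repsen("probabilities must lie in (0, 1)")
  if (cfg$sd_id < 0 || cfg$sd_region < 0 || cfg$sd_ibi < 0)
    stop_repsen("standard deviations must be non-negative")
  if (cfg$gestation_months <= 0L) stop_repsen("gestation_months must be > 0")
  if (length(cfg$season_months) &&
      !all(cfg$season_months %in% 1:12))
    stop_repsen("season_months must be within 1..12")
  if (any(cfg$hazard < 0)) stop_repsen("hazard must be non-negative")
  if (!is.null(cfg$birth_month_weights) &&
      (length(cfg$birth_month_weights) != 12L ||
       any(cfg$birth_month_weights < 0)))
    stop_repsen("birth_month_weights must be 12 non-negative weights")
  invisible(cfg)
}

#' Ground-truth three-year reproduction probability
#'
#' The conditional (random effects at zero) trajectory used by the
#' simulator: logit-linear with slope `slope_pre` from `p_start` up to the
#' first threshold, logit-linear rise reaching `peak_prob` at the second
#' threshold, then a linear decline on the probability scale of
#' `post_peak_decline` per 3-year bin, floored at `floor_prob`. The curve
#' is continuous in age.
#'
#' @param cfg a [sim_config()].
#' @param age age in years (vectorised); must be at least the minimum
#'   reproductive age (5).
#' @param high_stress_born logical or 0/1 flag (vectorised) selecting the
#'   birth-season group.
#' @return probability of reproducing at least once in the 3-year bin
#'   centred on `age`.
#' @export
true_reproduction_probability <- function(cfg, age, high_stress_born) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(age < cfg$min_reproduction_age))
    stop_repsen("age must be >= ", cfg$min_reproduction_age)
  grp <- ifelse(as.logical(high_stress_born), "high_stress", "other")
  n <- max(length(age), length(grp))
  age <- rep_len(age, n)
  grp <- rep_len(grp, n)
  T1 <- cfg$thresholds[1]
  T2 <- cfg$thresholds[2]
  p0 <- cfg$p_start[grp]
  s0 <- cfg$slope_pre[grp]
  pk <- cfg$peak_prob[grp]
  dec <- cfg$post_peak_decline[grp]
  lp_T1 <- logit(p0) + s0 * (T1 - cfg$min_reproduction_age)
  rise <- (logit(pk) - lp_T1) / (T2 - T1)
  p <- numeric(n)
  pre <- age <= T1
  mid <- age > T1 & age <= T2
  post <- age > T2
  p[pre] <- invlogit(logit(p0[pre]) +
                       s0[pre] * (age[pre] - cfg$min_reproduction_age))
  p[mid] <- invlogit(lp_T1[mid] + rise[mid] * (age[mid] - T1))
  p[post] <- pmax(pk[post] - dec[post] * (age[post] - T2) / 3, cfg$floor_prob)
  p
}

## sample death ages (from age 5) under the piecewise-constant hazard
sample_death_age <- function(n, hazard, breaks, from = 5) {
  e <- stats::rexp(n)
  edges <- c(from, breaks, Inf)
  death <- rep(NA_real_, n)
  remaining <- e
  for (k in seq_along(hazard)) {
    dur <- edges[k + 1] - edges[k]
    cum <- hazard[k] * dur
    hit <- is.na(death) & (remaining < cum | k == length(hazard))
    death[hit] <- edges[k] + remaining[hit] / max(hazard[k], 1e-12)
    remaining <- remaining - cum
  }
  death
}

## truncated-normal draw (lower truncation) by inverse CDF
rtnorm_lower <- function(n, mean, sd, lower) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(pmin(u, 1 - 1e-12), mean, sd)
}

#' Simulate a population of female life histories
#'
#' Each female receives a birth date, region, and Gaussian logit random
#' intercepts (individual and region). Her reproduction is drawn
#' bin-by-bin: for every 3-year age bin started before her last-seen age, a
#' Bernoulli draw with probability
#' `invlogit(logit(p_true(bin mid)) + b_id + b_region)` decides whether she
#' calves in that bin; a successful draw is dated inside the bin using an
#' inter-birth-interval draw (truncated normal, floored at the refractory
#' minimum of gestation + 1 year) so that consecutive calvings always
#' respect the refractory gap. Deaths follow the configured piecewise
#' hazard; survivors are censored at the study end year (or the maximum
#' observed age).
#'
#' @param cfg a [sim_config()].
#' @return a data frame with one row per female: `id`, `birth_year`,
#'   `birth_month`, `region`, `mother_id`, `birth_order_flag`,
#'   `maternal_age`, `last_seen_age`, `censored_flag` and the list-column
#'   `calving_ages`. The ground-truth random intercepts are attached as
#'   attribute `"truth"`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  region_levels <- sprintf("R%02d", seq_len(cfg$n_regions))
  empty <- data.frame(
    id = integer(0), birth_year = integer(0), birth_month = integer(0),
    region = factor(character(0), levels = region_levels),
    mother_id = integer(0), birth_order_flag = integer(0),
    maternal_age = numeric(0), last_seen_age = numeric(0),
    censored_flag = integer(0), stringsAsFactors = FALSE)
  empty$calving_ages <- list()
  if (cfg$n_females == 0L) return(empty)

  set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_females
  birth_year <- sample(seq(cfg$birth_year_range[1], cfg$birth_year_range[2]),
                       n, replace = TRUE)
  bw <- cfg$birth_month_weights %||% rep(1, 12)
  birth_month <- sample(1:12, n, replace = TRUE, prob = bw)
  region <- factor(sample(region_levels, n, replace = TRUE),
                   levels = region_levels)
  b_id <- stats::rnorm(n, 0, cfg$sd_id)
  b_region <- stats::rnorm(cfg$n_regions, 0, cfg$sd_region)
  names(b_region) <- region_levels

  death_age <- sample_death_age(n, cfg$hazard, cfg$hazard_breaks,
                                from = cfg$min_reproduction_age)
  censor_age <- pmin(cfg$study_end_year - birth_year, cfg$max_age)
  ## females must be observed at least to the minimum reproductive age
  censor_age <- pmax(censor_age, cfg$min_reproduction_age)
  last_seen <- round(pmin(death_age, censor_age), 3)
  censored <- as.integer(censor_age <= death_age)

  hs_born <- as.integer(birth_month %in% cfg$season_months)
  refract <- cfg$gestation_months / 12 + 1

  calvings <- vector("list", n)
  start0 <- cfg$min_reproduction_age
  for (i in seq_len(n)) {
    starts <- seq(start0, last_seen[i], by = 3)
    if (!length(starts)) { calvings[[i]] <- numeric(0); next }
    mids <- starts + 1
    p_true <- true_reproduction_probability(cfg, mids, hs_born[i])
    p_bin <- invlogit(logit(p_true) + b_id[i] + b_region[as.character(region[i])])
    rep_draw <- stats::rbinom(length(starts), 1L, p_bin)
    ages <- numeric(0)
    prev <- -Inf
    for (k in seq_along(starts)) {
      if (rep_draw[k] == 0L) next
      lo <- max(starts[k], prev + refract)
      hi <- min(starts[k] + 3 - 1e-3, last_seen[i])
      if (lo > hi) next  # died early in the bin or refractory edge
      if (is.infinite(prev)) {
        a <- stats::runif(1, lo, hi)
      } else {
        gap <- rtnorm_lower(1, cfg$mean_ibi, cfg$sd_ibi, refract)
        a <- min(max(prev + gap, lo), hi)
      }
      a <- round(a, 3)
      ages <- c(ages, a)
      prev <- a
    }
    calvings[[i]] <- ages
  }

  known <- birth_year >= cfg$covar_known_from
  birth_order_flag <- ifelse(known, stats::rbinom(n, 1L, 0.7), NA_integer_)
  maternal_age <- ifelse(known, round(rtnorm_lower(n, 24, 7, 10), 1),
                         NA_real_)
  mother_id <- ifelse(known, n + seq_len(n), NA_integer_)

  out <- data.frame(
    id = seq_len(n), birth_year = birth_year, birth_month = birth_month,
    region = region, mother_id = as.integer(mother_id),
    birth_order_flag = as.integer(birth_order_flag),
    maternal_age = maternal_age, last_seen_age = last_seen,
    censored_flag = censored, stringsAsFactors = FALSE)
  out$calving_ages <- calvings
  attr(out, "truth") <- list(b_id = b_id, b_region = b_region,
                             high_stress_born = hs_born)
  out
}

#' Configuration for the hormone-sampling simulator
#'
#' Defaults emulate a year of monthly faecal glucocorticoid metabolite
#' (GCM) sampling of 37 non-pregnant reproductive-aged (17-55 y) females:
#' baseline month mean 45.6 ng/g dry faeces, elevated to 68.1 ng/g in
#' June-August. The within-female monthly SD of 10 ng/g reproduces the
#' scale of month-to-month variation implied by the strong month effect in
#' such data (see the package vignette); the between-female SD of 8 ng/g
#' gives a realistic intra-class correlation around 0.4.
#'
#' @param n_females number of sampled females.
#' @param months calendar months sampled (default all 12).
#' @param baseline_mean,elevated_mean month means in ng/g dry faeces.
#' @param elevated_months months at `elevated_mean` (default June-August).
#' @param sd_within within-female monthly SD (ng/g).
#' @param sd_between_female SD of the female-level intercept (ng/g).
#' @param age_range sampled females' age range (years).
#' @param missing_fraction fraction of female-months lost (set to ~0.2 to
#'   mimic field sample loss, e.g. 354 usable of 444 scheduled samples).
#' @param seed master seed.
#' @return a list of class `gcm_sim_config`.
#' @export
gcm_sim_config <- function(n_females = 37L, months = 1:12,
                           baseline_mean = 45.6, elevated_months = 6:8,
                           elevated_mean = 68.1, sd_within = 10,
                           sd_between_female = 8, age_range = c(17, 55),
                           missing_fraction = 0, seed = 1L) {
  cfg <- list(n_females = as.integer(n_females), months = as.integer(months),
              baseline_mean = baseline_mean,
              elevated_months = as.integer(elevated_months),
              elevated_mean = elevated_mean, sd_within = sd_within,
              sd_between_female = sd_between_female,
              age_range = age_range,
              missing_fraction = missing_fraction, seed = as.integer(seed))
  if (cfg$baseline_mean <= 0 || cfg$elevated_mean <= 0)
    stop_repsen("month means must be positive")
  if (cfg$sd_within < 0 || cfg$sd_between_female < 0)
    stop_repsen("standard deviations must be non-negative")
  if (length(cfg$elevated_months) && !all(cfg$elevated_months %in% 1:12))
    stop_repsen("elevated_months must be within 1..12")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1)
    stop_repsen("missing_fraction must be in [0, 1)")
  structure(cfg, class = "gcm_sim_config")
}

#' Simulate monthly glucocorticoid metabolite samples
#'
#' Concentration = month mean + female intercept + within-female noise,
#' truncated at zero. One row per female x month (minus any configured
#' missingness).
#'
#' @param cfg a [gcm_sim_config()].
#' @return data frame with `female_id`, `age`, `month`,
#'   `concentration_ng_g`.
#' @export
simulate_gcm <- function(cfg) {
  stopifnot(inherits(cfg, "gcm_sim_config"))
  set.seed(derive_seed(cfg$seed, 2L))
  ids <- sprintf("F%02d", seq_len(cfg$n_females))
  ages <- round(stats::runif(cfg$n_females, cfg$age_range[1],
                             cfg$age_range[2]), 1)
  b_f <- stats::rnorm(cfg$n_females, 0, cfg$sd_between_female)
  grid <- expand.grid(female = seq_len(cfg$n_females), month = cfg$months,
                      KEEP.OUT.ATTRS = FALSE)
  month_mean <- ifelse(grid$month %in% cfg$elevated_months,
                       cfg$elevated_mean, cfg$baseline_mean)
  conc <- month_mean + b_f[grid$female] +
    stats::rnorm(nrow(grid), 0, cfg$sd_within)
  out <- data.frame(female_id = ids[grid$female], age = ages[grid$female],
                    month = as.integer(grid$month),
                    concentration_ng_g = round(pmax(conc, 0), 3),
                    stringsAsFactors = FALSE)
  if (cfg$missing_fraction > 0) {
    keep <- stats::runif(nrow(out)) >= cfg$missing_fraction
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out[order(out$female_id, out$month), , drop = FALSE]
}
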