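## From individual life histories to the 3-year observation-bin modelling
## table: season flags, bin construction, covariates, senescent subset.

#' High-stress season labelling of a birth month
#'
#' @param birth_month calendar month 1-12 (vectorised).
#' @param season_months integer months making up the high-stress season
#'   (possibly empty).
#' @return integer flag, 1 when the month falls in the season.
#' @export
label_birth_season <- function(birth_month, season_months = 6:8) {
  birth_month <- check_month(birth_month)
  as.integer(birth_month %in% season_months)
}

#' Conception date from a birth date
#'
#' Backs up a calendar (year, month) by the gestation length. Adding the
#' gestation back recovers the birth date exactly.
#'
#' @param birth_year,birth_month birth date (month 1-12; vectorised).
#' @param gestation_months gestation length in months (default 22).
#' @return data frame with columns `year` and `month`.
#' @export
conception_date <- function(birth_year, birth_month, gestation_months = 22L) {
  birth_month <- check_month(birth_month)
  tot <- (birth_year * 12L + (birth_month - 1L)) - as.integer(gestation_months)
  data.frame(year = tot %/% 12L, month = tot %% 12L + 1L)
}

#' Build the 3-year observation-bin table
#'
#' One row per female per 3-year age bin from the earliest reproductive age
#' onward. A bin is opened whenever its start age is at most the female's
#' last-seen age (partial final bins are retained; censoring is controlled
#' downstream through the censored flag and age-at-last-sighting
#' covariates). A bin scores `reproduced = 1` when at least one calving age
#' falls inside it -- two calvings in one bin still score 1. Bin membership
#' uses completed integer age, so bins are the closed integer ranges
#' `[5+3k, 7+3k]`.
#'
#' @param records individual table as from [simulate_population()] (or
#'   [read_individuals_csv()]).
#' @param bin_width bin width in years (default 3).
#' @param start_age first bin start age (default 5).
#' @param drop_partial drop final bins that were not observed for their
#'   full width (the female's first bin is always kept). The default
#'   (FALSE) keeps partial bins and relies on the censored-status and
#'   age-at-last-sighting covariates downstream; TRUE is useful for
#'   trajectory-recovery simulations where terminal exposure clipping
#'   would masquerade as late-life nonlinearity.
#' @return data frame with `id`, `bin_start_age`, `bin_mid_age`,
#'   `reproduced`.
#' @export
build_observation_bins <- function(records, bin_width = 3, start_age = 5,
                                   drop_partial = FALSE) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) {
    return(data.frame(id = integer(0), bin_start_age = numeric(0),
                      bin_mid_age = numeric(0), reproduced = integer(0)))
  }
  calv <- records$calving_ages
  n_bins <- pmax(floor((records$last_seen_age - start_age) / bin_width), 0) + 1
  id <- rep(records$id, n_bins)
  bin_index <- sequence(n_bins) - 1L
  bin_start <- start_age + bin_width * bin_index
  n_calv <- lengths(calv)
  ages <- unlist(calv, use.names = FALSE)
  if (length(ages)) {
    cid <- rep(records$id, n_calv)
    cls <- rep(records$last_seen_age, n_calv)
    bad <- ages < start_age | ages > cls + bin_width
    if (any(bad))
      stop_repsen("calving age outside any observation bin for id ",
                  paste(unique(cid[bad]), collapse = ", "))
    ck <- (floor(ages) - start_age) %/% bin_width
    hit <- unique(paste(cid, ck))
    reproduced <- as.integer(paste(id, bin_index) %in% hit)
  } else {
    reproduced <- integer(length(id))
  }
  out <- data.frame(id = id, bin_start_age = bin_start,
                    bin_mid_age = bin_start + 1, reproduced = reproduced)
  if (drop_partial) {
    full_ls <- rep(records$last_seen_age, n_bins)
    out <- out[out$bin_start_age + bin_width <= full_ls |
                 out$bin_start_age == start_age, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Attach modelling covariates to the observation-bin table
#'
#' Adds the birth-season and conception-season flags, birth decade (first
#' decade as reference level), censoring flag, scaled age terms and the
#' age-at-last-sighting linear and quadratic terms. Rows whose required
#' covariates are missing are dropped with a message; optional maternal
#' covariates (birth order, maternal age) are carried through as-is and
#' only restrict the dedicated subset analyses.
#'
#' @param bins output of [build_observation_bins()].
#' @param records the individual table the bins were built from.
#' @param season_months high-stress season months (from
#'   [high_stress_season()] or fixed).
#' @param gestation_months gestation used for the conception-season flag.
#' @param scale_age divide age and last-sighting age by 100 (the scaling
#'   used in the threshold-search models). The unscaled `bin_mid_age` is
#'   always kept.
#' @return modelling table: one row per female-bin with columns
#'   `reproduced`, `age_scaled`, `high_stress_born`,
#'   `high_stress_conceived`, `birth_decade`, `censored_flag`, `last_age`,
#'   `last_age_sq`, `region`, `birth_order_flag`, `maternal_age`, plus ids
#'   and raw ages.
#' @export
attach_covariates <- function(bins, records, season_months = 6:8,
                              gestation_months = 22L, scale_age = TRUE) {
  stopifnot(is.data.frame(bins), is.data.frame(records))
  idx <- match(bins$id, records$id)
  if (anyNA(idx)) stop_repsen("bins contain ids absent from records")
  rec <- records[idx, , drop = FALSE]
  conc <- conception_date(rec$birth_year, rec$birth_month, gestation_months)
  decade <- 10L * (rec$birth_year %/% 10L)
  decade_levels <- sort(unique(10L * (records$birth_year %/% 10L)))
  scale_div <- if (scale_age) 100 else 1
  out <- data.frame(
    id = bins$id,
    bin_start_age = bins$bin_start_age,
    bin_mid_age = bins$bin_mid_age,
    reproduced = bins$reproduced,
    age_scaled = bins$bin_mid_age / scale_div,
    high_stress_born = label_birth_season(rec$birth_month, season_months),
    high_stress_conceived = label_birth_season(conc$month, season_months),
    birth_decade = factor(paste0(decade, "s"),
                          levels = paste0(decade_levels, "s")),
    censored_flag = rec$censored_flag,
    last_age = rec$last_seen_age / scale_div,
    last_age_sq = (rec$last_seen_age / scale_div)^2,
    region = rec$region,
    birth_order_flag = rec$birth_order_flag,
    maternal_age = rec$maternal_age,
    stringsAsFactors = FALSE)
  required <- c("reproduced", "age_scaled", "high_stress_born",
                "birth_decade", "censored_flag", "last_age", "region")
  complete <- stats::complete.cases(out[required])
  if (any(!complete)) {
    message(sum(!complete), " bin row(s) dropped for missing required covariates")
    out <- out[complete, , drop = FALSE]
  }
  attr(out, "scale_age") <- scale_age
  attr(out, "season_months") <- as.integer(season_months)
  rownames(out) <- NULL
  out
}

#' Restrict the modelling table to the senescent phase
#'
#' Keeps the bins from the post-peak (declining) phase of the trajectory,
#' by default all bins with mid-age at least 24.
#'
#' @param table modelling table from [attach_covariates()].
#' @param start_bin_mid first retained bin mid-age.
#' @return the filtered table; a warning is raised when it is empty.
#' @export
senescent_subset <- function(table, start_bin_mid = 24) {
  out <- table[table$bin_mid_age >= start_bin_mid, , drop = FALSE]
  if (!nrow(out)) warning("senescent subset is empty")
  attr(out, "scale_age") <- attr(table, "scale_age")
  attr(out, "season_months") <- attr(table, "season_months")
  attr(out, "start_bin_mid") <- start_bin_mid
  rownames(out) <- NULL
  out
}
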