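## Post-peak (senescent phase) analyses: the birth-season x age interaction
## on the probability of reproduction, maternal-confounder subsets, the
## conception-season sensitivity analysis, probability-scale decline rates
## and the peak-bin comparison.

senescence_formula <- function(season_var, age_var = "age_c",
                               extra = character(0),
                               random_terms = c("id", "region"),
                               interaction = TRUE, with_decade = TRUE) {
  age_part <- if (interaction) paste(season_var, "*", age_var)
              else paste(season_var, "+", age_var)
  stats::as.formula(paste(
    "reproduced ~", age_part, "+",
    paste(c(extra, "last_age", "last_age_sq", "censored_flag",
            if (with_decade) "birth_decade"), collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random_terms), collapse = " + ")))
}

prepare_senescence_data <- function(table, season_var, peak_mid, scale_age) {
  if (!nrow(table)) stop_repsen("senescent table is empty")
  if (any(table$bin_mid_age < peak_mid))
    stop_repsen("table contains pre-senescent bins (mid-age < ", peak_mid,
                "); apply senescent_subset() first")
  v <- table[[season_var]]
  if (is.null(v)) stop_repsen("column ", season_var, " missing")
  if (length(unique(v[!is.na(v)])) < 2L)
    stop_repsen("only one ", season_var,
                " group present; interaction inestimable")
  d <- table
  ## age centred at the peak so the season main effect is the peak-height
  ## contrast; optionally on the /100 scale used in the threshold search
  d$age_c <- (d$bin_mid_age - peak_mid) / (if (scale_age) 100 else 1)
  d$birth_decade <- droplevels(factor(d$birth_decade))
  d
}

#' Senescent-phase model with the birth-season x age interaction
#'
#' Fits the binomial GLMM of the 3-year reproduction flag on the
#' high-stress birth-season flag, age (centred at the peak bin mid-age),
#' their interaction, the age-at-last-sighting linear and quadratic terms,
#' the censored flag and birth decade, with individual and region random
#' intercepts. The interaction is tested by a likelihood-ratio test
#' against the model without it.
#'
#' @param table senescent-phase modelling table (see [senescent_subset()]).
#' @param peak_mid peak bin mid-age at which age is centred (default 24);
#'   also the earliest mid-age allowed in `table`.
#' @param scale_age put the centred age on the /100 scale (default FALSE:
#'   age in years, coefficients per year).
#' @param season_var season flag column (`"high_stress_born"` or
#'   `"high_stress_conceived"`).
#' @param control a [glmm_control()].
#' @return list of class `senescence_fit`: `fit` (full model),
#'   `fit_no_interaction`, `interaction_lrt`, `peak_mid`, `season_var`.
#' @export
fit_senescence_models <- function(table, peak_mid = 24, scale_age = FALSE,
                                  season_var = "high_stress_born",
                                  control = glmm_control()) {
  d <- prepare_senescence_data(table, season_var, peak_mid, scale_age)
  wd <- nlevels(d$birth_decade) > 1L
  full <- fit_glmm(senescence_formula(season_var, with_decade = wd), d,
                   "binomial", control = control)
  reduced <- fit_glmm(senescence_formula(season_var, interaction = FALSE,
                                         with_decade = wd),
                      d, "binomial",
                      start = list(theta = full$theta), control = control)
  structure(list(fit = full, fit_no_interaction = reduced,
                 interaction_lrt = likelihood_ratio_test(full, reduced),
                 peak_mid = peak_mid, scale_age = scale_age,
                 season_var = season_var, data = d),
            class = "senescence_fit")
}

#' @export
print.senescence_fit <- function(x, ...) {
  cat(sprintf("Senescent-phase model (age >= %g, season flag: %s)\n",
              x$peak_mid, x$season_var))
  print(x$fit)
  cat(sprintf("%s x age interaction: chi^2(%d) = %.3f, p = %.4g\n",
              x$season_var, x$interaction_lrt$df,
              x$interaction_lrt$chi_square, x$interaction_lrt$p_value))
  invisible(x)
}

#' Maternal-covariate subset models (birth order / maternal age)
#'
#' Repeats the senescent-phase analysis on the subset of females with the
#' requested maternal covariate recorded, adding that covariate to the
#' model. Reports the LRT for the covariate itself and for its interaction
#' with the birth-season flag, plus the season x age interaction LRT on
#' the subset.
#'
#' @param table senescent-phase modelling table.
#' @param mode `"birth_order"` or `"maternal_age"`.
#' @param peak_mid,scale_age,control as in [fit_senescence_models()].
#' @return list of class `subset_effect_fit` with `fit` (model including
#'   the covariate), `covariate_lrt`, `covariate_season_lrt`,
#'   `interaction_lrt` (season x age), `n_females`, `n_rows`.
#' @export
subset_effect_models <- function(table, mode = c("birth_order",
                                                 "maternal_age"),
                                 peak_mid = 24, scale_age = FALSE,
                                 control = glmm_control()) {
  mode <- match.arg(mode)
  covar <- switch(mode, birth_order = "birth_order_flag",
                  maternal_age = "maternal_age")
  if (!covar %in% names(table)) stop_repsen("column ", covar, " missing")
  sub <- table[!is.na(table[[covar]]), , drop = FALSE]
  if (!nrow(sub))
    stop_repsen("covariate ", covar, " is missing for every row")
  if (length(unique(sub[[covar]])) < 2L)
    stop_repsen("covariate ", covar, " is constant in the subset")
  d <- prepare_senescence_data(sub, "high_stress_born", peak_mid, scale_age)
  wd <- nlevels(d$birth_decade) > 1L

  with_cov <- fit_glmm(
    senescence_formula("high_stress_born", extra = covar, with_decade = wd),
    d, "binomial", control = control)
  warm <- list(theta = with_cov$theta)
  without_cov <- fit_glmm(
    senescence_formula("high_stress_born", with_decade = wd), d,
    "binomial", start = warm, control = control)
  with_cov_season <- fit_glmm(
    senescence_formula("high_stress_born",
                       extra = c(covar, paste0("high_stress_born:", covar)),
                       with_decade = wd),
    d, "binomial", start = warm, control = control)
  no_inter <- fit_glmm(
    senescence_formula("high_stress_born", extra = covar,
                       interaction = FALSE, with_decade = wd),
    d, "binomial", start = warm, control = control)

  structure(list(
    mode = mode, covariate = covar, fit = with_cov,
    covariate_lrt = likelihood_ratio_test(with_cov, without_cov),
    covariate_season_lrt = likelihood_ratio_test(with_cov_season, with_cov),
    interaction_lrt = likelihood_ratio_test(with_cov, no_inter),
    n_females = length(unique(d$id)), n_rows = nrow(d)),
    class = "subset_effect_fit")
}

#' Conception-season sensitivity analysis
#'
#' Repeats the senescent-phase interaction analysis with the high-stress
#' conception-season flag (birth month shifted back by the gestation
#' length) in place of the birth-season flag.
#'
#' @param table senescent-phase modelling table (must carry
#'   `high_stress_conceived`).
#' @param peak_mid,scale_age,control as in [fit_senescence_models()].
#' @return the `senescence_fit` for the conception-season flag.
#' @export
conception_sensitivity <- function(table, peak_mid = 24, scale_age = FALSE,
                                   control = glmm_control()) {
  fit_senescence_models(table, peak_mid = peak_mid, scale_age = scale_age,
                        season_var = "high_stress_conceived",
                        control = control)
}

#' Probability-scale decline rates per birth-season group
#'
#' Average decline of the model-predicted probability of reproduction per
#' 3-year step over the post-peak age range, per season group, with
#' random effects at zero. By default the predictions are averaged over
#' the observed covariate rows of the senescent table (standardisation /
#' G-computation), which makes the declines comparable to the marginal
#' age trajectory; `ref_mode = "reference"` instead holds the covariates
#' at fixed reference values (not censored, earliest birth decade,
#' last-sighting age at its subset mean, overridable via `ref`).
#'
#' @param sf a `senescence_fit`.
#' @param from_age,to_age age range (bin mid-ages) over which the decline
#'   is averaged; `to_age` defaults to the oldest observed bin.
#' @param step bin width in years.
#' @param ref_mode `"average"` (default) or `"reference"`.
#' @param ref optional named list overriding reference covariate values
#'   (used with `ref_mode = "reference"`).
#' @return list with per-group mean declines (probability per 3-year bin,
#'   positive = declining) and the underlying predicted trajectories.
#' @export
decline_rates <- function(sf, from_age = NULL, to_age = NULL, step = 3,
                          ref_mode = c("average", "reference"),
                          ref = list()) {
  stopifnot(inherits(sf, "senescence_fit"))
  ref_mode <- match.arg(ref_mode)
  if (length(ref)) ref_mode <- "reference"
  d <- sf$data
  from_age <- from_age %||% sf$peak_mid
  to_age <- to_age %||% max(d$bin_mid_age)
  if (to_age <= from_age) stop_repsen("degenerate age range")
  mids <- seq(from_age, to_age, by = step)
  scale_div <- if (sf$scale_age) 100 else 1
  if (ref_mode == "average") {
    traj <- function(group) {
      vapply(mids, function(a) {
        nd <- d
        nd$age_c <- (a - sf$peak_mid) / scale_div
        nd[[sf$season_var]] <- group
        mean(marginal_predict(sf$fit, nd))
      }, numeric(1))
    }
    p1 <- traj(1L)
    p0 <- traj(0L)
  } else {
    newd <- expand.grid(bin_mid_age = mids, group = c(1L, 0L),
                        KEEP.OUT.ATTRS = FALSE)
    newd$age_c <- (newd$bin_mid_age - sf$peak_mid) / scale_div
    newd[[sf$season_var]] <- newd$group
    newd$censored_flag <- ref$censored_flag %||% 0L
    newd$last_age <- ref$last_age %||% mean(d$last_age)
    newd$last_age_sq <- ref$last_age_sq %||% (newd$last_age^2)
    decs <- levels(droplevels(factor(d$birth_decade)))
    newd$birth_decade <- factor(ref$birth_decade %||% decs[1],
                                levels = decs)
    p <- marginal_predict(sf$fit, newd)
    p1 <- p[newd$group == 1L]
    p0 <- p[newd$group == 0L]
  }
  list(high_stress = mean(-diff(p1)), other = mean(-diff(p0)),
       ages = mids,
       predicted = data.frame(bin_mid_age = mids, high_stress = p1,
                              other = p0))
}

#' Peak-bin comparison of reproduction between season groups
#'
#' Welch two-sample t-test on the binary reproduction outcome in the peak
#' bin, between high-stress-born and other-born females. The statistic is
#' oriented as (other minus high-stress), so a negative t means the
#' high-stress-born group had the higher peak mean.
#'
#' @param table modelling table (any phase; only the peak bin is used).
#' @param peak_bin_mid mid-age of the peak bin (default 24).
#' @param season_var season flag column.
#' @return list with `t_statistic`, `p_value`, group means and standard
#'   errors, group sizes.
#' @export
peak_probability_test <- function(table, peak_bin_mid = 24,
                                  season_var = "high_stress_born") {
  rows <- table[table$bin_mid_age == peak_bin_mid, , drop = FALSE]
  y1 <- rows$reproduced[rows[[season_var]] == 1L]
  y0 <- rows$reproduced[rows[[season_var]] == 0L]
  if (length(y1) < 2L || length(y0) < 2L)
    stop_repsen("need at least 2 observations per season group in the peak bin")
  se <- function(v) stats::sd(v) / sqrt(length(v))
  if (stats::var(y1) + stats::var(y0) == 0) {
    tt <- list(statistic = c(t = 0),
               p.value = if (mean(y0) == mean(y1)) 1 else 0)
  } else {
    tt <- stats::t.test(y0, y1, var.equal = FALSE)
  }
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_high_stress = mean(y1), se_high_stress = se(y1),
       mean_other = mean(y0), se_other = se(y0),
       n_high_stress = length(y1), n_other = length(y0))
}
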