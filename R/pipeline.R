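## End-to-end pipeline: hormone season derivation -> cohort construction ->
## age-trajectory selection -> senescence-phase models -> lifetime models,
## with all stage outputs written as deterministic CSV/JSON files.

#' Serialisable summary of a GLMM fit
#'
#' Mirrors the conventional mixed-model results layout: a fixed-effects
#' table (Estimate, Std. Error, z value, Pr(>|z|)) and a random-effects
#' table (Variance, Std. Dev.), plus fit statistics.
#'
#' @param fit a `glmm_fit`.
#' @return a plain list suitable for JSON serialisation.
#' @export
fit_report <- function(fit) {
  list(family = fit$family,
       fixed_effects = fit$coef_table,
       random_effects = fit$varcomp,
       residual_sd = if (is.na(fit$sigma)) NULL else fit$sigma,
       logLik = fit$logLik, AIC = fit$AIC, k = fit$df,
       n_obs = fit$n_obs, n_groups = as.list(fit$n_groups),
       converged = fit$converged, boundary = fit$boundary)
}

lrt_report <- function(lrt) {
  list(chi_square = lrt$chi_square, df = lrt$df, p_value = lrt$p_value)
}

#' Pipeline configuration
#'
#' Bundles the simulator configurations and analysis options for
#' [run_pipeline()]. All randomness derives from `seed`; two runs with the
#' same configuration produce byte-identical output files.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param sim a [sim_config()]; its seed is re-derived from `seed`.
#' @param gcm a [gcm_sim_config()]; its seed is re-derived from `seed`.
#' @param individuals_csv,gcm_csv optional paths to existing input tables;
#'   when given, simulation of that input is skipped.
#' @param alpha significance level for the elevated-month contrasts.
#' @param baseline_month baseline month of the season derivation.
#' @param grid a [threshold_grid()] for the trajectory search.
#' @param scale_age use the /100 age scaling in the bin-level models.
#' @param senescence_scale_age age scale of the senescent-phase models.
#' @param peak_mid senescent-phase start / centring age; `NULL` (default)
#'   uses the second threshold of the best trajectory model (falling back
#'   to 24 when the best model has none).
#' @param write_files write stage outputs under `out_dir` (disable for
#'   purely in-memory runs).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("repsen_run_"), seed = 1L,
                            sim = sim_config(seed = seed),
                            gcm = gcm_sim_config(seed = seed),
                            individuals_csv = NULL, gcm_csv = NULL,
                            alpha = 0.05, baseline_month = 1L,
                            grid = threshold_grid(),
                            scale_age = TRUE,
                            senescence_scale_age = FALSE,
                            peak_mid = NULL,
                            write_files = TRUE) {
  sim$seed <- derive_seed(seed, 11L)
  gcm$seed <- derive_seed(seed, 12L)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 gcm = gcm, individuals_csv = individuals_csv,
                 gcm_csv = gcm_csv, alpha = alpha,
                 baseline_month = as.integer(baseline_month), grid = grid,
                 scale_age = scale_age,
                 senescence_scale_age = senescence_scale_age,
                 peak_mid = peak_mid, write_files = write_files),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  strip <- config[setdiff(names(config), c("out_dir", "write_files"))]
  writeLines(utils::capture.output(utils::str(strip, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (i) hormone simulation or loading and derivation of
#' the high-stress season plus the season-vs-month model comparison; (ii)
#' life-history simulation or loading and construction of the 3-year
#' observation-bin table with covariates; (iii) age-trajectory model
#' selection over the threshold grid; (iv) senescent-phase interaction,
#' subset and conception-season analyses, decline rates and the peak-bin
#' test; (v) lifetime reproductive success models and the season contrast.
#' Stage outputs are written as CSV/JSON under `config$out_dir` together
#' with a run log carrying the seed and configuration hash.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `season`,
#'   `season_comparison`, `records`, `bins`, `selection`, `senescence`,
#'   `subset_birth_order`, `subset_maternal_age`, `conception`,
#'   `declines`, `peak_test`, `lifetime`, `contrast`, `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- proc.time()[["elapsed"]]
  files <- character(0)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", config_hash(config)),
                 sprintf("package_version: %s",
                         as.character(utils::packageVersion("repsen"))))
  out <- function(name) file.path(config$out_dir, name)
  if (config$write_files && !dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    message(sprintf(...))
  }

  ## stage 1: hormones and season
  gcm_tab <- if (!is.null(config$gcm_csv)) {
    if (!file.exists(config$gcm_csv))
      stop_repsen("hormone input not found: ", config$gcm_csv)
    read_gcm_csv(config$gcm_csv)
  } else {
    simulate_gcm(config$gcm)
  }
  season <- derive_season(gcm_tab, baseline_month = config$baseline_month,
                          alpha = config$alpha)
  if (!length(season$months))
    stop_repsen("no high-stress season detected; cannot label cohorts")
  cmp <- season_vs_month(gcm_tab, season, config$baseline_month)
  note("stage gcm_season: %d samples, season = %s", nrow(gcm_tab),
       paste(season$months, collapse = ","))

  ## stage 2: cohort
  records <- if (!is.null(config$individuals_csv)) {
    if (!file.exists(config$individuals_csv))
      stop_repsen("individual input not found: ", config$individuals_csv)
    read_individuals_csv(config$individuals_csv)
  } else {
    simulate_population(config$sim)
  }
  bins0 <- build_observation_bins(records)
  bins <- attach_covariates(bins0, records,
                            season_months = season$months,
                            gestation_months = config$sim$gestation_months,
                            scale_age = config$scale_age)
  note("stage cohort_builder: %d females, %d bin rows", nrow(records),
       nrow(bins))

  ## stage 3: trajectory selection
  sel <- select_trajectory(bins, config$grid)
  note("stage age_trajectory: best model %s", sel$best)

  ## stage 4: senescence
  peak_mid <- config$peak_mid %||%
    (if (is.finite(sel$best_thresholds[2])) sel$best_thresholds[2] else 24)
  sen_tab <- senescent_subset(bins, start_bin_mid = peak_mid)
  sen <- fit_senescence_models(sen_tab, peak_mid = peak_mid,
                               scale_age = config$senescence_scale_age)
  sub_bo <- tryCatch(subset_effect_models(sen_tab, "birth_order",
                                          peak_mid = peak_mid,
                                          scale_age = config$senescence_scale_age),
                     repsen_error = function(e) e)
  sub_ma <- tryCatch(subset_effect_models(sen_tab, "maternal_age",
                                          peak_mid = peak_mid,
                                          scale_age = config$senescence_scale_age),
                     repsen_error = function(e) e)
  conc <- tryCatch(conception_sensitivity(sen_tab, peak_mid = peak_mid,
                                          scale_age = config$senescence_scale_age),
                   repsen_error = function(e) e)
  declines <- decline_rates(sen)
  peak <- peak_probability_test(bins, peak_bin_mid = peak_mid)
  note("stage senescence: interaction chi^2 = %.3f (p = %.4g)",
       sen$interaction_lrt$chi_square, sen$interaction_lrt$p_value)

  ## stage 5: lifetime
  lt <- build_lifetime_table(records, season_months = season$months)
  lt_fits <- fit_lifetime_models(lt)
  contrast <- season_contrast(lt_fits)
  note("stage lifetime: raw season contrast %+.1f%%",
       contrast$raw_pct_difference)

  if (config$write_files) {
    files <- c(
      individuals = write_individuals_csv(records, out("individuals.csv")),
      gcm = write_gcm_csv(gcm_tab, out("gcm.csv")),
      season = write_json_report(list(
        months = season$months, alpha = season$alpha,
        baseline_month = season$baseline_month,
        month_means = as.list(season$month_means),
        month_test = season$fit$month_test,
        season_vs_month = list(
          aic_month = cmp$aic_month, aic_season = cmp$aic_season,
          lrt = lrt_report(cmp$lrt),
          pct_elevation_fitted = cmp$pct_elevation_fitted,
          pct_elevation_pooled = cmp$pct_elevation_pooled)),
        out("season.json")),
      bins = write_bins_csv(bins, out("bins.csv")),
      selection = write_selection_csv(sel, out("selection.csv")),
      senescence = write_json_report(list(
        peak_mid = peak_mid,
        main = fit_report(sen$fit),
        interaction_lrt = lrt_report(sen$interaction_lrt),
        birth_order_subset = if (inherits(sub_bo, "subset_effect_fit")) list(
          fit = fit_report(sub_bo$fit),
          covariate_lrt = lrt_report(sub_bo$covariate_lrt),
          covariate_season_lrt = lrt_report(sub_bo$covariate_season_lrt),
          interaction_lrt = lrt_report(sub_bo$interaction_lrt)) else
            list(error = conditionMessage(sub_bo)),
        maternal_age_subset = if (inherits(sub_ma, "subset_effect_fit")) list(
          fit = fit_report(sub_ma$fit),
          covariate_lrt = lrt_report(sub_ma$covariate_lrt),
          covariate_season_lrt = lrt_report(sub_ma$covariate_season_lrt),
          interaction_lrt = lrt_report(sub_ma$interaction_lrt)) else
            list(error = conditionMessage(sub_ma)),
        conception = if (inherits(conc, "senescence_fit")) list(
          interaction_lrt = lrt_report(conc$interaction_lrt)) else
            list(error = conditionMessage(conc)),
        decline_per_bin = list(high_stress = declines$high_stress,
                               other = declines$other),
        peak_test = peak),
        out("senescence_report.json")),
      lifetime = write_json_report(list(
        poisson = fit_report(lt_fits$poisson_fit),
        binomial = fit_report(lt_fits$binomial_fit),
        contrast = list(
          mean_calves_high_stress = contrast$mean_calves_high_stress,
          mean_calves_other = contrast$mean_calves_other,
          raw_pct_difference = contrast$raw_pct_difference,
          rate_ratio = contrast$rate_ratio,
          poisson_season_lrt = lrt_report(contrast$poisson_season_lrt),
          binomial_season_lrt = lrt_report(contrast$binomial_season_lrt))),
        out("lifetime_report.json")))
    log_lines <- c(log_lines,
                   sprintf("bins_dropped_rows: %d",
                           nrow(bins0) - nrow(bins)))
    writeLines(log_lines, out("run_log.txt"))
    files <- c(files, log = out("run_log.txt"))
  }
  message(sprintf("pipeline finished in %.1f s",
                  proc.time()[["elapsed"]] - t_start))
  structure(list(season = season, season_comparison = cmp,
                 records = records, bins = bins, selection = sel,
                 senescence = sen, subset_birth_order = sub_bo,
                 subset_maternal_age = sub_ma, conception = conc,
                 declines = declines, peak_test = peak,
                 lifetime = lt_fits, contrast = contrast,
                 peak_mid = peak_mid, files = files,
                 config = config), class = "pipeline_result")
}

#' Plot mean three-yearly reproduction by age and birth-season group
#'
#' Base-graphics summary: per-bin raw means with standard-error whiskers
#' for each birth-season group, optionally overlaid with a fitted model's
#' marginal predictions.
#'
#' @param bins modelling table from [attach_covariates()].
#' @param sf optional `senescence_fit` whose predicted trajectories are
#'   drawn over the senescent phase.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the per-group bin summary table.
#' @export
plot_reproduction_trajectory <- function(bins, sf = NULL, ...) {
  agg <- stats::aggregate(reproduced ~ bin_mid_age + high_stress_born,
                          data = bins,
                          FUN = function(v) c(mean = mean(v),
                                              se = stats::sd(v) / sqrt(length(v))))
  agg <- do.call(data.frame, agg)
  names(agg)[3:4] <- c("mean", "se")
  graphics::plot(agg$bin_mid_age, agg$mean, type = "n",
                 xlab = "age (bin mid, years)",
                 ylab = "P(reproduced in 3-y bin)", ...)
  for (g in c(0, 1)) {
    a <- agg[agg$high_stress_born == g, ]
    col <- if (g == 1) "firebrick" else "steelblue"
    graphics::points(a$bin_mid_age, a$mean, col = col, pch = 19)
    graphics::arrows(a$bin_mid_age, a$mean - a$se, a$bin_mid_age,
                     a$mean + a$se, angle = 90, code = 3, length = 0.02,
                     col = col)
  }
  if (!is.null(sf)) {
    dec <- decline_rates(sf)
    graphics::lines(dec$predicted$bin_mid_age, dec$predicted$high_stress,
                    col = "firebrick")
    graphics::lines(dec$predicted$bin_mid_age, dec$predicted$other,
                    col = "steelblue")
  }
  graphics::legend("topright", legend = c("other-born", "high-stress-born"),
                   col = c("steelblue", "firebrick"), pch = 19, bty = "n")
  invisible(agg)
}
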