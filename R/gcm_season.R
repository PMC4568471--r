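## Monthly glucocorticoid metabolite (GCM) variation and derivation of the
## high-stress season: the maximal run of consecutive calendar months whose
## mean concentration is significantly above a baseline month.

#' Mixed model of GCM concentration on calendar month
#'
#' Gaussian random-intercept model (female as grouping factor) of
#' concentration on a 12-level month factor, fitted by ML. The baseline
#' month is the factor reference level, so coefficients are contrasts
#' against it. A joint Wald test of the month factor (and its F-statistic
#' version) is attached.
#'
#' @param samples GCM table (`female_id`, `month`, `concentration_ng_g`).
#' @param baseline_month reference month (default 1, January).
#' @param log_transform model `log(concentration)` instead of the raw scale.
#' @return a `glmm_fit` with extra fields `month_levels`, `baseline_month`,
#'   `month_test` (list: `chi_square`, `df`, `p_value`, `f_value`).
#' @export
fit_month_model <- function(samples, baseline_month = 1L,
                            log_transform = FALSE) {
  stopifnot(all(c("female_id", "month", "concentration_ng_g") %in%
                  names(samples)))
  samples$month <- check_month(samples$month)
  present <- sort(unique(samples$month))
  if (length(present) < 2L) stop_repsen("need samples from at least 2 months")
  if (length(unique(samples$female_id)) < 2L)
    stop_repsen("need samples from at least 2 females")
  if (!baseline_month %in% present)
    stop_repsen("baseline month ", baseline_month, " absent from data")
  if (length(present) < 12L)
    warning("month(s) with no samples dropped: ",
            paste(setdiff(1:12, present), collapse = ", "))
  d <- data.frame(
    conc = if (log_transform) log(pmax(samples$concentration_ng_g, 1e-6))
           else samples$concentration_ng_g,
    month_f = stats::relevel(factor(samples$month, levels = present),
                             ref = as.character(baseline_month)),
    female_id = factor(samples$female_id))
  fit <- fit_glmm(conc ~ month_f + (1 | female_id), d, "gaussian")
  ## joint Wald test of all month contrasts
  sel <- grep("^month_f", names(fit$coefficients))
  b <- fit$coefficients[sel]
  V <- fit$vcov[sel, sel, drop = FALSE]
  chi <- as.numeric(t(b) %*% solve(V, b))
  df <- length(sel)
  fit$month_levels <- present
  fit$baseline_month <- as.integer(baseline_month)
  fit$month_test <- list(chi_square = chi, df = df,
                         p_value = stats::pchisq(chi, df, lower.tail = FALSE),
                         f_value = chi / df)
  fit
}

## month means implied by the fitted month model (reference + contrasts)
fitted_month_means <- function(fit) {
  base <- fit$coefficients[["(Intercept)"]]
  out <- vapply(fit$month_levels, function(m) {
    if (m == fit$baseline_month) return(base)
    base + fit$coefficients[[paste0("month_f", m)]]
  }, numeric(1))
  names(out) <- fit$month_levels
  out
}

#' Months significantly elevated above the baseline
#'
#' Months whose contrast against the baseline month is positive with
#' two-sided Wald p below `alpha`. No multiple-testing correction is
#' applied across the 11 contrasts (configurable via `alpha`).
#'
#' @param fit result of [fit_month_model()].
#' @param alpha per-contrast significance level.
#' @return integer vector of elevated months (possibly empty).
#' @export
elevated_months <- function(fit, alpha = 0.05) {
  if (is.null(fit$month_levels))
    stop_repsen("fit must come from fit_month_model()")
  tab <- fit$coef_table
  sel <- grepl("^month_f", tab$term)
  months <- as.integer(sub("^month_f", "", tab$term[sel]))
  keep <- tab$estimate[sel] > 0 & tab$p_value[sel] < alpha
  sort(months[keep])
}

#' Derive the high-stress season from a set of elevated months
#'
#' The season is the maximal run of consecutive months (circular across
#' December-January) within the elevated set; ties between equally long
#' runs are broken by the higher mean fitted concentration.
#'
#' @param months integer vector of elevated months (possibly empty).
#' @param month_means optional named vector of month means used for tie
#'   breaking (names "1".."12"); unnamed runs break ties by earliest start.
#' @param alpha,baseline_month metadata recorded in the result.
#' @return a list of class `season_definition` with `months` (in calendar
#'   order along the run), `alpha`, `baseline_month`, `month_means`.
#' @export
high_stress_season <- function(months, month_means = NULL, alpha = 0.05,
                               baseline_month = 1L) {
  months <- sort(unique(as.integer(months)))
  runs <- list()
  if (length(months)) {
    in_set <- 1:12 %in% months
    if (all(in_set)) {
      runs <- list(1:12)
    } else {
      ## walk the circular calendar starting after a gap month
      gap <- which(!in_set)[1]
      order_months <- as.integer(((gap:(gap + 11) - 1) %% 12) + 1)
      cur <- integer(0)
      for (m in order_months) {
        if (in_set[m]) {
          cur <- c(cur, m)
        } else if (length(cur)) {
          runs <- c(runs, list(cur))
          cur <- integer(0)
        }
      }
      if (length(cur)) runs <- c(runs, list(cur))
    }
  }
  best <- integer(0)
  if (length(runs)) {
    lens <- lengths(runs)
    cand <- runs[lens == max(lens)]
    if (length(cand) > 1L && !is.null(month_means)) {
      mm <- vapply(cand, function(r) {
        mean(month_means[as.character(r)], na.rm = TRUE) }, numeric(1))
      cand <- cand[order(-mm)]
    }
    best <- as.integer(cand[[1]])
  }
  structure(list(months = best, alpha = alpha,
                 baseline_month = as.integer(baseline_month),
                 month_means = month_means),
            class = "season_definition")
}

#' Derive the high-stress season directly from hormone samples
#'
#' Convenience wrapper: fits the month model, finds elevated months, and
#' extracts the maximal consecutive run.
#'
#' @inheritParams fit_month_model
#' @param alpha per-contrast significance level.
#' @return a `season_definition` (see [high_stress_season()]) with the
#'   month-model fit attached as `fit`.
#' @export
derive_season <- function(samples, baseline_month = 1L, alpha = 0.05,
                          log_transform = FALSE) {
  fit <- fit_month_model(samples, baseline_month, log_transform)
  mm <- fitted_month_means(fit)
  season <- high_stress_season(elevated_months(fit, alpha), mm,
                               alpha = alpha,
                               baseline_month = baseline_month)
  season$fit <- fit
  season
}

#' @export
print.season_definition <- function(x, ...) {
  cat("High-stress season:",
      if (length(x$months)) paste(month.abb[x$months], collapse = "-")
      else "(none)", "\n")
  invisible(x)
}

#' Compare season (binary) and month (12-level) codings of GCM variation
#'
#' Fits both models with the identical female random intercept on identical
#' rows and reports both AICs and log-likelihoods, the likelihood-ratio
#' test of the month model (larger) against the nested season coding with
#' the parameter-count degrees of freedom, and two versions of the percent
#' elevation of the season over the remaining months (pooled sample means,
#' and unweighted means of fitted month means).
#'
#' @param samples GCM table.
#' @param season a `season_definition` (or integer months).
#' @param baseline_month baseline for the month coding.
#' @return list of class `season_month_comparison`.
#' @export
season_vs_month <- function(samples, season, baseline_month = 1L) {
  months <- if (inherits(season, "season_definition")) season$months
            else as.integer(season)
  if (!length(months)) stop_repsen("season is empty; nothing to compare")
  month_fit <- fit_month_model(samples, baseline_month)
  d <- data.frame(conc = samples$concentration_ng_g,
                  in_season = as.integer(samples$month %in% months),
                  female_id = factor(samples$female_id))
  season_fit <- fit_glmm(conc ~ in_season + (1 | female_id), d, "gaussian")
  lrt <- likelihood_ratio_test(month_fit, season_fit, check_nesting = FALSE)
  mm <- fitted_month_means(month_fit)
  in_s <- as.integer(names(mm)) %in% months
  pct_fitted <- 100 * (mean(mm[in_s]) - mean(mm[!in_s])) / mean(mm[!in_s])
  pooled_in <- mean(samples$concentration_ng_g[samples$month %in% months])
  pooled_out <- mean(samples$concentration_ng_g[!samples$month %in% months])
  structure(list(
    season_months = months,
    aic_month = month_fit$AIC, aic_season = season_fit$AIC,
    loglik_month = month_fit$logLik, loglik_season = season_fit$logLik,
    lrt = lrt,
    season_preferred_by_aic = season_fit$AIC < month_fit$AIC,
    pct_elevation_fitted = pct_fitted,
    pct_elevation_pooled = 100 * (pooled_in - pooled_out) / pooled_out,
    month_fit = month_fit, season_fit = season_fit),
    class = "season_month_comparison")
}

#' @export
print.season_month_comparison <- function(x, ...) {
  cat(sprintf("Season vs month coding of GCM:\n  AIC season %.2f vs month %.2f (%s preferred)\n",
              x$aic_season, x$aic_month,
              if (x$season_preferred_by_aic) "season" else "month"))
  cat(sprintf("  LRT month over season: chi^2(%d) = %.2f, p = %.3g\n",
              x$lrt$df, x$lrt$chi_square, x$lrt$p_value))
  cat(sprintf("  Season elevation: %.1f%% (fitted means), %.1f%% (pooled)\n",
              x$pct_elevation_fitted, x$pct_elevation_pooled))
  invisible(x)
}
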