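## Age-trajectory characterisation: candidate models for the age term
## (null, polynomial, broken-stick with one or two thresholds on a grid),
## all fitted with the same base covariates and random intercepts, ranked
## by AIC.

#' Truncated-line (linear spline) basis for broken-stick age terms
#'
#' Returns `[a, (a - T1)+, (a - T2)+, ...]`, giving a continuous
#' piecewise-linear predictor with a free slope in each segment.
#'
#' @param age numeric age vector (any scale, e.g. years/100).
#' @param thresholds strictly increasing threshold vector on the same
#'   scale as `age` (0, 1 or 2 thresholds).
#' @return matrix with one column per basis term.
#' @export
piecewise_basis <- function(age, thresholds = numeric(0)) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop_repsen("thresholds must be strictly increasing")
  out <- cbind(age)
  for (t in thresholds) out <- cbind(out, pmax(age - t, 0))
  colnames(out) <- c("age", if (length(thresholds))
    paste0("age_over_", seq_along(thresholds)))
  out
}

#' Grid of candidate threshold placements
#'
#' @param single_range ages scanned for the single-threshold models
#'   (default 9 to 45 in steps of 3, i.e. every bin mid-age).
#' @param double_first_range,double_second_range ranges scanned for the
#'   first and second threshold of the two-threshold models.
#' @param min_gap_years minimum distance between the two thresholds (>= 6
#'   keeps at least one full bin strictly between them).
#' @param min_points_per_segment minimum number of observed bin mid-ages
#'   (inclusive) in every segment; applied only when `bin_mids` is given.
#' @param bin_mids observed bin mid-ages, used for the segment-occupancy
#'   constraint.
#' @return list of class `threshold_grid`.
#' @export
threshold_grid <- function(single_range = seq(9, 45, by = 3),
                           double_first_range = seq(12, 39, by = 3),
                           double_second_range = seq(18, 45, by = 3),
                           min_gap_years = 6,
                           min_points_per_segment = 3L,
                           bin_mids = NULL) {
  structure(list(single_range = single_range,
                 double_first_range = double_first_range,
                 double_second_range = double_second_range,
                 min_gap_years = min_gap_years,
                 min_points_per_segment = min_points_per_segment,
                 bin_mids = bin_mids), class = "threshold_grid")
}

#' Enumerate candidate age-trajectory models
#'
#' Candidates are: a null model without age terms; linear, quadratic and
#' cubic age polynomials; every single-threshold broken stick on the grid;
#' and every ordered threshold pair satisfying the minimum-gap rule and
#' (when `bin_mids` is supplied) the per-segment occupancy rule. Order is
#' deterministic.
#'
#' @param grid a [threshold_grid()].
#' @return data frame with `label`, `type`, `t1`, `t2`.
#' @export
enumerate_candidates <- function(grid = threshold_grid()) {
  if (!length(grid$single_range) && !length(grid$double_first_range))
    stop_repsen("empty threshold grid")
  base <- data.frame(label = c("null", "linear", "quadratic", "cubic"),
                     type = c("null", "poly1", "poly2", "poly3"),
                     t1 = NA_real_, t2 = NA_real_,
                     stringsAsFactors = FALSE)
  singles <- data.frame(label = sprintf("thr(%g)", grid$single_range),
                        type = "thr1", t1 = grid$single_range,
                        t2 = NA_real_, stringsAsFactors = FALSE)
  pairs <- expand.grid(t1 = grid$double_first_range,
                       t2 = grid$double_second_range,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$t2 - pairs$t1 >= grid$min_gap_years, , drop = FALSE]
  if (!is.null(grid$bin_mids)) {
    mids <- sort(unique(grid$bin_mids))
    npts <- function(lo, hi) sum(mids >= lo & mids <= hi)
    keep <- mapply(function(a, b) {
      npts(-Inf, a) >= grid$min_points_per_segment &&
        npts(a, b) >= grid$min_points_per_segment &&
        npts(b, Inf) >= grid$min_points_per_segment
    }, pairs$t1, pairs$t2)
    pairs <- pairs[keep, , drop = FALSE]
    keep1 <- vapply(singles$t1, function(a) {
      npts(-Inf, a) >= grid$min_points_per_segment &&
        npts(a, Inf) >= grid$min_points_per_segment
    }, logical(1))
    singles <- singles[keep1, , drop = FALSE]
  }
  pairs <- pairs[order(pairs$t1, pairs$t2), , drop = FALSE]
  doubles <- data.frame(label = sprintf("thr(%g,%g)", pairs$t1, pairs$t2),
                        type = "thr2", t1 = pairs$t1, t2 = pairs$t2,
                        stringsAsFactors = FALSE)
  out <- rbind(base, singles, doubles)
  rownames(out) <- NULL
  out
}

## covariate columns added to the data for one candidate's age terms
candidate_columns <- function(cand, age_years, scale_div) {
  a <- age_years / scale_div
  switch(cand$type,
    null = NULL,
    poly1 = data.frame(age1 = a),
    poly2 = data.frame(age1 = a, age2 = a^2),
    poly3 = data.frame(age1 = a, age2 = a^2, age3 = a^3),
    thr1 = data.frame(age1 = a, age2 = pmax(a - cand$t1 / scale_div, 0)),
    thr2 = data.frame(age1 = a, age2 = pmax(a - cand$t1 / scale_div, 0),
                      age3 = pmax(a - cand$t2 / scale_div, 0)))
}

#' Fit and rank the candidate age-trajectory models
#'
#' Every candidate is fitted as a binomial GLMM for the 3-year reproduction
#' flag with identical base fixed effects (birth-season flag, birth decade,
#' censored flag, last-sighting age and its square) and identical random
#' intercepts (individual and region); candidates differ only in their age
#' terms. Models are ranked by AIC; exact ties (below `1e-6`) go to the
#' model with fewer parameters. Non-converged candidates are recorded but
#' excluded from selection.
#'
#' @param table modelling table from [attach_covariates()].
#' @param grid a [threshold_grid()]; its `bin_mids` default to the observed
#'   mid-ages of `table`.
#' @param base_terms base fixed-effect terms shared by all candidates.
#' @param random_terms grouping factors for the random intercepts.
#' @param control a [glmm_control()].
#' @return list of class `trajectory_selection`: `table` (label,
#'   thresholds, k, logLik, AIC, delta_aic, converged), `best` (label) and
#'   `fits` (the best candidate's `glmm_fit`).
#' @export
select_trajectory <- function(table, grid = NULL,
                              base_terms = c("high_stress_born",
                                             "birth_decade",
                                             "censored_flag", "last_age",
                                             "last_age_sq"),
                              random_terms = c("id", "region"),
                              control = glmm_control()) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  scale_div <- if (isTRUE(attr(table, "scale_age"))) 100 else 1
  if (is.null(grid)) grid <- threshold_grid(bin_mids = table$bin_mid_age)
  if (is.null(grid$bin_mids)) grid$bin_mids <- table$bin_mid_age
  cands <- enumerate_candidates(grid)
  table$birth_decade <- droplevels(factor(table$birth_decade))

  rows <- vector("list", nrow(cands))
  fits <- vector("list", nrow(cands))
  warm <- NULL
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    cols <- candidate_columns(cand, table$bin_mid_age, scale_div)
    d <- table
    age_terms <- character(0)
    if (!is.null(cols)) {
      d <- cbind(table, cols)
      age_terms <- names(cols)
    }
    fml <- stats::as.formula(paste(
      "reproduced ~",
      paste(c(age_terms, base_terms), collapse = " + "), "+",
      paste(sprintf("(1 | %s)", random_terms), collapse = " + ")))
    fit <- tryCatch(
      fit_glmm(fml, d, "binomial", start = list(theta = warm),
               control = control),
      error = function(e) NULL)
    if (!is.null(fit)) warm <- fit$theta
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      label = cand$label, t1 = cand$t1, t2 = cand$t2,
      k = if (is.null(fit)) NA_integer_ else fit$df,
      logLik = if (is.null(fit)) NA_real_ else fit$logLik,
      AIC = if (is.null(fit)) NA_real_ else fit$AIC,
      converged = !is.null(fit) && fit$converged,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$converged & is.finite(tab$AIC)
  if (!any(ok)) stop_repsen("no candidate model converged")
  if (any(!ok))
    warning(sum(!ok), " candidate(s) failed to converge and were excluded")
  ## rank: AIC, exact ties to fewer parameters, then enumeration order
  aic_key <- round(tab$AIC / 1e-6) * 1e-6
  ord <- order(!ok, aic_key, tab$k, seq_len(nrow(tab)))
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  best_i <- ord[1]
  structure(list(table = tab, best = tab$label[1],
                 best_thresholds = c(tab$t1[1], tab$t2[1]),
                 best_fit = fits[[best_i]],
                 scale_div = scale_div),
            class = "trajectory_selection")
}

#' @export
print.trajectory_selection <- function(x, n = 8, ...) {
  cat("Age-trajectory model selection (AIC):\n")
  print(utils::head(x$table, n), row.names = FALSE, digits = 6)
  cat("Best model:", x$best, "\n")
  invisible(x)
}

#' Write the selection table to CSV
#'
#' @param selection a `trajectory_selection`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(selection, path) {
  utils::write.csv(selection$table, path, row.names = FALSE)
  invisible(path)
}
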