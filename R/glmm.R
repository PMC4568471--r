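## Random-intercept GLMM fitting by maximum likelihood with a Laplace
## approximation to the integrated likelihood. Supports binomial(logit),
## poisson(log) and gaussian(identity) families and crossed random
## intercepts. The Laplace objective is maximised jointly over the fixed
## effects and log-SD variance parameters with analytic gradients; the
## random-effect mode is profiled out by penalised IRLS on sparse matrices.

#' Control parameters for the GLMM fitter
#'
#' @param pirls_maxit maximum penalised IRLS iterations for the random-effect
#'   mode search at each objective evaluation.
#' @param pirls_tol convergence tolerance on the relative change of the
#'   penalised log-likelihood within PIRLS.
#' @param outer_maxit maximum iterations of the outer BFGS optimiser over
#'   fixed effects and log standard deviations.
#' @param outer_reltol relative tolerance of the outer optimiser on the
#'   Laplace log-likelihood.
#' @param log_sd_min,log_sd_max box for the log standard deviation of each
#'   variance component; estimates at `log_sd_min` are boundary (zero
#'   variance) fits and are flagged, not errors.
#' @param boundary_tol standard deviations below this are reported as
#'   boundary estimates.
#' @param restarts number of deterministic starting points tried for the
#'   outer optimisation (best final likelihood wins). All starts are fixed so
#'   that refitting identical data is bit-reproducible.
#' @return a list of class `glmm_control`.
#' @export
glmm_control <- function(pirls_maxit = 80L, pirls_tol = 1e-11,
                         outer_maxit = 400L, outer_reltol = 1e-9,
                         log_sd_min = -5, log_sd_max = 4,
                         boundary_tol = 1e-2, restarts = 1L) {
  structure(list(pirls_maxit = pirls_maxit, pirls_tol = pirls_tol,
                 outer_maxit = outer_maxit, outer_reltol = outer_reltol,
                 log_sd_min = log_sd_min, log_sd_max = log_sd_max,
                 boundary_tol = boundary_tol, restarts = restarts),
            class = "glmm_control")
}

split_plus <- function(e) {
  if (is.call(e) && identical(e[[1]], quote(`+`)) && length(e) == 3L) {
    c(split_plus(e[[2]]), split_plus(e[[3]]))
  } else {
    list(e)
  }
}

## Split an lme4-style formula `y ~ x1 + x2 + (1 | g1) + (1 | g2)` into the
## fixed-effect formula and the random-intercept grouping factor names.
parse_glmm_formula <- function(formula) {
  if (length(formula) != 3L) stop_repsen("formula must have a response")
  parts <- split_plus(formula[[3]])
  is_bar <- vapply(parts, function(p) {
    is.call(p) && identical(p[[1]], quote(`(`)) &&
      is.call(p[[2]]) && identical(p[[2]][[1]], quote(`|`))
  }, logical(1))
  groups <- vapply(parts[is_bar], function(p) {
    bar <- p[[2]]
    if (!identical(bar[[2]], 1) && !identical(bar[[2]], quote(`1`)))
      stop_repsen("only random intercepts '(1 | group)' are supported")
    deparse(bar[[3]])
  }, character(1))
  fixed_terms <- parts[!is_bar]
  rhs <- if (length(fixed_terms)) {
    Reduce(function(a, b) call("+", a, b), fixed_terms)
  } else {
    1
  }
  fixed <- stats::as.formula(call("~", formula[[2]], rhs),
                             env = environment(formula))
  list(fixed = fixed, groups = groups)
}

glmm_linkinv <- function(family) {
  switch(family, binomial = stats::plogis, poisson = exp, gaussian = identity)
}

## Build design matrices shared by fit_glmm() and brute_force_loglik().
build_glmm_design <- function(formula, data, family) {
  pf <- parse_glmm_formula(formula)
  mf_formula <- pf$fixed
  if (length(pf$groups)) {
    mf_formula <- stats::update(
      pf$fixed,
      paste("~ . +", paste(pf$groups, collapse = " + ")))
  }
  mf <- stats::model.frame(mf_formula, data, na.action = stats::na.omit,
                           drop.unused.levels = TRUE)
  n_dropped <- length(attr(mf, "na.action"))
  if (nrow(mf) == 0L) stop_repsen("no complete observations to fit")
  y <- stats::model.response(mf)
  if (family == "binomial") {
    if (is.factor(y)) y <- as.numeric(y) - 1
    if (is.logical(y)) y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop_repsen("binomial response must be 0/1")
  }
  fixed_terms <- stats::terms(pf$fixed, data = mf)
  X <- stats::model.matrix(fixed_terms, mf)
  ## deterministically drop aliased columns (first-come kept)
  qrX <- qr(X)
  dropped_cols <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped_cols <- colnames(X)[-keep]
    warning("dropping aliased fixed-effect column(s): ",
            paste(dropped_cols, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  group_factors <- lapply(pf$groups, function(g) droplevels(factor(mf[[g]])))
  names(group_factors) <- pf$groups
  list(y = as.numeric(y), X = X, group_factors = group_factors,
       fixed_terms = fixed_terms, xlevels = stats::.getXlevels(fixed_terms, mf),
       contrasts = attr(X, "contrasts"), n_dropped = n_dropped,
       dropped_cols = dropped_cols, mf = mf)
}

#' Fit a random-intercept GLMM by Laplace-approximate maximum likelihood
#'
#' Fits a generalised linear mixed model with independent Gaussian random
#' intercepts for each grouping factor named in the formula (lme4-style
#' `(1 | group)` terms). The marginal likelihood is integrated over the
#' random effects with a Laplace approximation (exact for the gaussian
#' family) and maximised jointly over the fixed effects and the log standard
#' deviations of the variance components using analytic gradients; the
#' random-effect mode is profiled out by penalised IRLS on sparse matrices.
#' Estimation is by ML (not REML) throughout, so likelihood-ratio tests
#' between fixed-effect structures are valid.
#'
#' @param formula model formula, e.g. `y ~ x1 + x2 + (1 | id) + (1 | region)`.
#' @param data data frame containing response, covariates and grouping
#'   factors. Rows with missing values in any used variable are dropped
#'   (count recorded in the fit as `n_dropped`).
#' @param family one of `"binomial"` (logit link), `"poisson"` (log link),
#'   `"gaussian"` (identity link).
#' @param pin_variance optional named numeric vector pinning the variance of
#'   the named grouping factors to zero, e.g. `c(id = 0)`; pinned factors
#'   drop out of the model and of the parameter count.
#' @param start optional list with elements `beta` and/or `theta` (log SDs,
#'   gaussian residual log SD last) used as starting values.
#' @param control a [glmm_control()] list.
#' @return an object of class `glmm_fit` with components `coefficients`,
#'   `coef_table` (Estimate / Std. Error / z value / Pr(>|z|)), `vcov`,
#'   `varcomp` (per-factor variance and SD), `sigma` (gaussian residual SD),
#'   `logLik`, `df` (fixed coefficients + free variance parameters), `AIC`,
#'   `n_obs`, `n_groups`, `converged` and `boundary` flags.
#' @seealso [brute_force_loglik()] for an independent check of the reported
#'   log-likelihood, [likelihood_ratio_test()], [marginal_predict()].
#' @export
fit_glmm <- function(formula, data,
                     family = c("binomial", "poisson", "gaussian"),
                     pin_variance = NULL, start = NULL,
                     control = glmm_control()) {
  family <- match.arg(family)
  des <- build_glmm_design(formula, data, family)
  y <- des$y
  X <- des$X
  n <- length(y)
  p <- ncol(X)
  is_gaussian <- family == "gaussian"
  linkinv <- glmm_linkinv(family)

  ## bounded inverse link inside the optimisation: a Poisson rate above
  ## e^30 can only arise from a divergent line-search excursion and would
  ## overflow the working weights
  if (family == "poisson") linkinv <- function(eta) exp(pmin(eta, 30))

  groups_all <- names(des$group_factors)
  pinned <- character(0)
  if (!is.null(pin_variance)) {
    if (!all(names(pin_variance) %in% groups_all))
      stop_repsen("pin_variance names must be grouping factors in the formula")
    if (!all(pin_variance == 0))
      stop_repsen("only pinning variances to exactly 0 is supported")
    pinned <- names(pin_variance)
  }
  ## order free factors by decreasing level count: the first factor's block
  ## of Z'WZ is then the (large) diagonal block of the arrow structure
  free_groups <- setdiff(groups_all, pinned)
  if (length(free_groups) > 1L) {
    sizes <- vapply(des$group_factors[free_groups], nlevels, integer(1))
    free_groups <- free_groups[order(-sizes)]
  }
  if (length(free_groups) > 2L)
    stop_repsen("at most two free random-intercept factors are supported")
  facs <- des$group_factors[free_groups]
  qs <- vapply(facs, nlevels, integer(1))
  q <- as.integer(sum(qs))
  n_groups <- vapply(des$group_factors, nlevels, integer(1))

  g1 <- if (length(facs) >= 1L) as.integer(facs[[1]]) else integer(0)
  g2 <- if (length(facs) >= 2L) as.integer(facs[[2]]) else integer(0)
  two_fac <- length(facs) == 2L
  q1 <- if (q > 0) qs[[1]] else 0L
  q2 <- if (two_fac) qs[[2]] else 0L
  idx1 <- seq_len(q1)
  idx2 <- if (two_fac) q1 + seq_len(q2) else integer(0)
  comp_index <- rep(seq_along(qs), qs)

  ## dense "arrow" random-effect algebra: for random intercepts the
  ## factor-1 block of Z'WZ is diagonal and the factor-2 block is small,
  ## so factorisation, solves and selected-inverse diagonals are all
  ## closed-form dense operations (no sparse matrices needed). Group sums
  ## use a precomputed sort order + cumsum (every level is non-empty
  ## after droplevels, so the boundary bookkeeping is exact).
  grp_sum <- function(g, nlev) {
    ord <- order(g, method = "radix")
    ends <- cumsum(tabulate(g, nlev))
    function(v) {
      cs <- cumsum(v[ord])[ends]
      c(cs[1], diff(cs))
    }
  }
  rs1 <- if (q1 > 0) grp_sum(g1, q1) else function(v) numeric(0)
  rs2 <- if (two_fac) grp_sum(g2, q2) else function(v) numeric(0)
  ## sparse pattern of the factor-1 x factor-2 coupling block
  if (two_fac) {
    pair_id <- (g1 - 1L) * q2 + g2
    upid <- sort(unique(pair_id))
    pair_sum <- grp_sum(match(pair_id, upid), length(upid))
    B_template <- matrix(0, q1, q2)
    B_rows <- ((upid - 1L) %/% q2) + 1L
    B_cols <- ((upid - 1L) %% q2) + 1L
    B_index <- cbind(B_rows, B_cols)
  }
  Zu <- function(u) {
    if (!two_fac) return(u[g1])
    u[idx1][g1] + u[idx2][g2]
  }
  Ztv <- function(v) if (two_fac) c(rs1(v), rs2(v)) else rs1(v)
  chol_solve2 <- function(ch, b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
  arrow_factor <- function(w, dinv_vec) {
    d1 <- rs1(w) + dinv_vec[idx1]
    if (any(d1 <= 0) || anyNA(d1)) return(NULL)
    if (!two_fac) {
      return(list(
        ldet = sum(log(d1)),
        solve = function(b) b / d1,
        diag1 = 1 / d1, diag2 = numeric(0),
        c_obs = (1 / d1)[g1]))
    }
    B <- B_template
    B[B_index] <- pair_sum(w)
    d2 <- rs2(w) + dinv_vec[idx2]
    Binvd <- B / d1
    S <- diag(d2, q2) - crossprod(B, Binvd)
    chS <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(chS)) return(NULL)
    Sinv <- chol2inv(chS)
    M <- Binvd %*% Sinv
    diag1 <- 1 / d1 + rowSums(M * Binvd)
    list(
      ldet = sum(log(d1)) + 2 * sum(log(diag(chS))),
      solve = function(b) {
        b <- as.matrix(b)
        b1 <- b[idx1, , drop = FALSE]
        b2 <- b[idx2, , drop = FALSE]
        x2 <- chol_solve2(chS, b2 - crossprod(Binvd, b1))
        x1 <- (b1 - B %*% x2) / d1
        out <- rbind(x1, x2)
        if (ncol(out) == 1L) as.numeric(out) else out
      },
      diag1 = diag1, diag2 = diag(Sinv),
      c_obs = diag1[g1] + diag(Sinv)[g2] - 2 * M[cbind(g1, g2)])
  }

  ## closed-form conditional log-likelihoods (numerically stable forms;
  ## cheaper than the d* density calls in the inner loop)
  lfact_y <- if (family == "poisson") sum(lgamma(y + 1)) else 0
  loglik_cond <- function(eta, scale) {
    switch(family,
      binomial = sum(y * eta) -
        sum(pmax(eta, 0) + log1p(exp(-abs(eta)))),
      poisson = sum(y * eta) - sum(exp(pmin(eta, 30))) - lfact_y,
      gaussian = -0.5 * (length(y) * log(2 * pi * scale^2) +
                           sum((y - eta)^2) / scale^2))
  }
  wfun <- function(mu) {
    switch(family,
      binomial = pmax(mu * (1 - mu), 1e-12),
      poisson = pmin(pmax(mu, 1e-12), 1e10),
      gaussian = rep(1, length(mu)))
  }
  ## derivative of the IRLS weight w.r.t. the linear predictor
  wprime <- function(mu) {
    switch(family,
      binomial = mu * (1 - mu) * (1 - 2 * mu),
      poisson = mu,
      gaussian = rep(0, length(mu)))
  }

  ## ---- GLM path: no free random effects -------------------------------
  irls_glm <- function() {
    beta <- rep(0, p)
    if (is_gaussian) {
      beta <- as.numeric(qr.coef(qr(X), y))
      eta <- as.numeric(X %*% beta)
      sig <- sqrt(sum((y - eta)^2) / n)
      return(list(beta = beta, scale = sig, ll = loglik_cond(eta, sig),
                  conv = TRUE))
    }
    eta <- rep(if (family == "binomial") 0 else log(mean(y) + 0.1), n)
    ll_old <- -Inf
    conv <- FALSE
    for (it in seq_len(control$pirls_maxit)) {
      mu <- linkinv(eta)
      w <- wfun(mu)
      z <- eta + (y - mu) / w
      fit <- stats::lm.wfit(X, z, w)
      beta <- fit$coefficients
      eta <- as.numeric(X %*% beta)
      ll <- loglik_cond(eta, 1)
      if (abs(ll - ll_old) < control$pirls_tol * (abs(ll) + 0.1)) {
        conv <- TRUE
        break
      }
      ll_old <- ll
    }
    list(beta = beta, scale = 1, ll = ll, conv = conv)
  }

  if (q == 0L) {
    gf <- irls_glm()
    beta <- gf$beta
    names(beta) <- colnames(X)
    eta <- as.numeric(X %*% beta)
    mu <- linkinv(eta)
    w <- if (is_gaussian) rep(1 / gf$scale^2, n) else wfun(mu)
    vcov_beta <- tryCatch(solve(crossprod(X * sqrt(w))),
                          error = function(e) matrix(NA_real_, p, p))
    fit <- finalize_glmm_fit(
      beta = beta, vcov_beta = vcov_beta,
      varcomp_free = NULL, sds = numeric(0), scale = gf$scale,
      ll = gf$ll, p = p, n = n, family = family, is_gaussian = is_gaussian,
      free_groups = character(0), pinned = pinned, n_groups = n_groups,
      converged = gf$conv, des = des, formula = formula,
      theta = numeric(0), ranef = list(), control = control)
    return(fit)
  }

  ## ---- PIRLS over the random effects at fixed (beta, theta) -----------
  state <- new.env(parent = emptyenv())
  state$u <- numeric(q)
  state$key <- NULL

  pirls_u <- function(beta, sds, scale) {
    dinv_vec <- 1 / sds[comp_index]^2
    eta_x <- as.numeric(X %*% beta)
    u <- state$u
    fail <- function(eta, mu, w) {
      state$u <- numeric(q)
      list(lap = -Inf, u = state$u, eta = eta, mu = mu, w = w, fac = NULL,
           dinv_vec = dinv_vec, pirls_conv = FALSE, sds = sds, scale = scale)
    }
    if (is_gaussian) {
      w <- rep(1 / scale^2, n)
      fac <- arrow_factor(w, dinv_vec)
      if (is.null(fac)) return(fail(eta_x, eta_x, w))
      u <- fac$solve(Ztv(w * (y - eta_x)))
      eta <- eta_x + Zu(u)
      mu <- eta
      pirls_conv <- TRUE
    } else {
      pen <- function(u, eta) loglik_cond(eta, 1) - 0.5 * sum(dinv_vec * u^2)
      eta <- eta_x + Zu(u)
      obj <- pen(u, eta)
      if (!is.finite(obj)) {
        u <- numeric(q)
        eta <- eta_x
        obj <- pen(u, eta)
      }
      if (!is.finite(obj)) {
        ## linear predictor degenerate at this (beta, theta); report -Inf
        ## so the outer line search backs off
        return(fail(eta, linkinv(eta), wfun(linkinv(eta))))
      }
      pirls_conv <- FALSE
      for (it in seq_len(control$pirls_maxit)) {
        mu <- linkinv(eta)
        w <- wfun(mu)
        fac <- arrow_factor(w, dinv_vec)
        if (is.null(fac)) break
        u_new <- fac$solve(Ztv(w * (eta - eta_x) + (y - mu)))
        if (any(!is.finite(u_new))) break
        step <- 1
        repeat {
          cand <- u + step * (u_new - u)
          eta_c <- eta_x + Zu(cand)
          obj_c <- pen(cand, eta_c)
          if (is.finite(obj_c) && obj_c >= obj - 1e-12) break
          step <- step / 2
          if (step < 1e-10) break
        }
        if (!is.finite(obj_c)) { pirls_conv <- TRUE; break }
        rel <- abs(obj_c - obj) / (abs(obj) + 0.1)
        u <- cand
        eta <- eta_c
        obj <- obj_c
        if (rel < control$pirls_tol) { pirls_conv <- TRUE; break }
      }
      mu <- linkinv(eta)
      w <- wfun(mu)
      fac <- arrow_factor(w, dinv_vec)
    }
    if (!all(is.finite(u)) || max(abs(u)) > 1e8) return(fail(eta, mu, w))
    state$u <- u
    if (is.null(fac)) return(fail(eta, mu, w))
    ll_cond <- loglik_cond(eta, scale)
    lap <- ll_cond - 0.5 * sum(dinv_vec * u^2) - sum(qs * 2 * log(sds)) / 2 -
      0.5 * fac$ldet
    if (!is.finite(lap) || lap < -1e12) return(fail(eta, mu, w))
    list(lap = lap, u = u, eta = eta, mu = mu, w = w, fac = fac,
         dinv_vec = dinv_vec, pirls_conv = pirls_conv, sds = sds,
         scale = scale)
  }

  ## analytic gradient of the Laplace objective w.r.t. (beta, log sds
  ## [, log scale]), at the profiled random-effect mode; uses the
  ## selected-inverse diagonals and observation leverages
  ## c_i = (Z Huu^{-1} Z')_{ii} from the arrow factorisation
  laplace_grad <- function(st) {
    fac <- st$fac
    u <- st$u
    if (is_gaussian) {
      resid <- y - st$eta
      g_beta <- as.numeric(crossprod(X, resid)) / st$scale^2
      g_theta <- vapply(seq_along(qs), function(f) {
        uf <- u[comp_index == f]
        trf <- sum(if (f == 1L) fac$diag1 else fac$diag2)
        sum(uf^2) / st$sds[f]^2 - qs[f] + trf / st$sds[f]^2
      }, numeric(1))
      tr_dinv <- sum(fac$diag1 * st$dinv_vec[idx1]) +
        (if (two_fac) sum(fac$diag2 * st$dinv_vec[idx2]) else 0)
      g_scale <- -n + sum(resid^2) / st$scale^2 + (q - tr_dinv)
      return(c(g_beta, g_theta, g_scale))
    }
    wp <- wprime(st$mu)
    tvec <- fac$c_obs * wp
    s <- fac$solve(Ztv(tvec))
    v <- st$w * Zu(s)
    g_beta <- as.numeric(crossprod(X, (y - st$mu) - 0.5 * (tvec - v)))
    g_theta <- vapply(seq_along(qs), function(f) {
      sel <- comp_index == f
      uf <- u[sel]
      sf <- st$sds[f]
      trf <- sum(if (f == 1L) fac$diag1 else fac$diag2)
      sum(uf^2) / sf^2 - qs[f] + trf / sf^2 - sum(s[sel] * uf) / sf^2
    }, numeric(1))
    c(g_beta, g_theta)
  }

  n_theta <- length(qs) + as.integer(is_gaussian)
  clamp_theta <- function(th) pmin(pmax(th, control$log_sd_min),
                                   control$log_sd_max)
  split_psi <- function(psi) {
    beta <- psi[seq_len(p)]
    th <- clamp_theta(psi[p + seq_len(n_theta)])
    sds <- exp(th[seq_along(qs)])
    scale <- if (is_gaussian) exp(th[n_theta]) else 1
    list(beta = beta, sds = sds, scale = scale, theta = th)
  }
  cache <- new.env(parent = emptyenv())
  eval_at <- function(psi) {
    key <- paste(psi, collapse = ",")
    if (identical(cache$key, key)) return(cache$st)
    sp <- split_psi(psi)
    st <- pirls_u(sp$beta, sp$sds, sp$scale)
    cache$key <- key
    cache$st <- st
    st
  }
  negfn <- function(psi) {
    st <- eval_at(psi)
    if (!is.finite(st$lap)) return(1e10)
    -st$lap
  }
  neggr <- function(psi) {
    st <- eval_at(psi)
    if (!is.finite(st$lap)) return(rep(0, length(psi)))
    g <- laplace_grad(st)
    ## clamp: freeze gradient for components pinned at the box edge
    th <- psi[p + seq_len(n_theta)]
    at_lo <- th <= control$log_sd_min
    at_hi <- th >= control$log_sd_max
    gth <- g[p + seq_len(n_theta)]
    gth[at_lo & gth < 0] <- 0
    gth[at_hi & gth > 0] <- 0
    g[p + seq_len(n_theta)] <- gth
    -g
  }

  ## starting values: quick GLM fit for beta, moderate SDs for theta
  glm0 <- irls_glm()
  beta0 <- glm0$beta
  theta0 <- rep(log(0.5), length(qs))
  if (is_gaussian) theta0 <- c(theta0, log(max(glm0$scale, 1e-3)))
  if (!is.null(start)) {
    if (!is.null(start$beta) && length(start$beta) == p) beta0 <- start$beta
    if (!is.null(start$theta) && length(start$theta) == n_theta)
      theta0 <- clamp_theta(start$theta)
  }
  starts <- list(c(beta0, theta0))
  if (control$restarts > 1L)
    starts <- c(starts, list(c(beta0, theta0 - log(5))),
                if (control$restarts > 2L) list(c(beta0, theta0 + log(3))))
  best <- NULL
  run_opt <- function(psi0) {
    state$u <- numeric(q)
    cache$key <- NULL
    stats::optim(psi0, negfn, neggr, method = "BFGS",
                 control = list(maxit = control$outer_maxit,
                                reltol = control$outer_reltol))
  }
  for (psi0 in starts) {
    op <- run_opt(psi0)
    if (is.null(best) || op$value < best$value) best <- op
  }
  ## a variance component driven to the boundary can hide a shallow
  ## interior optimum; when the profile looks flat there (probe within
  ## 0.5 log-units), rerun the optimisation from a small positive value
  if (control$outer_maxit > 0L) {
    th <- best$par[p + seq_len(n_theta)]
    low <- th < log(0.02)
    if (any(low)) {
      psi2 <- best$par
      psi2[p + which(low)] <- log(0.15)
      probe <- negfn(psi2)
      if (is.finite(probe) && probe < best$value + 0.5) {
        op2 <- run_opt(psi2)
        if (op2$value < best$value) best <- op2
      }
    }
  }
  psi_hat <- best$par
  psi_hat[p + seq_len(n_theta)] <- clamp_theta(psi_hat[p + seq_len(n_theta)])
  opt_conv <- best$convergence %in% c(0L, 1L)  # 1 = maxit; flagged below
  hit_maxit <- best$convergence == 1L

  cache$key <- NULL
  state$u <- numeric(q)
  sp <- split_psi(psi_hat)
  st <- pirls_u(sp$beta, sp$sds, sp$scale)
  if (!is.finite(st$lap))
    stop_repsen("model fit diverged: non-finite likelihood at the optimum")
  beta <- sp$beta
  names(beta) <- colnames(X)

  ## conditional covariance of beta: Schur complement of the penalised
  ## Fisher information at the mode
  vcov_beta <- matrix(NA_real_, p, p)
  if (!is.null(st$fac)) {
    XtWX <- crossprod(X * sqrt(st$w))
    WX <- X * st$w
    ZtWX <- matrix(vapply(seq_len(p), function(j) Ztv(WX[, j]), numeric(q)),
                   nrow = q, ncol = p)
    HinvZtWX <- st$fac$solve(ZtWX)
    Info <- XtWX - crossprod(ZtWX, as.matrix(HinvZtWX))
    vcov_beta <- tryCatch(solve(Info),
                          error = function(e) matrix(NA_real_, p, p))
  }
  dimnames(vcov_beta) <- list(names(beta), names(beta))

  ranef_hat <- split(st$u, rep(free_groups, qs))
  for (f in free_groups) names(ranef_hat[[f]]) <- levels(facs[[f]])

  finalize_glmm_fit(
    beta = beta, vcov_beta = vcov_beta,
    varcomp_free = data.frame(group = free_groups, variance = sp$sds^2,
                              sd = sp$sds,
                              boundary = sp$sds < control$boundary_tol,
                              stringsAsFactors = FALSE),
    sds = sp$sds, scale = sp$scale, ll = st$lap, p = p, n = n,
    family = family, is_gaussian = is_gaussian, free_groups = free_groups,
    pinned = pinned, n_groups = n_groups,
    converged = (opt_conv && !hit_maxit) && st$pirls_conv,
    des = des, formula = formula, theta = sp$theta, ranef = ranef_hat,
    control = control)
}

finalize_glmm_fit <- function(beta, vcov_beta, varcomp_free, sds, scale, ll,
                              p, n, family, is_gaussian, free_groups, pinned,
                              n_groups, converged, des, formula, theta,
                              ranef, control) {
  se <- sqrt(pmax(diag(vcov_beta), 0))
  zval <- beta / se
  coef_table <- data.frame(term = names(beta), estimate = as.numeric(beta),
                           std_error = se, z_value = zval,
                           p_value = 2 * stats::pnorm(-abs(zval)),
                           row.names = NULL, stringsAsFactors = FALSE)
  varcomp <- varcomp_free %||%
    data.frame(group = character(0), variance = numeric(0), sd = numeric(0),
               boundary = logical(0), stringsAsFactors = FALSE)
  if (length(pinned)) {
    varcomp <- rbind(varcomp,
                     data.frame(group = pinned, variance = 0, sd = 0,
                                boundary = TRUE, stringsAsFactors = FALSE))
  }
  k <- p + length(free_groups) + as.integer(is_gaussian)
  structure(list(
    coefficients = beta, coef_table = coef_table, vcov = vcov_beta,
    varcomp = varcomp, sigma = if (is_gaussian) scale else NA_real_,
    logLik = ll, df = k, AIC = -2 * ll + 2 * k,
    n_obs = n, n_groups = n_groups,
    converged = converged,
    boundary = any(varcomp$boundary[varcomp$group %in% free_groups]),
    family = family, formula = formula,
    fixed_terms = des$fixed_terms, xlevels = des$xlevels,
    contrasts = des$contrasts, groups = names(des$group_factors),
    pinned = pinned, theta = theta, ranef = ranef,
    n_dropped = des$n_dropped, dropped_cols = des$dropped_cols,
    model_frame = des$mf), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Random-intercept GLMM (%s family, Laplace ML)\n", x$family))
  cat(sprintf("  n = %d obs; logLik = %.3f; AIC = %.2f; k = %d%s\n",
              x$n_obs, x$logLik, x$AIC, x$df,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  cat("Fixed effects:\n")
  tab <- x$coef_table
  tab[-1] <- lapply(tab[-1], function(c) signif(c, digits))
  print(tab, row.names = FALSE)
  if (nrow(x$varcomp)) {
    cat("Random effects:\n")
    vc <- x$varcomp
    vc$variance <- signif(vc$variance, digits)
    vc$sd <- signif(vc$sd, digits)
    print(vc, row.names = FALSE)
  }
  if (!is.na(x$sigma)) cat(sprintf("Residual SD: %.4f\n", x$sigma))
  invisible(x)
}

#' @export
logLik.glmm_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.glmm_fit <- function(object, ...) object$coefficients

#' @export
vcov.glmm_fit <- function(object, ...) object$vcov

#' Likelihood-ratio test between two nested GLMM fits
#'
#' Compares a full model to a reduced model fitted by ML on the same rows.
#' The statistic is clipped at zero (a reduced model can beat the full one
#' only through convergence noise; a warning is raised when that happens).
#'
#' @param full,reduced `glmm_fit` objects; `reduced` must be nested in
#'   `full` (its fixed-effect terms a subset) and fitted to the same data.
#' @param check_nesting verify that the reduced coefficient names are a
#'   subset of the full model's.
#' @return a list of class `glmm_lrt` with `chi_square`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced, check_nesting = TRUE) {
  if (!inherits(full, "glmm_fit") || !inherits(reduced, "glmm_fit"))
    stop_repsen("both arguments must be glmm_fit objects")
  if (full$n_obs != reduced$n_obs)
    stop_repsen("row-count mismatch between fits (", full$n_obs, " vs ",
                reduced$n_obs, ")")
  if (full$family != reduced$family)
    stop_repsen("fits use different families")
  if (check_nesting &&
      !all(names(reduced$coefficients) %in% names(full$coefficients)))
    stop_repsen("models are not nested: reduced has terms absent from full")
  if (!is.finite(full$logLik) || !is.finite(reduced$logLik))
    stop_repsen("non-finite log-likelihood; a fit did not converge")
  df <- full$df - reduced$df
  if (df < 1L) stop_repsen("full model must have more parameters than reduced")
  chi <- 2 * (full$logLik - reduced$logLik)
  if (chi < 0) {
    if (chi < -0.01)
      warning(sprintf(
        "logLik(full) < logLik(reduced) by %.4f; check convergence",
        -chi / 2))
    else
      warning("negative LRT statistic within convergence tolerance; clipped to 0")
    chi <- 0
  }
  structure(list(chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE)),
            class = "glmm_lrt")
}

#' @export
print.glmm_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chi^2(%d) = %.3f, p = %.4g\n",
              x$df, x$chi_square, x$p_value))
  invisible(x)
}

#' Population-level predictions from a GLMM fit
#'
#' Evaluates the inverse link of the fixed-effect linear predictor with all
#' random effects at zero, i.e. the response of a typical (median) group.
#'
#' @param fit a `glmm_fit`.
#' @param newdata data frame of covariate rows; factor levels must have been
#'   seen during fitting.
#' @param type `"response"` (default) or `"link"`.
#' @return numeric vector of predictions.
#' @export
marginal_predict <- function(fit, newdata, type = c("response", "link")) {
  type <- match.arg(type)
  tt <- stats::delete.response(fit$fixed_terms)
  m <- stats::model.frame(tt, newdata, xlev = fit$xlevels,
                          na.action = stats::na.fail)
  Xn <- stats::model.matrix(tt, m, contrasts.arg = fit$contrasts)
  if (!all(names(fit$coefficients) %in% colnames(Xn)))
    stop_repsen("newdata does not produce the fitted design columns")
  Xn <- Xn[, names(fit$coefficients), drop = FALSE]
  eta <- as.numeric(Xn %*% fit$coefficients)
  if (type == "link") return(eta)
  glmm_linkinv(fit$family)(eta)
}

#' Laplace-approximate log-likelihood at fixed parameter values
#'
#' Evaluates the same Laplace objective that [fit_glmm()] maximises, at
#' user-supplied fixed effects and variance parameters (the random-effect
#' mode is still profiled out numerically). Useful for validating the
#' approximation against [brute_force_loglik()] at identical parameters.
#'
#' @inheritParams fit_glmm
#' @param beta named fixed-effect vector (model-matrix column names).
#' @param sd named vector of random-intercept SDs, one per grouping factor.
#' @param sigma residual SD (gaussian family only).
#' @return the Laplace log-likelihood (scalar).
#' @export
laplace_loglik <- function(formula, data,
                           family = c("binomial", "poisson", "gaussian"),
                           beta, sd, sigma = NULL) {
  family <- match.arg(family)
  pf <- parse_glmm_formula(formula)
  if (is.null(names(sd)) && length(sd) == length(pf$groups))
    names(sd) <- pf$groups
  ## factor order inside the fit is by decreasing level count; passing the
  ## full named set keeps the mapping unambiguous
  sizes <- vapply(pf$groups, function(g)
    nlevels(droplevels(factor(data[[g]]))), integer(1))
  ord <- names(sort(-sizes))
  theta <- log(pmax(unname(sd[ord]), 1e-12))
  if (family == "gaussian") {
    if (is.null(sigma)) stop_repsen("sigma required for gaussian family")
    theta <- c(theta, log(sigma))
  }
  des0 <- build_glmm_design(formula, data, family)
  beta_use <- unname(beta[colnames(des0$X)])
  if (anyNA(beta_use)) stop_repsen("beta names must match model columns")
  fit <- fit_glmm(formula, data, family,
                  start = list(beta = beta_use, theta = theta),
                  control = glmm_control(outer_maxit = 0L))
  fit$logLik
}

## --- brute-force likelihood oracle -------------------------------------

gauss_hermite <- function(nodes) {
  ## Golub-Welsch for the physicists' Hermite weight exp(-x^2)
  i <- seq_len(nodes - 1)
  J <- matrix(0, nodes, nodes)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  w <- sqrt(pi) * ev$vectors[1, ]^2
  ord <- order(x)
  list(x = x[ord], w = w[ord])
}

#' Brute-force marginal log-likelihood of a random-intercept GLMM
#'
#' Computes the integrated log-likelihood at fixed parameter values by dense
#' numerical integration over the random effects: adaptive 1-D quadrature
#' (via [stats::integrate()]) per group of the first factor, and a
#' Gauss-Hermite product grid over the second factor's effects when two
#' factors are present. Intended as an independent accuracy oracle for the
#' Laplace approximation on small instances; the product grid limits the
#' second factor to at most 3 levels.
#'
#' @param formula,data,family as in [fit_glmm()].
#' @param beta named fixed-effect coefficient vector (names must match the
#'   model matrix columns).
#' @param sd named vector of random-intercept standard deviations, one per
#'   grouping factor in the formula. Zero-SD factors integrate out exactly.
#' @param sigma residual SD (gaussian family only).
#' @param grid_nodes Gauss-Hermite nodes per dimension for the second
#'   factor's product grid.
#' @return the marginal log-likelihood (scalar).
#' @export
brute_force_loglik <- function(formula, data,
                               family = c("binomial", "poisson", "gaussian"),
                               beta, sd = numeric(0), sigma = NULL,
                               grid_nodes = 41L) {
  family <- match.arg(family)
  des <- build_glmm_design(formula, data, family)
  y <- des$y
  X <- des$X
  if (is.null(names(beta))) names(beta) <- colnames(X)
  if (!setequal(names(beta), colnames(X)))
    stop_repsen("beta names must match model matrix columns")
  eta0 <- as.numeric(X %*% beta[colnames(X)])
  scale <- if (family == "gaussian") {
    if (is.null(sigma)) stop_repsen("sigma required for gaussian family")
    sigma
  } else 1
  groups <- des$group_factors
  if (length(sd) != length(groups))
    stop_repsen("need one sd per grouping factor")
  if (is.null(names(sd)) && length(sd)) names(sd) <- names(groups)
  sd <- sd[names(groups)]
  active <- names(groups)[sd > 0]
  cond_ll <- function(yi, eta) {
    switch(family,
      binomial = sum(stats::dbinom(yi, 1, stats::plogis(eta), log = TRUE)),
      poisson = sum(stats::dpois(yi, exp(eta), log = TRUE)),
      gaussian = sum(stats::dnorm(yi, eta, scale, log = TRUE)))
  }
  if (length(active) == 0L) return(cond_ll(y, eta0))
  if (length(active) > 2L)
    stop_repsen("at most two non-degenerate grouping factors supported")

  integrate_factor <- function(eta_base, fac, s) {
    total <- 0
    for (lev in levels(fac)) {
      idx <- which(fac == lev)
      if (!length(idx)) next
      e <- eta_base[idx]
      yi <- y[idx]
      cll <- function(u) {
        vapply(u, function(ui) {
          cond_ll(yi, e + ui) + stats::dnorm(ui, 0, s, log = TRUE)
        }, numeric(1))
      }
      m <- max(cll(seq(-5 * s, 5 * s, length.out = 61)))
      val <- stats::integrate(function(u) exp(cll(u) - m), -Inf, Inf,
                              rel.tol = 1e-10, abs.tol = 0)$value
      total <- total + log(val) + m
    }
    total
  }

  if (length(active) == 1L) {
    return(integrate_factor(eta0, groups[[active]], sd[[active]]))
  }

  ## two factors: Gauss-Hermite product grid over the SECOND factor's
  ## effects, adaptive 1-D integration per group of the first inside each
  ## grid point
  f1 <- groups[[active[1]]]
  f2 <- groups[[active[2]]]
  s1 <- sd[[active[1]]]
  s2 <- sd[[active[2]]]
  q2 <- nlevels(f2)
  if (q2 > 3L)
    stop_repsen("instance too large: second factor limited to 3 levels")
  gh <- gauss_hermite(grid_nodes)
  combos <- as.matrix(expand.grid(rep(list(seq_len(grid_nodes)), q2)))
  Z2 <- stats::model.matrix(~ 0 + f2)
  log_terms <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    v <- sqrt(2) * s2 * gh$x[combos[ci, ]]
    lw <- sum(log(gh$w[combos[ci, ]] / sqrt(pi)))
    eta_base <- eta0 + as.numeric(Z2 %*% v)
    log_terms[ci] <- lw + integrate_factor(eta_base, f1, s1)
  }
  m <- max(log_terms)
  m + log(sum(exp(log_terms - m)))
}
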