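test_that("zero-variance fits agree with the independent GLM oracle", {
  d <- make_binomial_cluster_data(seed = 11)
  for (fam in c("binomial", "poisson", "gaussian")) {
    d2 <- d
    if (fam == "poisson") {
      set.seed(3)
      d2$y <- rpois(nrow(d), exp(0.2 + 0.4 * d$x))
    }
    if (fam == "gaussian") {
      set.seed(4)
      d2$y <- 1 + 0.5 * d$x + rnorm(nrow(d), 0, 1.3)
    }
    fit <- fit_glmm(y ~ x + (1 | g), d2, fam, pin_variance = c(g = 0))
    oracle <- glm(y ~ x, data = d2,
                  family = switch(fam, binomial = binomial(),
                                  poisson = poisson(), gaussian = gaussian()))
    expect_lt(max(abs(coef(fit) - coef(oracle))), 1e-3)
    expect_lt(abs(fit$logLik - as.numeric(logLik(oracle))), 1e-4)
  }
})

test_that("Laplace log-likelihood matches brute-force integration on small instances", {
  ## binomial, one factor: Laplace is approximate but close when both
  ## routes are evaluated at the same moderate parameter values
  set.seed(21)
  for (rep in 1:5) {
    g <- factor(rep(1:6, each = 5))
    x <- rnorm(30)
    b <- rnorm(6, 0, 0.6)
    d <- data.frame(y = rbinom(30, 1, plogis(0.2 + 0.5 * x + b[g])),
                    x = x, g = g)
    beta <- c("(Intercept)" = 0.2, x = 0.5)
    lap <- laplace_loglik(y ~ x + (1 | g), d, "binomial", beta = beta,
                          sd = c(g = 0.6))
    bf <- brute_force_loglik(y ~ x + (1 | g), d, "binomial", beta = beta,
                             sd = c(g = 0.6))
    expect_lt(abs(lap - bf), 0.05)
  }
  ## gaussian: Laplace is exact; also check the closed-form MVN oracle
  set.seed(22)
  g <- factor(rep(1:5, each = 4))
  d <- data.frame(y = rnorm(20, 1, 1) + rnorm(5, 0, 0.8)[g],
                  x = rnorm(20), g = g)
  fit <- fit_glmm(y ~ x + (1 | g), d, "gaussian", control = quick_ctl())
  bf <- brute_force_loglik(y ~ x + (1 | g), d, "gaussian",
                           beta = coef(fit), sd = c(g = fit$varcomp$sd),
                           sigma = fit$sigma)
  mvn <- gaussian_marginal_loglik(y ~ x + (1 | g), d, coef(fit),
                                  c(g = fit$varcomp$sd), fit$sigma)
  expect_lt(abs(fit$logLik - bf), 1e-6)
  expect_lt(abs(bf - mvn), 1e-8)
})

test_that("two-factor brute force agrees with Laplace and handles sd = 0 exactly", {
  set.seed(23)
  g <- factor(rep(1:6, each = 4))
  reg <- factor(rep(rep(1:2, 3), each = 4))
  x <- rnorm(24)
  d <- data.frame(y = rbinom(24, 1, plogis(0.3 * x +
                    rnorm(6, 0, 0.5)[g] + rnorm(2, 0, 0.3)[reg])),
                  x = x, g = g, reg = reg)
  fit <- fit_glmm(y ~ x + (1 | g) + (1 | reg), d, "binomial",
                  control = quick_ctl())
  sds <- setNames(fit$varcomp$sd, fit$varcomp$group)
  bf <- brute_force_loglik(y ~ x + (1 | g) + (1 | reg), d, "binomial",
                           beta = coef(fit), sd = sds[c("g", "reg")])
  expect_lt(abs(fit$logLik - bf), 0.05)
  ## degenerate integral: sd 0 must equal the plain GLM log-likelihood
  bf0 <- brute_force_loglik(y ~ x + (1 | g), d, "binomial",
                            beta = c("(Intercept)" = 0.1, x = 0.4),
                            sd = c(g = 0))
  eta <- 0.1 + 0.4 * d$x
  expect_equal(bf0, sum(dbinom(d$y, 1, plogis(eta), log = TRUE)),
               tolerance = 1e-12)
})

test_that("fits agree with lme4 on moderate two-factor data", {
  skip_if_not_installed("lme4")
  d <- make_two_factor_data(seed = 31)
  fit <- fit_glmm(y ~ x + (1 | g) + (1 | reg), d, "binomial")
  m <- suppressMessages(lme4::glmer(y ~ x + (1 | g) + (1 | reg), d,
                                    binomial))
  expect_lt(abs(fit$logLik - as.numeric(logLik(m))), 1e-3)
  expect_lt(max(abs(coef(fit) - lme4::fixef(m))), 1e-3)
  dg <- make_two_factor_data(family = "gaussian", seed = 32)
  fitg <- fit_glmm(y ~ x + (1 | g) + (1 | reg), dg, "gaussian")
  mg <- lme4::lmer(y ~ x + (1 | g) + (1 | reg), dg, REML = FALSE)
  expect_lt(abs(fitg$logLik - as.numeric(logLik(mg))), 1e-3)
})

test_that("gaussian variance components match closed-form ANOVA ML on balanced data", {
  ## balanced one-way design: ML estimators have closed forms
  set.seed(41)
  a <- 30; m <- 6
  g <- factor(rep(1:a, each = m))
  d <- data.frame(y = 2 + rnorm(a, 0, 1.1)[g] + rnorm(a * m, 0, 0.9), g = g)
  fit <- fit_glmm(y ~ 1 + (1 | g), d, "gaussian",
                  control = glmm_control(outer_reltol = 1e-13))
  gm <- mean(d$y)
  group_means <- tapply(d$y, d$g, mean)
  sse <- sum((d$y - group_means[d$g])^2)
  ssa <- m * sum((group_means - gm)^2)
  sig2_hat <- sse / (a * (m - 1))
  tau2_hat <- max(ssa / (a * m) - sig2_hat / m, 0)
  expect_lt(abs(fit$sigma^2 - sig2_hat), 1e-6)
  expect_lt(abs(fit$varcomp$variance - tau2_hat), 1e-6)
  expect_lt(abs(unname(coef(fit)["(Intercept)"]) - gm), 1e-6)
})

test_that("likelihood never decreases when a term is added", {
  for (s in 1:4) {
    d <- make_two_factor_data(seed = 100 + s)
    d$junk <- rnorm(nrow(d))
    f0 <- fit_glmm(y ~ x + (1 | g) + (1 | reg), d, "binomial")
    f1 <- fit_glmm(y ~ x + junk + (1 | g) + (1 | reg), d, "binomial",
                   start = list(theta = f0$theta))
    expect_gte(f1$logLik, f0$logLik - 1e-6)
  }
})

test_that("fit is invariant to row order and group relabelling", {
  d <- make_binomial_cluster_data(seed = 51)
  f1 <- fit_glmm(y ~ x + (1 | g), d, "binomial")
  set.seed(52)
  perm <- sample(nrow(d))
  f2 <- fit_glmm(y ~ x + (1 | g), d[perm, ], "binomial")
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
  d3 <- d
  d3$g <- factor(paste0("grp_", rev(as.integer(d$g))))
  f3 <- fit_glmm(y ~ x + (1 | g), d3, "binomial")
  expect_equal(f1$logLik, f3$logLik, tolerance = 1e-6)
})

test_that("likelihood ratio test handles identical, nested and invalid inputs", {
  d <- make_binomial_cluster_data(seed = 61)
  f <- fit_glmm(y ~ x + (1 | g), d, "binomial")
  ## identical models: chi = 0, p = 1 (self-comparison has df 0 -> error)
  f2 <- fit_glmm(y ~ x + I(2 * x) + (1 | g), d, "binomial")
  expect_error(likelihood_ratio_test(f, f), "more parameters")
  r <- fit_glmm(y ~ 1 + (1 | g), d, "binomial")
  lrt <- likelihood_ratio_test(f, r)
  expect_gte(lrt$chi_square, 0)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p_value,
               pchisq(lrt$chi_square, 1, lower.tail = FALSE))
  ## row-count mismatch
  r2 <- fit_glmm(y ~ 1 + (1 | g), d[-1, ], "binomial")
  expect_error(likelihood_ratio_test(f, r2), "mismatch")
  ## non-nested
  d$z <- rnorm(nrow(d))
  fz <- fit_glmm(y ~ z + (1 | g), d, "binomial")
  expect_error(likelihood_ratio_test(f2, fz), "not nested")
})

test_that("null LRT rejection rate is near the nominal level", {
  ## true interaction absent; chi-square(1) calibration of the test
  set.seed(71)
  rej <- logical(120)
  warm <- NULL
  for (r in seq_along(rej)) {
    g <- factor(rep(1:50, each = 5))
    x <- rnorm(250)
    z <- rbinom(250, 1, 0.5)
    y <- rbinom(250, 1, plogis(-0.3 + 0.4 * x + 0.3 * z +
                                 rnorm(50, 0, 0.5)[g]))
    d <- data.frame(y, x, z, g)
    f1 <- fit_glmm(y ~ x * z + (1 | g), d, "binomial", start = warm)
    f0 <- fit_glmm(y ~ x + z + (1 | g), d, "binomial",
                   start = list(theta = f1$theta))
    warm <- list(theta = f1$theta)
    rej[r] <- suppressWarnings(likelihood_ratio_test(f1, f0)$p_value) < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.055)
})

test_that("marginal_predict evaluates the inverse-link fixed-effect predictor", {
  ## constructed intercept-only binomial fit at the senescent-phase
  ## intercept scale: logistic(-2.122) ~ 0.107
  fake <- structure(list(
    coefficients = c("(Intercept)" = -2.122),
    fixed_terms = terms(y ~ 1), xlevels = NULL, contrasts = NULL,
    family = "binomial"), class = "glmm_fit")
  expect_equal(marginal_predict(fake, data.frame(row = 1)),
               plogis(-2.122), tolerance = 1e-12)
  fake$coefficients <- c("(Intercept)" = 0)
  expect_equal(marginal_predict(fake, data.frame(row = 1)), 0.5)
  fake$family <- "poisson"
  expect_equal(marginal_predict(fake, data.frame(row = 1)), 1)
  ## real fit: predictions must match X beta through the link
  d <- make_binomial_cluster_data(seed = 81)
  f <- fit_glmm(y ~ x + (1 | g), d, "binomial")
  nd <- data.frame(x = c(-1, 0, 2))
  expect_equal(marginal_predict(f, nd),
               plogis(coef(f)[1] + coef(f)[2] * nd$x),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(marginal_predict(f, data.frame(z = 1)))
})

test_that("missing rows are dropped and counted, aliased columns dropped with warning", {
  d <- make_binomial_cluster_data(seed = 91)
  d$x[1:7] <- NA
  f <- fit_glmm(y ~ x + (1 | g), d, "binomial")
  expect_equal(f$n_dropped, 7L)
  expect_equal(f$n_obs, nrow(d) - 7L)
  d2 <- make_binomial_cluster_data(seed = 92)
  d2$x2 <- 2 * d2$x
  expect_warning(f2 <- fit_glmm(y ~ x + x2 + (1 | g), d2, "binomial"),
                 "aliased")
  expect_false("x2" %in% names(coef(f2)))
})

test_that("boundary variance estimates are flagged, not errors", {
  set.seed(95)
  g <- factor(rep(1:30, each = 6))
  d <- data.frame(y = rbinom(180, 1, 0.4), x = rnorm(180), g = g)
  f <- fit_glmm(y ~ x + (1 | g), d, "binomial")
  expect_true(is.finite(f$logLik))
  if (f$varcomp$sd[1] < 0.01) expect_true(f$boundary)
})
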