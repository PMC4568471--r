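## Shared fixtures and small helpers. Everything is generated in code
## under fixed seeds; no data files.

quick_ctl <- function() glmm_control(outer_reltol = 1e-8)

## small clustered binomial dataset with known structure
make_binomial_cluster_data <- function(n_groups = 40, n_per = 5,
                                       beta = c(-0.5, 0.7), sd_g = 0.8,
                                       seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_groups), each = n_per))
  x <- stats::rnorm(n_groups * n_per)
  b <- stats::rnorm(n_groups, 0, sd_g)
  eta <- beta[1] + beta[2] * x + b[g]
  data.frame(y = stats::rbinom(n_groups * n_per, 1, stats::plogis(eta)),
             x = x, g = g)
}

## two crossed grouping factors
make_two_factor_data <- function(n_groups = 50, n_per = 5, n_reg = 5,
                                 family = "binomial", seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_groups), each = n_per))
  reg <- factor(rep(rep(seq_len(n_reg), length.out = n_groups),
                    each = n_per))
  x <- stats::rnorm(n_groups * n_per)
  eta <- -0.3 + 0.5 * x + stats::rnorm(n_groups, 0, 0.7)[g] +
    stats::rnorm(n_reg, 0, 0.3)[reg]
  y <- switch(family,
              binomial = stats::rbinom(length(eta), 1, stats::plogis(eta)),
              poisson = stats::rpois(length(eta), exp(eta)),
              gaussian = eta + stats::rnorm(length(eta), 0, 1.1))
  data.frame(y = y, x = x, g = g, reg = reg)
}

## closed-form marginal Gaussian log-likelihood (independent oracle)
gaussian_marginal_loglik <- function(formula, data, beta, sd, sigma) {
  des <- repsen:::build_glmm_design(formula, data, "gaussian")
  y <- des$y
  X <- des$X
  n <- length(y)
  V <- diag(sigma^2, n)
  for (nm in names(des$group_factors)) {
    Zf <- stats::model.matrix(~ 0 + des$group_factors[[nm]])
    V <- V + sd[[nm]]^2 * tcrossprod(Zf)
  }
  r <- y - as.numeric(X %*% beta[colnames(X)])
  ch <- chol(V)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

## tiny senescent-phase dataset builder used across senescence tests
make_senescent_table <- function(n_females = 400, seed = 1,
                                 equal_declines = FALSE,
                                 drop_partial = FALSE) {
  dec <- if (equal_declines) c(high_stress = 0.0073, other = 0.0073)
         else c(high_stress = 0.022, other = 0.0073)
  pk <- if (equal_declines) c(high_stress = 0.34, other = 0.34)
        else c(high_stress = 0.46, other = 0.34)
  cfg <- sim_config(n_females = n_females, post_peak_decline = dec,
                    peak_prob = pk, seed = seed)
  pop <- simulate_population(cfg)
  bins <- attach_covariates(
    build_observation_bins(pop, drop_partial = drop_partial), pop)
  senescent_subset(bins)
}
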