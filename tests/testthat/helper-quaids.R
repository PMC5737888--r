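## Shared fixtures and independent oracles for the test suite.

## Independent naive evaluation of the budget-share system (scalar loops,
## written separately from the vectorized production code).
naive_shares <- function(par, lnp, lnm, z = NULL) {
  G <- length(par$alpha)
  alpha <- par$alpha
  if (!is.null(par$rho) && !is.null(z))
    for (i in seq_len(G)) alpha[i] <- alpha[i] + sum(par$rho[i, ] * z)
  lna <- par$alpha0
  for (j in seq_len(G)) lna <- lna + alpha[j] * lnp[j]
  for (l in seq_len(G)) for (j in seq_len(G))
    lna <- lna + 0.5 * par$gamma[l, j] * lnp[l] * lnp[j]
  b <- 1
  for (j in seq_len(G)) b <- b * exp(lnp[j])^par$beta[j]
  x <- lnm - lna
  w <- numeric(G)
  for (i in seq_len(G)) {
    w[i] <- alpha[i] + par$beta[i] * x + par$lambda[i] / b * x^2
    for (j in seq_len(G)) w[i] <- w[i] + par$gamma[i, j] * lnp[j]
  }
  w
}

## Centered demand-system shifters for a generated survey.
survey_z <- function(hh, centers) {
  cbind(age = hh$head_age - centers[["age"]],
        education = hh$head_education - centers[["education"]],
        ae = hh$adult_equivalents - centers[["ae"]])
}

## Preset tuned for recovery studies: latent-mode censoring (the observed
## share is exactly D times the noisy latent share, the quantity the
## two-step mean model describes) and a cluster count in the spirit of the
## emulated survey's 226 municipalities.
recovery_config <- function(n, seed, n_clusters = 100, ...) {
  colombia_preset(n, seed = seed, censoring_mode = "latent",
                  share_participation_corr = 0.4,
                  n_clusters = n_clusters, ...)
}

## Censored two-step fit on a latent-mode survey at the true prices,
## using the generator's true participation indicators.
fit_latent_survey <- function(s, cfg, control = quaids_control()) {
  hh <- s$households
  z <- survey_z(hh, cfg$z_centers)
  fs <- suppressWarnings(fit_participation(
    hh, s$log_prices, cfg$groups, response = s$truth$D))
  fit <- quaids_fgnls(s$shares, s$log_prices, log(hh$total_expenditure),
                      z, Phi = fs$Phi, phi = fs$phi,
                      alpha0 = cfg$true_params$alpha0,
                      control = control, group_names = cfg$groups)
  fit$first_stage <- fs
  fit
}

## True parameter set augmented with the implied censoring coefficients.
truth_with_delta <- function(s) {
  tp <- s$truth$params
  demand_parameters(tp$alpha, tp$beta, tp$lambda, tp$gamma, rho = tp$rho,
                    delta = rep(s$truth$delta, length(tp$alpha)),
                    alpha0 = tp$alpha0, group_names = tp$groups)
}

## DGP-truth elasticity matrix at the sample means of a generated survey
## (expectation version of every evaluation-point ingredient).
truth_elasticities <- function(s, cfg) {
  hh <- s$households
  n <- nrow(hh)
  G <- cfg$n_groups
  par <- truth_with_delta(s)
  PhiT <- stats::pnorm(s$truth$Dstar)
  phiT <- stats::dnorm(s$truth$Dstar)
  wstar <- PhiT * s$truth$latent_shares +
    matrix(par$delta, n, G, byrow = TRUE) * phiT
  pt <- list(lnp = colMeans(s$log_prices),
             lnm = mean(log(hh$total_expenditure)),
             z = colMeans(survey_z(hh, cfg$z_centers)),
             w_star = colMeans(wstar), Phi = colMeans(PhiT),
             phi = colMeans(phiT), Dstar = colMeans(s$truth$Dstar),
             tau = cfg$participation$tau)
  elasticity_matrix(par, pt)$e
}

## Stack the free coefficients of a fit/parameter object for bias
## bookkeeping in Monte-Carlo loops.
flatten_params <- function(par, delta = TRUE) {
  c(par$alpha, par$beta, as.numeric(par$gamma), par$lambda,
    if (delta && !is.null(par$delta)) par$delta)
}
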