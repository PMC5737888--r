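test_that("identity-weight system estimation matches an independent nonlinear least-squares oracle", {
  ## 3-good toy, no demographics, no censoring: the package estimate must
  ## agree with a hand-parameterized BFGS minimization of the stacked
  ## sum-of-squares criterion built on the naive share evaluator
  set.seed(61)
  G <- 3; n <- 400
  true <- random_demand_parameters(G, 0, sd = 0.03, alpha0 = 0)
  lnp <- matrix(rnorm(n * G, 0, 0.25), n, G)
  lnm <- rnorm(n, 2, 0.4)
  u <- matrix(rnorm(n * G, 0, 0.015), n, G)
  W <- evaluate_shares(true, lnp, lnm) + (u - rowMeans(u))

  unpack <- function(th) {
    a <- c(th[1], th[2], 1 - th[1] - th[2])
    b <- c(th[3], th[4], -th[3] - th[4])
    l <- c(th[5], th[6], -th[5] - th[6])
    g <- matrix(c(th[7], th[8], -th[7] - th[8],
                  th[8], th[9], -th[8] - th[9],
                  -th[7] - th[8], -th[8] - th[9],
                  th[7] + 2 * th[8] + th[9]), 3, 3)
    demand_parameters(a, b, l, g, alpha0 = 0)
  }
  crit <- function(th) {
    par <- unpack(th)
    sum(vapply(seq_len(n), function(h)
      sum((W[h, ] - naive_shares(par, lnp[h, ], lnm[h]))^2), numeric(1)))
  }
  th0 <- c(true$alpha[1:2], true$beta[1:2], true$lambda[1:2],
           true$gamma[1, 1], true$gamma[1, 2], true$gamma[2, 2])
  opt <- optim(th0, crit, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  oracle <- unpack(opt$par)

  fit <- quaids_fgnls(W, lnp, lnm, alpha0 = 0,
                      control = quaids_control(identity_weight = TRUE,
                                               tol_param = 1e-9,
                                               tol_crit = 1e-12))
  expect_lt(max(abs(fit$par$alpha - oracle$alpha)), 2e-3)
  expect_lt(max(abs(fit$par$beta - oracle$beta)), 2e-3)
  expect_lt(max(abs(fit$par$gamma - oracle$gamma)), 2e-3)
  expect_lt(max(abs(fit$par$lambda - oracle$lambda)), 2e-3)
  ## and both lie at (essentially) the same criterion value
  expect_lt(abs(crit(c(fit$par$alpha[1:2], fit$par$beta[1:2],
                       fit$par$lambda[1:2], fit$par$gamma[1, 1],
                       fit$par$gamma[1, 2], fit$par$gamma[2, 2])) -
                  opt$value) / opt$value, 1e-3)
})

test_that("estimation is invariant to reordering the equations", {
  set.seed(62)
  cfg <- recovery_config(1500, seed = 62, n_clusters = 30)
  s <- generate_survey(cfg)
  hh <- s$households
  z <- survey_z(hh, cfg$z_centers)
  fs <- suppressWarnings(fit_participation(hh, s$log_prices,
                                           response = s$truth$D))
  ctl <- quaids_control(tol_param = 1e-8, tol_crit = 1e-10)
  fit1 <- quaids_fgnls(s$shares, s$log_prices, log(hh$total_expenditure),
                       z, Phi = fs$Phi, phi = fs$phi, alpha0 = 2,
                       control = ctl, group_names = quaids_groups)
  perm <- c(4, 9, 1, 7, 3, 6, 2, 8, 5)
  fit2 <- quaids_fgnls(s$shares[, perm], s$log_prices[, perm],
                       log(hh$total_expenditure), z,
                       Phi = fs$Phi[, perm], phi = fs$phi[, perm],
                       alpha0 = 2, control = ctl,
                       group_names = quaids_groups[perm])
  expect_lt(max(abs(fit2$par$alpha[order(perm)] - fit1$par$alpha)), 1e-5)
  expect_lt(max(abs(fit2$par$gamma[order(perm), order(perm)] -
                      fit1$par$gamma)), 1e-5)
  expect_lt(max(abs(fit2$par$delta[order(perm)] - fit1$par$delta)), 1e-5)
})

test_that("every fit satisfies the theory restrictions by construction", {
  s <- generate_survey(colombia_preset(1000, seed = 63))
  pl <- quaids_pipeline(s$households, alpha0 = 2,
                        control = quaids_control(tol_param = 1e-4,
                                                 max_iter = 60))
  expect_true(check_quaids_constraints(pl$fit$par, tol = 1e-8))
  ## latent predicted shares add to one even though augmented means do not
  z <- sweep(cbind(s$households$head_age, s$households$head_education,
                   s$households$adult_equivalents), 2,
             pl$fit$z_center)
  w_lat <- evaluate_shares(pl$fit$par, price_matrix(pl$prices,
                                                    s$households$cluster_id),
                           log(s$households$total_expenditure), z)
  expect_lt(max(abs(rowSums(w_lat) - 1)), 1e-8)
  expect_gt(max(abs(rowSums(pl$fit$fitted) - 1)), 1e-4)
})

test_that("uncensored estimation recovers the generating parameters", {
  R <- 10
  est <- NULL; tru <- NULL
  for (r in seq_len(R)) {
    cfg <- colombia_preset(4000, seed = 640 + r, censoring_mode = "latent",
                           n_clusters = 50)
    cfg$participation$rates <- rep(0.9999, 9)
    s <- generate_survey(cfg)
    hh <- s$households
    fit <- quaids_fgnls(s$shares, s$log_prices,
                        log(hh$total_expenditure),
                        survey_z(hh, cfg$z_centers), alpha0 = 2,
                        group_names = quaids_groups)
    est <- rbind(est, flatten_params(fit$par, delta = FALSE))
    tru <- rbind(tru, flatten_params(s$truth$params, delta = FALSE))
  }
  err <- est - tru
  bias <- colMeans(err)
  mcse <- apply(err, 2, sd) / sqrt(R)
  ## the large majority of parameters show no detectable bias (the MC
  ## standard errors are themselves noisy at 10 replicates)
  expect_gte(mean(abs(bias) <= 2 * mcse), 0.85)
  expect_lt(max(abs(bias)), 0.02)
})

test_that("an anchor above the expenditure range is flagged", {
  s <- generate_survey(colombia_preset(300, seed = 65))
  expect_warning(
    quaids_fgnls(s$shares, s$log_prices,
                 log(s$households$total_expenditure),
                 alpha0 = 20,
                 control = quaids_control(max_iter = 3)),
    "alpha0")
})

test_that("household weights reweight the criterion", {
  set.seed(66)
  G <- 3; n <- 500
  true <- random_demand_parameters(G, 0, sd = 0.03, alpha0 = 0)
  lnp <- matrix(rnorm(n * G, 0, 0.25), n, G)
  lnm <- rnorm(n, 2, 0.4)
  u <- matrix(rnorm(n * G, 0, 0.01), n, G)
  W <- evaluate_shares(true, lnp, lnm) + (u - rowMeans(u))
  half <- seq_len(n) <= n / 2
  wts <- ifelse(half, 1, 1e-8)
  fit_w <- quaids_fgnls(W, lnp, lnm, alpha0 = 0, weights = wts)
  fit_h <- quaids_fgnls(W[half, ], lnp[half, ], lnm[half], alpha0 = 0)
  expect_lt(max(abs(fit_w$par$gamma - fit_h$par$gamma)), 1e-4)
})
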