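make_point <- function(par, seed) {
  set.seed(seed)
  G <- length(par$alpha)
  tau <- matrix(rnorm(G * G, 0, 0.05), G, G)
  diag(tau) <- -0.3
  list(tau = tau, pi_exp = rep(0.2, G),
       intercepts = rnorm(G, 0.8, 0.2),
       lnp = rnorm(G, 0, 0.15), lnm = 4.2, z = rnorm(3, 0, 0.3))
}

test_that("the analytic elasticity matrix matches a finite-difference oracle at O(h^2)", {
  set.seed(71)
  worst <- c(`0.001` = 0, `1e-04` = 0)
  for (r in 1:10) {
    par <- random_demand_parameters(9, 3, sd = 0.01, censoring = TRUE,
                                    alpha0 = 2)
    pp <- make_point(par, 710 + r)
    pt <- evaluation_point(pp$lnp, pp$lnm, pp$z, par = par, tau = pp$tau,
                           pi_exp = pp$pi_exp, intercepts = pp$intercepts)
    e <- elasticity_matrix(par, pt)$e
    for (h in c(1e-3, 1e-4)) {
      fd <- vapply(1:9, function(j) {
        up <- pp$lnp; up[j] <- up[j] + h
        dn <- pp$lnp; dn[j] <- dn[j] - h
        (augmented_demand(par, up, pp$lnm, pp$z, pp$tau, pp$pi_exp,
                          pp$intercepts)$log_quantity -
           augmented_demand(par, dn, pp$lnm, pp$z, pp$tau, pp$pi_exp,
                            pp$intercepts)$log_quantity) / (2 * h)
      }, numeric(9))
      worst[as.character(h)] <- max(worst[as.character(h)],
                                    max(abs(e - fd)))
    }
  }
  expect_lt(worst[["0.001"]], 1e-4)
  expect_lt(worst[["1e-04"]], 1e-6)
})

test_that("the uncensored lambda-free limit reproduces the classic AIDS formula", {
  set.seed(72)
  for (r in 1:10) {
    par0 <- random_demand_parameters(9, 3, sd = 0.01, alpha0 = 2)
    par <- demand_parameters(par0$alpha, par0$beta, numeric(9),
                             par0$gamma, rho = par0$rho, alpha0 = 2)
    lnp <- rnorm(9, 0, 0.15); lnm <- 4.2; z <- rnorm(3, 0, 0.3)
    w <- drop(evaluate_shares(par, lnp, lnm, z))
    pt <- list(lnp = lnp, lnm = lnm, z = z, w_star = w,
               Phi = rep(1, 9), phi = rep(0, 9), Dstar = rep(0, 9),
               tau = matrix(0, 9, 9))
    e <- elasticity_matrix(par, pt)$e
    ## separately coded AIDS Marshallian elasticities
    aj <- par$alpha + drop(par$rho %*% z) + drop(par$gamma %*% lnp)
    eA <- -diag(9) + (par$gamma - outer(par$beta, aj)) / w
    expect_lt(max(abs(e - eA)), 1e-12)
  }
})

test_that("price and expenditure elasticities aggregate to homogeneity", {
  set.seed(73)
  for (r in 1:10) {
    par <- random_demand_parameters(9, 3, sd = 0.01, alpha0 = 2)
    lnp <- rnorm(9, 0, 0.15); lnm <- 4.2; z <- rnorm(3, 0, 0.3)
    w <- drop(evaluate_shares(par, lnp, lnm, z))
    pt <- list(lnp = lnp, lnm = lnm, z = z, w_star = w,
               Phi = rep(1, 9), phi = rep(0, 9), Dstar = rep(0, 9),
               tau = matrix(0, 9, 9))
    e <- elasticity_matrix(par, pt)$e
    ee <- expenditure_elasticities(par, lnp, lnm, z)
    expect_lt(max(abs(rowSums(e) + ee)), 1e-8)
  }
})

test_that("elasticities are invariant to a joint price-expenditure rescaling", {
  set.seed(74)
  par <- random_demand_parameters(9, 3, sd = 0.01, censoring = TRUE,
                                  alpha0 = 2)
  pp <- make_point(par, 74)
  pt <- evaluation_point(pp$lnp, pp$lnm, pp$z, par = par, tau = pp$tau,
                         pi_exp = pp$pi_exp, intercepts = pp$intercepts)
  e1 <- elasticity_matrix(par, pt)$e
  pt2 <- pt
  pt2$lnp <- pt$lnp + 0.4        # evaluation-point terms held fixed
  pt2$lnm <- pt$lnm + 0.4
  e2 <- elasticity_matrix(par, pt2)$e
  expect_lt(max(abs(e1 - e2)), 1e-10)
})

test_that("a zero mean share is rejected", {
  par <- random_demand_parameters(3, 0, sd = 0.01, alpha0 = 0)
  pt <- list(lnp = rep(0, 3), lnm = 2, z = NULL,
             w_star = c(0, 0.5, 0.5), Phi = rep(1, 3), phi = rep(0, 3),
             Dstar = rep(0, 3), tau = matrix(0, 3, 3))
  expect_error(elasticity_matrix(par, pt), "positive")
})

test_that("significance stars follow the two-sided normal convention", {
  e <- matrix(c(-2.8, -1.0, -0.5, -0.1), 2, 2)
  se <- matrix(1, 2, 2)
  s <- cquaids:::significance_stars(e, se)
  expect_equal(as.vector(s), c("***", "", "", ""))
  s2 <- cquaids:::significance_stars(matrix(c(1.7, 2.1, 2.6, 3)),
                                     matrix(1, 4, 1))
  expect_equal(as.vector(s2), c("*", "**", "***", "***"))
})

test_that("bootstrap standard errors are reproducible and well-formed", {
  s <- generate_survey(colombia_preset(500, seed = 75))
  ctl <- quaids_control(tol_param = 1e-3, max_iter = 40)
  b1 <- suppressWarnings(bootstrap_elasticities(
    s$households, n_reps = 3, seed = 9, alpha0 = 2, control = ctl))
  b2 <- suppressWarnings(bootstrap_elasticities(
    s$households, n_reps = 3, seed = 9, alpha0 = 2, control = ctl))
  expect_identical(b1$se, b2$se)
  expect_true(all(b1$se >= 0))
  expect_equal(dim(b1$se), c(9, 9))
  expect_true(all(b1$stars %in% c("", "*", "**", "***")))
  b3 <- suppressWarnings(bootstrap_elasticities(
    s$households, n_reps = 3, seed = 10, alpha0 = 2, control = ctl))
  expect_false(identical(b1$se, b3$se))
  ## long-form export carries estimates, SEs and stars
  df <- as.data.frame(b1)
  expect_equal(nrow(df), 81)
  expect_true(all(c("elasticity", "se", "stars") %in% names(df)))
})
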