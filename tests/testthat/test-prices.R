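test_that("noise-free cluster prices are recovered exactly", {
  cfg <- colombia_preset(600, seed = 41, quality_noise_sd = 0,
                         epsilon = rep(0, 9), eta = matrix(0, 9, 6))
  s <- generate_survey(cfg)
  prices <- cluster_price_set(s$households)
  pm <- price_matrix(prices, s$households$cluster_id)
  expect_lt(max(abs(pm - s$log_prices)), 1e-10)
  expect_false(any(prices$imputed))
})

test_that("cluster demeaning equals explicit cluster-indicator least squares", {
  set.seed(42)
  n <- 300
  cl <- sample(1:8, n, replace = TRUE)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.5 * x1 - 0.2 * x2 + rnorm(8)[cl] + rnorm(n, 0, 0.3)
  dm <- function(v) v - ave(v, cl)
  b_within <- qr.coef(qr(cbind(dm(x1), dm(x2))), dm(y))
  b_lsdv <- coef(lm(y ~ x1 + x2 + factor(cl)))[c("x1", "x2")]
  expect_equal(unname(b_within), unname(b_lsdv), tolerance = 1e-10)
})

test_that("quality coefficients are recovered from the unit-value model", {
  ## forward model with exogenous quantities: ln v = ln p_c + eps ln q +
  ## eta'z + u; expenditure is quantity times unit value
  set.seed(43)
  eps_true <- 0.08
  eta_true <- 0.02
  hits <- 0
  R <- 30
  ests <- numeric(R)
  for (r in seq_len(R)) {
    n <- 2500; ncl <- 25
    cl <- sample.int(ncl, n, replace = TRUE)
    lnp_c <- rnorm(ncl, log(0.7), 0.15)
    lnq <- rnorm(n, 1, 0.6)
    edu <- round(rnorm(n, 12, 4))
    lnv <- lnp_c[cl] + eps_true * lnq + eta_true * edu + rnorm(n, 0, 0.05)
    hh <- data.frame(household_id = 1:n, cluster_id = cl,
                     head_age = round(rnorm(n, 47, 12)),
                     head_gender = rbinom(n, 1, 0.6),
                     head_education = edu,
                     adult_equivalents = runif(n, 1, 6),
                     has_children = rbinom(n, 1, 0.7),
                     single_household = rbinom(n, 1, 0.05),
                     exp_test = exp(lnq + lnv), qty_test = exp(lnq))
    fit <- estimate_unit_value_model(hh, "test")
    ests[r] <- fit$epsilon
    if (abs(fit$eta[["head_education"]] - eta_true) < 0.01 &&
        !fit$clusters$imputed[1])
      hits <- hits + 1
  }
  mc_se <- sd(ests) / sqrt(R)
  expect_lt(abs(mean(ests) - eps_true), 3 * mc_se)
  expect_gte(hits / R, 0.9)
})

test_that("clusters with no purchasers get an imputed, flagged price", {
  cfg <- colombia_preset(400, seed = 44)
  s <- generate_survey(cfg)
  hh <- s$households
  drop_cl <- hh$cluster_id == 1
  hh$exp_ssb[drop_cl] <- 0
  hh$qty_ssb[drop_cl] <- 0
  fit <- estimate_unit_value_model(hh, "ssb")
  expect_true(fit$clusters$imputed[fit$clusters$cluster_id == 1])
  expect_equal(fit$clusters$ln_price[fit$clusters$cluster_id == 1],
               mean(fit$clusters$ln_price[!fit$clusters$imputed]))
  ## every household still receives a full price vector
  pm <- price_matrix(cluster_price_set(hh), hh$cluster_id)
  expect_true(all(is.finite(pm)))
})

test_that("recovered SSB prices average near the preset unit-value level", {
  s <- generate_survey(colombia_preset(6000, seed = 45))
  prices <- cluster_price_set(s$households)
  ssb <- prices[prices$group == "ssb", ]
  ## mean exponentiated cluster price close to the 0.71 USD/L target;
  ## cluster log prices have sd 0.1 so the cross-cluster mean carries
  ## both lognormal curvature and estimation noise
  expect_lt(abs(mean(exp(ssb$ln_price)) - 0.71), 0.035)
})

test_that("collinear unit-value regressors are reported by name", {
  cfg <- colombia_preset(300, seed = 46)
  s <- generate_survey(cfg)
  hh <- s$households
  hh$head_education <- hh$adult_equivalents   # force exact collinearity
  expect_error(estimate_unit_value_model(hh, "grains"), "collinear")
})

test_that("control-function residuals are orthogonal to the instruments", {
  s <- generate_survey(colombia_preset(1500, seed = 47))
  res <- expenditure_control_residual(s$households)
  expect_lt(abs(mean(res$residual)), 1e-8)
  ## regressing the residual back on the instruments returns zeros
  X <- model.matrix(~ ses + factor(cluster_id) + head_age + head_gender +
                      head_education + adult_equivalents,
                    s$households)
  b <- qr.coef(qr(X), res$residual)
  expect_lt(max(abs(b)), 1e-8)
})

test_that("constant-only instruments give demeaned log expenditure", {
  s <- generate_survey(colombia_preset(200, seed = 48))
  res <- expenditure_control_residual(s$households,
                                      instruments = character(0))
  lnm <- log(s$households$total_expenditure)
  expect_equal(res$residual, lnm - mean(lnm), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a rank-deficient instrument set is rejected with the offending column", {
  s <- generate_survey(colombia_preset(200, seed = 49))
  hh <- s$households
  hh$dup_edu <- hh$head_education
  expect_error(
    expenditure_control_residual(hh, instruments = c("head_education",
                                                     "dup_edu")),
    "dup_edu")
})

test_that("the first-stage expenditure model explains the share the DGP built in", {
  ## R^2 of the instrument regression tracks the DGP's own explained
  ## variance fraction across replicates
  diffs <- vapply(1:10, function(r) {
    s <- generate_survey(colombia_preset(2000, seed = 400 + r))
    hh <- s$households
    res <- expenditure_control_residual(hh)
    ex <- s$config$expenditure
    amen <- (hh$amen_gas + hh$amen_electricity + hh$amen_water) / 3
    sys <- ex$ses_mid * (hh$ses == "midhigh") + ex$amenities * amen +
      ex$age * hh$head_age + ex$education * hh$head_education +
      ex$ae * hh$adult_equivalents
    lnm <- log(hh$total_expenditure)
    r2_dgp <- 1 - (ex$sd^2 + ex$cluster_sd^2) / var(lnm)
    attr(res, "r_squared") - r2_dgp
  }, numeric(1))
  ## cluster effects are absorbed by the cluster indicators, so the fitted
  ## R^2 slightly exceeds the noise-based DGP value; the gap stays small
  expect_lt(abs(mean(diffs)), 0.03)
  expect_lt(sd(diffs), 0.03)
})
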