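test_that("adult-equivalent weights follow the age schedule", {
  expect_equal(adult_equivalents(30), 1.0)
  expect_equal(adult_equivalents(c(4, 8, 15, 40)), 3.45)
  ## boundary table: stated ranges inclusive, age 5 takes the infant weight
  expect_equal(adult_equivalents(0), 0.77)
  expect_equal(adult_equivalents(5), 0.77)
  expect_equal(adult_equivalents(6), 0.80)
  expect_equal(adult_equivalents(12), 0.80)
  expect_equal(adult_equivalents(12.9), 0.80)   # completed years
  expect_equal(adult_equivalents(13), 0.88)
  expect_equal(adult_equivalents(18), 0.88)
  expect_equal(adult_equivalents(19), 1.0)
  expect_equal(adult_equivalents(c(5, 6, 13, 19)), 0.77 + 0.80 + 0.88 + 1)
  expect_error(adult_equivalents(numeric(0)), "empty")
  expect_error(adult_equivalents(-1), "nonnegative")
})

test_that("the generator is deterministic given the seed", {
  s1 <- generate_survey(colombia_preset(400, seed = 31))
  s2 <- generate_survey(colombia_preset(400, seed = 31))
  expect_identical(s1$households, s2$households)
  expect_identical(s1$shares, s2$shares)
  s3 <- generate_survey(colombia_preset(400, seed = 32))
  expect_false(identical(s1$shares, s3$shares))
})

test_that("noise-free unit values equal the cluster price exactly", {
  cfg <- colombia_preset(500, seed = 33, quality_noise_sd = 0,
                         epsilon = rep(0, 9), eta = matrix(0, 9, 6))
  s <- generate_survey(cfg)
  E <- as.matrix(s$households[, paste0("exp_", quaids_groups)])
  Q <- as.matrix(s$households[, paste0("qty_", quaids_groups)])
  pos <- E > 0
  uv <- log(E[pos]) - log(Q[pos])
  expect_lt(max(abs(uv - s$log_prices[pos])), 1e-10)
})

test_that("simulated SSB participation matches the preset target", {
  s <- generate_survey(colombia_preset(6000, seed = 34))
  rate <- mean(s$households$exp_ssb > 0)
  ## binomial Monte-Carlo error around the 32.4% target
  expect_lt(abs(rate - 0.324), 3 * sqrt(0.324 * 0.676 / 6000))
})

test_that("observed shares add to one per household after renormalization", {
  s <- generate_survey(colombia_preset(800, seed = 35))
  expect_lt(max(abs(rowSums(s$shares) - 1)), 1e-12)
  ## expenditure and quantity are zero together or positive together
  E <- as.matrix(s$households[, paste0("exp_", quaids_groups)])
  Q <- as.matrix(s$households[, paste0("qty_", quaids_groups)])
  expect_true(all((E > 0) == (Q > 0)))
  expect_true(all(rowSums(E) > 0))
})

test_that("participation rates are monotone in the participation target", {
  base <- colombia_preset(3000, seed = 36)
  lo <- base; lo$participation$rates[3] <- 0.15
  hi <- base; hi$participation$rates[3] <- 0.55
  r_lo <- mean(generate_survey(lo)$households$exp_ssb > 0)
  r_hi <- mean(generate_survey(hi)$households$exp_ssb > 0)
  expect_lt(r_lo, r_hi)
})

test_that("with censoring off, mean shares converge to the latent system at mean covariates", {
  cfg <- colombia_preset(8000, seed = 37, censoring_mode = "latent")
  cfg$participation$rates <- rep(0.9999, 9)
  s <- generate_survey(cfg)
  got <- colMeans(s$shares)
  want <- colMeans(s$truth$latent_shares)
  ## sampling error of a mean share is below share_noise_sd / sqrt(n)
  expect_lt(max(abs(got - want)), 6 * cfg$share_noise_sd / sqrt(8000))
})

test_that("a mismatched parameter dimension is a configuration error", {
  par3 <- random_demand_parameters(3, 3)
  expect_error(generator_config(100, par3), "number of goods")
})

test_that("survey files are written as plain text and carry the ground truth", {
  s <- generate_survey(colombia_preset(120, seed = 38))
  d <- tempfile()
  paths <- write_survey(s, d)
  expect_true(all(file.exists(paths)))
  hh <- read.csv(paths["households"])
  expect_equal(nrow(hh), 120)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(sum(truth$alpha), 1, tolerance = 1e-10)
  unlink(d, recursive = TRUE)
})
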