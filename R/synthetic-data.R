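#' Food group labels used by the packaged presets
#'
#' Nine mutually exclusive food-at-home groups: unsweetened milk; tea,
#' bottled water and coffee; sugar-sweetened beverages; sweets and candies
#' (incl. sugar); other dairy products; grain-based staples; meats and
#' animal products; fruits and vegetables; condiments and snacks
#' (residual group).
#' @export
quaids_groups <- c("milk", "teacoffee", "ssb", "sweets", "dairy",
                   "grains", "meats", "fruitveg", "condiments")

#' Adult-equivalent household size
#'
#' Converts a vector of member ages (years) into adult-equivalent units:
#' members aged 5 or under count 0.77, ages 6 through 12 count 0.80,
#' ages 13 through 18 count 0.88, and adults above 18 count 1.0.
#' Fractional ages are truncated to completed years before lookup, and the
#' stated ranges are treated as inclusive of both endpoints (so a
#' five-year-old counts 0.77).
#'
#' @param ages numeric vector of nonnegative member ages in years.
#' @return The adult-equivalent size of the household (positive scalar).
#' @examples
#' adult_equivalents(c(4, 8, 15, 40))  # 0.77 + 0.80 + 0.88 + 1 = 3.45
#' @export
adult_equivalents <- function(ages) {
  if (length(ages) == 0) stop("empty age vector")
  if (any(!is.finite(ages)) || any(ages < 0)) stop("ages must be nonnegative")
  yrs <- floor(ages)
  sum(ifelse(yrs <= 5, 0.77,
             ifelse(yrs <= 12, 0.80,
                    ifelse(yrs <= 18, 0.88, 1.0))))
}

ae_weight <- function(yrs) ifelse(yrs <= 5, 0.77,
                                  ifelse(yrs <= 12, 0.80,
                                         ifelse(yrs <= 18, 0.88, 1.0)))

#' Configuration of the synthetic survey generator
#'
#' Bundles everything the generator needs: the true demand parameters, the
#' participation (probit) model, the cluster price distribution, the
#' unit-value quality model, demographics and noise scales.  Most users
#' will start from [colombia_preset()] and override fields.
#'
#' @param n_households number of households to simulate.
#' @param true_params a constraint-consistent [demand_parameters()] object
#'   (its `rho` must have 3 columns: centered head age, head education,
#'   adult-equivalent size).
#' @param n_clusters number of municipal price clusters.
#' @param price_level numeric `G`-vector of mean unit values (currency per
#'   kg or liter) around which cluster log prices are drawn.
#' @param price_dispersion sd of cluster log prices around `log(price_level)`.
#' @param participation list with `tau` (`G x G` log-price coefficients),
#'   `pi` (`G` log-expenditure coefficients), `theta` (`G x 4` coefficients
#'   on centered education, centered adult-equivalents, children dummy,
#'   single dummy) and `rates` (`G` target participation fractions; the
#'   probit intercepts are calibrated against the realized sample so the
#'   expected participation equals `rates`).
#' @param epsilon numeric `G`-vector: quality (log-quantity) coefficients of
#'   the unit-value model.
#' @param eta `G x 6` matrix of unit-value demographic coefficients
#'   (head age, head gender, head education, adult equivalents, children
#'   dummy, single dummy).
#' @param quality_noise_sd sd of the idiosyncratic unit-value disturbance.
#' @param share_noise_sd sd of the (sum-zero projected) latent share noise.
#' @param share_participation_corr correlation between a group's raw share
#'   noise and its participation error; generates a nonzero true
#'   censoring-correction coefficient `delta`.
#' @param expenditure list of log-expenditure model coefficients
#'   (`intercept`, `ses_mid`, `amenities`, `age`, `education`, `ae`,
#'   `cluster_sd`, `sd`).
#' @param z_centers centering constants for (head age, head education,
#'   adult equivalents) used for the demand-system shifters.
#' @param censoring_mode `"selection"` (default): observed shares are the
#'   positive-purchase latent shares renormalized to the food budget, so
#'   every retained household's shares add to one.  `"latent"`: observed
#'   shares are `D * (w + noise)` with no renormalization, matching the
#'   two-step estimator's mean model exactly; used for recovery studies.
#' @param groups character vector of group names.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_households, true_params,
                             n_clusters = 20,
                             price_level = NULL,
                             price_dispersion = 0.10,
                             participation = NULL,
                             epsilon = NULL, eta = NULL,
                             quality_noise_sd = 0.05,
                             share_noise_sd = 0.01,
                             share_participation_corr = 0.4,
                             expenditure = NULL,
                             z_centers = c(age = 47.8, education = 12.2,
                                           ae = 3.83),
                             censoring_mode = c("selection", "latent"),
                             groups = quaids_groups,
                             seed = 1L) {
  G <- length(true_params$alpha)
  censoring_mode <- match.arg(censoring_mode)
  if (length(groups) != G)
    stop("length(groups) does not match the number of goods in true_params")
  if (is.null(price_level)) price_level <- rep(1, G)
  if (is.null(epsilon)) epsilon <- rep(0, G)
  if (is.null(eta)) eta <- matrix(0, G, 6)
  if (is.null(participation))
    participation <- list(
      tau = diag(-0.4, G) + 0.03 - diag(0.03, G),
      pi = rep(0.25, G),
      theta = matrix(c(0.01, 0.05, 0.15, -0.2), G, 4, byrow = TRUE),
      rates = rep(0.9, G))
  if (is.null(expenditure))
    expenditure <- list(intercept = 3.75, ses_mid = 0.25, amenities = 0.15,
                        age = 0.004, education = 0.02, ae = 0.08,
                        cluster_sd = 0.05, sd = 0.35)
  stopifnot(n_households > 0, n_clusters > 0,
            length(price_level) == G, price_dispersion >= 0,
            quality_noise_sd >= 0, share_noise_sd >= 0,
            abs(share_participation_corr) <= 1,
            length(participation$pi) == G,
            all(dim(participation$tau) == G),
            nrow(participation$theta) == G,
            length(participation$rates) == G,
            length(epsilon) == G, nrow(eta) == G, ncol(eta) == 6)
  check_quaids_constraints(true_params)
  structure(list(n_households = as.integer(n_households),
                 n_groups = G, n_clusters = as.integer(n_clusters),
                 true_params = true_params, price_level = price_level,
                 price_dispersion = price_dispersion,
                 participation = participation,
                 epsilon = epsilon, eta = eta,
                 quality_noise_sd = quality_noise_sd,
                 share_noise_sd = share_noise_sd,
                 share_participation_corr = share_participation_corr,
                 expenditure = expenditure, z_centers = z_centers,
                 censoring_mode = censoring_mode,
                 groups = groups, seed = as.integer(seed)),
            class = "generator_config")
}

## Calibrate the preset's gamma diagonal and alpha so that, at the preset
## evaluation point (mean log unit values, mean log expenditure, centered
## demographics), the latent shares equal the target shares and the
## uncensored own-price elasticities approach their targets.
calibrate_preset_params <- function(w_target, lnp, lnm, e_target,
                                    beta, lambda, rho, alpha0,
                                    groups, n_iter = 200) {
  G <- length(w_target)
  d <- w_target * (e_target + 1)
  alpha <- w_target
  par <- NULL
  for (it in seq_len(n_iter)) {
    gamma <- center_gamma(diag(d, G))
    ## choose alpha so shares at the evaluation point hit w_target
    for (j in 1:25) {
      lna <- alpha0 + sum(alpha * lnp) + 0.5 * drop(lnp %*% gamma %*% lnp)
      b <- exp(sum(beta * lnp)); x <- lnm - lna
      alpha <- w_target - drop(gamma %*% lnp) - beta * x - lambda * x^2 / b
    }
    par <- demand_parameters(alpha, beta, lambda, gamma, rho = rho,
                             alpha0 = alpha0, tol = 1e-7,
                             group_names = groups)
    idx <- quaids_indices(par, matrix(lnp, nrow = 1), lnm)
    mu <- beta + 2 * lambda * idx$x / idx$b
    e_own <- -1 + (diag(gamma) -
                     mu * (drop(idx$alpha_h) + drop(idx$pg)) -
                     lambda * beta * idx$x^2 / idx$b) / w_target
    step <- w_target * (e_target - e_own)
    if (max(abs(step)) < 1e-10) break
    d <- d + 0.8 * step
  }
  par
}

#' Colombia-like synthetic survey preset
#'
#' Generator configuration emulating an urban household income and
#' expenditure survey with nine food groups: group-level participation
#' rates, mean budget shares and mean unit values follow the published
#' descriptive targets for the Colombian 2006-2007 survey (e.g. 32.4%
#' of households purchasing sugar-sweetened beverages, a 2.5% mean SSB
#' budget share, a 0.71 USD/liter mean SSB unit value), and the true
#' price-coefficient matrix is calibrated so the latent own-price
#' elasticity of the SSB group is close to -1.6 at the preset means.
#' Expenditure is in 2007 USD per month; the translog anchor of the true
#' parameters is set to 2, below the minimum realized log expenditure.
#'
#' @param n_households number of households (default 5000).
#' @param seed integer seed.
#' @param ... overrides passed on to [generator_config()].
#' @return A `generator_config` object.
#' @export
colombia_preset <- function(n_households = 5000, seed = 1L, ...) {
  dots <- list(...)
  shares <- c(0.095, 0.027, 0.025, 0.045, 0.132, 0.179, 0.266, 0.191, 0.040)
  uv <- c(0.69, 0.13, 0.71, 0.94, 2.32, 1.40, 3.65, 0.89, 5.56)
  rates <- c(0.764, 0.630, 0.324, 0.765, 0.919, 0.944, 0.876, 0.918, 0.792)
  e_own <- c(-1.05, -1.35, -1.616, -0.80, -0.94, -0.85, -0.84, -0.96, -1.01)
  beta <- c(0.010, -0.005, 0.003, -0.008, 0.010, -0.020, 0.015, -0.010, 0.005)
  lambda <- c(0.002, -0.001, 0.001, -0.002, 0.002, -0.003, 0.002, -0.002,
              0.001)
  G <- 9L
  ## small demographic shifters (age, education, adult equivalents), with
  ## zero column sums
  rho <- matrix(c(-2, 1, -1, 1, 2, -2, 3, -1, -1,
                  3, 1, 2, -2, 1, -3, 2, -2, -2,
                  4, -1, 1, 2, 1, 3, -5, -3, -2) * 1e-3, G, 3)
  rho <- sweep(rho, 2, colMeans(rho))
  lnm0 <- 4.71                       # preset mean log expenditure (USD/month)
  par <- calibrate_preset_params(shares, log(uv), lnm0, e_own,
                                 beta, lambda, rho, alpha0 = 2,
                                 groups = quaids_groups)
  tau <- diag(-0.40 - 0.03, G) + 0.03
  theta <- cbind(education = rep(0.012, G), ae = rep(0.05, G),
                 children = c(0.25, 0.05, 0.20, 0.20, 0.15, 0.05, 0.05,
                              0.05, 0.10),
                 single = rep(-0.25, G))
  eta <- cbind(age = rep(2e-4, G), gender = rep(-0.005, G),
               education = rep(0.004, G), ae = rep(-0.003, G),
               children = rep(-0.01, G), single = rep(0.01, G))
  args <- list(
    n_households = n_households, true_params = par,
    price_level = uv,
    participation = list(tau = tau, pi = rep(0.25, G), theta = theta,
                         rates = rates),
    epsilon = rep(0.05, G), eta = eta,
    seed = seed)
  do.call(generator_config, utils::modifyList(args, dots))
}

#' Simulate a household expenditure survey from a known QUAIDS process
#'
#' Draws municipal cluster log prices, household demographics and total
#' food expenditure; evaluates latent budget shares at the true parameters
#' plus sum-zero Gaussian share noise; draws per-group purchase decisions
#' from probit participation indices whose errors may be correlated with
#' the share noise; and converts observed expenditures into quantities via
#' a unit-value model in which log unit value is the cluster log price
#' plus a quality term in log quantity, demographics and noise.
#' Households with no purchases in any group have their participation
#' errors redrawn (the count is recorded).
#'
#' @param config a [generator_config()], e.g. from [colombia_preset()].
#' @return A list of class `quaids_survey` with elements
#'   \item{households}{data frame, one row per household: identifiers,
#'     demographics, amenities, weight, and per-group `exp_*` / `qty_*`
#'     columns (zero together or positive together per group);}
#'   \item{shares}{`n x G` observed budget-share matrix used as the
#'     estimation response;}
#'   \item{log_prices}{`n x G` matrix of the household's true cluster log
#'     prices;}
#'   \item{cluster_prices}{data frame of true cluster log prices;}
#'   \item{truth}{ground truth: `params`, the calibrated probit
#'     `intercepts`, `delta` (implied censoring-correction coefficients),
#'     `epsilon`, `eta`, participation indices, and the resample count.}
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_households; G <- config$n_groups
  par <- config$true_params
  groups <- config$groups

  ## --- cluster prices -------------------------------------------------
  C <- matrix(stats::rnorm(config$n_clusters * G,
                           mean = rep(log(config$price_level),
                                      each = config$n_clusters),
                           sd = config$price_dispersion),
              config$n_clusters, G, dimnames = list(NULL, groups))
  cluster_id <- sample.int(config$n_clusters, n, replace = TRUE)
  lnp <- C[cluster_id, , drop = FALSE]

  ## --- demographics ---------------------------------------------------
  ses <- ifelse(stats::runif(n) < 0.608, "low", "midhigh")
  mid <- ses == "midhigh"
  head_age <- round(pmin(pmax(stats::rnorm(n, ifelse(mid, 50.2, 46.4), 14),
                              18), 95))
  head_gender <- as.integer(stats::runif(n) < ifelse(mid, 0.62, 0.64))
  head_education <- round(pmin(pmax(
    stats::rnorm(n, ifelse(mid, 14.7, 10.6), 3.5), 0), 22))
  n_adults_extra <- stats::rpois(n, 1.5)
  n_children <- stats::rpois(n, 1.6)
  child_ages <- lapply(n_children, function(k)
    if (k > 0) sample(0:17, k, replace = TRUE) else integer(0))
  adult_ae <- 1 + n_adults_extra          # adults weight 1.0 each
  child_ae <- vapply(child_ages, function(a)
    if (length(a)) sum(ae_weight(a)) else 0, numeric(1))
  ae <- adult_ae + child_ae
  household_size <- 1 + n_adults_extra + n_children
  has_children <- as.integer(n_children > 0)
  single_household <- as.integer(household_size == 1)
  amen_gas <- as.integer(stats::runif(n) < 0.85)
  amen_electricity <- as.integer(stats::runif(n) < 0.97)
  amen_water <- as.integer(stats::runif(n) < 0.92)
  amenities <- (amen_gas + amen_electricity + amen_water) / 3

  ## --- total food expenditure (log), driven by the instrument set ------
  ex <- config$expenditure
  cl_eff <- stats::rnorm(config$n_clusters, 0, ex$cluster_sd)
  lnm <- ex$intercept + ex$ses_mid * mid + ex$amenities * amenities +
    ex$age * head_age + ex$education * head_education + ex$ae * ae +
    cl_eff[cluster_id] + stats::rnorm(n, 0, ex$sd)
  m <- exp(lnm)

  ## --- latent shares + noise ------------------------------------------
  zc <- config$z_centers
  z_demand <- cbind(age = head_age - zc[["age"]],
                    education = head_education - zc[["education"]],
                    ae = ae - zc[["ae"]])
  w_lat <- evaluate_shares(par, lnp, lnm, z_demand)
  u_raw <- matrix(stats::rnorm(n * G, 0, config$share_noise_sd), n, G)
  u <- u_raw - rowMeans(u_raw)          # keeps adding-up exact

  ## --- participation ---------------------------------------------------
  pp <- config$participation
  z_probit <- cbind(head_education - zc[["education"]], ae - zc[["ae"]],
                    has_children, single_household)
  idx0 <- lnp %*% t(pp$tau) + outer(lnm, pp$pi) + z_probit %*% t(pp$theta)
  intercepts <- vapply(seq_len(G), function(i) {
    f <- function(t) mean(stats::pnorm(t + idx0[, i])) - pp$rates[i]
    stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  }, numeric(1))
  Dstar <- sweep(idx0, 2, intercepts, "+")
  rr <- config$share_participation_corr
  sdsh <- config$share_noise_sd
  draw_D <- function(rows) {
    k <- length(rows)
    e <- matrix(stats::rnorm(k * G), k, G)
    v <- if (sdsh > 0) rr * (u_raw[rows, , drop = FALSE] / sdsh) +
      sqrt(1 - rr^2) * e else e
    (Dstar[rows, , drop = FALSE] > v) * 1L
  }
  D <- draw_D(seq_len(n))
  resampled <- 0L
  empty <- which(rowSums(D) == 0)
  while (length(empty) > 0 && resampled < 100L * n) {
    resampled <- resampled + length(empty)
    D[empty, ] <- draw_D(empty)
    empty <- empty[rowSums(D[empty, , drop = FALSE]) == 0]
  }

  ## --- observed shares -------------------------------------------------
  W <- D * (w_lat + u)
  if (config$censoring_mode == "selection") {
    W[D == 1L & W < 1e-3] <- 1e-3       # simplex floor for purchasers
    W <- W / rowSums(W)
  }

  ## --- expenditures, unit values, quantities ---------------------------
  E <- W * m
  lnv <- matrix(NA_real_, n, G)
  zuv <- cbind(head_age, head_gender, head_education, ae, has_children,
               single_household)
  for (i in seq_len(G)) {
    pos <- E[, i] > 0
    uqn <- stats::rnorm(n, 0, config$quality_noise_sd)
    lnv[pos, i] <- (lnp[pos, i] + config$epsilon[i] * log(E[pos, i]) +
                      drop(zuv[pos, , drop = FALSE] %*% config$eta[i, ]) +
                      uqn[pos]) / (1 + config$epsilon[i])
  }
  Q <- matrix(0, n, G)
  pos <- is.finite(lnv) & E > 0
  Q[pos] <- E[pos] / exp(lnv[pos])
  E[!pos] <- 0

  hh <- data.frame(household_id = seq_len(n), cluster_id = cluster_id,
                   weight = 1, ses = ses, head_age = head_age,
                   head_gender = head_gender,
                   head_education = head_education,
                   household_size = household_size,
                   adult_equivalents = ae, has_children = has_children,
                   single_household = single_household,
                   amen_gas = amen_gas,
                   amen_electricity = amen_electricity,
                   amen_water = amen_water,
                   total_expenditure = m)
  colnames(E) <- paste0("exp_", groups)
  colnames(Q) <- paste0("qty_", groups)
  B <- D
  colnames(B) <- paste0("buy_", groups)
  hh <- cbind(hh, as.data.frame(E), as.data.frame(Q), as.data.frame(B))
  colnames(W) <- groups

  structure(list(
    households = hh, shares = W, log_prices = lnp,
    cluster_prices = data.frame(
      cluster_id = rep(seq_len(config$n_clusters), G),
      group = rep(groups, each = config$n_clusters),
      ln_price = as.numeric(C)),
    truth = list(params = par, intercepts = intercepts,
                 delta = -rr * sdsh * (1 - 1 / G),
                 epsilon = config$epsilon, eta = config$eta,
                 Dstar = Dstar, D = D, latent_shares = w_lat,
                 cluster_log_prices = C, resampled = resampled),
    config = config), class = "quaids_survey")
}

#' Write a synthetic survey to plain-text files
#'
#' Writes the household table and true cluster prices as CSV and the
#' ground-truth parameters as JSON into `dir`.
#'
#' @param survey a `quaids_survey` from [generate_survey()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "quaids_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(households = file.path(dir, "households.csv"),
             prices = file.path(dir, "cluster_prices.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(survey$households, paths["households"],
                   row.names = FALSE)
  utils::write.csv(survey$cluster_prices, paths["prices"],
                   row.names = FALSE)
  tr <- survey$truth
  jsonlite::write_json(
    list(schema = "cquaids-truth-1",
         alpha0 = tr$params$alpha0, alpha = tr$params$alpha,
         beta = tr$params$beta, lambda = tr$params$lambda,
         gamma = tr$params$gamma, rho = tr$params$rho,
         delta = tr$delta, probit_intercepts = tr$intercepts,
         epsilon = tr$epsilon, resampled = tr$resampled),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
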