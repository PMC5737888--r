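#' Probit participation models for censored groups
#'
#' Fits, for each food group, a maximum-likelihood probit of the purchase
#' indicator on all group log prices, log total food expenditure, and
#' demographic shifters (head's education, adult-equivalent household
#' size, children and single-household dummies).  The head's age is
#' deliberately excluded here although it enters the demand system, and
#' the children/single dummies appear only here: the asymmetry between the
#' two shifter sets identifies the censoring correction.  Each household's
#' predicted probit index, normal CDF and density feed the two-step
#' censoring-corrected share system.
#'
#' @param households household data frame (see [generate_survey()]).
#' @param prices a [cluster_price_set()] or an `n x G` log-price matrix.
#' @param groups character vector of group names.
#' @param demographics columns used as probit shifters.
#' @param expenditure_scale `"log"` (default) enters total expenditure in
#'   logs; `"level"` uses the level.
#' @param response optional `n x G` 0/1 matrix of participation
#'   indicators; by default participation is read off positive
#'   expenditure.  Simulation studies on latent-mode synthetic data pass
#'   the generator's true indicators here, since a purchaser whose noisy
#'   latent share fell below zero carries no positive expenditure.
#' @param clamp predicted probabilities are clamped to
#'   `[clamp, 1 - clamp]` to keep later divisions finite.
#' @return A list of class `first_stage` with `Phi`, `phi`, `Dstar`
#'   (`n x G` matrices of CDF, density and linear index), `tau`
#'   (`G x G` matrix: row i holds group i's log-price coefficients),
#'   `coefficients` (full per-group coefficient vectors) and
#'   `participation` (observed purchase rates).
#' @export
fit_participation <- function(households, prices, groups = quaids_groups,
                              demographics = c("head_education",
                                               "adult_equivalents",
                                               "has_children",
                                               "single_household"),
                              expenditure_scale = c("log", "level"),
                              clamp = 1e-10, response = NULL) {
  expenditure_scale <- match.arg(expenditure_scale)
  n <- nrow(households)
  G <- length(groups)
  lnp <- if (is.matrix(prices)) prices else
    price_matrix(prices, households$cluster_id)
  m <- food_budget(households, groups)
  mreg <- if (expenditure_scale == "log") log(m) else m
  X <- cbind(`(Intercept)` = 1, lnp,
             expenditure = mreg,
             as.matrix(households[, demographics, drop = FALSE]))
  colnames(X)[1 + seq_len(G)] <- paste0("lnp_", groups)
  Phi <- phi <- Dstar <- matrix(NA_real_, n, G,
                                dimnames = list(NULL, groups))
  coefs <- vector("list", G); names(coefs) <- groups
  rates <- numeric(G)
  for (i in seq_len(G)) {
    y <- if (is.null(response))
      as.integer(households[[paste0("exp_", groups[i])]] > 0) else
        response[, i]
    rates[i] <- mean(y)
    if (rates[i] == 0 || rates[i] == 1)
      stop("group ", groups[i],
           " has no variation in participation; probit not estimable")
    if (rates[i] < 0.01 || rates[i] > 0.99)
      warning("group ", groups[i], " has participation ",
              signif(rates[i], 3),
              "; probit estimates flagged unstable", call. = FALSE)
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial(link = "probit"),
                     control = stats::glm.control(maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          warning("near-separation in probit for group ", groups[i],
                  "; consider removing the separating column",
                  call. = FALSE)
        invokeRestart("muffleWarning")
      })
    if (!fit$converged || any(abs(fit$coefficients) > 100, na.rm = TRUE))
      stop("probit for group ", groups[i], " did not converge; a ",
           "regressor may perfectly separate purchasers - remove it")
    b <- fit$coefficients
    b[is.na(b)] <- 0
    coefs[[i]] <- b
    Dstar[, i] <- drop(X %*% b)
    Phi[, i] <- pmin(pmax(stats::pnorm(Dstar[, i]), clamp), 1 - clamp)
    phi[, i] <- stats::dnorm(Dstar[, i])
  }
  tau <- t(vapply(coefs, function(b) b[paste0("lnp_", groups)], numeric(G)))
  dimnames(tau) <- list(groups, groups)
  structure(list(Phi = Phi, phi = phi, Dstar = Dstar, tau = tau,
                 coefficients = coefs,
                 participation = stats::setNames(rates, groups),
                 groups = groups),
            class = "first_stage")
}

#' Uncensored stand-in for a first stage
#'
#' Returns a `first_stage` object with all probabilities set to one and
#' densities to zero, so the augmented system collapses to the plain
#' latent QUAIDS.  Used for uncensored robustness fits and algebraic
#' limit tests.
#'
#' @param n number of households.
#' @param groups group names.
#' @export
uncensored_first_stage <- function(n, groups = quaids_groups) {
  G <- length(groups)
  one <- matrix(1, n, G, dimnames = list(NULL, groups))
  zero <- matrix(0, n, G, dimnames = list(NULL, groups))
  structure(list(Phi = one, phi = zero, Dstar = one * Inf,
                 tau = matrix(0, G, G, dimnames = list(groups, groups)),
                 coefficients = NULL,
                 participation = stats::setNames(rep(1, G), groups),
                 groups = groups),
            class = "first_stage")
}
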