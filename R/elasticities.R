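#' Censoring-adjusted uncompensated price elasticities
#'
#' Evaluates the uncompensated (Marshallian) own- and cross-price
#' elasticity matrix of the censoring-augmented QUAIDS at a single
#' evaluation point,
#' \deqn{e_{ij} = -\delta_{ij} + \frac{1}{w_i^*}\Big[
#'   \Phi_i\big(\gamma_{ij} - \mu_i(\alpha_j + \textstyle\sum_k
#'   \gamma_{jk}\ln p_k) - \frac{\lambda_i\beta_j}{b(p)}
#'   [\ln(m/a(p))]^2\big) + \tau_j\,\phi_i\,(w_i - \delta_i D_i^*)\Big],}
#' with \eqn{\mu_i = \beta_i + \frac{2\lambda_i}{b(p)}\ln(m/a(p))},
#' \eqn{\delta_{ij}} the Kronecker delta, \eqn{\tau_j} the group-i probit
#' coefficient on \eqn{\ln p_j}, and \eqn{D_i^*} the probit index.  The
#' bracket combines the intensive margin (purchase amounts of buyers,
#' scaled by \eqn{\Phi_i}) and the extensive margin (households switching
#' purchasing on or off, through \eqn{\phi_i}).  In the uncensored limit
#' (\eqn{\Phi = 1, \phi = 0}) the expression reduces to the classic
#' QUAIDS Marshallian formula.
#'
#' @param par a [demand_parameters()] object, or a `quaids_fit` from
#'   [fit_augmented_quaids()] (whose stored sample means supply the
#'   evaluation point).
#' @param point evaluation point: a list with `lnp` (G log prices), `lnm`
#'   (log expenditure), `z` (K shifters), `w_star` (G positive mean
#'   observed shares), `Phi`, `phi`, `Dstar` (G first-stage means) and
#'   `tau` (`G x G` probit log-price coefficients, rows = groups).
#'   See [evaluation_point()].
#' @return An object of class `elasticity_matrix`: the `G x G` matrix `e`
#'   (row = quantity group, column = price group) with the evaluation
#'   point attached; bootstrap standard errors and significance stars are
#'   added by [bootstrap_elasticities()].
#' @export
elasticity_matrix <- function(par, point = NULL) {
  if (inherits(par, "quaids_fit")) {
    if (is.null(point)) point <- par$means
    par <- par$par
  }
  G <- length(par$alpha)
  stopifnot(!is.null(point), length(point$w_star) == G)
  if (any(point$w_star <= 0))
    stop("evaluation-point mean shares must be strictly positive")
  lnp <- matrix(point$lnp, nrow = 1)
  z <- if (is.null(par$rho)) NULL else matrix(point$z, nrow = 1)
  idx <- quaids_indices(par, lnp, point$lnm, z)
  w_lat <- drop(evaluate_shares(par, point$lnp, point$lnm, point$z))
  mu <- par$beta + 2 * par$lambda * idx$x / idx$b
  aj <- drop(idx$alpha_h) + drop(idx$pg)       # alpha_j + sum_k gamma_jk lnp_k
  term1 <- par$gamma - outer(mu, aj) -
    outer(par$lambda, par$beta) * idx$x^2 / idx$b
  delta <- if (is.null(par$delta)) numeric(G) else par$delta
  tau <- if (is.null(point$tau)) matrix(0, G, G) else point$tau
  ext <- point$phi * (w_lat - delta * point$Dstar)
  e <- -diag(G) + (point$Phi * term1 + ext * tau) / point$w_star
  dimnames(e) <- list(par$groups, par$groups)
  structure(list(e = e, se = NULL, stars = NULL, evaluation_point = point,
                 groups = par$groups),
            class = "elasticity_matrix")
}

#' Assemble an elasticity evaluation point
#'
#' Either packs user-supplied means, or (given probit coefficients)
#' computes a self-consistent point at which the first-stage index, CDF
#' and density, the latent shares, and the augmented mean shares
#' \eqn{w_i^* = \Phi_i w_i + \delta_i \phi_i} all derive from the same
#' prices, expenditure and demographics.  The self-consistent form is
#' what a numerical derivative of augmented demand with respect to one
#' log price differentiates through.
#'
#' @param lnp G-vector of log prices.
#' @param lnm log expenditure.
#' @param z demand shifters (K-vector), `NULL` if none.
#' @param par a [demand_parameters()]; needed for the self-consistent
#'   form.
#' @param tau `G x G` probit log-price coefficients.
#' @param pi_exp G-vector of probit log-expenditure coefficients.
#' @param intercepts G-vector combining each group's probit intercept and
#'   demographic contribution at the chosen point.
#' @param w_star,Phi,phi,Dstar explicit means; supplied instead of `par`
#'   etc. when packing sample means.
#' @return A list usable as the `point` of [elasticity_matrix()].
#' @export
evaluation_point <- function(lnp, lnm, z = NULL, par = NULL, tau = NULL,
                             pi_exp = 0, intercepts = 0, w_star = NULL,
                             Phi = NULL, phi = NULL, Dstar = NULL) {
  if (!is.null(par)) {
    G <- length(par$alpha)
    if (is.null(tau)) tau <- matrix(0, G, G)
    Dstar <- intercepts + drop(tau %*% lnp) + pi_exp * lnm
    Phi <- stats::pnorm(Dstar)
    phi <- stats::dnorm(Dstar)
    w_lat <- drop(evaluate_shares(par, lnp, lnm, z))
    delta <- if (is.null(par$delta)) numeric(G) else par$delta
    w_star <- Phi * w_lat + delta * phi
  }
  list(lnp = lnp, lnm = lnm, z = z, w_star = w_star, Phi = Phi,
       phi = phi, Dstar = Dstar, tau = tau)
}

#' Augmented mean demand at a self-consistent point
#'
#' Returns the augmented mean shares and implied quantities
#' \eqn{q_i = w_i^* m / p_i} at given prices; the workhorse for
#' finite-difference checks of the elasticity formula.
#'
#' @inheritParams evaluation_point
#' @return List with `w_star`, `w_latent`, `Phi`, `phi`, `Dstar`,
#'   `log_quantity`.
#' @export
augmented_demand <- function(par, lnp, lnm, z = NULL, tau = NULL,
                             pi_exp = 0, intercepts = 0) {
  pt <- evaluation_point(lnp, lnm, z, par = par, tau = tau,
                         pi_exp = pi_exp, intercepts = intercepts)
  c(pt[c("w_star", "Phi", "phi", "Dstar")],
    list(w_latent = drop(evaluate_shares(par, lnp, lnm, z)),
         log_quantity = log(pt$w_star) + lnm - lnp))
}

#' @export
print.elasticity_matrix <- function(x, digits = 3, ...) {
  cat("Uncompensated price elasticities (rows: quantity, cols: price)\n")
  print(round(x$e, digits))
  if (!is.null(x$se)) {
    cat("\nBootstrap SEs (", x$n_reps_used, " replicates kept)\n", sep = "")
    print(round(x$se, digits))
  }
  invisible(x)
}

#' Long-form table of an elasticity matrix
#'
#' @param x an `elasticity_matrix`.
#' @param ... unused.
#' @return Data frame with columns `quantity_group`, `price_group`,
#'   `elasticity` and, when available, `se` and `stars`.
#' @export
as.data.frame.elasticity_matrix <- function(x, ...) {
  G <- length(x$groups)
  out <- data.frame(
    quantity_group = rep(x$groups, G),
    price_group = rep(x$groups, each = G),
    elasticity = as.numeric(x$e))
  if (!is.null(x$se)) {
    out$se <- as.numeric(x$se)
    out$stars <- as.character(x$stars)
  }
  out
}

significance_stars <- function(e, se) {
  z <- abs(e / se)
  p <- 2 * stats::pnorm(-z)
  s <- ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                                      ifelse(p < 0.1, "*", "")))
  array(s, dim = dim(e), dimnames = dimnames(e))
}

#' Bootstrap standard errors for the elasticity matrix
#'
#' Nonparametric bootstrap of the full two-step pipeline: households are
#' resampled with replacement (optionally whole municipal clusters), and
#' for each replicate the cluster prices, control-function residual,
#' probit first stage, system fit and elasticity matrix are recomputed at
#' the replicate's own means.  The standard error is the standard
#' deviation across replicates; two-sided significance stars use the
#' normal approximation `z = e / se` at the 0.1 / 0.05 / 0.01 levels.
#' Replicates whose fit fails or does not converge are dropped and
#' counted; losing more than 10% of replicates triggers a warning.
#'
#' @param households household data frame.
#' @param n_reps number of bootstrap replicates (>= 2; 500 for
#'   production-quality standard errors).
#' @param seed integer seed; the same seed reproduces the SE matrix
#'   exactly.
#' @param cluster_bootstrap resample whole clusters instead of households.
#' @param ... passed to [quaids_pipeline()] (e.g. `censored`, `alpha0`,
#'   `groups`, `control`).
#' @return The point-estimate `elasticity_matrix` with `se`, `stars`,
#'   `n_reps_used` and `n_reps_dropped` filled in.
#' @export
bootstrap_elasticities <- function(households, n_reps = 500, seed = 1L,
                                   cluster_bootstrap = FALSE, ...) {
  stopifnot(n_reps >= 2)
  set.seed(seed)
  base <- quaids_pipeline(households, ...)
  e0 <- base$elasticities
  G <- length(e0$groups)
  reps <- array(NA_real_, c(G, G, n_reps))
  kept <- 0L
  for (r in seq_len(n_reps)) {
    hh <- if (cluster_bootstrap) {
      cl <- sample(unique(households$cluster_id),
                   length(unique(households$cluster_id)), replace = TRUE)
      do.call(rbind, lapply(seq_along(cl), function(k) {
        h <- households[households$cluster_id == cl[k], , drop = FALSE]
        h$cluster_id <- k       # resampled clusters become distinct
        h
      }))
    } else households[sample.int(nrow(households), replace = TRUE), ,
                      drop = FALSE]
    er <- tryCatch(
      suppressWarnings(quaids_pipeline(hh, ...)$elasticities$e),
      error = function(e) NULL)
    if (!is.null(er)) {
      kept <- kept + 1L
      reps[, , kept] <- er
    }
  }
  if (kept < n_reps * 0.9)
    warning(n_reps - kept, " of ", n_reps,
            " bootstrap replicates failed and were dropped", call. = FALSE)
  if (kept < 2) stop("fewer than 2 bootstrap replicates converged")
  se <- apply(reps[, , seq_len(kept), drop = FALSE], c(1, 2), stats::sd)
  dimnames(se) <- dimnames(e0$e)
  e0$se <- se
  e0$stars <- significance_stars(e0$e, se)
  e0$n_reps_used <- kept
  e0$n_reps_dropped <- n_reps - kept
  e0
}
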