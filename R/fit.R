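#' Control settings for the system estimator
#'
#' @param max_iter maximum number of outer iterations.
#' @param tol_param convergence tolerance on the relative parameter change.
#' @param tol_crit convergence tolerance on the relative criterion change.
#' @param ridge relative ridge added to the normal equations if they are
#'   numerically singular.
#' @param identity_weight if `TRUE`, keep the residual weighting matrix at
#'   the identity instead of updating it from the residual covariance
#'   (one-step / equal-weight estimation, mainly for testing).
#' @export
quaids_control <- function(max_iter = 200, tol_param = 1e-5,
                           tol_crit = 1e-8, ridge = 1e-10,
                           identity_weight = FALSE) {
  list(max_iter = max_iter, tol_param = tol_param, tol_crit = tol_crit,
       ridge = ridge, identity_weight = identity_weight)
}

## Pseudo-inverse of the residual covariance.  Under adding-up with an
## uncensored response the residuals sum to zero by construction, so the
## covariance is structurally singular in the equal-share direction; that
## direction is dropped silently.  Any other (unexpected) singularity
## triggers a warning and the same generalized-inverse fallback.
sigma_inverse <- function(Sigma) {
  eg <- eigen(Sigma, symmetric = TRUE)
  G <- nrow(Sigma)
  tol <- max(eg$values) * 1e-10
  null <- eg$values < tol
  if (any(null)) {
    ones <- rep(1 / sqrt(G), G)
    expected <- all(vapply(which(null), function(j)
      abs(abs(sum(eg$vectors[, j] * ones)) - 1) < 1e-6, logical(1)))
    if (!expected)
      warning("residual covariance numerically singular; ",
              "using a generalized inverse", call. = FALSE)
  }
  vals <- ifelse(null, 0, 1 / pmax(eg$values, tol))
  list(inv = eg$vectors %*% (vals * t(eg$vectors)), rank = sum(!null))
}

#' Constrained system estimation of the augmented QUAIDS
#'
#' Estimates the (optionally censoring-augmented) QUAIDS share system by
#' iterated feasible generalized least squares.  The mean of equation
#' \eqn{i} is \eqn{\Phi_i w_i(\theta) + \delta_i \phi_i + \kappa_i r}
#' with \eqn{w_i(\theta)} the latent QUAIDS share, \eqn{\Phi_i,\phi_i}
#' the first-stage probit CDF and density, and \eqn{r} the
#' expenditure control-function residual.  All nine equations are kept in
#' the system (no equation is dropped); adding-up, homogeneity and
#' symmetry are imposed exactly by reparameterization, so every fit
#' satisfies the restrictions by construction.  Each outer iteration
#' (i) evaluates the price indices \eqn{a(p)}, \eqn{b(p)} at the current
#' parameters, (ii) solves the restricted generalized least-squares
#' problem of the system, which is linear in all coefficients once the
#' indices are fixed, and (iii) updates the residual covariance; the
#' scheme iterates to a fixed point of these three steps.
#'
#' @param W `n x G` observed budget-share matrix (the response).
#' @param lnp `n x G` household log prices.
#' @param lnm length-`n` log total food expenditure.
#' @param z optional `n x K` matrix of centered demographic shifters.
#' @param Phi,phi optional `n x G` first-stage CDF / density matrices;
#'   omitting them (or passing all ones / zeros) gives the uncensored
#'   system, in which no `delta` is estimated.
#' @param resid optional length-`n` control-function residual; when
#'   present, per-equation loadings `kappa` (summing to zero) are
#'   estimated.
#' @param alpha0 fixed translog anchor; a warning is issued if it does not
#'   lie below `min(lnm)`.
#' @param weights optional positive household weights.
#' @param start optional [demand_parameters()] to start from; the default
#'   starts at the mean-share intercepts with all slopes zero.
#' @param control a [quaids_control()] list.
#' @param group_names group labels.
#' @return An object of class `quaids_fit`: `par` (a
#'   [demand_parameters()]), `Sigma`, `fitted`, `residuals`,
#'   `criterion`, `iterations`, `converged`, and the data means needed to
#'   evaluate elasticities.
#' @export
quaids_fgnls <- function(W, lnp, lnm, z = NULL, Phi = NULL, phi = NULL,
                         resid = NULL, alpha0 = 5, weights = NULL,
                         start = NULL, control = quaids_control(),
                         group_names = colnames(W)) {
  n <- nrow(W); G <- ncol(W)
  stopifnot(all(dim(lnp) == c(n, G)), length(lnm) == n)
  if (is.null(group_names)) group_names <- paste0("g", seq_len(G))
  K <- if (is.null(z)) 0L else ncol(z)
  use_delta <- !is.null(phi) && any(phi != 0)
  use_kappa <- !is.null(resid)
  if (is.null(Phi)) Phi <- matrix(1, n, G)
  if (is.null(phi)) phi <- matrix(0, n, G)
  if (is.null(weights)) weights <- rep(1, n)
  if (alpha0 >= min(lnm))
    warning("alpha0 = ", alpha0, " is not below min(log expenditure) = ",
            signif(min(lnm), 4), call. = FALSE)

  lay <- dp_layout(G, K, use_delta, use_kappa)
  map <- dp_constraint_map(lay)
  A <- map$A; cc <- map$c

  ## starting values
  if (is.null(start)) {
    a0 <- pmax(colMeans(W), 0.01); a0 <- a0 / sum(a0)
    start <- demand_parameters(
      a0, numeric(G), numeric(G), matrix(0, G, G),
      rho = if (K > 0) matrix(0, G, K) else NULL,
      delta = if (use_delta) numeric(G) else NULL,
      kappa = if (use_kappa) numeric(G) else NULL,
      alpha0 = alpha0, group_names = group_names)
  }
  theta_full <- dp_to_full(start, lay)
  ## free coordinates consistent with theta_full (A has orthonormal-ish
  ## columns only per-block; recover free vector by least squares)
  theta_f <- qr.solve(A, theta_full - cc)

  Sinv <- diag(G)
  crit_old <- Inf
  converged <- FALSE
  wts <- weights / mean(weights)
  par_t <- dp_from_full(drop(A %*% theta_f) + cc, lay, alpha0, group_names)
  for (it in seq_len(control$max_iter)) {
    idx <- quaids_indices(par_t, lnp, lnm, z)
    q1 <- idx$x; q2 <- idx$x^2 / idx$b
    ## per-equation regressor blocks
    B <- lapply(seq_len(G), function(i) {
      Bi <- cbind(1, z, lnp, q1, q2) * Phi[, i]
      if (use_delta) Bi <- cbind(Bi, phi[, i])
      if (use_kappa) Bi <- cbind(Bi, resid)
      Bi
    })
    wB <- lapply(B, function(Bi) Bi * wts)
    ## residual covariance from current parameters
    tf <- drop(A %*% theta_f) + cc
    Tm <- matrix(tf, nrow = lay$p_eq)
    fitted <- vapply(seq_len(G), function(i) drop(B[[i]] %*% Tm[, i]),
                     numeric(n))
    R <- W - fitted
    crit <- sum((R %*% Sinv) * R * wts)
    if (!control$identity_weight) {
      Sigma <- crossprod(R * sqrt(wts)) / n
      Sinv <- sigma_inverse(Sigma)$inv
    } else Sigma <- diag(G)
    ## assemble restricted GLS normal equations
    M <- matrix(0, lay$p_full, lay$p_full)
    v <- numeric(lay$p_full)
    for (i in seq_len(G)) {
      ri <- (i - 1L) * lay$p_eq + seq_len(lay$p_eq)
      for (j in i:G) {
        if (abs(Sinv[i, j]) < 1e-14) next
        cj <- (j - 1L) * lay$p_eq + seq_len(lay$p_eq)
        blk <- Sinv[i, j] * crossprod(B[[i]], wB[[j]])
        M[ri, cj] <- blk
        if (i != j) M[cj, ri] <- t(blk)
      }
      v[ri] <- crossprod(B[[i]], wts * drop(W %*% Sinv[i, ]))
    }
    MA <- M %*% A
    lhs <- crossprod(A, MA)
    rhs <- crossprod(A, v - M %*% cc)
    lhs <- lhs + diag(control$ridge * max(abs(diag(lhs))), nrow(lhs))
    theta_new <- solve(lhs, rhs)
    dpar <- max(abs(theta_new - theta_f)) / (1 + max(abs(theta_f)))
    theta_f <- drop(theta_new)
    par_t <- dp_from_full(drop(A %*% theta_f) + cc, lay, alpha0,
                          group_names)
    dcrit <- abs(crit - crit_old) / (1 + abs(crit))
    crit_old <- crit
    if (dpar < control$tol_param && dcrit < control$tol_crit) {
      converged <- TRUE
      break
    }
  }
  if (!converged && control$max_iter > 5)
    warning("system estimation did not converge in ", control$max_iter,
            " iterations (last relative change ", signif(dpar, 3), ")",
            call. = FALSE)
  ## final fitted values / residuals at the returned parameters
  idx <- quaids_indices(par_t, lnp, lnm, z)
  w_lat <- evaluate_shares(par_t, lnp, lnm, z)
  fitted <- Phi * w_lat +
    (if (use_delta) phi * matrix(par_t$delta, n, G, byrow = TRUE) else 0) +
    (if (use_kappa) outer(resid, par_t$kappa) else 0)
  R <- W - fitted
  structure(list(par = par_t, Sigma = crossprod(R * sqrt(wts)) / n,
                 fitted = fitted, residuals = R,
                 criterion = crit_old, iterations = it,
                 converged = converged, n = n, groups = group_names,
                 use_delta = use_delta, use_kappa = use_kappa),
            class = "quaids_fit")
}

#' @export
print.quaids_fit <- function(x, ...) {
  cat("Censored QUAIDS system fit:", x$n, "households,",
      length(x$groups), "equations\n  converged:", x$converged,
      "after", x$iterations, "iterations; criterion", signif(x$criterion, 6),
      "\n")
  invisible(x)
}

#' Two-step censored QUAIDS fit from survey components
#'
#' Convenience wrapper assembling the estimation inputs from a household
#' table: observed budget shares, cluster log prices, centered demand
#' shifters (head's age and education, adult-equivalent size), the
#' first-stage probit predictions and the expenditure control-function
#' residual, then calling [quaids_fgnls()].
#'
#' @param households household data frame.
#' @param prices a [cluster_price_set()] or `n x G` log-price matrix.
#' @param first_stage a [fit_participation()] result, or `NULL` for an
#'   uncensored fit.
#' @param residuals an [expenditure_control_residual()] result (or a plain
#'   numeric vector), or `NULL` to omit the control function.
#' @param groups group names.
#' @param alpha0 fixed translog anchor (default 5; choose a value below
#'   the sample minimum of log expenditure).
#' @param z_center centering constants for (head age, head education,
#'   adult equivalents); defaults to the sample means.
#' @param weights optional household weights.
#' @param control a [quaids_control()].
#' @return A `quaids_fit` augmented with `means`: the sample means
#'   (observed shares, Phi, phi, probit index, log prices, log
#'   expenditure, shifters) and the probit price coefficients `tau`, as
#'   needed by [elasticity_matrix()].
#' @export
fit_augmented_quaids <- function(households, prices, first_stage = NULL,
                                 residuals = NULL, groups = quaids_groups,
                                 alpha0 = 5, z_center = NULL,
                                 weights = NULL,
                                 control = quaids_control()) {
  W <- budget_shares(households, groups)
  lnp <- if (is.matrix(prices)) prices else
    price_matrix(prices, households$cluster_id)
  lnm <- log(food_budget(households, groups))
  zraw <- cbind(age = households$head_age,
                education = households$head_education,
                ae = households$adult_equivalents)
  if (is.null(z_center)) z_center <- colMeans(zraw)
  z <- sweep(zraw, 2, z_center)
  if (is.null(first_stage))
    first_stage <- uncensored_first_stage(nrow(W), groups)
  res <- if (is.null(residuals)) NULL else
    if (is.data.frame(residuals)) residuals$residual else residuals
  fit <- quaids_fgnls(W, lnp, lnm, z, Phi = first_stage$Phi,
                      phi = first_stage$phi, resid = res,
                      alpha0 = alpha0, weights = weights,
                      control = control, group_names = groups)
  fit$z_center <- z_center
  fit$means <- list(
    w_star = colMeans(W), Phi = colMeans(first_stage$Phi),
    phi = colMeans(first_stage$phi),
    Dstar = colMeans(first_stage$Dstar),
    lnp = colMeans(lnp), lnm = mean(lnm), z = colMeans(z),
    tau = first_stage$tau)
  fit
}
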