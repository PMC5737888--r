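#' Evaluate latent QUAIDS budget shares
#'
#' Computes the latent (uncensored) budget shares of the quadratic almost
#' ideal demand system at given log prices, log total expenditure and
#' demographic shifters.  The translog price index
#' \eqn{\ln a(p) = \alpha_0 + \sum_j \alpha_j \ln p_j + \frac12 \sum_{l,j}
#' \gamma_{lj} \ln p_l \ln p_j} and the Cobb-Douglas aggregator
#' \eqn{b(p) = \prod_j p_j^{\beta_j}} are evaluated per observation, with
#' \eqn{\alpha_j} shifted by demographics through the `rho` matrix.
#'
#' Under the adding-up, homogeneity and symmetry restrictions the returned
#' shares sum to one for every observation, and are invariant to scaling
#' all prices and expenditure by a common factor.
#'
#' @param par a [demand_parameters()] object.
#' @param log_prices numeric `G`-vector, or `n x G` matrix of household log
#'   prices.
#' @param log_expenditure numeric scalar or `n`-vector of log total (food)
#'   expenditure.
#' @param z optional demographic shifters: `K`-vector or `n x K` matrix,
#'   on the (centered) scale used when the parameters were defined.
#' @return An `n x G` matrix of latent budget shares (a vector input
#'   returns a 1-row matrix).
#' @export
evaluate_shares <- function(par, log_prices, log_expenditure, z = NULL) {
  lnp <- if (is.matrix(log_prices)) log_prices else
    matrix(log_prices, nrow = 1)
  G <- length(par$alpha)
  stopifnot(ncol(lnp) == G, all(is.finite(lnp)),
            all(is.finite(log_expenditure)))
  n <- nrow(lnp)
  lnm <- rep_len(log_expenditure, n)
  alpha_h <- matrix(par$alpha, n, G, byrow = TRUE)
  if (!is.null(par$rho)) {
    if (is.null(z)) stop("parameters carry demographic shifters but z is missing")
    zm <- if (is.matrix(z)) z else matrix(z, nrow = 1)
    if (n > 1 && nrow(zm) == 1) zm <- zm[rep(1, n), , drop = FALSE]
    stopifnot(ncol(zm) == ncol(par$rho), nrow(zm) == n)
    alpha_h <- alpha_h + zm %*% t(par$rho)
  }
  pg <- lnp %*% par$gamma                     # row h: (Gamma ln p)_j
  lna <- par$alpha0 + rowSums(alpha_h * lnp) + 0.5 * rowSums(pg * lnp)
  b <- exp(drop(lnp %*% par$beta))
  x <- lnm - lna
  w <- alpha_h + pg +                          # gamma symmetric
    outer(x, par$beta) + outer(x^2 / b, par$lambda)
  colnames(w) <- par$groups
  w
}

## Internal: per-observation pieces of the price indices, reused by the
## fitting loop and the elasticity evaluator.
quaids_indices <- function(par, lnp, lnm, z = NULL) {
  n <- nrow(lnp); G <- length(par$alpha)
  alpha_h <- matrix(par$alpha, n, G, byrow = TRUE)
  if (!is.null(par$rho) && !is.null(z))
    alpha_h <- alpha_h + z %*% t(par$rho)
  pg <- lnp %*% par$gamma
  lna <- par$alpha0 + rowSums(alpha_h * lnp) + 0.5 * rowSums(pg * lnp)
  b <- exp(drop(lnp %*% par$beta))
  list(alpha_h = alpha_h, pg = pg, lna = lna, b = b, x = lnm - lna)
}

#' Expenditure elasticities in the uncensored limit
#'
#' Standard QUAIDS (Marshallian) expenditure elasticities
#' \eqn{e_i = 1 + \frac{1}{w_i}\left[\beta_i + \frac{2\lambda_i}{b(p)}
#' \ln(m/a(p))\right]}, evaluated at one point.  Used mainly to verify the
#' homogeneity aggregation property of the price-elasticity matrix; the
#' censored system has no comparably simple closed form.
#'
#' @inheritParams evaluate_shares
#' @return numeric `G`-vector of expenditure elasticities.
#' @export
expenditure_elasticities <- function(par, log_prices, log_expenditure,
                                     z = NULL) {
  lnp <- matrix(log_prices, nrow = 1)
  zm <- if (is.null(z)) NULL else matrix(z, nrow = 1)
  idx <- quaids_indices(par, lnp, log_expenditure, zm)
  w <- drop(evaluate_shares(par, log_prices, log_expenditure, z))
  mu <- par$beta + 2 * par$lambda * idx$x / idx$b
  stats::setNames(1 + mu / w, par$groups)
}
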