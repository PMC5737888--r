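#' QUAIDS parameter set
#'
#' Container for the full parameter set of a (possibly censoring-augmented)
#' Quadratic Almost Ideal Demand System with `G` good groups and `K`
#' demographic shifters.  The latent budget-share system is
#' \deqn{w_i = \alpha_i + \sum_j \gamma_{ij} \ln p_j +
#'       \beta_i \ln(m/a(p)) + \frac{\lambda_i}{b(p)} [\ln(m/a(p))]^2,}
#' with \eqn{\alpha_i = \alpha_{0i} + \sum_k \rho_{ik} z_k}, the translog
#' price index \eqn{\ln a(p)} anchored at the scalar `alpha0`, and the
#' Cobb-Douglas aggregator \eqn{b(p) = \prod_j p_j^{\beta_j}}.
#'
#' Consistency with demand theory requires adding-up
#' (\eqn{\sum_i \alpha_{0i} = 1}, \eqn{\sum_i \beta_i = \sum_i \lambda_i = 0},
#' \eqn{\sum_i \rho_{ik} = 0}), homogeneity (zero row sums of
#' \eqn{\gamma}) and Slutsky symmetry (\eqn{\gamma_{ij} = \gamma_{ji}}).
#' `demand_parameters()` validates these restrictions at construction.
#'
#' @param alpha numeric `G`-vector of share intercepts \eqn{\alpha_{0i}}
#'   (summing to 1).
#' @param beta numeric `G`-vector of log-expenditure slopes (summing to 0).
#' @param lambda numeric `G`-vector of quadratic expenditure terms
#'   (summing to 0).
#' @param gamma symmetric `G x G` price-coefficient matrix with zero row
#'   and column sums.
#' @param rho optional `G x K` matrix of demographic shifters with zero
#'   column sums; omit (NULL) for a system without demographics.
#' @param delta optional `G`-vector of censoring-correction coefficients
#'   (loadings on the probit density in the augmented system).
#' @param kappa optional `G`-vector of control-function coefficients
#'   (loadings on the expenditure residual, summing to 0).
#' @param alpha0 scalar anchor of the translog price index; conventionally
#'   fixed just below the sample minimum of log expenditure.
#' @param tol tolerance for the constraint checks.
#' @param group_names optional character vector of group labels.
#' @return An object of class `demand_parameters`.
#' @seealso [random_demand_parameters()], [evaluate_shares()]
#' @export
demand_parameters <- function(alpha, beta, lambda, gamma, rho = NULL,
                              delta = NULL, kappa = NULL, alpha0 = 5,
                              tol = 1e-8, group_names = NULL) {
  G <- length(alpha)
  stopifnot(G >= 2, length(beta) == G, length(lambda) == G,
            is.matrix(gamma), all(dim(gamma) == G))
  if (!is.null(rho)) {
    rho <- as.matrix(rho)
    stopifnot(nrow(rho) == G)
  }
  if (!is.null(delta)) stopifnot(length(delta) == G)
  if (!is.null(kappa)) stopifnot(length(kappa) == G)
  if (is.null(group_names)) {
    group_names <- rownames(gamma)
    if (is.null(group_names)) group_names <- paste0("g", seq_len(G))
  }
  par <- structure(
    list(alpha0 = alpha0,
         alpha = stats::setNames(as.numeric(alpha), group_names),
         beta = stats::setNames(as.numeric(beta), group_names),
         lambda = stats::setNames(as.numeric(lambda), group_names),
         gamma = structure(gamma, dimnames = list(group_names, group_names)),
         rho = rho, delta = if (is.null(delta)) NULL else as.numeric(delta),
         kappa = if (is.null(kappa)) NULL else as.numeric(kappa),
         groups = group_names),
    class = "demand_parameters")
  check_quaids_constraints(par, tol = tol)
  par
}

#' Verify adding-up, homogeneity and symmetry restrictions
#'
#' Checks that a parameter set satisfies the linear restrictions that make
#' the latent share system consistent with consumer theory, to a numerical
#' tolerance.
#'
#' @param par a [demand_parameters()] object.
#' @param tol numeric tolerance (default `1e-8`).
#' @param stop_on_fail if `TRUE` (default) violations raise an error;
#'   otherwise the function returns `FALSE` invisibly.
#' @return `TRUE` (invisibly) if all restrictions hold.
#' @export
check_quaids_constraints <- function(par, tol = 1e-8, stop_on_fail = TRUE) {
  bad <- character(0)
  if (abs(sum(par$alpha) - 1) > tol) bad <- c(bad, "sum(alpha) != 1")
  if (abs(sum(par$beta)) > tol)      bad <- c(bad, "sum(beta) != 0")
  if (abs(sum(par$lambda)) > tol)    bad <- c(bad, "sum(lambda) != 0")
  if (max(abs(par$gamma - t(par$gamma))) > tol)
    bad <- c(bad, "gamma not symmetric")
  if (max(abs(rowSums(par$gamma))) > tol)
    bad <- c(bad, "gamma row sums != 0")
  if (!is.null(par$rho) && max(abs(colSums(par$rho))) > tol)
    bad <- c(bad, "rho column sums != 0")
  if (!is.null(par$kappa) && abs(sum(par$kappa)) > tol)
    bad <- c(bad, "sum(kappa) != 0")
  if (length(bad)) {
    if (stop_on_fail)
      stop("parameter restrictions violated: ", paste(bad, collapse = "; "))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' @export
print.demand_parameters <- function(x, ...) {
  G <- length(x$alpha)
  cat("QUAIDS parameter set:", G, "goods",
      if (!is.null(x$rho)) sprintf(", %d demographic shifters", ncol(x$rho)),
      "\n  alpha0 =", x$alpha0,
      if (!is.null(x$delta)) "; censoring terms (delta) present",
      if (!is.null(x$kappa)) "; control-function terms (kappa) present", "\n")
  invisible(x)
}

## Symmetric centering: projects a square matrix onto the space of
## symmetric matrices with zero row/column sums (the gamma constraint set).
center_gamma <- function(S) {
  S <- (S + t(S)) / 2
  n <- nrow(S)
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% S %*% H
}

#' Draw a random constraint-consistent QUAIDS parameter set
#'
#' Generates a parameter set satisfying adding-up, homogeneity and symmetry
#' exactly, by drawing unconstrained Gaussian values and projecting them
#' onto the restriction set.  Used for property-style tests and simulation
#' studies.
#'
#' @param G number of goods.
#' @param K number of demographic shifters (0 for none).
#' @param sd scale of the random draws for `beta`, `lambda`, `gamma`, `rho`.
#' @param alpha0 translog anchor.
#' @param censoring if `TRUE`, include random `delta` and `kappa` terms.
#' @return A [demand_parameters()] object.
#' @export
random_demand_parameters <- function(G = 9, K = 3, sd = 0.02, alpha0 = 5,
                                     censoring = FALSE) {
  a <- abs(stats::rnorm(G, 1 / G, sd)) + 0.02
  a <- a / sum(a)
  b <- stats::rnorm(G, 0, sd); b <- b - mean(b)
  l <- stats::rnorm(G, 0, sd / 4); l <- l - mean(l)
  g <- center_gamma(matrix(stats::rnorm(G * G, 0, sd), G, G) -
                      diag(stats::runif(G, 0, 2 * sd)))
  r <- NULL
  if (K > 0) {
    r <- matrix(stats::rnorm(G * K, 0, sd / 4), G, K)
    r <- sweep(r, 2, colMeans(r))
  }
  d <- k <- NULL
  if (censoring) {
    d <- stats::rnorm(G, 0, sd / 2)
    k <- stats::rnorm(G, 0, sd / 2); k <- k - mean(k)
  }
  demand_parameters(a, b, l, g, rho = r, delta = d, kappa = k,
                    alpha0 = alpha0)
}

## ---- free-parameter mapping -------------------------------------------
##
## Estimation imposes the restrictions by reparameterization.  The full
## coefficient vector is laid out per equation i = 1..G as
##   [alpha0_i, rho_i1..rho_iK, gamma_i1..gamma_iG, beta_i, lambda_i,
##    (delta_i), (kappa_i)]
## and the free vector holds equations 1..G-1 of alpha/rho/beta/lambda/
## kappa, the upper triangle (incl. diagonal) of the leading
## (G-1)x(G-1) block of gamma, and all G delta.  theta_full = A theta_free
## + c reproduces every restriction exactly, whatever theta_free.

dp_layout <- function(G, K, use_delta = FALSE, use_kappa = FALSE) {
  p_eq <- 1 + K + G + 2 + as.integer(use_delta) + as.integer(use_kappa)
  Gm <- G - 1
  n_free <- Gm + Gm * K + Gm * (Gm + 1) / 2 + Gm + Gm +
    if (use_delta) G else 0
  n_free <- n_free + if (use_kappa) Gm else 0
  list(G = G, K = K, use_delta = use_delta, use_kappa = use_kappa,
       p_eq = p_eq, p_full = G * p_eq, n_free = n_free)
}

## position of coefficient j (within-equation) of equation i in the stacked
## full vector
dp_pos <- function(lay, i, j) (i - 1L) * lay$p_eq + j

## Build the affine map (A, c) from free to full coefficients.
dp_constraint_map <- function(lay) {
  G <- lay$G; K <- lay$K; Gm <- G - 1
  A <- matrix(0, lay$p_full, lay$n_free)
  cc <- numeric(lay$p_full)
  f <- 0L
  ## alpha0_i, i < G free; alpha0_G = 1 - sum
  for (i in seq_len(Gm)) {
    f <- f + 1L
    A[dp_pos(lay, i, 1L), f] <- 1
    A[dp_pos(lay, G, 1L), f] <- -1
  }
  cc[dp_pos(lay, G, 1L)] <- 1
  ## rho
  if (K > 0) for (k in seq_len(K)) for (i in seq_len(Gm)) {
    f <- f + 1L
    A[dp_pos(lay, i, 1L + k), f] <- 1
    A[dp_pos(lay, G, 1L + k), f] <- -1
  }
  ## gamma: free upper triangle of leading (G-1)x(G-1) block
  for (i in seq_len(Gm)) for (j in i:Gm) {
    f <- f + 1L
    A[dp_pos(lay, i, 1L + K + j), f] <- A[dp_pos(lay, i, 1L + K + j), f] + 1
    if (i != j)
      A[dp_pos(lay, j, 1L + K + i), f] <- A[dp_pos(lay, j, 1L + K + i), f] + 1
    ## gamma_iG = -sum_{j<G} gamma_ij ; symmetric entry gamma_Gi likewise
    A[dp_pos(lay, i, 1L + K + G), f] <- A[dp_pos(lay, i, 1L + K + G), f] - 1
    A[dp_pos(lay, G, 1L + K + i), f] <- A[dp_pos(lay, G, 1L + K + i), f] - 1
    if (i != j) {
      A[dp_pos(lay, j, 1L + K + G), f] <- A[dp_pos(lay, j, 1L + K + G), f] - 1
      A[dp_pos(lay, G, 1L + K + j), f] <- A[dp_pos(lay, G, 1L + K + j), f] - 1
    }
    ## gamma_GG accumulates +1 (diagonal) or +2 (off-diagonal pair)
    A[dp_pos(lay, G, 1L + K + G), f] <-
      A[dp_pos(lay, G, 1L + K + G), f] + if (i == j) 1 else 2
  }
  ## beta, lambda (sum-zero), delta (free), kappa (sum-zero)
  sum_zero <- function(off) {
    for (i in seq_len(Gm)) {
      f <<- f + 1L
      A[dp_pos(lay, i, off), f] <<- 1
      A[dp_pos(lay, G, off), f] <<- -1
    }
  }
  off_beta <- 1L + K + G + 1L
  sum_zero(off_beta)
  sum_zero(off_beta + 1L)
  off <- off_beta + 2L
  if (lay$use_delta) {
    for (i in seq_len(G)) {
      f <- f + 1L
      A[dp_pos(lay, i, off), f] <- 1
    }
    off <- off + 1L
  }
  if (lay$use_kappa) sum_zero(off)
  stopifnot(f == lay$n_free)
  list(A = A, c = cc)
}

## full stacked coefficient vector -> demand_parameters
dp_from_full <- function(theta, lay, alpha0 = 5, group_names = NULL) {
  G <- lay$G; K <- lay$K
  M <- matrix(theta, nrow = lay$p_eq)      # column i = equation i
  demand_parameters(
    alpha = M[1, ], beta = M[1 + K + G + 1, ], lambda = M[1 + K + G + 2, ],
    gamma = t(M[1 + K + seq_len(G), , drop = FALSE]),
    rho = if (K > 0) t(M[1 + seq_len(K), , drop = FALSE]) else NULL,
    delta = if (lay$use_delta) M[1 + K + G + 3, ] else NULL,
    kappa = if (lay$use_kappa) M[1 + K + G + 3 + lay$use_delta, ] else NULL,
    alpha0 = alpha0, tol = 1e-6, group_names = group_names)
}

## demand_parameters -> full stacked vector (inverse of dp_from_full)
dp_to_full <- function(par, lay) {
  G <- lay$G; K <- lay$K
  M <- matrix(0, lay$p_eq, G)
  M[1, ] <- par$alpha
  if (K > 0) M[1 + seq_len(K), ] <- t(par$rho)
  M[1 + K + seq_len(G), ] <- t(par$gamma)
  M[1 + K + G + 1, ] <- par$beta
  M[1 + K + G + 2, ] <- par$lambda
  if (lay$use_delta)
    M[1 + K + G + 3, ] <- if (is.null(par$delta)) 0 else par$delta
  if (lay$use_kappa)
    M[1 + K + G + 3 + lay$use_delta, ] <-
      if (is.null(par$kappa)) 0 else par$kappa
  as.numeric(M)
}
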