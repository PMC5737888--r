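## group-wise expenditure / quantity helpers ---------------------------

exp_cols <- function(groups) paste0("exp_", groups)
qty_cols <- function(groups) paste0("qty_", groups)

#' Observed budget shares from a household table
#'
#' Shares are each group's expenditure divided by the household's total
#' food expenditure (the row sum over groups).
#'
#' @param households household data frame with `exp_<group>` columns.
#' @param groups character vector of group names.
#' @return `n x G` share matrix.
#' @export
budget_shares <- function(households, groups = quaids_groups) {
  E <- as.matrix(households[, exp_cols(groups)])
  m <- food_budget(households, groups)
  if (any(m <= 0)) stop("households with zero total food expenditure")
  W <- E / m
  colnames(W) <- groups
  W
}

## Total food expenditure: the `total_expenditure` column when present,
## otherwise the row sum of the group expenditures (identical whenever
## observed shares add to one).
food_budget <- function(households, groups = quaids_groups) {
  if ("total_expenditure" %in% names(households))
    households$total_expenditure else
      rowSums(as.matrix(households[, exp_cols(groups)]))
}

uv_demog_cols <- c("head_age", "head_gender", "head_education",
                   "adult_equivalents", "has_children", "single_household")

#' Quality-adjusted cluster prices from unit values, one group
#'
#' Among purchasing households, regresses the log unit value (log
#' expenditure minus log quantity) on log quantity and household
#' demographics, absorbing municipal-cluster fixed effects by demeaning
#' all variables at the cluster level (all households in a cluster face
#' the same price).  The cluster log price is then recovered as the
#' cluster mean log unit value minus the quality and demographic
#' components evaluated at cluster means.  Clusters without purchasers of
#' the group receive the across-cluster mean log price, flagged as
#' imputed, so that every household carries a full price vector.
#'
#' @param households household data frame (needs `exp_`/`qty_` columns for
#'   the group, `cluster_id`, and the demographic columns
#'   `head_age`, `head_gender`, `head_education`, `adult_equivalents`,
#'   `has_children`, `single_household`).
#' @param group group name (without the `exp_` prefix).
#' @return List with `epsilon` (log-quantity coefficient), `eta` (named
#'   demographic coefficients), `n_obs`, and `clusters`: a data frame
#'   `cluster_id`, `ln_price`, `imputed`, `n_purchasers`.
#' @export
estimate_unit_value_model <- function(households, group) {
  e <- households[[paste0("exp_", group)]]
  q <- households[[paste0("qty_", group)]]
  if (is.null(e) || is.null(q)) stop("no expenditure/quantity columns for group ", group)
  pos <- e > 0 & q > 0
  cl_all <- sort(unique(households$cluster_id))
  cl <- households$cluster_id[pos]
  tab <- table(cl)
  if (sum(tab >= 2) < 2)
    stop("need at least 2 clusters with at least 2 purchasing households for group ",
         group)
  lnv <- log(e[pos]) - log(q[pos])
  X <- cbind(ln_q = log(q[pos]),
             as.matrix(households[pos, uv_demog_cols]))
  ## cluster demeaning (within transformation)
  dm <- function(v) v - ave(v, cl)
  y_w <- dm(lnv)
  X_w <- apply(X, 2, dm)
  ## regressors constant within every cluster (e.g. a dummy nobody in the
  ## purchasing subsample switches on) carry no within variation; their
  ## level is absorbed into the cluster price and their coefficient set
  ## to zero
  dropped <- colnames(X_w)[apply(abs(X_w), 2, max) < 1e-10]
  live <- setdiff(colnames(X_w), dropped)
  qrx <- qr(X_w[, live, drop = FALSE])
  if (qrx$rank < length(live)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    stop("collinear unit-value regressors for group ", group, ": ",
         paste(live[-keep], collapse = ", "))
  }
  coefs <- stats::setNames(numeric(ncol(X_w)), colnames(X_w))
  coefs[live] <- qr.coef(qrx, y_w)
  ## cluster price: cluster-mean unit value net of quality/demographics
  cmean <- function(v) as.numeric(tapply(v, cl, mean))
  Xc <- vapply(colnames(X), function(j) cmean(X[, j]),
               numeric(length(unique(cl))))
  lnp_c <- cmean(lnv) - drop(Xc %*% coefs)
  out <- data.frame(cluster_id = cl_all,
                    ln_price = NA_real_, imputed = TRUE,
                    n_purchasers = as.integer(0))
  ii <- match(sort(unique(cl)), cl_all)
  out$ln_price[ii] <- lnp_c
  out$imputed[ii] <- FALSE
  out$n_purchasers[match(as.integer(names(tab)), cl_all)] <- as.integer(tab)
  out$ln_price[out$imputed] <- mean(out$ln_price[!out$imputed])
  list(epsilon = unname(coefs["ln_q"]),
       eta = coefs[setdiff(names(coefs), "ln_q")],
       dropped = dropped, n_obs = sum(pos), clusters = out)
}

#' Cluster price set for all groups
#'
#' Runs [estimate_unit_value_model()] for each group and assembles the
#' quality-adjusted cluster log prices in long form.
#'
#' @inheritParams estimate_unit_value_model
#' @param groups character vector of group names.
#' @return A data frame of class `cluster_price_set` with columns
#'   `cluster_id`, `group`, `ln_price`, `imputed`, `n_purchasers`; the
#'   per-group unit-value coefficients are stored in
#'   `attr(, "coefficients")`.
#' @export
cluster_price_set <- function(households, groups = quaids_groups) {
  fits <- lapply(groups, function(g) estimate_unit_value_model(households, g))
  names(fits) <- groups
  long <- do.call(rbind, lapply(groups, function(g)
    cbind(group = g, fits[[g]]$clusters)))
  structure(long[, c("cluster_id", "group", "ln_price", "imputed",
                     "n_purchasers")],
            coefficients = lapply(fits, function(f)
              list(epsilon = f$epsilon, eta = f$eta, n_obs = f$n_obs)),
            groups = groups,
            class = c("cluster_price_set", "data.frame"))
}

#' Household-level log price matrix from a cluster price set
#'
#' Every household in a cluster receives that cluster's full price vector,
#' including for groups it did not purchase.
#'
#' @param prices a [cluster_price_set()].
#' @param cluster_ids household cluster assignments.
#' @return `n x G` matrix of log prices.
#' @export
price_matrix <- function(prices, cluster_ids) {
  groups <- attr(prices, "groups")
  wide <- matrix(NA_real_,
                 nrow = length(unique(prices$cluster_id)),
                 ncol = length(groups),
                 dimnames = list(sort(unique(prices$cluster_id)), groups))
  wide[cbind(match(prices$cluster_id, as.integer(rownames(wide))),
             match(prices$group, groups))] <- prices$ln_price
  out <- wide[match(cluster_ids, as.integer(rownames(wide))), , drop = FALSE]
  if (anyNA(out)) stop("missing cluster price for some household")
  rownames(out) <- NULL
  out
}

#' Control-function residual for total-expenditure endogeneity
#'
#' OLS of log total food expenditure on a set of instruments (by default:
#' SES stratum, cluster indicators, the basic-amenities index, and the
#' head's age, gender and education plus adult-equivalent household size).
#' The residual is carried into the demand system as an additional
#' regressor, absorbing the correlation between total expenditure and the
#' share disturbances.
#'
#' @param households household data frame.
#' @param instruments character vector of instrument column names;
#'   `"cluster_id"` and `"ses"` enter as indicator sets,
#'   `"amenities"` is computed as the mean of the three amenity dummies.
#'   An empty vector gives the constant-only model (demeaned log
#'   expenditure).
#' @param groups groups whose expenditures define the food budget.
#' @return Data frame `household_id`, `residual`, with the fitted
#'   coefficients in `attr(, "coefficients")` and the first-stage R^2 in
#'   `attr(, "r_squared")`.
#' @export
expenditure_control_residual <- function(
    households,
    instruments = c("ses", "cluster_id", "amenities", "head_age",
                    "head_gender", "head_education", "adult_equivalents"),
    groups = quaids_groups) {
  lnm <- log(food_budget(households, groups))
  X <- matrix(1, nrow(households), 1, dimnames = list(NULL, "(Intercept)"))
  for (v in instruments) {
    col <- switch(v,
      ses = if (length(unique(households$ses)) < 2) NULL else
        stats::model.matrix(~ ses, households)[, -1, drop = FALSE],
      cluster_id = if (length(unique(households$cluster_id)) < 2) NULL else
        stats::model.matrix(~ factor(cluster_id),
                            households)[, -1, drop = FALSE],
      amenities = cbind(amenities = (households$amen_gas +
                          households$amen_electricity +
                          households$amen_water) / 3),
      cbind(households[[v]]))
    if (is.null(col)) next
    if (is.null(dim(col)) || is.null(colnames(col)) ||
        any(colnames(col) == "")) colnames(col) <- v
    X <- cbind(X, col)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("rank-deficient instrument matrix; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrx, lnm)
  res <- lnm - drop(X %*% beta)
  r2 <- 1 - sum(res^2) / sum((lnm - mean(lnm))^2)
  structure(data.frame(household_id = households$household_id,
                       residual = res),
            coefficients = beta, r_squared = r2,
            class = c("expenditure_residual", "data.frame"))
}
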