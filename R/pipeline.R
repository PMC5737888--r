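#' Full two-step estimation pipeline
#'
#' Runs, in order: quality-adjusted cluster price construction from unit
#' values, the expenditure control-function regression, the per-group
#' probit first stage, the constrained system fit, and the elasticity
#' matrix at the sample means.  Each stage's output is returned; errors
#' are annotated with the stage that produced them.
#'
#' @param households household data frame (see [generate_survey()]).
#' @param groups group names.
#' @param censored fit the censoring-augmented system (default) or the
#'   plain uncensored QUAIDS.
#' @param control_function include the expenditure control-function
#'   residual (default `TRUE`).
#' @param alpha0 fixed translog anchor.
#' @param z_center centering constants for the demand shifters (sample
#'   means by default; pass explicitly to keep strata or bootstrap
#'   replicates on a common scale).
#' @param weights optional household weights.
#' @param participation_from `"expenditure"` (default) infers each
#'   group's purchase indicator from positive expenditure;
#'   `"indicator"` reads explicit `buy_<group>` columns (as written by
#'   [generate_survey()]), which recovery studies on latent-mode
#'   synthetic data need.
#' @param control a [quaids_control()].
#' @return List with `prices`, `residuals`, `first_stage`, `fit`,
#'   `elasticities`.
#' @export
quaids_pipeline <- function(households, groups = quaids_groups,
                            censored = TRUE, control_function = TRUE,
                            alpha0 = 5, z_center = NULL, weights = NULL,
                            participation_from = c("expenditure",
                                                   "indicator"),
                            control = quaids_control()) {
  participation_from <- match.arg(participation_from)
  resp <- if (participation_from == "indicator")
    as.matrix(households[, paste0("buy_", groups)]) else NULL
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
  prices <- stage("price_construction", cluster_price_set(households, groups))
  res <- if (control_function)
    stage("expenditure_control", expenditure_control_residual(
      households, groups = groups)) else NULL
  fs <- if (censored)
    stage("first_stage", fit_participation(households, prices, groups,
                                           response = resp))
  else NULL
  fit <- stage("demand_system", fit_augmented_quaids(
    households, prices, first_stage = fs, residuals = res,
    groups = groups, alpha0 = alpha0, z_center = z_center,
    weights = weights, control = control))
  el <- stage("elasticities", elasticity_matrix(fit))
  list(prices = prices, residuals = res, first_stage = fs, fit = fit,
       elasticities = el)
}

#' Survey descriptive statistics
#'
#' Per-group participation rates, mean budget shares and mean unit
#' values, plus household demographics, overall and by SES stratum,
#' weighted by the `weight` column when present.
#'
#' @param households household data frame.
#' @param groups group names.
#' @return List of class `quaids_descriptives` with data frames `items`
#'   (group-level statistics, one column block per stratum and overall)
#'   and `demographics`.
#' @export
descriptives <- function(households, groups = quaids_groups) {
  w <- if ("weight" %in% names(households)) households$weight else
    rep(1, nrow(households))
  strata <- list(total = rep(TRUE, nrow(households)))
  if ("ses" %in% names(households)) {
    for (s in sort(unique(households$ses)))
      strata[[s]] <- households$ses == s
  } else warning("no 'ses' column; overall statistics only", call. = FALSE)
  W <- budget_shares(households, groups)
  E <- as.matrix(households[, exp_cols(groups)])
  Q <- as.matrix(households[, qty_cols(groups)])
  wmean <- function(x, keep) sum(x[keep] * w[keep]) / sum(w[keep])
  items <- lapply(strata, function(keep) {
    data.frame(
      group = groups,
      participation = vapply(seq_along(groups), function(i)
        wmean(E[, i] > 0, keep), numeric(1)),
      mean_share = vapply(seq_along(groups), function(i)
        wmean(W[, i], keep), numeric(1)),
      mean_unit_value = vapply(seq_along(groups), function(i) {
        p <- keep & E[, i] > 0 & Q[, i] > 0
        sum((E[p, i] / Q[p, i]) * w[p]) / sum(w[p])
      }, numeric(1)))
  })
  demog_cols <- intersect(c("head_age", "head_gender", "head_education",
                            "adult_equivalents", "household_size",
                            "total_expenditure"), names(households))
  demographics <- do.call(rbind, lapply(names(strata), function(s) {
    keep <- strata[[s]]
    data.frame(stratum = s, n = sum(keep),
               t(vapply(demog_cols, function(v)
                 wmean(households[[v]], keep), numeric(1))))
  }))
  structure(list(items = items, demographics = demographics),
            class = "quaids_descriptives")
}

#' @export
print.quaids_descriptives <- function(x, ...) {
  cat("Household survey descriptives\n\nDemographics:\n")
  print(x$demographics, row.names = FALSE, digits = 4)
  cat("\nGroup statistics (overall):\n")
  print(x$items$total, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize fitted demand parameters to JSON
#'
#' @param par a [demand_parameters()] object.
#' @param path output file.
#' @export
write_demand_parameters <- function(par, path) {
  jsonlite::write_json(
    list(schema = "cquaids-params-1", groups = par$groups,
         alpha0 = par$alpha0, alpha = par$alpha, beta = par$beta,
         lambda = par$lambda, gamma = par$gamma, rho = par$rho,
         delta = par$delta, kappa = par$kappa),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read demand parameters written by [write_demand_parameters()]
#' @param path JSON file.
#' @return A [demand_parameters()] object.
#' @export
read_demand_parameters <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, "cquaids-params-1"))
    stop("unrecognized parameter schema: ", j$schema)
  demand_parameters(j$alpha, j$beta, j$lambda, as.matrix(j$gamma),
                    rho = if (is.null(j$rho)) NULL else as.matrix(j$rho),
                    delta = j$delta, kappa = j$kappa, alpha0 = j$alpha0,
                    tol = 1e-6, group_names = j$groups)
}

#' Run the complete workflow from a configuration list
#'
#' Simulates (or loads) a survey, runs the estimation pipeline (optionally
#' per SES stratum), optionally bootstraps elasticity standard errors and
#' projects an SSB tax, and - when `out_dir` is given - writes every
#' artifact (CSV/JSON) together with a run manifest recording the
#' configuration, seed, package version, timestamps and file digests, so
#' any output can be regenerated from the manifest alone.
#'
#' @param config list with elements (all optional unless noted):
#'   `n_households` (simulation size, default 2000), `seed` (root seed,
#'   default 1), `survey` (an existing `quaids_survey`, overrides
#'   simulation), `censored` (default TRUE), `control_function`
#'   (default TRUE), `alpha0` (default 2, matching the packaged preset's
#'   expenditure scale), `stratify` (`NULL` or `"ses"`), `n_boot`
#'   (bootstrap replicates, 0 to skip), `tax` (list passed to
#'   [tax_scenario()]; its `own_price_elasticity` defaults to the fitted
#'   SSB own-price elasticity), `out_dir` (output directory).
#' @return List with `survey`, `pipeline`, optional `strata`,
#'   `projection`, and `manifest`; invisibly when writing to disk.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(
    list(n_households = 2000, seed = 1L, survey = NULL, censored = TRUE,
         control_function = TRUE, alpha0 = 2, stratify = NULL,
         n_boot = 0, tax = NULL, out_dir = NULL), config)
  t0 <- Sys.time()
  survey <- if (!is.null(cfg$survey)) cfg$survey else
    generate_survey(colombia_preset(cfg$n_households, seed = cfg$seed))
  hh <- survey$households
  pl <- quaids_pipeline(hh, censored = cfg$censored,
                        control_function = cfg$control_function,
                        alpha0 = cfg$alpha0)
  if (cfg$n_boot > 0)
    pl$elasticities <- bootstrap_elasticities(
      hh, n_reps = cfg$n_boot, seed = cfg$seed + 1L,
      censored = cfg$censored, control_function = cfg$control_function,
      alpha0 = cfg$alpha0)
  out <- list(survey = survey, pipeline = pl)
  if (identical(cfg$stratify, "ses")) {
    out$strata <- lapply(split(hh, hh$ses), function(h)
      quaids_pipeline(h, censored = cfg$censored,
                      control_function = cfg$control_function,
                      alpha0 = cfg$alpha0))
    out$ses_comparison <- data.frame(
      group = quaids_groups,
      vapply(out$strata, function(p) diag(p$elasticities$e),
             numeric(length(quaids_groups))))
  }
  if (!is.null(cfg$tax)) {
    tx <- cfg$tax
    if (is.null(tx$own_price_elasticity))
      tx$own_price_elasticity <- pl$elasticities$e["ssb", "ssb"]
    out$projection <- revenue_table(do.call(tax_scenario, tx),
                                    read_baseline())
  }
  if (!is.null(cfg$out_dir)) {
    d <- cfg$out_dir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    write_survey(survey, d)
    utils::write.csv(as.data.frame(pl$prices), file.path(d, "prices.csv"),
                     row.names = FALSE)
    write_demand_parameters(pl$fit$par, file.path(d, "params.json"))
    utils::write.csv(as.data.frame(pl$elasticities),
                     file.path(d, "elasticities.csv"), row.names = FALSE)
    if (!is.null(out$projection))
      utils::write.csv(out$projection, file.path(d, "projection.csv"),
                       row.names = FALSE)
    files <- list.files(d, full.names = TRUE)
    manifest <- list(package = "cquaids",
                     version = as.character(utils::packageVersion("cquaids")),
                     config = cfg[setdiff(names(cfg), c("survey", "out_dir"))],
                     seed = cfg$seed,
                     started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                     finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     digests = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
    return(invisible(out))
  }
  out
}

#' Own-price elasticities by SES stratum, plotted
#'
#' @param ses_comparison the `ses_comparison` element of [run_pipeline()]
#'   output (columns: group, one column per stratum).
#' @return A ggplot object.
#' @export
plot_ses_elasticities <- function(ses_comparison) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  long <- stats::reshape(ses_comparison, direction = "long",
                         varying = setdiff(names(ses_comparison), "group"),
                         v.names = "elasticity", timevar = "stratum",
                         times = setdiff(names(ses_comparison), "group"))
  ggplot2::ggplot(long, ggplot2::aes(x = group, y = elasticity,
                                     fill = stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Own-price elasticity")
}

#' Projected post-tax volume path, plotted
#'
#' @param projection a [revenue_table()] result.
#' @param baseline the matching [read_baseline()] series.
#' @return A ggplot object.
#' @export
plot_projection <- function(projection, baseline = read_baseline()) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- rbind(
    data.frame(year = baseline$year, volume = baseline$volume_mn_l,
               series = "no tax (forecast)"),
    data.frame(year = projection$year, volume = projection$post_tax_volume,
               series = "with tax"))
  ggplot2::ggplot(df, ggplot2::aes(x = year, y = volume,
                                   colour = series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "SSB sales (million liters)")
}
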