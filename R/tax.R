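#' Ad-valorem SSB tax scenario
#'
#' Bundles the policy levers of the projection: the ad-valorem tax rate,
#' the fraction of the tax passed through to consumer prices, the flat
#' annual inflation rate applied to the pre-tax price path, the first
#' year the tax is in force, and the own-price elasticity that maps the
#' consumer price change into a volume change.
#'
#' @param own_price_elasticity uncompensated own-price elasticity of the
#'   taxed group (e.g. -1.616 for sugar-sweetened beverages from the
#'   fitted censored model).
#' @param tax_rate ad-valorem tax rate as a fraction (default 0.20).
#' @param pass_through fraction of the tax reflected in consumer prices
#'   (default 1, complete pass-through).
#' @param inflation flat annual inflation rate (default 0.03).
#' @param start_year first year the tax applies (default 2017).
#' @param vat optional value-added-tax rate used only when revenue is to
#'   be computed on pre-VAT prices; 0 (default) reproduces the headline
#'   arithmetic.
#' @param exchange_rate COP per USD, context only (default 3000).
#' @return List of class `tax_scenario`.
#' @export
tax_scenario <- function(own_price_elasticity, tax_rate = 0.20,
                         pass_through = 1.0, inflation = 0.03,
                         start_year = 2017, vat = 0,
                         exchange_rate = 3000) {
  stopifnot(tax_rate >= 0, pass_through >= 0, pass_through <= 1, vat >= 0)
  structure(list(own_price_elasticity = own_price_elasticity,
                 tax_rate = tax_rate, pass_through = pass_through,
                 inflation = inflation, start_year = as.integer(start_year),
                 vat = vat, exchange_rate = exchange_rate),
            class = "tax_scenario")
}

#' Baseline sales and fiscal-revenue series
#'
#' Reads (or validates) the projection inputs: per year, the average
#' pre-tax price per liter (USD), the forecast sales volume with no tax
#' (million liters), and total government fiscal revenue (million USD).
#' The packaged fixture `colombia_ssb_baseline_2016_2020.csv` carries the
#' published 2016 price and volume, the 2017-2020 fiscal-revenue
#' forecasts, and no-tax volume forecasts for 2017-2020 that are
#' back-solved from the published post-tax volumes under a 20% tax with
#' elasticity -1.616 (the publication does not print the no-tax path
#' itself).
#'
#' @param path CSV with columns `year`, `price_usd_per_l`, `volume_mn_l`,
#'   `fiscal_revenue_mm_usd`; defaults to the packaged Colombia fixture.
#' @return Data frame of class `baseline_series`.
#' @export
read_baseline <- function(path = system.file(
  "extdata", "colombia_ssb_baseline_2016_2020.csv", package = "cquaids")) {
  b <- utils::read.csv(path)
  need <- c("year", "price_usd_per_l", "volume_mn_l",
            "fiscal_revenue_mm_usd")
  if (!all(need %in% names(b))) stop("baseline is missing columns: ",
                                     paste(setdiff(need, names(b)),
                                           collapse = ", "))
  if (any(diff(b$year) != 1)) stop("baseline years must be consecutive")
  if (any(b$volume_mn_l <= 0, na.rm = TRUE))
    stop("baseline volumes must be positive")
  structure(b[order(b$year), ], class = c("baseline_series", "data.frame"))
}

#' Projected consumer price under inflation and an ad-valorem tax
#'
#' `price = base_price * (1 + inflation)^years_elapsed *
#' (1 + pass_through * tax_rate)`.  Full precision is kept; rounding to
#' two decimals happens only at reporting.
#'
#' @param base_price pre-tax price in the base year (currency per liter).
#' @param inflation flat annual inflation rate.
#' @param years_elapsed whole years since the base year (>= 0).
#' @param tax_rate ad-valorem tax rate.
#' @param pass_through fraction of the tax passed to consumer prices.
#' @return Projected consumer price per liter.
#' @examples
#' project_price(0.67, 0.03, 1, 0.20, 1.0)   # ~0.828, reported as 0.83
#' @export
project_price <- function(base_price, inflation, years_elapsed, tax_rate,
                          pass_through = 1.0) {
  stopifnot(base_price > 0)
  if (any(years_elapsed < 0)) stop("years_elapsed must be nonnegative")
  base_price * (1 + inflation)^years_elapsed *
    (1 + pass_through * tax_rate)
}

#' Post-tax sales volume from an own-price elasticity
#'
#' Applies the constant-elasticity first-order response
#' `volume * (1 + elasticity * price_change)` to a no-tax volume
#' forecast, floored at zero.
#'
#' @param no_tax_volume forecast volume with no tax (million liters).
#' @param elasticity own-price elasticity (negative for normal demand).
#' @param price_change relative consumer price change caused by the tax
#'   (e.g. `pass_through * tax_rate`).
#' @return Post-tax volume (million liters).
#' @examples
#' post_tax_volume(3819.44, -1.616, 0.20)    # ~2585, a ~32% drop
#' @export
post_tax_volume <- function(no_tax_volume, elasticity, price_change) {
  stopifnot(all(no_tax_volume > 0))
  pmax(no_tax_volume * (1 + elasticity * price_change), 0)
}

#' Yearly tax projection table
#'
#' Applies the ad-valorem tax to each year's pre-tax price (the
#' baseline's own per-year price forecast where available, otherwise
#' chained from the base year with [project_price()]), applies the
#' elasticity response to each year's no-tax volume forecast, and
#' computes tax revenue as post-tax volume times the reported (two
#' decimal) price times the tax rate, together with its share of total
#' fiscal revenue.
#'
#' @param scenario a [tax_scenario()].
#' @param baseline a [read_baseline()] series covering the year before
#'   `start_year` through the last projection year.
#' @return Data frame of class `projection_table` with per-year columns
#'   `taxed_price` (USD/L, two decimals), `post_tax_volume` (million L),
#'   `tax_revenue` (million USD, full precision) and
#'   `revenue_share_of_fiscal` (fraction; `NA` with a warning for years
#'   without a fiscal-revenue entry).
#' @export
revenue_table <- function(scenario, baseline) {
  stopifnot(inherits(scenario, "tax_scenario"))
  y0 <- scenario$start_year - 1L
  if (!(y0 %in% baseline$year))
    stop("baseline must include the pre-tax base year ", y0)
  base_price <- baseline$price_usd_per_l[baseline$year == y0]
  if (!is.finite(base_price))
    stop("baseline price for the base year ", y0, " is missing")
  yrs <- baseline$year[baseline$year >= scenario$start_year]
  price_change <- scenario$pass_through * scenario$tax_rate
  pre_tax <- baseline$price_usd_per_l[match(yrs, baseline$year)]
  chained <- base_price * (1 + scenario$inflation)^(yrs - y0)
  pre_tax[!is.finite(pre_tax)] <- chained[!is.finite(pre_tax)]
  full_price <- pre_tax * (1 + scenario$pass_through * scenario$tax_rate)
  taxed_price <- round(full_price, 2)
  vol0 <- baseline$volume_mn_l[match(yrs, baseline$year)]
  vol <- post_tax_volume(vol0, scenario$own_price_elasticity, price_change)
  taxable_price <- taxed_price / (1 + scenario$vat)
  revenue <- vol * taxable_price * scenario$tax_rate
  fiscal <- baseline$fiscal_revenue_mm_usd[match(yrs, baseline$year)]
  if (anyNA(fiscal))
    warning("fiscal-revenue entries missing for: ",
            paste(yrs[is.na(fiscal)], collapse = ", "),
            "; revenue share omitted for those years", call. = FALSE)
  structure(data.frame(year = yrs, taxed_price = taxed_price,
                       no_tax_volume = vol0, post_tax_volume = vol,
                       tax_revenue = revenue,
                       revenue_share_of_fiscal = revenue / fiscal),
            scenario = scenario,
            class = c("projection_table", "data.frame"))
}

#' @export
print.projection_table <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf(
    "Ad-valorem tax projection: rate %.0f%%, pass-through %.0f%%, elasticity %.3f\n",
    100 * sc$tax_rate, 100 * sc$pass_through, sc$own_price_elasticity))
  out <- data.frame(year = x$year,
                    `price/L` = sprintf("%.2f", x$taxed_price),
                    `volume (mn L)` = round(x$post_tax_volume),
                    `revenue (MM USD)` = round(x$tax_revenue),
                    `share of fiscal` = ifelse(
                      is.na(x$revenue_share_of_fiscal), "-",
                      sprintf("%.2f%%", 100 * x$revenue_share_of_fiscal)),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}
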