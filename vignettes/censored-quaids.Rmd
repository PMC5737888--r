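---
title: "Censored QUAIDS estimation and beverage-tax projection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored QUAIDS estimation and beverage-tax projection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cquaids)
```

## The demand model

The package estimates food demand for a household that allocates its
food-at-home budget $m$ across $G$ groups (the packaged presets use the
nine-group classification of the Colombian urban expenditure survey:
milk; tea, water and coffee; sugar-sweetened beverages; sweets and
candies; other dairy; grains; meats; fruits and vegetables; condiments
and snacks).  The latent budget shares follow the Quadratic Almost Ideal
Demand System,

$$w_i = \alpha_i + \sum_j \gamma_{ij}\ln p_j
      + \beta_i \ln\!\frac{m}{a(p)}
      + \frac{\lambda_i}{b(p)}\left[\ln\frac{m}{a(p)}\right]^2,$$

with the translog index
$\ln a(p) = \alpha_0 + \sum_j \alpha_j \ln p_j + \tfrac12 \sum_{l,j}
\gamma_{lj}\ln p_l \ln p_j$, the Cobb–Douglas aggregator
$b(p) = \prod_j p_j^{\beta_j}$, and demographic heterogeneity entering
through $\alpha_i = \alpha_{0i} + \sum_k \rho_{ik} z_k$.  The shifters
$z$ are the head's age and education and the adult-equivalent household
size, centered before they enter so that $\alpha_{0i}$ keeps the scale
of a mean share.  Adding-up, homogeneity and symmetry
($\sum_i\alpha_{0i}=1$, $\sum_i\beta_i=\sum_i\lambda_i=0$,
$\sum_i\rho_{ik}=0$, $\gamma_{ij}=\gamma_{ji}$ with zero row sums) are
imposed exactly by reparameterization: the optimizer works on a free
subset and the constrained entries are reconstructed, so every fit
satisfies the restrictions to machine precision (`check_quaids_constraints()`
verifies them at $10^{-8}$).

The scalar $\alpha_0$ is not identified separately and is fixed, by
convention just below the sample minimum of log expenditure (the
estimator warns otherwise).  The classical default is 5 for expenditure
recorded in Colombian pesos; the packaged synthetic preset records
expenditure in 2007 USD per month, where the same convention gives 2.
$\alpha_0$ is a pure normalization of the $\ln a(p)$ intercept, so this
choice moves $\alpha_{0i}$ but not elasticities.

## Prices from unit values

Expenditure surveys report expenditures and quantities, not prices.
Unit values (expenditure over quantity) proxy prices but embed quality
choice and measurement error.  Following the standard
municipal-cluster approach, `estimate_unit_value_model()` assumes all
households of a cluster face one price and regresses, among purchasers,

$$\ln v_{ihc} = \ln p_{ic} + \epsilon_i \ln q_{ihc}
  + \textstyle\sum_l \eta_{il} z_{lhc} + u_{ihc},$$

absorbing the cluster fixed effect by within-cluster demeaning.  The
cluster log price is recovered as the cluster mean log unit value net of
the quality terms evaluated at cluster means; all households of a
cluster — purchasers or not — then carry the full price vector, which
the probit and demand stages require.  Two conventions are the
package's own (the aggregation point for the recovery step is not
pinned down by the approach itself): the evaluation point is the
cluster mean of $\ln q$ and $z$, and clusters with no purchasers of a
group receive the cross-cluster mean log price, flagged `imputed`.
Regressors with no within-cluster variation among purchasers (e.g. a
dummy nobody switches on in a small bootstrap resample) are dropped
with a zero coefficient — their level is absorbed into the price — while
genuine collinearity remains an error naming the columns.

Total-expenditure endogeneity is handled with a control function:
`expenditure_control_residual()` regresses log food expenditure on SES
stratum, cluster indicators, a basic-amenities index (mean of the gas,
electricity and drinking-water dummies — the aggregation is the
package's choice), and the head's age, gender, education and household
size; the residual enters each share equation with loading $\kappa_i$,
$\sum_i \kappa_i = 0$ for internal consistency of the latent system.

## Censoring: the two-step correction

Between a fifth and two thirds of households report no purchase in a
given group.  `fit_participation()` estimates one probit per group on
all $G$ log prices, log expenditure and demographic shifters, and the
share system is augmented to

$$w_i^{*} = \hat\Phi_i\, w_i(\theta) + \delta_i \hat\phi_i + u_i,$$

so the mean of the observed share combines the purchase probability and
the selection term.  Identification of $\delta_i$ rests on an exclusion
restriction: the head's age enters the demand system but not the
probit, while the children and single-household dummies enter the
probit only.  Both shifter sets are configurable.  Expenditure enters
the probit in logs by default (a `level` switch is provided).  Predicted
probabilities are clamped to $[10^{-10}, 1-10^{-10}]$ before any
division.  Because the augmented system no longer adds up, all nine
equations are kept — no equation is dropped — and the estimates are
invariant to reordering the groups (a property the tests assert).  One
numerical footnote: with an intercept, the probit score equates a
*weighted* mean of $y-\hat\Phi$ to zero, so the mean of $\hat\Phi$
matches the empirical participation rate closely (about $10^{-4}$ in
the packaged simulations) but not as an exact identity.

## Estimation scheme

All coefficients are estimated jointly by an iterated feasible
generalized least-squares scheme that exploits the model's conditional
linearity: holding the indices $\ln(m/a(p))$ and $b(p)$ fixed at the
current parameters, the augmented system is linear in every
coefficient, so each outer iteration (i) evaluates the indices,
(ii) solves the restricted generalized least-squares problem of the
stacked $G$-equation system, and (iii) re-estimates the residual
covariance; the scheme iterates these steps to a joint fixed point.
This conditional-linearization update (in the lineage of iterated
linear-least-squares estimators for AIDS-type systems) solves moment
conditions that hold exactly at the true parameters, and the test suite
confirms on a three-good system that its equal-weight fixed point
coincides with a direct BFGS minimization of the stacked nonlinear
least-squares criterion.  Convergence is declared when the relative
parameter change falls below `tol_param` (default $10^{-5}$) and the
relative criterion change below `tol_crit` ($10^{-8}$), with at most
`max_iter` (200) iterations.  In the uncensored case the residual
covariance is structurally singular (residuals add to zero), and the
weighting uses its generalized inverse — the adding-up direction is
dropped silently, any other singularity warns.  Starting values are the
mean-share intercepts with all slopes at zero.  Household weights, when
supplied, multiply the criterion; estimation is unweighted by default.

## Elasticities

`elasticity_matrix()` evaluates the censoring-adjusted uncompensated
elasticities

$$e_{ij} = -\mathbb{1}\{i=j\} + \frac{1}{w_i^{*}}\Big[
  \Phi_i\Big(\gamma_{ij} - \mu_i\big(\alpha_j + \sum_k\gamma_{jk}\ln p_k\big)
  - \frac{\lambda_i\beta_j}{b(p)}\big[\ln\tfrac{m}{a(p)}\big]^2\Big)
  + \tau_j\,\phi_i\,(w_i - \delta_i D_i^{*})\Big],$$

with $\mu_i = \beta_i + \frac{2\lambda_i}{b(p)}\ln(m/a(p))$ and
$\tau_j$ the group-$i$ probit coefficient on $\ln p_j$.  The second
term carries the extensive margin: a price change moves households onto
or off the group.  The formula is exactly the derivative of log
augmented demand in log price holding the evaluation point's
construction fixed, which the tests confirm against central finite
differences at $O(h^2)$; in the uncensored limit it reduces to the
classic AIDS expression, and together with the expenditure elasticities
$e_i = 1 + \mu_i/w_i$ it aggregates to zero (homogeneity).

The evaluation point is the arithmetic sample mean of each ingredient —
observed shares, $\hat\Phi$, $\hat\phi$, the probit index, log prices,
log expenditure and the shifters.  Means of *log* prices are geometric
means of prices; a user preferring the log of arithmetic-mean prices
can pass any point explicitly through `evaluation_point()`.

Standard errors come from a nonparametric bootstrap
(`bootstrap_elasticities()`): households are resampled with replacement
(a cluster-resampling flag is provided; the default treats households
as the sampling unit), the full pipeline — prices, control function,
probits, system fit — is re-run per replicate, and the SE is the
across-replicate standard deviation; 500 replicates is the
production-quality default.  Significance stars are two-sided normal at
0.1/0.05/0.01.  Failed replicates are dropped and counted; losing more
than 10% warns.

## The synthetic survey generator

`generate_survey()` draws from a fully known process so that every
stage is testable without external data: cluster log prices i.i.d.
normal around group-specific levels; demographics with marginals
matching the published survey descriptives (head's age averaging 47.8
years, education 12.2 years, 3.83 adult equivalents per household, a
61/39 low vs mid-high SES split); log expenditure driven by the
control-function instruments plus noise; latent shares from the true
QUAIDS plus mean-zero share noise projected to sum to zero; and
per-group purchase indicators from probit indices whose intercepts are
calibrated so expected participation hits the published rates (32.4%
for sugar-sweetened beverages).  Unit values follow the forward model
$\ln v = \ln p_c + \epsilon \ln q + \eta'z + u$ solved jointly with
$q = e/v$.  The `colombia_preset()` pins the latent shares at the
published mean expenditure shares, the price levels at the published
unit values, and calibrates the $\gamma$ diagonal so the latent
own-price elasticities at the preset means equal the published
estimates (notably $-1.616$ for the SSB group); expenditure is in 2007
USD per month.

Two censoring modes are provided.  The default `"selection"` mode mimics
observed data: non-purchased groups are zeroed and the remaining
expenditures renormalized to the food budget (with a small positive
floor), so shares add to one exactly.  This renormalization is a
realism feature — it also means the two-step mean model is only an
approximation under this mode, exactly as in real applications.  The
`"latent"` mode instead records $D_i(w_i + u_i)$ without
renormalization, which *is* the mean model of the two-step estimator;
recovery and coverage studies use it, together with the generator's
true purchase indicators (`buy_*` columns, `participation_from =
"indicator"`), because a purchaser whose noisy latent share fell below
zero leaves no positive expenditure to infer participation from.
Correlation between share noise and participation errors
(`share_participation_corr`, default 0.4) makes the implied true
$\delta_i$ nonzero.  What passing these tests shows is that the
estimator recovers the process it is designed for; the generator does
not emulate the real survey's two-stage sampling design, survey
weights (passed through only), item-level heterogeneity within groups,
or reconstituted powdered products, so recovery here does not certify
behavior under those features.

Simulation scales in the shipped tests are the package's own choices:
parameter recovery uses 50 surveys of 10,000 households with 100 price
clusters (the emulated survey has 226 municipalities; the default
preset's 20 clusters are a convenient small stand-in, but price-related
coefficients are weakly identified with so few clusters), and bootstrap
confidence-interval calibration uses 50 surveys of 1,200 households
with 30 bootstrap replicates each.

## Tax projection

`revenue_table()` turns an own-price elasticity and a baseline forecast
into post-tax prices, volumes and revenue for an ad-valorem tax.  Each
year's taxed consumer price is the pre-tax price times
$(1 + \text{pass-through}\times\text{rate})$; the pre-tax price is the
baseline's own per-year forecast when present, otherwise chained from
the base year at the flat inflation rate via `project_price()`.  The
packaged Colombian baseline stores the published 2016 price (0.67
USD/L) and the pre-tax prices implied by the published 2017–2020 taxed
path; exact 3% chaining from 0.67 reproduces that path except in 2018,
where it gives 0.85 against the published 0.86 — a rounding wrinkle in
the source inputs, which is why the per-year column is authoritative.
The published table also omits the no-tax volume forecasts for
2017–2020; the fixture back-solves them from the published post-tax
volumes under elasticity $-1.616$ and a 20% price rise (e.g. 3,819.4
million liters in 2017), as documented in `read_baseline()`.  Volumes
respond once through $1 + e\cdot\Delta p$ applied to each year's no-tax
forecast (the baseline's own growth path is retained), floored at
zero.  Revenue is post-tax volume × the reported two-decimal price ×
the tax rate — the convention that reproduces the published revenue
cells; prices are reported at 2 decimals and volumes/revenues rounded
only in printing.  A VAT adjustment (computing revenue on pre-VAT
prices) is available through `tax_scenario(vat = ...)` and off by
default, since the headline arithmetic does not use it.

## Known limitations

* The estimator targets the two-step mean model; under heavy censoring
  with renormalized observed shares (the realistic `"selection"` mode)
  its estimates inherit the usual approximation error of two-step
  censored demand systems.
* Elasticities at sample means divide by mean observed shares; groups
  with tiny mean shares produce noisy, occasionally positive own-price
  estimates in small samples.
* No curvature (negativity) restrictions are imposed, and no
  compensated elasticities or welfare measures are computed.
* The bootstrap default resamples households i.i.d.; with strong
  intra-municipality dependence the cluster-bootstrap flag is the
  safer choice.
* The $\delta_i$ carry no cross-equation restriction (none is implied
  by the augmented system), and the control-function loadings are
  restricted to sum to zero as an internal-consistency convention.
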