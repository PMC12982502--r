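#' Emission-model parameters
#'
#' Constants of the nitrogen-balance emission models and unit conversions:
#' expected N2O-N emission `exp(n2o_intercept + n2o_slope * balance)` and
#' nitrate-N leaching `exp(no3_intercept + no3_slope * balance)`
#' (kg ha^-1, balance in kg N ha^-1); literature-derived variances used for
#' gamma uncertainty propagation; the 100-yr global warming potential of
#' N2O; the N2O-N to N2O (44/28) and N to NH3 (17/14) mass conversions; and
#' the Haber-Bosch manufacture emission factor (kg CO2 per kg NH3).
#'
#' The default `var_n2o` and `var_no3` are synthetic placeholders of a
#' realistic order of magnitude, not literature-review results; supply your
#' own values for real analyses (a warning is issued when the defaults are
#' used in propagation). Expected emission differences are insensitive to
#' them; only the spread of propagated draws depends on them.
#'
#' @param n2o_intercept,n2o_slope N2O-N model coefficients (default 0.339,
#'   0.0047).
#' @param no3_intercept,no3_slope Nitrate-N model coefficients (default
#'   2.459, 0.0061).
#' @param var_n2o,var_no3 Emission variances ((kg ha^-1)^2) for gamma
#'   propagation.
#' @param gwp_n2o kg CO2-e per kg N2O (default 265, 100-yr horizon).
#' @param haber_bosch_ef kg CO2 emitted per kg NH3 manufactured (default
#'   2.16).
#' @return Object of class `emission_params`.
#' @export
emission_params <- function(n2o_intercept = 0.339, n2o_slope = 0.0047,
                            no3_intercept = 2.459, no3_slope = 0.0061,
                            var_n2o = 1.0, var_no3 = 36.0,
                            gwp_n2o = 265, haber_bosch_ef = 2.16) {
  if (any(c(var_n2o, var_no3, gwp_n2o, haber_bosch_ef) <= 0))
    stop("variances, GWP and emission factor must be positive")
  defaults <- missing(var_n2o) && missing(var_no3)
  structure(list(n2o_intercept = n2o_intercept, n2o_slope = n2o_slope,
                 no3_intercept = no3_intercept, no3_slope = no3_slope,
                 var_n2o = var_n2o, var_no3 = var_no3,
                 gwp_n2o = gwp_n2o,
                 n_to_n2o_mass = 44 / 28, n_to_nh3_mass = 17 / 14,
                 haber_bosch_ef = haber_bosch_ef,
                 default_variances = defaults),
            class = "emission_params")
}

#' Social prices
#'
#' @param p_ghg Social cost of greenhouse-gas emissions, $ per t CO2-e
#'   (default 50).
#' @param p_leaching Social cost of N leaching, $ per kg N (default 18.54).
#' @return Object of class `social_prices`.
#' @export
social_prices <- function(p_ghg = 50, p_leaching = 18.54) {
  if (p_ghg < 0 || p_leaching < 0) stop("prices must be non-negative")
  structure(list(p_ghg = p_ghg, p_leaching = p_leaching),
            class = "social_prices")
}

#' Soil-surface nitrogen balance
#'
#' Applied fertilizer N minus N removed in grain; the single predictor of
#' the emission models. May be negative at low rates (mining of soil N).
#'
#' @param rate Fertilizer N applied, kg ha^-1 (the only N input in these
#'   trials).
#' @param grain_n N removed in grain, kg ha^-1.
#' @return `rate - grain_n`, kg ha^-1.
#' @export
n_balance <- function(rate, grain_n) rate - grain_n

#' Expected N2O-N emission and nitrate-N leaching at a given N balance
#'
#' @param balance N balance, kg ha^-1 (vectorized).
#' @param params An [emission_params()].
#' @return List with vectors `n2o_n` and `no3_n` (kg ha^-1).
#' @export
expected_emissions <- function(balance, params = emission_params()) {
  list(n2o_n = exp(params$n2o_intercept + params$n2o_slope * balance),
       no3_n = exp(params$no3_intercept + params$no3_slope * balance))
}

#' Gamma uncertainty propagation for emission expectations
#'
#' Each expected emission E is replaced by one draw from
#' gamma(shape = E^2 / var, rate = E / var) — a distribution with mean E
#' and the literature variance — turning plug-in expectations into an
#' uncertainty-carrying sample.
#'
#' @param expectation Vector of expected emissions (kg ha^-1, all > 0).
#' @param variance Literature variance ((kg ha^-1)^2, > 0).
#' @param seed Integer seed.
#' @return Vector of gamma draws, one per expectation.
#' @export
gamma_propagate <- function(expectation, variance, seed = 1L) {
  if (any(expectation <= 0))
    stop("expectations must be positive for gamma propagation")
  if (!is.numeric(variance) || length(variance) != 1 || variance <= 0)
    stop("'variance' must be a single positive number; ",
         "set it in emission_params()")
  set.seed(seed)
  stats::rgamma(length(expectation), shape = expectation^2 / variance,
                rate = expectation / variance)
}

#' CO2 from fertilizer manufacture avoided by an N-rate reduction
#'
#' Converts the reduced fertilizer N mass to ammonia (x 17/14) and applies
#' the Haber-Bosch manufacture emission factor.
#'
#' @param delta_n N-rate reduction, kg N ha^-1 (>= 0).
#' @param params An [emission_params()].
#' @return kg CO2 ha^-1 avoided.
#' @examples
#' fert_co2(22)  # ~57.7
#' @export
fert_co2 <- function(delta_n, params = emission_params()) {
  if (any(delta_n < 0)) stop("'delta_n' must be non-negative")
  delta_n * params$n_to_nh3_mass * params$haber_bosch_ef
}

#' Monetized social benefit of emission and leaching reductions
#'
#' `SB = (GHG_dN2O + GHG_dfert) * P_GHG + dN_leaching * P_leaching`, where
#' the avoided N2O-N is converted to N2O mass (x 44/28), normalized to
#' CO2-e with the GWP factor, summed with the avoided manufacture CO2,
#' converted from kg to t, and priced; the leaching term is priced
#' directly in kg N.
#'
#' @param d_n2o_n Avoided N2O-N, kg ha^-1 (vectorized).
#' @param d_fert_co2 Avoided manufacture CO2, kg ha^-1.
#' @param d_leach Avoided nitrate-N leaching, kg N ha^-1.
#' @param prices A [social_prices()].
#' @param params An [emission_params()] (GWP and mass conversions).
#' @return Social benefit, $ ha^-1.
#' @export
social_benefit <- function(d_n2o_n, d_fert_co2, d_leach,
                           prices = social_prices(),
                           params = emission_params()) {
  co2e <- d_n2o_n * params$n_to_n2o_mass * params$gwp_n2o + d_fert_co2
  co2e / 1000 * prices$p_ghg + d_leach * prices$p_leaching
}

#' Default planted-area table for the eight Corn Belt states
#'
#' Approximate five-year (2019-2023) average maize planted areas in
#' hectares, rounded from public USDA-NASS statistics. Supply your own
#' table for other regions or periods.
#'
#' @return Data.frame with columns `state`, `hectares`.
#' @export
default_areas <- function() {
  utils::read.csv(system.file("extdata", "state_maize_area.csv",
                              package = "onrisk"))
}

#' Scale a per-hectare quantity to state and regional totals
#'
#' Multiplies a per-hectare value (and its standard error) by each state's
#' planted area and sums. Under the stated assumption that every state
#' follows the same yield response simultaneously, errors are perfectly
#' correlated across states, so the SE scales linearly with the summed
#' area.
#'
#' @param value_per_ha Per-hectare value ($ ha^-1 or kg ha^-1).
#' @param areas Data.frame with columns `state`, `hectares`.
#' @param se_per_ha Optional per-hectare standard error.
#' @param states States to include (default: all rows of `areas`); an
#'   error lists any state missing from `areas`.
#' @return List with `by_state` (data.frame `state, hectares, total,
#'   total_se`) and `total`, `total_se`.
#' @export
scale_to_region <- function(value_per_ha, areas = default_areas(),
                            se_per_ha = NA_real_, states = NULL) {
  if (is.null(states)) states <- areas$state
  missing <- setdiff(states, areas$state)
  if (length(missing))
    stop("no planted area for state(s): ", paste(missing, collapse = ", "))
  sub <- areas[match(states, areas$state), ]
  by_state <- data.frame(state = sub$state, hectares = sub$hectares,
                         total = value_per_ha * sub$hectares,
                         total_se = se_per_ha * sub$hectares)
  list(by_state = by_state, total = sum(by_state$total),
       total_se = se_per_ha * sum(sub$hectares))
}

#' Environmental and social benefit of a staged N-rate reduction
#'
#' Implements the emission half of the pipeline for one site/scenario.
#' For each retained grain-N posterior draw, the N balance at the high and
#' low rates is formed from the draw's population-level grain-N curve
#' (Eq.-style plug-in: balance = rate - predicted grain N), the expected
#' N2O-N and nitrate-N follow from the nitrogen-balance models, and
#' uncertainty is propagated by sampling each expectation from a
#' moment-matched gamma distribution. Reductions (high minus low) are
#' reported as draw means with draw SDs; negative propagated differences
#' are kept as-is (truncation would bias the benefit upward). The avoided
#' manufacture CO2 is deterministic in the rate reduction.
#'
#' @param grain_draws A `qp_draws` object for the grain-N response.
#' @param rate_high,rate_low N rates bracketing the reduction, kg ha^-1.
#' @param params An [emission_params()].
#' @param prices A [social_prices()].
#' @param seed Seed for the gamma propagation.
#' @param extrapolate Passed to [posterior_predictive()].
#' @return One-row data.frame: rates, `d_no3_n`, `d_no3_n_sd`, `d_n2o_n`,
#'   `d_n2o_n_sd`, `d_no3_pct`, `d_n2o_pct` (percent of the high-rate
#'   expectation), `d_fert_co2`, `co2e`, `sb_per_ha`, `sb_per_ha_sd`.
#' @export
env_social_report <- function(grain_draws, rate_high, rate_low,
                              params = emission_params(),
                              prices = social_prices(), seed = 1L,
                              extrapolate = FALSE) {
  stopifnot(inherits(grain_draws, "qp_draws"))
  if (isTRUE(params$default_variances))
    warning("using placeholder emission variances; set var_n2o / var_no3 ",
            "in emission_params() from your own literature review",
            call. = FALSE)
  gn <- posterior_predictive(grain_draws, c(rate_high, rate_low),
                             extrapolate = extrapolate)
  bal_hi <- n_balance(rate_high, gn[, 1])
  bal_lo <- n_balance(rate_low, gn[, 2])
  em_hi <- expected_emissions(bal_hi, params)
  em_lo <- expected_emissions(bal_lo, params)
  n2o_hi <- gamma_propagate(em_hi$n2o_n, params$var_n2o, derive_seed(seed, 1))
  n2o_lo <- gamma_propagate(em_lo$n2o_n, params$var_n2o, derive_seed(seed, 2))
  no3_hi <- gamma_propagate(em_hi$no3_n, params$var_no3, derive_seed(seed, 3))
  no3_lo <- gamma_propagate(em_lo$no3_n, params$var_no3, derive_seed(seed, 4))
  d_n2o <- n2o_hi - n2o_lo
  d_no3 <- no3_hi - no3_lo
  d_fert <- fert_co2(rate_high - rate_low, params)
  sb <- social_benefit(d_n2o, d_fert, d_no3, prices, params)
  data.frame(site = attr(grain_draws, "site_id"),
             from_rate = rate_high, to_rate = rate_low,
             d_no3_n = mean(d_no3), d_no3_n_sd = stats::sd(d_no3),
             d_n2o_n = mean(d_n2o), d_n2o_n_sd = stats::sd(d_n2o),
             d_no3_pct = 100 * mean(em_hi$no3_n - em_lo$no3_n) /
               mean(em_hi$no3_n),
             d_n2o_pct = 100 * mean(em_hi$n2o_n - em_lo$n2o_n) /
               mean(em_hi$n2o_n),
             d_fert_co2 = d_fert,
             co2e = mean(d_n2o) * params$n_to_n2o_mass * params$gwp_n2o +
               d_fert,
             sb_per_ha = mean(sb), sb_per_ha_sd = stats::sd(sb))
}
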