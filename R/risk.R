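#' Site reliability filter rule
#'
#' Sites are excluded from inference when any monitored Gelman-Rubin
#' statistic exceeds `rhat_high`, or when the expected agronomic optimum
#' E[AONR] exceeds the highest tested N rate (yield plateau reached only by
#' extrapolation).
#'
#' @param rhat_low,rhat_high Acceptable Rhat interval (default [1, 1.02]).
#' @param max_tested_rate Highest N rate implemented in the trials
#'   (kg ha^-1), default 315.
#' @return Object of class `site_filter_rule`.
#' @export
site_filter_rule <- function(rhat_low = 1, rhat_high = 1.02,
                             max_tested_rate = 315) {
  if (rhat_low > rhat_high) stop("'rhat_low' must be <= 'rhat_high'")
  structure(list(rhat_low = rhat_low, rhat_high = rhat_high,
                 max_tested_rate = max_tested_rate),
            class = "site_filter_rule")
}

#' Filter fitted sites to those reliable for inference
#'
#' @param sites Named list (one element per site) of lists with components
#'   `convergence` (a [gelman_rubin()] report) and `optima` (an
#'   `optima_dist` or its [summarize_optima()] table).
#' @param rule A [site_filter_rule()].
#' @return List with `retained` (character vector of site ids) and
#'   `excluded` (data.frame `site`, `reason`).
#' @export
filter_sites <- function(sites, rule = site_filter_rule()) {
  retained <- character(0)
  exc <- list()
  for (id in names(sites)) {
    s <- sites[[id]]
    reasons <- character(0)
    if (any(s$convergence$rhat > rule$rhat_high, na.rm = TRUE))
      reasons <- c(reasons, sprintf("Gelman-Rubin > %.3g", rule$rhat_high))
    e_aonr <- if (inherits(s$optima, "optima_dist")) mean(s$optima$aonr)
              else s$optima$mean[s$optima$quantity == "AONR"]
    if (e_aonr > rule$max_tested_rate)
      reasons <- c(reasons, "plateau beyond tested range")
    if (length(reasons))
      exc[[id]] <- data.frame(site = id,
                              reason = paste(reasons, collapse = "; "))
    else retained <- c(retained, id)
  }
  excluded <- if (length(exc)) do.call(rbind, exc)
              else data.frame(site = character(0), reason = character(0))
  rownames(excluded) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Summarize a yield-loss draw distribution
#'
#' Bookkeeping shared by all reduction cases: the expected loss is the draw
#' mean, the 95% credible interval comes from the 0.025/0.975 draw
#' quantiles, and the probability of loss is the fraction of draws with
#' strictly positive loss (ties at exactly zero count as non-loss).
#'
#' @param loss Numeric vector of per-draw yield losses (kg ha^-1; positive
#'   = yield lost at the lower rate).
#' @param reference_yield Expected yield (kg ha^-1) used as the
#'   relative-loss denominator.
#' @return One-row data.frame: `expected_loss`, `loss_q025`, `loss_q975`,
#'   `p_loss`, `reference_yield`, `relative_loss_pct`.
#' @export
summarize_loss <- function(loss, reference_yield = NA_real_) {
  qs <- draw_quantile(loss, c(0.025, 0.975))
  data.frame(expected_loss = mean(loss), loss_q025 = qs[1],
             loss_q975 = qs[2], p_loss = mean(loss > 0),
             reference_yield = reference_yield,
             relative_loss_pct = 100 * mean(loss) / reference_yield)
}

#' Yield-loss distribution between two N rates
#'
#' For every retained posterior draw d, the loss is
#' `mu_d(rate_high) - mu_d(rate_low)`: each draw's population-level mean
#' curve (block effect at 0, no residual noise) evaluated at the two fixed
#' rates. Because each draw's curve is non-decreasing in the rate, a draw
#' contributes a strictly positive loss exactly when its own breakpoint
#' lies above `rate_low`; the probability of loss is the fraction of such
#' draws.
#'
#' @param draws A `qp_draws` object (yield model).
#' @param rate_high,rate_low The higher (current) and lower (reduced) N
#'   rates, kg ha^-1.
#' @param reference_rate Rate whose expected yield is the relative-loss
#'   denominator (default `rate_high`).
#' @param extrapolate Allow rates outside the tested range.
#' @return List with `loss` (per-draw vector) and `report` (one-row
#'   data.frame from [summarize_loss()] plus the rates).
#' @export
yield_loss <- function(draws, rate_high, rate_low,
                       reference_rate = rate_high, extrapolate = FALSE) {
  if (rate_low > rate_high) stop("'rate_low' must be <= 'rate_high'")
  pp <- posterior_predictive(draws, c(rate_high, rate_low, reference_rate),
                             extrapolate = extrapolate)
  loss <- pp[, 1] - pp[, 2]
  rep <- summarize_loss(loss, reference_yield = mean(pp[, 3]))
  rep <- cbind(data.frame(from_rate = rate_high, to_rate = rate_low,
                          n_reduction = rate_high - rate_low,
                          n_reduction_pct = 100 * (rate_high - rate_low) /
                            rate_high), rep)
  list(loss = loss, report = rep)
}

#' Staged N-reduction risk analysis for one site
#'
#' Builds the full reduction schedule: Phase I goes from the expected
#' agronomic optimum E[AONR] to the expected economic optimum E[EONR];
#' Phase II cases 1-4 go from E[EONR] down to the 0.4, 0.3, 0.2 and 0.1
#' quantiles of the EONR posterior; the combined row goes from E[AONR]
#' straight to the `combined_quantile` (default 0.3, the "safest case")
#' EONR quantile. Relative losses are expressed against the expected yield
#' at E[AONR] for Phase I and the combined reduction, and against the
#' expected yield at E[EONR] for the Phase II cases.
#'
#' @param draws A `qp_draws` object (yield model) for a retained site.
#' @param optima The matching `optima_dist` (must contain EONR draws).
#' @param case_quantiles EONR quantiles defining Phase II cases (default
#'   0.4, 0.3, 0.2, 0.1 for cases 1-4).
#' @param combined_quantile EONR quantile for the combined (Phase I + II)
#'   reduction; default 0.3.
#' @param extrapolate Passed to [yield_loss()].
#' @return A `risk_report` data.frame, one row per case, with columns
#'   `site, case, from_rate, to_rate, n_reduction, n_reduction_pct,
#'   expected_loss, loss_q025, loss_q975, p_loss, reference_yield,
#'   relative_loss_pct`.
#' @export
run_phases <- function(draws, optima, case_quantiles = c(0.4, 0.3, 0.2, 0.1),
                       combined_quantile = 0.3, extrapolate = FALSE) {
  stopifnot(inherits(optima, "optima_dist"))
  if (is.null(optima$eonr)) stop("'optima' must contain EONR draws")
  e_aonr <- mean(optima$aonr)
  e_eonr <- mean(optima$eonr)
  qs <- draw_quantile(optima$eonr, case_quantiles)
  q_comb <- draw_quantile(optima$eonr, combined_quantile)
  rows <- list()
  add <- function(case, from, to, ref) {
    yl <- yield_loss(draws, from, to, reference_rate = ref,
                     extrapolate = extrapolate)
    cbind(data.frame(site = attr(draws, "site_id"), case = case), yl$report)
  }
  rows$phase1 <- add("phase1", e_aonr, e_eonr, e_aonr)
  for (k in seq_along(case_quantiles))
    rows[[paste0("case", k)]] <-
      add(paste0("case", k), e_eonr, min(qs[k], e_eonr), e_eonr)
  rows$combined <- add("combined", e_aonr, min(q_comb, e_eonr), e_aonr)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("risk_report", "data.frame")
  out
}

#' Select representative high / medium / low uncertainty sites
#'
#' Labels the retained site with the widest EONR 95% credible interval
#' "A" (high uncertainty), the one closest to the median width "B"
#' (medium), and the narrowest "C" (low). Ties are broken by lexical site
#' id order.
#'
#' @param widths Data.frame with columns `site` and `width` (EONR CrI
#'   width, kg ha^-1), e.g. the EONR rows of [summarize_optima()] tables.
#' @return Named character vector `c(A = ..., B = ..., C = ...)`.
#' @export
select_scenarios <- function(widths) {
  if (nrow(widths) < 3) stop("need >= 3 retained sites to pick scenarios")
  w <- widths[order(-widths$width, widths$site), ]
  a <- w$site[1]
  c_ <- w$site[nrow(w)]
  med <- stats::median(w$width)
  mid <- w[!(w$site %in% c(a, c_)), , drop = FALSE]
  mid <- mid[order(abs(mid$width - med), mid$site), ]
  c(A = a, B = mid$site[1], C = c_)
}
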