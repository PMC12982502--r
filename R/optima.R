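#' Price-ratio distribution from gamma parameters or moments
#'
#' The price ratio PR (kg of maize grain needed to pay for 1 kg of
#' fertilizer N) is modelled as gamma(shape, rate) with mean shape/rate and
#' variance shape/rate^2. `pr_from_moments()` moment-matches a mean and a
#' variance; `pr_dist()` takes the parameters directly.
#'
#' @param shape,rate Positive gamma parameters.
#' @param mean,variance Positive PR moments (kg/kg and (kg/kg)^2).
#' @return Object of class `pr_dist` (list with `shape`, `rate`).
#' @examples
#' pr_from_moments(5.34, 1.87)  # shape 15.25, rate 2.86
#' @export
pr_dist <- function(shape, rate) {
  if (shape <= 0 || rate <= 0) stop("'shape' and 'rate' must be positive")
  structure(list(shape = shape, rate = rate), class = "pr_dist")
}

#' @rdname pr_dist
#' @export
pr_from_moments <- function(mean, variance) {
  g <- gamma_from_moments(mean, variance)
  pr_dist(g$shape, g$rate)
}

#' Posterior distributions of the agronomic and economic optimum N rates
#'
#' Monte-Carlo transformation of the posterior draws: per draw,
#' AONR = beta1 / (2 * beta2) (the breakpoint, where the yield curve's
#' first derivative is zero) and EONR = (beta1 - PR) / (2 * beta2) (where
#' the derivative equals the price ratio). One independent PR value is
#' sampled per posterior draw (1:1 coupling, not nested). Draws whose
#' sampled PR exceeds beta1 would give a negative rate and are clamped to
#' EONR = 0.
#'
#' @param draws A `qp_draws` object from [fit_site()].
#' @param pr A [pr_dist()], a single non-negative number (fixed PR, for
#'   oracle checks and sensitivity analyses), or `NULL` to skip the EONR.
#' @param seed Seed for the PR samples.
#' @return Object of class `optima_dist`: data.frame with columns `chain`,
#'   `draw`, `aonr` and (when `pr` is given) `eonr`, `pr_sample`;
#'   attribute `site_id`.
#' @export
derive_optima <- function(draws, pr = NULL, seed = 1L) {
  stopifnot(inherits(draws, "qp_draws"))
  out <- data.frame(chain = draws$chain, draw = draws$draw,
                    aonr = draws$beta1 / (2 * draws$beta2))
  if (!is.null(pr)) {
    if (inherits(pr, "pr_dist")) {
      set.seed(seed)
      prs <- stats::rgamma(nrow(draws), shape = pr$shape, rate = pr$rate)
    } else if (is.numeric(pr) && length(pr) == 1 && pr >= 0) {
      prs <- rep(pr, nrow(draws))
    } else stop("'pr' must be a pr_dist or a single non-negative number")
    out$pr_sample <- prs
    out$eonr <- pmax((draws$beta1 - prs) / (2 * draws$beta2), 0)
  }
  structure(out, class = c("optima_dist", "data.frame"),
            site_id = attr(draws, "site_id"))
}

#' @rdname derive_optima
#' @export
derive_aonr <- function(draws) derive_optima(draws, pr = NULL)

#' @rdname derive_optima
#' @param ... Passed to [derive_optima()].
#' @export
derive_eonr <- function(draws, pr, ...) derive_optima(draws, pr = pr, ...)

#' Empirical quantile with the linear-interpolation convention
#'
#' Order statistics with linear interpolation at h = (n - 1) p + 1
#' (the "type 7" rule), fixed package-wide so summaries are
#' bit-reproducible.
#'
#' @param x Numeric draws.
#' @param p Probabilities in [0, 1].
#' @return Quantile values.
#' @export
draw_quantile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

#' Summarize optimum-rate posterior distributions
#'
#' @param optima An `optima_dist` from [derive_optima()] (>= 100 draws).
#' @param quantiles Extra quantiles to report besides 0.025 and 0.975
#'   (default 0.1, 0.2, 0.3, 0.4: the staged-reduction cases).
#' @return Data.frame with one row per available quantity (`AONR`,
#'   `EONR`): columns `site`, `quantity`, `mean`, `q025`, `q975`, `width`
#'   (the 95% credible interval width, q975 - q025), `relative_width`
#'   (width as % of the mean), and one `q*` column per extra quantile.
#' @export
summarize_optima <- function(optima, quantiles = c(0.1, 0.2, 0.3, 0.4)) {
  stopifnot(inherits(optima, "optima_dist"))
  if (nrow(optima) < 100)
    stop("summaries need >= 100 draws (got ", nrow(optima), ")")
  one <- function(v, label) {
    qs <- draw_quantile(v, c(0.025, 0.975, quantiles))
    row <- data.frame(site = attr(optima, "site_id"), quantity = label,
                      mean = mean(v), q025 = qs[1], q975 = qs[2],
                      width = qs[2] - qs[1],
                      relative_width = 100 * (qs[2] - qs[1]) / mean(v))
    extra <- as.data.frame(as.list(qs[-(1:2)]))
    names(extra) <- sprintf("q%03d", round(quantiles * 100))
    cbind(row, extra)
  }
  out <- one(optima$aonr, "AONR")
  if (!is.null(optima$eonr)) out <- rbind(out, one(optima$eonr, "EONR"))
  rownames(out) <- NULL
  out
}
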