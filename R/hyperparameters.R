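#' Gamma distribution from a mean and a variance
#'
#' Moment matching used throughout the package: a gamma(shape, rate)
#' distribution has mean shape/rate and variance shape/rate^2, so the
#' parameters reproducing a target mean m and variance v are
#' shape = m^2 / v and rate = m / v.
#'
#' @param mean,variance Positive numbers.
#' @return List with elements `shape` and `rate`.
#' @examples
#' gamma_from_moments(5.34, 1.87)  # shape 15.25, rate 2.86
#' @export
gamma_from_moments <- function(mean, variance) {
  if (!is.numeric(mean) || !is.numeric(variance) ||
      any(mean <= 0) || any(variance <= 0))
    stop("'mean' and 'variance' must be positive")
  list(shape = mean^2 / variance, rate = mean / variance)
}

#' Prior hyperparameters for the hierarchical quadratic-plateau yield model
#'
#' Gamma (shape, rate) priors for the intercept, slope, curvature and
#' residual SD, plus the upper bound of the flat prior on the block-effect
#' SD. Gamma priors keep all four parameters on their positive support; the
#' block SD gets a uniform(0, `sigma_b_bound`) prior.
#'
#' @param beta0,beta1,beta2,sigma_e Each a list/vector with elements
#'   `shape` and `rate` (both > 0), e.g. from [gamma_from_moments()].
#' @param sigma_b_bound Upper bound (kg ha^-1) of the flat block-SD prior;
#'   default 5000.
#' @return Object of class `qp_hyperparameters`.
#' @export
hyperparameters <- function(beta0, beta1, beta2, sigma_e,
                            sigma_b_bound = 5000) {
  chk <- function(p, nm) {
    p <- as.list(p)
    if (is.null(p$shape) || is.null(p$rate) || p$shape <= 0 || p$rate <= 0)
      stop("hyperparameters for '", nm, "' need positive shape and rate")
    list(shape = as.numeric(p$shape), rate = as.numeric(p$rate))
  }
  if (sigma_b_bound <= 0) stop("'sigma_b_bound' must be > 0")
  structure(list(beta0 = chk(beta0, "beta0"), beta1 = chk(beta1, "beta1"),
                 beta2 = chk(beta2, "beta2"), sigma_e = chk(sigma_e, "sigma_e"),
                 sigma_b_bound = sigma_b_bound),
            class = "qp_hyperparameters")
}

#' Default per-state hyperparameter table
#'
#' Ships a table of gamma priors per US Corn Belt state, elicited by fitting
#' the quadratic-plateau model with wide uniform priors to synthetic
#' reference trials whose agronomic optima span 108-291 kg ha^-1 (the range
#' observed across the region), then moment-matching each parameter's
#' posterior mean and variance to a gamma distribution (see
#' [elicit_hyperparameters()]). The generating script is shipped in
#' `data-raw/`.
#'
#' @param state Optional two-letter state code (e.g. `"IA"`); when given,
#'   returns that state's [hyperparameters()] object instead of the table.
#' @return A data.frame with columns `state, parameter, shape, rate,
#'   sigma_b_bound`, or a `qp_hyperparameters` object when `state` is given.
#' @export
default_hyperparameters <- function(state = NULL) {
  path <- system.file("extdata", "default_hyperparameters.csv",
                      package = "onrisk")
  tab <- utils::read.csv(path)
  if (is.null(state)) return(tab)
  hyperparameters_from_table(tab, state)
}

#' Build a `qp_hyperparameters` object from a long-format table
#'
#' @param tab Data.frame with columns `state, parameter, shape, rate,
#'   sigma_b_bound`; `parameter` spans beta0, beta1, beta2, sigma_e.
#' @param state State code present in `tab`.
#' @return A [hyperparameters()] object.
#' @export
hyperparameters_from_table <- function(tab, state) {
  sub <- tab[tab$state == state, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no hyperparameters for state '", state, "'")
  get <- function(p) {
    row <- sub[sub$parameter == p, , drop = FALSE]
    if (nrow(row) != 1) stop("expected one '", p, "' row for ", state)
    list(shape = row$shape, rate = row$rate)
  }
  hyperparameters(get("beta0"), get("beta1"), get("beta2"), get("sigma_e"),
                  sigma_b_bound = sub$sigma_b_bound[1])
}

#' Elicit per-state hyperparameters from reference trials
#'
#' Fits the quadratic-plateau yield model with wide uniform priors to each
#' reference site of a state, pools the posterior draws across that state's
#' sites, and converts each parameter's pooled posterior mean m and variance
#' v into gamma(shape = m^2/v, rate = m/v) priors for the state. States
#' whose reference fit fails convergence
#' (any split-Rhat above `rhat_max`) fall back to `fallback` and are listed
#' in the `flagged` attribute.
#'
#' @param reference A `trial_table` with a `state` column (or a named list
#'   of `trial_table`s, names = states).
#' @param spec A [model_spec()] controlling the reference MCMC (its
#'   hyperparameters slot is ignored; wide uniforms are used).
#' @param rhat_max Convergence threshold for the reference fits (1.05: these
#'   fits only set priors, not inference).
#' @param fallback `qp_hyperparameters` used for non-convergent states.
#' @return Data.frame in the [default_hyperparameters()] layout, with
#'   attribute `flagged` naming fallback states.
#' @export
elicit_hyperparameters <- function(reference, spec = model_spec(),
                                   rhat_max = 1.05, fallback = NULL) {
  if (is.data.frame(reference)) {
    if (is.null(reference$state)) stop("'reference' needs a 'state' column")
    reference <- split(reference, reference$state)
  }
  rows <- list(); flagged <- character(0)
  for (st in names(reference)) {
    sites <- split(reference[[st]], reference[[st]]$site_id)
    fit <- try({
      fits <- lapply(sites, fit_site, spec = spec, priors = "wide_uniform")
      conv_ok <- all(vapply(fits, function(f)
        all(gelman_rubin(f)$rhat <= rhat_max, na.rm = TRUE), logical(1)))
      if (!conv_ok) stop("reference fit did not converge")
      do.call(rbind, lapply(fits, as.data.frame))
    }, silent = TRUE)
    ok <- !inherits(fit, "try-error")
    if (!ok) {
      flagged <- c(flagged, st)
      if (is.null(fallback)) next
      h <- fallback
      rows[[st]] <- data.frame(
        state = st, parameter = c("beta0", "beta1", "beta2", "sigma_e"),
        shape = vapply(h[1:4], `[[`, 0, "shape"),
        rate = vapply(h[1:4], `[[`, 0, "rate"),
        sigma_b_bound = h$sigma_b_bound)
      next
    }
    draws <- fit
    par <- c("beta0", "beta1", "beta2", "sigma_e")
    g <- lapply(par, function(p)
      gamma_from_moments(mean(draws[[p]]), stats::var(draws[[p]])))
    rows[[st]] <- data.frame(
      state = st, parameter = par,
      shape = vapply(g, `[[`, 0, "shape"),
      rate = vapply(g, `[[`, 0, "rate"),
      sigma_b_bound = 5000)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}
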