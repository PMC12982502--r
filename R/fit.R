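#' MCMC and model specification for a site-level fit
#'
#' @param response `"yield"` or `"grain_n"`.
#' @param mean_form `"quadratic_plateau"` (quadratic up to the breakpoint
#'   beta1/(2*beta2), flat beyond) or `"quadratic"`.
#' @param hyperparameters A [hyperparameters()] object (yield model only;
#'   the grain-N model uses fixed wide uniform priors). When `NULL`, the
#'   shipped default for `state` is used at fit time.
#' @param state Two-letter state code used to look up shipped defaults when
#'   `hyperparameters` is `NULL`; default `"IA"`.
#' @param n_chains Number of parallel chains (>= 2, so convergence can be
#'   diagnosed). Default 4.
#' @param n_iter Total iterations per chain (default 60000).
#' @param n_warmup Warm-up (burn-in) iterations discarded per chain
#'   (default 30000; must be < `n_iter`).
#' @param thin Keep 1 draw in `thin` after warm-up (default 10;
#'   `n_iter - n_warmup` must be divisible by `thin`).
#' @param n_adapt Sampler adaptation iterations before warm-up.
#' @param seed Integer seed; per-chain RNG streams are derived from it.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(response = c("yield", "grain_n"),
                       mean_form = c("quadratic_plateau", "quadratic"),
                       hyperparameters = NULL, state = "IA",
                       n_chains = 4, n_iter = 60000, n_warmup = 30000,
                       thin = 10, n_adapt = 1000, seed = 1L) {
  response <- match.arg(response)
  mean_form <- match.arg(mean_form)
  if (n_chains < 2) stop("'n_chains' must be >= 2 (convergence diagnostics)")
  if (n_warmup >= n_iter) stop("'n_warmup' must be < 'n_iter'")
  if (thin < 1) stop("'thin' must be >= 1")
  if ((n_iter - n_warmup) %% thin != 0)
    stop("(n_iter - n_warmup) must be divisible by 'thin'")
  if (!is.null(hyperparameters) &&
      !inherits(hyperparameters, "qp_hyperparameters"))
    stop("'hyperparameters' must come from hyperparameters()")
  structure(list(response = response, mean_form = mean_form,
                 hyperparameters = hyperparameters, state = state,
                 n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup), thin = as.integer(thin),
                 n_adapt = as.integer(n_adapt), seed = as.integer(seed)),
            class = "model_spec")
}

#' Reduced-effort MCMC profile
#'
#' Convenience wrapper around [model_spec()] with settings sized for test
#' suites and simulation studies: `"fast"` runs 4 chains of 5000 iterations
#' (2500 warm-up, thin 5; 2000 retained draws), `"full"` reproduces the
#' reference settings (4 chains, 60000 iterations, 30000 warm-up, thin 10;
#' 12000 retained draws).
#'
#' @param profile `"fast"` or `"full"`.
#' @param ... Passed on to [model_spec()] (e.g. `response`, `seed`).
#' @return A `model_spec`.
#' @export
mcmc_profile <- function(profile = c("fast", "full"), ...) {
  profile <- match.arg(profile)
  if (profile == "fast")
    model_spec(n_iter = 5000, n_warmup = 2500, thin = 5, n_adapt = 500, ...)
  else
    model_spec(...)
}

# Build the JAGS model string. `priors` is a named list of strings, one per
# stochastic parameter; `mean_form` picks the plateau or plain quadratic arm.
qp_jags_model <- function(mean_form, priors) {
  arm <- if (mean_form == "quadratic_plateau") {
    "    mu[i] <- beta0 + tau[block[i]] +
      ifelse(x[i] < bp, beta1 * x[i] - beta2 * x[i]^2,
             beta1 * bp - beta2 * bp^2)"
  } else {
    "    mu[i] <- beta0 + tau[block[i]] + beta1 * x[i] - beta2 * x[i]^2"
  }
  bp <- if (mean_form == "quadratic_plateau")
    "  bp <- beta1 / (2 * beta2)" else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n", arm, "\n",
    "    y[i] ~ dnorm(mu[i], prec_e)\n",
    "  }\n", bp, "\n",
    "  ", priors$beta0, "\n  ", priors$beta1, "\n  ", priors$beta2, "\n",
    "  for (j in 1:J) { tau[j] ~ dnorm(0, prec_b) }\n",
    "  ", priors$sigma_b, "\n",
    "  prec_b <- 1 / (sigma_b^2 + 1.0E-12)\n",
    "  ", priors$sigma_e, "\n",
    "  prec_e <- 1 / (sigma_e^2 + 1.0E-12)\n",
    "}\n")
}

qp_priors <- function(kind, h = NULL) {
  switch(kind,
    gamma = list(
      beta0 = sprintf("beta0 ~ dgamma(%.10g, %.10g)",
                      h$beta0$shape, h$beta0$rate),
      beta1 = sprintf("beta1 ~ dgamma(%.10g, %.10g)",
                      h$beta1$shape, h$beta1$rate),
      beta2 = sprintf("beta2 ~ dgamma(%.10g, %.10g)",
                      h$beta2$shape, h$beta2$rate),
      sigma_b = sprintf("sigma_b ~ dunif(0, %.10g)", h$sigma_b_bound),
      sigma_e = sprintf("sigma_e ~ dgamma(%.10g, %.10g)",
                        h$sigma_e$shape, h$sigma_e$rate)),
    wide_uniform = list(
      beta0 = "beta0 ~ dunif(0, 30000)",
      beta1 = "beta1 ~ dunif(0, 300)",
      beta2 = "beta2 ~ dunif(1.0E-6, 2)",
      sigma_b = "sigma_b ~ dunif(0, 5000)",
      sigma_e = "sigma_e ~ dunif(0, 5000)"),
    grain_n = list(
      beta0 = "beta0 ~ dunif(0, 300)",
      beta1 = "beta1 ~ dunif(0, 5)",
      beta2 = "beta2 ~ dunif(1.0E-9, 2)",
      sigma_b = "sigma_b ~ dunif(0, 1000)",
      sigma_e = "sigma_e ~ dunif(0, 1000)"),
    stop("unknown prior kind '", kind, "'"))
}

# Upper support limits implied by each prior family, used to keep initial
# values inside the prior support.
qp_prior_limits <- function(kind, h = NULL) {
  switch(kind,
    gamma = c(beta0 = Inf, beta1 = Inf, beta2 = Inf,
              sigma_e = Inf, sigma_b = h$sigma_b_bound),
    wide_uniform = c(beta0 = 30000, beta1 = 300, beta2 = 2,
                     sigma_e = 5000, sigma_b = 5000),
    grain_n = c(beta0 = 300, beta1 = 5, beta2 = 2,
                sigma_e = 1000, sigma_b = 1000))
}

# Least-squares quadratic-plateau pre-fit by profiling the breakpoint:
# for a fixed breakpoint the mean is linear in (beta0, beta1, beta2) via
# the clipped regressors pmin(x, bp) and pmin(x, bp)^2, so a grid over
# candidate breakpoints plus lm() gives near-exact starting values.
qp_prefit <- function(y, x) {
  grid <- seq(min(x) + diff(range(x)) / 50, 1.5 * max(x), length.out = 60)
  best <- NULL; best_sse <- Inf
  for (bp in grid) {
    xc <- pmin(x, bp)
    cf <- try(stats::lm(y ~ xc + I(xc^2)), silent = TRUE)
    if (inherits(cf, "try-error")) next
    sse <- sum(stats::residuals(cf)^2)
    if (sse < best_sse) { best_sse <- sse; best <- stats::coef(cf) }
  }
  if (is.null(best) || !all(is.finite(best))) return(NULL)
  c(beta0 = max(best[[1]], 1e-3), beta1 = max(best[[2]], 1e-3),
    beta2 = max(-best[[3]], 1e-6), sse = best_sse)
}

# Data-informed starting values: the quadratic-plateau pre-fit centres the
# chains near the likelihood ridge (essential when residual noise is tiny
# and the posterior is sharply peaked); per-chain multiplicative jitter
# keeps the chains overdispersed enough for split-Rhat to mean something.
# Falls back to prior-generated inits when the response is all missing or
# the pre-fit fails.
qp_inits <- function(jd, limits, spec) {
  clip <- function(v, hi) min(max(v, 1e-8), if (is.finite(hi)) 0.95 * hi
                              else v)
  base <- NULL
  have <- is.finite(jd$y)
  if (sum(have) >= 4) {
    pf <- qp_prefit(jd$y[have], jd$x[have])
    if (!is.null(pf)) {
      se <- max(sqrt(pf[["sse"]] / sum(have)),
                1e-4 * stats::sd(jd$y[have]), 1e-6)
      base <- c(pf[c("beta0", "beta1", "beta2")], sigma_e = se)
    }
  }
  lapply(seq_len(spec$n_chains), function(k) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = derive_seed(spec$seed, k))
    if (!is.null(base)) {
      set.seed(derive_seed(spec$seed, 100 + k))
      jit <- exp(stats::rnorm(4, 0, 0.15))
      ini$beta0 <- clip(base[["beta0"]] * jit[1], limits[["beta0"]])
      ini$beta1 <- clip(base[["beta1"]] * jit[2], limits[["beta1"]])
      ini$beta2 <- clip(base[["beta2"]] * jit[3], limits[["beta2"]])
      ini$sigma_e <- clip(base[["sigma_e"]] * jit[4], limits[["sigma_e"]])
      ini$sigma_b <- clip(stats::runif(1, 1, 100), limits[["sigma_b"]])
    }
    ini
  })
}

check_one_site <- function(data, response) {
  if (!is.data.frame(data)) stop("'data' must be a trial table data.frame")
  needed <- c("site_id", "block_id", "n_rate", response)
  missing <- setdiff(needed, names(data))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  if (length(unique(data$site_id)) != 1)
    stop("fit expects data from exactly one site")
  if (length(unique(data$n_rate)) < 2)
    stop("fit failure: need >= 2 distinct N rates")
  if (length(unique(data$block_id)) < 2)
    stop("fit failure: need >= 2 blocks")
  y <- data[[response]]
  if (!all(is.na(y)) && stats::var(y, na.rm = TRUE) == 0)
    stop("fit failure: degenerate data (all responses equal); ",
         "site flagged non-convergent")
  invisible(TRUE)
}

run_jags <- function(data, response, mean_form, priors, spec, limits) {
  blocks <- sort(unique(data$block_id))
  jd <- list(y = as.numeric(data[[response]]),
             x = as.numeric(data$n_rate),
             block = match(data$block_id, blocks),
             N = nrow(data), J = length(blocks))
  model_str <- qp_jags_model(mean_form, priors)
  inits <- qp_inits(jd, limits, spec)
  mod <- rjags::jags.model(textConnection(model_str), data = jd,
                           inits = inits, n.chains = spec$n_chains,
                           n.adapt = spec$n_adapt, quiet = TRUE)
  if (spec$n_warmup > 0)
    stats::update(mod, spec$n_warmup, progress.bar = "none")
  monitors <- c("beta0", "beta1", "beta2", "sigma_b", "sigma_e", "tau")
  samp <- rjags::coda.samples(mod, monitors,
                              n.iter = spec$n_iter - spec$n_warmup,
                              thin = spec$thin, progress.bar = "none")
  new_qp_draws(samp, data, response, mean_form, spec)
}

new_qp_draws <- function(coda_list, data, response, mean_form, spec) {
  per_chain <- lapply(seq_along(coda_list), function(k) {
    m <- as.matrix(coda_list[[k]])
    colnames(m) <- sub("^tau\\[(\\d+)\\]$", "tau.\\1", colnames(m))
    df <- as.data.frame(m)
    df$chain <- k
    df$draw <- seq_len(nrow(df))
    df
  })
  df <- do.call(rbind, per_chain)
  front <- c("chain", "draw", "beta0", "beta1", "beta2", "sigma_b", "sigma_e")
  df <- df[, c(front, setdiff(names(df), front))]
  structure(df,
            class = c("qp_draws", "data.frame"),
            site_id = unique(data$site_id),
            response = response,
            mean_form = mean_form,
            rates = sort(unique(data$n_rate)),
            mcmc = spec[c("n_chains", "n_iter", "n_warmup", "thin", "seed")])
}

#' @export
print.qp_draws <- function(x, ...) {
  cat(sprintf("<qp_draws> site %s, response %s, form %s: %d draws (%d chains)\n",
              attr(x, "site_id"), attr(x, "response"), attr(x, "mean_form"),
              nrow(x), attr(x, "mcmc")$n_chains))
  invisible(x)
}

#' Fit the hierarchical Bayesian quadratic-plateau yield model to one site
#'
#' Likelihood: yield ~ Normal(mu, sigma_e) with
#' mu = beta0 + tau_block + beta1*x - beta2*x^2 below the draw's own
#' breakpoint beta1/(2*beta2) and constant at the plateau beyond it — the
#' breakpoint is re-evaluated for every MCMC draw, never fixed at a point
#' estimate. Priors: gamma on beta0, beta1, beta2 and sigma_e (per-state
#' elicited hyperparameters), Normal(0, sigma_b) block effects with
#' sigma_b ~ uniform(0, bound). Sampling is by Gibbs/slice MCMC (JAGS);
#' rows with missing response are treated as missing data, so a table of
#' all-NA responses returns draws from the prior.
#'
#' @param data One site's `trial_table` rows.
#' @param spec A [model_spec()]; its chain/iteration settings and
#'   hyperparameters are honoured.
#' @param priors Prior family: `"gamma"` (elicited, default for yield) or
#'   `"wide_uniform"` (used when eliciting hyperparameters from reference
#'   data).
#' @return A `qp_draws` data.frame: one row per retained draw (exactly
#'   `n_chains * (n_iter - n_warmup) / thin` rows) with columns `chain,
#'   draw, beta0, beta1, beta2, sigma_b, sigma_e, tau.1..tau.J`, plus
#'   attributes `site_id`, `response`, `mean_form`, `rates`, `mcmc`.
#' @export
fit_site <- function(data, spec = model_spec(),
                     priors = c("gamma", "wide_uniform")) {
  priors <- match.arg(priors)
  check_one_site(data, "yield")
  h <- spec$hyperparameters
  if (priors == "gamma" && is.null(h))
    h <- default_hyperparameters(spec$state)
  run_jags(data, "yield", spec$mean_form, qp_priors(priors, h), spec,
           qp_prior_limits(priors, h))
}

#' Fit the grain-N response model to one site
#'
#' Same hierarchical structure as [fit_site()] but for grain N content
#' (kg ha^-1) versus N rate, with fixed wide uniform priors:
#' beta0 ~ U(0, 300), beta1 ~ U(0, 5), beta2 ~ U(0, 2),
#' sigma_b ~ U(0, 1000), sigma_e ~ U(0, 1000). With `form = "auto"` the
#' quadratic-plateau form is fitted first; if the posterior-mean breakpoint
#' exceeds the highest tested rate (the plateau was never reached inside
#' the design) the site is refitted with the plain quadratic form.
#'
#' @param data One site's `trial_table` rows (needs a `grain_n` column).
#' @param spec A [model_spec()] (chain/iteration settings; priors fixed).
#' @param form `"auto"` (default), `"quadratic_plateau"` or `"quadratic"`.
#' @return A `qp_draws` object with `response = "grain_n"`.
#' @export
fit_grain_n <- function(data, spec = model_spec(response = "grain_n"),
                        form = c("auto", "quadratic_plateau", "quadratic")) {
  form <- match.arg(form)
  check_one_site(data, "grain_n")
  pr <- qp_priors("grain_n")
  lim <- qp_prior_limits("grain_n")
  if (form == "quadratic")
    return(run_jags(data, "grain_n", "quadratic", pr, spec, lim))
  fit <- run_jags(data, "grain_n", "quadratic_plateau", pr, spec, lim)
  if (form == "auto") {
    bp <- mean(fit$beta1 / (2 * fit$beta2))
    if (is.finite(bp) && bp > max(data$n_rate))
      fit <- run_jags(data, "grain_n", "quadratic", pr, spec, lim)
  }
  fit
}

#' Posterior distribution of the mean response at given N rates
#'
#' Evaluates each retained draw's population-level mean curve (block effect
#' tau marginalized at 0) at the requested rates; optionally adds one
#' residual draw per cell to emulate a new-observation predictive
#' distribution.
#'
#' @param draws A `qp_draws` object.
#' @param rates N rates (kg ha^-1) at which to predict.
#' @param include_residual Add Normal(0, sigma_e) noise per draw x rate
#'   (default `FALSE`: the population-level curve).
#' @param extrapolate Allow rates outside the tested range (default
#'   `FALSE`: out-of-range rates are an error).
#' @param seed Seed for the residual noise (only used when
#'   `include_residual = TRUE`).
#' @return Matrix with one row per draw and one column per rate
#'   (`dimnames` carry the rates).
#' @export
posterior_predictive <- function(draws, rates, include_residual = FALSE,
                                 extrapolate = FALSE, seed = 1L) {
  stopifnot(inherits(draws, "qp_draws"))
  tested <- attr(draws, "rates")
  if (!extrapolate &&
      (any(rates > max(tested) + 1e-9) || any(rates < min(tested) - 1e-9)))
    stop("rate(s) outside the tested range [", min(tested), ", ",
         max(tested), "]; set extrapolate = TRUE to override")
  form <- attr(draws, "mean_form")
  out <- vapply(rates, function(r) {
    if (form == "quadratic_plateau")
      qp_mean(r, draws$beta0, draws$beta1, draws$beta2)
    else
      draws$beta0 + draws$beta1 * r - draws$beta2 * r^2
  }, numeric(nrow(draws)))
  out <- matrix(out, nrow = nrow(draws),
                dimnames = list(NULL, format(rates, trim = TRUE)))
  if (include_residual) {
    set.seed(seed)
    out <- out + matrix(stats::rnorm(length(out), 0, rep(draws$sigma_e,
                                                         length(rates))),
                        nrow = nrow(draws))
  }
  out
}
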