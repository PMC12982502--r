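# Shared fixtures: hand-built posterior-draw objects and cached MCMC fits.

# Build a qp_draws object directly from parameter values, bypassing MCMC.
# Used to test derived-quantity code against hand-computable oracles.
make_draws <- function(beta0, beta1, beta2, sigma_b = 0, sigma_e = 0,
                       site = "S", rates = seq(0, 315, by = 45),
                       form = "quadratic_plateau", n_chains = 2) {
  n <- max(length(beta0), length(beta1), length(beta2))
  df <- data.frame(chain = rep_len(seq_len(n_chains), n),
                   draw = seq_len(n),
                   beta0 = rep_len(beta0, n), beta1 = rep_len(beta1, n),
                   beta2 = rep_len(beta2, n),
                   sigma_b = rep_len(sigma_b, n),
                   sigma_e = rep_len(sigma_e, n))
  structure(df, class = c("qp_draws", "data.frame"),
            site_id = site, response = "yield", mean_form = form,
            rates = rates,
            mcmc = list(n_chains = n_chains, n_iter = NA, n_warmup = NA,
                        thin = NA, seed = NA))
}

make_optima <- function(aonr, eonr = NULL, site = "S") {
  df <- data.frame(chain = 1L, draw = seq_along(aonr), aonr = aonr)
  if (!is.null(eonr)) df$eonr <- eonr
  structure(df, class = c("optima_dist", "data.frame"), site_id = site)
}

# Moderately informative gamma priors centred on a realistic maize site;
# used where tests need a well-mixing fit that is not tied to the shipped
# per-state defaults.
test_hyper <- function() {
  hyperparameters(
    beta0 = gamma_from_moments(9000, 800^2),
    beta1 = gamma_from_moments(60, 9^2),
    beta2 = gamma_from_moments(0.15, 0.03^2),
    sigma_e = gamma_from_moments(500, 75^2),
    sigma_b_bound = 600)
}

# One cached fit of scenario preset B so several test files can share it.
.fit_cache <- new.env(parent = emptyenv())
cached_fit_B <- function() {
  if (is.null(.fit_cache$B)) {
    tt <- simulate_site(scenario_presets()$B)
    spec <- model_spec(n_iter = 20000, n_warmup = 10000, thin = 10,
                       seed = 42L)
    .fit_cache$B <- fit_site(tt, spec)
  }
  .fit_cache$B
}
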