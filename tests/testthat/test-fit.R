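test_that("model specifications are validated", {
  expect_error(model_spec(n_chains = 1), "n_chains")
  expect_error(model_spec(n_iter = 100, n_warmup = 100), "n_warmup")
  expect_error(model_spec(thin = 0), "thin")
  expect_error(model_spec(n_iter = 103, n_warmup = 100, thin = 2),
               "divisible")
  fast <- mcmc_profile("fast")
  expect_equal(fast$n_iter, 5000L)
  expect_equal(mcmc_profile("full")$n_iter, 60000L)
})

test_that("retained-draw bookkeeping and support constraints hold", {
  tt <- simulate_site(site_config("bk", 9000, 60, 0.15, 300, 500, seed = 2))
  spec <- model_spec(n_chains = 3, n_iter = 1200, n_warmup = 400,
                     thin = 4, n_adapt = 200, seed = 5,
                     hyperparameters = test_hyper())
  fit <- fit_site(tt, spec)
  expect_equal(nrow(fit), 3 * (1200 - 400) / 4)
  expect_equal(as.integer(table(fit$chain)), rep(200L, 3))
  for (p in c("beta0", "beta1", "beta2", "sigma_e"))
    expect_true(all(fit[[p]] > 0))
  expect_true(all(fit$sigma_b >= 0 & fit$sigma_b <= 600))
  expect_true(all(paste0("tau.", 1:4) %in% names(fit)))
})

test_that("degenerate or malformed data is refused", {
  tt <- simulate_site(site_config("d", 9000, 60, 0.15, 300, 500, seed = 3))
  flat <- tt; flat$yield <- 8000
  expect_error(fit_site(flat), "degenerate")
  one_rate <- tt[tt$n_rate == 90, ]
  expect_error(fit_site(one_rate), "2 distinct N rates")
  one_block <- tt[tt$block_id == 1, ]
  expect_error(fit_site(one_block), "2 blocks")
  no_yield <- tt[, setdiff(names(tt), "yield")]
  expect_error(fit_site(no_yield), "yield")
  two_sites <- rbind(tt, transform(tt, site_id = "other"))
  expect_error(fit_site(two_sites), "one site")
})

test_that("noise-free data recovers the generating parameters within 1%", {
  cfg <- site_config("nf", 9000, 60, 0.15, sigma_b = 0, sigma_e = 0,
                     grain_n_sigma_b = 0, grain_n_sigma_e = 0, seed = 6)
  tt <- simulate_site(cfg)
  spec <- model_spec(n_iter = 20000, n_warmup = 10000, thin = 10, seed = 11L)
  fit <- fit_site(tt, spec, priors = "wide_uniform")
  # with sigma_e ~ 0 the intercept is identified only jointly with a common
  # shift of the free block effects, so test beta0 + mean(tau)
  b0 <- fit$beta0 + rowMeans(fit[, paste0("tau.", 1:4)])
  expect_equal(mean(b0), 9000, tolerance = 0.01)
  expect_equal(mean(fit$beta1), 60, tolerance = 0.01)
  expect_equal(mean(fit$beta2), 0.15, tolerance = 0.01)
  expect_lt(mean(fit$sigma_e), 50)
})

test_that("with no observed responses the posterior returns the prior", {
  tt <- simulate_site(site_config("pr", 9000, 60, 0.15, 300, 500, seed = 8))
  tt$yield <- NA_real_
  h <- test_hyper()
  spec <- model_spec(n_iter = 6000, n_warmup = 1000, thin = 5,
                     seed = 21, hyperparameters = h)
  fit <- fit_site(tt, spec)
  expect_equal(mean(fit$beta1), h$beta1$shape / h$beta1$rate,
               tolerance = 0.05)
  expect_equal(mean(fit$beta2), h$beta2$shape / h$beta2$rate,
               tolerance = 0.05)
  expect_equal(mean(fit$sigma_b), 300, tolerance = 0.1)  # U(0, 600) mean
})

test_that("noise-free grain-N surface is recovered and the plateau form kept", {
  cfg <- site_config("gn", 9000, 60, 0.15, 0, 0,
                     grain_n_params = c(60, 0.5, 0.001),
                     grain_n_sigma_b = 0, grain_n_sigma_e = 0, seed = 13)
  tt <- simulate_site(cfg)
  spec <- model_spec(response = "grain_n", n_iter = 20000, n_warmup = 10000,
                     thin = 10, seed = 14L)
  fit <- fit_grain_n(tt, spec)
  # breakpoint 250 lies inside the tested range, so the plateau form stays
  expect_equal(attr(fit, "mean_form"), "quadratic_plateau")
  g0 <- fit$beta0 + rowMeans(fit[, paste0("tau.", 1:4)])
  expect_equal(mean(g0), 60, tolerance = 0.01)
  expect_equal(mean(fit$beta1), 0.5, tolerance = 0.01)
  expect_equal(mean(fit$beta2), 0.001, tolerance = 0.015)
})

test_that("a linear grain-N response selects the quadratic form", {
  # plateau far beyond the design: grain N keeps rising over 0..315
  cfg <- site_config("lin", 9000, 60, 0.15, 0, 0,
                     grain_n_params = c(60, 0.4, 0.0004),
                     grain_n_sigma_b = 2, grain_n_sigma_e = 4, seed = 15)
  tt <- simulate_site(cfg)
  spec <- mcmc_profile("fast", response = "grain_n", seed = 16L)
  fit <- fit_grain_n(tt, spec)
  expect_equal(attr(fit, "mean_form"), "quadratic")
  pp <- posterior_predictive(fit, seq(0, 315, by = 45))
  expect_true(all(diff(colMeans(pp)) > 0))
})

test_that("posterior predictions follow the piecewise-mean oracle", {
  fit <- cached_fit_B()
  pp0 <- posterior_predictive(fit, 0)
  expect_equal(unname(pp0[, 1]), fit$beta0)
  # far above every draw's breakpoint the prediction is the plateau
  pp_hi <- posterior_predictive(fit, 315)
  bp <- fit$beta1 / (2 * fit$beta2)
  plateau <- fit$beta0 + fit$beta1^2 / (4 * fit$beta2)
  idx <- bp < 315
  expect_equal(unname(pp_hi[idx, 1]), plateau[idx])
  # oracle check on a handful of draws at an interior rate
  pp_mid <- posterior_predictive(fit, 150)
  for (d in c(1, 50, 500)) {
    expect_equal(unname(pp_mid[d, 1]),
                 qp_mean(150, fit$beta0[d], fit$beta1[d], fit$beta2[d]))
  }
})

test_that("extrapolation is refused unless enabled, and residual noise widens intervals", {
  fit <- cached_fit_B()
  expect_error(posterior_predictive(fit, 400), "extrapolate")
  expect_silent(posterior_predictive(fit, 400, extrapolate = TRUE))
  width <- function(m) diff(draw_quantile(m[, 1], c(0.025, 0.975)))
  pp <- posterior_predictive(fit, 150)
  ppn <- posterior_predictive(fit, 150, include_residual = TRUE, seed = 3)
  expect_lt(width(pp), width(ppn))
})
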