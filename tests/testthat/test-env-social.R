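test_that("nitrogen balance is plain subtraction, negatives allowed", {
  expect_equal(n_balance(180, 120), 60)
  expect_equal(n_balance(0, 40), -40)
  expect_equal(n_balance(c(100, 200), c(90, 150)), c(10, 50))
})

test_that("emission expectations match the closed forms", {
  em0 <- expected_emissions(0)
  expect_equal(em0$n2o_n, exp(0.339))
  expect_equal(em0$no3_n, exp(2.459))
  expect_equal(expected_emissions(100)$n2o_n, exp(0.809))
  expect_equal(expected_emissions(100)$n2o_n, 2.2456, tolerance = 1e-4)
  # strictly monotone in the balance
  b <- seq(-50, 250, by = 10)
  expect_true(all(diff(expected_emissions(b)$n2o_n) > 0))
  expect_true(all(diff(expected_emissions(b)$no3_n) > 0))
})

test_that("gamma propagation preserves the expectation", {
  draws <- gamma_propagate(rep(2, 1e5), variance = 1, seed = 31)
  # gamma(4, 2): mean 2, sd 1; MC standard error 1/sqrt(1e5)
  expect_equal(mean(draws), 2, tolerance = 3 / sqrt(1e5) / 2)
  expect_equal(var(draws), 1, tolerance = 0.05)
  # vanishing variance degenerates to the expectation
  tight <- gamma_propagate(c(1.5, 2.5), variance = 1e-8, seed = 5)
  expect_equal(tight, c(1.5, 2.5), tolerance = 1e-3)
  expect_error(gamma_propagate(2, variance = 0), "positive")
  expect_error(gamma_propagate(-1, variance = 1), "positive")
})

test_that("propagated differences agree with plug-in expectations", {
  set.seed(71)
  bal_hi <- rnorm(4000, 80, 10)
  bal_lo <- bal_hi - 25
  e_hi <- expected_emissions(bal_hi)$no3_n
  e_lo <- expected_emissions(bal_lo)$no3_n
  d <- gamma_propagate(e_hi, 36, seed = 1) - gamma_propagate(e_lo, 36, seed = 2)
  mc_se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - mean(e_hi - e_lo)), 3 * mc_se)
})

test_that("fertilizer-manufacture CO2 uses the ammonia mass conversion", {
  expect_equal(fert_co2(22), 22 * 17 / 14 * 2.16)
  expect_equal(round(fert_co2(22)), 58)
  expect_equal(round(fert_co2(14)), 37)
  expect_equal(fert_co2(0), 0)
  expect_error(fert_co2(-1), "non-negative")
})

test_that("social benefit matches hand arithmetic and is price-linear", {
  expect_equal(social_benefit(0, 0, 1), 18.54)
  expect_equal(social_benefit(0, 0, 0), 0)
  hand <- (0.1 * 44 / 28 * 265 + 50) / 1000 * 50 + 18.54
  expect_equal(social_benefit(0.1, 50, 1), hand)
  expect_equal(hand, 23.12, tolerance = 0.005)
  # additive in its three terms
  expect_equal(social_benefit(0.1, 50, 1),
               social_benefit(0.1, 0, 0) + social_benefit(0, 50, 0) +
                 social_benefit(0, 0, 1))
  # linear in each price
  p2 <- social_prices(p_ghg = 100, p_leaching = 18.54)
  expect_equal(social_benefit(0.1, 50, 0, p2),
               2 * social_benefit(0.1, 50, 0))
  # doubling the GWP factor scales only the N2O term
  pg <- emission_params(gwp_n2o = 530)
  expect_equal(social_benefit(0.1, 0, 1, params = pg) - 18.54,
               2 * (social_benefit(0.1, 0, 1) - 18.54))
})

test_that("regional scaling multiplies areas and flags missing states", {
  areas <- data.frame(state = c("IA", "IL"), hectares = c(1e6, 2e6))
  sc <- scale_to_region(10, areas)
  expect_equal(sc$total, 30e6)
  expect_equal(sc$by_state$total, c(10e6, 20e6))
  # perfect correlation: SE scales with the summed area
  sc2 <- scale_to_region(10, areas, se_per_ha = 2)
  expect_equal(sc2$total_se, 2 * 3e6)
  expect_error(scale_to_region(10, areas, states = c("IA", "KS", "WI")),
               "KS.*WI")
  ship <- default_areas()
  expect_setequal(ship$state,
                  c("IA", "IL", "IN", "MN", "MO", "ND", "NE", "WI"))
  expect_true(all(ship$hectares > 0))
})

test_that("the per-scenario report composes balance, emissions and prices", {
  gd <- make_draws(beta0 = rep(c(60, 65), 100), beta1 = 0.5, beta2 = 0.001,
                   site = "G")
  attr(gd, "response") <- "grain_n"
  params <- emission_params(var_n2o = 0.5, var_no3 = 20)
  rep <- env_social_report(gd, rate_high = 200, rate_low = 170,
                           params = params, seed = 7)
  # plug-in oracle recomputed by hand
  gn <- posterior_predictive(gd, c(200, 170))
  em_hi <- expected_emissions(200 - gn[, 1], params)
  em_lo <- expected_emissions(170 - gn[, 2], params)
  expect_equal(rep$d_n2o_pct,
               100 * mean(em_hi$n2o_n - em_lo$n2o_n) / mean(em_hi$n2o_n))
  expect_equal(rep$d_fert_co2, fert_co2(30))
  # propagated means stay near the plug-in differences
  expect_equal(rep$d_no3_n, mean(em_hi$no3_n - em_lo$no3_n),
               tolerance = 3 * rep$d_no3_n_sd / sqrt(nrow(gd)) /
                 abs(mean(em_hi$no3_n - em_lo$no3_n)))
  # a rate cut on a concave-below-plateau response reduces emissions less,
  # in percent, than the rate itself
  expect_lt(rep$d_n2o_pct, 100 * 30 / 200)
  expect_gt(rep$d_n2o_pct, 0)
})

test_that("placeholder emission variances warn once per report", {
  gd <- make_draws(beta0 = 60, beta1 = 0.5, beta2 = 0.001)
  attr(gd, "response") <- "grain_n"
  expect_warning(env_social_report(gd, 200, 170, seed = 2), "placeholder")
  expect_silent(env_social_report(gd, 200, 170, seed = 2,
                                  params = emission_params(var_n2o = 1,
                                                           var_no3 = 36)))
})
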