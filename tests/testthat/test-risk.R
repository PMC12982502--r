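test_that("hand-enumerated loss draws are summarized correctly", {
  rep <- summarize_loss(c(-1, 2, 3, -2), reference_yield = 100)
  expect_equal(rep$expected_loss, 0.5)
  expect_equal(rep$p_loss, 0.5)
  expect_equal(rep$relative_loss_pct, 0.5)
  expect_equal(rep$loss_q025, draw_quantile(c(-1, 2, 3, -2), 0.025))
  # ties at exactly zero count as non-loss
  expect_equal(summarize_loss(c(0, 0, 1, -1))$p_loss, 0.25)
})

test_that("probability of loss and of gain are complementary", {
  set.seed(19)
  loss <- rnorm(2000, 0.2)  # continuous: no exact zeros
  rep <- summarize_loss(loss)
  expect_equal(rep$p_loss + mean(loss <= 0), 1)
})

test_that("the site filter applies both exclusion rules with reasons", {
  mk <- function(rhat, e_aonr) list(
    convergence = data.frame(quantity = c("beta1", "aonr"),
                             rhat = c(1.0, rhat), ess = c(500, 500)),
    optima = make_optima(rep(e_aonr, 200)))
  sites <- list(good = mk(1.00, 200), bad_conv = mk(1.05, 200),
                bad_extrap = mk(1.01, 330), bad_both = mk(1.2, 400))
  flt <- filter_sites(sites, site_filter_rule(max_tested_rate = 315))
  expect_equal(flt$retained, "good")
  expect_setequal(flt$excluded$site, c("bad_conv", "bad_extrap", "bad_both"))
  expect_match(flt$excluded$reason[flt$excluded$site == "bad_conv"],
               "Gelman-Rubin")
  expect_match(flt$excluded$reason[flt$excluded$site == "bad_extrap"],
               "plateau beyond tested range")
  expect_match(flt$excluded$reason[flt$excluded$site == "bad_both"],
               "Gelman-Rubin.*plateau")
})

test_that("yield loss between two rates follows the per-draw mean curves", {
  d <- make_draws(beta0 = c(9000, 9500, 8800, 9200),
                  beta1 = c(60, 50, 70, 55),
                  beta2 = c(0.15, 0.20, 0.25, 0.14))
  yl <- yield_loss(d, rate_high = 180, rate_low = 120)
  oracle <- qp_mean(180, d$beta0, d$beta1, d$beta2) -
    qp_mean(120, d$beta0, d$beta1, d$beta2)
  expect_equal(yl$loss, unname(oracle))
  expect_equal(yl$report$expected_loss, mean(oracle))
  expect_equal(yl$report$p_loss, mean(oracle > 0))
  expect_equal(yl$report$reference_yield,
               mean(qp_mean(180, d$beta0, d$beta1, d$beta2)))
  # identity reduction: nothing lost
  yl0 <- yield_loss(d, 150, 150)
  expect_true(all(yl0$loss == 0))
  expect_equal(yl0$report$p_loss, 0)
  expect_error(yield_loss(d, 120, 180), "rate_low")
})

test_that("loss reports are invariant to draw order", {
  set.seed(23)
  d <- make_draws(beta0 = runif(50, 8000, 10000),
                  beta1 = runif(50, 40, 80),
                  beta2 = runif(50, 0.1, 0.3))
  perm <- sample(50)
  dp <- make_draws(d$beta0[perm], d$beta1[perm], d$beta2[perm])
  expect_equal(yield_loss(d, 200, 150)$report,
               yield_loss(dp, 200, 150)$report)
})

test_that("staged reductions: ordering, telescoping, and risk monotonicity", {
  fit <- cached_fit_B()
  opt <- derive_optima(fit, pr_from_moments(5.34, 1.87), seed = 4)
  rr <- run_phases(fit, opt)
  expect_s3_class(rr, "risk_report")
  expect_setequal(rr$case, c("phase1", paste0("case", 1:4), "combined"))
  cases <- rr[grep("^case", rr$case), ]
  # case target rates strictly decrease from case1 to case4
  expect_true(all(diff(cases$to_rate) < 0))
  # risk grows with the depth of the cut
  expect_true(all(diff(cases$expected_loss) >= 0))
  expect_true(all(diff(cases$p_loss) >= -1e-12))
  # combined reduction telescopes exactly: phase1 + case2 (quantile 0.3)
  expect_equal(rr$n_reduction[rr$case == "combined"],
               rr$n_reduction[rr$case == "phase1"] +
                 rr$n_reduction[rr$case == "case2"])
  # and is at least as costly as phase1 alone
  expect_gte(rr$expected_loss[rr$case == "combined"],
             rr$expected_loss[rr$case == "phase1"])
  # reference conventions: phase1/combined vs E[AONR], cases vs E[EONR]
  pp <- posterior_predictive(fit, c(mean(opt$aonr), mean(opt$eonr)))
  expect_equal(rr$reference_yield[rr$case == "phase1"], mean(pp[, 1]))
  expect_equal(rr$reference_yield[rr$case == "case3"], mean(pp[, 2]))
})

test_that("scenario selection picks max, median and min EONR width", {
  w <- data.frame(site = c("s1", "s2", "s3", "s4", "s5"),
                  width = c(40, 90, 55, 120, 70))
  sel <- select_scenarios(w)
  expect_equal(unname(sel["A"]), "s4")
  expect_equal(unname(sel["C"]), "s1")
  expect_equal(unname(sel["B"]), "s5")  # width 70 = median
  # ties broken lexically
  tie <- data.frame(site = c("b", "a", "c"), width = c(50, 50, 50))
  expect_equal(unname(select_scenarios(tie)), c("a", "b", "c"))
  expect_error(select_scenarios(w[1:2, ]), "3 retained sites")
})
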