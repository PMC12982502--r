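#' Pipeline run configuration
#'
#' Bundles every input of the end-to-end analysis. File-path arguments are
#' read with the package CSV readers; in-memory objects are used as given.
#'
#' @param trials A `trial_table` or path to its CSV.
#' @param out_dir Output directory (created if absent).
#' @param mcmc A [model_spec()] or profile name for [mcmc_profile()].
#' @param hyperparameters Long-format hyperparameter table (or CSV path);
#'   `NULL` uses the shipped per-state defaults.
#' @param pr A [pr_dist()]; default the moment-matched gamma for a price
#'   ratio with mean 5.34 and variance 1.87 kg/kg.
#' @param target_quantile EONR quantile of the combined reduction, in
#'   (0, 0.5]; default 0.3.
#' @param filter_rule A [site_filter_rule()].
#' @param params An [emission_params()].
#' @param prices A [social_prices()].
#' @param areas Planted-area table (or CSV path); `NULL` uses
#'   [default_areas()].
#' @param seed Master seed; every site fit, PR sample and propagation seed
#'   derives from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(trials, out_dir = "onrisk-run",
                       mcmc = "fast", hyperparameters = NULL,
                       pr = pr_from_moments(5.34, 1.87),
                       target_quantile = 0.3,
                       filter_rule = site_filter_rule(),
                       params = emission_params(),
                       prices = social_prices(),
                       areas = NULL, seed = 1L) {
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.character(hyperparameters))
    hyperparameters <- utils::read.csv(hyperparameters)
  if (is.character(areas)) areas <- utils::read.csv(areas)
  if (is.character(mcmc)) mcmc <- mcmc_profile(mcmc)
  if (!(target_quantile > 0 && target_quantile <= 0.5))
    stop("'target_quantile' must lie in (0, 0.5]")
  structure(list(trials = trials, out_dir = out_dir, mcmc = mcmc,
                 hyperparameters = hyperparameters, pr = pr,
                 target_quantile = target_quantile,
                 filter_rule = filter_rule, params = params,
                 prices = prices, areas = areas, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full uncertainty-aware N-reduction pipeline
#'
#' Step 1: fit the Bayesian quadratic-plateau yield model per site and
#' derive AONR/EONR posterior distributions. Step 2: filter unreliable
#' sites, quantify yield-loss risk for the staged reductions, and select
#' high/medium/low-uncertainty scenario sites. Step 3: fit the grain-N
#' model for the scenario sites and translate rate reductions into N2O,
#' nitrate and manufacture-CO2 reductions. Step 4: monetize and scale to
#' the regional planted area. Writes all tables (CSV), the convergence and
#' regional summaries (JSON), and a reproducibility manifest to
#' `config$out_dir`, and returns them invisibly.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return (Invisibly) a list: `optima_summary`, `convergence`, `filter`,
#'   `risk_report`, `scenarios`, `env_social`, `region`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sites <- split(config$trials, config$trials$site_id)
  say("Step 1: fitting %d site(s)", length(sites))

  per_site <- list()
  for (i in seq_along(sites)) {
    id <- names(sites)[i]
    dat <- sites[[i]]
    spec <- config$mcmc
    spec$seed <- derive_seed(config$seed, i)
    if (!is.null(config$hyperparameters) && !is.null(dat$state))
      spec$hyperparameters <-
        hyperparameters_from_table(config$hyperparameters, dat$state[1])
    fit <- fit_site(dat, spec)
    opt <- derive_optima(fit, config$pr, seed = derive_seed(config$seed,
                                                            1000 + i))
    conv <- gelman_rubin(fit, opt, rhat_max = config$filter_rule$rhat_high)
    per_site[[id]] <- list(data = dat, fit = fit, optima = opt,
                           convergence = conv,
                           summary = summarize_optima(opt))
    utils::write.csv(as.data.frame(fit),
                     file.path(config$out_dir, paste0("draws_", id, ".csv")),
                     row.names = FALSE)
    say("  site %s: %d draws, max Rhat %.3f", id, nrow(fit),
        max(conv$rhat))
  }

  conv_all <- do.call(rbind, lapply(names(per_site), function(id)
    cbind(site = id, per_site[[id]]$convergence)))
  flt <- filter_sites(per_site, config$filter_rule)
  say("Step 2: %d/%d site(s) retained", length(flt$retained),
      length(per_site))

  risk <- NULL; scen <- NULL; env <- NULL; region <- NULL
  if (length(flt$retained)) {
    risk <- do.call(rbind, lapply(flt$retained, function(id)
      run_phases(per_site[[id]]$fit, per_site[[id]]$optima,
                 combined_quantile = config$target_quantile)))
    widths <- do.call(rbind, lapply(flt$retained, function(id) {
      s <- per_site[[id]]$summary
      data.frame(site = id, width = s$width[s$quantity == "EONR"])
    }))
    scen_sites <- if (nrow(widths) >= 3) select_scenarios(widths)
                  else stats::setNames(widths$site,
                                       LETTERS[seq_len(nrow(widths))])
    scen <- data.frame(scenario = names(scen_sites), site = scen_sites,
                       row.names = NULL)

    say("Step 3/4: environmental and social benefit for %d scenario(s)",
        nrow(scen))
    env_rows <- list()
    for (k in seq_len(nrow(scen))) {
      id <- scen$site[k]
      ps <- per_site[[id]]
      gspec <- config$mcmc
      gspec$response <- "grain_n"
      gspec$seed <- derive_seed(config$seed, 2000 + k)
      gfit <- fit_grain_n(ps$data, gspec)
      e_aonr <- mean(ps$optima$aonr)
      e_eonr <- mean(ps$optima$eonr)
      q_t <- draw_quantile(ps$optima$eonr, config$target_quantile)
      phases <- list(phase1 = c(e_aonr, e_eonr),
                     phase2 = c(e_eonr, min(q_t, e_eonr)),
                     total = c(e_aonr, min(q_t, e_eonr)))
      for (ph in names(phases)) {
        r <- env_social_report(gfit, phases[[ph]][1], phases[[ph]][2],
                               config$params, config$prices,
                               seed = derive_seed(config$seed, 3000 + k))
        env_rows[[paste(id, ph)]] <-
          cbind(data.frame(scenario = scen$scenario[k], phase = ph), r)
      }
    }
    env <- do.call(rbind, env_rows)
    rownames(env) <- NULL
    tot <- env[env$phase == "total", , drop = FALSE]
    region <- lapply(seq_len(nrow(tot)), function(k) {
      sc <- scale_to_region(tot$sb_per_ha[k], areas = if (is.null(config$areas))
        default_areas() else config$areas, se_per_ha = tot$sb_per_ha_sd[k])
      list(scenario = tot$scenario[k], site = tot$site[k],
           sb_total_usd = sc$total, sb_total_se_usd = sc$total_se)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("onrisk")),
    seed = config$seed,
    mcmc = config$mcmc[c("n_chains", "n_iter", "n_warmup", "thin")],
    target_quantile = config$target_quantile,
    n_sites = length(per_site), retained = flt$retained,
    timestamp = format(Sys.time(), tz = "UTC"))

  wcsv <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(config$out_dir, f), row.names = FALSE)
  optima_summary <- do.call(rbind, lapply(per_site, `[[`, "summary"))
  rownames(optima_summary) <- NULL
  wcsv(optima_summary, "optima_summary.csv")
  wcsv(conv_all, "convergence.csv")
  wcsv(flt$excluded, "excluded_sites.csv")
  wcsv(risk, "risk_report.csv")
  wcsv(scen, "scenarios.csv")
  wcsv(env, "env_social.csv")
  jsonlite::write_json(list(region = region, manifest = manifest),
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(per_site = per_site, optima_summary = optima_summary,
                 convergence = conv_all, filter = flt, risk_report = risk,
                 scenarios = scen, env_social = env, region = region,
                 manifest = manifest))
}
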