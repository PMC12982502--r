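#' Configuration for one simulated N-rate trial site
#'
#' Describes the generative model of a single site-year: a quadratic-plateau
#' grain-yield surface with additive block effects and Gaussian residuals,
#' plus a grain-N response surface, laid out as a randomized complete block
#' design (RCBD; every N rate appears once in every block).
#'
#' @param site_id Character site label.
#' @param beta0 Yield at zero N, kg ha^-1.
#' @param beta1 Linear yield response, kg yield per kg N.
#' @param beta2 Quadratic curvature, kg yield per (kg N)^2; must be > 0.
#' @param sigma_b Block-effect SD, kg ha^-1 (>= 0).
#' @param sigma_e Residual SD of yield, kg ha^-1 (>= 0).
#' @param rates Numeric vector of N rates, kg ha^-1 (all >= 0). Default is
#'   the 8-rate design 0 to 315 in steps of 45.
#' @param n_blocks Number of complete blocks (>= 2); default 4.
#' @param grain_n_params Length-3 numeric `(g0, g1, g2)`: intercept, slope
#'   and curvature of the grain-N surface (kg N ha^-1 scale).
#' @param grain_n_form `"quadratic_plateau"` (default) or `"quadratic"`.
#' @param grain_n_sigma_b,grain_n_sigma_e Block and residual SDs of the
#'   grain-N surface, kg ha^-1.
#' @param seed Integer seed making [simulate_site()] deterministic.
#' @return An object of class `site_config` (a validated list).
#' @export
site_config <- function(site_id, beta0, beta1, beta2, sigma_b, sigma_e,
                        rates = seq(0, 315, by = 45), n_blocks = 4,
                        grain_n_params = c(45, 0.52, 0.0013),
                        grain_n_form = c("quadratic_plateau", "quadratic"),
                        grain_n_sigma_b = 4, grain_n_sigma_e = 8,
                        seed = 1L) {
  grain_n_form <- match.arg(grain_n_form)
  if (length(rates) == 0) stop("invalid config: 'rates' must be non-empty")
  if (!is.numeric(beta2) || beta2 <= 0)
    stop("invalid config: 'beta2' must be > 0")
  if (any(rates < 0)) stop("invalid config: all rates must be >= 0")
  if (n_blocks < 2) stop("invalid config: 'n_blocks' must be >= 2")
  if (sigma_b < 0 || sigma_e < 0)
    stop("invalid config: SDs must be non-negative")
  if (length(grain_n_params) != 3)
    stop("invalid config: 'grain_n_params' must be (g0, g1, g2)")
  structure(
    list(site_id = as.character(site_id), beta0 = beta0, beta1 = beta1,
         beta2 = beta2, sigma_b = sigma_b, sigma_e = sigma_e,
         rates = as.numeric(rates), n_blocks = as.integer(n_blocks),
         grain_n_params = as.numeric(grain_n_params),
         grain_n_form = grain_n_form,
         grain_n_sigma_b = grain_n_sigma_b,
         grain_n_sigma_e = grain_n_sigma_e,
         seed = as.integer(seed)),
    class = "site_config")
}

grain_n_mean <- function(x, g, form) {
  if (form == "quadratic_plateau" && g[3] > 0) {
    qp_mean(x, g[1], g[2], g[3])
  } else {
    g[1] + g[2] * x - g[3] * x^2
  }
}

#' Simulate one RCBD nitrogen-rate trial
#'
#' Draws one complete trial from the generative model in `config`: for block
#' j, yield at rate x is `qp_mean(x) + tau_j + e` with
#' `tau_j ~ N(0, sigma_b)` and `e ~ N(0, sigma_e)`; grain N comes from its
#' own surface with its own block effects and residuals, truncated below at
#' zero and (elementwise) below the simulated yield, since grain N is a small
#' fraction of grain mass.
#'
#' @param config A [site_config()].
#' @return A `data.frame` (class `trial_table`) with columns `site_id`,
#'   `block_id`, `n_rate`, `yield`, `grain_n`; one row per (block, rate),
#'   i.e. `n_blocks * length(rates)` rows.
#' @examples
#' tt <- simulate_site(site_config("demo", 9000, 60, 0.15, 300, 500))
#' nrow(tt)  # 32 for the default 8 rates x 4 blocks
#' @export
simulate_site <- function(config) {
  if (!inherits(config, "site_config")) stop("'config' must be a site_config")
  set.seed(config$seed)
  rates <- config$rates
  J <- config$n_blocks
  tau_y <- stats::rnorm(J, 0, config$sigma_b)
  tau_g <- stats::rnorm(J, 0, config$grain_n_sigma_b)
  grid <- expand.grid(n_rate = rates, block_id = seq_len(J),
                      KEEP.OUT.ATTRS = FALSE)
  mu_y <- qp_mean(grid$n_rate, config$beta0, config$beta1, config$beta2)
  yield <- mu_y + tau_y[grid$block_id] +
    stats::rnorm(nrow(grid), 0, config$sigma_e)
  yield <- pmax(yield, 0)
  mu_g <- grain_n_mean(grid$n_rate, config$grain_n_params, config$grain_n_form)
  grain_n <- mu_g + tau_g[grid$block_id] +
    stats::rnorm(nrow(grid), 0, config$grain_n_sigma_e)
  grain_n <- pmax(grain_n, 0)
  grain_n <- pmin(grain_n, pmax(yield - 1e-9, 0))
  out <- data.frame(site_id = config$site_id,
                    block_id = grid$block_id,
                    n_rate = grid$n_rate,
                    yield = yield,
                    grain_n = grain_n)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Simulate a batch of sites with per-site seed streams
#'
#' A master seed is split deterministically into one stream per site, so a
#' multi-site batch is reproducible as a whole and each site individually.
#'
#' @param configs List of [site_config()] objects.
#' @param master_seed Integer; overrides each config's own seed with
#'   `derive_seed(master_seed, i)`.
#' @return A single stacked `trial_table`.
#' @export
simulate_trials <- function(configs, master_seed = NULL) {
  stopifnot(length(configs) >= 1)
  tabs <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    if (!is.null(master_seed)) cfg$seed <- derive_seed(master_seed, i)
    simulate_site(cfg)
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash keeping results in 32-bit range.
#' @param master_seed,index Integers.
#' @return Integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 48271 + index * 16807) %% 2147483646L)
}

#' Preset site configurations spanning low to high optimum-rate uncertainty
#'
#' Three named configurations ("A" high, "B" medium, "C" low uncertainty)
#' emulating contrasting maize yield responses on the standard 8-rate,
#' 4-block design. Curvatures and slopes are set so the agronomic optima
#' fall near 254, 205 and 174 kg ha^-1 and the Phase I reduction (mean price
#' ratio / (2 * beta2)) near 22, 19 and 14 kg ha^-1; residual noise
#' decreases from A to C so posterior credible intervals of the optima
#' shrink in the same order.
#'
#' @param seed Master seed stamped into the presets (per-site streams via
#'   [derive_seed()]).
#' @return Named list of three [site_config()] objects (`A`, `B`, `C`).
#' @export
scenario_presets <- function(seed = 20260925L) {
  mk <- function(id, b0, b1, b2, sb, se, g, i)
    site_config(id, b0, b1, b2, sigma_b = sb, sigma_e = se,
                grain_n_params = g, seed = derive_seed(seed, i))
  list(
    A = mk("A", 8200, 62.6, 0.1232, 420, 2600, c(48, 0.56, 0.00110), 1),
    B = mk("B", 9400, 58.6, 0.1429, 320, 1000, c(52, 0.52, 0.00127), 2),
    C = mk("C", 10200, 67.6, 0.1943, 260, 400, c(55, 0.50, 0.00144), 3)
  )
}

#' Read / write trial tables
#'
#' Plain-text CSV interface: columns `site_id, block_id, n_rate, yield,
#' grain_n`, one header row, UTF-8.
#'
#' @param trials A `trial_table` data.frame.
#' @param path File path.
#' @return `read_trials()` returns a validated `trial_table`.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  needed <- c("site_id", "block_id", "n_rate", "yield", "grain_n")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  class(df) <- c("trial_table", "data.frame")
  df
}
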