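#' Rank-normalized split-Rhat for a set of chains
#'
#' Modern, conservative variant of the Gelman-Rubin potential scale
#' reduction factor: each chain is split in half (catching within-chain
#' drift), all draws are replaced by their normal scores
#' `qnorm((rank - 3/8) / (S + 1/4))` (robust to heavy tails), and the
#' classic between/within variance ratio
#' `sqrt(((n - 1)/n * W + B/n) / W)` is computed on the split,
#' rank-normalized chains. Values are >= 1 by construction (up to floating
#' point) and near 1 for well-mixed chains.
#'
#' @param x Matrix with one column per chain (iterations in rows), or a
#'   numeric vector plus `chain` ids.
#' @param chain Optional integer vector of chain ids when `x` is a vector.
#' @return The split-Rhat value (scalar).
#' @export
split_rhat <- function(x, chain = NULL) {
  if (!is.null(chain)) {
    parts <- split(as.numeric(x), chain)
    n <- min(lengths(parts))
    x <- vapply(parts, function(p) p[seq_len(n)], numeric(n))
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("split_rhat needs >= 2 chains")
  n <- nrow(x)
  if (n < 4) stop("split_rhat needs >= 4 draws per chain to split")
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  # rank-normalize jointly across all split chains
  S <- length(xs)
  z <- stats::qnorm((rank(xs, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  z <- matrix(z, nrow = half)
  m <- ncol(z)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  # the raw ratio can dip to sqrt((n-1)/n) when B ~ 0; floor at 1 so the
  # statistic is >= 1 by construction
  max(1, sqrt(((half - 1) / half * W + B / half) / W))
}

#' Convergence report for a fitted site
#'
#' Computes rank-normalized split-Rhat and effective sample size for every
#' monitored model parameter and, optionally, for the derived optimum-rate
#' quantities (AONR, EONR), which is how inference-relevant convergence is
#' judged: a site passes when every monitored Rhat lies in [1, 1.02].
#'
#' @param draws A `qp_draws` object (>= 2 chains, >= 10 retained draws per
#'   chain).
#' @param optima Optional `optima_dist` from [derive_optima()]; its AONR
#'   and EONR draws are monitored too.
#' @param rhat_max Pass threshold (default 1.02).
#' @return Data.frame of class `convergence_report` with columns
#'   `quantity`, `rhat`, `ess`, and attribute `pass` (all Rhat <=
#'   `rhat_max`).
#' @export
gelman_rubin <- function(draws, optima = NULL, rhat_max = 1.02) {
  stopifnot(inherits(draws, "qp_draws"))
  chains <- draws$chain
  if (length(unique(chains)) < 2)
    stop("gelman_rubin needs >= 2 chains")
  if (min(table(chains)) < 10)
    stop("gelman_rubin needs >= 10 retained draws per chain")
  mon <- list(beta0 = draws$beta0, beta1 = draws$beta1, beta2 = draws$beta2,
              sigma_b = draws$sigma_b, sigma_e = draws$sigma_e)
  if (!is.null(optima)) {
    stopifnot(inherits(optima, "optima_dist"))
    if (!is.null(optima$aonr)) mon$aonr <- optima$aonr
    if (!is.null(optima$eonr)) mon$eonr <- optima$eonr
  }
  rhat <- vapply(mon, split_rhat, numeric(1), chain = chains)
  ess <- vapply(mon, function(v) {
    ml <- coda::as.mcmc.list(lapply(split(v, chains), coda::mcmc))
    unname(coda::effectiveSize(ml))
  }, numeric(1))
  out <- data.frame(quantity = names(mon), rhat = unname(rhat),
                    ess = unname(ess), row.names = NULL)
  class(out) <- c("convergence_report", "data.frame")
  attr(out, "rhat_max") <- rhat_max
  attr(out, "pass") <- all(out$rhat <= rhat_max)
  out
}
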