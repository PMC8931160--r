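#' Configuration of a sequential Bayes-factor design analysis
#'
#' Describes a two-boundary sequential correlation design: bivariate-normal
#' observations with true correlation `true_rho` accumulate, and at each look
#' the correlation Bayes factor is computed; sampling stops when it crosses
#' `bf_upper` (evidence for an association) or `bf_lower` (evidence for the
#' null), or at `n_max`.
#'
#' Two look-schedule presets are provided. `"registered"` is the schedule a
#' preregistered study of this kind states: first look at 100 participants,
#' then every 10 up to 300. `"fine"` looks after every participant from
#' n = 20, and is useful for mapping the full stopping-time distribution.
#' The default prior is the uniform stretched beta (`width = 1`), the
#' conventional default width for correlation design analyses; note that
#' narrower priors (e.g. the "medium" width 1/3 used for estimation, or a
#' truncated Cauchy with scale sqrt(2)/2) bound the attainable null evidence
#' above 0.1 for all n <= 300, making the lower boundary unreachable — see
#' the package vignette.
#'
#' @param true_rho generating correlation.
#' @param bf_upper,bf_lower evidence boundaries, `0 < bf_lower < 1 < bf_upper`.
#' @param n_start,step,n_max look schedule; overridden by `preset` if given.
#' @param preset `"registered"` (100/10/300), `"fine"` (20/1/300), or `NULL`
#'   to use the explicit schedule arguments.
#' @param n_sims Monte-Carlo replicates.
#' @param prior a [correlation_prior()]; default uniform stretched beta.
#' @param seed RNG seed.
#' @return `"coged_design_config"` list.
#' @export
sequential_design_config <- function(true_rho = 0.3, bf_upper = 10, bf_lower = 0.1,
                                     n_start = 100L, step = 10L, n_max = 300L,
                                     preset = NULL, n_sims = 1000L,
                                     prior = correlation_prior("stretched_beta", width = 1),
                                     seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("registered", "fine"))
    if (preset == "registered") { n_start <- 100L; step <- 10L; n_max <- 300L }
    if (preset == "fine") { n_start <- 20L; step <- 1L; n_max <- 300L }
  }
  if (!(bf_lower > 0 && bf_lower < 1 && bf_upper > 1))
    stop("configuration error: need 0 < bf_lower < 1 < bf_upper")
  if (abs(true_rho) >= 1) stop("configuration error: true_rho must lie in (-1, 1)")
  if (n_start < 4) stop("configuration error: n_start must be >= 4")
  if (n_max < n_start) stop("configuration error: n_max must be >= n_start")
  if (n_sims < 1) stop("empty-result error: n_sims must be >= 1")
  structure(list(true_rho = true_rho, bf_upper = bf_upper, bf_lower = bf_lower,
                 n_start = as.integer(n_start), step = as.integer(step),
                 n_max = as.integer(n_max), n_sims = as.integer(n_sims),
                 prior = prior, seed = as.integer(seed)),
            class = "coged_design_config")
}

#' Simulate a sequential Bayes-factor correlation design
#'
#' For each replicate, a stream of bivariate-normal pairs with correlation
#' `true_rho` is generated once up front and grows across looks (data are
#' never regenerated). At each look the exact correlation Bayes factor of
#' the accumulated sample is computed with the same evidence kernel as
#' [bayes_correlation()]; the replicate stops at the first boundary crossing
#' or at `n_max`. Fully seeded and reproducible.
#'
#' @param config a [sequential_design_config()].
#' @return `"coged_design_result"`: list with `stopping_n` and `decision`
#'   (`"hit_H1"`, `"hit_H0"`, `"max_n_reached"`) per replicate, boundary-hit
#'   proportions, median stopping n among H1 hits and among H0 hits, the
#'   misleading-evidence rate (the boundary contradicting the generating
#'   truth), and the config.
#' @examples
#' simulate_sequential(sequential_design_config(true_rho = 0.5, n_sims = 50,
#'                                              preset = "fine", n_max = 100))
#' @export
simulate_sequential <- function(config = sequential_design_config()) {
  stopifnot(inherits(config, "coged_design_config"))
  set.seed(config$seed)
  nmax <- config$n_max
  nsims <- config$n_sims
  rho <- config$true_rho
  X <- matrix(stats::rnorm(nmax * nsims), nmax)
  Y <- rho * X + sqrt(1 - rho^2) * matrix(stats::rnorm(nmax * nsims), nmax)
  csx <- apply(X, 2, cumsum); csy <- apply(Y, 2, cumsum)
  csxx <- apply(X^2, 2, cumsum); csyy <- apply(Y^2, 2, cumsum)
  csxy <- apply(X * Y, 2, cumsum)

  looks <- unique(c(seq(config$n_start, nmax, by = config$step), nmax))
  stopping_n <- rep(NA_integer_, nsims)
  decision <- rep("max_n_reached", nsims)
  active <- rep(TRUE, nsims)
  for (n in looks) {
    idx <- which(active)
    if (!length(idx)) break
    sx <- csx[n, idx]; sy <- csy[n, idx]
    num <- csxy[n, idx] - sx * sy / n
    den <- sqrt((csxx[n, idx] - sx^2 / n) * (csyy[n, idx] - sy^2 / n))
    r <- pmin(pmax(num / den, -0.9999), 0.9999)
    bf <- bf10_correlation_kernel(r, n, prior = config$prior)
    h1 <- bf >= config$bf_upper
    h0 <- !h1 & bf <= config$bf_lower
    stopping_n[idx[h1]] <- n; decision[idx[h1]] <- "hit_H1"
    stopping_n[idx[h0]] <- n; decision[idx[h0]] <- "hit_H0"
    active[idx[h1 | h0]] <- FALSE
  }
  stopping_n[is.na(stopping_n)] <- nmax
  props <- c(hit_H1 = mean(decision == "hit_H1"),
             hit_H0 = mean(decision == "hit_H0"),
             max_n_reached = mean(decision == "max_n_reached"))
  med <- function(which) if (any(decision == which))
    stats::median(stopping_n[decision == which]) else NA_real_
  misleading <- if (rho == 0) props[["hit_H1"]] else if (rho > 0) props[["hit_H0"]] else NA_real_
  structure(list(stopping_n = stopping_n, decision = decision,
                 proportions = props,
                 median_n_H1 = med("hit_H1"), median_n_H0 = med("hit_H0"),
                 misleading_rate = misleading,
                 looks = looks, config = config),
            class = "coged_design_result")
}

#' @export
print.coged_design_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Sequential BF design: rho = %.2f, boundaries %.3g / %.3g, looks %d/%d/%d, %d sims\n",
              cfg$true_rho, cfg$bf_lower, cfg$bf_upper, cfg$n_start, cfg$step,
              cfg$n_max, cfg$n_sims))
  cat(sprintf("  P(hit H1) = %.3f (median n = %s); P(hit H0) = %.3f (median n = %s); P(n_max) = %.3f\n",
              x$proportions[["hit_H1"]], format(x$median_n_H1),
              x$proportions[["hit_H0"]], format(x$median_n_H0),
              x$proportions[["max_n_reached"]]))
  invisible(x)
}

#' Sequential design analysis under the registered look schedule
#'
#' Convenience wrapper: runs [simulate_sequential()] under the registered
#' schedule (first look at 100 participants, then every 10 to 300) and also
#' reports the probability of terminating inconclusively at `n_max`.
#'
#' @param true_rho generating correlation.
#' @param n_sims replicates.
#' @param seed RNG seed.
#' @param ... further arguments to [sequential_design_config()].
#' @return a `"coged_design_result"` (see [simulate_sequential()]); the
#'   inconclusive-termination probability is `proportions["max_n_reached"]`.
#' @export
planned_design_summary <- function(true_rho = 0.3, n_sims = 1000L, seed = 1L, ...) {
  simulate_sequential(sequential_design_config(true_rho = true_rho,
                                               preset = "registered",
                                               n_sims = n_sims, seed = seed, ...))
}
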