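# Independent oracles used by the tests. These deliberately share no code
# with the package implementations they check.

# --- correlation Bayes factor by adaptive quadrature -------------------------
# 2F1(1/2, 1/2; c; z) through its Euler integral (substituted t = u^2 to tame
# the endpoint singularity), integrated with stats::integrate -- a different
# algorithm from the package's Gauss series.
oracle_hyp2f1_half <- function(c0, z) {
  f <- function(u) (1 - u^2)^(c0 - 1.5) * (1 - z * u^2)^(-0.5)
  val <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  2 * exp(lgamma(c0) - lgamma(0.5) - lgamma(c0 - 0.5)) * val
}

# reduced likelihood of r given rho (normalised at rho = 0)
oracle_corr_lik <- function(rho, r, n) {
  sapply(rho, function(p)
    (1 - p^2)^((n - 1) / 2) * (1 - p * r)^(1.5 - n) *
      oracle_hyp2f1_half(n - 0.5, (1 + p * r) / 2) /
      oracle_hyp2f1_half(n - 0.5, 0.5))
}

# BF10 as a ratio of marginal likelihoods, via adaptive quadrature over rho
oracle_bf10_corr <- function(r, n, prior_density) {
  stats::integrate(function(p) oracle_corr_lik(p, r, n) * prior_density(p),
                   -1, 1, rel.tol = 1e-9)$value
}

# --- staircase enumeration ---------------------------------------------------
# Recursive, scalar re-implementation of the titration rules: follows a
# deterministic threshold agent and also enumerates every choice path.
oracle_staircase <- function(sv_true, base, n_trials = 5L) {
  choose_high <- function(ol, oh) {
    gap <- if (sv_true <= 1) sv_true * oh - ol else oh - (2 - sv_true) * ol
    gap > 0
  }
  titrated <- base
  side_high <- choose_high(base, base)
  for (k in seq_len(n_trials - 1L)) {
    ol <- if (side_high) base else titrated
    oh <- if (side_high) titrated else base
    # the offer pair shown on trial k; the choice on it drives adjustment k
    chose_high <- if (k == 1L) side_high else choose_high(ol, oh)
    chose_titrated <- chose_high == side_high
    titrated <- titrated + if (chose_titrated) -base / 2^k else base / 2^k
  }
  titrated
}

# all endpoints reachable by any choice path (2^(n_trials-1) adjustment signs)
oracle_all_endpoints <- function(base, n_trials = 5L) {
  signs <- expand.grid(rep(list(c(-1, 1)), n_trials - 1L))
  steps <- base / 2^seq_len(n_trials - 1L)
  sort(unique(base + as.matrix(signs) %*% steps))
}

# --- misc --------------------------------------------------------------------
# closed-form partial correlation from zero-order correlations
oracle_partial_r <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

make_bivariate <- function(n, rho) {
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(x, y)
}
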