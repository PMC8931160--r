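# small simulated mixed-model datasets, built directly (not via the cohort
# generator) so the models are tested against known coefficients
sim_mixed <- function(n_part, slope = -0.09, icpt = 0.8, u_sd = 0.2, e_sd = 0.1,
                      perf_effect = 0) {
  load <- rep(rep(1:3, each = 3), n_part)
  id <- rep(seq_len(n_part), each = 9)
  u <- stats::rnorm(n_part, 0, u_sd)
  hit <- stats::runif(n_part * 9, 0.6, 0.95)
  sv <- icpt + slope * (load - 1) + u[id] + perf_effect * hit + stats::rnorm(n_part * 9, 0, e_sd)
  data.frame(participant_id = id, load = load, sv = sv, hit_rate = hit)
}

test_that("the load slope is recovered with nominal interval coverage", {
  set.seed(101)
  hits <- replicate(100, {
    d <- sim_mixed(120)
    f <- fit_effort_model(d, "sv", "load")
    co <- f$coefficients[f$coefficients$term == "load", ]
    co$ci_lower <= -0.09 && -0.09 <= co$ci_upper
  })
  expect_gte(sum(hits), 90)
})

test_that("degenerate inputs fail loudly", {
  d <- sim_mixed(30)
  d$sv <- 1
  expect_error(fit_effort_model(d, "sv", "load"), "zero variance")
  d2 <- sim_mixed(30)
  d2$load2 <- d2$load
  expect_error(fit_effort_model(d2, "sv", c("load", "load2")), "singular|collinear")
  d3 <- sim_mixed(30)
  d3$flat <- 1
  expect_error(fit_effort_model(d3, "sv", c("load", "flat")), "constant")
})

test_that("one observation per participant degenerates exactly to OLS", {
  set.seed(102)
  full <- sim_mixed(80)
  pick <- (seq_len(80) - 1) * 9 + 1 + 3 * ((seq_len(80) - 1) %% 3) # one row each, loads vary
  d <- full[pick, ]
  f <- fit_effort_model(d, "sv", "load")
  ols <- stats::lm(sv ~ I(load - min(load)), data = d)
  expect_equal(f$coefficients$estimate, unname(stats::coef(ols)), tolerance = 1e-6)
  expect_equal(f$ranef_var, 0)
})

test_that("with no trait variance the mixed fit matches the OLS oracle", {
  set.seed(103)
  d <- sim_mixed(100, u_sd = 0)
  f <- fit_effort_model(d, "sv", "load")
  ols <- stats::lm(sv ~ I(load - 1), data = d)
  expect_lt(f$ranef_var, 0.002)
  expect_equal(f$coefficients$estimate, unname(stats::coef(ols)), tolerance = 0.01)
  expect_true(f$r2 >= 0 && f$r2 <= 1)
})

test_that("fixed-effect residual means keep the trait variance", {
  set.seed(104)
  co <- generate_cohort(cohort_config(n_participants = 200, seed = 41))
  sv <- score_choices(co$choices)
  wm <- sv[sv$domain == "working_memory", ]
  res <- residualize_domain(wm, co$performance)
  msv <- summarise_mean_sv(wm)
  m <- merge(res, msv, by = "participant_id")
  # with covariates nearly unrelated to the trait, averaged fixed-effect
  # residuals are the centred participant means
  expect_gt(stats::cor(m$mean_residual, m$mean_sv), 0.95)
  expect_lt(abs(mean(res$mean_residual)), 0.02)
})

test_that("residualization is idempotent on participant means", {
  set.seed(105)
  co <- generate_cohort(cohort_config(n_participants = 80, seed = 43))
  sv <- score_choices(co$choices)
  sp <- sv[sv$domain == "speech", ]
  r1 <- residualize_domain(sp, co$performance)
  sp2 <- sp
  fit <- attr(r1, "fit")
  sp2$sv <- fit$residuals_fixed
  r2 <- residualize_domain(sp2, co$performance)
  expect_lt(max(abs(r2$mean_residual - r1$mean_residual)), 1e-8)
})

test_that("a perfectly linear load effect leaves near-zero residuals", {
  d <- data.frame(participant_id = rep(1:20, each = 9),
                  load = rep(rep(1:3, each = 3), 20))
  d$sv <- 1 - 0.1 * (d$load - 1)
  d$sv <- d$sv + stats::rnorm(nrow(d), 0, 1e-8) # break exact singularity only
  f <- fit_effort_model(d, "sv", "load")
  expect_lt(max(abs(f$residuals_fixed)), 1e-6)
})

test_that("rating models detect load effects and reject bad inputs", {
  set.seed(106)
  co <- generate_cohort(cohort_config(n_participants = 120, seed = 47))
  fits <- fit_ratings_models(co$ratings)
  expect_setequal(names(fits), c("mental_demand", "effort", "frustration"))
  for (s in names(fits)) {
    load_row <- fits[[s]]$coefficients[fits[[s]]$coefficients$term == "load", ]
    expect_gt(load_row$ci_lower, 0) # ratings rise with load
    expect_true(fits[[s]]$r2 >= 0 && fits[[s]]$r2 <= 1)
  }
  bad <- co$ratings
  bad$rating[1] <- 25
  expect_error(fit_ratings_models(bad), "1-21")
  flat <- co$ratings
  flat$rating <- 10
  expect_error(fit_ratings_models(flat), "zero variance")
})

test_that("cross-domain correlation of residual means recovers the trait", {
  set.seed(107)
  rs <- replicate(6, {
    seed <- sample.int(1e6, 1)
    co <- generate_cohort(cohort_config(n_participants = 300, rho_domains = 0.5,
                                        p_no_headphones = 0, p_incomplete = 0,
                                        seed = seed))
    sv <- score_choices(co$choices)
    r_wm <- residualize_domain(sv[sv$domain == "working_memory", ], co$performance)
    r_sp <- residualize_domain(sv[sv$domain == "speech", ], co$performance)
    m <- merge(r_wm, r_sp, by = "participant_id")
    stats::cor(m$mean_residual.x, m$mean_residual.y)
  })
  expect_lt(abs(stats::median(rs) - 0.5), 0.1)
})
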