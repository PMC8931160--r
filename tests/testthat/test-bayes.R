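test_that("priors integrate to one and are symmetric about zero", {
  for (p in list(correlation_prior(), correlation_prior("stretched_beta", 1),
                 correlation_prior("truncated_cauchy"))) {
    expect_equal(stats::integrate(p$density, -1, 1)$value, 1, tolerance = 1e-6)
    expect_equal(p$density(0.4), p$density(-0.4))
  }
  expect_error(correlation_prior(width = -1), "positive")
})

test_that("strong signals and long null runs move the Bayes factor correctly", {
  set.seed(201)
  x <- stats::rnorm(20)
  y <- x + stats::rnorm(20, 0, 1e-3)
  res <- bayes_correlation(x, y)
  expect_gt(res$r_median, 0.9)
  expect_gt(res$bf10, 100)
  expect_true(res$ci95[1] <= res$r_median && res$r_median <= res$ci95[2])
  xy <- make_bivariate(5000, 0)
  expect_lt(bayes_correlation(xy[, 1], xy[, 2])$bf10, 1)
})

test_that("input contracts are enforced", {
  expect_error(bayes_correlation(1:3, 1:3), "at least 4")
  expect_error(bayes_correlation(rep(1, 10), stats::rnorm(10)), "zero variance")
  expect_error(bayes_correlation(stats::rnorm(5), c(1, 2, NA, 4, 5)), "finite")
})

test_that("the grid Bayes factor matches an independent quadrature oracle", {
  set.seed(202)
  for (k in 1:12) {
    n <- sample(10:60, 1)
    xy <- make_bivariate(n, stats::runif(1, -0.7, 0.7))
    for (p in list(correlation_prior(), correlation_prior("stretched_beta", 1))) {
      got <- bayes_correlation(xy[, 1], xy[, 2], prior = p)$bf10
      want <- oracle_bf10_corr(stats::cor(xy[, 1], xy[, 2]), n, p$density)
      expect_lt(abs(got / want - 1), 0.01)
    }
  }
})

test_that("known Bayes factors are reproduced at the printed precision", {
  # reference values from an independent implementation of the exact
  # correlation Bayes factor (Ly et al. analytic form)
  r_to_xy <- function(r, n) {
    x <- scale(stats::rnorm(n))[, 1]
    e <- scale(stats::resid(stats::lm(stats::rnorm(n) ~ x)))[, 1]
    cbind(x, r * x + sqrt(1 - r^2) * e)
  }
  set.seed(203)
  xy <- r_to_xy(0.42, 37)
  expect_equal(bayes_correlation(xy[, 1], xy[, 2])$bf10, 6.7472, tolerance = 1e-3)
  expect_equal(bayes_correlation(xy[, 1], xy[, 2],
                                 prior = correlation_prior("stretched_beta", 1))$bf10,
               5.1369, tolerance = 1e-3)
  xy <- r_to_xy(-0.25, 80)
  expect_equal(bayes_correlation(xy[, 1], xy[, 2])$bf10, 2.6573, tolerance = 1e-3)
})

test_that("the correlation test is invariant to affine transforms", {
  set.seed(204)
  xy <- make_bivariate(60, 0.4)
  a <- bayes_correlation(xy[, 1], xy[, 2])
  b <- bayes_correlation(3 * xy[, 1] - 7, -2 * xy[, 2] + 11)
  expect_equal(abs(b$r_median), abs(a$r_median), tolerance = 1e-10)
  expect_equal(b$bf10, a$bf10, tolerance = 1e-10)
})

test_that("evidence for a real correlation accumulates with sample size", {
  set.seed(205)
  med_bf <- sapply(c(50, 100, 200), function(n) {
    stats::median(replicate(20, {
      xy <- make_bivariate(n, 0.3)
      bayes_correlation(xy[, 1], xy[, 2])$bf10
    }))
  })
  expect_true(all(diff(med_bf) > 0))
})

test_that("credible intervals cover a true correlation of 0.3 at n = 104", {
  set.seed(206)
  covered <- replicate(200, {
    xy <- make_bivariate(104, 0.3)
    ci <- bayes_correlation(xy[, 1], xy[, 2])$ci95
    ci[1] <= 0.3 && 0.3 <= ci[2]
  })
  expect_gte(mean(covered), 0.9)
})

test_that("partial correlation removes covariates and discounts the sample size", {
  set.seed(207)
  n <- 120
  z <- stats::rnorm(n)
  x <- stats::rnorm(n); y <- 0.4 * x + stats::rnorm(n, 0, 0.9)
  zo <- bayes_correlation(x, y)
  orth <- bayes_partial_correlation(x, y, cbind(z1 = stats::resid(stats::lm(z ~ x + y))))
  expect_equal(orth$r_median, zo$r_median, tolerance = 0.02)
  expect_equal(orth$n_effective, n - 1)
  expect_error(bayes_partial_correlation(x, y, cbind(y)), "zero residual variance")
  expect_error(bayes_partial_correlation(x, y, cbind(a = z, b = 2 * z)), "rank deficient")
})

test_that("a shared confounder attenuates the partial correlation as theory says", {
  set.seed(208)
  n <- 4000
  z <- stats::rnorm(n)
  x <- 0.6 * z + stats::rnorm(n, 0, 0.8)
  y <- 0.6 * z + stats::rnorm(n, 0, 0.8)
  zo <- stats::cor(x, y)
  want <- oracle_partial_r(zo, stats::cor(x, z), stats::cor(y, z))
  got <- bayes_partial_correlation(x, y, cbind(z))
  expect_equal(got$r_median, want, tolerance = 0.03)
  expect_lt(got$r_median, bayes_correlation(x, y)$r_median)
})

test_that("paired contrasts reproduce reference Bayes factors and behave in t", {
  # construct difference vectors with exact t statistics, then compare with
  # reference values from an independent JZS implementation
  d_for_t <- function(t, n) {
    d <- scale(stats::rnorm(n))[, 1]
    d + t / sqrt(n)
  }
  set.seed(209)
  expect_equal(paired_t_bf(d_for_t(2.5, 50))$bf10, 2.5398, tolerance = 1e-3)
  expect_equal(paired_t_bf(d_for_t(0, 30))$bf10, 0.19438, tolerance = 1e-3)
  expect_equal(paired_t_bf(d_for_t(4, 104))$bf10, 153.8798, tolerance = 1e-3)
  expect_equal(paired_t_bf(d_for_t(-1.5, 20))$bf10, 0.60911, tolerance = 1e-3)
  # monotone and continuous in |t| at fixed n
  bfs <- sapply(seq(0, 5, by = 0.25), function(t) paired_t_bf(d_for_t(t, 40))$bf10)
  expect_true(all(diff(bfs) > 0))
  near0 <- paired_t_bf(c(rep(0, 19), 1e-9) + stats::rnorm(20, 0, 1e-6))
  expect_lt(near0$bf10, 1)
  expect_error(paired_t_bf(rep(0.5, 10)), "zero variance")
  expect_error(paired_t_bf(c(1, 2)), "at least 3")
})

test_that("a standardized paired effect of 0.4 at n = 104 is usually decisive", {
  set.seed(210)
  bfs <- replicate(20, paired_t_bf(stats::rnorm(104, 0.4, 1))$bf10)
  expect_gt(mean(bfs > 10), 0.7)
})
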