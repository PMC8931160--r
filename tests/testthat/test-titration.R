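test_that("the default schedule yields 45 decision trials from 9 unique cells", {
  set.seed(1)
  sch <- schedule_trials("working_memory")
  expect_equal(sch$n_decision_trials, 45)
  expect_length(sch$cells, 9)
  keys <- sapply(sch$cells, function(c) paste(c$load, c$base_amount))
  expect_equal(sort(keys), sort(paste(rep(1:3, 3), rep(c(2, 3, 4), each = 3))))
  expect_equal(schedule_trials(loads = 1, amounts = 2)$n_decision_trials, 5)
  expect_error(schedule_trials(loads = c(1, 1, 2)), "duplicate")
  set.seed(7); a <- schedule_trials()
  set.seed(7); b <- schedule_trials()
  expect_identical(a, b)
})

test_that("the staircase follows the halving schedule from the worked example", {
  # base $2, low-effort option chosen on trials 1 and 2:
  # trial 2 must offer $1 for the low-effort task against the fixed $2
  seen <- list()
  chooser <- function(ol, oh) { seen[[length(seen) + 1]] <<- c(ol, oh); "low" }
  ts <- run_titration(offer_cell("working_memory", 1, 2), chooser)
  expect_equal(unname(seen[[2]]), c(1, 2))
  expect_equal(ts$trials$offer_low[1], 2)
  expect_equal(ts$trials$offer_high[1], 2)
  expect_equal(ts$titrated_side, "low")
  # always choosing the titrated side walks it down: 2 - 1 - .5 - .25 - .125
  expect_equal(ts$indifference_point, 0.125)
})

test_that("deterministic threshold agents land within one final step of truth", {
  ts <- run_titration(offer_cell("working_memory", 1, 2), threshold_chooser(0.6))
  expect_equal(ts$indifference_point, 1.125) # hand-traced staircase path
  expect_lt(abs(ts$indifference_point - 0.6 * 2), 2 / 2^4)
  # strict alternation gives the signed partial sum base*(1 - 1/2 + 1/4 - ...)
  alt <- local({ i <- 0; function(ol, oh) { i <<- i + 1; if (i %% 2) "low" else "high" } })
  ts2 <- run_titration(offer_cell("working_memory", 1, 2), alt)
  expect_equal(ts2$indifference_point, 2 * (1 - 1/2 + 1/4 - 1/8 + 1/16))
})

test_that("estimated value is monotone in the agent's true value", {
  cell <- offer_cell("speech", 2, 3)
  svs <- seq(0.05, 1.95, by = 0.05)
  est <- sapply(svs, function(s) {
    ts <- run_titration(cell, threshold_chooser(s))
    indifference_to_sv(ts$indifference_point, 3, ts$initial_choice)
  })
  expect_true(all(diff(est) >= 0))
})

test_that("offers stay in [0, 2 * base] and trial one is the equal-offer trial", {
  set.seed(42)
  for (base in c(2, 3, 4)) {
    rand <- function(ol, oh) sample(c("low", "high"), 1)
    ts <- run_titration(offer_cell("working_memory", 3, base), rand)
    expect_true(all(ts$trials$offer_low >= 0 & ts$trials$offer_low <= 2 * base))
    expect_true(all(ts$trials$offer_high >= 0 & ts$trials$offer_high <= 2 * base))
    expect_equal(ts$trials$offer_low[1], base)
    expect_equal(ts$trials$offer_high[1], base)
  }
})

test_that("staircase endpoints agree with the recursive enumeration oracle", {
  for (base in c(2, 3, 4)) {
    ends <- oracle_all_endpoints(base)
    for (sv in c(0.07, 0.33, 0.5, 0.81, 1.2, 1.77)) {
      ts <- run_titration(offer_cell("working_memory", 1, base), threshold_chooser(sv))
      expect_equal(ts$indifference_point, oracle_staircase(sv, base))
      expect_true(any(abs(ends - ts$indifference_point) < 1e-12))
    }
  }
})

test_that("replay reproduces a run and flags tampered or empty logs", {
  ts <- run_titration(offer_cell("speech", 1, 4), threshold_chooser(0.45))
  rp <- replay_titration(ts$trials, ts$cell)
  expect_equal(rp$indifference_point, ts$indifference_point)
  expect_equal(rp$trials, ts$trials)
  bad <- ts$trials
  bad$offer_low[3] <- bad$offer_low[3] + 0.3
  expect_error(replay_titration(bad, ts$cell), "trial 3")
  expect_error(replay_titration(ts$trials[0, ], ts$cell), "no trials")
  wrong_base <- ts$trials
  wrong_base$offer_low[1] <- 3
  expect_error(replay_titration(wrong_base, ts$cell), "trial 1")
})

test_that("choice_policy is a logistic in the offer-value gap", {
  expect_equal(choice_policy(1, 2, 2, 0.5), 0.5)   # indifferent at equal offers
  expect_equal(choice_policy(0.6, 2, 2, 0), 0)     # 1.2 < 2: easy option
  expect_equal(choice_policy(1.5, 2, 2, 0), 1)     # 3 > 2: hard option
  expect_gt(choice_policy(0.9, 2, 2, 0.2), choice_policy(0.6, 2, 2, 0.2))
  expect_error(choice_policy(1, -2, 2, 0.1), "positive")
  expect_error(choice_policy(1, 2, 2, -0.1), ">= 0")
})
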