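test_that("indifference points map to the 0-2 subjective-value scale", {
  expect_equal(indifference_to_sv(2, 2, "low"), 1)
  expect_equal(indifference_to_sv(2, 2, "high"), 1) # continuous at ip = base
  expect_equal(indifference_to_sv(1.20, 2, "low"), 0.60)
  expect_equal(indifference_to_sv(1.00, 2, "high"), 1.50)
  expect_error(indifference_to_sv(2.5, 2, "low"), "outside")
  expect_error(indifference_to_sv(1, 2, "middle"), "initial_choice")
})

test_that("mean subjective value requires the complete 9-cell grid", {
  loads <- rep(1:3, 3); amts <- rep(c(2, 3, 4), each = 3)
  expect_equal(mean_sv(rep(1, 9), loads, amts), 1)
  expect_equal(mean_sv(rep(0.5, 9), loads, amts), 0.5)
  expect_error(mean_sv(rep(0.5, 8), loads[-1], amts[-1]), "completeness")
  expect_error(mean_sv(rep(0.5, 9), rep(1, 9), rep(2, 9)), "duplicated")
})

test_that("keyword intelligibility scores normalised token matches", {
  kw <- c("dog", "ran", "park", "big")
  expect_equal(keyword_intelligibility("the DOG ran.", kw), 0.5)
  expect_equal(keyword_intelligibility("Big park: dog ran!", kw), 1)
  expect_equal(keyword_intelligibility("ran park big dog extra words", kw), 1)
  expect_equal(keyword_intelligibility("", kw), 0)
  expect_equal(keyword_intelligibility(NA_character_, kw), 0)
  # a repeated keyword needs to be typed as often as it is listed
  expect_equal(keyword_intelligibility("dog dog", c("dog", "dog", "cat", "sat")), 0.5)
  expect_equal(keyword_intelligibility("dog", c("dog", "dog", "cat", "sat")), 0.25)
  expect_error(keyword_intelligibility("anything", character(0)), "empty")
})

test_that("composites are sums of sample z-scores", {
  p <- data.frame(participant_id = 1:3,
                  lspan = c(30, 40, 50), ospan = c(35, 45, 55), symspan = c(20, 28, 36),
                  bas = c(30, 40, 50), grapes = c(10, 15, 20), spsrq = c(8, 12, 16))
  comp <- build_composites(p)
  expect_equal(comp$wm_capacity, c(-3, 0, 3))         # each component z = -1, 0, 1
  expect_equal(comp$reward_sensitivity, c(-3, 0, 3))
  expect_equal(sum(comp$wm_capacity), 0)
  # invariance to affine rescaling of a component
  p2 <- p; p2$ospan <- 9 * p2$ospan - 100
  expect_equal(build_composites(p2)$wm_capacity, comp$wm_capacity)
  p3 <- p; p3$grapes <- 15
  expect_error(build_composites(p3), "grapes")
})

test_that("exclusion rules drop the right participants in each mode", {
  p <- data.frame(participant_id = 1:12,
                  no_headphones = c(rep(TRUE, 2), rep(FALSE, 10)),
                  incomplete_discounting = c(FALSE, FALSE, TRUE, rep(FALSE, 9)))
  msv <- setNames(c(rep(0.7, 11), 1.2), 1:12)
  prim <- apply_exclusions(p, msv, "primary")
  expect_equal(prim$report$n_retained, 9)
  expect_equal(prim$report$counts[["no_headphones"]], 2)
  expect_true(12 %in% prim$retained$participant_id)       # seeker kept in primary
  sens <- apply_exclusions(p, msv, "drop_effort_seekers")
  expect_equal(sens$report$n_retained, 8)
  expect_false(12 %in% sens$retained$participant_id)
  expect_true(any(grepl("effort_seeker", sens$report$dropped$reason)))
  clean <- p; clean$no_headphones <- FALSE; clean$incomplete_discounting <- FALSE
  expect_equal(apply_exclusions(clean, NULL, "primary")$report$n_retained, 12)
})

test_that("noise-free cohorts are rescored to truth within the staircase bound", {
  cfg <- cohort_config(n_participants = 25, cell_noise_sd = 0, softmax_temperature = 0,
                       p_no_headphones = 0, p_incomplete = 0, seed = 9)
  co <- generate_cohort(cfg)
  scores <- score_choices(co$choices)
  cellm <- stats::aggregate(scores$sv,
                            by = list(participant_id = scores$participant_id,
                                      domain = scores$domain, load = scores$load),
                            FUN = mean)
  m <- merge(cellm, co$truth, by = c("participant_id", "domain", "load"))
  expect_true(all(abs(m$x - m$sv_true) <= 1 / 2^4 + 1e-12))
})

test_that("scoring a choices table is the same as replaying each series", {
  co <- generate_cohort(cohort_config(n_participants = 6, seed = 31))
  sv <- score_choices(co$choices)
  expect_equal(nrow(sv), 6 * 2 * 9)
  g <- co$choices[co$choices$participant_id == 3 & co$choices$domain == "speech" &
                    co$choices$load == 2 & co$choices$base_amount == 4, ]
  ts <- replay_titration(g[, c("trial_index", "offer_low", "offer_high", "choice")],
                         offer_cell("speech", 2, 4))
  row <- sv[sv$participant_id == 3 & sv$domain == "speech" & sv$load == 2 &
              sv$base_amount == 4, ]
  expect_equal(row$indifference_point, ts$indifference_point)
  expect_equal(row$sv, indifference_to_sv(ts$indifference_point, 4, ts$initial_choice))
  bad <- co$choices
  bad$offer_high[10] <- bad$offer_high[10] + 1
  expect_error(score_choices(bad), "validation error")
})
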