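#' Configuration of a synthetic discounting cohort
#'
#' Collects every generative parameter of the simulated study. The defaults
#' are the package's "paperlike" condition set: a cross-domain latent
#' correlation of 0.3, mean subjective values declining with load by about
#' 0.09 (working memory) and 0.19 (speech) per level, a ~5% minority of
#' effort seekers, exclusion rates matching a ~132-recruited / ~104-retained
#' cohort, and near-zero correlations of the capacity / reward-sensitivity /
#' need-for-cognition traits with discounting.
#'
#' @param n_participants cohort size before exclusions.
#' @param rho_domains target correlation of the two domain latents, in
#'   `[-1, 1]`.
#' @param sv_intercept_by_domain named vector: mean true subjective value at
#'   the lowest high-effort load, per domain; values must lie in (0, 2).
#' @param sv_load_slope_by_domain named vector: per-level decrement of mean
#'   subjective value.
#' @param subject_sd SD of the participant latent effort-value offset on the
#'   subjective-value scale.
#' @param cell_noise_sd SD of the per-cell subjective-value noise.
#' @param softmax_temperature choice-noise scale in offer-currency units
#'   (0 = deterministic choices).
#' @param p_effort_seeker proportion of effort seekers per domain: the top
#'   quantile of the domain latent receives an intercept shift above 1.
#'   (A quantile cut rather than an independent coin flip: an independent
#'   participant-level mixture would correlate the domains even at
#'   `rho_domains = 0`.)
#' @param seeker_scale slope (relative to `subject_sd`) with which an effort
#'   seeker's subjective value continues above 1 as the domain latent
#'   exceeds the seeker threshold; the tail map is continuous, so the
#'   cross-domain correlation structure survives the mixture.
#' @param perf_model coefficients of the performance model: logistic models
#'   for N-back hit and correct-rejection rates (intercept, per-level slope,
#'   capacity loading), a linear model for mean RT in ms, a logistic model
#'   for speech intelligibility against SNR in dB, observation noise SDs,
#'   and `sv_weight`, the weight with which a participant's
#'   load-specific performance deviation feeds back into true subjective
#'   value.
#' @param composite_loadings loadings of the span totals on the capacity
#'   factor and of the questionnaire totals on the reward-sensitivity factor.
#' @param r_capacity_sv,r_reward_sv,r_ncs_sv target correlations of the
#'   latent traits with the standardised effort latent.
#' @param p_no_headphones,p_incomplete exclusion-flag rates.
#' @param amounts base offer amounts in dollars.
#' @param n_trials_per_cell choices per titration series.
#' @param seed root RNG seed; per-participant substreams are derived from it
#'   by counter, so participant `i` is identical in cohorts of any size.
#' @return `"coged_cohort_config"` list.
#' @export
cohort_config <- function(n_participants = 132,
                          rho_domains = 0.3,
                          sv_intercept_by_domain = c(working_memory = 0.78, speech = 0.80),
                          sv_load_slope_by_domain = c(working_memory = 0.09, speech = 0.19),
                          subject_sd = 0.20,
                          cell_noise_sd = 0.10,
                          softmax_temperature = 0.10,
                          p_effort_seeker = 5 / 104,
                          seeker_scale = 2,
                          perf_model = list(
                            hit = c(icpt = 3.2, level = -0.6, capacity = 0.5),
                            cr = c(icpt = 3.6, level = -0.4, capacity = 0.4),
                            rt = c(icpt = 550, level = 60, capacity = -30),
                            intel = c(icpt = 2.8, snr = 0.35, capacity = 0.3),
                            rate_noise_sd = 0.05, rt_noise_sd = 40,
                            sv_weight = 0.3),
                          composite_loadings = list(
                            spans = c(lspan = 6, ospan = 8, symspan = 5),
                            reward = c(bas = 4, grapes = 2.5, spsrq = 2.5)),
                          r_capacity_sv = 0.10,
                          r_reward_sv = 0.05,
                          r_ncs_sv = 0.10,
                          p_no_headphones = 10 / 132,
                          p_incomplete = 18 / 132,
                          amounts = c(2, 3, 4),
                          n_trials_per_cell = 5L,
                          seed = 1L) {
  probs <- c(p_effort_seeker = p_effort_seeker, p_no_headphones = p_no_headphones,
             p_incomplete = p_incomplete)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1] (",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "), ")")
  if (abs(rho_domains) > 1) stop("configuration error: rho_domains must lie in [-1, 1]")
  if (any(sv_intercept_by_domain <= 0 | sv_intercept_by_domain >= 2))
    stop("configuration error: sv intercepts must lie in (0, 2)")
  if (n_participants < 1) stop("configuration error: n_participants must be >= 1")
  if (subject_sd < 0 || cell_noise_sd < 0 || softmax_temperature < 0)
    stop("configuration error: SDs and temperature must be >= 0")
  cfg <- as.list(environment())
  cfg$probs <- NULL
  structure(cfg, class = "coged_cohort_config")
}

# per-participant substream seed, counter-derived from the root seed
participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(i)) %% 2147483629)
}

# reference (population-average) performance used to centre the
# performance -> subjective-value feedback
perf_reference <- function(pm, level, snr) {
  list(hit = stats::plogis(pm$hit["icpt"] + pm$hit["level"] * level),
       intel = stats::plogis(pm$intel["icpt"] + pm$intel["snr"] * snr))
}

#' Generate a synthetic discounting cohort
#'
#' Draws, for each participant, a domain-general motivation latent and two
#' correlated domain latents, a true subjective-value grid per domain and
#' load, load-dependent task performance, workload ratings, span and
#' questionnaire totals, exclusion metadata, and a full choice log produced
#' by running every titration series with a softmax agent whose indifference
#' points sit at the true subjective values. Ground truth is retained for
#' parameter-recovery tests.
#'
#' @param config a [cohort_config()].
#' @return `"coged_cohort"`: list of data frames `participants`, `latents`,
#'   `truth`, `performance`, `ratings`, `choices`, plus the `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 4, seed = 42))
#' head(cohort$truth)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "coged_cohort_config"))
  n <- config$n_participants
  domains <- c("working_memory", "speech")
  loads <- 1:3
  snr_by_level <- c(0, -4, -8, -12) # familiarization levels 1..4
  pm <- config$perf_model
  r <- abs(config$rho_domains)
  sgn <- if (config$rho_domains >= 0) 1 else -1
  q_seek <- stats::qnorm(1 - config$p_effort_seeker)
  amounts <- config$amounts
  ntr <- config$n_trials_per_cell
  cells <- expand.grid(load = loads, amount = amounts) # 9 per domain
  n_cells <- nrow(cells)

  # pre-allocated accumulators; data frames are assembled once after the loop
  scale_icpt <- c(mental_demand = 7, effort = 8, frustration = 4)
  scale_slope <- c(mental_demand = 3.7, effort = 2.5, frustration = 1.0)
  rat_template <- expand.grid(scale = names(scale_icpt), load = loads, domain = domains,
                              stringsAsFactors = FALSE)
  n_rat <- nrow(rat_template) # 18
  n_ch <- 2L * n_cells * ntr  # choice rows per participant
  part_mat <- matrix(NA_real_, n, 7,
                     dimnames = list(NULL, c("lspan", "ospan", "symspan",
                                             "bas", "grapes", "spsrq", "ncs")))
  excl_mat <- matrix(NA, n, 2)
  lat_mat <- matrix(NA_real_, n, 6,
                    dimnames = list(NULL, c("g", "u_wm", "u_speech", "capacity",
                                            "reward_sens", "ncs_latent")))
  seek_mat <- matrix(NA, n, 2)
  truth_mat <- matrix(NA_real_, n, 6) # wm loads 1..3, then speech loads 1..3
  hit_mat <- cr_mat <- rt_mat <- intel_mat <- matrix(NA_real_, n, 4)
  rat_mat <- matrix(NA_real_, n, n_rat)
  # choice randomness is drawn inside each participant's substream but the
  # staircases themselves run in one vectorised batch after the loop
  n_series <- 2L * n * n_cells
  sv_cell_all <- numeric(n_series)
  un_all <- matrix(NA_real_, n_series, ntr)
  perm <- integer(n_series) # presentation order of series rows
  for (i in seq_len(n)) {
    set.seed(participant_seed(config$seed, i))
    g <- stats::rnorm(1)
    e_dom <- stats::rnorm(2)
    u <- c(working_memory = NA_real_, speech = NA_real_)
    u["working_memory"] <- sqrt(r) * g + sqrt(1 - r) * e_dom[1]
    u["speech"] <- sgn * sqrt(r) * g + sqrt(1 - r) * e_dom[2]
    var_mean_u <- (1 + config$rho_domains) / 2
    z_sv <- if (var_mean_u > 1e-12) unname(u[1] + u[2]) / 2 / sqrt(var_mean_u) else g
    e_traits <- stats::rnorm(3)
    capacity <- config$r_capacity_sv * z_sv + sqrt(1 - config$r_capacity_sv^2) * e_traits[1]
    reward <- config$r_reward_sv * z_sv + sqrt(1 - config$r_reward_sv^2) * e_traits[2]
    ncs_lat <- config$r_ncs_sv * z_sv + sqrt(1 - config$r_ncs_sv^2) * e_traits[3]

    # familiarization performance, levels 1..4 in each domain
    hit_noise <- stats::rnorm(4, 0, pm$rate_noise_sd)
    cr_noise <- stats::rnorm(4, 0, pm$rate_noise_sd)
    rt_noise <- stats::rnorm(4, 0, pm$rt_noise_sd)
    int_noise <- stats::rnorm(4, 0, pm$rate_noise_sd)
    lv <- 1:4
    hit <- pmin(pmax(stats::plogis(pm$hit["icpt"] + pm$hit["level"] * lv +
                                     pm$hit["capacity"] * capacity) + hit_noise, 0.01), 0.999)
    cr <- pmin(pmax(stats::plogis(pm$cr["icpt"] + pm$cr["level"] * lv +
                                    pm$cr["capacity"] * capacity) + cr_noise, 0.01), 0.999)
    rt <- pm$rt["icpt"] + pm$rt["level"] * lv + pm$rt["capacity"] * capacity + rt_noise
    intel <- pmin(pmax(stats::plogis(pm$intel["icpt"] + pm$intel["snr"] * snr_by_level +
                                       pm$intel["capacity"] * capacity) + int_noise, 0.01), 0.999)

    # true subjective-value grid (per domain x load), with performance feedback
    seeker <- u > q_seek
    ref <- perf_reference(pm, lv, snr_by_level)
    perf_dev <- rbind(working_memory = (hit - ref$hit)[loads + 1L],
                      speech = (intel - ref$intel)[loads + 1L])
    sv_true <- matrix(NA_real_, 2, 3, dimnames = list(domains, NULL))
    for (d in domains) {
      if (!seeker[d]) {
        raw <- config$sv_intercept_by_domain[d] -
          config$sv_load_slope_by_domain[d] * (loads - 1) +
          config$subject_sd * u[d] +
          pm$sv_weight * perf_dev[d, ]
        sv_true[d, ] <- pmin(pmax(raw, 0), 1)
      } else {
        # continuous tail map: the effort-seeker branch continues above the
        # 1.0 ceiling with slope seeker_scale in the latent, so the
        # transform u -> SV stays monotone without a jump at the threshold
        raw <- 1 + config$seeker_scale * config$subject_sd * (u[d] - q_seek) -
          config$sv_load_slope_by_domain[d] * (loads - 1) +
          pm$sv_weight * perf_dev[d, ]
        sv_true[d, ] <- pmin(pmax(raw, 1), 2)
      }
    }

    # workload ratings (1-21 visual-analog), three scales per domain x load
    rat_noise <- stats::rnorm(n_rat, 0, 2.5)
    rat_mat[i, ] <- pmin(pmax(scale_icpt[rat_template$scale] +
                                scale_slope[rat_template$scale] * (rat_template$load - 1) +
                                1.2 * u[rat_template$domain] + rat_noise, 1), 21)

    # span and questionnaire totals
    qn <- stats::rnorm(7)
    ld <- config$composite_loadings
    spans <- c(lspan = unname(40 + ld$spans[["lspan"]] * capacity + 4 * qn[1]),
               ospan = unname(45 + ld$spans[["ospan"]] * capacity + 5 * qn[2]),
               symspan = unname(28 + ld$spans[["symspan"]] * capacity + 3 * qn[3]))
    quest <- c(bas = unname(40 + ld$reward[["bas"]] * reward + 3 * qn[4]),
               grapes = unname(15 + ld$reward[["grapes"]] * reward + 2 * qn[5]),
               spsrq = unname(12 + ld$reward[["spsrq"]] * reward + 2 * qn[6]),
               ncs = unname(62 + 9 * ncs_lat + 6 * qn[7]))

    # discounting choices: per domain, randomised cell order, softmax agent
    for (di in 1:2) {
      d <- domains[di]
      cell_noise <- stats::rnorm(n_cells, 0, config$cell_noise_sd)
      ord <- sample.int(n_cells)
      un <- matrix(stats::runif(n_cells * ntr), n_cells, ntr)
      sv_cell <- sv_true[d, cells$load] + cell_noise
      sv_cell <- if (seeker[d]) pmin(pmax(sv_cell, 1), 2) else pmin(pmax(sv_cell, 0), 1)
      block <- ((i - 1L) * 2L + (di - 1L)) * n_cells
      sv_cell_all[block + seq_len(n_cells)] <- sv_cell
      un_all[block + seq_len(n_cells), ] <- un
      perm[block + seq_len(n_cells)] <- block + ord
    }

    excl <- stats::runif(2)
    part_mat[i, ] <- c(spans, quest)
    excl_mat[i, ] <- c(excl[1] < config$p_no_headphones, excl[2] < config$p_incomplete)
    lat_mat[i, ] <- c(g, u[["working_memory"]], u[["speech"]], capacity, reward, ncs_lat)
    seek_mat[i, ] <- seeker
    truth_mat[i, ] <- c(sv_true["working_memory", ], sv_true["speech", ])
    hit_mat[i, ] <- hit; cr_mat[i, ] <- cr; rt_mat[i, ] <- rt; intel_mat[i, ] <- intel
  }

  base_all <- rep(cells$amount, 2L * n)
  sim <- staircase_sim(sv_cell_all, base_all, config$softmax_temperature, ntr, un_all)
  series_load <- cells$load[(perm - 1L) %% n_cells + 1L]
  series_base <- cells$amount[(perm - 1L) %% n_cells + 1L]

  ids <- seq_len(n)
  participants <- data.frame(participant_id = ids, part_mat,
                             no_headphones = excl_mat[, 1],
                             incomplete_discounting = excl_mat[, 2])
  latents <- data.frame(participant_id = ids, lat_mat,
                        seeker_wm = seek_mat[, 1], seeker_speech = seek_mat[, 2])
  truth <- data.frame(participant_id = rep(ids, each = 6),
                      domain = rep(rep(domains, each = 3), n),
                      load = rep(loads, 2 * n),
                      sv_true = as.vector(t(truth_mat)))
  performance <- data.frame(participant_id = rep(ids, each = 8),
                            domain = rep(rep(domains, each = 4), n),
                            level = rep(1:4, 2 * n),
                            snr = rep(c(rep(NA_real_, 4), snr_by_level), n),
                            hit_rate = as.vector(t(cbind(hit_mat, matrix(NA_real_, n, 4)))),
                            cr_rate = as.vector(t(cbind(cr_mat, matrix(NA_real_, n, 4)))),
                            mean_rt = as.vector(t(cbind(rt_mat, matrix(NA_real_, n, 4)))),
                            intelligibility = as.vector(t(cbind(matrix(NA_real_, n, 4), intel_mat))))
  ratings <- data.frame(participant_id = rep(ids, each = n_rat),
                        domain = rep(rat_template$domain, n),
                        load = rep(rat_template$load, n),
                        scale = rep(rat_template$scale, n),
                        rating = as.vector(t(rat_mat)))
  choices <- data.frame(participant_id = rep(ids, each = n_ch),
                        domain = rep(rep(domains, each = n_cells * ntr), n),
                        load = rep(series_load, each = ntr),
                        base_amount = rep(series_base, each = ntr),
                        trial_index = rep(rep(seq_len(n_cells * ntr), 2), n),
                        offer_low = as.vector(t(sim$offer_low[perm, , drop = FALSE])),
                        offer_high = as.vector(t(sim$offer_high[perm, , drop = FALSE])),
                        choice = as.vector(t(sim$choice[perm, , drop = FALSE])))
  out <- list(config = config, participants = participants, latents = latents,
              truth = truth, performance = performance, ratings = ratings,
              choices = choices)
  class(out) <- "coged_cohort"
  out
}

#' @export
print.coged_cohort <- function(x, ...) {
  cat(sprintf("COG-ED synthetic cohort: %d participants, %d choice rows, seed %d\n",
              nrow(x$participants), nrow(x$choices), x$config$seed))
  invisible(x)
}

# vectorised titration staircase for a batch of cells. sv, base: vectors of
# cell true values and base amounts; un: uniforms, one column per trial.
# Uses the indifference-consistent utility gap so the downstream 0-2
# transform recovers sv as choice noise vanishes.
staircase_sim <- function(sv, base, temperature, n_trials, un) {
  m <- length(sv)
  offer_low <- offer_high <- matrix(NA_real_, m, n_trials)
  choice <- matrix(NA_character_, m, n_trials)
  p_high <- function(oh, ol) {
    gap <- utility_gap(sv, oh, ol)
    if (temperature == 0) as.numeric(gap > 0) else stats::plogis(gap / temperature)
  }
  offer_low[, 1] <- offer_high[, 1] <- base
  choice[, 1] <- ifelse(un[, 1] < p_high(base, base), "high", "low")
  side <- choice[, 1]
  titrated <- base
  for (k in seq_len(n_trials - 1L)) {
    step <- base / 2^k
    titrated <- titrated + ifelse(choice[, k] == side, -step, step)
    offer_low[, k + 1L] <- ifelse(side == "low", titrated, base)
    offer_high[, k + 1L] <- ifelse(side == "low", base, titrated)
    choice[, k + 1L] <- ifelse(un[, k + 1L] < p_high(offer_high[, k + 1L], offer_low[, k + 1L]),
                               "high", "low")
  }
  list(offer_low = offer_low, offer_high = offer_high, choice = choice,
       indifference_point = titrated, initial_choice = side)
}
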