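#' Write cohort tables to a directory
#'
#' Writes the plain-CSV schemas shared by simulated and real exports:
#' `participants.csv`, `choices.csv`, `ratings.csv`, `performance.csv` and
#' `truth.csv` (truth only when ground truth is available). Currency columns
#' are serialised with four decimal digits — offers are dyadic multiples of
#' the base amount (base / 2, base / 4, ...), so four digits round-trips the
#' staircase arithmetic exactly.
#'
#' @param cohort a `"coged_cohort"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  stopifnot(inherits(cohort, "coged_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ch <- cohort$choices
  ch$offer_low <- sprintf("%.4f", ch$offer_low)
  ch$offer_high <- sprintf("%.4f", ch$offer_high)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(ch, file.path(dir, "choices.csv"), row.names = FALSE)
  utils::write.csv(cohort$ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
  utils::write.csv(cohort$performance, file.path(dir, "performance.csv"), row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read cohort tables from a directory
#'
#' Inverse of [write_cohort_tables()]; numeric offer columns are restored
#' exactly (they are dyadic rationals within four decimal digits).
#'
#' @param dir directory containing the CSV tables.
#' @return `"coged_cohort"`-shaped list (without a config; `truth` present
#'   only if `truth.csv` exists).
#' @export
read_cohort_tables <- function(dir) {
  need <- c("participants.csv", "choices.csv", "ratings.csv", "performance.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss)) stop("missing tables in '", dir, "': ", paste(miss, collapse = ", "))
  ch <- utils::read.csv(file.path(dir, "choices.csv"))
  ch$offer_low <- as.numeric(ch$offer_low)
  ch$offer_high <- as.numeric(ch$offer_high)
  ch$base_amount <- as.numeric(ch$base_amount)
  out <- list(participants = utils::read.csv(file.path(dir, "participants.csv")),
              choices = ch,
              ratings = utils::read.csv(file.path(dir, "ratings.csv")),
              performance = utils::read.csv(file.path(dir, "performance.csv")))
  tr <- file.path(dir, "truth.csv")
  if (file.exists(tr)) out$truth <- utils::read.csv(tr)
  class(out) <- "coged_cohort"
  out
}

#' Validate cohort tables
#'
#' Schema, range and cross-file consistency checks: required columns;
#' subjective values in [0, 2] where present; ratings in [1, 21]; SNR in
#' {0, -4, -8, -12}; familiarization levels in 1..4 and choice loads in
#' 1..3; every participant id in the choices / ratings tables must appear in
#' the participants table. Violations are collected, not thrown.
#'
#' @param cohort `"coged_cohort"` or list of tables as from
#'   [read_cohort_tables()].
#' @return data frame of violations (`table`, `row`, `column`, `problem`);
#'   zero rows when clean.
#' @export
validate_tables <- function(cohort) {
  v <- list()
  note <- function(table, row, column, problem)
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row, column = column,
                                       problem = problem)
  req <- list(
    participants = c("participant_id", "lspan", "ospan", "symspan", "bas", "grapes",
                     "spsrq", "ncs", "no_headphones", "incomplete_discounting"),
    choices = c("participant_id", "domain", "load", "base_amount", "trial_index",
                "offer_low", "offer_high", "choice"),
    ratings = c("participant_id", "domain", "load", "scale", "rating"),
    performance = c("participant_id", "domain", "level", "snr", "hit_rate",
                    "cr_rate", "mean_rt", "intelligibility"))
  for (tb in names(req)) {
    if (is.null(cohort[[tb]])) { note(tb, NA, NA, "table missing"); next }
    for (col in setdiff(req[[tb]], names(cohort[[tb]])))
      note(tb, NA, col, "column missing")
  }
  chk <- function(tb, col, bad, problem) {
    for (i in which(bad)) note(tb, i, col, problem)
  }
  if (!is.null(cohort$ratings) && "rating" %in% names(cohort$ratings))
    chk("ratings", "rating",
        cohort$ratings$rating < 1 | cohort$ratings$rating > 21,
        "rating outside [1, 21]")
  if (!is.null(cohort$performance) && "snr" %in% names(cohort$performance))
    chk("performance", "snr",
        !is.na(cohort$performance$snr) & !cohort$performance$snr %in% c(0, -4, -8, -12),
        "SNR not in {0, -4, -8, -12}")
  if (!is.null(cohort$performance) && "level" %in% names(cohort$performance))
    chk("performance", "level", !cohort$performance$level %in% 1:4,
        "level not in 1..4")
  if (!is.null(cohort$choices)) {
    ch <- cohort$choices
    if ("load" %in% names(ch)) chk("choices", "load", !ch$load %in% 1:3, "load not in 1..3")
    if ("choice" %in% names(ch))
      chk("choices", "choice", !ch$choice %in% c("low", "high"), "choice not low/high")
    if (all(c("offer_low", "offer_high") %in% names(ch)))
      chk("choices", "offer_low", ch$offer_low < 0 | ch$offer_high < 0, "negative offer")
    if (!is.null(cohort$participants) &&
        all(c("participant_id") %in% names(cohort$participants))) {
      orphan <- !ch$participant_id %in% cohort$participants$participant_id
      chk("choices", "participant_id", orphan, "participant missing from participants table")
    }
  }
  if (!is.null(cohort$truth) && "sv_true" %in% names(cohort$truth))
    chk("truth", "sv_true", cohort$truth$sv_true < 0 | cohort$truth$sv_true > 2,
        "sv_true outside [0, 2]")
  if (length(v)) do.call(rbind, v)
  else data.frame(table = character(), row = integer(), column = character(),
                  problem = character())
}

#' Run the full discounting analysis pipeline
#'
#' Orchestrates the whole analysis on a cohort: exclusions, scoring, the
#' pooled load x domain model, the three-stage correlational test of
#' domain-general cognitive motivation (zero-order; residualised for load
#' and performance; partial, additionally controlling the capacity and
#' reward-sensitivity composites), per-load paired domain contrasts,
#' workload-rating models, and exploratory need-for-cognition correlations.
#' Both the primary sample and the effort-seeker sensitivity sample are
#' analysed. All randomness lives in the cohort generation; given a cohort,
#' the pipeline is deterministic.
#'
#' @param cohort a `"coged_cohort"` (simulated or read from tables).
#' @param prior [correlation_prior()] for all correlation tests.
#' @param out_dir optional directory; when given, tables and a JSON report
#'   are written there.
#' @param include_design optionally a [sequential_design_config()] to run a
#'   design analysis alongside; `NULL` to skip.
#' @return `"coged_report"`: nested list with `exclusions`, `mean_sv`,
#'   `load_domain_model`, `h1_zero_order`, `h2_residualized`, `h3_partial`,
#'   `domain_contrasts`, `ratings_models`, `ncs_exploratory`, `sensitivity`
#'   (the same correlation blocks after dropping effort seekers), and
#'   `design` (if requested).
#' @export
run_pipeline <- function(cohort, prior = correlation_prior(), out_dir = NULL,
                         include_design = NULL) {
  stopifnot(inherits(cohort, "coged_cohort"))
  viol <- validate_tables(cohort)
  if (nrow(viol))
    stop("schema violations: ", paste(utils::head(
      sprintf("%s[%s].%s: %s", viol$table, viol$row, viol$column, viol$problem), 5),
      collapse = "; "))

  sv_all <- score_choices(cohort$choices)
  msv_all <- summarise_mean_sv(sv_all)
  grand <- tapply(msv_all$mean_sv, msv_all$participant_id, mean)
  excl <- apply_exclusions(cohort$participants, mean_sv_grand = grand, "primary")
  keep <- excl$retained$participant_id

  analyse <- function(ids) {
    sv <- sv_all[sv_all$participant_id %in% ids, ]
    msv <- msv_all[msv_all$participant_id %in% ids, ]
    wide <- merge(msv[msv$domain == "working_memory", c("participant_id", "mean_sv")],
                  msv[msv$domain == "speech", c("participant_id", "mean_sv")],
                  by = "participant_id", suffixes = c("_wm", "_speech"))
    perf <- cohort$performance[cohort$performance$participant_id %in% ids, ]

    h1 <- bayes_correlation(wide$mean_sv_wm, wide$mean_sv_speech, prior = prior)
    res_wm <- residualize_domain(sv[sv$domain == "working_memory", ], perf)
    res_sp <- residualize_domain(sv[sv$domain == "speech", ], perf)
    res <- merge(res_wm[, c("participant_id", "mean_residual")],
                 res_sp[, c("participant_id", "mean_residual")],
                 by = "participant_id", suffixes = c("_wm", "_speech"))
    h2 <- bayes_correlation(res$mean_residual_wm, res$mean_residual_speech, prior = prior)
    comp <- build_composites(cohort$participants[cohort$participants$participant_id %in% ids, ])
    comp <- comp[match(res$participant_id, comp$participant_id), ]
    h3 <- bayes_partial_correlation(res$mean_residual_wm, res$mean_residual_speech,
                                    comp[, c("wm_capacity", "reward_sensitivity")],
                                    prior = prior)
    contrasts <- lapply(1:3, function(l) {
      cellm <- stats::aggregate(sv$sv, by = list(participant_id = sv$participant_id,
                                                 domain = sv$domain, load = sv$load), mean)
      cl <- cellm[cellm$load == l, ]
      w <- merge(cl[cl$domain == "working_memory", c("participant_id", "x")],
                 cl[cl$domain == "speech", c("participant_id", "x")],
                 by = "participant_id", suffixes = c("_wm", "_speech"))
      paired_t_bf(w$x_speech - w$x_wm)
    })
    names(contrasts) <- paste0("load_", 1:3)
    parts <- cohort$participants[match(wide$participant_id, cohort$participants$participant_id), ]
    ncs <- list(
      working_memory = bayes_correlation(parts$ncs, wide$mean_sv_wm, prior = prior),
      speech = bayes_correlation(parts$ncs, wide$mean_sv_speech, prior = prior),
      composite = bayes_correlation(parts$ncs, (wide$mean_sv_wm + wide$mean_sv_speech) / 2,
                                    prior = prior))
    list(n = nrow(wide), h1_zero_order = h1, h2_residualized = h2, h3_partial = h3,
         residuals = res, mean_sv_wide = wide, domain_contrasts = contrasts,
         ncs_exploratory = ncs,
         residual_fits = list(working_memory = attr(res_wm, "fit"),
                              speech = attr(res_sp, "fit")))
  }

  primary <- analyse(keep)
  seekers <- names(grand)[grand > 1]
  sens_ids <- setdiff(keep, as.numeric(seekers))
  sensitivity <- analyse(sens_ids)

  sv_keep <- sv_all[sv_all$participant_id %in% keep, ]
  sv_keep$domain <- factor(sv_keep$domain)
  pooled <- fit_effort_model(sv_keep, "sv", c("load", "domain", "load:domain"))
  rat <- cohort$ratings[cohort$ratings$participant_id %in% keep, ]
  ratings_models <- fit_ratings_models(rat)

  design <- if (!is.null(include_design)) simulate_sequential(include_design) else NULL

  report <- list(exclusions = excl$report,
                 n_retained = length(keep),
                 mean_sv = msv_all,
                 load_domain_model = pooled,
                 primary = primary,
                 sensitivity = sensitivity,
                 ratings_models = ratings_models,
                 design = design,
                 prior = list(family = prior$family, width = prior$width),
                 seed = cohort$config$seed)
  class(report) <- "coged_report"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort_tables(cohort, out_dir)
    utils::write.csv(sv_all, file.path(out_dir, "sv_scores.csv"), row.names = FALSE)
    utils::write.csv(rbind(primary$residuals), file.path(out_dir, "residuals.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_to_json(report), file.path(out_dir, "analysis_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  report
}

# plain-list view of a report for JSON serialisation
report_to_json <- function(report) {
  corr <- function(x) list(r_median = x$r_median, ci95 = x$ci95, bf10 = x$bf10,
                           n = x$n, n_effective = x$n_effective, prior = x$prior)
  contr <- function(x) list(t = x$t_statistic, df = x$df, ci95 = x$ci95, bf10 = x$bf10)
  fitj <- function(f) list(coefficients = f$coefficients, ranef_var = f$ranef_var,
                           r2 = f$r2)
  block <- function(b) list(n = b$n,
                            h1_zero_order = corr(b$h1_zero_order),
                            h2_residualized = corr(b$h2_residualized),
                            h3_partial = corr(b$h3_partial),
                            domain_contrasts = lapply(b$domain_contrasts, contr),
                            ncs_exploratory = lapply(b$ncs_exploratory, corr))
  out <- list(
    seed = report$seed,
    prior = report$prior,
    exclusions = list(counts = as.list(report$exclusions$counts),
                      n_input = report$exclusions$n_input,
                      n_retained = report$exclusions$n_retained),
    load_domain_model = fitj(report$load_domain_model),
    primary = block(report$primary),
    sensitivity = block(report$sensitivity),
    ratings_models = lapply(report$ratings_models, fitj))
  if (!is.null(report$design))
    out$design <- list(proportions = as.list(report$design$proportions),
                       median_n_H1 = report$design$median_n_H1,
                       median_n_H0 = report$design$median_n_H0)
  out
}

#' @export
print.coged_report <- function(x, ...) {
  cat(sprintf("COG-ED analysis report (n retained = %d of %d)\n",
              x$exclusions$n_retained, x$exclusions$n_input))
  cat("Primary sample:\n  H1 zero-order:  "); print(x$primary$h1_zero_order)
  cat("  H2 residualized: "); print(x$primary$h2_residualized)
  cat("  H3 partial:      "); print(x$primary$h3_partial)
  cat(sprintf("Sensitivity sample (effort seekers dropped, n = %d):\n  H1: ",
              x$sensitivity$n))
  print(x$sensitivity$h1_zero_order)
  invisible(x)
}
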