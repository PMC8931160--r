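#' Convert an indifference point to a subjective value
#'
#' For participants who initially chose the low-effort option (the low side
#' was titrated), the subjective value of the high-effort task is the
#' indifference point divided by the base amount, in `[0, 1]`. For
#' participants who initially chose the high-effort option (the high side
#' was titrated), it is `1 + (base - ip) / base`, in `[1, 2]`; values above 1
#' indicate a preference for the harder task. Both branches give 1 at
#' `ip = base`.
#'
#' @param indifference_point titrated offer at the end of the series.
#' @param base_amount base (fixed) offer.
#' @param initial_choice `"low"` or `"high"` (trial-1 choice). Vectorised.
#' @return subjective value in `[0, 2]`.
#' @export
indifference_to_sv <- function(indifference_point, base_amount, initial_choice) {
  if (any(indifference_point < -1e-9 | indifference_point > base_amount + 1e-9))
    stop("indifference point outside [0, base_amount]")
  if (!all(initial_choice %in% c("low", "high")))
    stop("'initial_choice' must be 'low' or 'high'")
  ifelse(initial_choice == "low",
         indifference_point / base_amount,
         1 + (base_amount - indifference_point) / base_amount)
}

#' Mean subjective value over the condition grid
#'
#' Average of one participant x domain's subjective values over the 9
#' (3 loads x 3 amounts) cells. Missing or duplicated cells are an error,
#' never silently imputed.
#'
#' @param sv numeric vector of cell subjective values.
#' @param load,amount cell labels, same length as `sv`.
#' @param n_cells expected number of cells (default 9).
#' @return arithmetic mean.
#' @export
mean_sv <- function(sv, load, amount, n_cells = 9L) {
  if (length(sv) != n_cells)
    stop("completeness error: expected ", n_cells, " cells, got ", length(sv))
  key <- paste(load, amount)
  if (anyDuplicated(key)) stop("completeness error: duplicated cells ",
                               paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(!is.finite(sv))) stop("completeness error: non-finite subjective values")
  mean(sv)
}

#' Keyword intelligibility score for one sentence
#'
#' Proportion of a sentence's key words that a typed response reproduces.
#' Matching is by exact token equality after lower-casing and stripping
#' punctuation; each key word is credited at most once (a repeated key word
#' must be typed as often as it is listed).
#'
#' @param typed_response character scalar, the participant's transcription.
#' @param keywords character vector of key words (4 in the standard task).
#' @return proportion in `[0, 1]`, a multiple of `1/length(keywords)`.
#' @examples
#' keyword_intelligibility("the DOG ran.", c("dog", "ran", "park", "big")) # 0.5
#' @export
keyword_intelligibility <- function(typed_response, keywords) {
  if (length(keywords) == 0L) stop("empty keyword list")
  normalise <- function(s) {
    s <- tolower(s)
    s <- gsub("[[:punct:]]", " ", s)
    strsplit(trimws(s), "[[:space:]]+")[[1]]
  }
  tokens <- if (is.na(typed_response) || !nzchar(trimws(typed_response)))
    character(0) else normalise(typed_response)
  hits <- 0L
  for (kw in tolower(gsub("[[:punct:]]", "", keywords))) {
    j <- match(kw, tokens)
    if (!is.na(j)) {
      hits <- hits + 1L
      tokens <- tokens[-j]
    }
  }
  hits / length(keywords)
}

#' Working-memory capacity and reward-sensitivity composites
#'
#' Sums of z-scores: the capacity composite adds the z-scored totals of the
#' three span tasks (L-span, O-span, Sym-span); the reward-sensitivity
#' composite adds the z-scored BAS total, GRAPES reward expectancy and SPSRQ
#' reward sensitivity. Standardisation uses the supplied (analyzed) sample's
#' mean and SD, so composites are invariant to affine rescaling of any raw
#' component.
#'
#' @param participants data frame with columns `lspan`, `ospan`, `symspan`,
#'   `bas`, `grapes`, `spsrq` (no missing values).
#' @return data frame with `participant_id` (if present), `wm_capacity`,
#'   `reward_sensitivity`.
#' @export
build_composites <- function(participants) {
  span_cols <- c("lspan", "ospan", "symspan")
  rew_cols <- c("bas", "grapes", "spsrq")
  for (col in c(span_cols, rew_cols)) {
    if (!col %in% names(participants)) stop("missing component column '", col, "'")
    v <- participants[[col]]
    if (any(!is.finite(v))) stop("missing values in component '", col, "'")
    if (stats::sd(v) == 0) stop("zero variance in component '", col, "'")
  }
  z <- function(v) (v - mean(v)) / stats::sd(v)
  out <- data.frame(
    wm_capacity = rowSums(sapply(span_cols, function(c) z(participants[[c]]))),
    reward_sensitivity = rowSums(sapply(rew_cols, function(c) z(participants[[c]])))
  )
  if ("participant_id" %in% names(participants))
    out <- cbind(participant_id = participants$participant_id, out)
  out
}

#' Apply the study's exclusion rules
#'
#' Primary exclusions drop participants who reported not using headphones
#' during the speech task or did not complete all parts of both discounting
#' tasks. The sensitivity mode additionally drops effort seekers, defined as
#' a grand-mean subjective value above 1 across all conditions of both
#' domains; that flag is reported in both modes but only acted on in the
#' sensitivity re-analysis, mirroring the study's reporting of results with
#' and without those participants.
#'
#' @param participants data frame with `participant_id`, logical
#'   `no_headphones` and `incomplete_discounting` columns.
#' @param mean_sv_grand named numeric vector of grand-mean subjective values
#'   (names = participant ids), used for the effort-seeker flag; may be
#'   `NULL` when scores are unavailable (flag then FALSE).
#' @param sensitivity_mode `"primary"` or `"drop_effort_seekers"`.
#' @return list with `retained` (data frame of retained participants) and
#'   `report` (per-participant flags, counts per flag, retained n, dropped
#'   ids with reasons).
#' @export
apply_exclusions <- function(participants, mean_sv_grand = NULL,
                             sensitivity_mode = c("primary", "drop_effort_seekers")) {
  sensitivity_mode <- match.arg(sensitivity_mode)
  stopifnot(all(c("participant_id", "no_headphones", "incomplete_discounting") %in%
                  names(participants)))
  seeker <- rep(FALSE, nrow(participants))
  if (!is.null(mean_sv_grand)) {
    idx <- match(participants$participant_id, names(mean_sv_grand))
    seeker <- !is.na(idx) & mean_sv_grand[idx] > 1
  }
  flags <- data.frame(
    participant_id = participants$participant_id,
    no_headphones = as.logical(participants$no_headphones),
    incomplete_discounting = as.logical(participants$incomplete_discounting),
    effort_seeker_mean_sv_gt_1 = as.logical(seeker)
  )
  drop <- flags$no_headphones | flags$incomplete_discounting
  if (sensitivity_mode == "drop_effort_seekers") drop <- drop | flags$effort_seeker_mean_sv_gt_1
  reasons <- apply(flags[, -1, drop = FALSE], 1, function(f) {
    r <- names(f)[f]
    if (sensitivity_mode == "primary")
      r <- setdiff(r, "effort_seeker_mean_sv_gt_1")
    paste(r, collapse = "+")
  })
  report <- list(
    flags = flags,
    counts = c(no_headphones = sum(flags$no_headphones),
               incomplete_discounting = sum(flags$incomplete_discounting),
               effort_seeker_mean_sv_gt_1 = sum(flags$effort_seeker_mean_sv_gt_1)),
    mode = sensitivity_mode,
    n_input = nrow(participants),
    n_retained = sum(!drop),
    dropped = data.frame(participant_id = flags$participant_id[drop],
                         reason = reasons[drop])
  )
  list(retained = participants[!drop, , drop = FALSE], report = report)
}

#' Score a table of choice logs into subjective values
#'
#' Groups `choices` rows by participant x domain x load x amount, replays
#' each titration series through [replay_titration()] and converts the
#' resulting indifference points with [indifference_to_sv()].
#'
#' @param choices data frame in the `choices.csv` schema: `participant_id`,
#'   `domain`, `load`, `base_amount`, `trial_index`, `offer_low`,
#'   `offer_high`, `choice`.
#' @return data frame with one row per cell: `participant_id`, `domain`,
#'   `load`, `base_amount`, `initial_choice`, `indifference_point`, `sv`.
#' @export
score_choices <- function(choices) {
  req <- c("participant_id", "domain", "load", "base_amount", "trial_index",
           "offer_low", "offer_high", "choice")
  miss <- setdiff(req, names(choices))
  if (length(miss)) stop("choices table missing columns: ", paste(miss, collapse = ", "))
  ord <- order(choices$participant_id, choices$domain, choices$load,
               choices$base_amount, choices$trial_index)
  ch <- choices[ord, , drop = FALSE]
  key <- paste(ch$participant_id, ch$domain, ch$load, ch$base_amount)
  sizes <- rle(key)$lengths
  if (length(unique(sizes)) != 1L)
    stop("validation error: unequal trial counts across cells")
  ntr <- sizes[1]
  first <- seq(1, nrow(ch), by = ntr)
  base <- ch$base_amount[first]
  # vectorised replay of every staircase at once; same rules as
  # replay_titration, which remains the single-series reference path
  ol <- matrix(ch$offer_low, ncol = ntr, byrow = TRUE)
  oh <- matrix(ch$offer_high, ncol = ntr, byrow = TRUE)
  cc <- matrix(ch$choice, ncol = ntr, byrow = TRUE)
  tol <- 1e-9
  bad <- which(abs(ol[, 1] - base) > tol | abs(oh[, 1] - base) > tol)
  if (length(bad))
    stop("validation error at trial 1 of cell ", bad[1],
         ": offers must both equal the base amount")
  if (!all(cc %in% c("low", "high")))
    stop("validation error: choices must be 'low' or 'high'")
  side <- cc[, 1]
  titrated <- base
  for (k in seq_len(ntr - 1L)) {
    step <- base / 2^k
    titrated <- titrated + ifelse(cc[, k] == side, -step, step)
    fixed_ok <- abs(ifelse(side == "low", oh[, k + 1L], ol[, k + 1L]) - base) <= tol
    titr_ok <- abs(ifelse(side == "low", ol[, k + 1L], oh[, k + 1L]) - titrated) <= tol
    bad <- which(!(fixed_ok & titr_ok))
    if (length(bad))
      stop("validation error at trial ", k + 1L, " of cell ", bad[1],
           ": offer sequence violates the step schedule")
  }
  out <- data.frame(participant_id = ch$participant_id[first],
                    domain = ch$domain[first],
                    load = ch$load[first],
                    base_amount = base,
                    initial_choice = side,
                    indifference_point = titrated,
                    sv = indifference_to_sv(titrated, base, side))
  rownames(out) <- NULL
  out
}

#' Per-participant, per-domain mean subjective values
#'
#' @param sv_scores output of [score_choices()].
#' @return data frame `participant_id`, `domain`, `mean_sv` (each mean taken
#'   over the complete 9-cell grid via [mean_sv()]).
#' @export
summarise_mean_sv <- function(sv_scores) {
  key <- interaction(sv_scores$participant_id, sv_scores$domain, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(sv_scores)), key), function(idx) {
    g <- sv_scores[idx, ]
    data.frame(participant_id = g$participant_id[1], domain = g$domain[1],
               mean_sv = mean_sv(g$sv, g$load, g$base_amount))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$domain), ]
}
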