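#' Define one offer cell of the discounting phase
#'
#' A cell is one high-effort task level paired with one base reward amount.
#' Load levels index the high-effort options (working memory: 2-, 3-, 4-back;
#' speech: -4, -8, -12 dB SNR), always contrasted against the easiest level
#' (1-back / 0 dB) at a fixed offer.
#'
#' @param domain `"working_memory"` or `"speech"`.
#' @param load high-effort level index, 1, 2 or 3.
#' @param base_amount base offer in dollars, one of 2, 3, 4 by default
#'   (any positive amount is accepted).
#' @return `"coged_offer_cell"` list.
#' @export
offer_cell <- function(domain = c("working_memory", "speech"), load, base_amount) {
  domain <- match.arg(domain)
  if (!load %in% 1:3) stop("'load' must be 1, 2 or 3")
  if (!is.numeric(base_amount) || base_amount <= 0) stop("'base_amount' must be positive")
  structure(list(domain = domain, load = as.integer(load), base_amount = base_amount),
            class = "coged_offer_cell")
}

#' Schedule the decision trials of one domain
#'
#' Crosses the load levels with the base amounts and randomises the order of
#' the resulting cells; titration series run back-to-back within a cell, so
#' the interleaving is at the series level. The default 3 loads x 3 amounts
#' with 5 choices per cell gives the canonical 45 decision trials per domain.
#'
#' @param domain domain label passed to [offer_cell()].
#' @param loads integer vector of load levels.
#' @param amounts numeric vector of base amounts.
#' @param n_trials_per_cell choices per cell (default 5).
#' @return list with `cells` (randomised list of [offer_cell()]s) and
#'   `n_decision_trials`.
#' @export
schedule_trials <- function(domain = "working_memory", loads = 1:3, amounts = c(2, 3, 4),
                            n_trials_per_cell = 5L) {
  if (anyDuplicated(loads) || anyDuplicated(amounts))
    stop("duplicate load or amount levels")
  grid <- expand.grid(load = loads, amount = amounts)
  ord <- sample.int(nrow(grid))
  cells <- lapply(ord, function(i) offer_cell(domain, grid$load[i], grid$amount[i]))
  list(cells = cells, n_decision_trials = nrow(grid) * as.integer(n_trials_per_cell))
}

#' Run the titration staircase for one cell
#'
#' Trial 1 offers the base amount for both options; the option chosen on
#' trial 1 becomes the titrated side. After the choice on trial
#' `k` (`k = 1 .. n_trials_per_cell - 1`) the titrated offer moves by
#' `base_amount / 2^k`: down if the titrated option was just chosen, up
#' otherwise. The fixed side stays at the base amount throughout. The
#' indifference point is the titrated offer after the final adjustment,
#' i.e. the offer shown on the last trial; the last choice is recorded but
#' schedules no further adjustment.
#'
#' @param cell an [offer_cell()].
#' @param chooser `function(offer_low, offer_high)` returning `"low"` or
#'   `"high"`; must always return a choice.
#' @param n_trials_per_cell number of choices (default 5, i.e. 4 adjustments).
#' @return `"coged_titration"`: list with `cell`, `trials` (data frame with
#'   `trial_index`, `offer_low`, `offer_high`, `choice`), `titrated_side`,
#'   `initial_choice` and `indifference_point`.
#' @examples
#' avoider <- threshold_chooser(0.6) # values the hard task at 60%
#' run_titration(offer_cell("working_memory", 1, 2), avoider)
#' @export
run_titration <- function(cell, chooser, n_trials_per_cell = 5L) {
  stopifnot(inherits(cell, "coged_offer_cell"))
  n_trials_per_cell <- as.integer(n_trials_per_cell)
  if (n_trials_per_cell < 2L) stop("need at least 2 trials per cell")
  base <- cell$base_amount
  offers <- matrix(NA_real_, n_trials_per_cell, 2,
                   dimnames = list(NULL, c("low", "high")))
  choices <- character(n_trials_per_cell)
  offers[1, ] <- c(base, base)
  ch <- tryCatch(chooser(base, base),
                 error = function(e) stop("chooser failed on ", cell$domain,
                                          " load ", cell$load, " $", base, ": ",
                                          conditionMessage(e)))
  choices[1] <- match.arg(ch, c("low", "high"))
  side <- choices[1]
  titrated <- base
  for (k in seq_len(n_trials_per_cell - 1L)) {
    step <- base / 2^k
    titrated <- titrated + if (choices[k] == side) -step else step
    offers[k + 1L, ] <- if (side == "low") c(titrated, base) else c(base, titrated)
    ch <- tryCatch(chooser(offers[k + 1L, "low"], offers[k + 1L, "high"]),
                   error = function(e) stop("chooser failed on ", cell$domain,
                                            " load ", cell$load, " $", base, ": ",
                                            conditionMessage(e)))
    choices[k + 1L] <- match.arg(ch, c("low", "high"))
  }
  structure(list(
    cell = cell,
    trials = data.frame(trial_index = seq_len(n_trials_per_cell),
                        offer_low = offers[, "low"], offer_high = offers[, "high"],
                        choice = choices),
    titrated_side = side,
    initial_choice = choices[1],
    indifference_point = titrated
  ), class = "coged_titration")
}

#' Deterministic threshold chooser
#'
#' Agent that values performing the high-effort option at `sv_true` times its
#' offer and picks the better deal; exact ties go to the low-effort option
#' (conservative: never overstates effort seeking). For effort seekers
#' (`sv_true > 1`) the rule is the indifference-consistent mirror on the
#' low-effort side, so that the standard subjective-value transform recovers
#' `sv_true` on both branches (see [choice_policy()]).
#'
#' @param sv_true true subjective value in `[0, 2]`.
#' @return `function(offer_low, offer_high)` returning `"low"` or `"high"`.
#' @export
threshold_chooser <- function(sv_true) {
  force(sv_true)
  function(offer_low, offer_high) {
    if (utility_gap(sv_true, offer_high, offer_low) > 0) "high" else "low"
  }
}

# signed preference for the high-effort option; zero at indifference.
# sv <= 1: the hard task's pay is discounted by sv (titration of the low side
#   converges to sv * base). sv > 1: the easy task's pay is discounted by
#   (2 - sv) (titration of the high side converges to (2 - sv) * base), the
#   inverse of the 0-2 scoring transform for initial-high choosers.
utility_gap <- function(sv_true, offer_high, offer_low) {
  ifelse(sv_true <= 1,
         sv_true * offer_high - offer_low,
         offer_high - (2 - sv_true) * offer_low)
}

#' Stochastic choice rule over an offer pair
#'
#' Probability of choosing the high-effort option: logistic in the utility
#' difference `(sv_true * offer_high - offer_low) / temperature`, the choice
#' noise scale being expressed in offer currency. As `temperature -> 0` the
#' rule becomes the deterministic threshold choice.
#'
#' @param sv_true subjective value of the high-effort task in `[0, 2]`.
#' @param offer_high,offer_low positive offers.
#' @param temperature positive noise scale in currency units, or exactly 0
#'   for the deterministic limit.
#' @return probability of choosing the high-effort option (vectorised).
#' @export
choice_policy <- function(sv_true, offer_high, offer_low, temperature) {
  if (any(offer_high <= 0) || any(offer_low <= 0)) stop("offers must be positive")
  if (any(temperature < 0)) stop("'temperature' must be >= 0")
  gap <- sv_true * offer_high - offer_low
  ifelse(temperature == 0, as.numeric(gap > 0), stats::plogis(gap / temperature))
}

#' Re-score a logged titration series
#'
#' Validates that a choice log obeys the staircase rules (equal offers at the
#' base amount on trial 1, fixed side constant, halving step schedule) and
#' recomputes the indifference point. Inconsistent logs raise an error naming
#' the first offending trial rather than being silently corrected.
#'
#' @param trials data frame with `trial_index`, `offer_low`, `offer_high`,
#'   `choice` rows of one cell, in order.
#' @param cell the [offer_cell()] the log belongs to.
#' @return `"coged_titration"` identical to the [run_titration()] output that
#'   produced the log.
#' @export
replay_titration <- function(trials, cell) {
  stopifnot(inherits(cell, "coged_offer_cell"))
  if (is.null(trials) || nrow(trials) == 0L) stop("no trials in log")
  trials <- trials[order(trials$trial_index), , drop = FALSE]
  n <- nrow(trials)
  base <- cell$base_amount
  tol <- 1e-9
  if (abs(trials$offer_low[1] - base) > tol || abs(trials$offer_high[1] - base) > tol)
    stop("validation error at trial 1: offers must both equal the base amount")
  if (!all(trials$choice %in% c("low", "high")))
    stop("validation error: choices must be 'low' or 'high'")
  side <- trials$choice[1]
  fixed_col <- if (side == "low") "offer_high" else "offer_low"
  titr_col <- if (side == "low") "offer_low" else "offer_high"
  titrated <- base
  for (k in seq_len(n - 1L)) {
    step <- base / 2^k
    titrated <- titrated + if (trials$choice[k] == side) -step else step
    if (abs(trials[[fixed_col]][k + 1L] - base) > tol)
      stop("validation error at trial ", k + 1L, ": fixed-side offer must stay at the base amount")
    if (abs(trials[[titr_col]][k + 1L] - titrated) > tol)
      stop("validation error at trial ", k + 1L, ": titrated offer violates the step schedule")
  }
  structure(list(cell = cell,
                 trials = data.frame(trial_index = seq_len(n),
                                     offer_low = trials$offer_low,
                                     offer_high = trials$offer_high,
                                     choice = trials$choice),
                 titrated_side = side,
                 initial_choice = side,
                 indifference_point = titrated),
            class = "coged_titration")
}
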