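#!/usr/bin/env Rscript
# Step 2: replay the titration logs and score subjective values.
#
# Reads the choice logs written by step 1, re-derives every indifference
# point from the staircase rules (tampered logs would fail loudly), converts
# them to the 0-2 subjective-value scale, and reports the exclusion
# bookkeeping for both analysis modes.

suppressPackageStartupMessages(library(coged))

cohort <- read_cohort_tables("results/cohort")
stopifnot(nrow(validate_tables(cohort)) == 0)

scores <- score_choices(cohort$choices)
write.csv(scores, "results/sv_scores.csv", row.names = FALSE)

msv <- summarise_mean_sv(scores)
grand <- tapply(msv$mean_sv, msv$participant_id, mean)
primary <- apply_exclusions(cohort$participants, grand, "primary")
sensitivity <- apply_exclusions(cohort$participants, grand, "drop_effort_seekers")

jsonlite::write_json(list(primary = primary$report[c("counts", "n_input", "n_retained")],
                          sensitivity = sensitivity$report[c("counts", "n_input", "n_retained")]),
                     "results/exclusions.json", auto_unbox = TRUE, pretty = TRUE)

by_dl <- aggregate(scores$sv, by = list(domain = scores$domain, load = scores$load), mean)
message("mean subjective value by domain and load:")
for (i in seq_len(nrow(by_dl)))
  message(sprintf("  %-15s load %d: %.3f", by_dl$domain[i], by_dl$load[i], by_dl$x[i]))
message(sprintf("retained %d / %d (primary); %d effort seeker(s) flagged",
                primary$report$n_retained, primary$report$n_input,
                primary$report$counts[["effort_seeker_mean_sv_gt_1"]]))
message("wrote results/sv_scores.csv, results/exclusions.json")
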