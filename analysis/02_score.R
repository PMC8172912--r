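#!/usr/bin/env Rscript

# Step 2 — score every session.
#
# Reads the program files written by 01_simulate.R through the validating
# parsers (exactly as coordinator-submitted files would be read), computes
# the trimmed consensus and SDI for every quantity, and adjudicates every
# registered laboratory.  Writes verdicts.csv and aggregates.csv under
# results/.

suppressPackageStartupMessages(library(cd4eqa))

submissions <- parse_submissions("results/program/submissions.csv")
manifest <- parse_panel_manifest("results/program/manifest.csv")
stopifnot(nrow(attr(submissions, "rejected")) == 0)

res <- score_program(submissions, manifest)
readr::write_csv(res$verdicts, "results/verdicts.csv", na = "")
readr::write_csv(res$aggregates, "results/aggregates.csv", na = "")
readr::write_csv(res$scores, "results/scores.csv", na = "")

n_out <- sum(res$aggregates$n_outliers)
message(sprintf("scored %d lab-sessions over %d consensus groups",
                nrow(res$verdicts), nrow(res$aggregates)))
message(sprintf("  outlier exclusions from the consensus: %d", n_out))
message(sprintf("  verdicts: %s",
                paste(sprintf("%s %d", names(table(res$verdicts$outcome)),
                              table(res$verdicts$outcome)), collapse = ", ")))
message("wrote results/{verdicts,aggregates,scores}.csv")
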