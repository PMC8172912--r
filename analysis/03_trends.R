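#!/usr/bin/env Rscript

# Step 3 — longitudinal participation, performance and error-phase trends.
#
# Produces the per-session summary, the session-by-instrument pass/fail
# table, the per-instrument failure-rate series and the phase distribution
# of the recorded errors, both for the simulated program and — as a
# cross-check of the trend arithmetic — reconstructed from the program's
# published session counts.

suppressPackageStartupMessages(library(cd4eqa))

verdicts <- readr::read_csv("results/verdicts.csv", show_col_types = FALSE)
errors <- parse_error_log("results/program/errors.csv")

ss <- summarize_session(verdicts)
it <- instrument_table(verdicts)
fr <- failure_rate_series(verdicts)
pd <- phase_distribution(errors)
readr::write_csv(ss, "results/session_summary.csv", na = "")
readr::write_csv(it, "results/instrument_table.csv", na = "")
readr::write_csv(fr, "results/failure_rate_series.csv", na = "")
readr::write_csv(pd, "results/phase_distribution.csv", na = "")

message("simulated program:")
message(sprintf("  participation: %s",
                paste(ss$n_registered, collapse = " ")))
message(sprintf("  fail %% among reporting: %s",
                paste(round_half_up(ss$pct_fail), collapse = " ")))
message(sprintf("  error phases: %s",
                paste(sprintf("%s %.1f%%", pd$phase, pd$pct), collapse = ", ")))

# published-counts reconstruction (exact arithmetic check of the trend layer)
pub <- counts_to_verdicts(cameroon_session_counts())
pub_ss <- summarize_session(pub)
readr::write_csv(pub_ss, "results/published_session_summary.csv", na = "")
message("published counts, reconstructed:")
message(sprintf("  fail %% among reporting: %s",
                paste(round_half_up(pub_ss$pct_fail), collapse = " ")))
message("wrote results/{session_summary,instrument_table,failure_rate_series,phase_distribution,published_session_summary}.csv")
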