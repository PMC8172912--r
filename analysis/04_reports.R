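#!/usr/bin/env Rscript

# Step 4 — coordinator and laboratory reports.
#
# Renders the coordinator report for every session and the individual
# laboratory reports for the final session, each as structured JSON plus a
# plain-text rendering, under results/reports/.

suppressPackageStartupMessages(library(cd4eqa))

submissions <- parse_submissions("results/program/submissions.csv")
manifest <- parse_panel_manifest("results/program/manifest.csv")
errors <- parse_error_log("results/program/errors.csv")

res <- score_program(submissions, manifest)
for (sid in names(res$sessions)) {
  write_report(render_coordinator_report(res$sessions[[sid]], errors),
               "results/reports")
}
last <- res$sessions[[length(res$sessions)]]
for (k in seq_len(nrow(last$verdicts))) {
  write_report(render_lab_report(last$verdicts[k, ], last$scores, errors),
               "results/reports")
}
message(sprintf("wrote %d coordinator reports and %d laboratory reports to results/reports/",
                length(res$sessions), nrow(last$verdicts)))
message("sample (final session):")
message(paste(utils::head(format(render_coordinator_report(last, errors)), 12),
              collapse = "\n"))
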