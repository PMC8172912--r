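#!/usr/bin/env Rscript

# Step 1 — generate the synthetic national EQA program.
#
# The raw submissions of the Cameroon program are not public, so the whole
# analysis runs on a synthetic program with known ground truth whose
# registrant schedule, instrument mix, unable-to-report rates and declining
# error pressure are anchored to the program's published session counts
# (see cameroon_program_config()).  Writes the program input files under
# results/program/.

suppressPackageStartupMessages(library(cd4eqa))

cfg <- cameroon_program_config(seed = 48)
program <- generate_program(cfg)
write_program(program, "results/program")

message(sprintf("generated %d sessions, %d lab-session registrations",
                cfg$n_sessions, nrow(program$ground_truth)))
message(sprintf("  reporting: %d   unable to report: %d",
                sum(!program$ground_truth$unable),
                sum(program$ground_truth$unable)))
message(sprintf("  injected errors: %d (%s)", nrow(program$errors),
                paste(sprintf("%s %d", phase_distribution(program$errors)$phase,
                              phase_distribution(program$errors)$n),
                      collapse = ", ")))
message("wrote results/program/{submissions,manifest,errors,ground_truth}.csv")
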