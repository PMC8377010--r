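#!/usr/bin/env Rscript

# Step 6: cohort-level reporting.
#
# Aggregates the per-patient call sets into the screening report:
# carrier fraction, per-class counts and percentages, substitution
# spectrum of the called SNVs, and the Pearson correlation of mutation
# count with age. Writes results/report/.

suppressMessages(library(sgrscreen))

in_dir <- "results/cohort"
calls_dir <- "results/calls"
out_dir <- "results/report"

meta <- read.delim(file.path(in_dir, "cohort.tsv"))
calls_by_patient <- lapply(meta$id, function(id)
  read.delim(file.path(calls_dir, paste0(id, ".tsv"))))
names(calls_by_patient) <- meta$id

report <- cohort_report(calls_by_patient, meta)
write_cohort_report(report, out_dir)
print(report)

cls <- report$classification$classes
for (i in seq_len(nrow(cls)))
  message(sprintf("  %-14s %3d (%.1f%%)", cls$class[i], cls$count[i],
                  cls$percent_1dp[i]))
if (!is.null(report$spectrum)) {
  message("substitution spectrum of called SNVs:")
  message(paste(sprintf("  %s %.1f%%", names(report$spectrum),
                        100 * report$spectrum), collapse = "\n"))
}
message("report written to ", out_dir)
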