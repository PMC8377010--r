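#!/usr/bin/env Rscript

# Step 5: exhaustive SNV space, selection statistics, and score
# enrichment.
#
# Enumerates all 3L possible SNVs of the coding sequence (L = 738 gives
# 2214), tabulates consequence classes, computes the neutral N/S
# expectation, the dN/dS of the cohort's called SNVs, and compares a
# synthetic deleteriousness score between called SNVs and the full space
# (unpaired two-sample t-test).

suppressMessages(library(sgrscreen))

in_dir <- "results/cohort"
calls_f <- "results/calls/all_calls.tsv"
out_dir <- "results/snv_space"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ref_genome <- read_fasta(file.path(in_dir, "reference.fa"))
cds <- read_cds_table(file.path(in_dir, "cds.tsv"), ref_genome)[[1L]]

space <- enumerate_snvs(cds)
write.table(space$records, file.path(out_dir, "snv_space.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("SNV space: ", nrow(space$records), " records over ",
        nchar(cds$cds_seq), " coding nt")
print(space$class_counts)
message(sprintf("expected (neutral) N/S ratio: %.3f",
                expected_ns_ratio(space)))

calls <- read.delim(calls_f)
snv_calls <- calls[nchar(calls$ref) == 1L & nchar(calls$alt) == 1L, ]
summary <- list(
  n_space = nrow(space$records),
  class_counts = as.list(space$class_counts),
  expected_ns_ratio = expected_ns_ratio(space))
if (any(snv_calls$consequence == "synonymous")) {
  summary$dnds <- observed_dnds(snv_calls, space)
  message(sprintf("observed dN/dS of %d called SNVs: %.2f (1 = neutral)",
                  nrow(snv_calls), summary$dnds))
} else {
  message("no synonymous call in this cohort; dN/dS undefined ",
          "(small-cohort outcome, see the methods vignette)")
}

# synthetic deleteriousness scores: observed calls vs the whole space
scored <- add_scores(space, synthetic_score_table(space, seed = 20L))
obs <- data.frame(cds_pos = genomic_to_cds_pos(cds, cds$chrom,
                                               snv_calls$pos),
                  alt = if (cds$strand == "+") snv_calls$alt
                        else vapply(snv_calls$alt, revcomp, character(1L)))
obs <- obs[!is.na(obs$cds_pos), ]
if (nrow(obs) >= 2L) {
  tt <- score_background_test(obs, scored)
  message(sprintf(
    "score comparison: mean(observed) = %.1f vs mean(space) = %.1f, t = %.2f, p = %.3g",
    tt$mean_obs, tt$mean_all, tt$t, tt$p_two_sided))
  summary$score_test <- tt
}
jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
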