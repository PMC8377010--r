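#!/usr/bin/env Rscript

# Step 2: ultra-deep somatic calling over the cohort.
#
# For every patient SAM from step 1: drop duplicate-flagged records, pile
# up the locus, call alleles with the exact binomial error model at the
# locus-capture regime (VAF >= 0.5%, >= 3 alt reads, Bonferroni over
# 3 x sites), mask the constitutional het SNP positions, and write one VCF
# and one TSV per patient plus a combined call table. Ends by comparing
# calls against the planted truth.

suppressMessages(library(sgrscreen))

in_dir <- "results/cohort"
out_dir <- "results/calls"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ref_genome <- read_fasta(file.path(in_dir, "reference.fa"))
cds <- read_cds_table(file.path(in_dir, "cds.tsv"), ref_genome)[[1L]]
truth <- read.delim(file.path(in_dir, "truth.tsv"))
meta <- read.delim(file.path(in_dir, "cohort.tsv"))
cfg <- caller_config("locus")

all_calls <- list()
for (id in meta$id) {
  sam <- read_sam(file.path(in_dir, paste0(id, ".sam")))
  snp_pos <- truth$pos[truth$patient == id & truth$kind == "het_snp"]
  calls <- call_patient(sam, ref_genome, cds, cfg,
                        exclude_positions = snp_pos)
  write_vcf(calls, ref_genome, file.path(out_dir, paste0(id, ".vcf")), id)
  write.table(calls, file.path(out_dir, paste0(id, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  all_calls[[id]] <- calls
}

combined <- do.call(rbind, lapply(names(all_calls), function(id) {
  x <- all_calls[[id]]
  if (nrow(x)) cbind(patient = id, x) else NULL
}))
write.table(combined, file.path(out_dir, "all_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# recovery against truth: callable = planted SNV/indel clones at VAF >= 2x
# the calling threshold (cell fraction >= 4 * vaf_min)
planted <- truth[truth$kind %in% c("snv", "indel"), ]
callable <- planted[planted$expected_vaf >= 2 * cfg$vaf_min, ]
hit <- mapply(function(p, pos) {
  any(all_calls[[p]]$pos == pos)
}, callable$patient, callable$pos)
message(sprintf("called %d variants across %d patients", nrow(combined),
                length(all_calls)))
message(sprintf("recovered %d / %d callable planted clones (%.1f%%)",
                sum(hit), nrow(callable), 100 * mean(hit)))
bias <- mapply(function(p, pos, ev) {
  v <- all_calls[[p]]$vaf[all_calls[[p]]$pos == pos]
  if (length(v)) v[1L] - ev else NA_real_
}, callable$patient, callable$pos, callable$expected_vaf)
message(sprintf("mean VAF bias on recovered clones: %+.4f",
                mean(bias, na.rm = TRUE)))
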