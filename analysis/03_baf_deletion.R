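#!/usr/bin/env Rscript

# Step 3: mosaic-deletion scan from B-allele frequencies.
#
# For every patient, computes the BAF of each constitutional heterozygous
# SNP from the deduplicated pileup, tests deviation from 0.5 with the
# exact binomial (Bonferroni over SNPs), segments runs of deviating SNPs,
# and estimates the affected cell fraction f = (1 - 2 BAF)/(1 - BAF).
# The cohort plants one deletion patient at f = 0.37.

suppressMessages(library(sgrscreen))

in_dir <- "results/cohort"
out_dir <- "results/baf"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ref_genome <- read_fasta(file.path(in_dir, "reference.fa"))
cds <- read_cds_table(file.path(in_dir, "cds.tsv"), ref_genome)[[1L]]
truth <- read.delim(file.path(in_dir, "truth.tsv"))
meta <- read.delim(file.path(in_dir, "cohort.tsv"))

seg_rows <- list()
snp_rows <- list()
for (id in meta$id) {
  sam <- read_sam(file.path(in_dir, paste0(id, ".sam")))
  snp_pos <- truth$pos[truth$patient == id & truth$kind == "het_snp"]
  scan <- baf_scan(sam, ref_genome, cds$chrom, snp_pos)
  if (nrow(scan$snps))
    snp_rows[[id]] <- cbind(patient = id, scan$snps)
  if (nrow(scan$segments))
    seg_rows[[id]] <- cbind(patient = id, scan$segments)
}
snps <- do.call(rbind, snp_rows)
segs <- do.call(rbind, seg_rows)
write.table(snps, file.path(out_dir, "snp_baf.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(segs, file.path(out_dir, "segments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("SNPs scanned: ", nrow(snps), " across ", length(snp_rows),
        " informative patients")
if (is.null(segs)) {
  message("no deviating segment detected")
} else {
  for (i in seq_len(nrow(segs)))
    message(sprintf(
      "%s: deviating segment %d-%d (%d SNPs), mean minor BAF %.3f, estimated cell fraction %.1f%%",
      segs$patient[i], segs$start[i], segs$end[i], segs$n_snps[i],
      segs$mean_minor_baf[i], 100 * segs$cell_fraction[i]))
  truth_del <- truth[truth$kind == "het_deletion", ]
  message(sprintf("planted deletion: %s at f = %.2f (expected BAF %.4f)",
                  truth_del$patient[1L], truth_del$cell_fraction[1L],
                  truth_del$expected_baf[1L]))
}
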