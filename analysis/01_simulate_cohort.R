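#!/usr/bin/env Rscript

# Step 1: build the synthetic study materials.
#
# Generates the two-chromosome reference with the embedded 738-nt,
# five-exon coding sequence, then a 14-patient locus-capture cohort
# (mean deduplicated depth 2807x) in which patient 1 additionally carries
# a mosaic heterozygous deletion of the locus (37% of cells) and patient 2
# a reciprocal translocation with one breakpoint in the last intron.
# Writes the reference FASTA, the CDS annotation, per-patient SAM files,
# and the truth/metadata tables under results/cohort/.

suppressMessages(library(sgrscreen))

seed <- 20L
out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ref <- simulate_reference(seed = seed)
write_fasta(ref$genome, file.path(out_dir, "reference.fa"))
write_cds_table(ref$cds, file.path(out_dir, "cds.tsv"))
message("reference: ", paste(names(ref$genome), collapse = ", "),
        "; CDS ", ref$cds$name, " with ", nchar(ref$cds$cds_seq),
        " coding nt (", nchar(ref$cds$protein), " aa)")

cspec <- cohort_spec(n_patients = 14L, depth_regime = "locus_capture",
                     seed = seed, include_deletion_patient = TRUE,
                     include_translocation_patient = TRUE)
cohort <- simulate_cohort(cspec, ref$genome, ref$cds)
write_cohort_tables(cohort, out_dir)

# the read-level truth additionally carries the constitutional het SNPs
# (with their expected BAFs), needed downstream to mask germline positions
truth_rows <- list()
for (sp in cohort$patients) {
  reads <- simulate_patient_reads(sp, ref$genome, ref$cds)
  write_sam(reads$sam, ref$genome,
            file.path(out_dir, paste0(sp$id, ".sam")))
  truth_rows[[sp$id]] <- reads$truth
}
truth <- do.call(rbind, truth_rows)
write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
n_events <- table(cohort$truth$kind)
message("cohort of ", length(cohort$patients), " patients written to ",
        out_dir)
message("planted events: ",
        paste(names(n_events), n_events, sep = "=", collapse = ", "))
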