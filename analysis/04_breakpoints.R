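#!/usr/bin/env Rscript

# Step 4: translocation breakpoint localization from chimeric reads.
#
# Runs the soft-clip endpoint extraction / positional clustering /
# mate-chromosome filtering chain on each patient, on both chromosomes
# with the other as partner, and reports retained windows. The cohort
# plants one reciprocal translocation patient with the locus-side
# breakpoint in the last intron of the coding sequence.

suppressMessages(library(sgrscreen))

in_dir <- "results/cohort"
out_dir <- "results/breakpoints"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ref_genome <- read_fasta(file.path(in_dir, "reference.fa"))
truth <- read.delim(file.path(in_dir, "truth.tsv"))
meta <- read.delim(file.path(in_dir, "cohort.tsv"))
chroms <- names(ref_genome)

rows <- list()
for (id in meta$id) {
  sam <- read_sam(file.path(in_dir, paste0(id, ".sam")))
  bp <- suppressMessages(
    locate_breakpoints(sam, chroms[1L], chroms[2L]))
  if (nrow(bp)) rows[[id]] <- cbind(patient = id, bp)
}
clusters <- do.call(rbind, rows)
write.table(clusters, file.path(out_dir, "clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ret <- clusters[clusters$retained, , drop = FALSE]
message(nrow(clusters), " soft-clip clusters across the cohort; ",
        nrow(ret), " retained after mate-chromosome filtering")
for (i in seq_len(nrow(ret)))
  message(sprintf(
    "%s: retained window %s:%d-%d, %d endpoints, %d inter-chromosomal mates",
    ret$patient[i], ret$chrom[i], ret$start[i], ret$end[i],
    ret$n_endpoints[i], ret$n_interchrom_mates[i]))
tl <- truth[truth$kind == "translocation", ]
if (nrow(tl))
  message(sprintf("planted junction: %s %s:%d <-> %s (cell fraction %.2f)",
                  tl$patient[1L], tl$chrom[1L], tl$pos[1L], tl$partner[1L],
                  tl$cell_fraction[1L]))
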