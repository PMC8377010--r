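# sgrscreen

Somatic genetic rescue screening from ultra-deep targeted sequencing.

In inherited bone marrow failure (e.g. Shwachman–Diamond syndrome),
hematopoietic clones can acquire somatic mutations that bypass the
germline defect and expand under positive selection. Detecting these
clones — point mutations down to 0.25% variant allele frequency (VAF),
mosaic heterozygous deletions, and reciprocal translocations — requires
ultra-deep sequencing of the rescue locus plus statistics that separate
sub-percent clones from sequencing error. `sgrscreen` is the complete
computational pipeline for such a screen, written for analysts working on
low-level somatic mosaicism, together with a synthetic-cohort read
simulator that makes every stage testable without access to restricted
patient data.

## What it computes

* **Low-VAF somatic calls.** After removing duplicate-flagged reads, each
  pileup site is tested per alternative allele: call iff
  `VAF >= vaf_min` (0.5% locus-capture mode, 0.25% cDNA-capture mode),
  `alt reads >= 3`, and the exact binomial tail
  `P(X >= k | depth, eps)` falls below `alpha / (3 * sites)`
  (Bonferroni; `eps = 1e-3` by default). A heterozygous clone in cell
  fraction `f` has expected VAF `f/2`. Calls are annotated (missense,
  nonsense, synonymous, start/stop-loss, frameshift, in-frame indel)
  with protein changes like `N106S`.
* **Mosaic deletions from BAF.** At constitutional het SNPs a deletion in
  fraction `f` of cells shifts the B-allele frequency to
  `(1 - f)/(2 - f)`; the scan tests each SNP against 0.5 (exact binomial,
  Bonferroni), segments runs of deviating SNPs, and inverts
  `f = (1 - 2 BAF)/(1 - BAF)`.
* **Translocation breakpoints from chimeric reads.** Soft-clipped reads'
  last aligned positions (start + lengths of `M, D, N, =, X` − 1) are
  clustered (book-ended merge) and clusters are retained iff their mate
  chromosomes are exactly `{same, partner}`.
* **SNV space and selection.** All `3L` SNVs of the coding sequence
  (`L = 738` → 2214 records) with consequence classes; count-based
  `dN/dS = (Nobs/Sobs) / (Npossible/Spossible)` (1 = neutral);
  deleteriousness-score enrichment versus the full space by unpaired
  t-test (scores are consumed as an external table).
* **Cohort reports.** Carrier fractions, classification percentages,
  pyrimidine-reference substitution spectrum, Pearson count–age
  correlation.

## Worked example

```r
library(sgrscreen)

ref <- simulate_reference(seed = 1)    # 2-chromosome genome, 738-nt CDS
p <- cds_to_genomic_pos(ref$cds, 317L)
sp <- patient_spec("P01", age = 20, events = list(
  snv_event(ref$cds$chrom, p,
            substring(ref$genome[[ref$cds$chrom]], p, p), "G",
            cell_fraction = 0.08)),
  mean_depth = 2807, het_snp_positions = c(1100L, 2100L), seed = 11)
reads <- simulate_patient_reads(sp, ref$genome, ref$cds)
call_patient(reads$sam, ref$genome, ref$cds, caller_config("locus"),
             exclude_positions = sp$het_snp_positions)
#>    chrom  pos ref alt alt_count depth        vaf       p_error consequence protein_change
#> 1 chr20S 1517   T   G       114  2602 0.04381245 5.984049e-142    missense          L106R
```

The planted clone (cell fraction 8%, expected VAF 4%) is recovered at an
estimated VAF of 4.4% at deduplicated depth 2602, with the binomial
error-model tail reported in `p_error`; its codon change is annotated
against the embedded coding sequence.

```r
space <- enumerate_snvs(ref$cds)
nrow(space$records)        #> 2214
expected_ns_ratio(space)   #> 3.169492  (possible nonsyn / possible syn)
```

## The analysis workflow

Numbered drivers under `analysis/` run the whole screen on a synthetic
14-patient locus-capture cohort (mean deduplicated depth 2807×, one
patient with a 37%-cell mosaic deletion, one with a reciprocal
translocation) and write tables under `results/`:

1. `01_simulate_cohort.R` — reference, cohort, per-patient SAM, truth.
2. `02_call_mutations.R` — dedup → pileup → binomial calling → VCF/TSV.
3. `03_baf_deletion.R` — BAF scan, deviation segments, cell fractions.
4. `04_breakpoints.R` — soft-clip clustering and mate filtering.
5. `05_snv_space_dnds.R` — SNV space, dN/dS, score comparison.
6. `06_cohort_report.R` — carrier fraction, classification, spectrum,
   count–age correlation.

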