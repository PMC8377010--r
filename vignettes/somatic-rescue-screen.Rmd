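---
title: "Screening for somatic genetic rescue by ultra-deep targeted sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for somatic genetic rescue by ultra-deep targeted sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgrscreen)
```

## The screening problem

In inherited bone marrow failure syndromes such as Shwachman–Diamond
syndrome (SDS), hematopoietic cells can acquire somatic mutations that
counteract the germline defect — *somatic genetic rescue*. Rescued clones
gain a selective advantage and expand, but most remain small: the cell
fractions of interest run from fractions of a percent to a few tens of
percent. Detecting them requires ultra-deep targeted sequencing of the
rescue locus (here, a 738-nt coding sequence, the length of human eIF6)
and statistical machinery that separates sub-percent clones from
sequencing error.

`sgrscreen` implements the full computational side of such a screen:

1. **Low-VAF somatic calling** from a duplicate-aware pileup with an exact
   binomial error model (`dedup()`, `pileup()`, `call_variants()`).
2. **Mosaic-deletion detection** from the B-allele frequency (BAF) of
   constitutional heterozygous SNPs, with cell-fraction estimation
   (`baf_scan()`, `estimate_cell_fraction()`).
3. **Translocation breakpoint localization** from soft-clipped chimeric
   reads (`locate_breakpoints()`).
4. **Exhaustive SNV-space enumeration** with consequence classification,
   count-based dN/dS, and deleteriousness-score background comparison
   (`enumerate_snvs()`, `observed_dnds()`, `score_background_test()`).
5. **Cohort reporting**: carrier fractions, classification percentages,
   substitution spectra, count–age correlation (`cohort_report()`).
6. A **synthetic-cohort generator** (`simulate_reference()`,
   `simulate_cohort()`, `simulate_patient_reads()`) that stands in for the
   restricted patient data and makes every stage testable end to end.

The numbered scripts under `analysis/` run these stages as a narrative
workflow and write their tables under `results/`.

## The calling model

At each reference position the deduplicated pileup yields a depth $n$ and
per-allele counts. Under the null, alternative-allele reads arise from a
uniform per-base error process with rate $\varepsilon$ (default $10^{-3}$),
so the alt count is Binomial$(n, \varepsilon)$. An allele with $k$
supporting reads is called iff

* $k/n \ge v_{\min}$ — the screening VAF threshold: $v_{\min} = 0.005$ in
  locus-capture mode (mean deduplicated depth ≈ 2807×) and $0.0025$ in
  cDNA-capture mode (≈ 26,873×);
* $k \ge$ `min_alt_reads` (default 3), suppressing singleton errors at
  extreme depth;
* the one-sided exact binomial tail $P(X \ge k \mid n, \varepsilon)$ is
  below $\alpha / (3 \cdot \text{sites})$ — Bonferroni over the three
  alternative alleles at every piled-up site. Bonferroni (not FDR) keeps
  the family-wise guarantee parameter-free and matches a screen defined by
  hard VAF cut-offs.

Because the synthetic generator's error process is uniform by
construction, the caller's null is *exactly* correct on simulated data;
the type-I suite verifies that the expected count of false calls per null
patient stays below $\alpha$. On real data the uniform-$\varepsilon$ null
is an idealization — context-specific error modes (e.g. oxidative damage
artifacts) would need a site-specific error model, which is out of scope.
A heterozygous somatic SNV present in a cell fraction $f$ has expected
VAF $f/2$; the recovery suite checks that clones with VAF $\ge 2 v_{\min}$
at depth $\ge 2000$ are recovered in at least 95% of simulations and that
the VAF estimate is unbiased.

Known constitutional variants (the het SNPs used by the BAF scan) present
as ~50% VAF calls and are masked via `exclude_positions` in
`call_patient()` — the screen counts somatic mutations only.

## BAF-based mosaic deletion detection

At a constitutional heterozygous SNP, a diploid sample has allele balance
0.5. If a fraction $f$ of cells loses one allele, the expected read
fraction of the deleted allele is

$$\mathrm{BAF} = \frac{1-f}{2-f}, \qquad \hat f = \frac{1-2\,\mathrm{BAF}}{1-\mathrm{BAF}},$$

the second expression being the exact inverse used by
`estimate_cell_fraction()` (a BAF of 0.3865 corresponds to 37% of cells).
Each SNP's deviation from 0.5 is tested with a two-sided exact binomial
test; SNPs deviate when $p < \alpha/n_{\text{SNPs}}$, and maximal runs of
at least `min_snps = 2` consecutive deviating SNPs with a consistent minor
allele form segments. The run rule is this package's explicit
operationalization of a "sharp BAF deviation"; the minor-allele
convention (`min(baf, 1 - baf)`) makes results invariant to which
haplotype the generator labels A or B.

Two caveats are deliberate. First, tightly spaced SNPs share covering
fragments, so their binomial noise is correlated and the run rule can
occasionally promote two same-direction fluctuations to a segment at high
depth (the analysis workflow shows one such borderline segment at
$\hat f \approx 0.09$); real screens confirm candidate deletions with
orthogonal assays, whose laboratory side is out of scope here. Second,
no multi-state segmentation (CBS/HMM) is attempted — the target is a
single small locus.

## Breakpoint localization from chimeric reads

Reads spanning a translocation junction align with a soft clip at the
breakpoint and often have mates on the partner chromosome. The chain is:

1. `extract_endpoints()`: keep mapped records with MAPQ ≥ 1 whose CIGAR
   contains `S`, and record the *last aligned position* — the alignment
   start plus the lengths of the reference-consuming operations
   `{M, D, N, =, X}` minus one. (A classical `awk` implementation of this
   step recognizes only `M` and `D`; the package consumes the full set
   because modern aligners may emit `=`/`X`, and the equivalence test uses
   M/D-only fixtures so both definitions agree.)
2. `cluster_endpoints()`: merge endpoints at most `max_gap = 1` apart —
   the book-ended merge semantics of merging adjacent single-base
   intervals with `bedtools merge -d 0`.
3. `filter_clusters()`: retain a cluster iff its distinct mate-chromosome
   set is exactly `{"=", partner}` — same-chromosome *and*
   partner-chromosome mates present, no third chromosome.

The clip side is recorded but not used for filtering. As a consequence,
reads whose *leading* bases are clipped (anchored on the far side of the
junction) produce a secondary, wider retained window downstream of the
true breakpoint; the primary windows in the test suite pinpoint the
junction to 1–3 bases, and interpretation of secondary windows is left to
the user, mirroring how such screens report both a clean and a "less
clear" breakpoint side.

## The SNV space and selection statistics

`enumerate_snvs()` produces all $3L$ single-nucleotide substitutions of an
$L$-nt CDS ($L = 738$ gives $n = 2214$) and classifies each against the
standard nuclear code: `synonymous`, `missense`, `nonsense`, `stop_loss`,
or `start_loss` (every substitution in the initiator codon). The
classifier is validated against a brute-force oracle that translates full
mutant CDS copies.

The neutral expectation is the possible-count ratio
$E = N_{\text{possible}}/S_{\text{possible}}$ over the space, and

$$\mathrm{dN/dS} = \frac{N_{\text{obs}}/S_{\text{obs}}}{E},$$

simple Nei–Gojobori-style site counting without transition/transversion
weighting. Nonsense, stop-loss and start-loss count as non-synonymous on
both sides, so a uniform draw from the space has dN/dS exactly 1; an
`exclude_start_loss` flag removes initiator-codon records from both sides
because published counts are sometimes ambiguous about M1 substitutions.
With observed class counts of 31 missense + 10 nonsense + 1 start-loss
versus 4 synonymous (an observed ratio of 10.5) and $E \approx 3.1$–3.2,
dN/dS lands at ≈ 3.3–3.4. Two sensitivities are documented rather than
hidden: the reference CDS here is a synthetic stand-in (below), and
count-based dN/dS ignores mutational-spectrum bias — a C>T-dominated
spectrum makes the effective neutral ratio differ slightly from the
unweighted $E$, which is why the neutral-cohort dN/dS in the analysis
workflow hovers near but not exactly at 1 for small call sets.

Deleteriousness scores are consumed as an external per-SNV table (4-column
TSV), never computed: `score_background_test()` compares observed variants
against the full space with an unpaired Student's t-test (equal variance
by default — the convention of the field's figure legends — Welch via
`welch = TRUE`). `synthetic_score_table()` provides a synthetic stand-in
whose class structure (truncating > missense > synonymous) mimics what any
deleteriousness predictor shows on a coding locus.

## What the synthetic cohort emulates — and what it does not

`simulate_reference()` builds a two-chromosome genome with an embedded
738-nt, five-exon CDS; interior codons are drawn uniformly from the 61
sense codons. The real rescue-locus CDS is not redistributable inside this
package, so the stand-in is *synthetic by design*; its expected N/S ratio
(≈ 3.10 ± 0.10 across seeds) matches the typical value of a human coding
sequence, and all space-level statistics are computed from the generated
sequence at run time, never hard-coded.

`simulate_cohort()` emulates the statistical structure of an SDS-like
screen:

* **Cohort**: default 26 patients; ages gamma-distributed (mean ≈ 15 y,
  clamped to 0.47–52.2 y).
* **Mutation counts**: Poisson with rate $1.6 + 0.065 \cdot \text{age}$,
  zero-inflated (20% of patients have no rescue propensity), reproducing a
  mean of ≈ 2 mutations/patient, a carrier fraction near two thirds, and a
  positive count–age correlation of $r \approx 0.4$.
* **Clone sizes**: VAFs log-uniform on [0.25%, 28%], so small clones
  dominate, as observed in clonal hematopoiesis.
* **Spectrum**: substitution classes drawn from a C>T-dominated spectrum
  (51.1% C>T, T>C second; `default_spectrum_weights()`), the signature of
  spontaneous cytosine deamination in blood.
* **Reads**: 130 + 130 bp pairs on 200 bp fragments; per-patient depths
  log-normal around 2807× (locus capture) or 26,873× (cDNA capture);
  uniform sequencing errors (default $10^{-3}$); PCR duplicates emitted
  with the SAM duplicate flag set (default rate 0.1 — the duplicate *rate*
  and error profile of real libraries are not published, so both are
  config-exposed); one patient with a mosaic heterozygous deletion (37% of
  cells) and one with a reciprocal translocation whose locus-side
  breakpoint falls in the last intron.

Haplotypes are explicit: het SNP alternate alleles ride on haplotype B,
deletions remove one haplotype's fragments, and junction fragments carry a
haplotype too, so BAF expectations hold exactly by construction.

Not emulated: base-quality variation, GC bias, indel sequencing errors,
strand-specific error modes, mapping ambiguity (reads are emitted
pre-aligned), and selection on specific residues. Passing tests therefore
demonstrate the *statistical machinery* under its stated assumptions, not
performance on real libraries. Somatic indels are injected only when the
event sits comfortably inside a read (a small edge bias the VAF-recovery
suite does not cover for indels), and reciprocal-translocation coverage
changes are modeled only through fragment thinning and junction fragments.

## Numerical choices and problem sizes

Master seeds spawn per-patient seeds by fixed arithmetic
(`seed + patient index`), so cohorts are reproducible stream by stream and
byte-identical for a fixed spec. Exact binomial tails are used throughout
(`pbinom`/`binom.test`) — depths span two orders of magnitude and the
normal approximation is unnecessary. Percentages in reports are rendered
to one decimal place (standard rounding) with raw fractions kept in
machine output. Degenerate inputs fail loudly: zero-depth SNPs, CDSs
without a start/stop, `N` bases in enumeration, missing scores, and
undefined dN/dS (no observed synonymous variant) are all errors, not
silent defaults.

The test suite runs its simulations at reduced but statistically adequate
sizes — null-calibration over 200 patients at depth 2000, recovery over
10–20 seeds per setting, breakpoint recovery over ~10 random junctions,
spectrum recovery at 2000 draws — chosen so every guarantee is checked
with meaningful power while the whole suite completes in minutes. The
acceptance script (`scripts/acceptance.R`) re-runs the pipeline at the
screening depths themselves (2807× end-to-end; one 26,873× patient for
the low-VAF regime).

## Design decisions that were genuinely open

* **Caller internals**: the published screen used GATK plus freebayes
  (`-F 0.0005`); this package substitutes a transparent binomial pileup
  caller because the screen's contribution is the *design* (dedup, depth,
  thresholds), not the caller internals, and a self-contained caller has
  an exact null on synthetic data.
* **Bonferroni over sites×3**, not FDR — matches hard-threshold screening
  semantics.
* **`min_alt_reads = 3`** and the absence of a strand-balance rule are
  config knobs with documented defaults; the published screen states
  neither.
* **MAPQ ≥ 1** everywhere, reusing the one mapping-quality filter the
  chimeric-read procedure specifies.
* **1-based inclusive coordinates** internally (SAM/VCF convention);
  BED-like interval files are 0-based half-open on disk and converted at
  the I/O boundary.
* **Assembly-agnostic**: no genome build is hard-coded anywhere; the
  coordinate frame is whatever reference is supplied.
* **Pearson p-values** use the standard t approximation
  ($t = r\sqrt{(n-2)/(1-r^2)}$, via `cor.test`).

## Worked example

```{r example, eval = FALSE}
library(sgrscreen)

ref <- simulate_reference(seed = 1)          # 738-nt CDS, two chromosomes
sp <- patient_spec("P01", age = 20, events = list(
  snv_event(ref$cds$chrom, cds_to_genomic_pos(ref$cds, 317L),
            substring(ref$genome[[ref$cds$chrom]],
                      cds_to_genomic_pos(ref$cds, 317L),
                      cds_to_genomic_pos(ref$cds, 317L)),
            "G", cell_fraction = 0.08)),
  mean_depth = 2807, seed = 11)
reads <- simulate_patient_reads(sp, ref$genome, ref$cds)
call_patient(reads$sam, ref$genome, ref$cds, caller_config("locus"))

space <- enumerate_snvs(ref$cds)
nrow(space$records)                          # 2214
expected_ns_ratio(space)                     # ~3.1-3.2
```

## Limitations

The package analyzes a single small locus; it is not a genome-wide somatic
caller, CNV segmenter, or general SV discovery tool. dN/dS is count-based
and unweighted; codon-model maximum-likelihood estimates would differ.
All performance guarantees are demonstrated on the synthetic generator's
assumptions, which idealize real sequencing in the ways listed above.
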