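#' B-allele frequencies at constitutional heterozygous SNPs
#'
#' For each SNP, the B-allele frequency is `b_count / (a_count + b_count)`
#' and `p_dev` is the two-sided exact binomial test of the B count against
#' the diploid expectation of one half.
#'
#' @param snps data.frame with columns `chrom`, `pos`, `a_count`, `b_count`.
#' @return the input with added columns `baf` and `p_dev`.
#' @export
compute_baf <- function(snps) {
  n <- snps$a_count + snps$b_count
  if (any(n < 1L)) stop("SNP with zero total allele count")
  snps$baf <- snps$b_count / n
  snps$p_dev <- vapply(seq_len(nrow(snps)), function(i)
    binom.test(snps$b_count[i], n[i], p = 0.5)$p.value, numeric(1L))
  snps
}

#' Extract SNP allele counts from pileup sites
#'
#' Convenience bridge from the caller's pileup: at each given position the
#' A allele is the reference base, the B allele the most frequent
#' non-reference base.
#'
#' @param sites pileup data.frame from [pileup()].
#' @param positions SNP positions to extract.
#' @return data.frame suitable for [compute_baf()].
#' @export
snp_counts_from_pileup <- function(sites, positions) {
  i <- match(positions, sites$pos)
  if (anyNA(i)) stop("SNP position outside the piled-up region")
  s <- sites[i, , drop = FALSE]
  cnt <- as.matrix(s[, DNA_BASES])
  a_count <- cnt[cbind(seq_len(nrow(s)), match(s$ref, DNA_BASES))]
  cnt[cbind(seq_len(nrow(s)), match(s$ref, DNA_BASES))] <- -1L
  b_idx <- max.col(cnt, ties.method = "first")
  data.frame(chrom = s$chrom, pos = s$pos, a_count = a_count,
             b_count = cnt[cbind(seq_len(nrow(s)), b_idx)],
             stringsAsFactors = FALSE)
}

#' Estimate the mosaic cell fraction from a minor-allele BAF
#'
#' Inverts the expected minor-allele frequency `(1 - f)/(2 - f)` of a
#' heterozygous deletion present in a fraction `f` of cells:
#' `f = (1 - 2 baf) / (1 - baf)`.
#'
#' @param minor_baf minor-allele BAF in `[0, 0.5]`.
#' @return estimated cell fraction in `[0, 1]`.
#' @export
estimate_cell_fraction <- function(minor_baf) {
  if (any(minor_baf < 0 | minor_baf > 0.5))
    stop("minor-allele BAF must lie in [0, 0.5]; pass min(baf, 1 - baf)")
  (1 - 2 * minor_baf) / (1 - minor_baf)
}

#' Detect mosaic-deletion segments from BAF deviation
#'
#' A SNP deviates when its exact binomial `p_dev` falls below
#' `alpha / n_snps` (Bonferroni). Maximal runs of at least `min_snps`
#' consecutive deviating SNPs whose minor allele is consistently below one
#' half form deviating segments; the segment's cell fraction is estimated
#' from its mean minor-allele BAF.
#'
#' @param snps data.frame from [compute_baf()], sorted by position.
#' @param alpha family-wise significance level.
#' @param min_snps minimum run length forming a segment.
#' @return data.frame of segments: `chrom, start, end, n_snps,
#'   mean_minor_baf, cell_fraction, p_min, deviating`.
#' @export
detect_deviation <- function(snps, alpha = 0.05, min_snps = 2L) {
  if (!nrow(snps))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      mean_minor_baf = numeric(), cell_fraction = numeric(),
                      p_min = numeric(), deviating = logical()))
  if (is.unsorted(snps$pos)) stop("SNPs must be sorted by position")
  thresh <- alpha / nrow(snps)
  dev <- snps$p_dev < thresh
  runs <- rle(dev)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  for (k in which(runs$values & runs$lengths >= min_snps)) {
    idx <- seq.int(starts[k], ends[k])
    minor <- pmin(snps$baf[idx], 1 - snps$baf[idx])
    segs[[length(segs) + 1L]] <- data.frame(
      chrom = snps$chrom[idx[1L]], start = snps$pos[idx[1L]],
      end = snps$pos[idx[length(idx)]], n_snps = length(idx),
      mean_minor_baf = mean(minor),
      cell_fraction = estimate_cell_fraction(min(mean(minor), 0.5)),
      p_min = min(snps$p_dev[idx]), deviating = TRUE,
      stringsAsFactors = FALSE)
  }
  if (length(segs)) do.call(rbind, segs) else
    detect_deviation(snps[0L, , drop = FALSE])
}

#' BAF scan of a patient's alignments
#'
#' Convenience chain: dedup, pile up, extract SNP counts, compute BAFs,
#' and segment deviations.
#'
#' @param sam a `sam_frame`.
#' @param genome a `ReferenceGenome`.
#' @param chrom chromosome of the SNPs.
#' @param positions constitutional het SNP positions.
#' @param alpha,min_snps see [detect_deviation()].
#' @return list with `snps` (per-SNP BAF table) and `segments`.
#' @export
baf_scan <- function(sam, genome, chrom, positions, alpha = 0.05,
                     min_snps = 2L) {
  if (!length(positions)) {
    empty <- data.frame(chrom = character(), pos = integer(),
                        a_count = integer(), b_count = integer(),
                        baf = numeric(), p_dev = numeric(),
                        stringsAsFactors = FALSE)
    return(list(snps = empty, segments = detect_deviation(empty)))
  }
  sites <- pileup(dedup(sam), genome, chrom, min(positions), max(positions))
  snps <- compute_baf(snp_counts_from_pileup(sites, sort(positions)))
  list(snps = snps, segments = detect_deviation(snps, alpha, min_snps))
}
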