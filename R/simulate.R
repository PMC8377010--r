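SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Default substitution-class weights for the synthetic cohort
#'
#' The six pyrimidine-reference substitution classes. The default is
#' dominated by C>T transitions (51.1% of events), the spectrum expected
#' from spontaneous cytosine deamination in blood, with T>C as the second
#' most frequent class.
#'
#' @return named numeric vector over C>A, C>G, C>T, T>A, T>C, T>G, summing
#'   to 1.
#' @export
default_spectrum_weights <- function() {
  c("C>A" = 0.07, "C>G" = 0.06, "C>T" = 0.511,
    "T>A" = 0.06, "T>C" = 0.22, "T>G" = 0.079)
}

#' Expected B-allele frequency under a mosaic heterozygous deletion
#'
#' In a sample where a fraction `f` of cells has lost one allele at a
#' constitutional heterozygous SNP, the allele copy numbers are 1 (retained
#' allele) and `1 - f` (deleted allele) per cell on average, so the expected
#' read fractions are `1/(2 - f)` and `(1 - f)/(2 - f)`.
#'
#' @param f cell fraction carrying the deletion, in `[0, 1]`.
#' @param allele `"deleted"` or `"retained"`.
#' @return expected allele fraction; the two alleles sum to 1.
#' @export
expected_baf <- function(f, allele = c("deleted", "retained")) {
  allele <- match.arg(allele)
  if (any(f < 0 | f > 1)) stop("cell fraction must lie in [0, 1]")
  if (allele == "deleted") (1 - f) / (2 - f) else 1 / (2 - f)
}

## ---- clonal events ---------------------------------------------------------

#' Clonal event constructors
#'
#' A clonal event is an acquired genetic lesion present in a fraction
#' `cell_fraction` of cells: a somatic SNV or small indel on one haplotype,
#' a heterozygous interstitial deletion, or a reciprocal translocation.
#'
#' @param chrom,pos,ref,alt SNV/indel coordinates and alleles (VCF-style,
#'   left-anchored for indels).
#' @param start,end deleted interval (1-based inclusive).
#' @param deleted_allele which constitutional haplotype is lost, `"A"` or
#'   `"B"` (the B haplotype carries the alternate allele at het SNPs).
#' @param chromA,posA,chromB,posB the two breakpoint positions of a
#'   reciprocal translocation: the derivative chromosomes join
#'   `chromA[..posA]` to `chromB[posB+1..]` and `chromB[..posB]` to
#'   `chromA[posA+1..]`.
#' @param cell_fraction fraction of cells carrying the event, in `(0, 1]`.
#' @return a list of class `clonal_event`.
#' @name clonal_event
NULL

new_event <- function(kind, cell_fraction, ...) {
  if (cell_fraction <= 0 || cell_fraction > 1)
    stop("cell_fraction must lie in (0, 1]")
  structure(list(kind = kind, cell_fraction = cell_fraction, ...),
            class = "clonal_event")
}

#' @rdname clonal_event
#' @export
snv_event <- function(chrom, pos, ref, alt, cell_fraction) {
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L)
  if (ref == alt) stop("ref and alt must differ")
  new_event("snv", cell_fraction, chrom = chrom, pos = as.integer(pos),
            ref = ref, alt = alt)
}

#' @rdname clonal_event
#' @export
indel_event <- function(chrom, pos, ref, alt, cell_fraction) {
  if (nchar(ref) == nchar(alt)) stop("indel alleles must differ in length")
  if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L))
    stop("indel alleles must share a left anchor base")
  new_event("indel", cell_fraction, chrom = chrom, pos = as.integer(pos),
            ref = ref, alt = alt)
}

#' @rdname clonal_event
#' @export
het_deletion_event <- function(chrom, start, end, cell_fraction,
                               deleted_allele = "B") {
  stopifnot(start <= end, deleted_allele %in% c("A", "B"))
  new_event("het_deletion", cell_fraction, chrom = chrom,
            start = as.integer(start), end = as.integer(end),
            deleted_allele = deleted_allele)
}

#' @rdname clonal_event
#' @export
translocation_event <- function(chromA, posA, chromB, posB, cell_fraction) {
  new_event("translocation", cell_fraction, chromA = chromA,
            posA = as.integer(posA), chromB = chromB, posB = as.integer(posB))
}

#' Patient specification for the read simulator
#'
#' @param id patient identifier.
#' @param age age in years.
#' @param events list of [clonal_event] objects.
#' @param mean_depth target deduplicated depth over the capture region.
#' @param error_rate uniform per-base sequencing error rate.
#' @param duplicate_rate fraction of fragments emitted a second time with the
#'   SAM duplicate flag set.
#' @param het_snp_positions integer vector of constitutional heterozygous SNP
#'   positions (on the target chromosome).
#' @param seed integer seed for this patient's read stream.
#' @param group cohort group label.
#' @return a list of class `patient_spec`.
#' @export
patient_spec <- function(id, age, events = list(), mean_depth = 2807L,
                         error_rate = 1e-3, duplicate_rate = 0.1,
                         het_snp_positions = integer(), seed = 1L,
                         group = "affected") {
  stopifnot(age >= 0, mean_depth > 0, error_rate >= 0, error_rate <= 0.05,
            duplicate_rate >= 0, duplicate_rate < 1)
  ev_pos <- unlist(lapply(events, function(e)
    if (e$kind %in% c("snv", "indel")) e$pos else NULL))
  if (length(intersect(ev_pos, het_snp_positions)))
    stop("het SNP positions must be distinct from event positions")
  structure(list(id = id, age = age, events = events,
                 mean_depth = as.integer(mean_depth),
                 error_rate = error_rate, duplicate_rate = duplicate_rate,
                 het_snp_positions = as.integer(het_snp_positions),
                 seed = as.integer(seed), group = group),
            class = "patient_spec")
}

## ---- reference simulation --------------------------------------------------

#' Default multi-exon CDS layout for the synthetic locus
#'
#' 738 coding nucleotides (245 residues plus the stop codon, the length of
#' human eIF6) split over five exons with intervening introns, mirroring a
#' compact intron-containing target locus.
#'
#' @param chrom chromosome to carry the CDS.
#' @param strand strand of the CDS.
#' @param start leftmost genomic position of the first exon.
#' @return a list describing the layout.
#' @export
default_cds_layout <- function(chrom = "chr20S", strand = "+", start = 1001L) {
  list(name = "EIF6S", chrom = chrom, strand = strand, start = as.integer(start),
       exon_coding = c(150L, 180L, 120L, 144L, 144L),
       introns = c(200L, 150L, 180L, 250L))
}

random_coding_seq <- function(coding_nt) {
  stopifnot(coding_nt %% 3L == 0L, coding_nt >= 6L)
  n_interior <- coding_nt / 3L - 2L
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_interior, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Simulate a reference genome with an embedded coding sequence
#'
#' Background sequence is uniform random ACGT; the coding sequence starts
#' with ATG, ends with a stop codon, and its interior codons are drawn
#' uniformly from the 61 sense codons. Deterministic for a fixed seed.
#'
#' @param seed integer seed.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param cds_layout layout as produced by [default_cds_layout()].
#' @return a list with elements `genome` (a `ReferenceGenome`) and `cds`
#'   (a `CodingSequence`).
#' @export
simulate_reference <- function(seed = 1L,
                               chrom_lengths = c(chr20S = 4000L, chr16S = 3000L),
                               cds_layout = default_cds_layout()) {
  set.seed(seed)
  coding_nt <- sum(cds_layout$exon_coding)
  n_ex <- length(cds_layout$exon_coding)
  if (length(cds_layout$introns) != n_ex - 1L)
    stop("need one intron fewer than exons")
  footprint <- coding_nt + sum(cds_layout$introns)
  chrom <- cds_layout$chrom
  if (!chrom %in% names(chrom_lengths)) stop("CDS chromosome not in genome")
  if (cds_layout$start + footprint - 1L > chrom_lengths[[chrom]])
    stop("CDS footprint [", cds_layout$start, ", ",
         cds_layout$start + footprint - 1L, "] exceeds chromosome length ",
         chrom_lengths[[chrom]])
  seqs <- vapply(chrom_lengths, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), character(1L))
  names(seqs) <- names(chrom_lengths)

  cds_seq <- random_coding_seq(coding_nt)
  # genomic layout left to right; transcript order follows strand
  gen_ex <- if (cds_layout$strand == "+") cds_layout$exon_coding
            else rev(cds_layout$exon_coding)
  starts <- cds_layout$start +
    cumsum(c(0L, head(gen_ex, -1L) + cds_layout$introns))
  ends <- starts + gen_ex - 1L
  # transcript-order pieces of the coding sequence
  piece_ends <- cumsum(cds_layout$exon_coding)
  piece_starts <- piece_ends - cds_layout$exon_coding + 1L
  pieces <- substring(cds_seq, piece_starts, piece_ends)
  s <- seqs[[chrom]]
  for (i in seq_len(n_ex)) {
    gi <- if (cds_layout$strand == "+") i else n_ex - i + 1L
    piece <- if (cds_layout$strand == "+") pieces[i] else revcomp(pieces[i])
    substr(s, starts[gi], ends[gi]) <- piece
  }
  seqs[[chrom]] <- s
  genome <- reference_genome(seqs)
  segments <- cbind(start = starts, end = ends)
  if (cds_layout$strand == "-")
    segments <- segments[rev(seq_len(n_ex)), , drop = FALSE]
  cds <- extract_cds(genome, cds_layout$name, chrom, cds_layout$strand,
                     segments)
  stopifnot(identical(cds$cds_seq, cds_seq))
  list(genome = genome, cds = cds)
}

## ---- read simulation -------------------------------------------------------

# default capture regions: the CDS footprint padded by one insert length,
# plus a window around each translocation breakpoint
default_regions <- function(spec, genome, cds, insert) {
  fp <- range(cds$segments)
  regions <- data.frame(chrom = cds$chrom,
                        start = max(1L, fp[1L] - insert),
                        end = min(chrom_length(genome, cds$chrom),
                                  fp[2L] + insert),
                        stringsAsFactors = FALSE)
  for (e in spec$events) {
    if (e$kind != "translocation") next
    for (side in list(c(e$chromA, e$posA), c(e$chromB, e$posB))) {
      ch <- side[[1L]]; p <- as.integer(side[[2L]])
      w <- data.frame(chrom = ch, start = max(1L, p - 3L * insert),
                      end = min(chrom_length(genome, ch), p + 3L * insert),
                      stringsAsFactors = FALSE)
      covered <- regions$chrom == ch & regions$start <= p & regions$end >= p
      if (!any(covered)) regions <- rbind(regions, w)
    }
  }
  regions
}

apply_base_at <- function(seqs, read_pos, target_pos, base) {
  # write `base` into reads covering target_pos; read_pos = alignment starts
  off <- target_pos - read_pos + 1L
  ok <- off >= 1L & off <= nchar(seqs)
  if (any(ok)) substr(seqs[ok], off[ok], off[ok]) <- base
  seqs
}

#' Simulate one patient's paired-end reads over the capture regions
#'
#' Emits coordinate-sortable SAM records (130 + 130 bp pairs, 200 bp
#' fragments by default) with uniform sequencing errors, PCR duplicates
#' flagged with the SAM duplicate bit, somatic SNVs/indels injected into a
#' binomial `f/2` share of overlapping fragments, haplotype-aware
#' heterozygous SNP alleles, coverage loss on the deleted haplotype inside
#' mosaic deletions, and soft-clipped junction fragments with
#' inter-chromosomal mates for reciprocal translocations.
#'
#' @param spec a [patient_spec()].
#' @param genome a `ReferenceGenome`.
#' @param cds the target `CodingSequence` (defines the default capture
#'   region).
#' @param read_len read length in bp.
#' @param insert fragment (insert) size in bp.
#' @param regions optional data.frame (chrom, start, end) of capture regions.
#' @return a list with `sam` (a `sam_frame`) and `truth` (a data.frame of
#'   realized events with expected VAF/BAF).
#' @export
simulate_patient_reads <- function(spec, genome, cds, read_len = 130L,
                                   insert = 200L, regions = NULL) {
  stopifnot(inherits(spec, "patient_spec"))
  set.seed(spec$seed)
  if (is.null(regions)) regions <- default_regions(spec, genome, cds, insert)

  frag <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    L <- chrom_length(genome, ch)
    lo <- max(1L, regions$start[i] - insert + 1L)
    hi <- min(L - insert + 1L, regions$end[i])
    n <- round(spec$mean_depth * (regions$end[i] - regions$start[i] + 1L) /
                 (2 * read_len))
    data.frame(chrom = ch,
               start = sample(seq.int(lo, hi), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  n_frag <- nrow(frag)
  frag$hap <- sample(c(1L, 2L), n_frag, replace = TRUE)

  truth <- list()
  junction_reads <- list()

  # haplotype losses from mosaic deletions
  for (e in spec$events) {
    if (e$kind == "het_deletion") {
      del_hap <- if (e$deleted_allele == "A") 1L else 2L
      mutant <- runif(n_frag) < e$cell_fraction
      overlaps <- frag$chrom == e$chrom &
        frag$start <= e$end & frag$start + insert - 1L >= e$start
      keep <- !(mutant & frag$hap == del_hap & overlaps)
      frag <- frag[keep, , drop = FALSE]
      n_frag <- nrow(frag)
      truth[[length(truth) + 1L]] <- data.frame(
        patient = spec$id, kind = "het_deletion", chrom = e$chrom,
        pos = e$start, end = e$end, ref = NA, alt = NA,
        cell_fraction = e$cell_fraction, expected_vaf = NA,
        expected_baf = expected_baf(e$cell_fraction, "deleted"),
        partner = NA, stringsAsFactors = FALSE)
    }
    if (e$kind == "translocation") {
      # thin out normal fragments spanning either breakpoint in mutant cells
      mutant <- runif(n_frag) < e$cell_fraction
      spansA <- frag$chrom == e$chromA & frag$start <= e$posA &
        frag$start + insert - 1L > e$posA
      spansB <- frag$chrom == e$chromB & frag$start <= e$posB &
        frag$start + insert - 1L > e$posB
      frag <- frag[!(mutant & (spansA | spansB)), , drop = FALSE]
      n_frag <- nrow(frag)
    }
  }

  ## normal (reference-ordered) fragments -> read pairs
  r1_pos <- frag$start
  r2_pos <- frag$start + insert - read_len
  chromseq <- unclass(genome)
  r1_seq <- substring(chromseq[frag$chrom], r1_pos, r1_pos + read_len - 1L)
  r2_seq <- substring(chromseq[frag$chrom], r2_pos, r2_pos + read_len - 1L)

  # constitutional het SNPs ride on haplotype 2 (the B allele)
  snp_alt <- character(0)
  if (length(spec$het_snp_positions)) {
    refb <- substring(chromseq[cds$chrom], spec$het_snp_positions,
                      spec$het_snp_positions)
    snp_alt <- unname(COMPLEMENT[refb])  # transversion-free arbitrary choice
    same <- snp_alt == refb
    snp_alt[same] <- ifelse(refb[same] == "A", "G", "A")
    for (k in seq_along(spec$het_snp_positions)) {
      p <- spec$het_snp_positions[k]
      onb <- frag$hap == 2L & frag$chrom == cds$chrom
      r1_seq[onb] <- apply_base_at(r1_seq[onb], r1_pos[onb], p, snp_alt[k])
      r2_seq[onb] <- apply_base_at(r2_seq[onb], r2_pos[onb], p, snp_alt[k])
      dels <- Filter(function(e) e$kind == "het_deletion" &&
                       e$chrom == cds$chrom && e$start <= p && e$end >= p,
                     spec$events)
      ebaf <- if (length(dels)) {
        d <- dels[[1L]]
        expected_baf(d$cell_fraction,
                     if (d$deleted_allele == "B") "deleted" else "retained")
      } else 0.5
      truth[[length(truth) + 1L]] <- data.frame(
        patient = spec$id, kind = "het_snp", chrom = cds$chrom, pos = p,
        end = p, ref = refb[k], alt = snp_alt[k], cell_fraction = NA,
        expected_vaf = NA, expected_baf = ebaf, partner = NA,
        stringsAsFactors = FALSE)
    }
  }

  ## somatic SNVs and indels: carrier fragments at rate f/2
  indel_jobs <- list()
  for (e in spec$events) {
    if (e$kind == "snv") {
      carrier <- runif(n_frag) < e$cell_fraction / 2
      onc <- carrier & frag$chrom == e$chrom
      r1_seq[onc] <- apply_base_at(r1_seq[onc], r1_pos[onc], e$pos, e$alt)
      r2_seq[onc] <- apply_base_at(r2_seq[onc], r2_pos[onc], e$pos, e$alt)
      truth[[length(truth) + 1L]] <- data.frame(
        patient = spec$id, kind = "snv", chrom = e$chrom, pos = e$pos,
        end = e$pos, ref = e$ref, alt = e$alt,
        cell_fraction = e$cell_fraction,
        expected_vaf = e$cell_fraction / 2, expected_baf = NA, partner = NA,
        stringsAsFactors = FALSE)
    } else if (e$kind == "indel") {
      carrier <- which(runif(n_frag) < e$cell_fraction / 2 &
                         frag$chrom == e$chrom)
      indel_jobs[[length(indel_jobs) + 1L]] <- list(event = e, idx = carrier)
      truth[[length(truth) + 1L]] <- data.frame(
        patient = spec$id, kind = "indel", chrom = e$chrom, pos = e$pos,
        end = e$pos, ref = e$ref, alt = e$alt,
        cell_fraction = e$cell_fraction,
        expected_vaf = e$cell_fraction / 2, expected_baf = NA, partner = NA,
        stringsAsFactors = FALSE)
    }
  }

  r1_cigar <- rep(paste0(read_len, "M"), n_frag)
  r2_cigar <- rep(paste0(read_len, "M"), n_frag)

  # indel carriers: rebuild seq and CIGAR where the event sits comfortably
  # inside the read; edge-clipped carriers fall back to the reference allele
  for (job in indel_jobs) {
    e <- job$event
    dlen <- nchar(e$ref) - nchar(e$alt)  # >0 deletion, <0 insertion
    for (i in job$idx) {
      for (r in 1:2) {
        pos0 <- if (r == 1L) r1_pos[i] else r2_pos[i]
        lead <- e$pos - pos0 + 1L  # matched bases up to and incl. anchor
        if (lead < 2L || lead > read_len - max(2L, abs(dlen) + 2L)) next
        if (dlen > 0L) {  # deletion of dlen bases after the anchor
          rest <- read_len - lead
          seqi <- paste0(substring(chromseq[e$chrom], pos0, e$pos),
                         substring(chromseq[e$chrom], e$pos + dlen + 1L,
                                   e$pos + dlen + rest))
          cigi <- paste0(lead, "M", dlen, "D", rest, "M")
        } else {  # insertion
          ins <- substring(e$alt, 2L)
          rest <- read_len - lead - nchar(ins)
          seqi <- paste0(substring(chromseq[e$chrom], pos0, e$pos), ins,
                         substring(chromseq[e$chrom], e$pos + 1L,
                                   e$pos + rest))
          cigi <- paste0(lead, "M", nchar(ins), "I", rest, "M")
        }
        if (r == 1L) { r1_seq[i] <- seqi; r1_cigar[i] <- cigi }
        else { r2_seq[i] <- seqi; r2_cigar[i] <- cigi }
      }
    }
  }

  ## junction fragments for translocations (both reciprocal derivatives)
  for (e in spec$events) {
    if (e$kind != "translocation") next
    derivs <- list(list(lch = e$chromA, lpos = e$posA,
                        rch = e$chromB, rpos = e$posB + 1L),
                   list(lch = e$chromB, lpos = e$posB,
                        rch = e$chromA, rpos = e$posA + 1L))
    cov_rate <- spec$mean_depth * insert / (2 * read_len)
    snp_tab <- if (length(spec$het_snp_positions))
      data.frame(chrom = cds$chrom, pos = spec$het_snp_positions,
                 alt = snp_alt, stringsAsFactors = FALSE)
    else NULL
    for (d in derivs) {
      n_junc <- rbinom(1L, round(cov_rate), e$cell_fraction)
      if (n_junc == 0L) next
      left_len <- sample(seq.int(10L, insert - 10L), n_junc, replace = TRUE)
      hap2 <- runif(n_junc) < 0.5   # junction fragments carry a haplotype too
      for (j in seq_len(n_junc)) {
        jr <- make_junction_pair(chromseq, d, left_len[j], read_len, insert,
                                 sprintf("%s:J%s:%d:%d", spec$id, d$lch,
                                         e$posA, j),
                                 snps = if (hap2[j]) snp_tab else NULL)
        junction_reads[[length(junction_reads) + 1L]] <- jr
      }
    }
    truth[[length(truth) + 1L]] <- data.frame(
      patient = spec$id, kind = "translocation", chrom = e$chromA,
      pos = e$posA, end = e$posA, ref = NA, alt = NA,
      cell_fraction = e$cell_fraction, expected_vaf = NA, expected_baf = NA,
      partner = paste0(e$chromB, ":", e$posB), stringsAsFactors = FALSE)
  }

  qname <- sprintf("%s:F%06d", spec$id, seq_len(n_frag))
  f1 <- FLAG_PAIRED + FLAG_PROPER + FLAG_MATE_REVERSE + FLAG_FIRST
  f2 <- FLAG_PAIRED + FLAG_PROPER + FLAG_REVERSE + FLAG_LAST
  sam <- rbind(
    data.frame(qname = qname, flag = f1, rname = frag$chrom, pos = r1_pos,
               mapq = 60L, cigar = r1_cigar, rnext = "=", pnext = r2_pos,
               tlen = insert, seq = r1_seq, qual = NA,
               stringsAsFactors = FALSE),
    data.frame(qname = qname, flag = f2, rname = frag$chrom, pos = r2_pos,
               mapq = 60L, cigar = r2_cigar, rnext = "=", pnext = r1_pos,
               tlen = -insert, seq = r2_seq, qual = NA,
               stringsAsFactors = FALSE))
  if (length(junction_reads))
    sam <- rbind(sam, do.call(rbind, junction_reads))

  ## uniform sequencing errors over aligned+clipped bases
  if (spec$error_rate > 0) {
    n_read <- nrow(sam)
    k <- rbinom(1L, n_read * read_len, spec$error_rate)
    if (k > 0L) {
      ridx <- sample.int(n_read, k, replace = TRUE)
      off <- sample.int(read_len, k, replace = TRUE)
      shift <- sample.int(3L, k, replace = TRUE)
      keep <- !duplicated(paste0(ridx, "_", off))
      ridx <- ridx[keep]; off <- off[keep]; shift <- shift[keep]
      rank <- stats::ave(seq_along(ridx), ridx, FUN = seq_along)
      for (r in seq_len(max(rank))) {
        sel <- which(rank == r)
        i <- ridx[sel]
        s <- sam$seq[i]
        cur <- substring(s, off[sel], off[sel])
        bi <- match(cur, DNA_BASES)
        ok <- !is.na(bi)
        if (!any(ok)) next
        newb <- DNA_BASES[(bi[ok] - 1L + shift[sel][ok]) %% 4L + 1L]
        substr(s[ok], off[sel][ok], off[sel][ok]) <- newb
        sam$seq[i] <- s
      }
    }
  }

  ## PCR duplicates: emit flagged copies of a fraction of fragments
  if (spec$duplicate_rate > 0) {
    n_dup <- round(spec$duplicate_rate * n_frag)
    if (n_dup > 0L) {
      dup_q <- sample(qname, n_dup)
      dup <- sam[sam$qname %in% dup_q, , drop = FALSE]
      dup$flag <- dup$flag + FLAG_DUP
      dup$qname <- paste0(dup$qname, ":dup")
      sam <- rbind(sam, dup)
    }
  }

  sam$qual <- strrep("I", nchar(sam$seq))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(patient = character(), kind = character())
  list(sam = as_sam_frame(sam), truth = truth)
}

# build one junction-spanning read pair on a derivative chromosome;
# reads are anchored on the side holding the majority of their bases, the
# remainder soft-clipped (the clipped bases come from the partner chromosome)
make_junction_pair <- function(chromseq, d, left_len, read_len, insert,
                               qname, snps = NULL) {
  right_len <- insert - left_len
  fragseq <- paste0(
    substring(chromseq[d$lch], d$lpos - left_len + 1L, d$lpos),
    substring(chromseq[d$rch], d$rpos, d$rpos + right_len - 1L))
  if (!is.null(snps)) {
    for (k in seq_len(nrow(snps))) {
      p <- snps$pos[k]
      off <- if (snps$chrom[k] == d$lch && p > d$lpos - left_len &&
                 p <= d$lpos) p - d$lpos + left_len
             else if (snps$chrom[k] == d$rch && p >= d$rpos &&
                      p < d$rpos + right_len) left_len + p - d$rpos + 1L
             else next
      substr(fragseq, off, off) <- snps$alt[k]
    }
  }
  place <- function(frag_off) {
    # frag_off: 1-based offset of the read's first base in the fragment;
    # the read's first base maps to lpos - left_len + frag_off on the left
    # chromosome
    rseq <- substring(fragseq, frag_off, frag_off + read_len - 1L)
    n_left <- max(0L, min(read_len, left_len - frag_off + 1L))
    n_right <- read_len - n_left
    if (n_left >= n_right && n_left > 0L) {
      list(rname = d$lch, pos = d$lpos - left_len + frag_off,
           cigar = if (n_right > 0L) paste0(n_left, "M", n_right, "S")
                   else paste0(read_len, "M"),
           seq = rseq)
    } else {
      list(rname = d$rch,
           pos = d$rpos + max(0L, frag_off - left_len - 1L),
           cigar = if (n_left > 0L) paste0(n_left, "S", n_right, "M")
                   else paste0(read_len, "M"),
           seq = rseq)
    }
  }
  a <- place(1L)
  b <- place(insert - read_len + 1L)
  rn <- function(x, y) if (x$rname == y$rname) "=" else y$rname
  f1 <- FLAG_PAIRED + FLAG_MATE_REVERSE + FLAG_FIRST
  f2 <- FLAG_PAIRED + FLAG_REVERSE + FLAG_LAST
  data.frame(qname = qname, flag = c(f1, f2),
             rname = c(a$rname, b$rname), pos = c(a$pos, b$pos),
             mapq = 60L, cigar = c(a$cigar, b$cigar),
             rnext = c(rn(a, b), rn(b, a)), pnext = c(b$pos, a$pos),
             tlen = c(0L, 0L), seq = c(a$seq, b$seq), qual = NA,
             stringsAsFactors = FALSE)
}

## ---- cohort simulation -----------------------------------------------------

#' Cohort specification
#'
#' Defines the statistical structure of a synthetic patient cohort: the
#' substitution-class spectrum, the clone-size (VAF) range, the sequencing
#' depth regime, and the somatic event mix. Defaults emulate an ultra-deep
#' targeted screen of an SDS-like cohort: C>T-dominated spectrum, clones
#' from 0.25% to 28% VAF, and mean deduplicated depths of 2807x
#' (locus capture) or 26,873x (cDNA capture).
#'
#' @param n_patients number of patients.
#' @param spectrum_weights named probabilities over the six
#'   pyrimidine-reference substitution classes; must sum to 1.
#' @param vaf_range clone VAF range `[low, high]` (log-uniform sampling).
#' @param depth_regime `"locus_capture"` (mean 2807x) or `"cdna_capture"`
#'   (mean 26,873x).
#' @param seed master seed; per-patient seeds are `seed + patient index`.
#' @param p_snv probability that a somatic event is an SNV (otherwise a
#'   small indel).
#' @param age_range admissible age range in years.
#' @param include_deletion_patient add one patient carrying a mosaic
#'   heterozygous deletion of the locus (cell fraction 0.37).
#' @param include_translocation_patient add one patient carrying a
#'   reciprocal translocation with one breakpoint inside the locus.
#' @param error_rate,duplicate_rate per-patient sequencing error and
#'   duplicate rates.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 26L,
                        spectrum_weights = default_spectrum_weights(),
                        vaf_range = c(0.0025, 0.28),
                        depth_regime = c("cdna_capture", "locus_capture"),
                        seed = 1L, p_snv = 0.82,
                        age_range = c(0.47, 52.2),
                        include_deletion_patient = FALSE,
                        include_translocation_patient = FALSE,
                        error_rate = 1e-3, duplicate_rate = 0.1) {
  depth_regime <- match.arg(depth_regime)
  if (abs(sum(spectrum_weights) - 1) > 1e-9)
    stop("spectrum weights must sum to 1")
  stopifnot(vaf_range[1L] > 0, vaf_range[1L] <= vaf_range[2L],
            vaf_range[2L] <= 1)
  structure(list(n_patients = as.integer(n_patients),
                 spectrum_weights = spectrum_weights, vaf_range = vaf_range,
                 depth_regime = depth_regime, seed = as.integer(seed),
                 p_snv = p_snv, age_range = age_range,
                 include_deletion_patient = include_deletion_patient,
                 include_translocation_patient = include_translocation_patient,
                 error_rate = error_rate, duplicate_rate = duplicate_rate),
            class = "cohort_spec")
}

regime_mean_depth <- function(regime) {
  switch(regime, locus_capture = 2807L, cdna_capture = 26873L)
}

#' Draw substitution events over the coding footprint
#'
#' Samples substitution classes from `weights` and places each event at a
#' uniformly chosen coding position carrying the class's reference
#' pyrimidine or its purine complement (in which case the alleles are
#' complemented, preserving the pyrimidine-reference class).
#'
#' @param n number of substitutions.
#' @param genome a `ReferenceGenome`.
#' @param cds a `CodingSequence` restricting candidate positions.
#' @param weights spectrum weights (see [default_spectrum_weights()]).
#' @return data.frame with `pos`, `ref`, `alt`, `class`.
#' @export
sample_substitutions <- function(n, genome, cds,
                                 weights = default_spectrum_weights()) {
  gpos <- cds_to_genomic_pos(cds, seq_len(nchar(cds$cds_seq)))
  refb <- substring(genome[[cds$chrom]], gpos, gpos)
  classes <- sample(names(weights), n, replace = TRUE, prob = weights)
  pyr <- substr(classes, 1L, 1L)
  altp <- substr(classes, 3L, 3L)
  by_pyr <- split(seq_len(n), pyr)
  out_pos <- integer(n); out_ref <- character(n); out_alt <- character(n)
  for (p in names(by_pyr)) {
    idx <- by_pyr[[p]]
    cand <- gpos[refb == p | refb == COMPLEMENT[[p]]]
    pick <- sample(cand, length(idx), replace = TRUE)
    rb <- substring(genome[[cds$chrom]], pick, pick)
    a <- ifelse(rb == p, altp[idx], unname(COMPLEMENT[altp[idx]]))
    out_pos[idx] <- pick; out_ref[idx] <- rb; out_alt[idx] <- a
  }
  data.frame(pos = out_pos, ref = out_ref, alt = out_alt,
             class = classes, stringsAsFactors = FALSE)
}

#' Simulate a patient cohort specification set
#'
#' Ages follow a right-skewed (gamma) distribution with mean ~15 years;
#' expected somatic mutation counts rise linearly with age (Poisson counts
#' with a zero-inflated propensity), producing the positive count-versus-age
#' correlation expected from age-accumulating clonal hematopoiesis. Each
#' somatic SNV's class follows the cohort spectrum; VAFs are log-uniform on
#' `vaf_range`; per-patient depths are log-normal around the regime mean.
#'
#' @param cspec a [cohort_spec()].
#' @param genome a `ReferenceGenome`.
#' @param cds the target `CodingSequence`.
#' @return list with `patients` (list of [patient_spec()]) and `truth`
#'   (data.frame of all planted events with expectations).
#' @export
simulate_cohort <- function(cspec, genome, cds) {
  set.seed(cspec$seed)
  n <- cspec$n_patients
  ages <- pmin(pmax(stats::rgamma(n, shape = 1.6, scale = 9.6),
                    cspec$age_range[1L]), cspec$age_range[2L])
  propensity <- runif(n) > 0.2          # zero-inflation of mutation propensity
  lambda <- (1.6 + 0.065 * ages) * propensity
  n_mut <- rpois(n, lambda)
  depth <- round(stats::rlnorm(n, log(regime_mean_depth(cspec$depth_regime)),
                               0.35))
  footprint <- range(cds$segments)
  gpos_all <- cds_to_genomic_pos(cds, seq_len(nchar(cds$cds_seq)))

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(cspec$seed + i)
    events <- list()
    if (n_mut[i] > 0L) {
      vafs <- exp(runif(n_mut[i], log(cspec$vaf_range[1L]),
                        log(cspec$vaf_range[2L])))
      is_snv <- runif(n_mut[i]) < cspec$p_snv
      subs <- sample_substitutions(sum(is_snv), genome, cds,
                                   cspec$spectrum_weights)
      si <- 0L
      for (k in seq_len(n_mut[i])) {
        f <- min(1, 2 * vafs[k])
        if (is_snv[k]) {
          si <- si + 1L
          events[[k]] <- snv_event(cds$chrom, subs$pos[si], subs$ref[si],
                                   subs$alt[si], f)
        } else {
          dlen <- sample(1:5, 1L)
          p <- sample(gpos_all[gpos_all + dlen <= footprint[2L]], 1L)
          ref <- substring(genome[[cds$chrom]], p, p + dlen)
          events[[k]] <- indel_event(cds$chrom, p, ref,
                                     substr(ref, 1L, 1L), f)
        }
      }
    }
    if (cspec$include_deletion_patient && i == 1L) {
      events[[length(events) + 1L]] <- het_deletion_event(
        cds$chrom, max(1L, footprint[1L] - 200L),
        min(chrom_length(genome, cds$chrom), footprint[2L] + 200L), 0.37)
    }
    if (cspec$include_translocation_patient && i == 2L) {
      partner <- setdiff(names(genome), cds$chrom)[1L]
      if (is.na(partner)) stop("translocation patient needs a second chromosome")
      gs <- cds$segments[order(cds$segments[, 1L]), , drop = FALSE]
      ns <- nrow(gs)  # breakpoint in the last intron of the locus
      intron_mid <- floor((gs[ns - 1L, 2L] + gs[ns, 1L]) / 2)
      events[[length(events) + 1L]] <- translocation_event(
        partner, floor(chrom_length(genome, partner) / 2), cds$chrom,
        intron_mid, 0.4)
    }
    snp_n <- sample(3:8, 1L)
    cand <- setdiff(seq.int(footprint[1L], footprint[2L]),
                    vapply(events, function(e)
                      if (e$kind %in% c("snv", "indel")) e$pos else NA_integer_,
                      integer(1L)))
    patients[[i]] <- patient_spec(
      id = sprintf("P%02d", i), age = ages[i], events = events,
      mean_depth = depth[i], error_rate = cspec$error_rate,
      duplicate_rate = cspec$duplicate_rate,
      het_snp_positions = sort(sample(cand, snp_n)),
      seed = cspec$seed + i, group = "affected")
  }
  truth <- do.call(rbind, lapply(patients, function(p) {
    rows <- lapply(p$events, function(e) {
      data.frame(patient = p$id, kind = e$kind,
                 chrom = if (e$kind == "translocation") e$chromA else e$chrom,
                 pos = switch(e$kind, translocation = e$posA,
                              het_deletion = e$start, e$pos),
                 end = switch(e$kind, translocation = e$posA,
                              het_deletion = e$end, e$pos),
                 ref = if (e$kind %in% c("snv", "indel")) e$ref else NA,
                 alt = if (e$kind %in% c("snv", "indel")) e$alt else NA,
                 cell_fraction = e$cell_fraction,
                 expected_vaf = if (e$kind %in% c("snv", "indel"))
                   e$cell_fraction / 2 else NA,
                 expected_baf = if (e$kind == "het_deletion")
                   expected_baf(e$cell_fraction, "deleted") else NA,
                 partner = if (e$kind == "translocation")
                   paste0(e$chromB, ":", e$posB) else NA,
                 stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows) else NULL
  }))
  list(patients = patients, truth = truth)
}

#' Write the cohort truth and metadata tables
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- data.frame(
    id = vapply(cohort$patients, `[[`, character(1L), "id"),
    age = vapply(cohort$patients, `[[`, numeric(1L), "age"),
    group = vapply(cohort$patients, `[[`, character(1L), "group"),
    mean_depth = vapply(cohort$patients, `[[`, integer(1L), "mean_depth"))
  write.table(meta, file.path(dir, "cohort.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
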