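#' Caller configuration
#'
#' The screening thresholds of the ultra-deep targeted caller. `locus`
#' capture mode calls clones at VAF >= 0.5%; `cdna` capture mode, run at
#' roughly tenfold higher depth, calls at VAF >= 0.25%. An allele must also
#' be supported by at least `min_alt_reads` deduplicated reads and must
#' reject the sequencing-error null (one-sided exact binomial tail at
#' per-base error rate `error_rate`) at level `alpha` after Bonferroni
#' correction over `3 * n_sites` alternative alleles.
#'
#' @param mode `"locus"` or `"cdna"`; sets the default `vaf_min`.
#' @param vaf_min minimum variant allele fraction (default 0.005 for
#'   `locus`, 0.0025 for `cdna`).
#' @param error_rate assumed uniform per-base sequencing error rate.
#' @param alpha family-wise significance level.
#' @param min_alt_reads minimum deduplicated alt-supporting reads.
#' @return a list of class `caller_config`.
#' @export
caller_config <- function(mode = c("locus", "cdna"), vaf_min = NULL,
                          error_rate = 1e-3, alpha = 0.05,
                          min_alt_reads = 3L) {
  mode <- match.arg(mode)
  if (is.null(vaf_min)) vaf_min <- if (mode == "locus") 0.005 else 0.0025
  stopifnot(vaf_min > 0, vaf_min < 1, error_rate > 0, alpha > 0, alpha < 1)
  if (error_rate >= vaf_min)
    stop("error_rate must be below vaf_min for the binomial null to separate")
  structure(list(mode = mode, vaf_min = vaf_min, error_rate = error_rate,
                 alpha = alpha, min_alt_reads = as.integer(min_alt_reads)),
            class = "caller_config")
}

#' Remove duplicate-flagged records
#'
#' Drops every record whose SAM FLAG carries the 0x400 duplicate bit,
#' preserving order. Idempotent.
#'
#' @param sam a `sam_frame`.
#' @return the deduplicated `sam_frame`.
#' @export
dedup <- function(sam) {
  as_sam_frame(sam[!has_flag(sam$flag, FLAG_DUP), , drop = FALSE])
}

#' Duplicate-aware base pileup over a region
#'
#' Walks each record's CIGAR, counting the read base at every
#' reference-aligned position (`M`, `=`, `X`). Soft- and hard-clipped bases
#' contribute nothing; deletions (`D`) and insertions (`I`) are counted as
#' indel alleles anchored at the last aligned base before the event.
#' Records that are unmapped, below `min_mapq`, or whose CIGAR length
#' disagrees with the sequence length are skipped (the latter counted in
#' the `n_skipped` attribute).
#'
#' @param sam a `sam_frame` (typically after [dedup()]).
#' @param genome a `ReferenceGenome`.
#' @param chrom chromosome to pile up.
#' @param start,end 1-based inclusive region bounds.
#' @param min_mapq minimum mapping quality (default 1).
#' @return data.frame with columns `chrom, pos, ref, depth, A, C, G, T`;
#'   attribute `indels` is a data.frame `(pos, allele, count)` with
#'   samtools-style allele strings (`"-3"`, `"+TT"`); attribute `n_skipped`
#'   counts malformed records.
#' @export
pileup <- function(sam, genome, chrom, start, end, min_mapq = 1L) {
  L <- chrom_length(genome, chrom)
  start <- max(1L, as.integer(start)); end <- min(L, as.integer(end))
  reg_len <- end - start + 1L
  keep <- sam$rname == chrom & !has_flag(sam$flag, FLAG_UNMAPPED) &
    sam$mapq >= min_mapq & sam$cigar != "*"
  sam <- sam[keep, , drop = FALSE]
  counts <- matrix(0L, nrow = 4L, ncol = reg_len,
                   dimnames = list(DNA_BASES, NULL))
  del_cover <- integer(reg_len)        # deletion-spanning reads per site
  indels <- list()
  n_skipped <- 0L

  simple <- grepl("^[0-9]+M$", sam$cigar)
  if (any(simple)) {
    ss <- sam[simple, , drop = FALSE]
    lens <- nchar(ss$seq)
    ok <- lens == as.integer(sub("M$", "", ss$cigar))
    n_skipped <- n_skipped + sum(!ok)
    ss <- ss[ok, , drop = FALSE]; lens <- lens[ok]
    if (nrow(ss)) {
      lut <- integer(128L)
      lut[utf8ToInt("ACGT")] <- 1:4
      codes <- utf8ToInt(paste(ss$seq, collapse = ""))
      bi <- lut[codes]
      poss <- sequence(lens) - 1L + rep(ss$pos, lens)
      okb <- poss >= start & poss <= end & bi > 0L
      tab <- tabulate((poss[okb] - start) * 4L + bi[okb], 4L * reg_len)
      counts <- counts + matrix(tab, nrow = 4L)
    }
  }
  complex_idx <- which(!simple)
  for (i in complex_idx) {
    cg <- tryCatch(parse_cigar(sam$cigar[i]), error = function(e) NULL)
    if (is.null(cg)) { n_skipped <- n_skipped + 1L; next }
    qlen <- sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X")])
    if (qlen != nchar(sam$seq[i])) { n_skipped <- n_skipped + 1L; next }
    rpos <- sam$pos[i]; qoff <- 0L
    last_aligned <- rpos - 1L
    for (k in seq_along(cg$op)) {
      op <- cg$op[k]; n <- cg$len[k]
      if (op %in% c("M", "=", "X")) {
        p <- seq.int(rpos, rpos + n - 1L)
        b <- substring(sam$seq[i], qoff + 1L, qoff + n)
        bs <- strsplit(b, "", fixed = TRUE)[[1L]]
        inreg <- p >= start & p <= end
        bi <- match(bs[inreg], DNA_BASES)
        pi <- p[inreg] - start + 1L
        okb <- !is.na(bi)
        if (any(okb))
          counts[cbind(bi[okb], pi[okb])] <-
            counts[cbind(bi[okb], pi[okb])] + 1L
        last_aligned <- rpos + n - 1L
        rpos <- rpos + n; qoff <- qoff + n
      } else if (op == "D" || op == "N") {
        if (op == "D" && last_aligned >= start && last_aligned <= end) {
          indels[[length(indels) + 1L]] <-
            c(pos = last_aligned, allele = paste0("-", n))
          span <- seq.int(rpos, rpos + n - 1L)
          span <- span[span >= start & span <= end]
          del_cover[span - start + 1L] <- del_cover[span - start + 1L] + 1L
        }
        rpos <- rpos + n
      } else if (op == "I") {
        if (last_aligned >= start && last_aligned <= end)
          indels[[length(indels) + 1L]] <-
            c(pos = last_aligned,
              allele = paste0("+", substring(sam$seq[i], qoff + 1L, qoff + n)))
        qoff <- qoff + n
      } else if (op %in% c("S")) {
        qoff <- qoff + n
      }  # H, P consume nothing here
    }
  }
  refb <- strsplit(substring(genome[[chrom]], start, end), "",
                   fixed = TRUE)[[1L]]
  out <- data.frame(chrom = chrom, pos = seq.int(start, end), ref = refb,
                    depth = as.integer(colSums(counts)) + del_cover,
                    A = counts["A", ], C = counts["C", ],
                    G = counts["G", ], T = counts["T", ],
                    stringsAsFactors = FALSE)
  ind <- if (length(indels)) {
    m <- do.call(rbind, indels)
    agg <- stats::aggregate(list(count = rep(1L, nrow(m))),
                            by = list(pos = as.integer(m[, "pos"]),
                                      allele = m[, "allele"]), FUN = sum)
    agg[order(agg$pos), , drop = FALSE]
  } else data.frame(pos = integer(), allele = character(), count = integer())
  attr(out, "indels") <- ind
  attr(out, "n_skipped") <- n_skipped
  out
}

binom_tail <- function(alt, depth, eps) {
  # one-sided P(X >= alt | depth, eps)
  pbinom(alt - 1L, depth, eps, lower.tail = FALSE)
}

#' Call low-VAF somatic variants from a pileup
#'
#' An alternative allele is called iff its VAF is at least `cfg$vaf_min`,
#' it is supported by at least `cfg$min_alt_reads` reads, and its one-sided
#' exact binomial tail probability under the error rate is below
#' `cfg$alpha` Bonferroni-corrected over `3 * n_sites` alternative alleles.
#' Indel alleles observed in the pileup are tested the same way. Calls are
#' annotated with their coding consequence against `cds`.
#'
#' @param sites pileup as returned by [pileup()].
#' @param cfg a [caller_config()].
#' @param cds a `CodingSequence` for consequence annotation.
#' @param genome the `ReferenceGenome` (needed to spell indel alleles).
#' @return data.frame of variant calls with columns `chrom, pos, ref, alt,
#'   alt_count, depth, vaf, p_error, consequence, protein_change`.
#' @export
call_variants <- function(sites, cfg, cds, genome) {
  stopifnot(inherits(cfg, "caller_config"))
  n_tests <- 3L * nrow(sites)
  thresh <- cfg$alpha / n_tests
  nonzero <- sites$depth > 0L
  calls <- list()
  s <- sites[nonzero, , drop = FALSE]
  for (b in DNA_BASES) {
    cnt <- s[[b]]
    cand <- which(s$ref != b & cnt > 0L)
    if (!length(cand)) next
    vaf <- cnt[cand] / s$depth[cand]
    p <- binom_tail(cnt[cand], s$depth[cand], cfg$error_rate)
    ok <- vaf >= cfg$vaf_min & cnt[cand] >= cfg$min_alt_reads & p < thresh
    if (!any(ok)) next
    i <- cand[ok]
    calls[[b]] <- data.frame(chrom = s$chrom[i], pos = s$pos[i],
                             ref = s$ref[i], alt = b, alt_count = cnt[i],
                             depth = s$depth[i], vaf = vaf[ok],
                             p_error = p[ok], stringsAsFactors = FALSE)
  }
  ind <- attr(sites, "indels")
  if (!is.null(ind) && nrow(ind)) {
    di <- match(ind$pos, sites$pos)
    depth <- sites$depth[di]
    ok <- !is.na(di) & depth > 0L
    ind <- ind[ok, , drop = FALSE]; depth <- depth[ok]
    if (nrow(ind)) {
      vaf <- ind$count / depth
      p <- binom_tail(ind$count, depth, cfg$error_rate)
      keep <- vaf >= cfg$vaf_min & ind$count >= cfg$min_alt_reads & p < thresh
      if (any(keep)) {
        ii <- which(keep)
        anchor <- substring(genome[[sites$chrom[1L]]], ind$pos[ii],
                            ind$pos[ii])
        isdel <- startsWith(ind$allele[ii], "-")
        dlen <- ifelse(isdel, as.integer(sub("^-", "", ind$allele[ii])), 0L)
        ref <- ifelse(isdel,
                      substring(genome[[sites$chrom[1L]]], ind$pos[ii],
                                ind$pos[ii] + dlen),
                      anchor)
        alt <- ifelse(isdel, anchor,
                      paste0(anchor, sub("^\\+", "", ind$allele[ii])))
        calls[["indel"]] <- data.frame(
          chrom = sites$chrom[1L], pos = ind$pos[ii], ref = ref, alt = alt,
          alt_count = ind$count[ii], depth = depth[ii], vaf = vaf[keep],
          p_error = p[keep], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), alt_count = integer(), depth = integer(),
               vaf = numeric(), p_error = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    csq <- lapply(seq_len(nrow(out)), function(i)
      annotate_consequence(genome, cds, out$chrom[i], out$pos[i],
                           out$ref[i], out$alt[i]))
    out$consequence <- vapply(csq, `[[`, character(1L), "consequence")
    out$protein_change <- vapply(csq, `[[`, character(1L), "protein_change")
  } else {
    out$consequence <- character(0)
    out$protein_change <- character(0)
  }
  out
}

codon_aa <- function(codon) {
  if (grepl("N", codon)) stop("cannot translate codon containing N: ", codon)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the coding consequence of a variant
#'
#' SNVs inside the coding segments are classified by comparing the
#' reference and mutant codons: `synonymous`, `missense`, `nonsense`
#' (gain of stop), `stop_loss`, or `start_loss` (any substitution in the
#' initiator codon). Indels are `frameshift` when the length change is not
#' a multiple of three, `inframe_indel` otherwise. Variants outside the
#' segments are `noncoding`. Protein change is formatted as
#' `<refAA><codon#><altAA>` (e.g. `N106S`, `Q93*`).
#'
#' @param genome a `ReferenceGenome`.
#' @param cds a `CodingSequence`.
#' @param chrom,pos,ref,alt the variant (VCF-style; indels left-anchored
#'   with a shared first base).
#' @return list with `consequence` and `protein_change`.
#' @export
annotate_consequence <- function(genome, cds, chrom, pos, ref, alt) {
  refobs <- substring(genome[[chrom]], pos, pos + nchar(ref) - 1L)
  if (refobs != ref)
    stop("ref allele ", ref, " does not match reference ", refobs,
         " at ", chrom, ":", pos)
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    cpos <- genomic_to_cds_pos(cds, chrom, pos)
    if (is.na(cpos))
      return(list(consequence = "noncoding", protein_change = NA_character_))
    cref <- if (cds$strand == "+") ref else unname(COMPLEMENT[ref])
    calt <- if (cds$strand == "+") alt else unname(COMPLEMENT[alt])
    if (substring(cds$cds_seq, cpos, cpos) != cref)
      stop("internal CDS/reference inconsistency at offset ", cpos)
    if (grepl("N", cref, fixed = TRUE) || grepl("N", calt, fixed = TRUE))
      stop("cannot classify substitution involving N at ", chrom, ":", pos)
    cls <- classify_cds_substitution(cds$cds_seq, cpos, calt)
    return(list(consequence = cls$consequence,
                protein_change = cls$protein_change))
  }
  # indel: affected genomic span is the bases after the shared anchor
  dlen <- nchar(alt) - nchar(ref)
  span <- if (dlen < 0L) seq.int(pos + 1L, pos + nchar(ref) - 1L)
          else c(pos, pos + 1L)
  cspan <- genomic_to_cds_pos(cds, chrom, span)
  if (all(is.na(cspan)))
    return(list(consequence = "noncoding", protein_change = NA_character_))
  ci <- (min(cspan, na.rm = TRUE) - 1L) %/% 3L + 1L
  aa <- codon_aa(substring(cds$cds_seq, 3L * ci - 2L, 3L * ci))
  if (abs(dlen) %% 3L != 0L)
    list(consequence = "frameshift", protein_change = paste0(aa, ci, "fs"))
  else
    list(consequence = "inframe_indel",
         protein_change = paste0(aa, ci, if (dlen < 0L) "del" else "ins"))
}

#' Run the full calling chain for one patient
#'
#' Deduplicates, piles up the locus footprint (coding segments plus
#' `pad` flanking bases), and calls variants.
#'
#' @param sam a `sam_frame`.
#' @param genome a `ReferenceGenome`.
#' @param cds the target `CodingSequence`.
#' @param cfg a [caller_config()].
#' @param pad flanking bases around the CDS footprint to pile up.
#' @param coding_only drop `noncoding` calls (the screening definition
#'   considers coding-sequence variants).
#' @param exclude_positions positions of known constitutional variants
#'   (e.g. heterozygous SNPs used for the BAF scan) to mask from somatic
#'   calling.
#' @return data.frame of calls (see [call_variants()]).
#' @export
call_patient <- function(sam, genome, cds, cfg = caller_config(), pad = 50L,
                         coding_only = TRUE, exclude_positions = integer()) {
  fp <- range(cds$segments)
  sites <- pileup(dedup(sam), genome, cds$chrom, fp[1L] - pad, fp[2L] + pad)
  calls <- call_variants(sites, cfg, cds, genome)
  if (length(exclude_positions))
    calls <- calls[!calls$pos %in% exclude_positions, , drop = FALSE]
  if (coding_only) calls <- calls[calls$consequence != "noncoding", ,
                                  drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Write calls as VCF 4.2
#'
#' INFO fields: `VAF` (variant allele fraction), `DP` (deduplicated depth),
#' `AC` (alt read count), `PERR` (binomial error-model tail probability),
#' `CSQ` (consequence), `PCHANGE` (protein change).
#'
#' @param calls data.frame from [call_variants()].
#' @param genome a `ReferenceGenome` (contig header lines).
#' @param path output path.
#' @param sample_id sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, genome, path, sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome),
                   nchar(unclass(genome))),
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Deduplicated depth\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt read count\">",
           "##INFO=<ID=PERR,Number=1,Type=Float,Description=\"Binomial error-model tail probability\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Coding consequence\">",
           "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
           sprintf("##sample=%s", sample_id),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF=%.6g;DP=%d;AC=%d;PERR=%.3g;CSQ=%s;PCHANGE=%s",
    calls$chrom, calls$pos, calls$ref, calls$alt, calls$vaf, calls$depth,
    calls$alt_count, calls$p_error, calls$consequence,
    ifelse(is.na(calls$protein_change), ".", calls$protein_change))
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()] back into a calls table
#' @param path path to the VCF.
#' @return data.frame of calls.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      alt_count = integer(), depth = integer(),
                      vaf = numeric(), p_error = numeric(),
                      consequence = character(),
                      protein_change = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(parts, `[[`, character(1L), 8L)
  get <- function(key) sub(sprintf(".*%s=([^;]*).*", key), "\\1", info)
  data.frame(chrom = vapply(parts, `[[`, character(1L), 1L),
             pos = as.integer(vapply(parts, `[[`, character(1L), 2L)),
             ref = vapply(parts, `[[`, character(1L), 4L),
             alt = vapply(parts, `[[`, character(1L), 5L),
             alt_count = as.integer(get("AC")),
             depth = as.integer(get("DP")),
             vaf = as.numeric(get("VAF")),
             p_error = as.numeric(get("PERR")),
             consequence = get("CSQ"),
             protein_change = ifelse(get("PCHANGE") == ".", NA_character_,
                                     get("PCHANGE")),
             stringsAsFactors = FALSE)
}
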