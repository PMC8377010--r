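#' Last reference-aligned position of a read
#'
#' Adds the lengths of the reference-consuming CIGAR operations
#' (`M, D, N, =, X`) to the alignment start and subtracts one; `I, S, H, P`
#' consume no reference. Invariant to adding leading or trailing soft
#' clips.
#'
#' @param pos 1-based alignment start position(s).
#' @param cigar CIGAR string(s), same length as `pos`.
#' @return integer vector of 1-based last aligned positions.
#' @export
last_aligned_pos <- function(pos, cigar) {
  mapply(function(p, cg) {
    c <- parse_cigar(cg)
    p + sum(c$len[c$op %in% c("M", "D", "N", "=", "X")]) - 1L
  }, as.integer(pos), cigar, USE.NAMES = FALSE)
}

#' Extract soft-clip endpoints from alignments on one chromosome
#'
#' Keeps mapped records on `source_chrom` with mapping quality at least
#' `min_mapq` whose CIGAR contains a soft clip, and records the position of
#' the last aligned base together with the mate chromosome (`"="` marks a
#' same-chromosome mate).
#'
#' @param sam a `sam_frame`.
#' @param source_chrom chromosome to scan.
#' @param min_mapq minimum mapping quality (default 1, mirroring a
#'   `samtools view -q 1` prefilter).
#' @return data.frame `chrom, last_aligned, cigar, mate_chrom, mapq`.
#' @export
extract_endpoints <- function(sam, source_chrom, min_mapq = 1L) {
  keep <- sam$rname == source_chrom & !has_flag(sam$flag, FLAG_UNMAPPED) &
    sam$mapq >= min_mapq & grepl("S", sam$cigar, fixed = TRUE)
  s <- sam[keep, , drop = FALSE]
  if (!nrow(s))
    return(data.frame(chrom = character(), last_aligned = integer(),
                      cigar = character(), mate_chrom = character(),
                      mapq = integer(), stringsAsFactors = FALSE))
  data.frame(chrom = source_chrom,
             last_aligned = last_aligned_pos(s$pos, s$cigar),
             cigar = s$cigar, mate_chrom = s$rnext, mapq = s$mapq,
             stringsAsFactors = FALSE)
}

#' Cluster clip endpoints by position
#'
#' Endpoints are sorted by position; consecutive positions differing by at
#' most `max_gap` merge into one cluster. The default `max_gap = 1`
#' reproduces book-ended merging of adjacent one-base intervals (the
#' semantics of `bedtools merge -d 0` on single-position features). Each
#' cluster records its window, endpoint count, the distinct mate-chromosome
#' set, and the number of inter-chromosomal mates.
#'
#' @param endpoints data.frame from [extract_endpoints()].
#' @param max_gap maximum position difference merged into one cluster.
#' @return data.frame `chrom, start, end, n_endpoints, mate_set,
#'   n_interchrom_mates` with `mate_set` a comma-separated sorted set.
#' @export
cluster_endpoints <- function(endpoints, max_gap = 1L) {
  if (!nrow(endpoints))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_endpoints = integer(),
                      mate_set = character(), n_interchrom_mates = integer(),
                      stringsAsFactors = FALSE))
  if (length(unique(endpoints$chrom)) > 1L)
    stop("endpoints must come from a single chromosome")
  e <- endpoints[order(endpoints$last_aligned), , drop = FALSE]
  newclust <- c(TRUE, diff(e$last_aligned) > max_gap)
  id <- cumsum(newclust)
  do.call(rbind, lapply(split(seq_len(nrow(e)), id), function(idx) {
    mates <- e$mate_chrom[idx]
    data.frame(chrom = e$chrom[idx[1L]],
               start = min(e$last_aligned[idx]),
               end = max(e$last_aligned[idx]),
               n_endpoints = length(idx),
               mate_set = paste(sort(unique(mates), method = "radix"),
                                collapse = ","),
               n_interchrom_mates = sum(mates != "=" & mates != e$chrom[idx]),
               stringsAsFactors = FALSE)
  }))
}

#' Filter clusters by mate-chromosome evidence
#'
#' A cluster is retained iff its distinct mate-chromosome set is exactly
#' `{"=", partner_chrom}`: both same-chromosome and partner-chromosome
#' mates must be present, and no third chromosome may appear.
#'
#' @param clusters data.frame from [cluster_endpoints()].
#' @param partner_chrom the putative translocation partner.
#' @return the input with a logical `retained` column.
#' @export
filter_clusters <- function(clusters, partner_chrom) {
  want <- paste(sort(c("=", partner_chrom), method = "radix"),
                collapse = ",")
  clusters$retained <- clusters$mate_set == want
  clusters
}

#' Localize reciprocal translocation breakpoints from chimeric reads
#'
#' Runs the soft-clip extraction, positional clustering, and
#' mate-chromosome filtering chain on each of the two chromosomes with the
#' other as partner, and reports the retained windows with their support.
#'
#' @param sam a `sam_frame` covering both chromosomes.
#' @param chromA,chromB the two chromosomes of the putative translocation.
#' @param min_mapq,max_gap see [extract_endpoints()] and
#'   [cluster_endpoints()].
#' @return data.frame of all clusters on both chromosomes with their
#'   `retained` flag; retained rows are the candidate breakpoint windows.
#' @export
locate_breakpoints <- function(sam, chromA, chromB, min_mapq = 1L,
                               max_gap = 1L) {
  one <- function(self, partner) {
    cl <- cluster_endpoints(extract_endpoints(sam, self, min_mapq), max_gap)
    filter_clusters(cl, partner)
  }
  out <- rbind(one(chromA, chromB), one(chromB, chromA))
  rownames(out) <- NULL
  if (!any(out$retained))
    message("no retained breakpoint cluster on ", chromA, "/", chromB)
  out
}
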