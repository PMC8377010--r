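#' @importFrom stats pbinom rbinom runif rnorm binom.test cor.test t.test median sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a reference genome from named sequences
#'
#' A reference genome is an ordered set of chromosome sequences over the
#' alphabet ACGTN. Sequences are uppercased on construction.
#'
#' @param seqs named character vector of DNA sequences.
#' @return an object of class `ReferenceGenome` (a named character vector).
#' @export
reference_genome <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) < 1L)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence of ", names(seqs)[bad][1L],
         " contains characters outside ACGTN")
  structure(seqs, class = "ReferenceGenome")
}

#' @export
print.ReferenceGenome <- function(x, ...) {
  cat("ReferenceGenome with", length(x), "chromosome(s):\n")
  for (nm in names(x)) cat(" ", nm, ":", nchar(x[[nm]]), "bp\n")
  invisible(x)
}

#' Length of a chromosome
#' @param genome a `ReferenceGenome`.
#' @param chrom chromosome name.
#' @return integer length in bases.
#' @export
chrom_length <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  nchar(genome[[chrom]])
}

#' Read a FASTA file into a ReferenceGenome
#'
#' Parsing is delegated to [Biostrings::readDNAStringSet()]; sequences are
#' uppercased and restricted to the ACGTN alphabet. A record containing any
#' other character is reported with the 1-based line number where it occurs.
#'
#' @param path path to a FASTA file.
#' @return a `ReferenceGenome`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bad_line <- function() {
    lines <- readLines(path)
    hits <- which(!startsWith(lines, ">") & grepl("[^ACGTNacgtn]", lines))
    if (!length(hits)) return(NULL)
    rec <- sub("^>", "", sub("\\s.*$", "",
                             lines[max(which(startsWith(lines, ">") &
                                               seq_along(lines) < hits[1L]))]))
    stop("invalid character outside ACGTN in record '", rec,
         "' (line ", hits[1L], ")", call. = FALSE)
  }
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e) {
               bad_line()
               stop("malformed FASTA in ", path, ": ",
                    conditionMessage(e), call. = FALSE)
             }),
    warning = function(w) {
      if (grepl("invalid one-letter sequence", conditionMessage(w)))
        bad_line()
      invokeRestart("muffleWarning")
    })
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(grepl("[^ACGTN]", seqs))) bad_line()
  reference_genome(seqs)
}

#' Write a ReferenceGenome to FASTA
#' @param genome a `ReferenceGenome`.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

validate_segments <- function(segments) {
  segments <- as.matrix(segments)
  if (ncol(segments) != 2L) stop("segments must have two columns (start, end)")
  storage.mode(segments) <- "integer"
  colnames(segments) <- c("start", "end")
  if (any(segments[, 1L] > segments[, 2L]))
    stop("segment start greater than end")
  o <- order(segments[, 1L])
  s <- segments[o, , drop = FALSE]
  if (nrow(s) > 1L && any(s[-1L, 1L] <= s[-nrow(s), 2L]))
    stop("segments overlap")
  segments
}

# transcript-order check: + strand ascending, - strand descending genomic
check_transcript_order <- function(segments, strand) {
  if (nrow(segments) < 2L) return(invisible(TRUE))
  starts <- segments[, 1L]
  ok <- if (strand == "+") all(diff(starts) > 0) else all(diff(starts) < 0)
  if (!ok) stop("segments not in 5'->3' transcript order for strand ", strand)
  invisible(TRUE)
}

translate_dna <- function(dna) {
  aa <- Biostrings::translate(Biostrings::DNAString(dna),
                              if.fuzzy.codon = "X")
  as.character(aa)
}

#' Extract and validate a coding sequence from a genome
#'
#' Concatenates the given segments in transcript order (reverse-complementing
#' on the minus strand), checks the open-reading-frame invariants (starts with
#' ATG, ends with a stop codon, length divisible by three and at least six),
#' and derives the protein translation under the standard nuclear code.
#'
#' @param genome a `ReferenceGenome`.
#' @param name identifier for the coding sequence.
#' @param chrom chromosome holding the CDS.
#' @param strand `"+"` or `"-"`.
#' @param segments two-column matrix of 1-based inclusive `[start, end]`
#'   exonic intervals, rows in 5'->3' transcript order (descending genomic
#'   coordinates on the minus strand).
#' @return an object of class `CodingSequence`: a list with elements `name`,
#'   `chrom`, `strand`, `segments`, `cds_seq` and `protein`.
#' @export
extract_cds <- function(genome, name, chrom, strand, segments) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  segments <- validate_segments(segments)
  check_transcript_order(segments, strand)
  L <- chrom_length(genome, chrom)
  if (any(segments < 1L) || any(segments[, 2L] > L))
    stop("segment outside chromosome bounds [1, ", L, "]")
  pieces <- substring(genome[[chrom]], segments[, 1L], segments[, 2L])
  if (strand == "-")
    pieces <- vapply(pieces, revcomp, character(1L), USE.NAMES = FALSE)
  cds_seq <- paste(pieces, collapse = "")
  new_coding_sequence(name, chrom, strand, segments, cds_seq)
}

new_coding_sequence <- function(name, chrom, strand, segments, cds_seq) {
  n <- nchar(cds_seq)
  if (n %% 3L != 0L) stop("CDS length ", n, " not divisible by 3")
  if (n < 6L) stop("CDS length ", n, " below minimum of 6")
  if (substr(cds_seq, 1L, 3L) != "ATG")
    stop("CDS does not begin with ATG start codon")
  if (!substr(cds_seq, n - 2L, n) %in% STOP_CODONS)
    stop("CDS does not end with a stop codon")
  protein <- translate_dna(cds_seq)
  protein <- substr(protein, 1L, nchar(protein) - 1L)  # strip terminal stop
  structure(list(name = name, chrom = chrom, strand = strand,
                 segments = segments, cds_seq = cds_seq, protein = protein),
            class = "CodingSequence")
}

#' @export
print.CodingSequence <- function(x, ...) {
  cat("CodingSequence", x$name, "on", x$chrom, x$strand, "strand;",
      nrow(x$segments), "segment(s),", nchar(x$cds_seq), "coding nt,",
      nchar(x$protein), "aa\n")
  invisible(x)
}

#' Reverse complement of a DNA string
#' @param x a character scalar over ACGTN.
#' @return the reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Map genomic positions to CDS offsets
#'
#' Returns, for each genomic position, the 1-based transcript-order offset
#' within the spliced coding sequence, or `NA` for positions outside the
#' exonic segments (or on another chromosome). On the minus strand the
#' mapping runs antiparallel to genomic coordinates.
#'
#' @param cds a `CodingSequence`.
#' @param chrom chromosome of the positions.
#' @param pos integer vector of 1-based genomic positions.
#' @return integer vector of CDS offsets with `NA` for non-coding positions.
#' @export
genomic_to_cds_pos <- function(cds, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  if (!identical(chrom, cds$chrom)) return(out)
  seg <- cds$segments
  lens <- seg[, 2L] - seg[, 1L] + 1L
  before <- c(0L, cumsum(lens))[seq_len(nrow(seg))]
  for (i in seq_len(nrow(seg))) {
    inside <- pos >= seg[i, 1L] & pos <= seg[i, 2L]
    if (!any(inside)) next
    off <- if (cds$strand == "+") pos[inside] - seg[i, 1L] + 1L
           else seg[i, 2L] - pos[inside] + 1L
    out[inside] <- before[i] + off
  }
  out
}

#' Map CDS offsets back to genomic positions
#'
#' Inverse of [genomic_to_cds_pos()] over the exonic footprint.
#'
#' @param cds a `CodingSequence`.
#' @param cds_pos integer vector of 1-based offsets in `[1, nchar(cds_seq)]`.
#' @return integer vector of genomic positions.
#' @export
cds_to_genomic_pos <- function(cds, cds_pos) {
  n <- nchar(cds$cds_seq)
  if (any(cds_pos < 1L | cds_pos > n)) stop("CDS offset outside [1, ", n, "]")
  seg <- cds$segments
  lens <- seg[, 2L] - seg[, 1L] + 1L
  ends <- cumsum(lens)
  before <- c(0L, ends)[seq_len(nrow(seg))]
  idx <- findInterval(cds_pos - 1L, c(0L, ends), rightmost.closed = FALSE)
  off <- cds_pos - before[idx]
  if (cds$strand == "+") unname(seg[idx, 1L] + off - 1L)
  else unname(seg[idx, 2L] - off + 1L)
}

#' Read a coding-sequence annotation table
#'
#' Six tab-separated columns: name, chrom, strand, comma-separated segment
#' starts, comma-separated segment ends, frame placeholder. Intervals on disk
#' are 0-based half-open (BED convention) and converted to 1-based inclusive
#' in memory.
#'
#' @param path path to the annotation file.
#' @param genome a `ReferenceGenome` to extract sequences from.
#' @return a list of `CodingSequence` objects, named by their identifiers.
#' @export
read_cds_table <- function(path, genome) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 5L) stop("CDS table needs at least 5 columns")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    starts <- as.integer(strsplit(as.character(tab[i, 4L]), ",")[[1L]])
    ends <- as.integer(strsplit(as.character(tab[i, 5L]), ",")[[1L]])
    if (length(starts) != length(ends)) stop("ragged segment lists in row ", i)
    segments <- cbind(start = starts + 1L, end = ends)  # 0-based half-open -> 1-based
    extract_cds(genome, tab[i, 1L], tab[i, 2L], tab[i, 3L], segments)
  })
  names(out) <- tab[[1L]]
  out
}

#' Write coding sequences to an annotation table
#' @param cds_list a list of `CodingSequence` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_table <- function(cds_list, path) {
  if (inherits(cds_list, "CodingSequence")) cds_list <- list(cds_list)
  rows <- vapply(cds_list, function(cds) {
    paste(cds$name, cds$chrom, cds$strand,
          paste(cds$segments[, 1L] - 1L, collapse = ","),
          paste(cds$segments[, 2L], collapse = ","),
          0L, sep = "\t")
  }, character(1L))
  writeLines(rows, path)
  invisible(path)
}
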