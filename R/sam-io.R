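# SAM flag bits used throughout
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_LAST <- 0x80L
FLAG_DUP <- 0x400L

#' Test a SAM flag bit
#' @param flag integer vector of SAM FLAG values.
#' @param bit one of the SAM flag bit masks (e.g. `0x400` for duplicate).
#' @return logical vector.
#' @export
has_flag <- function(flag, bit) bitwAnd(as.integer(flag), as.integer(bit)) != 0L

#' Construct an alignment table
#'
#' Alignments are held as a plain data frame with the eleven mandatory SAM
#' columns (`qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq,
#' qual`), one row per record.
#'
#' @param qname,flag,rname,pos,mapq,cigar,rnext,pnext,tlen,seq,qual SAM fields.
#' @return a data.frame of class `sam_frame`.
#' @export
sam_frame <- function(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      rnext = character(), pnext = integer(),
                      tlen = integer(), seq = character(),
                      qual = character()) {
  df <- data.frame(qname = qname, flag = as.integer(flag), rname = rname,
                   pos = as.integer(pos), mapq = as.integer(mapq),
                   cigar = cigar, rnext = rnext, pnext = as.integer(pnext),
                   tlen = as.integer(tlen), seq = seq, qual = qual,
                   stringsAsFactors = FALSE)
  class(df) <- c("sam_frame", "data.frame")
  df
}

as_sam_frame <- function(df) {
  class(df) <- c("sam_frame", "data.frame")
  rownames(df) <- NULL
  df
}

#' Write alignments to a SAM text file
#'
#' Emits an `@HD`/`@SQ` header built from the genome and the records sorted
#' by chromosome (genome order) and position.
#'
#' @param sam a `sam_frame`.
#' @param genome a `ReferenceGenome` supplying `@SQ` lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   nchar(unclass(genome))))
  ord <- order(match(sam$rname, names(genome)), sam$pos, sam$qname, sam$flag)
  sam <- sam[ord, , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                  sam$cigar, sam$rnext, sam$pnext, sam$tlen, sam$seq,
                  sam$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM text file into an alignment table
#' @param path path to a SAM file.
#' @return a `sam_frame` (header lines are dropped).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(sam_frame())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop("truncated SAM record at line ", which(nf < 11L)[1L])
  f <- function(i) vapply(parts, `[[`, character(1L), i)
  sam_frame(qname = f(1L), flag = as.integer(f(2L)), rname = f(3L),
            pos = as.integer(f(4L)), mapq = as.integer(f(5L)),
            cigar = f(6L), rnext = f(7L), pnext = as.integer(f(8L)),
            tlen = as.integer(f(9L)), seq = f(10L), qual = f(11L))
}

# parse a CIGAR string into (lengths, ops); errors on malformed input
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar))
    return(list(len = integer(), op = character()))
  ops <- gsub("[0-9]", "", cigar)
  if (grepl("[^MIDNSHP=X]", ops) || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    stop("malformed CIGAR: ", cigar)
  len <- as.integer(strsplit(cigar, "[MIDNSHP=X]")[[1L]])
  list(len = len, op = strsplit(ops, "")[[1L]])
}
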