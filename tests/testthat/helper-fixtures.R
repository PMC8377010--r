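# Shared fixtures and independent oracles, all built in code at test time.

# tiny single-exon genome: chrA carries the 9-nt CDS ATG AAA TGA at 11..19
toy_genome <- function() {
  reference_genome(c(chrA = paste0("GGGGGGGGGG", "ATGAAATGA", "CCCCCCCCCC"),
                     chrB = strrep("ACGT", 10)))
}

toy_cds <- function(genome = toy_genome()) {
  extract_cds(genome, "toy", "chrA", "+", cbind(start = 11L, end = 19L))
}

# one-line SAM record with sensible defaults
rec <- function(rname = "chrA", pos = 1L, cigar = "10M",
                seq = strrep("A", 10L), flag = 0L, mapq = 60L,
                rnext = "=", pnext = pos, qname = "r1") {
  sam_frame(qname = qname, flag = flag, rname = rname, pos = pos,
            mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
            tlen = 0L, seq = seq, qual = strrep("I", nchar(seq)))
}

# random valid CDS embedded in a random single-chromosome genome;
# multi-exon and strand drawn at random
random_cds_fixture <- function(n_codons_interior, strand = NULL) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  coding <- 3L * (n_codons_interior + 2L)
  n_ex <- sample(1:3, 1L)
  cuts <- if (n_ex > 1L)
    sort(sample(seq_len(coding - 1L), n_ex - 1L)) else integer()
  exon_coding <- diff(c(0L, cuts, coding))
  introns <- if (n_ex > 1L) sample(20:60, n_ex - 1L, replace = TRUE)
             else integer()
  footprint <- coding + sum(introns)
  simulate_reference(
    seed = sample.int(1e6, 1L),
    chrom_lengths = c(chrZ = footprint + 200L),
    cds_layout = list(name = "rand", chrom = "chrZ", strand = strand,
                      start = 101L, exon_coding = exon_coding,
                      introns = introns))
}

# Brute-force consequence oracle: apply the substitution to a full copy of
# the CDS, translate both copies end to end with seqinr (independent code
# path), and classify by comparing the translations.
oracle_classify <- function(cds_seq, cpos, alt) {
  mutant <- cds_seq
  substr(mutant, cpos, cpos) <- alt
  tr <- function(s)
    seqinr::translate(seqinr::s2c(s), numcode = 1)
  p_ref <- tr(cds_seq)
  p_alt <- tr(mutant)
  ci <- (cpos - 1L) %/% 3L + 1L
  if (ci == 1L) return("start_loss")
  if (identical(p_ref, p_alt)) return("synonymous")
  if (p_alt[ci] == "*") return("nonsense")
  if (p_ref[ci] == "*" && p_alt[ci] != "*") return("stop_loss")
  "missense"
}

# Literal re-execution oracle for the chimeric-read procedure: runs the
# actual printed pipeline (samtools | cut | grep | awk | sort | bedtools
# merge) on a SAM file and returns the merged clusters.
literal_breakpoint_oracle <- function(sam, genome, source_chrom,
                                      partner_chrom) {
  td <- withr::local_tempdir()
  samf <- file.path(td, "in.sam")
  bamf <- file.path(td, "in.bam")
  write_sam(sam, genome, samf)
  ok <- system2("samtools", c("sort", "-o", bamf, samf),
                stdout = FALSE, stderr = FALSE) == 0L &&
    system2("samtools", c("index", bamf), stdout = FALSE,
            stderr = FALSE) == 0L
  if (!ok) stop("samtools unavailable or failed")
  awk <- paste0(
    "{pos=$2; split($3,a,\"[IMDSH]\"); split($3,b,\"[0-9]*\"); ",
    "nb=length(b); for (i=2; i<=nb; i++) if (b[i] ~ /[MD]/) ",
    "pos=pos+a[i-1]; ",
    "printf(\"%s\\t%s\\t%s\\t%s\\t%s\\t%s\\n\",$1,pos-1,pos-1,$3,$4,$5)}")
  cmd <- paste0("samtools view -q 1 ", shQuote(bamf), " ",
                shQuote(source_chrom),
                " | cut -f3,4,6-8 | grep S | awk '", awk,
                "' | sort -k2,2n | bedtools merge -d 0 -c 5,6",
                " -o distinct,distinct")
  out <- system(paste("LC_ALL=C", cmd), intern = TRUE)
  if (!length(out))
    return(data.frame(chrom = character(), start0 = integer(),
                      end0 = integer(), mate_set = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(out, "\t", fixed = TRUE))
  data.frame(chrom = parts[, 1L], start0 = as.integer(parts[, 2L]),
             end0 = as.integer(parts[, 3L]), mate_set = parts[, 4L],
             stringsAsFactors = FALSE)
}
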