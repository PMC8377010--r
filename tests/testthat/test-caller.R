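test_that("dedup removes exactly the duplicate-flagged records, idempotently", {
  clean <- do.call(rbind, lapply(1:90, function(i)
    rec(qname = paste0("r", i), pos = i)))
  dups <- do.call(rbind, lapply(1:10, function(i)
    rec(qname = paste0("d", i), pos = i, flag = 0x400L)))
  sam <- as_sam <- rbind(clean, dups)
  expect_identical(nrow(dedup(sam)), 90L)
  expect_identical(dedup(clean), sgrscreen::dedup(clean))
  expect_identical(dedup(dedup(sam)), dedup(sam))
  expect_identical(dedup(sam)$qname, clean$qname)  # order preserved
})

test_that("pileup walks CIGARs correctly and ignores soft clips", {
  g <- reference_genome(c(chrA = strrep("A", 60)))
  # 10M perfect read at 100.. -> use pos 21
  sam <- rec(pos = 21L, cigar = "10M", seq = strrep("A", 10))
  p <- pileup(sam, g, "chrA", 1L, 60L)
  expect_identical(sum(p$depth), 10L)
  expect_true(all(p$A[p$pos %in% 21:30] == 1L))

  # single mismatch at offset 5 (pos 25)
  s2 <- rec(pos = 21L, cigar = "10M", seq = "AAAACAAAAA")
  p2 <- pileup(s2, g, "chrA", 21L, 30L)
  expect_identical(p2$C[p2$pos == 25L], 1L)
  expect_identical(sum(p2$C), 1L)
  expect_identical(sum(p2$A), 9L)

  # 5S10M: clipped bases contribute nothing, alignment spans 10 bases
  s3 <- rec(pos = 21L, cigar = "5S10M", seq = paste0("CCCCC", strrep("A", 10)))
  p3 <- pileup(s3, g, "chrA", 1L, 60L)
  expect_identical(sum(p3$depth), 10L)
  expect_identical(range(p3$pos[p3$depth > 0L]), c(21L, 30L))

  # deletion: 4M2D4M consumes 10 reference bases, records a -2 allele
  s4 <- rec(pos = 21L, cigar = "4M2D4M", seq = strrep("A", 8))
  p4 <- pileup(s4, g, "chrA", 1L, 60L)
  ind <- attr(p4, "indels")
  expect_identical(ind$allele, "-2")
  expect_identical(ind$pos, 24L)
  expect_identical(p4$depth[p4$pos %in% 25:26], c(1L, 1L))

  # MAPQ 0 and unmapped records are excluded
  s5 <- rbind(rec(pos = 21L, mapq = 0L), rec(pos = 21L, flag = 0x4L))
  expect_identical(sum(pileup(s5, g, "chrA", 1L, 60L)$depth), 0L)

  # CIGAR/sequence length mismatch is skipped and counted
  s6 <- rec(pos = 21L, cigar = "11M", seq = strrep("A", 10))
  p6 <- pileup(s6, g, "chrA", 1L, 60L)
  expect_identical(attr(p6, "n_skipped"), 1L)
  expect_identical(sum(p6$depth), 0L)
})

test_that("binomial error filter matches independently computed tails", {
  # frozen oracle: sum(dbinom(10:2000, 2000, 1e-3)) computed by direct
  # summation of the binomial mass
  expect_equal(pbinom(9, 2000, 1e-3, lower.tail = FALSE), 4.583307e-05,
               tolerance = 1e-6)

  g <- reference_genome(c(chrA = paste0(strrep("C", 30), "ATGAAATGA",
                                        strrep("C", 30))))
  cds <- extract_cds(g, "t", "chrA", "+", cbind(31L, 39L))
  mk_sites <- function(alt_n, depth = 2000L) {
    s <- pileup(sam_frame(), g, "chrA", 31L, 39L)
    s$depth <- depth
    s$A <- ifelse(s$ref == "A", depth - ifelse(s$pos == 34L, alt_n, 0L), 0L)
    s$T <- ifelse(s$ref == "T", depth, 0L)
    s$G <- ifelse(s$ref == "G", depth, ifelse(s$pos == 34L, alt_n, 0L))
    s$C <- 0L
    s
  }
  cfg <- caller_config("locus", alpha = 0.05)
  # vaf exactly 0.005 with alt 10 of 2000: tail 4.58e-5 < 0.05/(3*9)
  calls <- call_variants(mk_sites(10L), cfg, cds, g)
  expect_identical(nrow(calls), 1L)
  expect_equal(calls$vaf, 0.005)
  expect_equal(calls$p_error, 4.583307e-05, tolerance = 1e-6)
  # alt 9 (vaf 0.0045) fails the VAF threshold
  expect_identical(nrow(call_variants(mk_sites(9L), cfg, cds, g)), 0L)
  # zero alt reads never called
  expect_identical(nrow(call_variants(mk_sites(0L), cfg, cds, g)), 0L)
  # min_alt_reads dominates at low depth
  cfg2 <- caller_config("locus", min_alt_reads = 3L)
  expect_identical(nrow(call_variants(mk_sites(2L, depth = 300L), cfg2,
                                      cds, g)), 0L)
})

test_that("consequence annotation matches hand-translated examples", {
  g <- toy_genome()  # ATG AAA TGA at 11..19
  cds <- toy_cds(g)
  # codon 2 base 1: AAA->GAA = K2E missense
  a <- annotate_consequence(g, cds, "chrA", 14L, "A", "G")
  expect_identical(a$consequence, "missense")
  expect_identical(a$protein_change, "K2E")
  # codon 2 base 3: AAA->AAG synonymous
  b <- annotate_consequence(g, cds, "chrA", 16L, "A", "G")
  expect_identical(b$consequence, "synonymous")
  # codon 1 base 1: start codon lost, M1L
  c <- annotate_consequence(g, cds, "chrA", 11L, "A", "C")
  expect_identical(c$consequence, "start_loss")
  expect_identical(c$protein_change, "M1L")
  # stop codon to sense: stop_loss
  d <- annotate_consequence(g, cds, "chrA", 17L, "T", "C")
  expect_identical(d$consequence, "stop_loss")
  # outside the CDS: noncoding
  e <- annotate_consequence(g, cds, "chrA", 5L, "G", "T")
  expect_identical(e$consequence, "noncoding")
  # ref mismatch is an error naming the position
  expect_error(annotate_consequence(g, cds, "chrA", 14L, "C", "G"), "14")
  # frameshift vs in-frame indels
  f <- annotate_consequence(g, cds, "chrA", 13L,
                            substring(g[["chrA"]], 13L, 15L), "G")
  expect_identical(f$consequence, "frameshift")
  h <- annotate_consequence(g, cds, "chrA", 13L,
                            substring(g[["chrA"]], 13L, 16L), "G")
  expect_identical(h$consequence, "inframe_indel")
})

test_that("consequence classifier agrees with full-translation brute force", {
  set.seed(7)
  for (trial in 1:4) {
    fix <- random_cds_fixture(sample(10:60, 1L))
    cds <- fix$cds
    L <- nchar(cds$cds_seq)
    refs <- strsplit(cds$cds_seq, "")[[1L]]
    idx <- sample(L, 60L, replace = TRUE)
    for (cpos in idx) {
      alt <- sample(setdiff(c("A", "C", "G", "T"), refs[cpos]), 1L)
      gpos <- cds_to_genomic_pos(cds, cpos)
      gref <- substring(fix$genome[[cds$chrom]], gpos, gpos)
      galt <- if (cds$strand == "+") alt else revcomp(alt)
      got <- annotate_consequence(fix$genome, cds, cds$chrom, gpos,
                                  gref, galt)
      expect_identical(got$consequence, oracle_classify(cds$cds_seq,
                                                        cpos, alt),
                       info = sprintf("trial %d cpos %d alt %s strand %s",
                                      trial, cpos, alt, cds$strand))
    }
  }
})

test_that("calling recovers planted clones and estimates VAF without bias", {
  ref <- simulate_reference(seed = 31)
  gpos <- cds_to_genomic_pos(ref$cds, c(100L, 400L, 650L))
  refb <- substring(ref$genome[[ref$cds$chrom]], gpos, gpos)
  alts <- vapply(refb, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1L], character(1L))
  hits <- 0L; est <- c()
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    sp <- patient_spec("P", 5, events = list(
      snv_event(ref$cds$chrom, gpos[1L], refb[1L], alts[1L], 0.02),
      snv_event(ref$cds$chrom, gpos[2L], refb[2L], alts[2L], 0.10),
      snv_event(ref$cds$chrom, gpos[3L], refb[3L], alts[3L], 0.30)),
      mean_depth = 2000L, seed = 100L + s)
    calls <- call_patient(sp |> simulate_patient_reads(ref$genome,
                                                       ref$cds) |>
                            getElement("sam"),
                          ref$genome, ref$cds, caller_config("locus"))
    found <- calls[match(gpos, calls$pos), ]
    hits <- hits + sum(!is.na(found$vaf))
    est <- c(est, found$vaf - c(0.01, 0.05, 0.15))
  }
  expect_gte(hits / (3L * n_seeds), 0.95)
  se <- sqrt(mean(c(0.01, 0.05, 0.15)) / (2000 * length(est)))
  expect_lt(abs(mean(est, na.rm = TRUE)), 3 * se)
})

test_that("VCF output round-trips calls", {
  ref <- simulate_reference(seed = 41)
  sp <- patient_spec("P", 5, events = list(
    snv_event(ref$cds$chrom, cds_to_genomic_pos(ref$cds, 200L),
              substring(ref$genome[[ref$cds$chrom]],
                        cds_to_genomic_pos(ref$cds, 200L),
                        cds_to_genomic_pos(ref$cds, 200L)),
              setdiff(c("A", "C", "G", "T"),
                      substring(ref$genome[[ref$cds$chrom]],
                                cds_to_genomic_pos(ref$cds, 200L),
                                cds_to_genomic_pos(ref$cds, 200L)))[1L],
              0.2)), mean_depth = 1500L, seed = 8L)
  out <- simulate_patient_reads(sp, ref$genome, ref$cds)
  calls <- call_patient(out$sam, ref$genome, ref$cds, caller_config("locus"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, ref$genome, f, "P")
  back <- read_vcf_calls(f)
  expect_identical(back$pos, calls$pos)
  expect_identical(back$consequence, calls$consequence)
  expect_equal(back$vaf, calls$vaf, tolerance = 1e-5)
})
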