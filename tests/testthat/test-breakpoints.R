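test_that("last_aligned_pos adds reference-consuming operations only", {
  expect_identical(last_aligned_pos(100L, "50M"), 149L)
  expect_identical(last_aligned_pos(100L, "30M5I20M10S"), 149L)
  expect_identical(last_aligned_pos(100L, "10S40M2D8M"), 149L)
  expect_identical(last_aligned_pos(100L, "40M3N10M"), 152L)
  expect_identical(last_aligned_pos(100L, "20=5X25M"), 149L)
  expect_error(last_aligned_pos(100L, "50Q"), "CIGAR")
  # invariance to added leading/trailing soft clips
  set.seed(3)
  for (i in 1:20) {
    core <- paste0(sample(20:80, 1L), "M", sample(1:5, 1L), "D",
                   sample(5:30, 1L), "M")
    p <- sample.int(5000L, 1L)
    base <- last_aligned_pos(p, core)
    expect_identical(last_aligned_pos(p, paste0("7S", core)), base)
    expect_identical(last_aligned_pos(p, paste0(core, "12S")), base)
    expect_identical(last_aligned_pos(p, paste0("3S", core, "9S")), base)
  }
})

test_that("endpoint extraction applies the soft-clip and MAPQ filters", {
  sam <- rbind(
    rec(rname = "chr16S", pos = 100L, cigar = "130M",
        seq = strrep("A", 130L)),                      # no S: excluded
    rec(rname = "chr16S", pos = 200L, cigar = "60M70S",
        seq = strrep("A", 130L), rnext = "chr20S"),
    rec(rname = "chr16S", pos = 300L, cigar = "60M70S",
        seq = strrep("A", 130L), mapq = 0L),           # MAPQ 0: excluded
    rec(rname = "chr20S", pos = 400L, cigar = "60M70S",
        seq = strrep("A", 130L)))                      # other chrom
  ep <- extract_endpoints(sam, "chr16S", min_mapq = 1L)
  expect_identical(nrow(ep), 1L)
  expect_identical(ep$last_aligned, 259L)
  expect_identical(ep$mate_chrom, "chr20S")
})

test_that("clustering uses book-ended merge semantics", {
  ep <- data.frame(chrom = "c", last_aligned = c(200L, 200L, 201L),
                   cigar = "60M70S", mate_chrom = c("=", "p", "p"),
                   mapq = 60L, stringsAsFactors = FALSE)
  cl <- cluster_endpoints(ep, max_gap = 1L)
  expect_identical(nrow(cl), 1L)
  expect_identical(c(cl$start, cl$end), c(200L, 201L))
  expect_identical(cl$n_endpoints, 3L)
  expect_identical(cl$mate_set, "=,p")
  expect_identical(cl$n_interchrom_mates, 2L)

  ep2 <- ep; ep2$last_aligned <- c(200L, 250L, 250L)
  expect_identical(nrow(cluster_endpoints(ep2, max_gap = 1L)), 2L)
  expect_identical(nrow(cluster_endpoints(ep[0L, ])), 0L)
})

test_that("mate-set filtering requires exactly same-chromosome plus partner", {
  cl <- data.frame(chrom = "chr16S", start = 1L, end = 2L, n_endpoints = 3L,
                   mate_set = c("=,chr20S", "=,chr17S,chr20S", "=",
                                "chr20S"),
                   n_interchrom_mates = 1L, stringsAsFactors = FALSE)
  out <- filter_clusters(cl, "chr20S")
  expect_identical(out$retained, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("breakpoint windows contain the junction across random simulations", {
  ref <- simulate_reference(seed = 61)
  n_sims <- 12L
  set.seed(99)
  posA <- sample(500:2500, n_sims)
  posB <- sample(500:3500, n_sims)
  for (i in seq_len(n_sims)) {
    sp <- patient_spec("P", 1, events = list(
      translocation_event("chr16S", posA[i], "chr20S", posB[i], 0.4)),
      mean_depth = 400L, seed = 700L + i)
    out <- simulate_patient_reads(sp, ref$genome, ref$cds)
    bp <- locate_breakpoints(out$sam, "chr16S", "chr20S")
    ret <- bp[bp$retained, ]
    a <- ret[ret$chrom == "chr16S", ]
    expect_true(nrow(a) >= 1L)
    expect_true(any(a$start <= posA[i] & a$end >= posA[i]),
                info = paste("sim", i))
    expect_true(all(a$end - a$start + 1L <= 130L))
    b <- ret[ret$chrom == "chr20S", ]
    expect_true(any(b$start <= posB[i] & b$end >= posB[i]),
                info = paste("sim", i))
  }
})

test_that("patients without a translocation yield no retained clusters", {
  ref <- simulate_reference(seed = 62)
  hits <- vapply(1:25, function(s) {
    sp <- patient_spec("P", 1, mean_depth = 600L, seed = 900L + s)
    out <- simulate_patient_reads(sp, ref$genome, ref$cds)
    suppressMessages(
      bp <- locate_breakpoints(out$sam, "chr20S", "chr16S"))
    sum(bp$retained)
  }, numeric(1L))
  expect_gte(mean(hits == 0L), 0.95)
})

test_that("reads on one chromosome only leave the partner side empty", {
  sam <- rec(rname = "chr16S", pos = 200L, cigar = "60M70S",
             seq = strrep("A", 130L), rnext = "chr20S")
  sam <- rbind(sam, rec(rname = "chr16S", pos = 201L, cigar = "59M71S",
                        seq = strrep("A", 130L), rnext = "="))
  bp <- locate_breakpoints(sam, "chr16S", "chr20S")
  expect_identical(unique(bp$chrom), "chr16S")
  expect_true(all(bp$retained))
})

test_that("module output matches a literal re-execution of the printed command", {
  # M/D-only CIGARs so the module's {M,D,N,=,X} rule and the command's
  # [MD] rule agree; chromosome names carry no "S" because the printed
  # `grep S` matches the whole line; fixture includes multi-read clusters,
  # a same-chromosome mate, a third-chromosome contaminant, and a MAPQ-0
  # record
  g <- reference_genome(c(chr16 = strrep("ACGT", 500),
                          chr20 = strrep("TTGA", 500),
                          chr9 = strrep("GATC", 500)))
  mk <- function(pos, cigar, rnext, mapq = 60L, qname = "q") {
    rec(rname = "chr16", pos = pos, cigar = cigar,
        seq = strrep("A", sum(as.integer(
          strsplit(cigar, "[MIDSH]")[[1L]])[
            strsplit(gsub("[0-9]+", "", cigar), "")[[1L]] %in%
              c("M", "I", "S")])),
        rnext = rnext, mapq = mapq, qname = qname)
  }
  sam <- rbind(
    mk(100L, "50M80S", "chr20", qname = "a"),
    mk(101L, "49M81S", "=", qname = "b"),
    mk(99L, "30M2D19M81S", "chr20", qname = "c"),    # same endpoint 149
    mk(400L, "60M70S", "chr20", qname = "d"),        # lone cluster
    mk(600L, "60M70S", "chr9", qname = "e"),         # wrong partner
    mk(800L, "60M70S", "chr20", mapq = 0L, qname = "f"),
    mk(900L, "130M", "chr20", qname = "g"))          # no soft clip
  ep <- extract_endpoints(sam, "chr16")
  cl <- filter_clusters(cluster_endpoints(ep), "chr20")
  orc <- literal_breakpoint_oracle(sam, g, "chr16", "chr20")

  expect_identical(nrow(cl), nrow(orc))
  # mate sets agree field by field (bedtools 'distinct' is sorted)
  expect_identical(cl$mate_set, orc$mate_set)
  # the printed awk's pos-1 equals the 1-based last aligned base, so
  # windows agree up to bedtools' one-base expansion of the zero-length
  # intervals it merges
  expect_true(all(cl$start >= orc$start0 & cl$start <= orc$start0 + 1L))
  expect_true(all(cl$end >= orc$end0 - 1L & cl$end <= orc$end0))
  # and the retained set matches the printed grep pattern
  grep_keep <- grepl("=,chr20|chr20,=", orc$mate_set) &
    !grepl("=,chr20,|chr20,=,", orc$mate_set)
  expect_identical(cl$retained, grep_keep)
})
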