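test_that("the SNV space of a 738-nt CDS has exactly 2214 records", {
  ref <- simulate_reference(seed = 71)
  space <- enumerate_snvs(ref$cds)
  expect_identical(nrow(space$records), 2214L)
  expect_identical(sum(space$class_counts), 2214L)
  expect_false(anyDuplicated(paste(space$records$cds_pos,
                                   space$records$alt)) > 0L)
})

test_that("the toy CDS space matches brute-force classification of all 18 SNVs", {
  g <- reference_genome(c(c1 = paste0("TTTT", "ATGTGA", "TTTT")))
  cds <- extract_cds(g, "toy", "c1", "+", cbind(5L, 10L))
  space <- enumerate_snvs(cds)
  expect_identical(nrow(space$records), 18L)
  want <- vapply(seq_len(18L), function(i)
    oracle_classify(cds$cds_seq, space$records$cds_pos[i],
                    space$records$alt[i]), character(1L))
  expect_identical(space$records$consequence, want)
  # all 9 substitutions of the initiator codon lose the start
  expect_true(all(space$records$consequence[space$records$cds_pos <= 3L] ==
                    "start_loss"))
  # the stop codon TGA tolerates TGA->TAA as a synonymous stop swap
  stoprec <- space$records[space$records$cds_pos > 3L, ]
  expect_true("stop_loss" %in% stoprec$consequence)
  expect_true("synonymous" %in% stoprec$consequence)
  # dN/dS of the whole toy space against itself is 1
  expect_equal(observed_dnds(space$records, space), 1)
})

test_that("space size and class partition hold for random CDSs", {
  set.seed(17)
  for (i in 1:6) {
    fix <- random_cds_fixture(sample(5:80, 1L))
    space <- enumerate_snvs(fix$cds)
    L <- nchar(fix$cds$cds_seq)
    expect_identical(nrow(space$records), 3L * L)
    expect_identical(sum(space$class_counts), 3L * L)
    # genomic positions map back to the CDS offsets
    expect_identical(
      genomic_to_cds_pos(fix$cds, fix$cds$chrom, space$records$gpos),
      space$records$cds_pos)
  }
})

test_that("expected N/S ratio follows the combinatorial count on 4-fold codons", {
  # CDS of k four-fold-degenerate codons (GGx glycine) between start and
  # stop: each interior codon contributes 6 nonsynonymous and 3 synonymous
  # substitutions; ATG adds 9 N and the stop codon TAA adds 7 N + 2 S
  for (k in c(4L, 10L)) {
    g <- reference_genome(c(c1 = paste0(
      "AA", "ATG", strrep("GGC", k), "TAA", "AA")))
    cds <- extract_cds(g, "ff", "c1", "+", cbind(3L, 3L + 3L * (k + 2L) - 1L))
    space <- enumerate_snvs(cds)
    interior <- space$records[space$records$codon_index > 1L &
                                space$records$codon_index < k + 2L, ]
    expect_identical(sum(interior$consequence != "synonymous"), 6L * k)
    expect_identical(sum(interior$consequence == "synonymous"), 3L * k)
    expect_equal(sum(interior$consequence != "synonymous") /
                   sum(interior$consequence == "synonymous"), 2)
    expect_equal(expected_ns_ratio(space), (6 * k + 9 + 7) / (3 * k + 2))
  }
})

test_that("observed dN/dS is ratio-invariant and neutral on uniform draws", {
  ref <- simulate_reference(seed = 72)
  space <- enumerate_snvs(ref$cds)
  obs <- space$records[space$records$consequence %in%
                         c("missense", "synonymous"), ][1:40, ]
  d1 <- observed_dnds(obs, space)
  d2 <- observed_dnds(rbind(obs, obs), space)
  expect_equal(d1, d2)
  expect_error(observed_dnds(
    space$records[space$records$consequence == "missense", ][1:5, ], space),
    "synonymous")

  # uniform subsamples of the space are neutral on average
  set.seed(5)
  draws <- replicate(200L, {
    sub <- space$records[sample.int(nrow(space$records), 400L), ]
    if (!any(sub$consequence == "synonymous")) return(NA_real_)
    observed_dnds(sub, space)
  })
  se <- sd(draws, na.rm = TRUE) / sqrt(sum(!is.na(draws)))
  expect_lt(abs(mean(draws, na.rm = TRUE) - 1), 3 * se + 0.02)
})

test_that("start-loss exclusion removes M1 records from both sides of the ratio", {
  ref <- simulate_reference(seed = 73)
  space <- enumerate_snvs(ref$cds)
  r_incl <- expected_ns_ratio(space)
  r_excl <- expected_ns_ratio(space, exclude_start_loss = TRUE)
  expect_equal(r_incl - r_excl,
               9 / space$class_counts[["synonymous"]])
  expect_equal(observed_dnds(space$records, space,
                             exclude_start_loss = TRUE), 1)
})

test_that("score background comparison reproduces closed-form t-tests", {
  # textbook check: {1,2,3} vs {2,3,4} equal variance gives t = -sqrt(1.5)
  tt <- unpaired_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -sqrt(1.5))
  expect_equal(tt$df, 4)
  # hand computation for 3 vs 4 values
  a <- c(30.2, 24.1, 28.5); b <- c(4.2, 9.9, 7.4, 6.0)
  sp2 <- (2 * var(a) + 3 * var(b)) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_hand), df = 5)
  tt2 <- unpaired_t(a, b)
  expect_equal(tt2$t, t_hand)
  expect_equal(tt2$p, p_hand)
  expect_error(unpaired_t(c(1, 1), c(1, 1)), "identical")

  ref <- simulate_reference(seed = 74)
  space <- add_scores(enumerate_snvs(ref$cds),
                      synthetic_score_table(enumerate_snvs(ref$cds),
                                            seed = 2L))
  # observed = whole space: means agree and t = 0
  res <- score_background_test(space$records, space)
  expect_equal(res$mean_obs, res$mean_all)
  expect_equal(res$t, 0)
  expect_equal(res$p_two_sided, 1)
  # nonsynonymous-biased observation scores above background
  obs <- space$records[space$records$consequence == "nonsense", ][1:10, ]
  res2 <- score_background_test(obs, space)
  expect_gt(res2$mean_obs, res2$mean_all)
  expect_lt(res2$p_two_sided, 1e-3)
  expect_equal(res2$df, 10 + nrow(space$records) - 2)
  # missing scores are reported by SNV
  sp2 <- space; sp2$records$score[1L] <- NA
  bad <- space$records[1L, , drop = FALSE]
  expect_error(score_background_test(bad, sp2), "missing score")
})

test_that("score tables round-trip through the 4-column format", {
  ref <- simulate_reference(seed = 75)
  space <- enumerate_snvs(ref$cds)
  tab <- synthetic_score_table(space, seed = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_score_table(f)
  expect_equal(back$score, tab$score, tolerance = 1e-12)
  space2 <- add_scores(space, back)
  expect_identical(sum(is.na(space2$records$score)), 0L)
})
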