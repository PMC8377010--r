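NONSYN_CLASSES <- c("missense", "nonsense", "stop_loss", "start_loss")

# classify a single-base substitution in CDS coordinates
classify_cds_substitution <- function(cds_seq, cpos, calt) {
  gc <- Biostrings::GENETIC_CODE
  ci <- (cpos - 1L) %/% 3L + 1L
  off <- (cpos - 1L) %% 3L + 1L
  codon <- substring(cds_seq, 3L * ci - 2L, 3L * ci)
  mutant <- codon
  substr(mutant, off, off) <- calt
  aa_ref <- unname(gc[codon]); aa_alt <- unname(gc[mutant])
  cons <- ifelse(ci == 1L, "start_loss",
          ifelse(aa_ref == aa_alt, "synonymous",
          ifelse(aa_alt == "*", "nonsense",
          ifelse(aa_ref == "*", "stop_loss", "missense"))))
  list(consequence = cons, codon_index = ci,
       protein_change = paste0(aa_ref, ci, aa_alt))
}

#' Enumerate every possible SNV of a coding sequence
#'
#' Produces all `3 L` single-nucleotide substitutions of an `L`-nucleotide
#' CDS, each classified by consequence (same logic as the caller's
#' annotation) and mapped back to genomic coordinates.
#'
#' @param cds a `CodingSequence`.
#' @return an object of class `SnvSpace`: list with `name`, `records`
#'   (data.frame `cds_pos, gpos, ref, alt, codon_index, consequence,
#'   protein_change`) and `class_counts`.
#' @export
enumerate_snvs <- function(cds) {
  L <- nchar(cds$cds_seq)
  if (grepl("N", cds$cds_seq, fixed = TRUE))
    stop("CDS contains N; SNV enumeration requires a fully resolved sequence")
  refs <- strsplit(cds$cds_seq, "", fixed = TRUE)[[1L]]
  cpos <- rep(seq_len(L), each = 3L)
  ref <- refs[cpos]
  alt <- unlist(lapply(refs, function(b) setdiff(DNA_BASES, b)),
                use.names = FALSE)
  cls <- classify_cds_substitution(cds$cds_seq, cpos, alt)
  gpos <- cds_to_genomic_pos(cds, cpos)
  records <- data.frame(cds_pos = cpos, gpos = gpos, ref = ref, alt = alt,
                        codon_index = cls$codon_index,
                        consequence = cls$consequence,
                        protein_change = cls$protein_change,
                        stringsAsFactors = FALSE)
  counts <- table(factor(records$consequence,
                         levels = c("synonymous", NONSYN_CLASSES)))
  stopifnot(nrow(records) == 3L * L, sum(counts) == 3L * L)
  structure(list(name = cds$name, records = records,
                 class_counts = counts), class = "SnvSpace")
}

#' @export
print.SnvSpace <- function(x, ...) {
  cat("SnvSpace of", x$name, "with", nrow(x$records), "records\n")
  print(x$class_counts)
  invisible(x)
}

#' Expected nonsynonymous/synonymous ratio under neutrality
#'
#' The ratio of possible nonsynonymous substitutions (missense, nonsense,
#' stop-loss, start-loss) to possible synonymous substitutions over the
#' full SNV space. A set of observed variants drawn uniformly from the
#' space has dN/dS of exactly 1 against this expectation.
#'
#' @param space an `SnvSpace`.
#' @param exclude_start_loss drop initiator-codon substitutions from the
#'   nonsynonymous count.
#' @return the expected N/S ratio.
#' @export
expected_ns_ratio <- function(space, exclude_start_loss = FALSE) {
  cls <- if (exclude_start_loss) setdiff(NONSYN_CLASSES, "start_loss")
         else NONSYN_CLASSES
  n_pos <- sum(space$class_counts[cls])
  s_pos <- space$class_counts[["synonymous"]]
  if (s_pos == 0L)
    stop("degenerate CDS: no synonymous substitution is possible")
  n_pos / s_pos
}

#' Observed dN/dS against the neutral expectation
#'
#' The observed nonsynonymous/synonymous variant-count ratio divided by
#' the ratio possible in the space (count-based site normalization without
#' transition/transversion weighting). A value of 1 indicates neutrality.
#'
#' @param observed data.frame of observed SNVs carrying a `consequence`
#'   column with the caller's class labels (indels must be excluded by the
#'   caller).
#' @param space the `SnvSpace` of the same CDS.
#' @param exclude_start_loss drop start-loss records from both numerator
#'   and expectation.
#' @return the dN/dS ratio.
#' @export
observed_dnds <- function(observed, space, exclude_start_loss = FALSE) {
  cls <- if (exclude_start_loss) setdiff(NONSYN_CLASSES, "start_loss")
         else NONSYN_CLASSES
  if (any(!observed$consequence %in% c("synonymous", NONSYN_CLASSES)))
    stop("observed records must be SNVs with coding consequence classes")
  obs_n <- sum(observed$consequence %in% cls)
  obs_s <- sum(observed$consequence == "synonymous")
  if (obs_s == 0L)
    stop("no observed synonymous variant; dN/dS undefined ",
         "(consider a pseudocount upstream if appropriate)")
  (obs_n / obs_s) / expected_ns_ratio(space, exclude_start_loss)
}

#' Read a per-SNV score table
#'
#' Four tab-separated columns: CDS position, ref, alt, score.
#'
#' @param path path to the table.
#' @return data.frame `cds_pos, ref, alt, score`.
#' @export
read_score_table <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("cds_pos", "ref", "alt", "score")
  if (any(!is.finite(tab$score))) stop("scores must be finite")
  tab
}

#' Attach scores to an SNV space
#' @param space an `SnvSpace`.
#' @param table a score table from [read_score_table()].
#' @return the space with a `score` column on its records (NA where the
#'   table has no entry).
#' @export
add_scores <- function(space, table) {
  key <- function(p, r, a) paste(p, r, a, sep = ":")
  i <- match(key(space$records$cds_pos, space$records$ref,
                 space$records$alt),
             key(table$cds_pos, table$ref, table$alt))
  space$records$score <- table$score[i]
  space
}

#' Generate a synthetic deleteriousness score table
#'
#' A stand-in for an external per-SNV deleteriousness score (such tables
#' are consumed as data, never computed here): scores are drawn from
#' class-dependent normal distributions so that truncating classes
#' (nonsense, start-loss, stop-loss) score higher than missense, which
#' scores higher than synonymous — the qualitative structure any
#' deleteriousness predictor shows on a coding locus.
#'
#' @param space an `SnvSpace`.
#' @param seed integer seed.
#' @return a score table (data.frame `cds_pos, ref, alt, score`).
#' @export
synthetic_score_table <- function(space, seed = 1L) {
  set.seed(seed)
  r <- space$records
  mu <- c(synonymous = 5, missense = 22, nonsense = 36, start_loss = 30,
          stop_loss = 30)[r$consequence]
  data.frame(cds_pos = r$cds_pos, ref = r$ref, alt = r$alt,
             score = pmax(0, stats::rnorm(nrow(r), mu, 6)),
             stringsAsFactors = FALSE)
}

#' Compare observed SNV scores against the full-space background
#'
#' Two-sample unpaired Student's t-test (equal variance by default; Welch
#' optional) of the observed variants' scores against the scores of every
#' possible SNV of the CDS.
#'
#' @param observed data.frame of observed SNVs with `cds_pos` and `alt`.
#' @param space an `SnvSpace` with scores attached ([add_scores()]).
#' @param welch use the Welch (unequal-variance) test.
#' @return list `mean_obs, mean_all, t, df, p_two_sided`.
#' @export
score_background_test <- function(observed, space, welch = FALSE) {
  if (is.null(space$records$score))
    stop("space has no scores; call add_scores() first")
  key <- function(p, a) paste(p, a, sep = ":")
  i <- match(key(observed$cds_pos, observed$alt),
             key(space$records$cds_pos, space$records$alt))
  obs <- space$records$score[i]
  if (anyNA(obs)) {
    bad <- which(is.na(obs))
    stop("missing score for observed SNV(s): ",
         paste(key(observed$cds_pos, observed$alt)[bad], collapse = ", "))
  }
  if (length(obs) < 2L) stop("need at least 2 observed scored SNVs")
  bg <- space$records$score[!is.na(space$records$score)]
  tt <- unpaired_t(obs, bg, welch = welch)
  list(mean_obs = mean(obs), mean_all = mean(bg), t = tt$t, df = tt$df,
       p_two_sided = tt$p)
}
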