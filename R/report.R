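#' Unpaired two-sample t-test
#'
#' Shared statistical utility: Student's equal-variance t-test by default,
#' Welch's (Satterthwaite degrees of freedom) when `welch = TRUE`.
#' Delegates to [stats::t.test()].
#'
#' @param a,b numeric score vectors (each of length >= 2).
#' @param welch use the unequal-variance test.
#' @return list `t, df, p`.
#' @export
unpaired_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(c(a, b)) == 0)
    stop("all pooled values identical; t statistic undefined")
  tt <- t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Pyrimidine-reference substitution class of an SNV
#'
#' Maps a substitution to one of the six classes C>A, C>G, C>T, T>A, T>C,
#' T>G; purine-reference substitutions are complemented first (G>A becomes
#' C>T).
#'
#' @param ref,alt single reference and alternate bases.
#' @return character vector of class labels.
#' @export
substitution_class <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("substitution_class is defined for single-base substitutions only")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, unname(COMPLEMENT[ref]), ref)
  a <- ifelse(pur, unname(COMPLEMENT[alt]), alt)
  paste0(r, ">", a)
}

#' Per-patient mutation summaries
#'
#' @param calls_by_patient named list of call data.frames (one per patient,
#'   possibly empty), names are patient ids.
#' @param metadata data.frame with columns `id`, `age` and optionally
#'   `group`.
#' @return data.frame, one row per patient ordered by id: `id, age, group,
#'   n_mutations, cumulative_vaf, max_vaf` plus one count column per
#'   consequence class.
#' @export
summarize_patients <- function(calls_by_patient, metadata) {
  ids <- names(calls_by_patient)
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  if (anyDuplicated(metadata$id)) stop("duplicate patient ids in metadata")
  classes <- c("synonymous", "missense", "nonsense", "stop_loss",
               "start_loss", "frameshift", "inframe_indel")
  rows <- lapply(ids, function(id) {
    calls <- calls_by_patient[[id]]
    m <- metadata[metadata$id == id, , drop = FALSE]
    if (!nrow(m)) stop("no metadata for patient ", id)
    n <- if (is.null(calls)) 0L else nrow(calls)
    cc <- if (n) table(factor(calls$consequence, levels = classes))
          else setNames(rep(0L, length(classes)), classes)
    data.frame(id = id, age = m$age[1L],
               group = if ("group" %in% names(m)) m$group[1L] else "affected",
               n_mutations = n,
               cumulative_vaf = if (n) sum(calls$vaf) else 0,
               max_vaf = if (n) max(calls$vaf) else 0,
               as.list(cc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of patients carrying at least one mutation
#' @param summaries data.frame from [summarize_patients()].
#' @return list `n_carriers, n_patients, fraction, percent`.
#' @export
carrier_fraction <- function(summaries) {
  k <- sum(summaries$n_mutations >= 1L)
  n <- nrow(summaries)
  list(n_carriers = k, n_patients = n, fraction = k / n,
       percent = 100 * k / n)
}

#' Classification table of called mutations
#'
#' Counts and percentages over consequence classes and over the SNV /
#' non-SNV split. Raw fractions are kept alongside percentages rendered to
#' one decimal place.
#'
#' @param calls data.frame of calls with `ref`, `alt`, `consequence`.
#' @return list with `n_total`, `n_snv`, `pct_snv`, and a data.frame
#'   `classes` (class, count, percent, percent_1dp).
#' @export
classify_mutation_table <- function(calls) {
  n <- nrow(calls)
  if (!n) return(list(n_total = 0L, n_snv = 0L, pct_snv = NA_real_,
                      classes = data.frame(class = character(),
                                           count = integer(),
                                           percent = numeric(),
                                           percent_1dp = numeric())))
  is_snv <- nchar(calls$ref) == 1L & nchar(calls$alt) == 1L
  cnt <- table(calls$consequence)
  classes <- data.frame(class = names(cnt), count = as.integer(cnt),
                        percent = 100 * as.integer(cnt) / n,
                        stringsAsFactors = FALSE)
  classes$percent_1dp <- round(classes$percent, 1L)
  classes <- classes[order(-classes$count), , drop = FALSE]
  rownames(classes) <- NULL
  list(n_total = n, n_snv = sum(is_snv), pct_snv = 100 * sum(is_snv) / n,
       classes = classes)
}

#' Substitution spectrum of SNV calls
#'
#' Fractions of the six pyrimidine-reference substitution classes.
#'
#' @param calls data.frame of SNV calls with `ref` and `alt` single bases.
#' @return named numeric vector of fractions over the six classes (sums
#'   to 1).
#' @export
substitution_spectrum <- function(calls) {
  if (any(nchar(calls$ref) != 1L | nchar(calls$alt) != 1L))
    stop("substitution_spectrum accepts SNVs only; filter indels first")
  lv <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  if (!nrow(calls)) return(setNames(rep(NA_real_, 6L), lv))
  cl <- substitution_class(calls$ref, calls$alt)
  tab <- table(factor(cl, levels = lv))
  as.vector(tab / sum(tab)) -> fr
  setNames(fr, lv)
}

#' Pearson correlation of mutation count with age
#'
#' Two-tailed p-value from the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, as
#' implemented by [stats::cor.test()].
#'
#' @param summaries data.frame from [summarize_patients()].
#' @param var which per-patient quantity to correlate with age
#'   (`"n_mutations"` or `"cumulative_vaf"`).
#' @return list `r, p_two_sided, n`.
#' @export
correlate_count_age <- function(summaries, var = "n_mutations") {
  x <- summaries$age
  y <- summaries[[var]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 patients with age and counts")
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
    stop("zero variance in age or ", var)
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p_two_sided = ct$p.value, n = sum(ok))
}

#' Assemble a cohort report
#'
#' Aggregates per-patient summaries into the cohort-level statistics:
#' group sizes, carrier fraction, classification table, substitution
#' spectrum of the SNV calls, and the count-versus-age correlation.
#'
#' @param calls_by_patient named list of per-patient call tables.
#' @param metadata data.frame with `id`, `age`, optional `group`.
#' @return list of class `cohort_report`.
#' @export
cohort_report <- function(calls_by_patient, metadata) {
  summaries <- summarize_patients(calls_by_patient, metadata)
  all_calls <- do.call(rbind, calls_by_patient)
  snvs <- if (!is.null(all_calls) && nrow(all_calls))
    all_calls[nchar(all_calls$ref) == 1L & nchar(all_calls$alt) == 1L, ,
              drop = FALSE]
  else NULL
  corr <- if (nrow(summaries) >= 3L &&
              stats::var(summaries$n_mutations) > 0 &&
              stats::var(summaries$age) > 0)
    correlate_count_age(summaries) else NULL
  structure(list(
    summaries = summaries,
    group_sizes = table(summaries$group),
    carrier = carrier_fraction(summaries),
    classification = classify_mutation_table(
      if (is.null(all_calls)) data.frame() else all_calls),
    spectrum = if (!is.null(snvs) && nrow(snvs)) substitution_spectrum(snvs)
               else NULL,
    count_age = corr), class = "cohort_report")
}

#' Write a cohort report to JSON and TSV
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$summaries, file.path(dir, "patient_summaries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    n_patients = report$carrier$n_patients,
    n_carriers = report$carrier$n_carriers,
    carrier_percent = report$carrier$percent,
    n_mutations = report$classification$n_total,
    n_snv = report$classification$n_snv,
    pct_snv = report$classification$pct_snv,
    classes = report$classification$classes,
    spectrum = as.list(report$spectrum),
    count_age = report$count_age)
  jsonlite::write_json(json, file.path(dir, "cohort_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort of", x$carrier$n_patients, "patients;",
      x$carrier$n_carriers, "carriers (",
      sprintf("%.1f%%", x$carrier$percent), ")\n")
  cat(x$classification$n_total, "mutations, of which",
      x$classification$n_snv, "SNVs (",
      sprintf("%.1f%%", x$classification$pct_snv), ")\n")
  if (!is.null(x$count_age))
    cat(sprintf("count ~ age: r = %.4f, p = %.4f (n = %d)\n",
                x$count_age$r, x$count_age$p_two_sided, x$count_age$n))
  invisible(x)
}
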