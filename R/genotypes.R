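#' Genotype dosage matrix
#'
#' Container for effect-allele dosages: an integer matrix with one row
#' per participant and one column per SNP, entries in \{0, 1, 2\} or `NA`
#' for failed calls. Dosage counts copies of the panel's effect allele
#' under the panel's fixed orientation.
#'
#' @param dosage numeric/integer matrix, participants x SNPs.
#' @param participant_ids row identifiers; defaults to existing rownames.
#' @param snp_ids column rsIDs; defaults to existing colnames.
#' @return a `genotype_matrix` (an integer matrix with dimnames).
#' @export
genotype_matrix <- function(dosage, participant_ids = rownames(dosage),
                            snp_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(participant_ids) || is.null(snp_ids))
    stop_n3("participant_ids and snp_ids are required (or set as dimnames)")
  if (length(participant_ids) != nrow(dosage) || length(snp_ids) != ncol(dosage))
    stop_n3("id lists must match the matrix dimensions exactly")
  if (anyDuplicated(participant_ids)) stop_n3("duplicated participant ids")
  if (anyDuplicated(snp_ids)) stop_n3("duplicated snp ids")
  storage.mode(dosage) <- "integer"
  ok <- is.na(dosage) | dosage %in% 0:2
  if (!all(ok)) stop_n3("dosages must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(as.character(participant_ids), as.character(snp_ids))
  class(dosage) <- c("genotype_matrix", class(matrix()))
  dosage
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d participants x %d SNPs (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

snp_column <- function(matrix, snp_id) {
  if (!snp_id %in% colnames(matrix))
    stop_n3("unknown SNP in genotype matrix: ", snp_id)
  matrix[, snp_id]
}

#' Effect-allele frequency of one SNP
#'
#' Frequency of the panel's effect allele among non-missing chromosomes:
#' sum of dosages over twice the number of non-missing participants.
#' Alleles are never re-oriented to the cohort minor allele; the value
#' can therefore exceed 0.5 in a cohort where the panel's rare allele is
#' common.
#'
#' @param matrix a [genotype_matrix()].
#' @param snp_id rsID, must be a column of `matrix`.
#' @return frequency in `[0, 1]`.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'                      dimnames = list(c("p1", "p2"), c("rs1", "rs2"))))
#' compute_maf(g, "rs1")
#' @export
compute_maf <- function(matrix, snp_id) {
  d <- snp_column(matrix, snp_id)
  d <- d[!is.na(d)]
  if (!length(d)) stop_n3("all genotypes missing for SNP ", snp_id)
  sum(d) / (2 * length(d))
}

#' Genotype counts of one SNP
#'
#' @param matrix a [genotype_matrix()].
#' @param snp_id rsID.
#' @return integer triple `(n_hom_other, n_het, n_hom_effect)` over
#'   non-missing participants.
#' @export
genotype_counts <- function(matrix, snp_id) {
  d <- snp_column(matrix, snp_id)
  d <- d[!is.na(d)]
  c(n_hom_other = sum(d == 0L), n_het = sum(d == 1L), n_hom_effect = sum(d == 2L))
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' One-degree-of-freedom Pearson chi-squared comparing observed genotype
#' counts (hom-other, het, hom-effect) to the Hardy-Weinberg expectations
#' n(1-p)^2, 2np(1-p), np^2 at the sample effect-allele frequency p. A
#' monomorphic SNP (p = 0 or 1) is reported as chi-squared 0, p-value 1
#' and flagged, not treated as an error.
#'
#' @param genotype_counts integer triple `(n_hom_other, n_het,
#'   n_hom_effect)`, or a [genotype_matrix()] together with `snp_id`.
#' @param snp_id optional rsID when `genotype_counts` is a matrix.
#' @param alpha significance level for the pass flag (default 0.05).
#' @return a one-row data frame: `snp_id`, `chi_squared`, `p_value`,
#'   `pass` (`p_value >= alpha`), `monomorphic`.
#' @examples
#' hwe_test(c(25, 50, 25))          # exact HWE proportions
#' hwe_test(c(30, 40, 30))          # chi-squared 4, p ~ 0.0455
#' @export
hwe_test <- function(genotype_counts, snp_id = NA_character_, alpha = 0.05) {
  if (inherits(genotype_counts, "genotype_matrix")) {
    if (is.na(snp_id)) stop_n3("snp_id required when passing a genotype matrix")
    genotype_counts <- genotype_counts(genotype_counts, snp_id)
  }
  cnt <- as.numeric(genotype_counts)
  if (length(cnt) != 3L || any(cnt < 0) || any(cnt != round(cnt)))
    stop_n3("genotype_counts must be three non-negative integers")
  n <- sum(cnt)
  if (n < 1) stop_n3("at least one genotyped participant required")
  p <- (2 * cnt[3] + cnt[2]) / (2 * n)
  monomorphic <- p == 0 || p == 1
  if (monomorphic) {
    chi2 <- 0
    pval <- 1
  } else {
    expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((cnt - expected)^2 / expected)
    pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  data.frame(
    snp_id = snp_id, chi_squared = chi2, p_value = pval,
    pass = pval >= alpha, monomorphic = monomorphic,
    stringsAsFactors = FALSE
  )
}

#' Hardy-Weinberg filter over a panel
#'
#' Tests every panel SNP for Hardy-Weinberg equilibrium in the cohort
#' and splits the panel into retained SNPs (p >= alpha) and excluded
#' ones, preserving the input order. Missing genotypes are dropped
#' per SNP before counting.
#'
#' @param matrix a [genotype_matrix()] containing every panel SNP.
#' @param panel a [snp_panel()].
#' @param alpha per-SNP significance level (default 0.05; no
#'   multiple-testing correction).
#' @return list with `retained` (a [snp_panel()]), `excluded` (data
#'   frame of failing test results) and `tests` (all per-SNP results).
#' @export
filter_hwe <- function(matrix, panel, alpha = 0.05) {
  panel <- validate_snp_panel(panel)
  if (!nrow(panel))
    return(list(retained = panel, excluded = empty_hwe_frame(), tests = empty_hwe_frame()))
  missing_snps <- setdiff(panel$snp_id, colnames(matrix))
  if (length(missing_snps))
    stop_n3("panel SNPs absent from genotype matrix: ",
            paste(missing_snps, collapse = ", "))
  tests <- do.call(rbind, lapply(panel$snp_id, function(s)
    hwe_test(genotype_counts(matrix, s), snp_id = s, alpha = alpha)))
  keep <- tests$pass
  retained <- panel[keep, , drop = FALSE]
  class(retained) <- class(panel)
  rownames(retained) <- NULL
  list(retained = retained, excluded = tests[!keep, , drop = FALSE], tests = tests)
}

empty_hwe_frame <- function() {
  data.frame(snp_id = character(), chi_squared = numeric(), p_value = numeric(),
             pass = logical(), monomorphic = logical(), stringsAsFactors = FALSE)
}

#' Allele-count frequency comparison between two groups
#'
#' Pearson chi-squared (1 df, no continuity correction) on the 2x2
#' allele-count table \{effect, other\} x \{group A, group B\}, as used to
#' compare rare-allele frequencies between cohorts or between responder
#' subgroups. Frequencies are reported as effect-count / total. When an
#' allele class is absent from both groups the table is degenerate and
#' the comparison is reported as chi-squared 0, p-value 1 with
#' `degenerate = TRUE`.
#'
#' @param counts_a,counts_b numeric pairs `(effect_alleles,
#'   total_alleles)` for the two groups.
#' @param snp_id optional rsID carried into the result.
#' @return one-row data frame: `snp_id`, `maf_a`, `maf_b`,
#'   `chi_squared`, `p_value`, `degenerate`.
#' @examples
#' compare_maf(c(10, 100), c(30, 100))   # chi-squared 12.5
#' @export
compare_maf <- function(counts_a, counts_b, snp_id = NA_character_) {
  check_pair <- function(x, label) {
    if (length(x) != 2L || any(!is.finite(x)) || x[2] < 2 || x[1] < 0 || x[1] > x[2])
      stop_n3("counts_", label, " must be (effect_alleles, total_alleles) with ",
              "total >= 2 and 0 <= effect <= total")
  }
  check_pair(counts_a, "a"); check_pair(counts_b, "b")
  tab <- rbind(
    effect = c(counts_a[1], counts_b[1]),
    other = c(counts_a[2] - counts_a[1], counts_b[2] - counts_b[1])
  )
  degenerate <- any(rowSums(tab) == 0)
  if (degenerate) {
    chi2 <- 0
    pval <- 1
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ht$statistic)
    pval <- unname(ht$p.value)
  }
  data.frame(
    snp_id = snp_id,
    maf_a = counts_a[1] / counts_a[2], maf_b = counts_b[1] / counts_b[2],
    chi_squared = chi2, p_value = pval, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

allele_counts_from_matrix <- function(matrix, snp_id) {
  d <- snp_column(matrix, snp_id)
  d <- d[!is.na(d)]
  c(sum(d), 2 * length(d))
}

#' Per-SNP QC and frequency report
#'
#' One row per panel SNP with its cohort effect-allele frequency,
#' Hardy-Weinberg test, a rare-variant flag, and (when reference
#' frequencies are supplied) the allele-count chi-squared comparison
#' against the reference cohort.
#'
#' The rare-variant flag is inclusive: `maf <= rare_threshold` (default
#' 0.05) is flagged. Reference comparisons assume the reference
#' frequency came from `reference_n` diploid individuals (allele counts
#' are rounded to the nearest integer).
#'
#' @param matrix a [genotype_matrix()].
#' @param panel a [snp_panel()].
#' @param reference_mafs optional named numeric vector, rsID ->
#'   reference effect-allele frequency.
#' @param reference_n diploid sample size behind `reference_mafs`.
#' @param rare_threshold rare-variant threshold (inclusive).
#' @param hwe_alpha alpha for the HWE pass flag.
#' @return data frame with columns `snp_id`, `locus`, `maf`,
#'   `hwe_chi2`, `hwe_p`, `hwe_pass`, `rare_flag`, `ref_maf`,
#'   `cmp_chi2`, `cmp_p`.
#' @export
maf_table <- function(matrix, panel, reference_mafs = NULL, reference_n = NULL,
                      rare_threshold = 0.05, hwe_alpha = 0.05) {
  panel <- validate_snp_panel(panel)
  rows <- lapply(panel$snp_id, function(s) {
    maf <- compute_maf(matrix, s)
    hw <- hwe_test(genotype_counts(matrix, s), snp_id = s, alpha = hwe_alpha)
    ref_maf <- cmp_chi2 <- cmp_p <- NA_real_
    if (!is.null(reference_mafs) && s %in% names(reference_mafs)) {
      if (is.null(reference_n))
        stop_n3("reference_n is required when reference_mafs is supplied")
      ref_maf <- unname(reference_mafs[[s]])
      ca <- allele_counts_from_matrix(matrix, s)
      cb <- c(round(ref_maf * 2 * reference_n), 2 * reference_n)
      cmp <- compare_maf(ca, cb, snp_id = s)
      cmp_chi2 <- cmp$chi_squared
      cmp_p <- cmp$p_value
    }
    data.frame(
      snp_id = s, locus = panel$locus[panel$snp_id == s], maf = maf,
      hwe_chi2 = hw$chi_squared, hwe_p = hw$p_value, hwe_pass = hw$pass,
      rare_flag = maf <= rare_threshold,
      ref_maf = ref_maf, cmp_chi2 = cmp_chi2, cmp_p = cmp_p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a QC report as TSV
#'
#' @param qc a data frame from [maf_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  write_tsv_fixed(qc, path)
  invisible(path)
}

# fixed 6-significant-digit formatting for byte-stable numeric output
write_tsv_fixed <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- signif(fmt[[j]], 6)
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
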