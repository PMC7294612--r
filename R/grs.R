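#' Direction sign from a prior odds ratio
#'
#' Maps the odds ratio of a prior association to the sign with which the
#' rare allele enters the genetic risk score: +1 for OR > 1 (each rare
#' allele copy raises the score), -1 for OR < 1. An OR of exactly 1 has
#' no defined direction and is an error; the caller must exclude the SNP
#' or set the sign explicitly.
#'
#' @param odds_ratio positive number.
#' @return `+1L` or `-1L`.
#' @examples
#' direction_from_or(2.3)  # +1
#' direction_from_or(0.4)  # -1
#' @export
direction_from_or <- function(odds_ratio) {
  if (!is_number(odds_ratio) || odds_ratio <= 0)
    stop_n3("odds_ratio must be a positive number")
  if (odds_ratio == 1)
    stop_n3("odds ratio of exactly 1 has no direction; exclude the SNP or set the sign explicitly")
  if (odds_ratio > 1) 1L else -1L
}

#' Signed rare-allele genetic risk score
#'
#' Computes, per participant, the unit-weight signed sum of effect-allele
#' dosages over the panel: score_i = sum_j direction_j x dosage_ij. A
#' heterozygote contributes one signed unit, a rare homozygote two;
#' major-allele homozygotes contribute nothing. The panel should already
#' be Hardy-Weinberg filtered (see [filter_hwe()]).
#'
#' Missing genotypes are handled by `missing_policy`:
#' \describe{
#'   \item{skip}{(default) a missing SNP contributes 0 and increments
#'     `n_missing`; participants whose missing fraction exceeds
#'     `max_missing_frac` are flagged, not dropped.}
#'   \item{strict}{any missing genotype is an error naming the
#'     participant and SNP.}
#'   \item{mean_impute}{a missing dosage is replaced by 2 x cohort MAF
#'     of that SNP; scores are then non-integer.}
#' }
#'
#' @param matrix a [genotype_matrix()] containing every panel SNP.
#' @param panel a [snp_panel()] (HWE-filtered).
#' @param missing_policy one of `"skip"`, `"strict"`, `"mean_impute"`.
#' @param max_missing_frac per-participant missing fraction above which
#'   `flag_high_missing` is set (default 0.2).
#' @return data frame with `participant_id`, `grs`, `n_snps_used`,
#'   `n_missing`, `flag_high_missing`.
#' @examples
#' g <- genotype_matrix(matrix(c(2L, 1L, 0L), 1, 3,
#'        dimnames = list("p1", c("rs1", "rs2", "rs3"))))
#' p <- snp_panel(c("rs1", "rs2", "rs3"), "L", "A", "G",
#'                direction = c(1, -1, 1))
#' compute_grs(g, p)$grs  # 2 - 1 + 0 = 1
#' @export
compute_grs <- function(matrix, panel,
                        missing_policy = c("skip", "strict", "mean_impute"),
                        max_missing_frac = 0.2) {
  missing_policy <- match.arg(missing_policy)
  panel <- validate_snp_panel(panel)
  absent <- setdiff(panel$snp_id, colnames(matrix))
  if (length(absent))
    stop_n3("panel SNPs absent from genotype matrix: ", paste(absent, collapse = ", "))
  dos <- matrix[, panel$snp_id, drop = FALSE]
  storage.mode(dos) <- "double"
  miss <- is.na(dos)
  if (missing_policy == "strict" && any(miss)) {
    idx <- which(miss, arr.ind = TRUE)[1, ]
    stop_n3("missing genotype for participant ", rownames(dos)[idx[1]],
            " at SNP ", colnames(dos)[idx[2]], " under strict policy")
  }
  if (missing_policy == "mean_impute") {
    for (j in which(colSums(miss) > 0)) {
      maf_j <- compute_maf(matrix, panel$snp_id[j])
      dos[miss[, j], j] <- 2 * maf_j
    }
  } else {
    dos[miss] <- 0
  }
  score <- drop(dos %*% panel$direction)
  n_missing <- rowSums(miss)
  n_used <- ncol(dos) - n_missing
  if (missing_policy == "mean_impute") n_used <- rep(ncol(dos), nrow(dos))
  data.frame(
    participant_id = rownames(dos),
    grs = unname(score),
    n_snps_used = as.integer(n_used),
    n_missing = as.integer(n_missing),
    flag_high_missing = n_missing / ncol(dos) > max_missing_frac,
    stringsAsFactors = FALSE
  )
}

#' Write GRS results as TSV
#'
#' @param grs data frame from [compute_grs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grs <- function(grs, path) {
  write_tsv_fixed(grs, path)
  invisible(path)
}
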