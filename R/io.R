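#' Read a genotype dosage matrix from TSV
#'
#' Expected layout: a header row of rsIDs, first column participant id,
#' remaining cells effect-allele dosages in \{0, 1, 2\} or `NA`.
#'
#' @param path path to the TSV file.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop_n3("genotype file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_n3("genotype TSV needs an id column plus >= 1 SNP column")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  genotype_matrix(mat, participant_ids = ids, snp_ids = colnames(tab)[-1])
}

#' Write a genotype dosage matrix as TSV
#'
#' @param matrix a [genotype_matrix()].
#' @param path output path.
#' @param id_column name of the first (participant id) column.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(matrix, path, id_column = "participant_id") {
  df <- data.frame(id = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF into panel-oriented dosages
#'
#' Reads biallelic sites from a VCF (GT field) and converts each call to
#' the count of the panel's effect allele. REF/ALT are matched against
#' the panel's allele pair: a site whose alleles do not match the panel
#' (either orientation) is an error — the reader never strand-flips or
#' guesses. Sites are matched to the panel by the VCF ID column.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @param panel a [snp_panel()]; only panel SNPs are kept.
#' @return a [genotype_matrix()] with one column per panel SNP found.
#' @export
read_genotypes_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_n3("reading VCF requires the 'vcfR' package")
  panel <- validate_snp_panel(panel)
  if (!file.exists(path)) stop_n3("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  keep <- which(ids %in% panel$snp_id)
  if (!length(keep)) stop_n3("no panel SNPs found in VCF: ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(ids, names(gt)))
  samples <- colnames(gt)
  dosage <- matrix(NA_integer_, nrow = length(samples), ncol = length(keep),
                   dimnames = list(samples, ids[keep]))
  for (j in seq_along(keep)) {
    i <- keep[j]
    snp <- ids[i]
    ref <- toupper(fix[i, "REF"]); alt <- toupper(fix[i, "ALT"])
    if (grepl(",", alt))
      stop_n3("multi-allelic site not supported: ", snp)
    prow <- panel[panel$snp_id == snp, ]
    if (setequal(c(ref, alt), c(prow$effect_allele, prow$other_allele))) {
      effect_is_alt <- alt == prow$effect_allele
    } else {
      stop_n3("VCF alleles ", ref, "/", alt, " do not match panel alleles ",
              prow$other_allele, "/", prow$effect_allele, " at ", snp,
              " (no silent strand flip)")
    }
    calls <- gt[i, ]
    alt_count <- count_alt_alleles(calls)
    dosage[, j] <- if (effect_is_alt) alt_count else 2L - alt_count
  }
  genotype_matrix(dosage)
}

count_alt_alleles <- function(calls) {
  out <- rep(NA_integer_, length(calls))
  ok <- !is.na(calls) & calls != "." & calls != "./." & calls != ".|."
  split_calls <- strsplit(calls[ok], "[/|]")
  out[ok] <- vapply(split_calls, function(a) {
    if (any(a == ".")) return(NA_integer_)
    if (!all(a %in% c("0", "1"))) stop_n3("unsupported GT allele code: ",
                                          paste(a, collapse = "/"))
    sum(a == "1")
  }, integer(1))
  out
}

#' Read a phenotype table from CSV
#'
#' Expected columns: `participant_id`, `age`, `sex`, `bmi`,
#' `tg_post_control`, `tg_post_epa`, `tg_post_dha`, and repeated
#' off-treatment triglyceride columns `tg_off_1` .. `tg_off_k` (k >= 2).
#' Triglycerides are in mmol/l.
#'
#' @param path path to the CSV file.
#' @return a data frame with an attached `tg_off` matrix attribute
#'   (participants x replicates).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_n3("phenotype file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotypes(tab)
}

validate_phenotypes <- function(tab) {
  required <- c("participant_id", "age", "sex", "bmi",
                "tg_post_control", "tg_post_epa", "tg_post_dha")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop_n3("phenotype table missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$participant_id)) stop_n3("duplicated participant ids")
  off_cols <- grep("^tg_off_[0-9]+$", names(tab), value = TRUE)
  tg_cols <- c("tg_post_control", "tg_post_epa", "tg_post_dha", off_cols)
  for (col in tg_cols) {
    v <- tab[[col]]
    if (any(!is.na(v) & v <= 0))
      stop_n3("non-positive triglyceride value in column ", col)
  }
  tab$participant_id <- as.character(tab$participant_id)
  tab
}

off_treatment_matrix <- function(phenotypes) {
  off_cols <- grep("^tg_off_[0-9]+$", names(phenotypes), value = TRUE)
  off_cols <- off_cols[order(as.integer(sub("^tg_off_", "", off_cols)))]
  m <- as.matrix(phenotypes[, off_cols, drop = FALSE])
  rownames(m) <- phenotypes$participant_id
  m
}
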