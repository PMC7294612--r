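#' SNP panel definition
#'
#' A SNP panel describes the variants entering a genetic risk score: one
#' row per SNP with its locus label, effect (rare) allele, other allele,
#' and a direction sign in \{+1, -1\} giving the sign with which each
#' copy of the effect allele enters the score. The sign encodes the
#' direction of the prior association's odds ratio: +1 where the rare
#' allele increased the odds of adverse triglyceride response (OR > 1),
#' -1 where it decreased them (OR < 1). SNPs genotyped through a
#' linkage-disequilibrium proxy carry the original rsID in
#' `replaced_from` and the LD r-squared in `ld_r2`.
#'
#' The effect allele is fixed by the panel (the discovery-cohort
#' definition) and is never re-estimated from the analysis cohort, so a
#' cohort where the panel's rare allele drifts above 50\% frequency keeps
#' a stable direction.
#'
#' @param snp_id character vector of rsIDs, unique.
#' @param locus gene-locus labels (e.g. "IQCJ", "NXPH1").
#' @param effect_allele,other_allele single-base allele symbols.
#' @param direction integer vector, each +1 or -1 (never 0).
#' @param replaced_from optional rsID of the originally selected SNP when
#'   this row is an LD replacement; `NA` otherwise.
#' @param ld_r2 LD r-squared with `replaced_from`, in (0, 1]; must be
#'   present exactly when `replaced_from` is.
#' @return a `snp_panel`: a data frame with the columns above.
#' @examples
#' snp_panel(
#'   snp_id = c("rs1", "rs2"), locus = c("L1", "L1"),
#'   effect_allele = c("A", "T"), other_allele = c("G", "C"),
#'   direction = c(+1, -1)
#' )
#' @seealso [compared_panel()] for the built-in 31-SNP omega-3 panel,
#'   [read_snp_panel()] to load a panel from YAML/JSON.
#' @export
snp_panel <- function(snp_id, locus, effect_allele, other_allele, direction,
                      replaced_from = NA_character_, ld_r2 = NA_real_) {
  n <- length(snp_id)
  panel <- data.frame(
    snp_id = as.character(snp_id),
    locus = rep_len(as.character(locus), n),
    effect_allele = rep_len(toupper(as.character(effect_allele)), n),
    other_allele = rep_len(toupper(as.character(other_allele)), n),
    direction = rep_len(as.integer(direction), n),
    replaced_from = rep_len(as.character(replaced_from), n),
    ld_r2 = rep_len(as.numeric(ld_r2), n),
    stringsAsFactors = FALSE
  )
  validate_snp_panel(panel)
}

validate_snp_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  required <- c("snp_id", "locus", "effect_allele", "other_allele", "direction")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols))
    stop_n3("snp_panel is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"replaced_from" %in% names(panel)) panel$replaced_from <- NA_character_
  if (!"ld_r2" %in% names(panel)) panel$ld_r2 <- NA_real_
  if (anyDuplicated(panel$snp_id))
    stop_n3("duplicated snp_id in panel: ",
            paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "))
  if (!all(panel$direction %in% c(-1L, 1L)))
    stop_n3("panel direction must be +1 or -1 for every SNP (0 is not allowed)")
  has_rep <- !is.na(panel$replaced_from) & nzchar(panel$replaced_from)
  has_r2 <- !is.na(panel$ld_r2)
  if (any(has_rep != has_r2))
    stop_n3("ld_r2 must be present exactly for LD-replacement SNPs")
  if (any(has_r2 & (panel$ld_r2 <= 0 | panel$ld_r2 > 1)))
    stop_n3("ld_r2 must lie in (0, 1]")
  panel$replaced_from[!has_rep] <- NA_character_
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d SNPs across %d loci (%d LD replacements)\n",
              nrow(x), length(unique(x$locus)), sum(!is.na(x$replaced_from))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a SNP panel from YAML or JSON
#'
#' The file holds a list of records with the fields of [snp_panel()]
#' (`snp_id`, `locus`, `effect_allele`, `other_allele`, `direction`, and
#' optionally `replaced_from` + `ld_r2`). Format is chosen from the file
#' extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path path to the panel file.
#' @return a validated [snp_panel()].
#' @export
read_snp_panel <- function(path) {
  if (!file.exists(path)) stop_n3("panel file not found: ", path)
  records <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop_n3("unrecognised panel format (expected .yaml/.yml or .json): ", path)
  }
  if (!length(records)) stop_n3("panel file contains no SNP records: ", path)
  get_field <- function(rec, field, default) {
    v <- rec[[field]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
  }
  snp_panel(
    snp_id = vapply(records, get_field, "", field = "snp_id", default = NA_character_),
    locus = vapply(records, get_field, "", field = "locus", default = NA_character_),
    effect_allele = vapply(records, get_field, "", field = "effect_allele", default = NA_character_),
    other_allele = vapply(records, get_field, "", field = "other_allele", default = NA_character_),
    direction = vapply(records, function(r) as.integer(get_field(r, "direction", NA_integer_)), 1L),
    replaced_from = vapply(records, get_field, "", field = "replaced_from", default = NA_character_),
    ld_r2 = vapply(records, function(r) as.numeric(get_field(r, "ld_r2", NA_real_)), 1.0)
  )
}

#' Write a SNP panel to YAML
#'
#' @param panel a [snp_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_panel <- function(panel, path) {
  panel <- validate_snp_panel(panel)
  records <- lapply(seq_len(nrow(panel)), function(i) {
    rec <- as.list(panel[i, , drop = FALSE])
    rec <- lapply(rec, function(v) v[[1]])
    if (is.na(rec$replaced_from)) rec$replaced_from <- rec$ld_r2 <- NULL
    rec
  })
  yaml::write_yaml(records, path)
  invisible(path)
}

#' The 31-SNP omega-3 triglyceride-response panel
#'
#' Returns the 31-SNP panel used to score the plasma triglyceride
#' response to omega-3 fatty acid supplementation, spanning the IQCJ,
#' NXPH1, PHF17, MYB, NELL1 and SLIT2 loci. Seven entries are
#' linkage-disequilibrium replacements for variants that could not be
#' genotyped on the original array; their source rsIDs and LD r-squared
#' values are carried in `replaced_from`/`ld_r2`. The accompanying
#' published rare-allele frequencies in the replication and discovery
#' cohorts (with the published 2x2 allele-count chi-squared comparison)
#' are attached as columns `maf_replication`, `maf_discovery`, `chi_squared`,
#' `p_value` when `with_reference = TRUE`.
#'
#' The discovery study's per-SNP odds-ratio directions were never
#' published, so `direction` is set to +1 for every SNP (the score then
#' reduces to a total rare-allele count); supply your own signs for a
#' signed score. Allele symbols are likewise synthetic placeholders
#' (effect "A", other "G") suitable for simulation, not for matching
#' real genotype calls.
#'
#' @param with_reference logical; attach the published frequency columns.
#' @return a [snp_panel()] (with extra reference columns if requested).
#' @export
compared_panel <- function(with_reference = FALSE) {
  path <- system.file("extdata", "compared_panel.csv", package = "n3grs",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  panel <- snp_panel(
    snp_id = tab$snp_id,
    locus = tab$locus,
    effect_allele = "A",
    other_allele = "G",
    direction = 1L,
    replaced_from = ifelse(nzchar(tab$replaced_from) & !is.na(tab$replaced_from),
                           tab$replaced_from, NA_character_),
    ld_r2 = tab$ld_r2
  )
  if (with_reference) {
    panel$maf_replication <- tab$maf_replication
    panel$maf_discovery <- tab$maf_discovery
    panel$chi_squared <- tab$chi_squared
    panel$p_value <- tab$p_value
  }
  panel
}
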