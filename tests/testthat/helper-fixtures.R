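# in-code fixtures shared across test files

# small mixed-sign panel
toy_panel <- function(n = 3, directions = NULL) {
  directions <- directions %||% rep_len(c(1L, -1L), n)
  snp_panel(
    snp_id = paste0("rs", seq_len(n)),
    locus = rep("LOC", n),
    effect_allele = "A", other_allele = "G",
    direction = directions
  )
}

# genotype matrix from a dosage matrix given as rows = participants
toy_genotypes <- function(dosages, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  snp_ids <- snp_ids %||% paste0("rs", seq_len(ncol(dosages)))
  genotype_matrix(dosages,
                  participant_ids = sprintf("p%02d", seq_len(nrow(dosages))),
                  snp_ids = snp_ids)
}

# genotype matrix realising exact genotype counts (hom-other, het, hom-effect)
genotypes_from_counts <- function(counts, snp_id = "rs1") {
  d <- rep(0:2, times = counts)
  toy_genotypes(matrix(d, ncol = 1), snp_ids = snp_id)
}

# minimal phenotype frame with configurable TG phases
toy_phenotypes <- function(tg_control, tg_epa = tg_control, tg_dha = tg_control,
                           off = NULL) {
  n <- length(tg_control)
  base <- data.frame(
    participant_id = sprintf("p%02d", seq_len(n)),
    age = 50, sex = rep_len(c("F", "M"), n), bmi = 29,
    tg_post_control = tg_control, tg_post_epa = tg_epa, tg_post_dha = tg_dha,
    stringsAsFactors = FALSE
  )
  if (is.null(off)) off <- matrix(rep(tg_control, 2), ncol = 2)
  colnames(off) <- paste0("tg_off_", seq_len(ncol(off)))
  cbind(base, off)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
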