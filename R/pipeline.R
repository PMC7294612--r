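#' Pipeline configuration
#'
#' Bundles inputs and thresholds for [run_pipeline()]. Inputs may be
#' in-memory objects (a [genotype_matrix()], phenotype data frame and
#' [snp_panel()]) or file paths (genotype TSV/VCF, phenotype CSV, panel
#' YAML/JSON), which are loaded on construction.
#'
#' @param genotypes [genotype_matrix()] or path.
#' @param phenotypes phenotype data frame or CSV path.
#' @param panel [snp_panel()] or YAML/JSON path.
#' @param hwe_alpha Hardy-Weinberg exclusion alpha (default 0.05).
#' @param rare_maf_threshold inclusive rare-variant threshold.
#' @param window responder window half-width (mmol/l) or `"estimate"`.
#' @param missing_policy passed to [compute_grs()].
#' @param treatments treatments to analyse.
#' @param reference_mafs,reference_n optional reference cohort allele
#'   frequencies (named vector) and diploid sample size for the QC
#'   comparison columns.
#' @param out_dir optional output directory for report files.
#' @param seed optional integer seed (only simulation-based extras use
#'   randomness; recorded in the run log).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, phenotypes, panel,
                            hwe_alpha = 0.05, rare_maf_threshold = 0.05,
                            window = 0.25,
                            missing_policy = "skip",
                            treatments = c("EPA", "DHA"),
                            reference_mafs = NULL, reference_n = NULL,
                            out_dir = NULL, seed = NULL) {
  if (is.character(genotypes)) {
    genotypes <- if (grepl("\\.vcf(\\.gz)?$", genotypes))
      read_genotypes_vcf(genotypes, if (is.character(panel)) read_snp_panel(panel) else panel)
    else read_genotypes_tsv(genotypes)
  }
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.character(panel)) panel <- read_snp_panel(panel)
  panel <- validate_snp_panel(panel)
  phenotypes <- validate_phenotypes(phenotypes)
  stopifnot(hwe_alpha >= 0, hwe_alpha <= 1,
            rare_maf_threshold >= 0, rare_maf_threshold <= 1,
            identical(window, "estimate") || (is_number(window) && window >= 0))
  treatments <- match.arg(treatments, c("EPA", "DHA"), several.ok = TRUE)
  config <- list(genotypes = genotypes, phenotypes = phenotypes, panel = panel,
                 hwe_alpha = hwe_alpha, rare_maf_threshold = rare_maf_threshold,
                 window = window, missing_policy = missing_policy,
                 treatments = treatments, reference_mafs = reference_mafs,
                 reference_n = reference_n, out_dir = out_dir, seed = seed)
  class(config) <- "pipeline_config"
  config
}

#' Run the full responder-prediction pipeline
#'
#' Executes, in order: Hardy-Weinberg filtering of the panel, the
#' per-SNP QC/frequency table, genetic risk scores on the retained
#' panel, TG-change computation and responder classification per
#' treatment, the proportional-odds fit (all classes), the binary fit
#' with non-responders excluded, subgroup allele-frequency comparisons,
#' and predicted-probability curves. Participants present in only one
#' of the genotype and phenotype inputs are dropped with a note in the
#' stage counts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return a `grs_pipeline` list: `qc` (maf table), `hwe` (filter
#'   result), `grs`, `labels`, and per-treatment `fits` (ordinal,
#'   binary, curves, subgroup tests), plus `counts` and `log`. When
#'   `config$out_dir` is set, TSV/JSON artifacts and a run log are
#'   written there.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  say <- function(...) if (!quiet) message(...)
  log_lines <- c(
    sprintf("n3grs %s | R %s", as.character(utils::packageVersion("n3grs")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("config: hwe_alpha=%g rare_maf_threshold=%g window=%s missing_policy=%s seed=%s",
            config$hwe_alpha, config$rare_maf_threshold,
            paste(config$window, collapse = ""), config$missing_policy,
            if (is.null(config$seed)) "none" else config$seed)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_n3("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  common <- intersect(rownames(config$genotypes), config$phenotypes$participant_id)
  if (!length(common)) stop_n3("no participants shared between genotypes and phenotypes")
  geno <- config$genotypes[rownames(config$genotypes) %in% common, , drop = FALSE]
  pheno <- config$phenotypes[config$phenotypes$participant_id %in% common, , drop = FALSE]
  log_lines <- c(log_lines, sprintf(
    "participants: %d genotyped, %d phenotyped, %d analysed",
    nrow(config$genotypes), nrow(config$phenotypes), length(common)))

  say("stage qc: HWE filter + frequency table")
  hwe <- stage("qc", filter_hwe(geno, config$panel, alpha = config$hwe_alpha))
  qc <- stage("qc", maf_table(geno, config$panel,
                              reference_mafs = config$reference_mafs,
                              reference_n = config$reference_n,
                              rare_threshold = config$rare_maf_threshold,
                              hwe_alpha = config$hwe_alpha))
  log_lines <- c(log_lines, sprintf(
    "qc: %d panel SNPs, %d retained after HWE (alpha=%g), %d excluded [%s], %d rare (maf <= %g)",
    nrow(config$panel), nrow(hwe$retained), config$hwe_alpha,
    nrow(hwe$excluded), paste(hwe$excluded$snp_id, collapse = ","),
    sum(qc$rare_flag), config$rare_maf_threshold))

  say("stage score: genetic risk score")
  grs <- stage("score", compute_grs(geno, hwe$retained,
                                    missing_policy = config$missing_policy))
  log_lines <- c(log_lines, sprintf(
    "score: %d participants scored, range [%g, %g], %d flagged high-missing",
    nrow(grs), min(grs$grs), max(grs$grs), sum(grs$flag_high_missing)))

  say("stage classify: TG change + responder classes")
  labels <- stage("classify", classify_cohort(pheno, treatments = config$treatments,
                                              window = config$window))
  w_used <- labels$window_used[1]
  log_lines <- c(log_lines, sprintf("classify: window w = %g mmol/l", w_used))

  fits <- list()
  counts <- list()
  for (tr in config$treatments) {
    say("stage associate: ", tr)
    lab_tr <- labels[labels$treatment == tr, ]
    d <- responder_data(list(grs = grs, labels = labels, phenotypes = pheno),
                        treatment = tr)
    ord <- stage(paste0("associate-", tr),
                 fit_ordinal(label ~ grs + age + sex + bmi, d))
    d_bin <- droplevels(d[d$label != "NR", , drop = FALSE])
    bin <- stage(paste0("associate-", tr),
                 fit_binary(label ~ grs + age + sex + bmi, d_bin))
    curves <- stage(paste0("curves-", tr), predict_curves(ord))
    subgroups <- lapply(list(c("R", "NR"), c("NR", "AR"), c("R", "AR")),
                        function(pair) {
      tryCatch(subgroup_maf_tests(geno, hwe$retained, lab_tr, pair),
               error = function(e) NULL)
    })
    names(subgroups) <- c("R-NR", "NR-AR", "R-AR")
    tab <- table(lab_tr$label)
    counts[[tr]] <- list(
      n_in = nrow(pheno), n_labelled = nrow(lab_tr), class_counts = tab,
      n_ordinal = ord$n_obs, n_binary = bin$n_obs, n_nr_excluded = unname(tab["NR"])
    )
    log_lines <- c(log_lines, sprintf(
      "%s: classes R=%d NR=%d AR=%d | ordinal OR=%.3f p=%.4g (n=%d) | binary OR=%.3f p=%.4g (n=%d)",
      tr, tab["R"], tab["NR"], tab["AR"], ord$or_grs, ord$wald_p, ord$n_obs,
      bin$or_grs, bin$wald_p, bin$n_obs))
    fits[[tr]] <- list(ordinal = ord, binary = bin, curves = curves,
                       subgroup_tests = subgroups)
  }

  result <- list(qc = qc, hwe = hwe, grs = grs, labels = labels,
                 window_used = w_used, fits = fits, counts = counts,
                 log = log_lines, config = config)
  class(result) <- "grs_pipeline"
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_qc_report(result$qc, file.path(dir, "qc_report.tsv"))
  write_grs(result$grs, file.path(dir, "grs.tsv"))
  write_classification(result$labels, file.path(dir, "classification.tsv"))
  report <- lapply(result$fits, function(f) {
    lapply(f[c("ordinal", "binary")], fit_report)
  })
  jsonlite::write_json(report, file.path(dir, "model_report.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  for (tr in names(result$fits))
    write_curves(result$fits[[tr]]$curves,
                 file.path(dir, sprintf("curves_%s.tsv", tolower(tr))))
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

fit_report <- function(fit) {
  list(
    model_kind = fit$model_kind,
    n_obs = fit$n_obs,
    category_counts = as.list(unclass(fit$category_counts)),
    score_term = fit$score_term,
    beta_grs = signif(fit$beta_grs, 6), or_grs = signif(fit$or_grs, 6),
    se_beta = signif(fit$se_beta, 6), wald_p = signif(fit$wald_p, 6),
    coefficients = as.list(signif(fit$coefficients, 6)),
    cutpoints = if (!is.null(fit$cutpoints)) as.list(signif(fit$cutpoints, 6)),
    logLik = signif(fit$logLik, 6),
    converged = fit$converged
  )
}

#' @export
print.grs_pipeline <- function(x, ...) {
  cat("Responder-prediction pipeline run\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
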