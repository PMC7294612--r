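RESPONSE_LEVELS <- c("R", "NR", "AR")

#' Crossover triglyceride change per treatment
#'
#' In the crossover design every participant serves as their own
#' control: the treatment effect on plasma triglycerides is the
#' post-supplementation level minus the post-control-phase level,
#' delta = TG_post_treatment - TG_post_control (mmol/l). Each
#' participant yields two deltas, one per supplementation (EPA, DHA).
#' When several post-phase replicates are available their mean is taken
#' as the phase value before the supplied table is built; the function
#' itself works on a single value per phase.
#'
#' @param phenotypes phenotype data frame (see [read_phenotypes()]).
#' @param treatment `"EPA"` or `"DHA"`.
#' @return numeric vector of TG changes, named by participant.
#' @examples
#' ph <- data.frame(participant_id = "p1", age = 50, sex = "F", bmi = 29,
#'                  tg_post_control = 1.40, tg_post_epa = 1.10,
#'                  tg_post_dha = 1.40)
#' compute_delta(ph, "EPA")  # -0.30
#' @export
compute_delta <- function(phenotypes, treatment = c("EPA", "DHA")) {
  treatment <- match.arg(treatment)
  post_col <- if (treatment == "EPA") "tg_post_epa" else "tg_post_dha"
  for (col in c("tg_post_control", post_col)) {
    bad <- is.na(phenotypes[[col]])
    if (any(bad))
      stop_n3("missing ", col, " for participant ",
              phenotypes$participant_id[which(bad)[1]])
  }
  delta <- phenotypes[[post_col]] - phenotypes$tg_post_control
  names(delta) <- phenotypes$participant_id
  delta
}

#' Percent triglyceride reduction
#'
#' Relative reduction from the pre-supplementation mean:
#' 100 (pre - post) / pre, reported to one decimal place.
#'
#' @param pre,post triglyceride levels (mmol/l); `pre` must be positive.
#' @return percent reduction, rounded to one decimal.
#' @examples
#' percent_change(1.43, 1.24)  # 13.3
#' percent_change(1.43, 1.16)  # 18.9
#' @export
percent_change <- function(pre, post) {
  if (any(pre <= 0)) stop_n3("pre-treatment triglycerides must be positive")
  round(100 * (pre - post) / pre, 1)
}

#' Intra-individual triglyceride variability window
#'
#' Estimates the half-width of the non-response window from repeated
#' off-treatment TG measurements: the per-participant sample standard
#' deviation (n-1 denominator) is computed over each participant's
#' replicates and averaged over the cohort.
#'
#' With few replicates per participant the sample SD underestimates the
#' true within-person SD (E[s] = c4(k) sigma; c4(4) = 0.921), so by
#' default the cohort mean is divided by c4(k) to make the window an
#' unbiased estimate of the intra-individual SD. Set
#' `correct_bias = FALSE` for the raw mean of sample SDs.
#'
#' @param phenotypes phenotype data frame with `tg_off_*` columns, or a
#'   numeric matrix of off-treatment replicates (participants x
#'   replicates).
#' @param correct_bias divide by the c4 unbiasedness constant (default
#'   `TRUE`).
#' @return window half-width w (mmol/l).
#' @examples
#' m <- matrix(c(1.0, 1.2, 1.4, 1.6), nrow = 1)
#' estimate_window(m, correct_bias = FALSE)  # 0.2582 (plain sample SD)
#' @export
estimate_window <- function(phenotypes, correct_bias = TRUE) {
  off <- if (is.matrix(phenotypes)) phenotypes else off_treatment_matrix(phenotypes)
  if (ncol(off) < 2L)
    stop_n3("at least 2 off-treatment measurements per participant are required")
  if (anyNA(off))
    stop_n3("missing off-treatment measurements are not supported")
  sds <- apply(off, 1, stats::sd)
  w <- mean(sds)
  if (correct_bias) w <- w / c4_constant(ncol(off))
  w
}

#' Classify triglyceride changes into responder subgroups
#'
#' Orders participants into the three responder subgroups by comparing
#' the TG change to the intra-individual variability window of
#' half-width w: responders (R) lowered TG by more than w
#' (delta < -w), adverse responders (AR) raised it by more than w
#' (delta > +w), and non-responders (NR) stayed within the window
#' (|delta| <= w; the boundary is inside the window).
#'
#' @param delta_tg numeric vector of TG changes (mmol/l).
#' @param window window half-width w >= 0 (mmol/l); default 0.25, the
#'   cohort value behind the method (see [estimate_window()] to derive
#'   a cohort-specific one).
#' @return ordered factor with levels R < NR < AR.
#' @examples
#' classify_response(c(-0.30, -0.25, 0.26), window = 0.25)  # R, NR, AR
#' @export
classify_response <- function(delta_tg, window = 0.25) {
  if (!is_number(window) || window < 0) stop_n3("window must be a non-negative number")
  lab <- ifelse(delta_tg < -window, "R", ifelse(delta_tg > window, "AR", "NR"))
  lab[is.na(delta_tg)] <- NA
  factor(lab, levels = RESPONSE_LEVELS, ordered = TRUE)
}

#' Responder classification for a cohort, both treatments
#'
#' Computes the crossover TG change and responder label per participant
#' and treatment. With `window = "estimate"` the window is derived from
#' the cohort's off-treatment replicates via [estimate_window()];
#' otherwise the supplied constant (mmol/l) is used.
#'
#' @param phenotypes phenotype data frame (see [read_phenotypes()]).
#' @param treatments treatments to classify (default both).
#' @param window window half-width in mmol/l, or `"estimate"`.
#' @return data frame `participant_id`, `treatment`, `delta_tg`,
#'   `label` (ordered R < NR < AR), `window_used`.
#' @export
classify_cohort <- function(phenotypes, treatments = c("EPA", "DHA"),
                            window = 0.25) {
  treatments <- match.arg(treatments, several.ok = TRUE)
  w <- if (identical(window, "estimate")) estimate_window(phenotypes) else window
  out <- do.call(rbind, lapply(treatments, function(tr) {
    delta <- compute_delta(phenotypes, tr)
    data.frame(
      participant_id = phenotypes$participant_id,
      treatment = tr,
      delta_tg = unname(delta),
      label = classify_response(delta, w),
      window_used = w,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Write responder classifications as TSV
#'
#' @param labels data frame from [classify_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(labels, path) {
  out <- labels
  out$label <- as.character(out$label)
  write_tsv_fixed(out, path)
  invisible(path)
}
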