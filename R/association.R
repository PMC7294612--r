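#' @details
#' Model: for ordered categories k = 1..K (R < NR < AR) and linear
#' predictor eta = x'beta, the cumulative logits are
#' logit P(Y <= k | x) = zeta_k - eta with a single slope vector across
#' cutpoints (proportional odds). Positive beta for the risk score means
#' higher scores shift probability mass toward the adverse end of the
#' ordering, so exp(beta) > 1 reads as increased adverse-response risk
#' per score unit.
#' @keywords internal
#' @name ologit-internal
NULL

# ---- internal maximum-likelihood machinery --------------------------------

ologit_loglik <- function(theta, y, X, K) {
  zeta <- theta[seq_len(K - 1)]
  beta <- theta[-seq_len(K - 1)]
  eta <- if (ncol(X)) drop(X %*% beta) else rep(0, length(y))
  upper <- c(zeta, Inf)[y] - eta
  lower <- c(-Inf, zeta)[y] - eta
  sum(log(pmax(stats::plogis(upper) - stats::plogis(lower), 1e-300)))
}

ologit_gradient <- function(theta, y, X, K) {
  zeta <- theta[seq_len(K - 1)]
  beta <- theta[-seq_len(K - 1)]
  n <- length(y)
  eta <- if (ncol(X)) drop(X %*% beta) else rep(0, n)
  a <- c(zeta, Inf)[y] - eta
  b <- c(-Inf, zeta)[y] - eta
  L <- pmax(stats::plogis(a) - stats::plogis(b), 1e-300)
  fa <- stats::dlogis(a); fa[!is.finite(a)] <- 0
  fb <- stats::dlogis(b); fb[!is.finite(b)] <- 0
  gz <- numeric(K - 1)
  for (m in seq_len(K - 1)) {
    gz[m] <- sum(fa[y == m] / L[y == m]) - sum(fb[y == m + 1] / L[y == m + 1])
  }
  gb <- if (ncol(X)) drop(crossprod(X, -(fa - fb) / L)) else numeric(0)
  c(gz, gb)
}

ologit_hessian_fd <- function(theta, y, X, K, h = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    hj <- h * (1 + abs(theta[j]))
    up <- dn <- theta
    up[j] <- up[j] + hj
    dn[j] <- dn[j] - hj
    H[, j] <- (ologit_gradient(up, y, X, K) - ologit_gradient(dn, y, X, K)) / (2 * hj)
  }
  (H + t(H)) / 2
}

ologit_fit <- function(y, X, K, reltol = 1e-8, gradtol = 1e-6, maxit = 100L) {
  n <- length(y)
  cum <- cumsum(tabulate(y, K))[seq_len(K - 1)] / n
  cum <- pmin(pmax(cum, 1 / (2 * n)), 1 - 1 / (2 * n))
  theta <- c(stats::qlogis(cum), rep(0, ncol(X)))
  ll <- ologit_loglik(theta, y, X, K)
  converged <- FALSE
  iter <- 0L
  stalled <- FALSE
  for (iter in seq_len(maxit)) {
    g <- ologit_gradient(theta, y, X, K)
    if (max(abs(g)) < gradtol) { converged <- TRUE; break }
    H <- ologit_hessian_fd(theta, y, X, K)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) {
      step <- solve(H - diag(1e-4 * (1 + abs(diag(H)))), g)
    }
    step <- -step
    # step-halve until the likelihood improves and cutpoints stay ordered
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      zeta <- cand[seq_len(K - 1)]
      ll_cand <- if (K > 2 && is.unsorted(zeta, strictly = TRUE)) -Inf
                 else ologit_loglik(cand, y, X, K)
      if (ll_cand > ll - 1e-12 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-10) { stalled <- TRUE; break }
    theta <- cand
    ll <- ll_cand
    # Newton is quadratic near the optimum: keep iterating to the
    # gradient criterion; the likelihood criterion only matters when
    # step-halving can no longer improve the fit
  }
  if (!converged)
    converged <- stalled && max(abs(ologit_gradient(theta, y, X, K))) < gradtol * 1e2
  if (max(abs(theta)) > 30)
    stop_n3("ordinal fit diverged (|coefficient| > 30): data are likely ",
            "completely separated on a predictor")
  H <- ologit_hessian_fd(theta, y, X, K)
  vcov <- tryCatch(solve(-H), error = function(e)
    stop_n3("singular information matrix: a predictor may be constant or collinear"))
  if (any(!is.finite(diag(vcov))) || any(diag(vcov) <= 0))
    stop_n3("information matrix is not positive definite; check predictors ",
            "for constancy or separation")
  list(theta = theta, zeta = theta[seq_len(K - 1)], beta = theta[-seq_len(K - 1)],
       vcov = vcov, logLik = ll, gradient = ologit_gradient(theta, y, X, K),
       iterations = iter, converged = converged)
}

# ---- model frame helpers ---------------------------------------------------

build_model_parts <- function(formula, data) {
  mf <- stats::model.frame(formula, data, drop.unused.levels = FALSE,
                           na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  int <- which(colnames(X) == "(Intercept)")
  if (length(int)) X <- X[, -int, drop = FALSE]
  list(mf = mf, y = y, X = X, terms = attr(mf, "terms"))
}

pick_score_term <- function(score_term, X) {
  if (!is.null(score_term)) {
    if (!score_term %in% colnames(X))
      stop_n3("score term '", score_term, "' is not a model-matrix column (have: ",
              paste(colnames(X), collapse = ", "), ")")
    return(score_term)
  }
  if ("grs" %in% colnames(X)) "grs" else colnames(X)[1]
}

# ---- ordinal fit -----------------------------------------------------------

#' Proportional-odds model of responder class on a genetic risk score
#'
#' Fits the cumulative-logit (proportional-odds) ordinal regression of
#' an ordered responder class on a genetic risk score and covariates by
#' maximum likelihood (Newton iterations with analytic gradient;
#' convergence when the relative log-likelihood change drops below 1e-8
#' or the gradient norm below 1e-6). With the class ordered
#' R < NR < AR, the reported odds ratio per score unit is exp(beta) and
#' OR > 1 means higher scores increase adverse-response risk.
#'
#' @param formula model formula; the response must be an ordered factor
#'   (e.g. `label ~ grs + age + sex + bmi`).
#' @param data data frame holding the variables.
#' @param score_term model-matrix column treated as the risk score for
#'   OR reporting (default `"grs"` if present, else the first term).
#' @return an object of class `c("grs_ordinal", "grs_fit")` with
#'   components `beta_grs`, `or_grs`, `se_beta`, `wald_p`,
#'   `coefficients` (slopes), `cutpoints`, `vcov` (cutpoints then
#'   slopes), `logLik`, `n_obs`, `converged`, `category_counts`.
#' @examples
#' sim <- simulate_study(sim_config(n_participants = 150, seed = 42))
#' d <- responder_data(sim, treatment = "EPA")
#' fit <- fit_ordinal(label ~ grs + age + sex + bmi, d)
#' summary(fit)
#' @seealso [fit_binary()] for the R-vs-AR model with non-responders
#'   excluded, [predict_curves()] for predicted-probability curves.
#' @export
fit_ordinal <- function(formula, data, score_term = NULL) {
  parts <- build_model_parts(formula, data)
  y_fac <- parts$y
  if (!is.factor(y_fac))
    stop_n3("the response must be an ordered factor (levels R < NR < AR)")
  observed <- levels(y_fac)[tabulate(as.integer(y_fac), nlevels(y_fac)) > 0]
  if (length(levels(y_fac)) > 2 && length(observed) < length(levels(y_fac)))
    stop_n3("response category absent from the data (",
            paste(setdiff(levels(y_fac), observed), collapse = ", "),
            "): collapse categories or use fit_binary() on the two observed classes")
  K <- nlevels(y_fac)
  if (K < 2) stop_n3("need at least two response categories")
  y <- as.integer(y_fac)
  X <- parts$X
  n <- length(y)
  if (n <= ncol(X) + K - 1)
    stop_n3("more parameters than observations")
  const_cols <- apply(X, 2, function(col) stats::var(col) == 0)
  if (any(const_cols))
    stop_n3("predictor constant across participants: ",
            paste(colnames(X)[const_cols], collapse = ", "))
  fit <- ologit_fit(y, X, K)
  score_term <- pick_score_term(score_term, X)
  beta <- fit$beta
  names(beta) <- colnames(X)
  zeta <- fit$zeta
  names(zeta) <- paste(levels(y_fac)[-K], levels(y_fac)[-1], sep = "|")
  vc <- fit$vcov
  dimnames(vc) <- list(c(names(zeta), names(beta)), c(names(zeta), names(beta)))
  j <- K - 1 + match(score_term, colnames(X))
  se <- sqrt(vc[j, j])
  z <- beta[[score_term]] / se
  out <- list(
    model_kind = "ordinal",
    formula = formula,
    score_term = score_term,
    beta_grs = unname(beta[[score_term]]),
    or_grs = exp(unname(beta[[score_term]])),
    se_beta = se,
    wald_z = z,
    wald_p = 2 * stats::pnorm(-abs(z)),
    coefficients = beta,
    cutpoints = zeta,
    covariate_coefficients = beta[setdiff(names(beta), score_term)],
    vcov = vc,
    logLik = fit$logLik,
    gradient = fit$gradient,
    iterations = fit$iterations,
    converged = fit$converged,
    n_obs = n,
    levels = levels(y_fac),
    category_counts = table(y_fac),
    xbar = colMeans(X),
    score_range = range(X[, score_term]),
    model_frame = parts$mf,
    terms = parts$terms
  )
  class(out) <- c("grs_ordinal", "grs_fit")
  if (!out$converged)
    warning("ordinal fit did not meet the convergence criterion; ",
            "inspect $gradient and $iterations", call. = FALSE)
  out
}

# ---- binary fit ------------------------------------------------------------

#' Binary logistic model of adverse vs favourable response
#'
#' Logistic regression of adverse response (AR = 1) against response
#' (R = 0) on a genetic risk score and covariates, for the analysis that
#' excludes non-responders. The response may be a factor with two
#' observed classes (last level is the event, so with R < AR the event
#' is AR) or a 0/1 vector. Delegates the ML fit to [stats::glm()] and
#' reports the score odds ratio with its Wald test.
#'
#' @inheritParams fit_ordinal
#' @return an object of class `c("grs_binary", "grs_fit")`, with the
#'   same headline components as [fit_ordinal()] (no cutpoints; the
#'   intercept is kept in `coefficients`) plus the underlying `glm` as
#'   `$glm`.
#' @examples
#' sim <- simulate_study(sim_config(n_participants = 200, seed = 7))
#' d <- responder_data(sim, treatment = "EPA")
#' d2 <- droplevels(subset(d, label != "NR"))
#' fit <- fit_binary(label ~ grs + age + sex + bmi, d2)
#' coef(fit)
#' @export
fit_binary <- function(formula, data, score_term = NULL) {
  parts <- build_model_parts(formula, data)
  y <- parts$y
  if (is.factor(y)) {
    y <- droplevels(y)
    if (nlevels(y) != 2)
      stop_n3("binary model needs exactly two observed classes, got: ",
              paste(levels(y), collapse = ", "),
              " (exclude non-responders upstream)")
    event <- levels(y)[2]
    y01 <- as.integer(y) - 1L
  } else {
    if (!all(y %in% c(0, 1))) stop_n3("numeric response must be 0/1")
    if (length(unique(y)) < 2) stop_n3("only one response class present")
    event <- "1"
    y01 <- as.integer(y)
  }
  X <- parts$X
  const_cols <- apply(X, 2, function(col) stats::var(col) == 0)
  if (any(const_cols))
    stop_n3("predictor constant across participants: ",
            paste(colnames(X)[const_cols], collapse = ", "))
  dat <- data.frame(.y = y01, X, check.names = FALSE)
  glm_formula <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                                       collapse = " + ")))
  fit <- suppressWarnings(stats::glm(glm_formula, data = dat, family = stats::binomial()))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_n3("inestimable coefficient (collinear predictors): ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  if (max(abs(cf[-1])) > 15 && any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    stop_n3("complete or quasi-complete separation detected (|coefficient| > 15 ",
            "with fitted probabilities at 0/1)")
  score_term <- pick_score_term(score_term, X)
  vc <- stats::vcov(fit)
  se <- sqrt(vc[score_term, score_term])
  z <- cf[[score_term]] / se
  slopes <- cf[-1]
  out <- list(
    model_kind = "binary",
    formula = formula,
    score_term = score_term,
    event_level = event,
    beta_grs = unname(cf[[score_term]]),
    or_grs = exp(unname(cf[[score_term]])),
    se_beta = se,
    wald_z = z,
    wald_p = 2 * stats::pnorm(-abs(z)),
    coefficients = cf,
    covariate_coefficients = slopes[setdiff(names(slopes), score_term)],
    vcov = vc,
    logLik = as.numeric(stats::logLik(fit)),
    iterations = fit$iter,
    converged = fit$converged,
    n_obs = length(y01),
    levels = if (is.factor(parts$y)) levels(y) else c("0", "1"),
    category_counts = table(factor(y01, 0:1,
                                   if (is.factor(parts$y)) levels(y) else c("0", "1"))),
    xbar = colMeans(X),
    score_range = range(X[, score_term]),
    glm = fit,
    terms = parts$terms
  )
  class(out) <- c("grs_binary", "grs_fit")
  out
}

# ---- methods ---------------------------------------------------------------

#' @export
coef.grs_fit <- function(object, ...) object$coefficients

#' @export
vcov.grs_fit <- function(object, ...) object$vcov

#' @export
logLik.grs_fit <- function(object, ...) {
  structure(object$logLik,
            df = length(object$coefficients) + length(object$cutpoints),
            class = "logLik")
}

#' @export
print.grs_fit <- function(x, digits = 4, ...) {
  kind <- if (x$model_kind == "ordinal") "Proportional-odds" else "Binary logistic"
  cat(sprintf("%s responder model (n = %d)\n", kind, x$n_obs))
  cat("Classes:", paste(sprintf("%s=%d", names(x$category_counts),
                                x$category_counts), collapse = ", "), "\n")
  cat(sprintf("Score term '%s': OR = %.*g per unit (beta = %.*g, SE = %.*g, p = %.*g)\n",
              x$score_term, digits, x$or_grs, digits, x$beta_grs,
              digits, x$se_beta, digits, x$wald_p))
  if (!is.null(x$cutpoints))
    cat("Cutpoints:", paste(sprintf("%s %.3f", names(x$cutpoints), x$cutpoints),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.grs_fit <- function(object, ...) {
  all_est <- if (object$model_kind == "ordinal")
    c(object$cutpoints, object$coefficients) else object$coefficients
  se <- sqrt(diag(object$vcov))[names(all_est)]
  z <- all_est / se
  tab <- cbind(Estimate = all_est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)),
               OR = exp(all_est))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.grs_fit"
  out
}

#' @export
print.summary.grs_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], has.Pvalue = TRUE)
  cat(sprintf("\nlogLik = %.4f, iterations = %d, converged = %s\n",
              x$fit$logLik, x$fit$iterations %||% NA_integer_, x$fit$converged))
  invisible(x)
}

ordinal_probs <- function(zeta, beta, X) {
  eta <- if (ncol(X)) drop(X %*% beta) else rep(0, nrow(X))
  K <- length(zeta) + 1
  cum <- vapply(zeta, function(z) stats::plogis(z - eta), numeric(length(eta)))
  cum <- cbind(matrix(cum, nrow = length(eta)), 1)
  probs <- cum - cbind(0, cum[, -K, drop = FALSE])
  probs
}

#' @export
predict.grs_ordinal <- function(object, newdata = NULL,
                                type = c("probs", "class", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) {
    stats::model.matrix(object$terms, object$model_frame)
  } else {
    mf <- stats::model.frame(stats::delete.response(object$terms), newdata)
    stats::model.matrix(stats::delete.response(object$terms), mf)
  }
  int <- which(colnames(X) == "(Intercept)")
  if (length(int)) X <- X[, -int, drop = FALSE]
  eta <- drop(X %*% object$coefficients)
  if (type == "link") return(eta)
  probs <- ordinal_probs(object$cutpoints, object$coefficients, X)
  colnames(probs) <- object$levels
  if (type == "class")
    return(factor(object$levels[max.col(probs)], levels = object$levels,
                  ordered = TRUE))
  probs
}

#' @export
predict.grs_binary <- function(object, newdata = NULL,
                               type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    p <- stats::predict(object$glm,
                        type = if (type == "link") "link" else "response")
  } else {
    mf <- stats::model.frame(stats::delete.response(object$terms), newdata)
    X <- stats::model.matrix(stats::delete.response(object$terms), mf)
    int <- which(colnames(X) == "(Intercept)")
    if (length(int)) X <- X[, -int, drop = FALSE]
    eta <- object$coefficients[["(Intercept)"]] + drop(X %*% object$coefficients[colnames(X)])
    p <- if (type == "link") eta else stats::plogis(eta)
  }
  if (type == "class")
    return(factor(ifelse(p > 0.5, object$levels[2], object$levels[1]),
                  levels = object$levels))
  p
}

#' @export
simulate.grs_ordinal <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  probs <- predict(object, type = "probs")
  out <- replicate(nsim, {
    k <- apply(probs, 1, function(p) sample.int(length(p), 1, prob = p))
    factor(object$levels[k], levels = object$levels, ordered = TRUE)
  }, simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' @export
plot.grs_fit <- function(x, ...) {
  plot(predict_curves(x), ...)
}

# ---- predicted-probability curves -----------------------------------------

#' Predicted-probability curves over the risk-score range
#'
#' Computes, on a grid of risk-score values, the fitted probability of
#' each responder class with covariates held at their sample means
#' (factor covariates, e.g. sex, at their observed proportions via the
#' model-matrix column means), together with 95\% confidence bands.
#'
#' Bands for the extreme classes (lowest and highest category, and both
#' classes of the binary model) use the delta method on the cumulative
#' linear predictor followed by the inverse-logit transform, so they
#' stay inside (0, 1). The middle class of the ordinal model is a
#' difference of two cumulative probabilities with no single linear
#' predictor; its band uses the delta method on the probability scale
#' (clipped to [0, 1]). `method = "simulation"` instead draws
#' coefficient vectors from the asymptotic normal and takes empirical
#' quantiles, for all classes.
#'
#' @param fit a [fit_ordinal()] or [fit_binary()] object.
#' @param grs_grid score values to evaluate; defaults to an even grid
#'   over the observed score range. Values outside the observed range
#'   are allowed and flagged in the `extrapolated` column.
#' @param level confidence level (default 0.95).
#' @param method `"delta"` (default) or `"simulation"`.
#' @param nsim draws for `method = "simulation"`.
#' @return a `grs_curves` data frame: `grs`, `category`, `probability`,
#'   `ci_low`, `ci_high`, `extrapolated`.
#' @export
predict_curves <- function(fit, grs_grid = NULL, level = 0.95,
                           method = c("delta", "simulation"), nsim = 2000) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "grs_fit"))
  if (!isTRUE(fit$converged))
    stop_n3("refusing to draw curves from a non-converged fit")
  if (is.null(grs_grid))
    grs_grid <- seq(fit$score_range[1], fit$score_range[2], length.out = 101)
  extrapolated <- grs_grid < fit$score_range[1] | grs_grid > fit$score_range[2]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  slopes <- if (fit$model_kind == "ordinal") fit$coefficients else fit$coefficients[-1]
  xnames <- names(slopes)
  Xg <- matrix(rep(fit$xbar, each = length(grs_grid)), nrow = length(grs_grid),
               dimnames = list(NULL, xnames))
  Xg[, fit$score_term] <- grs_grid
  if (fit$model_kind == "ordinal") {
    K <- length(fit$levels)
    zeta <- fit$cutpoints
    vc <- fit$vcov
    probs <- ordinal_probs(zeta, slopes, Xg)
    rows <- list()
    for (k in seq_len(K)) {
      pk <- probs[, k]
      if (method == "simulation") {
        ci <- curve_ci_sim(fit, Xg, k, level, nsim)
      } else if (k == 1 || k == K) {
        # single cumulative linear predictor: band on link scale
        m <- if (k == 1) 1 else K - 1
        grad <- cbind(outer(rep(1, nrow(Xg)), as.numeric(seq_len(K - 1) == m)), -Xg)
        lp <- zeta[m] - drop(Xg %*% slopes)
        se_lp <- sqrt(rowSums((grad %*% vc) * grad))
        lo <- stats::plogis(lp - zq * se_lp)
        hi <- stats::plogis(lp + zq * se_lp)
        ci <- if (k == 1) cbind(lo, hi) else cbind(1 - hi, 1 - lo)
      } else {
        # middle class: delta method on the probability scale
        lp_hi <- zeta[k] - drop(Xg %*% slopes)
        lp_lo <- zeta[k - 1] - drop(Xg %*% slopes)
        d_hi <- stats::dlogis(lp_hi)
        d_lo <- stats::dlogis(lp_lo)
        grad_z <- matrix(0, nrow(Xg), K - 1)
        grad_z[, k] <- d_hi
        grad_z[, k - 1] <- -d_lo
        grad <- cbind(grad_z, -(d_hi - d_lo) * Xg)
        se_p <- sqrt(rowSums((grad %*% vc) * grad))
        ci <- cbind(pmax(pk - zq * se_p, 0), pmin(pk + zq * se_p, 1))
      }
      rows[[k]] <- data.frame(grs = grs_grid, category = fit$levels[k],
                              probability = pk, ci_low = ci[, 1], ci_high = ci[, 2],
                              extrapolated = extrapolated, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
  } else {
    lp <- fit$coefficients[["(Intercept)"]] + drop(Xg %*% slopes)
    grad <- cbind(1, Xg)
    se_lp <- sqrt(rowSums((grad %*% fit$vcov) * grad))
    p1 <- stats::plogis(lp)
    lo <- stats::plogis(lp - zq * se_lp)
    hi <- stats::plogis(lp + zq * se_lp)
    out <- rbind(
      data.frame(grs = grs_grid, category = fit$levels[1], probability = 1 - p1,
                 ci_low = 1 - hi, ci_high = 1 - lo, extrapolated = extrapolated,
                 stringsAsFactors = FALSE),
      data.frame(grs = grs_grid, category = fit$levels[2], probability = p1,
                 ci_low = lo, ci_high = hi, extrapolated = extrapolated,
                 stringsAsFactors = FALSE)
    )
  }
  out$category <- factor(out$category, levels = fit$levels)
  rownames(out) <- NULL
  class(out) <- c("grs_curves", "data.frame")
  attr(out, "model_kind") <- fit$model_kind
  attr(out, "level") <- level
  out
}

curve_ci_sim <- function(fit, Xg, k, level, nsim) {
  theta <- if (fit$model_kind == "ordinal") c(fit$cutpoints, fit$coefficients)
           else fit$coefficients
  draws <- MASS::mvrnorm(nsim, theta, fit$vcov)
  K <- length(fit$levels)
  sims <- apply(draws, 1, function(th) {
    ordinal_probs(th[seq_len(K - 1)], th[-seq_len(K - 1)], Xg)[, k]
  })
  t(apply(sims, 1, stats::quantile,
          probs = c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' @export
plot.grs_curves <- function(x, main = NULL, xlab = "Genetic risk score",
                            ylab = "Predicted probability", ...) {
  cats <- levels(x$category)
  cols <- grDevices::hcl.colors(max(3, length(cats)), "Dark 3")[seq_along(cats)]
  band <- grDevices::adjustcolor("steelblue", alpha.f = 0.25)
  plot(NA, xlim = range(x$grs), ylim = c(0, 1), xlab = xlab, ylab = ylab,
       main = main %||% sprintf("Responder-class probability (%s model)",
                                attr(x, "model_kind")), ...)
  for (i in seq_along(cats)) {
    d <- x[x$category == cats[i], ]
    graphics::polygon(c(d$grs, rev(d$grs)), c(d$ci_low, rev(d$ci_high)),
                      col = band, border = NA)
    graphics::lines(d$grs, d$probability, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = cats, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Write predicted-probability curves as TSV
#'
#' @param curves a [predict_curves()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  out <- as.data.frame(curves)
  out$category <- as.character(out$category)
  write_tsv_fixed(out, path)
  invisible(path)
}

# ---- subgroup allele-frequency comparisons --------------------------------

#' Allele-frequency comparison between responder subgroups
#'
#' For every panel SNP, compares effect-allele counts between two
#' responder subgroups (e.g. R vs NR, NR vs AR, R vs AR) with the 2x2
#' allele-count chi-squared of [compare_maf()].
#'
#' @param matrix a [genotype_matrix()].
#' @param panel a [snp_panel()].
#' @param labels data frame with `participant_id` and `label` columns
#'   (one treatment's classification, see [classify_cohort()]).
#' @param pair length-2 character vector naming the two subgroups.
#' @return data frame of per-SNP comparisons (`maf_a` = first group of
#'   `pair`), ordered as the panel.
#' @export
subgroup_maf_tests <- function(matrix, panel, labels, pair = c("R", "AR")) {
  panel <- validate_snp_panel(panel)
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% labels$label))
    stop_n3("empty subgroup in pair ", paste(pair, collapse = " vs "))
  ids_a <- labels$participant_id[labels$label == pair[1]]
  ids_b <- labels$participant_id[labels$label == pair[2]]
  sub_a <- matrix[rownames(matrix) %in% ids_a, , drop = FALSE]
  sub_b <- matrix[rownames(matrix) %in% ids_b, , drop = FALSE]
  out <- do.call(rbind, lapply(panel$snp_id, function(s) {
    compare_maf(allele_counts_from_matrix(sub_a, s),
                allele_counts_from_matrix(sub_b, s), snp_id = s)
  }))
  out$group_a <- pair[1]
  out$group_b <- pair[2]
  rownames(out) <- NULL
  out
}

#' Assemble a modelling data frame from pipeline pieces
#'
#' Joins genetic risk scores, responder labels and covariates into the
#' data frame expected by [fit_ordinal()]/[fit_binary()]: one row per
#' participant with `grs`, `age`, `sex`, `bmi` and the ordered `label`
#' for the requested treatment.
#'
#' @param x either a simulation result from [simulate_study()] or a list
#'   with elements `grs` (from [compute_grs()]), `labels` (from
#'   [classify_cohort()]) and `phenotypes`.
#' @param treatment `"EPA"` or `"DHA"`.
#' @return data frame `participant_id`, `grs`, `age`, `sex`, `bmi`,
#'   `label` (ordered R < NR < AR).
#' @export
responder_data <- function(x, treatment = c("EPA", "DHA")) {
  treatment <- match.arg(treatment)
  labels <- x$labels[x$labels$treatment == treatment, ]
  d <- merge(x$grs[, c("participant_id", "grs")],
             x$phenotypes[, c("participant_id", "age", "sex", "bmi")],
             by = "participant_id")
  d <- merge(d, labels[, c("participant_id", "label")], by = "participant_id")
  d$label <- factor(as.character(d$label), levels = RESPONSE_LEVELS, ordered = TRUE)
  d$sex <- factor(d$sex)
  d[order(d$participant_id), , drop = FALSE]
}
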