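# helper: ordinal data drawn from a proportional-odds model
sim_ordinal_data <- function(n, beta, cutpoints = c(-0.2, 2.2), seed = NULL,
                             covariates = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  g <- rbinom(n, 12, 0.3)
  age <- rnorm(n, 53, 14)
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  bmi <- rnorm(n, 29, 4)
  eta <- beta * (g - mean(g))
  u <- runif(n)
  p1 <- plogis(cutpoints[1] - eta)
  p2 <- plogis(cutpoints[2] - eta)
  label <- ordered(ifelse(u < p1, "R", ifelse(u < p2, "NR", "AR")),
                   levels = c("R", "NR", "AR"))
  if (covariates) data.frame(label, grs = g, age, sex, bmi)
  else data.frame(label, grs = g)
}

test_that("the proportional-odds fitter matches MASS::polr", {
  d <- sim_ordinal_data(400, beta = log(1.3), seed = 21)
  fit <- fit_ordinal(label ~ grs + age + sex + bmi, d)
  ref <- MASS::polr(label ~ grs + age + sex + bmi, data = d, Hess = TRUE,
                    control = list(reltol = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$cutpoints), unname(ref$zeta), tolerance = 1e-5)
  expect_equal(fit$logLik, -ref$deviance / 2, tolerance = 1e-8)
  # polr orders its vcov (slopes, cutpoints); ours is (cutpoints, slopes)
  se_ref <- sqrt(diag(vcov(ref)))
  se_ref <- unname(se_ref[c(length(se_ref) - 1, length(se_ref),
                            seq_len(length(se_ref) - 2))])
  expect_equal(unname(sqrt(diag(fit$vcov))), se_ref, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(fit$or_grs, exp(fit$beta_grs))
  expect_lt(max(abs(fit$gradient)), 1e-6)
  expect_true(all(diff(fit$cutpoints) > 0))
})

test_that("ordinal fit with two categories reproduces binary logistic within 1e-6", {
  d <- sim_ordinal_data(300, beta = log(1.4), seed = 22)
  d2 <- droplevels(d[d$label != "NR", ])
  ord2 <- fit_ordinal(label ~ grs + age + sex + bmi, d2)
  bin <- fit_binary(label ~ grs + age + sex + bmi, d2)
  expect_equal(unname(coef(ord2)), unname(coef(bin)[-1]), tolerance = 1e-6)
  expect_equal(unname(ord2$cutpoints), -unname(coef(bin)[1]), tolerance = 1e-6)
  expect_equal(ord2$beta_grs, bin$beta_grs, tolerance = 1e-6)
})

test_that("reversing the category order negates the score coefficient", {
  d <- sim_ordinal_data(300, beta = log(1.3), seed = 23)
  fit <- fit_ordinal(label ~ grs + age + sex + bmi, d)
  d_rev <- d
  d_rev$label <- ordered(d$label, levels = rev(levels(d$label)))
  fit_rev <- fit_ordinal(label ~ grs + age + sex + bmi, d_rev)
  expect_equal(fit_rev$beta_grs, -fit$beta_grs, tolerance = 1e-6)
  expect_equal(unname(fit_rev$cutpoints), rev(-unname(fit$cutpoints)),
               tolerance = 1e-6)
})

test_that("ML score equations hold at the optimum; binary frequencies match exactly", {
  d <- sim_ordinal_data(500, beta = log(1.2), seed = 24)
  fit <- fit_ordinal(label ~ grs + age + sex + bmi, d)
  expect_lt(max(abs(fit$gradient)), 1e-6)
  # binary (K=2) intercept-containing model: mean fitted prob = class frequency
  d2 <- droplevels(d[d$label != "NR", ])
  bin <- fit_binary(label ~ grs + age + sex + bmi, d2)
  expect_equal(mean(predict(bin, type = "response")),
               mean(d2$label == "AR"), tolerance = 1e-9)
})

test_that("covariate-free binary fit matches the closed-form 2x2 log odds ratio", {
  # spec'd table: (R,high)=10, (AR,high)=20, (R,low)=20, (AR,low)=10
  d <- data.frame(
    label = ordered(rep(c("R", "AR", "R", "AR"), c(10, 20, 20, 10)),
                    levels = c("R", "AR")),
    grs = rep(c(1, 1, 0, 0), c(10, 20, 20, 10))
  )
  fit <- fit_binary(label ~ grs, d)
  expect_equal(fit$or_grs, 4.0, tolerance = 1e-6)
  expect_equal(fit$beta_grs, log(4), tolerance = 1e-6)

  # enumerated small tables: MLE log-OR equals the sample log odds ratio
  set.seed(25)
  cells <- expand.grid(a = c(3, 8, 20), b = c(4, 11), c = c(5, 17), d = c(6, 20))
  for (i in seq_len(nrow(cells))) {
    cc <- as.numeric(cells[i, ])
    dat <- data.frame(
      label = ordered(rep(c("R", "AR", "R", "AR"), cc), levels = c("R", "AR")),
      grs = rep(c(0, 0, 1, 1), cc)
    )
    fit_i <- fit_binary(label ~ grs, dat)
    expect_equal(fit_i$beta_grs, log((cc[1] * cc[4]) / (cc[2] * cc[3])),
                 tolerance = 1e-6)
  }
})

test_that("degenerate inputs raise informative errors", {
  d <- sim_ordinal_data(200, beta = 0, seed = 26)
  d$label[d$label == "AR"] <- "NR"  # drop a category
  expect_error(fit_ordinal(label ~ grs + age + sex + bmi, d), "fit_binary")
  d2 <- sim_ordinal_data(100, beta = 0, seed = 27)
  d2$grs <- 5
  expect_error(fit_ordinal(label ~ grs + age + sex + bmi, d2), "constant")
  d3 <- droplevels(sim_ordinal_data(100, 0, seed = 28))
  d3 <- d3[d3$label != "NR", ]
  d3$grs <- 3
  expect_error(fit_binary(label ~ grs, droplevels(d3)), "constant")
  # separation: score perfectly splits the classes
  d4 <- data.frame(
    label = ordered(rep(c("R", "AR"), each = 20), levels = c("R", "AR")),
    grs = rep(c(0, 1), each = 20)
  )
  expect_error(fit_binary(label ~ grs, d4), "separation")
})

test_that("Wald test for the score holds its nominal level under the null", {
  set.seed(2025)
  n_rep <- 2000
  p_reject <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- sim_ordinal_data(500, beta = 0, covariates = FALSE)
    fit <- fit_ordinal(label ~ grs, d, score_term = "grs")
    p_reject[i] <- fit$wald_p < 0.05
  }
  expect_gte(mean(p_reject), 0.035)
  expect_lte(mean(p_reject), 0.065)
})

test_that("predicted curves normalise, follow the fitted slope, and flag extrapolation", {
  d <- sim_ordinal_data(600, beta = log(1.4), seed = 31)
  fit <- fit_ordinal(label ~ grs + age + sex + bmi, d)
  cv <- predict_curves(fit)
  sums <- tapply(cv$probability, cv$grs, sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
  expect_true(all(cv$ci_low >= 0 & cv$ci_high <= 1))
  expect_true(all(cv$ci_low <= cv$probability & cv$probability <= cv$ci_high))
  # with beta > 0 (toward AR), P(R) decreases as the score grows
  pr <- cv[cv$category == "R", ]
  expect_true(all(diff(pr$probability) < 0))
  pa <- cv[cv$category == "AR", ]
  expect_true(all(diff(pa$probability) > 0))

  out_grid <- predict_curves(fit, grs_grid = c(min(d$grs) - 2, max(d$grs) + 2))
  expect_true(all(out_grid$extrapolated))

  # simulation bands agree broadly with delta-method bands
  cv_sim <- predict_curves(fit, grs_grid = c(2, 6), method = "simulation",
                           nsim = 4000)
  merged <- merge(cv, cv_sim, by = c("grs", "category"))
  expect_lt(max(abs(merged$ci_low.x - merged$ci_low.y)), 0.05)
})

test_that("a null fit yields flat curves at the marginal frequencies", {
  d <- sim_ordinal_data(2000, beta = 0, seed = 32, covariates = FALSE)
  fit <- fit_ordinal(label ~ grs, d, score_term = "grs")
  expect_gt(fit$wald_p, 0.001)
  expect_lt(abs(fit$or_grs - 1), 0.1)
  cv <- predict_curves(fit, grs_grid = c(0, 4, 8))
  freq <- prop.table(table(d$label))
  for (k in names(freq)) {
    pk <- cv$probability[cv$category == k]
    expect_lt(diff(range(pk)), 0.05)           # flat
    expect_lt(abs(mean(pk) - freq[[k]]), 0.05) # at the marginal frequency
  }
})

test_that("binary curves use the two-class fit and normalise", {
  d <- droplevels(subset(sim_ordinal_data(400, log(1.5), seed = 33),
                         label != "NR"))
  fit <- fit_binary(label ~ grs + age + sex + bmi, d)
  cv <- predict_curves(fit, grs_grid = 0:10)
  sums <- tapply(cv$probability, cv$grs, sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  pa <- cv[cv$category == "AR", ]
  expect_true(all(diff(pa$probability) > 0))
})

test_that("subgroup frequency comparisons delegate to the allele-count test", {
  set.seed(34)
  panel <- toy_panel(2)
  d <- matrix(rbinom(200, 2, 0.3), ncol = 2)
  g <- toy_genotypes(d)
  labels <- data.frame(
    participant_id = rownames(g),
    treatment = "EPA",
    label = rep(c("R", "AR"), each = 50),
    stringsAsFactors = FALSE
  )
  res <- subgroup_maf_tests(g, panel, labels, pair = c("R", "AR"))
  expect_equal(nrow(res), 2)
  # oracle: recompute from raw allele counts
  counts <- function(rows, j) c(sum(d[rows, j]), 2 * length(rows))
  manual <- compare_maf(counts(1:50, 1), counts(51:100, 1))
  expect_equal(res$chi_squared[1], manual$chi_squared)
  expect_equal(res$p_value[1], manual$p_value)

  identical_groups <- labels
  identical_groups$label <- rep(c("R", "AR"), 50)  # interleaved
  g_dup <- toy_genotypes(rbind(d[1:50, ], d[1:50, ]))
  lab_dup <- data.frame(participant_id = rownames(g_dup), treatment = "EPA",
                        label = rep(c("R", "AR"), each = 50))
  res_dup <- subgroup_maf_tests(g_dup, panel, lab_dup, pair = c("R", "AR"))
  expect_true(all(res_dup$p_value == 1))  # identical genotype data

  expect_error(subgroup_maf_tests(g, panel, labels, pair = c("R", "NR")),
               "empty subgroup")
})

test_that("a planted frequency-differentiated SNP attains the smallest subgroup p", {
  set.seed(35)
  panel <- toy_panel(5)
  n_per <- 120
  d <- cbind(
    rbinom(2 * n_per, 2, 0.25),
    rbinom(2 * n_per, 2, 0.25),
    c(rbinom(n_per, 2, 0.10), rbinom(n_per, 2, 0.45)),  # planted
    rbinom(2 * n_per, 2, 0.25),
    rbinom(2 * n_per, 2, 0.25)
  )
  g <- toy_genotypes(d)
  labels <- data.frame(participant_id = rownames(g), treatment = "EPA",
                       label = rep(c("R", "AR"), each = n_per))
  res <- subgroup_maf_tests(g, panel, labels, pair = c("R", "AR"))
  expect_equal(res$snp_id[which.min(res$p_value)], "rs3")
})
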