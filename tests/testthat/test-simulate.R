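test_that("the default configuration carries the study conditions", {
  cfg <- compared_preset()
  expect_equal(cfg$n_participants, 122L)
  expect_equal(nrow(cfg$panel), 31)
  expect_equal(cfg$baseline_tg_mean, 1.43)
  expect_equal(cfg$baseline_tg_sd, 0.71)
  expect_equal(cfg$intra_individual_sd, 0.25)
  expect_equal(cfg$window, 0.25)
  expect_equal(cfg$beta_grs, log(1.2))
  expect_equal(unname(cfg$treatment_effect[c("EPA", "DHA")]), c(0.133, 0.189))
  expect_equal(cfg$n_off_treatment, 4L)
})

test_that("config validation rejects out-of-range parameters", {
  bad_panel <- toy_panel(2)
  expect_error(sim_config(panel = bad_panel), "maf")
  bad_panel$maf <- c(0.3, 1.2)
  expect_error(sim_config(panel = bad_panel), "inside")
  expect_error(sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(cutpoints = c(2, 1)), "cutpoints")
})

test_that("simulated genotypes have the configured frequencies and HWE structure", {
  panel <- toy_panel(2)
  panel$maf <- c(0.30, 0.10)
  cfg <- sim_config(n_participants = 10000, panel = panel, seed = 50)
  g <- simulate_genotypes(cfg)
  expect_lt(abs(compute_maf(g, "rs1") - 0.30), 0.01)
  expect_lt(abs(compute_maf(g, "rs2") - 0.10), 0.01)
  expect_false(anyNA(g))
  # genotype proportions consistent with HWE
  expect_gt(hwe_test(genotype_counts(g, "rs1"))$p_value, 1e-4)

  cfg_miss <- sim_config(n_participants = 500, panel = panel,
                         missing_rate = 0.1, seed = 51)
  gm <- simulate_genotypes(cfg_miss)
  expect_gt(mean(is.na(gm)), 0.06)
  expect_lt(mean(is.na(gm)), 0.14)
})

test_that("simulation is reproducible bit-for-bit under a fixed seed", {
  cfg <- sim_config(n_participants = 80, seed = 52)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(unclass(s1$genotypes), unclass(s2$genotypes))
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_study(sim_config(n_participants = 80, seed = 53))
  expect_false(identical(unclass(s1$genotypes), unclass(s3$genotypes)))
})

test_that("with no score effect, class frequencies match the cutpoint probabilities", {
  cfg <- sim_config(n_participants = 6000, beta_grs = 0, seed = 54)
  sim <- simulate_study(cfg)
  labs <- sim$truth$class_epa
  p_expected <- c(R = 0.45, NR = 0.45, AR = 0.10)
  for (k in names(p_expected)) {
    se <- sqrt(p_expected[[k]] * (1 - p_expected[[k]]) / 6000)
    expect_lt(abs(mean(labs == k) - p_expected[[k]]), 3 * se + 1e-9)
  }
})

test_that("label-first simulation round-trips through classification exactly", {
  sim <- simulate_study(sim_config(n_participants = 400, seed = 55))
  lab_epa <- sim$labels[sim$labels$treatment == "EPA", ]
  lab_dha <- sim$labels[sim$labels$treatment == "DHA", ]
  expect_identical(as.character(lab_epa$label), as.character(sim$truth$class_epa))
  expect_identical(as.character(lab_dha$label), as.character(sim$truth$class_dha))
})

test_that("delta-first simulation produces classifiable responses without truth labels", {
  sim <- simulate_study(sim_config(n_participants = 200, seed = 56),
                        scheme = "delta_first")
  expect_true(all(is.na(sim$truth$class_epa)))
  expect_false(anyNA(sim$labels$label))
  expect_true(all(sim$phenotypes$tg_post_epa > 0))
})

test_that("simulated TG marginals track the configured study conditions", {
  sim <- simulate_study(sim_config(n_participants = 4000, seed = 57))
  ph <- sim$phenotypes
  expect_lt(abs(mean(ph$tg_post_control) - 1.43), 0.08)
  # both supplements lower TG on average, DHA more than EPA
  d_epa <- mean(ph$tg_post_epa - ph$tg_post_control)
  d_dha <- mean(ph$tg_post_dha - ph$tg_post_control)
  expect_lt(d_epa, -0.05)
  expect_lt(d_dha, d_epa)
})

test_that("simulated datasets round-trip through the disk format", {
  sim <- simulate_study(sim_config(n_participants = 30, seed = 58))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  g <- read_genotypes_tsv(file.path(dir, "genotypes.tsv"))
  expect_identical(unclass(g), unclass(sim$genotypes))
  ph <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(ph$tg_post_epa, sim$phenotypes$tg_post_epa, tolerance = 1e-4)
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$n_participants, 30)
  expect_equal(length(cfg_back$panel), 31)
})
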