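test_that("compute_maf counts effect alleles over non-missing chromosomes", {
  g0 <- toy_genotypes(matrix(0L, nrow = 5, ncol = 1))
  expect_equal(compute_maf(g0, "rs1"), 0)

  g2 <- toy_genotypes(matrix(2L, nrow = 10, ncol = 1))
  expect_equal(compute_maf(g2, "rs1"), 1)

  # genotype counts aa=9, Aa=42, AA=49 for effect allele a -> 0.30
  g <- genotypes_from_counts(c(49, 42, 9))
  expect_equal(compute_maf(g, "rs1"), (2 * 9 + 42) / 200)

  gm <- toy_genotypes(matrix(c(2L, NA, 0L, NA), ncol = 1))
  expect_equal(compute_maf(gm, "rs1"), 0.5)  # 2 of 4 non-missing chromosomes

  expect_error(compute_maf(g, "rs99"), "unknown SNP")
  g_all_na <- toy_genotypes(matrix(NA_integer_, nrow = 3, ncol = 1))
  expect_error(compute_maf(g_all_na, "rs1"), "missing")
})

test_that("compute_maf is invariant to participant order and cohort duplication", {
  set.seed(41)
  for (rep in 1:10) {
    d <- sample(0:2, 30, replace = TRUE)
    g <- toy_genotypes(matrix(d, ncol = 1))
    perm <- toy_genotypes(matrix(sample(d), ncol = 1))
    doubled <- toy_genotypes(matrix(c(d, d), ncol = 1))
    expect_equal(compute_maf(perm, "rs1"), compute_maf(g, "rs1"))
    expect_equal(compute_maf(doubled, "rs1"), compute_maf(g, "rs1"))
  }
})

test_that("hwe_test matches hand-computed Pearson statistics", {
  perfect <- hwe_test(c(25, 50, 25))
  expect_equal(perfect$chi_squared, 0)
  expect_equal(perfect$p_value, 1)

  dev <- hwe_test(c(30, 40, 30))
  expect_equal(dev$chi_squared, 4.0)
  expect_equal(dev$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_false(dev$pass)

  mono <- hwe_test(c(100, 0, 0))
  expect_equal(mono$chi_squared, 0)
  expect_equal(mono$p_value, 1)
  expect_true(mono$monomorphic)

  expect_error(hwe_test(c(-1, 2, 3)), "non-negative")
  expect_error(hwe_test(c(0, 0, 0)), "at least one")
})

test_that("hwe chi-squared equals the squared HWE z-statistic on enumerated triples", {
  # z = sqrt(n) * (obs hom-effect freq - phat^2) / (phat * qhat)
  for (n in c(4, 9, 17, 30)) {
    for (n2 in 0:n) for (n1 in 0:(n - n2)) {
      cnt <- c(n - n1 - n2, n1, n2)
      p <- (2 * cnt[3] + cnt[2]) / (2 * n)
      res <- hwe_test(cnt)
      if (p == 0 || p == 1) {
        expect_equal(res$chi_squared, 0)
      } else {
        z <- sqrt(n) * (cnt[3] / n - p^2) / (p * (1 - p))
        expect_equal(res$chi_squared, z^2, tolerance = 1e-9)
      }
    }
  }
})

test_that("filter_hwe partitions the panel and preserves order", {
  panel <- toy_panel(3)
  # rs2 grossly violates HWE (all heterozygous), rs1/rs3 exact HWE
  d <- cbind(rep(0:2, times = c(25, 50, 25)),
             rep(1L, 100),
             rep(0:2, times = c(36, 48, 16)))
  g <- toy_genotypes(d)
  res <- filter_hwe(g, panel, alpha = 0.05)
  expect_equal(res$retained$snp_id, c("rs1", "rs3"))
  expect_equal(res$excluded$snp_id, "rs2")
  expect_equal(nrow(res$retained) + nrow(res$excluded), nrow(panel))
  expect_length(intersect(res$retained$snp_id, res$excluded$snp_id), 0)

  # alpha = 0 retains everything
  res0 <- filter_hwe(g, panel, alpha = 0)
  expect_equal(nrow(res0$retained), 3)
  expect_equal(nrow(res0$excluded), 0)

  empty <- filter_hwe(g, panel[0, ], alpha = 0.05)
  expect_equal(nrow(empty$retained), 0)
})

test_that("hwe test holds its nominal type-I error under exact HWE sampling", {
  set.seed(2024)
  n_rep <- 2000
  rejected <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- stats::rbinom(122, 2, 0.3)
    rejected[i] <- hwe_test(c(sum(d == 0), sum(d == 1), sum(d == 2)))$p_value < 0.05
  }
  expect_gte(mean(rejected), 0.035)
  expect_lte(mean(rejected), 0.065)
})

test_that("compare_maf matches the 2x2 Pearson oracle and is symmetric", {
  cmp <- compare_maf(c(10, 100), c(30, 100))
  expect_equal(cmp$chi_squared, 12.5)
  expect_equal(cmp$p_value, pchisq(12.5, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(cmp$maf_a, 0.10)
  expect_equal(cmp$maf_b, 0.30)

  same <- compare_maf(c(17, 80), c(17, 80))
  expect_equal(same$chi_squared, 0)
  expect_equal(same$p_value, 1)

  degen <- compare_maf(c(0, 50), c(0, 50))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)

  set.seed(7)
  for (i in 1:20) {
    a <- c(rbinom(1, 60, 0.3), 60)
    b <- c(rbinom(1, 90, 0.2), 90)
    ab <- compare_maf(a, b)
    ba <- compare_maf(b, a)
    expect_equal(ab$chi_squared, ba$chi_squared)
    expect_equal(ab$p_value, ba$p_value)
  }

  expect_error(compare_maf(c(5, 1), c(1, 10)), "counts_a")
  expect_error(compare_maf(c(11, 10), c(1, 10)), "counts_a")
})

test_that("maf_table flags rare SNPs inclusively and joins reference comparisons", {
  panel <- toy_panel(3)
  # MAFs 0.05 (boundary), 0.30, 0.00? keep polymorphic: 0.05, 0.30, 0.10
  d <- cbind(rep(0:2, times = c(90, 10, 0)),       # maf 0.05
             rep(0:2, times = c(49, 42, 9)),       # maf 0.30
             rep(0:2, times = c(81, 18, 1)))       # maf 0.10
  g <- toy_genotypes(d)
  tab <- maf_table(g, panel)
  expect_equal(tab$maf, c(0.05, 0.30, 0.10))
  expect_equal(tab$rare_flag, c(TRUE, FALSE, FALSE))  # threshold inclusive
  expect_equal(maf_table(g, panel, rare_threshold = 0)$rare_flag,
               rep(FALSE, 3))

  with_ref <- maf_table(g, panel, reference_mafs = c(rs2 = 0.30), reference_n = 100)
  expect_true(is.na(with_ref$cmp_p[1]))
  expect_equal(with_ref$ref_maf[2], 0.30)
  expect_equal(with_ref$cmp_chi2[2], 0)  # identical counts
  expect_error(maf_table(g, panel, reference_mafs = c(rs2 = 0.3)), "reference_n")
})

test_that("genotype TSV and VCF readers agree with the in-memory matrix", {
  d <- rbind(c(0L, 2L), c(1L, NA), c(2L, 0L))
  g <- toy_genotypes(d)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(g, tsv)
  back <- read_genotypes_tsv(tsv)
  expect_equal(unclass(back), unclass(g))

  skip_if_not_installed("vcfR")
  panel <- snp_panel(c("rs1", "rs2"), "L", effect_allele = c("A", "T"),
                     other_allele = c("G", "C"), direction = 1L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp01\tp02\tp03",
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",   # effect = ALT
    "1\t200\trs2\tT\tC\t.\tPASS\t.\tGT\t0/0\t./.\t1/1"    # effect = REF
  ), vcf)
  gv <- read_genotypes_vcf(vcf, panel)
  expect_equal(unname(gv[, "rs1"]), c(0L, 1L, 2L))
  expect_equal(unname(gv[, "rs2"]), c(2L, NA, 0L))  # REF-oriented dosage flipped

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tp01",
    "1\t100\trs1\tC\tT\t.\tPASS\t.\tGT\t0/1"
  ), bad)
  expect_error(read_genotypes_vcf(bad, panel), "do not match panel alleles")
})
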