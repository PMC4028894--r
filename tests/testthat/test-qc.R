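test_that("mendelianCheck enumerates impossible trios", {
  expect_identical(mendelianCheck("aa", "aa", "ab"), "error")
  expect_identical(mendelianCheck("aa", "ab", "bb"), "error")
  expect_identical(mendelianCheck("aa", "bb", "ab"), "ok")
  expect_identical(mendelianCheck("aa", "bb", "aa"), "error")
  expect_identical(mendelianCheck("ab", "ab", "aa"), "ok")
  expect_identical(mendelianCheck("aa", NA, "ab"), "untestable")
  expect_identical(mendelianCheck("aa", "ab", NA), "untestable")
  expect_error(mendelianCheck("aa", "ab", "xz"), "malformed")
})

test_that("vectorised Mendelian errors agree with the scalar check", {
  set.seed(21)
  gts <- c("aa", "ab", "bb", NA)
  g <- matrix(sample(gts, 60 * 6, replace = TRUE), nrow = 60,
              dimnames = list(sprintf("m%02d", 1:60),
                              c("mo", "fa", "o1", "o2", "o3", "o4")))
  ind <- data.frame(id = colnames(g), family = "fam1",
                    role = c("mother", "father", rep("offspring", 4)))
  x <- genotypeMatrix(g, ind)
  err <- mendelianErrors(x)
  for (i in seq_len(nrow(g))) {
    for (j in 3:6) {
      want <- mendelianCheck(g[i, 1], g[i, 2], g[i, j])
      got <- err[i, j - 2L]
      expect_identical(is.na(got), want == "untestable")
      if (!is.na(got)) expect_identical(unname(got), want == "error")
    }
  }
})

test_that("heterozygosity excess counts non-missing calls only", {
  expect_equal(heterozygosityExcess(rep("ab", 96)), 1.0)
  expect_equal(heterozygosityExcess(c(rep("ab", 50), rep("aa", 50))), 0.5)
  h <- heterozygosityExcess(c(rep("ab", 71), rep("aa", 29)))
  expect_equal(h, 0.71)
  expect_gt(h, 0.70)
  expect_equal(heterozygosityExcess(c("ab", "aa", NA, NA)), 0.5)
  expect_error(heterozygosityExcess(c(NA_character_, NA)), "missing")
})

test_that("filter cascade removes the planted failures from a toy family", {
  # 6 SNPs x (2 parents + 4 offspring): one all-missing-in-offspring SNP,
  # one 80%-heterozygous SNP, one SNP with two planted Mendelian errors,
  # three clean SNPs
  g <- matrix(c(
    "ab", "aa", NA,   NA,   NA,   NA,     # >50% missing
    "ab", "ab", "ab", "ab", "ab", "ab",   # het = 100% > 70%
    "aa", "aa", "bb", "bb", "aa", "aa",   # two Mendelian errors
    "ab", "aa", "aa", "ab", "aa", "ab",   # clean
    "aa", "ab", "ab", "aa", "ab", "aa",   # clean
    "aa", "bb", "ab", "ab", "ab", "ab"    # clean
  ), nrow = 6, byrow = TRUE,
  dimnames = list(sprintf("s%d", 1:6), c("mo", "fa", "o1", "o2", "o3", "o4")))
  ind <- data.frame(id = colnames(g), family = "fam1",
                    role = c("mother", "father", rep("offspring", 4)))
  x <- genotypeMatrix(g, ind)
  res <- applyFilterCascade(x, indMendelMax = 10L)
  expect_identical(markerIds(res$matrix), c("s4", "s5", "s6"))
  st <- ledgerSteps(res$ledger)
  expect_equal(st$snps_eliminated,
               c(1L, 0L, 1L, 1L, 0L))
  expect_equal(st$snps_remaining[5], 3L)
})

test_that("disabled thresholds leave the matrix untouched", {
  x <- toyFamily()
  res <- applyFilterCascade(x, snpMissingness = 1, individualCallRate = 0,
                            hetThreshold = 1, snpMendelMax = 10^6,
                            indMendelMax = 10^6)
  expect_identical(genotypes(res$matrix), genotypes(x))
  st <- ledgerSteps(res$ledger)
  expect_true(all(st$snps_eliminated == 0L))
  expect_true(all(st$individuals_eliminated == 0L))
})

test_that("single Mendelian errors are masked, not discarded", {
  g <- matrix(c(
    "aa", "aa", "ab", "aa", "aa", "aa",   # one error at o1 -> masked
    "ab", "aa", "aa", "ab", "aa", "ab"    # clean
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("s1", "s2"), c("mo", "fa", "o1", "o2", "o3", "o4")))
  ind <- data.frame(id = colnames(g), family = "fam1",
                    role = c("mother", "father", rep("offspring", 4)))
  res <- applyFilterCascade(genotypeMatrix(g, ind), indMendelMax = 10L)
  expect_identical(markerIds(res$matrix), c("s1", "s2"))
  expect_true(is.na(genotypes(res$matrix)["s1", "o1"]))
})

test_that("SNPs without calls in both parents are missing for that family", {
  g <- matrix(c(
    NA,   "aa", "ab", "ab", "ab", "ab",   # mother uncalled -> family masked
    "ab", "aa", "aa", "ab", "aa", "ab"
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("s1", "s2"), c("mo", "fa", "o1", "o2", "o3", "o4")))
  ind <- data.frame(id = colnames(g), family = "fam1",
                    role = c("mother", "father", rep("offspring", 4)))
  res <- applyFilterCascade(genotypeMatrix(g, ind), snpMissingness = 1,
                            individualCallRate = 0, indMendelMax = 10L)
  expect_true(all(is.na(genotypes(res$matrix)["s1", ])))
})

test_that("the cascade is idempotent on its own output", {
  cfg <- simConfig(n_families = 2, n_offspring = 25, n_groups = 2,
                   markers_per_group = 30, psv_fraction = 0.15,
                   genotype_error_rate = 0.01, seed = 22)
  st <- simulateStudy(cfg)
  r1 <- applyFilterCascade(st$genotypes)
  r2 <- applyFilterCascade(r1$matrix)
  st2 <- ledgerSteps(r2$ledger)
  expect_true(all(st2$snps_eliminated == 0L))
  expect_true(all(st2$individuals_eliminated == 0L))
  expect_identical(genotypes(r2$matrix), genotypes(r1$matrix))
})

test_that("planted PSVs are recalled with few false removals", {
  cfg <- simConfig(n_families = 2, n_offspring = 40, n_groups = 3,
                   markers_per_group = 40, psv_fraction = 0.15,
                   genotype_error_rate = 0.005,
                   mean_depth_offspring = 12, seed = 23)
  st <- simulateStudy(cfg)
  res <- applyFilterCascade(st$genotypes)
  planted <- markerIds(st$genotypes)[markerInfo(st$genotypes)$is_psv]
  psvRemoved <- res$removed$psv_snps
  recall <- mean(planted %in% c(psvRemoved, res$removed$missing_snps))
  expect_gte(recall, 0.95)
  clean <- setdiff(markerIds(st$genotypes), planted)
  expect_lte(length(intersect(psvRemoved, clean)) / length(clean), 0.05)
})

test_that("ledger conservation holds after a full simulated run", {
  cfg <- simConfig(n_families = 2, n_offspring = 20, n_groups = 2,
                   markers_per_group = 20, seed = 24)
  st <- simulateStudy(cfg)
  res <- applyFilterCascade(st$genotypes)
  expect_true(validObject(res$ledger))
  st1 <- ledgerSteps(res$ledger)
  expect_equal(st1$snps_remaining[nrow(st1)], nrow(res$matrix))
  expect_equal(st1$individuals_remaining[nrow(st1)], ncol(res$matrix))
})
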