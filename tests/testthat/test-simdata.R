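test_that("co-located markers are always co-inherited", {
  set.seed(1)
  pos <- c(0, 25, 25, 60)
  for (sex in c("female", "male")) {
    for (i in 1:200) {
      h <- simulateMeiosis(pos, sex, bias = 3, length_cM = 60)$haplotype
      expect_identical(h[2], h[3])
    }
  }
})

test_that("crossover count matches the Poisson expectation at L = 100", {
  set.seed(2)
  n <- 10000
  cx <- replicate(n, length(simulateMeiosis(c(0, 100), "female")$crossovers))
  se <- sqrt(1 / n)   # Poisson(1) variance = 1
  expect_lt(abs(mean(cx) - 1), 3 * se)
})

test_that("male telomere bias concentrates crossovers at group ends", {
  set.seed(3)
  term <- function(bias) {
    cx <- unlist(replicate(4000, simulateMeiosis(c(0, 100), "male",
                                                 bias = bias)$crossovers))
    mean(cx < 20 | cx > 80)
  }
  expect_gt(term(5), term(0))
})

test_that("meiosis input validation", {
  expect_error(simulateMeiosis(numeric(0), "female"), "empty")
  expect_error(simulateMeiosis(c(0, 10), "male", bias = -1), "negative")
  expect_error(simulateMeiosis(c(5, 10), "female"), "start at 0")
})

test_that("noise-free family has no missing genotypes and no Mendelian errors", {
  cfg <- simConfig(n_families = 1, n_offspring = 20, n_groups = 2,
                   markers_per_group = 10, psv_fraction = 0,
                   genotype_error_rate = 0, min_call_depth = 0, seed = 4)
  st <- simulateStudy(cfg)
  expect_false(anyNA(genotypes(st$genotypes)))
  err <- mendelianErrors(st$genotypes)
  expect_equal(sum(err, na.rm = TRUE), 0)
  expect_null(st$truth$errors)
})

test_that("aaXbb markers yield only heterozygous clean offspring", {
  cfg <- simConfig(n_families = 1, n_offspring = 30, n_groups = 1,
                   markers_per_group = 20,
                   seg_type_probs = c(aaXaa = 0, aaXbb = 1, aaXab = 0,
                                      abXaa = 0, abXab = 0),
                   psv_fraction = 0, genotype_error_rate = 0,
                   min_call_depth = 0, n_anchors_per_group = 0, seed = 5)
  st <- simulateStudy(cfg)
  off <- genotypes(st$genotypes)[, offspringColumns(st$genotypes, "fam1")]
  expect_true(all(off == "ab"))
})

test_that("halving offspring depth increases missingness", {
  miss <- function(depth, seed) {
    cfg <- simConfig(n_families = 1, n_offspring = 15, n_groups = 1,
                     markers_per_group = 30, psv_fraction = 0,
                     genotype_error_rate = 0, mean_depth_offspring = depth,
                     seed = seed)
    st <- simulateStudy(cfg)
    off <- genotypes(st$genotypes)[, offspringColumns(st$genotypes, "fam1")]
    mean(is.na(off))
  }
  hi <- vapply(1:20, function(s) miss(10, s), numeric(1))
  lo <- vapply(1:20, function(s) miss(5, 100 + s), numeric(1))
  expect_gt(mean(lo), mean(hi))
})

test_that("PSV markers exceed the heterozygosity threshold detectably", {
  cfg <- simConfig(n_families = 2, n_offspring = 40, n_groups = 2,
                   markers_per_group = 25, psv_fraction = 0.2,
                   genotype_error_rate = 0, min_call_depth = 0, seed = 6)
  st <- simulateStudy(cfg)
  psv <- markerInfo(st$genotypes)$is_psv
  het <- apply(genotypes(st$genotypes)[psv, , drop = FALSE], 1,
               heterozygosityExcess)
  expect_gt(mean(het > 0.70), 0.95)
})

test_that("transmission consistency: clean genotypes are Mendelian-compatible", {
  cfg <- simConfig(n_families = 2, n_offspring = 25, n_groups = 2,
                   markers_per_group = 15, psv_fraction = 0,
                   genotype_error_rate = 0, seed = 7)
  st <- simulateStudy(cfg)
  err <- mendelianErrors(st$genotypes)
  expect_equal(sum(err, na.rm = TRUE), 0)
})

test_that("recombinant fraction recovers the Haldane expectation", {
  set.seed(8)
  d <- 15                       # cM between two adjacent markers
  n <- 6000
  st <- simStates(2, d, n, pos = c(0, d))
  rec <- mean(st[1, ] != st[2, ])
  rexp <- haldaneR(d)
  se <- sqrt(rexp * (1 - rexp) / n)
  expect_lt(abs(rec - rexp), 3 * se)
})

test_that("identical seed and config reproduce identical studies", {
  cfg <- simConfig(n_families = 2, n_offspring = 10, n_groups = 2,
                   markers_per_group = 10, seed = 9)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(genotypes(a$genotypes), genotypes(b$genotypes))
  expect_identical(a$truth$markers, b$truth$markers)
  expect_identical(a$alignments, b$alignments)
})

test_that("alignment tables encode homeologies and synteny design", {
  cfg0 <- simConfig(n_families = 2, n_offspring = 10, n_groups = 4,
                    markers_per_group = 30, homeolog_block_fraction = 0,
                    seed = 10)
  st0 <- simulateStudy(cfg0)
  hits0 <- filterHits(st0$alignments$rad_hits, "rad_locus")
  mg0 <- data.frame(marker_id = markerIds(st0$genotypes),
                    group = markerInfo(st0$genotypes)$true_group)
  hom0 <- detectHomeologies(assignContigs(mg0, hits0))
  expect_equal(hom0$total, 0)
  expect_equal(nrow(hom0$records), 0)

  cfg <- simConfig(n_families = 2, n_offspring = 10, n_groups = 4,
                   markers_per_group = 30, homeolog_block_fraction = 0.5,
                   ambiguous_outgroup_groups = 3L, seed = 11)
  st <- simulateStudy(cfg)
  hits <- filterHits(st$alignments$rad_hits, "rad_locus")
  mg <- data.frame(marker_id = markerIds(st$genotypes),
                   group = markerInfo(st$genotypes)$true_group)
  hom <- detectHomeologies(assignContigs(mg, hits))
  got <- sort(hom$records$groups)
  want <- sort(paste(st$truth$homeologs$group1, st$truth$homeologs$group2,
                     sep = "/"))
  expect_identical(got, want)

  # designated ambiguous group receives an exact two-way tie -> both assigned
  sp <- data.frame(marker_id = markerIds(st$genotypes),
                   parent = "all",
                   group = markerInfo(st$genotypes)$true_group)
  g1 <- filterHits(st$alignments$gene_hits_stage1, "gene")
  counts <- syntenyCounts(sp, g1, st$alignments$gene_annotation)
  syn <- assignSynteny(counts)
  amb <- st$truth$synteny[!is.na(st$truth$synteny$outgroup2), ]
  row <- syn[syn$group == amb$group[1], ]
  expect_identical(row$status, "assigned")
  expect_identical(row$outgroup,
                   paste(sort(c(amb$outgroup1[1], amb$outgroup2[1])),
                         collapse = "/"))
})
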