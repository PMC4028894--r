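test_that("segregation typing follows the sire-first convention", {
  s <- classifySegregation("aa", "ab")
  expect_identical(s$code, "aaXab")
  expect_identical(s$informative, "female")
  s <- classifySegregation("ab", "aa")
  expect_identical(s$code, "abXaa")
  expect_identical(s$informative, "male")
  expect_identical(classifySegregation("aa", "bb")$informative, "none")
  expect_identical(classifySegregation("aa", "bb")$code, "aaXbb")
  expect_identical(classifySegregation("ab", "ab")$informative, "both")
  expect_identical(classifySegregation("aa", "aa")$code, "aaXaa")
  # canonicalisation: hom/het pairs map onto the same codes
  expect_identical(classifySegregation("bb", "ab")$code, "aaXab")
  expect_error(classifySegregation(NA, "ab"), "non-missing")
})

test_that("transmittedState identifies the transmitted parental allele", {
  expect_equal(transmittedState("ab", "aa", "ab"), 1)   # b transmitted
  expect_equal(transmittedState("ab", "aa", "aa"), 0)   # a transmitted
  expect_true(is.na(transmittedState("ab", "aa", NA)))
  expect_true(is.na(transmittedState("ab", "aa", "bb")))  # Mendelian error
  expect_equal(transmittedState("ab", "bb", "ab"), 0)
  expect_equal(transmittedState("ab", "bb", "bb"), 1)
  # other parent heterozygous: only homozygous offspring are informative
  expect_equal(transmittedState("ab", "ab", "aa"), 0)
  expect_equal(transmittedState("ab", "ab", "bb"), 1)
  expect_true(is.na(transmittedState("ab", "ab", "ab")))
  expect_error(transmittedState("aa", "ab", "aa"), "heterozygous")
})

test_that("transmittedStates matrix agrees with the scalar reduction", {
  x <- toyFamily()
  st <- transmittedStates(x, "fam1", "mother")
  expect_identical(rownames(st), "mkA")          # only mkA is mother-het
  expect_equal(unname(st["mkA", ]), c(0, 1, 0, 1))
  st2 <- transmittedStates(x, "fam1", "father")
  expect_identical(rownames(st2), "mkB")
  expect_equal(unname(st2["mkB", ]), c(1, 0, 1, 0))
})

test_that("two-point estimate matches the worked example and handles limits", {
  s1 <- rep(c(0, 1), each = 20)
  s2 <- s1; s2[c(1:4, 21:24)] <- 1 - s2[c(1:4, 21:24)]
  tp <- estimateTwoPoint(s1, s2)
  expect_equal(tp@rHat, 0.2)
  expect_equal(tp@lod, 32 * log10(2 * 0.8) + 8 * log10(2 * 0.2))
  expect_equal(round(tp@lod, 2), 3.35)
  expect_identical(tp@nInformative, 40L)

  half <- s1; half[seq(1, 40, by = 2)] <- 1 - half[seq(1, 40, by = 2)]
  tp2 <- estimateTwoPoint(s1, half)
  expect_equal(tp2@rHat, 0.5)
  expect_equal(tp2@lod, 0)

  # phase symmetry: inverting one vector's labels changes nothing but phase
  tp3 <- estimateTwoPoint(s1, 1 - s2)
  expect_equal(tp3@rHat, tp@rHat)
  expect_equal(tp3@lod, tp@lod)
  expect_identical(sort(c(tp@phase, tp3@phase)), c("coupling", "repulsion"))

  expect_error(estimateTwoPoint(c(NA, NA), c(0, 1)), "overlapping")
})

test_that("closed-form LOD equals the grid-search oracle", {
  set.seed(31)
  for (case in 1:100) {
    N <- sample(10:300, 1)
    R <- sample(0:floor(N / 2), 1)
    s1 <- rep(0, N)
    s2 <- c(rep(1, R), rep(0, N - R))
    lod <- estimateTwoPoint(s1, s2)@lod
    expect_lt(abs(lod - gridLod(N, R)), 1e-6)
  }
})

test_that("r is recovered within binomial error across true values", {
  set.seed(32)
  N <- 200; reps <- 200
  for (r in c(0.05, 0.1, 0.2, 0.35)) {
    err <- replicate(reps, {
      s1 <- sample(0:1, N, replace = TRUE)
      flip <- stats::runif(N) < r
      s2 <- ifelse(flip, 1 - s1, s1)
      abs(estimateTwoPoint(s1, s2)@rHat - r)
    })
    expect_lte(mean(err), 2 * sqrt(r * (1 - r) / N))
  }
})

test_that("pairwiseLod via pooledLodMatrix matches per-pair estimates", {
  set.seed(33)
  st <- simStates(5, 40, 50, miss = 0.15)
  pl <- radlinkmap:::pairwiseLod(st)
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- !is.na(st[i, ]) & !is.na(st[j, ])
    tp <- estimateTwoPoint(st[i, ], st[j, ])
    expect_equal(pl$lod[i, j], tp@lod, tolerance = 1e-12)
    expect_equal(pl$n[i, j], sum(ok))
  }
})

test_that("anchor grouping follows the stepwise LOD schedule", {
  ids <- c("anc1", "anc2", "m_strong", "m_weak", "m_conflict")
  lod <- matrix(0, 5, 5, dimnames = list(ids, ids))
  lod["m_strong", "anc1"] <- lod["anc1", "m_strong"] <- 45
  lod["m_weak", "anc1"] <- lod["anc1", "m_weak"] <- 3.9
  lod["m_conflict", "anc1"] <- lod["anc1", "m_conflict"] <- 12
  lod["m_conflict", "anc2"] <- lod["anc2", "m_conflict"] <- 12
  anchors <- data.frame(marker_id = c("anc1", "anc2"),
                        linkage_group = c("1", "2"))
  asg <- assignLinkageGroups(lod, anchors)
  expect_identical(asg$group[asg$marker_id == "m_strong"], "1")
  expect_identical(asg$status[asg$marker_id == "m_strong"], "assigned")
  expect_identical(asg$status[asg$marker_id == "m_weak"], "unassigned")
  expect_identical(asg$status[asg$marker_id == "m_conflict"], "conflict")
  expect_error(assignLinkageGroups(lod, anchors, numeric(0)), "schedule")
  bad <- anchors; bad$linkage_group[1] <- NA
  expect_error(assignLinkageGroups(lod, bad), "known linkage-group")
})

test_that("lowering the minimum LOD never unassigns a marker", {
  cfg <- simConfig(n_families = 2, n_offspring = 30, n_groups = 3,
                   markers_per_group = 20,
                   seg_type_probs = c(aaXaa = 0, aaXbb = 0, aaXab = 0.35,
                                      abXaa = 0.35, abXab = 0.30),
                   psv_fraction = 0, genotype_error_rate = 0, seed = 34)
  st <- simulateStudy(cfg)
  lod <- pooledLodMatrix(st$genotypes)
  hi <- assignLinkageGroups(lod, st$anchors, lodSchedule = c(40, 20, 10))
  lo <- assignLinkageGroups(lod, st$anchors, lodSchedule = c(40, 20, 10, 6, 4))
  assignedHi <- hi$marker_id[hi$status %in% c("assigned", "anchor")]
  assignedLo <- lo$marker_id[lo$status %in% c("assigned", "anchor")]
  expect_true(all(assignedHi %in% assignedLo))
  # and assignments agree where both made one
  common <- intersect(assignedHi, assignedLo)
  expect_identical(hi$group[match(common, hi$marker_id)],
                   lo$group[match(common, lo$marker_id)])
})

test_that("simulated four-group genome is grouped without cross-assignments", {
  cfg <- simConfig(n_families = 2, n_offspring = 40, n_groups = 4,
                   markers_per_group = 50,
                   group_length_female = 90, group_length_male = 70,
                   seg_type_probs = c(aaXaa = 0, aaXbb = 0, aaXab = 0.35,
                                      abXaa = 0.35, abXab = 0.30),
                   psv_fraction = 0.1, genotype_error_rate = 0.002,
                   mean_depth_offspring = 10, seed = 35)
  st <- simulateStudy(cfg)
  qc <- applyFilterCascade(st$genotypes)
  asg <- assignLinkageGroups(pooledLodMatrix(qc$matrix), st$anchors)
  truthGroup <- markerInfo(qc$matrix)$true_group[match(asg$marker_id,
                                                       markerIds(qc$matrix))]
  ok <- asg$status %in% c("assigned", "anchor")
  expect_gte(mean(ok), 0.95)
  expect_equal(sum(asg$group[ok] != truthGroup[ok]), 0)
})
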