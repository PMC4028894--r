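mkHits <- function(query, target, evalue, bitscore = 100) {
  n <- length(query)
  data.frame(query = query, target = target,
             identity = rep(99, n), length = rep(95, n),
             evalue = rep(evalue, length.out = n),
             bitscore = rep(bitscore, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("hit filtering applies role thresholds and the top-two rule", {
  h <- mkHits(c("r1", "r1"), c("c1", "c2"), c(1e-40, 1e-10))
  out <- filterHits(h, "rad_locus")
  expect_equal(nrow(out), 1L)
  expect_identical(out$target, "c1")

  # query hitting three contigs past threshold is dropped entirely
  h3 <- mkHits(rep("r1", 3), c("c1", "c2", "c3"), rep(1e-40, 3))
  expect_equal(nrow(filterHits(h3, "rad_locus")), 0L)

  # PE role cut at 1e-80
  hp <- mkHits(c("p1", "p2"), c("c1", "c2"), c(1e-90, 1e-60))
  expect_identical(filterHits(hp, "pe_contig")$query, "p1")

  # gene role: best two by E-value, ties by bitscore then target id
  hg <- mkHits(rep("g1", 4), c("t1", "t2", "t3", "t4"),
               c(1e-8, 1e-12, 1e-8, 1e-3), bitscore = c(50, 90, 60, 10))
  out <- filterHits(hg, "gene")
  expect_setequal(out$target, c("t2", "t3"))   # 1e-12, then 1e-8 higher bitscore
  expect_error(filterHits(h, "other"), "arg")
})

test_that("contig assignment collects distinct linkage-group sets", {
  mg <- data.frame(marker_id = c("m1", "m2", "m3", "m4"),
                   group = c("4", "4", "11", NA))
  hits <- mkHits(paste0("RAD_", c("m1", "m2", "m3", "m4")),
                 c("c1", "c2", "c2", "c3"), 1e-50)
  ca <- assignContigs(mg, hits)
  expect_identical(ca$groups[ca$contig == "c1"], "4")
  expect_identical(ca$groups[ca$contig == "c2"], "11/4")
  expect_false("c3" %in% ca$contig)            # unmapped marker contributes nothing
})

test_that("homeology records partition the multi-group contigs", {
  ca <- data.frame(
    contig = sprintf("c%02d", 1:31),
    groups = c(rep("11/4", 25), rep("1/12", 3), rep("4", 2), "13/17/3"),
    n_groups = c(rep(2L, 25), rep(2L, 3), rep(1L, 2), 3L),
    stringsAsFactors = FALSE)
  hom <- detectHomeologies(ca)
  expect_equal(hom$total, 29L)
  expect_equal(sum(hom$records$shared_contigs), hom$total)
  expect_equal(hom$records$shared_contigs[hom$records$groups == "11/4"], 25L)
  expect_equal(hom$records$shared_contigs[hom$records$groups == "1/12"], 3L)
  expect_equal(hom$records$n_groups[hom$records$groups == "13/17/3"], 3L)
  # no multi-group contigs -> empty result
  none <- detectHomeologies(ca[ca$n_groups == 1L, ])
  expect_equal(none$total, 0L)
  expect_equal(nrow(none$records), 0L)
})

test_that("two-stage gene association reproduces the hand-counted fixture", {
  # 10 SNPs on one parent: 2 with stage-1 gene hits, 5 more via genome contigs
  snp <- data.frame(marker_id = sprintf("m%02d", 1:10), parent = "p1",
                    group = "1", stringsAsFactors = FALSE)
  s1 <- mkHits(paste0("RAD_", c("m01", "m02")), c("gA", "gB"), 1e-8)
  contigHits <- mkHits(paste0("RAD_", sprintf("m%02d", 1:10)),
                       c("c1", "c2", rep("c3", 5), "c4", "c5", "c6"), 1e-50)
  ca <- assignContigs(snp[, c("marker_id", "group")], contigHits)
  s2 <- mkHits("c3", "gC", 1e-9)
  res <- geneAssociate(snp, s1, s2, contigHits, ca)
  expect_equal(res$summary$stage1_pct, 20)
  expect_equal(res$summary$stage2_pct, 70)
  expect_true(all(res$perSnp$stage2[res$perSnp$stage1]))  # stage-1 subset
  unhit <- res$perSnp[res$perSnp$marker_id == "m08", ]
  expect_false(unhit$stage1 || unhit$stage2)
})

test_that("stage-2 requires the gene contig to sit on the SNP's own group", {
  snp <- data.frame(marker_id = c("m1", "m2"), parent = "p1",
                    group = c("1", "2"), stringsAsFactors = FALSE)
  contigHits <- mkHits(paste0("RAD_", c("m1", "m2")), c("c1", "c1"), 1e-50)
  ca <- assignContigs(snp[, c("marker_id", "group")], contigHits)
  s2 <- mkHits("c1", "gA", 1e-9)
  empty <- mkHits(character(), character(), numeric())
  res <- geneAssociate(snp, empty, s2, contigHits, ca)
  # c1 carries groups {1,2}: both SNPs stage-2 associated through it
  expect_true(all(res$perSnp$stage2))
  # restrict c1 to group 3: neither SNP's group matches
  ca2 <- ca; ca2$groups <- "3"
  res2 <- geneAssociate(snp, empty, s2, contigHits, ca2)
  expect_false(any(res2$perSnp$stage2))
})

test_that("synteny dominance rule with ties and per-parent consistency", {
  counts <- function(n, parent = "p1", group = "1")
    data.frame(parent = parent, group = group,
               outgroup_group = names(n), n = unname(n),
               stringsAsFactors = FALSE)
  # clear dominance: 10 >= 2 x 4
  syn <- assignSynteny(counts(c(A = 10, B = 4, C = 1)))
  expect_identical(syn$outgroup, "A")
  # 6 < 2 x 4: unassigned
  syn <- assignSynteny(counts(c(A = 6, B = 4)))
  expect_identical(syn$status, "unassigned")
  # exact tie, both at least twice the rest: both assigned
  syn <- assignSynteny(counts(c(A = 5, B = 5, C = 2)))
  expect_identical(syn$outgroup, "A/B")
  # inconsistent parents: assigned in p1, violated in p2 -> unassigned
  two <- rbind(counts(c(A = 10, B = 2)), counts(c(A = 3, B = 4), parent = "p2"))
  expect_identical(assignSynteny(two)$status, "unassigned")
  # parent with zero counts on the group is vacuously consistent
  vac <- rbind(counts(c(A = 10, B = 2)), counts(c(A = 0, B = 0), parent = "p2"))
  expect_identical(assignSynteny(vac)$outgroup, "A")
})

test_that("RAD locus and PE contig from one cut site count once", {
  snp <- data.frame(marker_id = "m1", parent = "p1", group = "1",
                    stringsAsFactors = FALSE)
  hits <- mkHits(c("RAD_m1", "PE_m1"), c("gA", "gA"), 1e-8)
  ann <- data.frame(gene_id = "gA", outgroup_group = "OG1",
                    stringsAsFactors = FALSE)
  cnt <- syntenyCounts(snp, hits, ann)
  expect_equal(cnt$n, 1L)
})
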