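#' Mendelian consistency of one offspring genotype
#'
#' An offspring genotype is a Mendelian error when it is impossible under
#' Mendelian transmission of the two parental genotypes at a biallelic locus;
#' the trio is untestable when any of the three genotypes is missing.
#'
#' @param mother_gt,father_gt,offspring_gt genotypes in
#'   \code{c("aa","ab","bb")} or \code{NA}.
#' @return \code{"ok"}, \code{"error"} or \code{"untestable"}.
#' @examples
#' mendelianCheck("aa", "aa", "ab")  # error
#' mendelianCheck("aa", "bb", "ab")  # ok
#' @export
mendelianCheck <- function(mother_gt, father_gt, offspring_gt) {
  gts <- c(mother_gt, father_gt, offspring_gt)
  if (any(!is.na(gts) & !(gts %in% GT_LEVELS)))
    stop("malformed genotype symbol: ", paste(setdiff(gts, c(GT_LEVELS, NA)), collapse = ", "))
  if (any(is.na(gts))) return("untestable")
  alleles <- list(aa = c("a", "a"), ab = c("a", "b"), bb = c("b", "b"))
  om <- alleles[[mother_gt]]
  of <- alleles[[father_gt]]
  oo <- alleles[[offspring_gt]]
  possible <- unique(apply(expand.grid(om, of, stringsAsFactors = FALSE), 1L,
                           function(z) paste(sort(z), collapse = "")))
  if (paste(sort(oo), collapse = "") %in% possible) "ok" else "error"
}

# vectorised Mendelian-error matrix for one family: TRUE where offspring
# genotype is impossible; NA where untestable
mendelianErrorMatrix <- function(g, motherCol, fatherCol, offCols) {
  mo <- g[, motherCol]
  fa <- g[, fatherCol]
  off <- g[, offCols, drop = FALSE]
  # impossible offspring alleles: an allele absent from a parent cannot come
  # from that parent; enumerate by parental-pair pattern
  err <- matrix(NA, nrow(off), ncol(off), dimnames = dimnames(off))
  testable <- !is.na(mo) & !is.na(fa)
  has <- function(p, a) !is.na(p) & (p == "ab" | p == paste0(a, a))
  # offspring allele pair (x, y): genotype possible iff one parent can give x
  # and the other can give y (either assignment)
  for (gt in GT_LEVELS) {
    a1 <- substr(gt, 1, 1); a2 <- substr(gt, 2, 2)
    ok <- (has(mo, a1) & has(fa, a2)) | (has(mo, a2) & has(fa, a1))
    w <- off == gt
    w[is.na(w)] <- FALSE
    err[w] <- rep(!ok & testable, ncol(off))[w]
  }
  err[is.na(off)] <- NA
  err[!testable, ] <- NA
  err
}

#' Heterozygosity of one SNP across individuals
#'
#' Proportion of heterozygous calls among non-missing genotypes; SNPs
#' exceeding the paralog threshold (0.70 by default in the cascade) are
#' treated as putative paralogous sequence variants (PSVs).
#'
#' @param genotypes character vector of genotypes for one SNP.
#' @return proportion in [0, 1].
#' @examples
#' heterozygosityExcess(c(rep("ab", 71), rep("aa", 29)))  # 0.71
#' @export
heterozygosityExcess <- function(genotypes) {
  called <- genotypes[!is.na(genotypes)]
  if (!length(called)) stop("all genotypes missing for this SNP")
  mean(called == "ab")
}

#' Start a filter ledger
#'
#' @param initialSnps,initialIndividuals counts before filtering.
#' @return an empty [FilterLedger-class].
#' @export
filterLedger <- function(initialSnps, initialIndividuals) {
  new("FilterLedger",
      steps = data.frame(step = character(), snps_eliminated = integer(),
                         snps_remaining = integer(),
                         individuals_eliminated = integer(),
                         individuals_remaining = integer(),
                         stringsAsFactors = FALSE),
      initialSnps = as.integer(initialSnps),
      initialIndividuals = as.integer(initialIndividuals))
}

#' Append a step to a filter ledger
#'
#' Remaining counts are derived from the previous step's remaining counts
#' minus the eliminations; the class validity re-checks the conservation
#' identity.
#'
#' @param ledger a [FilterLedger-class].
#' @param step step name.
#' @param snpsEliminated,individualsEliminated counts removed at this step.
#' @return the extended [FilterLedger-class].
#' @export
addLedgerStep <- function(ledger, step, snpsEliminated = 0L,
                          individualsEliminated = 0L) {
  st <- ledger@steps
  prev_s <- if (nrow(st)) st$snps_remaining[nrow(st)] else ledger@initialSnps
  prev_i <- if (nrow(st)) st$individuals_remaining[nrow(st)] else ledger@initialIndividuals
  st <- rbind(st, data.frame(step = step,
                             snps_eliminated = as.integer(snpsEliminated),
                             snps_remaining = as.integer(prev_s - snpsEliminated),
                             individuals_eliminated = as.integer(individualsEliminated),
                             individuals_remaining = as.integer(prev_i - individualsEliminated),
                             stringsAsFactors = FALSE))
  new("FilterLedger", steps = st, initialSnps = ledger@initialSnps,
      initialIndividuals = ledger@initialIndividuals)
}

#' SNP and individual quality-control cascade
#'
#' Applies, in order: (1) removal of SNPs missing in more than
#' \code{snpMissingness} of individuals; (2) removal of individuals genotyped
#' at fewer than \code{individualCallRate} of the SNPs; (3) removal of SNPs
#' with heterozygosity above \code{hetThreshold} across all retained
#' individuals of all families jointly, as putative PSVs; (4) removal of SNPs
#' with \code{snpMendelMax} or more Mendelian errors (counted per family and
#' summed) and masking of the offending genotype for SNPs with exactly one
#' error; (5) removal of individuals with more than \code{indMendelMax}
#' Mendelian errors.  Before any step, SNPs lacking a call in both parents of
#' a family are set to missing for that family's individuals.
#'
#' @param x a [GenotypeMatrix-class] with designated parents per family.
#' @param snpMissingness maximum tolerated missing proportion per SNP
#'   (default 0.5).
#' @param individualCallRate minimum call-rate proportion per individual
#'   (default 0.25).
#' @param hetThreshold PSV heterozygosity threshold (default 0.70, exceeded
#'   strictly).
#' @param snpMendelMax Mendelian-error count at which a SNP is discarded
#'   (default 2).
#' @param indMendelMax Mendelian-error count above which an individual is
#'   removed (default 200).
#' @return list with \code{matrix} (the filtered [GenotypeMatrix-class]),
#'   \code{ledger} (a [FilterLedger-class]) and \code{removed} (marker /
#'   individual ids eliminated at each step).
#' @export
applyFilterCascade <- function(x, snpMissingness = 0.5,
                               individualCallRate = 0.25,
                               hetThreshold = 0.70,
                               snpMendelMax = 2L,
                               indMendelMax = 200L) {
  stopifnot(snpMissingness >= 0, snpMissingness <= 1,
            individualCallRate >= 0, individualCallRate <= 1,
            hetThreshold >= 0, hetThreshold <= 1)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty genotype matrix")

  # parental-call rule: a SNP without a call in both parents of a family is
  # treated as missing for that family throughout
  g <- genotypes(x)
  for (fam in families(x)) {
    mc <- parentColumn(x, fam, "mother")
    fc <- parentColumn(x, fam, "father")
    if (is.na(mc) || is.na(fc)) next
    famCols <- which(individuals(x)$family == fam)
    nocall <- is.na(g[, mc]) | is.na(g[, fc])
    g[nocall, famCols] <- NA_character_
  }
  x <- genotypeMatrix(g, individuals(x), markerInfo(x), readDepth(x))

  ledger <- filterLedger(nrow(x), ncol(x))
  removed <- list()

  # (1) SNP missingness
  missProp <- rowMeans(is.na(genotypes(x)))
  dropSnp <- missProp > snpMissingness
  removed$missing_snps <- markerIds(x)[dropSnp]
  x <- x[!dropSnp, ]
  ledger <- addLedgerStep(ledger, "missing_genotypes_snps", sum(dropSnp), 0L)

  # (2) individual call rate
  callRate <- colMeans(!is.na(genotypes(x)))
  dropInd <- callRate < individualCallRate & individuals(x)$role == "offspring"
  removed$lowcall_individuals <- individuals(x)$id[dropInd]
  x <- x[, !dropInd]
  ledger <- addLedgerStep(ledger, "missing_genotypes_individuals", 0L, sum(dropInd))

  # (3) excess heterozygosity (putative PSVs), computed jointly over families
  het <- rowMeans(genotypes(x) == "ab", na.rm = TRUE)
  het[rowSums(!is.na(genotypes(x))) == 0L] <- 0
  dropPsv <- het > hetThreshold
  removed$psv_snps <- markerIds(x)[dropPsv]
  x <- x[!dropPsv, ]
  ledger <- addLedgerStep(ledger, "excess_heterozygosity_psvs", sum(dropPsv), 0L)

  # (4) Mendelian errors per SNP: discard at >= snpMendelMax, mask singletons
  err <- mendelianErrors(x)
  perSnp <- rowSums(err, na.rm = TRUE)
  dropMend <- perSnp >= snpMendelMax
  maskSnp <- which(!dropMend & perSnp == 1L)
  if (length(maskSnp)) {
    g <- genotypes(x)
    hit <- which(err == TRUE, arr.ind = TRUE)
    hit <- hit[hit[, 1L] %in% maskSnp, , drop = FALSE]
    if (nrow(hit)) {
      colG <- match(colnames(err)[hit[, 2L]], individuals(x)$id)
      g[cbind(hit[, 1L], colG)] <- NA_character_
    }
    x <- genotypeMatrix(g, individuals(x), markerInfo(x), readDepth(x))
  }
  removed$mendelian_snps <- markerIds(x)[dropMend]
  x <- x[!dropMend, ]
  ledger <- addLedgerStep(ledger, "mendelian_errors_snps", sum(dropMend), 0L)

  # (5) Mendelian errors per individual (offspring)
  err <- mendelianErrors(x)
  perOff <- colSums(err, na.rm = TRUE)
  dropOff <- rep(FALSE, ncol(x))
  offCols <- match(colnames(err), individuals(x)$id)
  dropOff[offCols[perOff > indMendelMax]] <- TRUE
  removed$mendelian_individuals <- individuals(x)$id[dropOff]
  x <- x[, !dropOff]
  ledger <- addLedgerStep(ledger, "mendelian_errors_individuals", 0L, sum(dropOff))

  list(matrix = x, ledger = ledger, removed = removed)
}

#' Mendelian-error matrix across all families
#'
#' @param x a [GenotypeMatrix-class].
#' @return logical matrix (markers x all offspring of all families): TRUE at
#'   Mendelian-inconsistent genotypes, NA where untestable.
#' @export
mendelianErrors <- function(x) {
  g <- genotypes(x)
  cols <- list()
  for (fam in families(x)) {
    mc <- parentColumn(x, fam, "mother")
    fc <- parentColumn(x, fam, "father")
    oc <- offspringColumns(x, fam)
    if (is.na(mc) || is.na(fc) || !length(oc)) next
    cols[[fam]] <- mendelianErrorMatrix(g, mc, fc, oc)
  }
  if (!length(cols)) return(matrix(NA, nrow(g), 0))
  do.call(cbind, cols)
}
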