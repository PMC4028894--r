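#' Classify the segregation type of a marker in one family
#'
#' The segregation code is written sire-first: \code{aaXab} means the sire is
#' homozygous and the dam heterozygous, i.e. a female-segregating marker;
#' \code{abXaa} is male-segregating; \code{abXab} segregates in both parents;
#' \code{aaXaa} and \code{aaXbb} yield no informative meioses.  Allele labels
#' are canonicalised per marker, so e.g. (bb, ab) also classifies as
#' \code{aaXab}.
#'
#' @param sire_gt,dam_gt parental genotypes in \code{c("aa","ab","bb")}; must
#'   be non-missing.
#' @return list with \code{code} (one of aaXaa, aaXbb, aaXab, abXaa, abXab)
#'   and \code{informative} (\code{"female"}, \code{"male"}, \code{"both"} or
#'   \code{"none"}).
#' @examples
#' classifySegregation("aa", "ab")  # female-segregating
#' classifySegregation("ab", "aa")  # male-segregating
#' @export
classifySegregation <- function(sire_gt, dam_gt) {
  if (is.na(sire_gt) || is.na(dam_gt))
    stop("parental genotypes must be non-missing to classify segregation")
  stopifnot(sire_gt %in% GT_LEVELS, dam_gt %in% GT_LEVELS)
  s_het <- sire_gt == "ab"
  d_het <- dam_gt == "ab"
  if (s_het && d_het)  return(list(code = "abXab", informative = "both"))
  if (s_het && !d_het) return(list(code = "abXaa", informative = "male"))
  if (!s_het && d_het) return(list(code = "aaXab", informative = "female"))
  if (sire_gt == dam_gt) list(code = "aaXaa", informative = "none")
  else                   list(code = "aaXbb", informative = "none")
}

#' Transmitted-allele state of one offspring at a parent-informative marker
#'
#' Reduces an offspring genotype at a marker heterozygous in the focal parent
#' to which of the focal parent's alleles was transmitted: 0 for allele a,
#' 1 for allele b, \code{NA} when the offspring genotype is missing,
#' uninformative, or Mendelian-inconsistent.  When the other parent is
#' homozygous its known contribution is subtracted; when the other parent is
#' also heterozygous (\code{abXab}), only homozygous offspring reveal the
#' transmitted allele and heterozygotes are recorded as missing.
#'
#' @param parent_gt focal parent genotype; must be \code{"ab"}.
#' @param other_gt other parent's genotype (\code{"aa"}, \code{"bb"} or
#'   \code{"ab"}).
#' @param offspring_gt offspring genotype or \code{NA}.
#' @return 0, 1 or \code{NA}.
#' @export
transmittedState <- function(parent_gt, other_gt, offspring_gt) {
  if (is.na(parent_gt) || parent_gt != "ab")
    stop("transmittedState requires the focal parent to be heterozygous (ab)")
  if (is.na(offspring_gt)) return(NA_real_)
  if (other_gt == "aa") {
    switch(offspring_gt, aa = 0, ab = 1, bb = NA_real_)
  } else if (other_gt == "bb") {
    switch(offspring_gt, bb = 1, ab = 0, aa = NA_real_)
  } else {
    switch(offspring_gt, aa = 0, bb = 1, ab = NA_real_)
  }
}

#' Transmitted-state matrix for one parent of one family
#'
#' Applies [transmittedState()] across all markers heterozygous in the focal
#' parent, for all offspring of the family.  Rows for markers where the focal
#' parent is homozygous or uncalled are dropped.
#'
#' @param x a [GenotypeMatrix-class].
#' @param family family identifier.
#' @param parentRole \code{"mother"} or \code{"father"}.
#' @param sexSpecificOnly if TRUE, keep only markers where the other parent is
#'   homozygous (the sex-specific segregating markers used for map building).
#' @return numeric matrix (informative markers x offspring) of 0/1/NA, with
#'   marker-id rownames; NULL when the parent is absent.
#' @export
transmittedStates <- function(x, family, parentRole = c("mother", "father"),
                              sexSpecificOnly = FALSE) {
  parentRole <- match.arg(parentRole)
  pc <- parentColumn(x, family, parentRole)
  oc <- parentColumn(x, family, setdiff(c("mother", "father"), parentRole))
  off <- offspringColumns(x, family)
  if (is.na(pc) || is.na(oc)) return(NULL)
  g <- genotypes(x)
  focal <- g[, pc]
  other <- g[, oc]
  keep <- !is.na(focal) & focal == "ab" & !is.na(other)
  if (sexSpecificOnly) keep <- keep & other != "ab"
  keep <- which(keep)
  og <- g[keep, off, drop = FALSE]
  oth <- other[keep]
  # vectorised transmittedState over the whole block
  homA <- oth == "aa"; homB <- oth == "bb"; het <- oth == "ab"
  st <- matrix(NA_real_, nrow = length(keep), ncol = length(off),
               dimnames = list(markerIds(x)[keep], individuals(x)$id[off]))
  o_aa <- og == "aa"; o_ab <- og == "ab"; o_bb <- og == "bb"
  st[homA & o_aa] <- 0; st[homA & o_ab] <- 1
  st[homB & o_bb] <- 1; st[homB & o_ab] <- 0
  st[het  & o_aa] <- 0; st[het  & o_bb] <- 1
  st
}

#' Two-point recombination fraction and LOD for one marker pair
#'
#' With N meioses scored at both markers and R state mismatches under the
#' better phase (R is the smaller of the mismatch and match counts), the
#' maximum-likelihood recombination fraction is r = R/N and the LOD is
#' (N - R) log10(2(1 - r)) + R log10(2r), with the r = 0 limit N log10 2.
#' LOD is the log10 likelihood ratio of linkage at r versus r = 0.5 and is
#' invariant to relabelling either marker's states (phase symmetry).
#'
#' @param states1,states2 transmitted-state vectors (0/1/NA) for the two
#'   markers over the same offspring.
#' @return a [TwoPointResult-class].
#' @examples
#' s1 <- rep(c(0, 1), each = 20)
#' s2 <- s1; s2[c(1:4, 21:24)] <- 1 - s2[c(1:4, 21:24)]
#' estimateTwoPoint(s1, s2)  # r = 0.2
#' @export
estimateTwoPoint <- function(states1, states2) {
  ok <- !is.na(states1) & !is.na(states2)
  n <- sum(ok)
  if (n < 1L) stop("no overlapping informative meioses for this pair")
  mism <- sum(states1[ok] != states2[ok])
  phase <- if (mism <= n - mism) "coupling" else "repulsion"
  R <- min(mism, n - mism)
  r <- R / n
  lod <- if (R == 0) n * log10(2)
         else (n - R) * log10(2 * (1 - r)) + R * log10(2 * r)
  new("TwoPointResult", rHat = r, lod = max(lod, 0), phase = phase,
      nInformative = as.integer(n))
}

# Pairwise LOD matrix for one state matrix (markers x meioses), vectorised.
# Returns list(lod, n): symmetric matrices.
pairwiseLod <- function(states) {
  A <- (!is.na(states)) & states == 0
  B <- (!is.na(states)) & states == 1
  storage.mode(A) <- "numeric"; storage.mode(B) <- "numeric"
  O <- A + B
  N <- O %*% t(O)
  M <- A %*% t(B) + B %*% t(A)
  R <- pmin(M, N - M)
  r <- ifelse(N > 0, R / N, 0.5)
  lod <- matrix(0, nrow(N), ncol(N), dimnames = dimnames(N))
  pos <- N > 0
  lod[pos] <- ifelse(R[pos] == 0, N[pos] * log10(2),
                     (N[pos] - R[pos]) * log10(2 * (1 - r[pos])) +
                       R[pos] * log10(pmax(2 * r[pos], 1e-300)))
  lod[lod < 0] <- 0
  diag(lod) <- 0
  list(lod = lod, n = N)
}

#' Pooled two-point LOD matrix across all informative parents
#'
#' For every pair of markers, two-point LOD scores are computed within each
#' parent in which both markers are informative (using that family's
#' offspring) and summed across parents: meioses from different parents are
#' independent, so their log likelihood ratios add.
#'
#' @param x a [GenotypeMatrix-class] (typically QC-filtered).
#' @return symmetric numeric matrix of summed LODs over all markers of
#'   \code{x} (markers informative nowhere get all-zero rows).
#' @export
pooledLodMatrix <- function(x) {
  m <- nrow(x)
  ids <- markerIds(x)
  total <- matrix(0, m, m, dimnames = list(ids, ids))
  for (fam in families(x)) {
    for (role in c("mother", "father")) {
      st <- transmittedStates(x, fam, role)
      if (is.null(st) || nrow(st) < 2L) next
      pl <- pairwiseLod(st)
      idx <- match(rownames(st), ids)
      total[idx, idx] <- total[idx, idx] + pl$lod
    }
  }
  total
}

#' Assign markers to linkage groups from anchors and two-point LODs
#'
#' Groups are seeded by anchor markers with known linkage-group labels.  For
#' each threshold of a descending LOD schedule, unassigned markers join a
#' group when their maximum two-point LOD to any current member reaches the
#' threshold for exactly one group; markers exceeding the threshold for two
#' or more groups are flagged conflicting and skipped at that level.  Joining
#' repeats to closure at each level before the threshold is lowered.
#'
#' @param lod symmetric marker x marker LOD matrix (e.g. from
#'   [pooledLodMatrix()]).
#' @param anchors data.frame with columns \code{marker_id},
#'   \code{linkage_group}; every group must be seeded by at least one anchor.
#' @param lodSchedule descending LOD thresholds (default \code{c(40, 20, 10,
#'   6, 4)}).
#' @return data.frame with columns \code{marker_id}, \code{group} (NA when
#'   unassigned), \code{max_lod}, \code{status} (\code{assigned},
#'   \code{anchor}, \code{unassigned} or \code{conflict}).
#' @export
assignLinkageGroups <- function(lod, anchors,
                                lodSchedule = c(40, 20, 10, 6, 4)) {
  if (!length(lodSchedule)) stop("LOD schedule must not be empty")
  if (any(is.na(anchors$linkage_group)))
    stop("anchor markers must carry a known linkage-group label")
  ids <- rownames(lod)
  anchors <- anchors[anchors$marker_id %in% ids, , drop = FALSE]
  grp <- stats::setNames(rep(NA_character_, length(ids)), ids)
  grp[anchors$marker_id] <- as.character(anchors$linkage_group)
  status <- stats::setNames(rep("unassigned", length(ids)), ids)
  status[anchors$marker_id] <- "anchor"
  maxlod <- stats::setNames(rep(0, length(ids)), ids)
  groups <- sort(unique(as.character(anchors$linkage_group)))

  for (thr in sort(lodSchedule, decreasing = TRUE)) {
    repeat {
      un <- which(is.na(grp))
      if (!length(un)) break
      memb <- lapply(groups, function(g) which(grp == g))
      # best LOD of each unassigned marker to each group
      gl <- vapply(memb, function(mi)
        if (length(mi)) apply(lod[un, mi, drop = FALSE], 1L, max) else
          rep(0, length(un)), numeric(length(un)))
      gl <- matrix(gl, nrow = length(un))
      hits <- gl >= thr
      nh <- rowSums(hits)
      maxlod[un] <- pmax(maxlod[un], apply(gl, 1L, max))
      conflict <- nh >= 2L
      status[un[conflict]] <- "conflict"
      joiners <- which(nh == 1L)
      if (!length(joiners)) break
      for (j in joiners) {
        g <- groups[which(hits[j, ])]
        grp[un[j]] <- g
        status[un[j]] <- "assigned"
      }
    }
  }
  data.frame(marker_id = ids, group = unname(grp),
             max_lod = unname(maxlod), status = unname(status),
             stringsAsFactors = FALSE)
}
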