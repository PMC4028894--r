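#' Filter BLAST-style alignment hits by query role
#'
#' Applies the role-specific E-value cut: 1e-30 for RAD loci against genome
#' contigs, 1e-80 for PE contigs against genome contigs, 1e-5 for contigs
#' against outgroup genes.  For the gene role only the two most significant
#' hits per query are kept (E-value ascending, then bitscore descending, then
#' target id).  For the genome-contig roles, queries aligning to more than
#' two genome contigs past the threshold are excluded entirely.
#'
#' @param hits data.frame with columns query, target, identity, length,
#'   evalue, bitscore.
#' @param role one of \code{"rad_locus"}, \code{"pe_contig"}, \code{"gene"}.
#' @param evalue optional override of the role's E-value threshold.
#' @return the filtered hit data.frame.
#' @export
filterHits <- function(hits, role = c("rad_locus", "pe_contig", "gene"),
                       evalue = NULL) {
  role <- match.arg(role)
  thr <- if (!is.null(evalue)) evalue
         else switch(role, rad_locus = 1e-30, pe_contig = 1e-80, gene = 1e-5)
  h <- hits[hits$evalue <= thr, , drop = FALSE]
  if (!nrow(h)) return(h)
  if (role == "gene") {
    o <- order(h$query, h$evalue, -h$bitscore, h$target)
    h <- h[o, , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(h)), h$query), function(i)
      i[seq_len(min(2L, length(i)))]), use.names = FALSE)
    h <- h[sort(keep), , drop = FALSE]
  } else {
    nt <- vapply(split(h$target, h$query), function(t) length(unique(t)),
                 integer(1))
    drop <- names(nt)[nt > 2L]
    h <- h[!(h$query %in% drop), , drop = FALSE]
  }
  rownames(h) <- NULL
  h
}

#' Assign reference genome contigs to linkage groups
#'
#' Each genome contig is labelled with the set of distinct linkage groups of
#' the mapped markers whose flanking contigs align to it (hits should already
#' have passed [filterHits()]).
#'
#' @param markerGroups data.frame with columns \code{marker_id},
#'   \code{group}; only rows with non-NA group are used.
#' @param hits filtered hit table whose query is \code{"RAD_<marker_id>"} (or
#'   the marker id itself) and whose target is a genome contig.
#' @return data.frame with columns \code{contig}, \code{groups}
#'   (slash-collapsed sorted group set), \code{n_groups}.
#' @export
assignContigs <- function(markerGroups, hits) {
  mg <- markerGroups[!is.na(markerGroups$group), , drop = FALSE]
  q <- sub("^RAD_", "", hits$query)
  grp <- mg$group[match(q, mg$marker_id)]
  ok <- !is.na(grp)
  if (!any(ok))
    return(data.frame(contig = character(), groups = character(),
                      n_groups = integer(), stringsAsFactors = FALSE))
  sets <- lapply(split(grp[ok], hits$target[ok]),
                 function(g) sort(unique(as.character(g))))
  data.frame(contig = names(sets),
             groups = vapply(sets, paste, character(1), collapse = "/"),
             n_groups = lengths(sets),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect homeologous linkage-group pairs from shared contigs
#'
#' Genome contigs assigned to two or more linkage groups mark residual
#' similarity between chromosome arms descended from the salmonid
#' whole-genome duplication.  One record is produced per distinct group set
#' of size >= 2, with the number of contigs assigned to exactly that set.
#'
#' @param contigAssignments output of [assignContigs()].
#' @return list with \code{records} (data.frame groups, n_groups,
#'   shared_contigs, contig ids collapsed with commas) and \code{total}
#'   (number of multi-group contigs).
#' @export
detectHomeologies <- function(contigAssignments) {
  multi <- contigAssignments[contigAssignments$n_groups >= 2L, , drop = FALSE]
  if (!nrow(multi))
    return(list(records = data.frame(groups = character(), n_groups = integer(),
                                     shared_contigs = integer(),
                                     contigs = character(),
                                     stringsAsFactors = FALSE),
                total = 0L))
  sp <- split(multi$contig, multi$groups)
  rec <- data.frame(groups = names(sp),
                    n_groups = vapply(names(sp), function(g)
                      length(strsplit(g, "/")[[1L]]), integer(1)),
                    shared_contigs = lengths(sp),
                    contigs = vapply(sp, paste, character(1), collapse = ","),
                    stringsAsFactors = FALSE, row.names = NULL)
  rec <- rec[order(-rec$shared_contigs, rec$groups), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, total = nrow(multi))
}

#' Two-stage gene association of mapped SNPs
#'
#' A mapped SNP is stage-1 gene-associated when its own flanking RAD/PE
#' contig aligns to an outgroup gene; it is stage-2 associated when it is
#' stage-1 associated or when a genome contig that (i) its flanking contig
#' aligns to and (ii) is assigned to the SNP's own linkage group, aligns to a
#' gene.  Per-parent counts and percentages are reported for both stages.
#'
#' @param snpParents data.frame with columns \code{marker_id}, \code{parent},
#'   \code{group}: the SNPs ordered on each parent's maps.
#' @param stage1Hits filtered RAD-contig -> gene hits (query
#'   \code{"RAD_<marker_id>"} or marker id).
#' @param stage2Hits filtered genome-contig -> gene hits.
#' @param contigHits filtered RAD-contig -> genome-contig hits.
#' @param contigAssignments output of [assignContigs()].
#' @return list with \code{perSnp} (marker_id, parent, stage1, stage2) and
#'   \code{summary} (per-parent mapped counts, stage counts and percentages).
#' @export
geneAssociate <- function(snpParents, stage1Hits, stage2Hits, contigHits,
                          contigAssignments) {
  s1q <- unique(sub("^RAD_", "", stage1Hits$query))
  geneContigs <- unique(stage2Hits$query)
  q <- sub("^RAD_", "", contigHits$query)

  # genome contigs linked to each marker, restricted to contigs assigned to
  # the marker's own linkage group
  ca <- contigAssignments
  markerContigs <- split(contigHits$target, q)

  stage1 <- snpParents$marker_id %in% s1q
  stage2 <- stage1
  for (i in which(!stage1)) {
    mc <- markerContigs[[snpParents$marker_id[i]]]
    if (is.null(mc)) next
    sets <- ca$groups[match(mc, ca$contig)]
    onGroup <- mc[!is.na(sets) &
                    vapply(strsplit(ifelse(is.na(sets), "", sets), "/"),
                           function(s) snpParents$group[i] %in% s, logical(1))]
    stage2[i] <- any(onGroup %in% geneContigs)
  }
  perSnp <- data.frame(marker_id = snpParents$marker_id,
                       parent = snpParents$parent,
                       stage1 = stage1, stage2 = stage2,
                       stringsAsFactors = FALSE)
  sm <- do.call(rbind, lapply(split(perSnp, perSnp$parent), function(d)
    data.frame(parent = d$parent[1L], mapped = nrow(d),
               stage1 = sum(d$stage1),
               stage1_pct = round(100 * mean(d$stage1), 1),
               stage2 = sum(d$stage2),
               stage2_pct = round(100 * mean(d$stage2), 1),
               stringsAsFactors = FALSE)))
  rownames(sm) <- NULL
  list(perSnp = perSnp, summary = sm)
}

#' Assign salmon linkage groups to outgroup linkage groups (synteny)
#'
#' For each salmon linkage group and mapping parent, gene-associated RAD loci
#' are counted per outgroup linkage group (a RAD locus and its PE contig
#' count once).  An outgroup group is assigned when its count is at least
#' twice that of every other outgroup group, in every parent with at least
#' one gene-associated locus on that salmon group.  When two outgroup groups
#' tie at the top and each has at least twice the count of every remaining
#' group, both are assigned.  Otherwise the salmon group is left unassigned.
#'
#' @param geneCounts data.frame with columns \code{parent}, \code{group}
#'   (salmon linkage group), \code{outgroup_group}, \code{n} (deduplicated
#'   RAD-locus count).
#' @param factor dominance factor (default 2: "twice or more").
#' @return data.frame with columns \code{group}, \code{outgroup}
#'   (slash-collapsed assignment or NA), \code{status} (\code{assigned} /
#'   \code{unassigned}).
#' @export
assignSynteny <- function(geneCounts, factor = 2) {
  candidate <- function(counts) {
    # counts: named vector over outgroup groups for one parent/salmon group
    counts <- sort(counts, decreasing = TRUE)
    if (!length(counts) || counts[1L] == 0) return(NULL)
    top <- counts[1L]
    tied <- names(counts)[counts == top]
    rest <- counts[counts < top]
    if (length(tied) == 1L) {
      if (!length(rest) || top >= factor * max(rest)) return(tied)
      return(NULL)
    }
    if (length(tied) == 2L &&
        (!length(rest) || top >= factor * max(rest))) return(sort(tied))
    NULL
  }
  out <- lapply(split(geneCounts, geneCounts$group), function(d) {
    cands <- lapply(split(d, d$parent), function(p) {
      v <- tapply(p$n, p$outgroup_group, sum)
      if (sum(v) == 0) return(NA)       # vacuous parent
      candidate(v)
    })
    cands <- cands[!vapply(cands, function(x) identical(x, NA), logical(1))]
    ok <- length(cands) > 0L && !any(vapply(cands, is.null, logical(1))) &&
      all(vapply(cands, function(x) identical(x, cands[[1L]]), logical(1)))
    data.frame(group = d$group[1L],
               outgroup = if (ok) paste(cands[[1L]], collapse = "/") else NA_character_,
               status = if (ok) "assigned" else "unassigned",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deduplicated per-parent gene-hit counts for synteny assignment
#'
#' Collapses RAD locus and PE contig queries from the same restriction site
#' to a single locus (queries are matched to markers by stripping the
#' \code{RAD_}/\code{PE_} prefix), joins genes to their outgroup linkage
#' groups, and counts loci per parent, salmon group and outgroup group.
#'
#' @param snpParents data.frame marker_id, parent, group (SNPs on each
#'   parent's map).
#' @param geneHits filtered contig -> gene hits.
#' @param geneAnnotation data.frame gene_id, outgroup_group.
#' @return data.frame parent, group, outgroup_group, n suitable for
#'   [assignSynteny()].
#' @export
syntenyCounts <- function(snpParents, geneHits, geneAnnotation) {
  locus <- sub("^(RAD|PE)_", "", geneHits$query)
  og <- geneAnnotation$outgroup_group[match(geneHits$target,
                                            geneAnnotation$gene_id)]
  lh <- unique(data.frame(locus = locus, outgroup_group = og,
                          stringsAsFactors = FALSE))
  mrg <- merge(snpParents, lh, by.x = "marker_id", by.y = "locus")
  if (!nrow(mrg))
    return(data.frame(parent = character(), group = character(),
                      outgroup_group = character(), n = integer(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(n = rep(1L, nrow(mrg))),
                          by = list(parent = mrg$parent, group = mrg$group,
                                    outgroup_group = mrg$outgroup_group),
                          FUN = sum)
  agg[order(agg$group, agg$parent, agg$outgroup_group), , drop = FALSE]
}
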