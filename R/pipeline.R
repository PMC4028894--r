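#' Pipeline configuration with study-standard defaults
#'
#' Collects every threshold of the analysis with its standard value: SNP
#' missingness 0.5 and individual call rate 0.25; PSV heterozygosity 0.70;
#' Mendelian limits of 2 errors per SNP and 200 per individual; the stepwise
#' LOD grouping schedule from 40 down to 4; ordering parameters nInit 5 and
#' THRES 4; ripple window 7 at LOD 4; terminal trimming at 30 cM (male) /
#' 20 cM (female); 5 cM marker-clustering intervals with a minimum of five;
#' alignment E-value cuts 1e-30 (RAD loci), 1e-80 (PE contigs), 1e-5 (genes);
#' and the 2x synteny dominance factor.
#'
#' @param sim a [simConfig()] describing the synthetic study to generate.
#' @param snpMissingness,individualCallRate,hetThreshold,snpMendelMax,indMendelMax
#'   QC thresholds, see [applyFilterCascade()].
#' @param lodSchedule descending LOD thresholds for [assignLinkageGroups()].
#' @param nInit,thres ordering parameters for [orderMarkers()].
#' @param rippleWindow,rippleLod ripple parameters; \code{rippleWindow = 0}
#'   disables the ripple pass.
#' @param trimMale,trimFemale terminal-gap trimming thresholds in cM.
#' @param intervalWidth,minIntervals marker-clustering interval parameters.
#' @param evalueRad,evaluePe,evalueGene alignment E-value thresholds.
#' @param syntenyFactor dominance factor for [assignSynteny()].
#' @param seed master seed for [runPipeline()].
#' @return a validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(sim = simConfig(),
                           snpMissingness = 0.5, individualCallRate = 0.25,
                           hetThreshold = 0.70, snpMendelMax = 2L,
                           indMendelMax = 200L,
                           lodSchedule = c(40, 20, 10, 6, 4),
                           nInit = 5L, thres = 4,
                           rippleWindow = 0L, rippleLod = 4,
                           trimMale = 30, trimFemale = 20,
                           intervalWidth = 5, minIntervals = 5L,
                           evalueRad = 1e-30, evaluePe = 1e-80,
                           evalueGene = 1e-5, syntenyFactor = 2,
                           seed = 1L) {
  cfg <- list(sim = sim, snpMissingness = snpMissingness,
              individualCallRate = individualCallRate,
              hetThreshold = hetThreshold,
              snpMendelMax = as.integer(snpMendelMax),
              indMendelMax = as.integer(indMendelMax),
              lodSchedule = lodSchedule, nInit = as.integer(nInit),
              thres = thres, rippleWindow = as.integer(rippleWindow),
              rippleLod = rippleLod, trimMale = trimMale,
              trimFemale = trimFemale, intervalWidth = intervalWidth,
              minIntervals = as.integer(minIntervals),
              evalueRad = evalueRad, evaluePe = evaluePe,
              evalueGene = evalueGene, syntenyFactor = syntenyFactor,
              seed = as.integer(seed))
  stopifnot(inherits(sim, "SimConfig"),
            cfg$snpMissingness >= 0, cfg$snpMissingness <= 1,
            cfg$individualCallRate >= 0, cfg$individualCallRate <= 1,
            cfg$hetThreshold >= 0, cfg$hetThreshold <= 1,
            length(cfg$lodSchedule) >= 1L, all(diff(cfg$lodSchedule) < 0),
            cfg$nInit >= 2L, cfg$intervalWidth > 0, cfg$minIntervals >= 1L,
            cfg$evalueRad > 0, cfg$evaluePe > 0, cfg$evalueGene > 0,
            cfg$syntenyFactor >= 1)
  structure(cfg, class = "PipelineConfig")
}

pipeLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Build all parental maps from a filtered matrix and group assignments
#'
#' For every family, parent and linkage group, collects the parent's
#' sex-specific segregating markers assigned to that group, orders them,
#' builds the Haldane map and trims spurious terminal markers.
#'
#' @param x filtered [GenotypeMatrix-class].
#' @param assignments data.frame from [assignLinkageGroups()].
#' @param config a [pipelineConfig()].
#' @return list of [ParentalMap-class] objects.
#' @export
buildAllMaps <- function(x, assignments, config = pipelineConfig()) {
  maps <- list()
  assigned <- assignments[assignments$status %in% c("assigned", "anchor") &
                            !is.na(assignments$group), , drop = FALSE]
  for (fam in families(x)) {
    for (role in c("mother", "father")) {
      st <- transmittedStates(x, fam, role, sexSpecificOnly = TRUE)
      if (is.null(st)) next
      sex <- if (role == "mother") "female" else "male"
      for (grp in sort(unique(assigned$group))) {
        mk <- intersect(rownames(st),
                        assigned$marker_id[assigned$group == grp])
        if (length(mk) < 2L) next
        map <- buildParentalMap(st[mk, , drop = FALSE],
                                parent = paste(fam, role, sep = "_"),
                                sex = sex, group = grp,
                                nInit = config$nInit, thres = config$thres,
                                rippleWindow = config$rippleWindow,
                                rippleLod = config$rippleLod)
        map <- trimTerminal(map, config$trimMale, config$trimFemale)
        maps[[paste(fam, role, grp, sep = ".")]] <- map
      }
    }
  }
  maps
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes, in order: simulate, QC, linkage grouping, per-parent ordering,
#' sex-difference comparison and comparative genomics, writing every stage's
#' outputs under \code{outDir} together with a JSON run manifest.  The same
#' configuration (including seed) reproduces byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param stages subset of stages to run (later stages require the in-memory
#'   results of earlier ones, so a prefix of the default vector).
#' @return invisible list with all stage results.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("radmap"),
                        stages = c("simulate", "qc", "group", "order",
                                   "sexdiff", "compgen")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config), "sim")],
                   sim = unclass(config$sim), stages = list())

  config$sim$seed <- config$seed
  pipeLog("simulate", "families=%d offspring=%d groups=%d markers/group=%d",
          config$sim$n_families, config$sim$n_offspring, config$sim$n_groups,
          config$sim$markers_per_group)
  sim <- simulateStudy(config$sim)
  res$sim <- sim
  writeGenotypes(sim$genotypes, file.path(outDir, "genotypes.tsv"))
  writeAnchors(sim$anchors, file.path(outDir, "anchors.tsv"))
  writeHits(sim$alignments$rad_hits, file.path(outDir, "rad_hits.tsv"))
  manifest$stages$simulate <- list(markers = nrow(sim$genotypes),
                                   individuals = ncol(sim$genotypes))
  if (!"qc" %in% stages) return(finishRun(res, manifest, outDir))

  qc <- applyFilterCascade(sim$genotypes,
                           snpMissingness = config$snpMissingness,
                           individualCallRate = config$individualCallRate,
                           hetThreshold = config$hetThreshold,
                           snpMendelMax = config$snpMendelMax,
                           indMendelMax = config$indMendelMax)
  res$qc <- qc
  writeLedger(qc$ledger, file.path(outDir, "filter_ledger"))
  writeGenotypes(qc$matrix, file.path(outDir, "genotypes_filtered.tsv"))
  pipeLog("qc", "%d -> %d SNPs, %d -> %d individuals",
          nrow(sim$genotypes), nrow(qc$matrix),
          ncol(sim$genotypes), ncol(qc$matrix))
  manifest$stages$qc <- list(snps_remaining = nrow(qc$matrix),
                             individuals_remaining = ncol(qc$matrix))
  if (!"group" %in% stages) return(finishRun(res, manifest, outDir))

  lod <- pooledLodMatrix(qc$matrix)
  assignments <- assignLinkageGroups(lod, sim$anchors, config$lodSchedule)
  res$assignments <- assignments
  utils::write.table(assignments, file.path(outDir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pipeLog("group", "%d/%d markers assigned (%d conflicts)",
          sum(assignments$status %in% c("assigned", "anchor")),
          nrow(assignments), sum(assignments$status == "conflict"))
  manifest$stages$group <-
    list(assigned = sum(assignments$status %in% c("assigned", "anchor")))
  if (!"order" %in% stages) return(finishRun(res, manifest, outDir))

  maps <- buildAllMaps(qc$matrix, assignments, config)
  res$maps <- maps
  writeMaps(maps, file.path(outDir, "maps.tsv"))
  writeMapChart(maps, file.path(outDir, "maps_mapchart.txt"))
  pipeLog("order", "%d parental maps built", length(maps))
  manifest$stages$order <- list(maps = length(maps))
  if (!"sexdiff" %in% stages) return(finishRun(res, manifest, outDir))

  profiles <- list()
  for (fam in families(qc$matrix)) {
    for (grp in unique(vapply(maps, function(m) m@group, character(1)))) {
      fm <- maps[[paste(fam, "mother", grp, sep = ".")]]
      mm <- maps[[paste(fam, "father", grp, sep = ".")]]
      if (is.null(fm) || is.null(mm)) next
      if (!length(fm@markers) || !length(mm@markers)) next
      if (mapLength(fm) <= 0 || mapLength(mm) <= 0) next
      pr <- clusteringProfile(fm, mm, config$intervalWidth, config$minIntervals)
      profiles <- c(profiles, pr)
    }
  }
  res$profiles <- profiles
  res$ratioTable <- mapRatioTable(maps)
  res$topIntervals <- if (length(profiles)) topIntervalAverage(profiles) else NULL
  if (length(profiles))
    writeProfiles(profiles, file.path(outDir, "interval_profiles.tsv"))
  if (!is.null(res$ratioTable))
    utils::write.table(res$ratioTable, file.path(outDir, "map_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  pipeLog("sexdiff", "%d interval profiles", length(profiles))
  manifest$stages$sexdiff <- list(profiles = length(profiles))
  if (!"compgen" %in% stages) return(finishRun(res, manifest, outDir))

  hits <- filterHits(sim$alignments$rad_hits, "rad_locus",
                     evalue = config$evalueRad)
  markerGroups <- assignments[, c("marker_id", "group")]
  contigs <- assignContigs(markerGroups, hits)
  hom <- detectHomeologies(contigs)
  snpParents <- mappedMarkerTable(qc$matrix, assignments)
  g1 <- filterHits(sim$alignments$gene_hits_stage1, "gene",
                   evalue = config$evalueGene)
  g2 <- filterHits(sim$alignments$gene_hits_stage2, "gene",
                   evalue = config$evalueGene)
  genes <- geneAssociate(snpParents, g1, g2, hits, contigs)
  counts <- syntenyCounts(snpParents, g1, sim$alignments$gene_annotation)
  synteny <- assignSynteny(counts, factor = config$syntenyFactor)
  res$compgen <- list(contigs = contigs, homeologies = hom, genes = genes,
                      synteny = synteny)
  utils::write.table(contigs, file.path(outDir, "contig_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hom$records[, c("groups", "n_groups", "shared_contigs")],
                     file.path(outDir, "homeologies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genes$summary, file.path(outDir, "gene_association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(synteny, file.path(outDir, "synteny.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pipeLog("compgen", "%d contigs assigned, %d homeologous sets, %d synteny assignments",
          nrow(contigs), nrow(hom$records),
          sum(synteny$status == "assigned"))
  manifest$stages$compgen <- list(contigs = nrow(contigs),
                                  homeologies = nrow(hom$records))
  finishRun(res, manifest, outDir)
}

#' Per-parent table of assigned, parent-informative markers
#'
#' The comparative-genomics stages count a marker for a mapping parent when
#' it is assigned to a linkage group and heterozygous in that parent (both
#' the sex-specific markers ordered on the parent's map and the markers
#' segregating in both parents).
#'
#' @param x filtered [GenotypeMatrix-class].
#' @param assignments data.frame from [assignLinkageGroups()].
#' @return data.frame with columns marker_id, parent, group.
#' @export
mappedMarkerTable <- function(x, assignments) {
  asg <- assignments[assignments$status %in% c("assigned", "anchor") &
                       !is.na(assignments$group), , drop = FALSE]
  g <- genotypes(x)
  rows <- list()
  for (fam in families(x)) {
    for (role in c("mother", "father")) {
      pc <- parentColumn(x, fam, role)
      if (is.na(pc)) next
      het <- rownames(g)[!is.na(g[, pc]) & g[, pc] == "ab"]
      mk <- intersect(het, asg$marker_id)
      if (!length(mk)) next
      rows[[paste(fam, role)]] <- data.frame(
        marker_id = mk, parent = paste(fam, role, sep = "_"),
        group = asg$group[match(mk, asg$marker_id)],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

finishRun <- function(res, manifest, outDir) {
  manifest$outputs <- sort(setdiff(list.files(outDir), "manifest.json"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$outDir <- outDir
  invisible(res)
}
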