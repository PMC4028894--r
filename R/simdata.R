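#' Configuration for the synthetic full-sib RAD-Seq study generator
#'
#' Defaults emulate the structure of the Atlantic salmon SalMap SbfI RAD-Seq
#' mapping study: two full-sib families of 46 offspring, 29 linkage groups
#' with roughly 8,000 markers in total, female maps near 97 cM and male maps
#' near 75 cM per group on average, telomere-biased male crossover placement,
#' coverage-gated genotype calls, paralog (PSV) contamination and a low
#' Mendelian genotyping-error rate.
#'
#' @param n_families number of full-sib families.
#' @param n_offspring offspring per family (>= 2).
#' @param n_groups number of linkage groups.
#' @param markers_per_group SNP markers per linkage group.
#' @param group_length_female,group_length_male linkage-group lengths in cM on
#'   the female and male recombination scales.
#' @param male_telomere_bias concentration (>= 0) of the male crossover
#'   density toward the group ends; 0 gives uniform placement as in females.
#' @param seg_type_probs named probability vector over the segregation types
#'   \code{aaXaa, aaXbb, aaXab, abXaa, abXab} (sire genotype first); must sum
#'   to 1.
#' @param mean_depth_parent,mean_depth_offspring mean read depths; parents are
#'   sequenced much deeper than offspring, as in the study design.
#' @param min_call_depth reads below which a genotype is a no-call.
#' @param psv_fraction proportion of markers that are collapsed paralogs
#'   emitting spurious heterozygous calls.
#' @param genotype_error_rate per-genotype probability of a random wrong call.
#' @param n_anchors_per_group markers per group flagged as anchors of known
#'   linkage group (forced to segregate in all parents, as the study's
#'   multi-allelic anchor markers effectively do).
#' @param homeolog_block_fraction proportion of a group's genome contigs that
#'   also receive alignment hits from its homeologous partner group.
#' @param n_outgroup_groups number of outgroup (stickleback-like) linkage
#'   groups carrying the annotated genes.
#' @param ambiguous_outgroup_groups indices of salmon linkage groups whose
#'   gene hits are split as an exact tie between two outgroup groups.
#' @param depth_spread_sdlog log-scale standard deviation of the
#'   per-individual mean depth (reproduces the spread of call rates with
#'   coverage).
#' @param psv_het_rate probability that a PSV marker emits a heterozygous
#'   call irrespective of transmission; must exceed the 0.70 filter threshold
#'   detectably.
#' @param seed integer seed used by [simulateStudy()].
#' @return a validated \code{SimConfig} list.
#' @export
simConfig <- function(n_families = 2L, n_offspring = 46L, n_groups = 29L,
                      markers_per_group = 275L,
                      group_length_female = 97, group_length_male = 75,
                      male_telomere_bias = 5,
                      seg_type_probs = c(aaXaa = 0.30, aaXbb = 0.06,
                                         aaXab = 0.21, abXaa = 0.23,
                                         abXab = 0.20),
                      mean_depth_parent = 30, mean_depth_offspring = 8,
                      min_call_depth = 6,
                      psv_fraction = 0.17, genotype_error_rate = 0.005,
                      n_anchors_per_group = 4L,
                      homeolog_block_fraction = 0.10,
                      n_outgroup_groups = 21L,
                      ambiguous_outgroup_groups = integer(0),
                      depth_spread_sdlog = 0.5,
                      psv_het_rate = 0.85,
                      seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              n_offspring = as.integer(n_offspring),
              n_groups = as.integer(n_groups),
              markers_per_group = as.integer(markers_per_group),
              group_length_female = group_length_female,
              group_length_male = group_length_male,
              male_telomere_bias = male_telomere_bias,
              seg_type_probs = seg_type_probs,
              mean_depth_parent = mean_depth_parent,
              mean_depth_offspring = mean_depth_offspring,
              min_call_depth = min_call_depth,
              psv_fraction = psv_fraction,
              genotype_error_rate = genotype_error_rate,
              n_anchors_per_group = as.integer(n_anchors_per_group),
              homeolog_block_fraction = homeolog_block_fraction,
              n_outgroup_groups = as.integer(n_outgroup_groups),
              ambiguous_outgroup_groups = as.integer(ambiguous_outgroup_groups),
              depth_spread_sdlog = depth_spread_sdlog,
              psv_het_rate = psv_het_rate,
              seed = as.integer(seed))
  props <- c(cfg$psv_fraction, cfg$genotype_error_rate,
             cfg$homeolog_block_fraction, cfg$psv_het_rate)
  stopifnot(all(props >= 0), all(props <= 1),
            abs(sum(cfg$seg_type_probs) - 1) < 1e-9,
            identical(names(cfg$seg_type_probs), SEG_TYPES),
            cfg$group_length_female > 0, cfg$group_length_male > 0,
            cfg$n_offspring >= 2L, cfg$male_telomere_bias >= 0,
            cfg$n_families >= 1L, cfg$n_groups >= 1L,
             cfg$markers_per_group >= 2L)
  structure(cfg, class = "SimConfig")
}

#' Simulate one meiosis across a linkage group
#'
#' Crossover counts follow a Poisson law with mean L/100 (Haldane model, no
#' interference).  Female crossovers are placed uniformly on [0, L]; male
#' crossovers are drawn from the symmetric U-shaped mixture
#' 0.5 Beta(1, 1 + bias) + 0.5 Beta(1 + bias, 1) scaled to [0, L], whose mass
#' in the terminal regions of the group grows with \code{bias} and which
#' reduces to the uniform density at \code{bias = 0}.  The transmitted
#' haplotype switches at each crossover.
#'
#' @param positions sorted marker positions in cM, starting at 0.
#' @param sex \code{"female"} or \code{"male"}.
#' @param bias telomere-bias concentration (>= 0); ignored for females.
#' @param length_cM length of the group (defaults to the last position).
#' @return list with \code{haplotype} (1/2 per marker: which parental
#'   haplotype was transmitted) and \code{crossovers} (positions in cM).
#' @export
simulateMeiosis <- function(positions, sex = c("female", "male"), bias = 0,
                            length_cM = max(positions)) {
  sex <- match.arg(sex)
  if (!length(positions)) stop("empty marker position list")
  if (bias < 0) stop("negative telomere bias")
  if (is.unsorted(positions) || positions[1] != 0)
    stop("positions must be sorted ascending and start at 0")
  L <- length_cM
  ncx <- stats::rpois(1L, L / 100)
  cx <- if (ncx == 0L) numeric(0)
        else if (sex == "female" || bias == 0) stats::runif(ncx, 0, L)
        else {
          left <- stats::runif(ncx) < 0.5
          u <- numeric(ncx)
          u[left]  <- stats::rbeta(sum(left), 1, 1 + bias)
          u[!left] <- stats::rbeta(sum(!left), 1 + bias, 1)
          u * L
        }
  start <- sample.int(2L, 1L)
  nswitch <- vapply(positions, function(p) sum(cx < p), numeric(1))
  list(haplotype = 1L + (start - 1L + nswitch) %% 2L,
       crossovers = sort(cx))
}

# ---- study-level truth -------------------------------------------------------

#' Generate the ground truth of a synthetic study
#'
#' Draws marker positions, per-family segregation types, parental phases,
#' PSV marker identities, anchor designations, genome-contig membership and
#' homeolog pairings.  Consumes the current RNG stream; [simulateStudy()]
#' seeds it from the configuration.
#'
#' @param config a [simConfig()] object.
#' @return a \code{SimTruth} list; see Details in the package vignette.
#' @export
simulateTruth <- function(config) {
  G <- config$n_groups; m <- config$markers_per_group
  fams <- paste0("fam", seq_len(config$n_families))
  markers <- list(); groups <- list()
  for (g in seq_len(G)) {
    pos <- sort(stats::runif(m, 0, config$group_length_female))
    pos <- pos - pos[1]
    ids <- sprintf("LG%02d_M%03d", g, seq_len(m))
    contig <- sprintf("GC%02d_%03d", g, ceiling(seq_len(m) / 3))
    anchor_idx <- unique(round(seq(1, m, length.out = config$n_anchors_per_group)))
    markers[[g]] <- data.frame(
      marker_id = ids, true_group = as.character(g),
      pos_female = pos,
      pos_male = pos * (config$group_length_male / config$group_length_female),
      contig = contig,
      is_anchor = seq_len(m) %in% anchor_idx,
      stringsAsFactors = FALSE)
  }
  markers <- do.call(rbind, markers)
  nM <- nrow(markers)
  markers$is_psv <- stats::runif(nM) < config$psv_fraction

  # segregation types per family (sire-first codes); anchors segregate in all
  # parents so that every group is seeded by informative markers
  seg <- matrix(sample(SEG_TYPES, nM * config$n_families, replace = TRUE,
                       prob = config$seg_type_probs),
                nrow = nM, dimnames = list(markers$marker_id, fams))
  seg[markers$is_anchor, ] <- "abXab"

  # parental phases: for each family/parent/marker, the allele carried by
  # haplotype 1 ("a" or "b"); only meaningful where the parent is ab
  phase <- list()
  for (fam in fams) {
    phase[[fam]] <- list(
      father = sample(c("a", "b"), nM, replace = TRUE),
      mother = sample(c("a", "b"), nM, replace = TRUE))
  }

  # homeolog pairing: consecutive groups paired; leftover group unpaired
  npair <- G %/% 2L
  homeologs <- if (npair)
    data.frame(group1 = as.character(2 * seq_len(npair) - 1L),
               group2 = as.character(2 * seq_len(npair)),
               stringsAsFactors = FALSE)
  else data.frame(group1 = character(), group2 = character())

  # dominant outgroup group per salmon group (exact tie for designated groups)
  og <- paste0("OG", ((seq_len(G) - 1L) %% config$n_outgroup_groups) + 1L)
  og2 <- paste0("OG", (seq_len(G) %% config$n_outgroup_groups) + 1L)
  synteny <- data.frame(group = as.character(seq_len(G)),
                        outgroup1 = og,
                        outgroup2 = ifelse(seq_len(G) %in%
                                             config$ambiguous_outgroup_groups,
                                           og2, NA_character_),
                        stringsAsFactors = FALSE)

  list(markers = markers, families = fams, seg_types = seg, phase = phase,
       homeologs = homeologs, synteny = synteny,
       crossovers = list(), errors = NULL)
}

segToParentGts <- function(code) {
  c(father = substr(code, 1, 2), mother = substr(code, 4, 5))
}

#' Simulate one family's genotypes
#'
#' Parental genotypes follow the family's segregation types; offspring
#' genotypes follow Mendelian transmission through [simulateMeiosis()].  PSV
#' markers overwrite calls with heterozygotes at the configured rate,
#' genotyping errors replace calls at \code{genotype_error_rate}, and every
#' genotype whose simulated read depth (Poisson around a log-normally drawn
#' per-individual mean) falls below \code{min_call_depth} is masked to
#' missing.
#'
#' @param config a [simConfig()].
#' @param truth a [simulateTruth()] result.
#' @param family family index (1-based).
#' @return list with \code{genotypes} (a [GenotypeMatrix-class] for this
#'   family), \code{crossovers} (per offspring/parent/group crossover
#'   positions) and \code{errors} (coordinates of injected genotype errors).
#' @export
simulateFamily <- function(config, truth, family = 1L) {
  fam <- truth$families[family]
  mk <- truth$markers
  nM <- nrow(mk); nOff <- config$n_offspring
  ids <- c(paste0(fam, "_mother"), paste0(fam, "_father"),
           sprintf("%s_off%02d", fam, seq_len(nOff)))
  ind <- data.frame(id = ids, family = fam,
                    role = c("mother", "father", rep("offspring", nOff)),
                    stringsAsFactors = FALSE)
  g <- matrix(NA_character_, nM, length(ids), dimnames = list(mk$marker_id, ids))

  seg <- truth$seg_types[, fam]
  pg <- t(vapply(seg, segToParentGts, character(2)))
  g[, 1L] <- pg[, "mother"]
  g[, 2L] <- pg[, "father"]

  # haplotype pair per parent: haplotype 1 carries the phase allele where the
  # parent is heterozygous, both haplotypes the same allele where homozygous
  hapAllele <- function(role, hap) {
    gt <- pg[, role]
    ph <- truth$phase[[fam]][[role]]
    ifelse(gt == "ab",
           ifelse(hap == 1L, ph, ifelse(ph == "a", "b", "a")),
           substr(gt, 1, 1))
  }
  hap1 <- list(mother = hapAllele("mother", 1L), father = hapAllele("father", 1L))
  hap2 <- list(mother = hapAllele("mother", 2L), father = hapAllele("father", 2L))

  crossovers <- list()
  byGroup <- split(seq_len(nM), mk$true_group)
  for (o in seq_len(nOff)) {
    offId <- ids[2L + o]
    alle <- matrix(NA_character_, nM, 2L)
    for (parent in c("mother", "father")) {
      sex <- if (parent == "mother") "female" else "male"
      pcol <- if (parent == "mother") 1L else 2L
      for (grp in names(byGroup)) {
        idx <- byGroup[[grp]]
        pos <- if (sex == "female") mk$pos_female[idx] else mk$pos_male[idx]
        L <- if (sex == "female") config$group_length_female else config$group_length_male
        mei <- simulateMeiosis(pos, sex,
                               bias = if (sex == "male") config$male_telomere_bias else 0,
                               length_cM = L)
        crossovers[[paste(offId, parent, grp, sep = ".")]] <- mei$crossovers
        alle[idx, pcol] <- ifelse(mei$haplotype == 1L, hap1[[parent]][idx],
                                  hap2[[parent]][idx])
      }
    }
    g[, 2L + o] <- paste0(pmin(alle[, 1L], alle[, 2L]),
                          pmax(alle[, 1L], alle[, 2L]))
  }

  # PSV contamination: collapsed paralogs emit ab irrespective of transmission
  psv <- which(mk$is_psv)
  if (length(psv)) {
    hit <- matrix(stats::runif(length(psv) * length(ids)) < config$psv_het_rate,
                  length(psv), length(ids))
    sub <- g[psv, , drop = FALSE]
    sub[hit] <- "ab"
    g[psv, ] <- sub
  }

  # genotyping errors
  errors <- NULL
  if (config$genotype_error_rate > 0) {
    flip <- which(matrix(stats::runif(length(g)) < config$genotype_error_rate,
                         nrow(g)))
    if (length(flip)) {
      old <- g[flip]
      g[flip] <- vapply(old, function(x) sample(setdiff(GT_LEVELS, x), 1L), character(1))
      errors <- data.frame(marker_id = mk$marker_id[(flip - 1L) %% nM + 1L],
                           individual = ids[(flip - 1L) %/% nM + 1L],
                           stringsAsFactors = FALSE)
    }
  }

  # coverage-gated calls: per-individual mean depth log-normal around the
  # configured mean, per-genotype depth Poisson
  meanDepth <- c(rep(config$mean_depth_parent, 2L),
                 rep(config$mean_depth_offspring, nOff))
  lambda <- exp(stats::rnorm(length(ids), log(meanDepth), config$depth_spread_sdlog))
  depth <- matrix(stats::rpois(nM * length(ids), rep(lambda, each = nM)),
                  nM, length(ids), dimnames = dimnames(g))
  g[depth < config$min_call_depth] <- NA_character_

  list(genotypes = genotypeMatrix(g, ind, mk, depth),
       crossovers = crossovers, errors = errors)
}

#' Combine per-family matrices into one study matrix
#' @noRd
combineFamilies <- function(fams) {
  g <- do.call(cbind, lapply(fams, function(f) genotypes(f$genotypes)))
  d <- do.call(cbind, lapply(fams, function(f) readDepth(f$genotypes)))
  ind <- do.call(rbind, lapply(fams, function(f) individuals(f$genotypes)))
  genotypeMatrix(g, ind, markerInfo(fams[[1L]]$genotypes), d)
}

#' Simulate a complete synthetic study
#'
#' Seeds the RNG from \code{config$seed}, generates the ground truth, the
#' genotype matrix for every family, the anchor table and the alignment-hit
#' tables.  Identical configuration (including seed) reproduces identical
#' output.
#'
#' @param config a [simConfig()].
#' @return list with \code{genotypes} (combined [GenotypeMatrix-class]),
#'   \code{truth} (ground-truth record including crossovers, injected errors,
#'   homeolog pairs and synteny design), \code{anchors} (data.frame
#'   marker_id, linkage_group) and \code{alignments} (see
#'   [simulateAlignmentTables()]).
#' @export
simulateStudy <- function(config) {
  set.seed(config$seed)
  truth <- simulateTruth(config)
  fams <- lapply(seq_len(config$n_families), function(i)
    simulateFamily(config, truth, i))
  truth$crossovers <- do.call(c, lapply(fams, `[[`, "crossovers"))
  truth$errors <- do.call(rbind, lapply(fams, `[[`, "errors"))
  anchors <- with(truth$markers[truth$markers$is_anchor, ],
                  data.frame(marker_id = marker_id, linkage_group = true_group,
                             stringsAsFactors = FALSE))
  aln <- simulateAlignmentTables(truth, config)
  list(genotypes = combineFamilies(fams), truth = truth,
       anchors = anchors, alignments = aln)
}

#' Simulate BLAST-style alignment-hit tables
#'
#' Emits (i) hits of each marker's flanking RAD contig against its true
#' genome contig, with additional cross-group hits for a configured fraction
#' of contigs in each homeologous pair; (ii) stage-1 hits of RAD contigs
#' against outgroup genes; (iii) stage-2 hits of genome contigs against the
#' same genes; and (iv) the gene annotation table (gene id, outgroup linkage
#' group).  Gene hits are carried by the markers segregating in all parents,
#' allocated so that each salmon group's dominant outgroup group receives at
#' least twice the hits of any other, except for designated ambiguous groups
#' which receive an exact two-way tie.
#'
#' @param truth a [simulateTruth()] result.
#' @param config the matching [simConfig()].
#' @return list of data.frames \code{rad_hits}, \code{gene_hits_stage1},
#'   \code{gene_hits_stage2}, \code{gene_annotation}; hit tables have the
#'   6-column BLAST-tabular shape (query, target, identity, length, evalue,
#'   bitscore).
#' @export
simulateAlignmentTables <- function(truth, config) {
  mk <- truth$markers
  hit <- function(q, t, e, len = 95) {
    if (!length(q)) return(data.frame(query = character(), target = character(),
                                      identity = numeric(), length = numeric(),
                                      evalue = numeric(), bitscore = numeric(),
                                      stringsAsFactors = FALSE))
    data.frame(query = q, target = t, identity = 99.0, length = len,
               evalue = e, bitscore = round(2 * len - log10(pmax(e, 1e-180))),
               stringsAsFactors = FALSE)
  }
  rad <- hit(paste0("RAD_", mk$marker_id), mk$contig, 1e-60)

  # homeologous blocks: a fraction of each pair's contigs also collect hits
  # from markers of the partner group (both directions of the pair)
  extra <- list()
  if (nrow(truth$homeologs) && config$homeolog_block_fraction > 0) {
    for (k in seq_len(nrow(truth$homeologs))) {
      g1 <- truth$homeologs$group1[k]; g2 <- truth$homeologs$group2[k]
      c1 <- unique(mk$contig[mk$true_group == g1])
      nh <- round(config$homeolog_block_fraction * length(c1))
      if (nh < 1L) next
      shared <- c1[seq_len(nh)]
      donors <- mk$marker_id[mk$true_group == g2][seq_len(nh)]
      extra[[k]] <- hit(paste0("RAD_", donors), shared, 1e-45)
    }
  }
  rad <- rbind(rad, do.call(rbind, extra))

  # gene placement on the markers segregating in every parent
  allParent <- apply(truth$seg_types == "abXab", 1L, all)
  gene_rows <- list(); ann_rows <- list(); s2 <- list()
  geneN <- 0L
  for (g in unique(mk$true_group)) {
    idx <- which(mk$true_group == g & allParent)
    if (length(idx) < 3L) next
    syn <- truth$synteny[truth$synteny$group == g, ]
    others <- setdiff(paste0("OG", seq_len(config$n_outgroup_groups)),
                      c(syn$outgroup1, syn$outgroup2))
    if (is.na(syn$outgroup2)) {
      nDom <- max(2L, ceiling(0.7 * length(idx)))
      nDom <- min(nDom, length(idx))
      nOther <- min(length(idx) - nDom, floor(nDom / 2) * min(2L, length(others)))
      ogs <- c(rep(syn$outgroup1, nDom),
               rep(others[seq_len(min(2L, length(others)))],
                   length.out = nOther))
    } else {
      # exact tie between outgroup1 and outgroup2, any third group at most
      # half of the tied count
      t2 <- max(2L, floor(length(idx) * 0.4))
      t2 <- min(t2, floor(length(idx) / 2))
      nOther <- min(length(idx) - 2L * t2, floor(t2 / 2))
      ogs <- c(rep(c(syn$outgroup1, syn$outgroup2), each = t2),
               rep(others[1L], length.out = max(nOther, 0L)))
    }
    use <- idx[seq_along(ogs)]
    genes <- sprintf("gene_%05d", geneN + seq_along(ogs))
    geneN <- geneN + length(ogs)
    gene_rows[[g]] <- hit(paste0("RAD_", mk$marker_id[use]), genes, 1e-8)
    s2[[g]] <- hit(mk$contig[use], genes, 1e-8, len = 400)
    ann_rows[[g]] <- data.frame(gene_id = genes, outgroup_group = ogs,
                                stringsAsFactors = FALSE)
  }
  list(rad_hits = rad,
       gene_hits_stage1 = do.call(rbind, gene_rows),
       gene_hits_stage2 = unique(do.call(rbind, s2)),
       gene_annotation = do.call(rbind, ann_rows))
}
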