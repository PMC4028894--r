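#' @import methods
NULL

GT_LEVELS <- c("aa", "ab", "bb")

SEG_TYPES <- c("aaXaa", "aaXbb", "aaXab", "abXaa", "abXab")

#' Per-family biallelic genotype container
#'
#' A \code{GenotypeMatrix} holds unphased biallelic genotypes (\code{"aa"},
#' \code{"ab"}, \code{"bb"} or \code{NA}) for the parents and offspring of one
#' or more two-parent full-sib families, one row per SNP marker and one column
#' per individual, together with per-individual pedigree metadata and an
#' optional read-depth matrix of the same shape.
#'
#' @slot genotypes character matrix, markers x individuals; entries in
#'   \code{c("aa","ab","bb")} or \code{NA} for no-calls.
#' @slot individuals data.frame with columns \code{id}, \code{family} and
#'   \code{role} (\code{"mother"}, \code{"father"} or \code{"offspring"}), one
#'   row per column of \code{genotypes}.
#' @slot markers data.frame of per-marker annotation (at least column
#'   \code{marker_id}), one row per row of \code{genotypes}.
#' @slot depth numeric matrix of simulated or observed read depths, either
#'   0 x 0 or the same dimension as \code{genotypes}.
#'
#' @seealso [genotypeMatrix()], [simulateStudy()], [applyFilterCascade()]
#' @export
setClass("GenotypeMatrix",
  representation(
    genotypes   = "matrix",
    individuals = "data.frame",
    markers     = "data.frame",
    depth       = "matrix"
  )
)

setValidity("GenotypeMatrix", function(object) {
  g <- object@genotypes
  msg <- character()
  if (!is.character(g))
    msg <- c(msg, "genotypes must be a character matrix")
  bad <- !is.na(g) & !(g %in% GT_LEVELS)
  if (any(bad))
    msg <- c(msg, sprintf("invalid genotype symbol(s): %s",
                          paste(unique(g[bad])[seq_len(min(3, sum(bad)))], collapse = ", ")))
  if (nrow(object@individuals) != ncol(g))
    msg <- c(msg, "individuals table must have one row per genotype column")
  if (!all(c("id", "family", "role") %in% names(object@individuals)))
    msg <- c(msg, "individuals table needs columns id, family, role")
  else {
    if (!all(object@individuals$role %in% c("mother", "father", "offspring")))
      msg <- c(msg, "individual roles must be mother/father/offspring")
    for (fam in unique(object@individuals$family)) {
      rl <- object@individuals$role[object@individuals$family == fam]
      if (sum(rl == "mother") > 1L || sum(rl == "father") > 1L)
        msg <- c(msg, sprintf("family %s has more than one mother or father", fam))
    }
  }
  if (nrow(object@markers) != nrow(g))
    msg <- c(msg, "markers table must have one row per genotype row")
  if (!("marker_id" %in% names(object@markers)))
    msg <- c(msg, "markers table needs a marker_id column")
  if (length(object@depth) && !identical(dim(object@depth), dim(g)))
    msg <- c(msg, "depth matrix must match genotype dimensions")
  if (length(msg)) msg else TRUE
})

#' Ordered record of a SNP/individual filtering procedure
#'
#' Mirrors the usual published filtering table: one row per step with the
#' number of SNPs and individuals eliminated at that step and remaining after
#' it.  Validity enforces the book-keeping identity
#' remaining(k) = remaining(k-1) - eliminated(k), separately for SNPs and
#' individuals.
#'
#' @slot steps data.frame with columns \code{step}, \code{snps_eliminated},
#'   \code{snps_remaining}, \code{individuals_eliminated},
#'   \code{individuals_remaining}.
#' @slot initialSnps,initialIndividuals counts before any filtering.
#'
#' @seealso [filterLedger()], [addLedgerStep()], [applyFilterCascade()]
#' @export
setClass("FilterLedger",
  representation(
    steps              = "data.frame",
    initialSnps        = "integer",
    initialIndividuals = "integer"
  )
)

setValidity("FilterLedger", function(object) {
  st <- object@steps
  need <- c("step", "snps_eliminated", "snps_remaining",
            "individuals_eliminated", "individuals_remaining")
  if (!all(need %in% names(st)))
    return(paste("steps must have columns", paste(need, collapse = ", ")))
  prev_s <- object@initialSnps
  prev_i <- object@initialIndividuals
  for (k in seq_len(nrow(st))) {
    if (st$snps_eliminated[k] < 0 || st$individuals_eliminated[k] < 0)
      return("eliminated counts must be non-negative")
    if (st$snps_remaining[k] != prev_s - st$snps_eliminated[k])
      return(sprintf("SNP conservation violated at step '%s'", st$step[k]))
    if (st$individuals_remaining[k] != prev_i - st$individuals_eliminated[k])
      return(sprintf("individual conservation violated at step '%s'", st$step[k]))
    prev_s <- st$snps_remaining[k]
    prev_i <- st$individuals_remaining[k]
  }
  TRUE
})

#' Two-point linkage estimate for one marker pair in one parent
#'
#' @slot rHat maximum-likelihood recombination fraction in [0, 0.5].
#' @slot lod log10 likelihood ratio of linkage at \code{rHat} versus free
#'   recombination (r = 0.5); non-negative.
#' @slot phase \code{"coupling"} if the state labels as given are the
#'   non-recombinant configuration, \code{"repulsion"} otherwise.
#' @slot nInformative number of meioses scored at both markers.
#'
#' @seealso [estimateTwoPoint()]
#' @export
setClass("TwoPointResult",
  representation(
    rHat         = "numeric",
    lod          = "numeric",
    phase        = "character",
    nInformative = "integer"
  )
)

setValidity("TwoPointResult", function(object) {
  if (object@rHat < 0 || object@rHat > 0.5) return("rHat must lie in [0, 0.5]")
  if (object@lod < -1e-9) return("lod must be non-negative")
  if (!object@phase %in% c("coupling", "repulsion")) return("bad phase")
  TRUE
})

#' One parent's ordered linkage-group map
#'
#' Ordered markers for a single linkage group in a single mapping parent, with
#' cumulative Haldane positions in centiMorgans (first marker at 0), the
#' adjacent-interval recombination fractions they derive from, and a per-marker
#' flag marking placements whose best position was not decisively better than
#' the runner-up.
#'
#' @slot parent parent identifier (e.g. \code{"fam1_mother"}).
#' @slot sex \code{"female"} or \code{"male"}.
#' @slot group linkage-group identifier.
#' @slot markers ordered marker ids.
#' @slot positions cumulative cM positions, non-decreasing, starting at 0.
#' @slot intervalR adjacent recombination fractions (length = markers - 1).
#' @slot ambiguous logical flag per marker.
#'
#' @seealso [buildParentalMap()], [trimTerminal()], [mapLength()]
#' @export
setClass("ParentalMap",
  representation(
    parent    = "character",
    sex       = "character",
    group     = "character",
    markers   = "character",
    positions = "numeric",
    intervalR = "numeric",
    ambiguous = "logical"
  )
)

setValidity("ParentalMap", function(object) {
  n <- length(object@markers)
  if (length(object@positions) != n) return("positions/markers length mismatch")
  if (length(object@ambiguous) != n) return("ambiguous/markers length mismatch")
  if (n > 0 && length(object@intervalR) != n - 1L)
    return("intervalR must have one entry per adjacent interval")
  if (n > 0) {
    if (abs(object@positions[1]) > 1e-9) return("first position must be 0")
    if (any(diff(object@positions) < -1e-9)) return("positions must be non-decreasing")
    d <- diff(object@positions)
    h <- haldaneCM(pmin(object@intervalR, 0.5 - 1e-12))
    if (length(d) && any(abs(d - h) > 1e-6))
      return("positions must accumulate Haldane distances of intervalR")
  }
  if (!object@sex %in% c("female", "male")) return("sex must be female or male")
  TRUE
})

#' Marker-clustering interval profile for one parental map
#'
#' Percentages of a map's markers falling into consecutive equal-width
#' intervals, used to contrast marker clustering between male and female maps.
#'
#' @slot parent,sex,group identifiers as in [ParentalMap].
#' @slot width interval width in cM.
#' @slot percent per-interval marker percentages (sums to 100 for a non-empty
#'   map); at least 5 intervals.
#' @slot topIntervals indices of the five most populated intervals, by
#'   decreasing percentage.
#'
#' @seealso [clusteringProfile()], [topIntervalAverage()]
#' @export
setClass("IntervalProfile",
  representation(
    parent       = "character",
    sex          = "character",
    group        = "character",
    width        = "numeric",
    percent      = "numeric",
    topIntervals = "integer"
  )
)

setValidity("IntervalProfile", function(object) {
  if (length(object@percent) < 5L) return("at least 5 intervals required")
  if (any(object@percent < -1e-9)) return("percentages must be non-negative")
  s <- sum(object@percent)
  if (s > 0 && abs(s - 100) > 1e-9) return("percentages must sum to 100")
  if (length(object@topIntervals) != 5L) return("topIntervals must have length 5")
  TRUE
})
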