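#' Construct a GenotypeMatrix
#'
#' @param genotypes character matrix (markers x individuals) with entries
#'   \code{"aa"}, \code{"ab"}, \code{"bb"} or \code{NA}.  Symbols are
#'   normalised: alleles within a genotype are unordered, so \code{"ba"} is
#'   accepted and stored as \code{"ab"}.
#' @param individuals data.frame with columns \code{id}, \code{family},
#'   \code{role}; defaults to a single family of offspring plus no parents
#'   (only useful for toy matrices).
#' @param markers data.frame of per-marker annotation with a \code{marker_id}
#'   column; defaults to the genotype rownames.
#' @param depth optional numeric read-depth matrix of the same shape.
#' @return a validated [GenotypeMatrix-class] object.
#' @examples
#' g <- matrix(c("aa", "ab", "ab", "bb"), nrow = 2,
#'             dimnames = list(c("m1", "m2"), c("i1", "i2")))
#' ind <- data.frame(id = c("i1", "i2"), family = "fam1",
#'                   role = c("mother", "father"))
#' genotypeMatrix(g, ind)
#' @export
genotypeMatrix <- function(genotypes, individuals = NULL, markers = NULL,
                           depth = matrix(numeric(), 0, 0)) {
  genotypes <- normalizeGenotypes(genotypes)
  if (is.null(individuals)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(genotypes)))
    individuals <- data.frame(id = ids, family = "fam1", role = "offspring",
                              stringsAsFactors = FALSE)
  }
  if (is.null(markers)) {
    mid <- rownames(genotypes)
    if (is.null(mid)) mid <- paste0("m", seq_len(nrow(genotypes)))
    markers <- data.frame(marker_id = mid, stringsAsFactors = FALSE)
  }
  rownames(genotypes) <- markers$marker_id
  colnames(genotypes) <- individuals$id
  if (length(depth)) dimnames(depth) <- dimnames(genotypes)
  new("GenotypeMatrix", genotypes = genotypes, individuals = individuals,
      markers = markers, depth = depth)
}

# "ba" -> "ab", "AA" -> "aa"; anything else left for the validity check to flag
normalizeGenotypes <- function(g) {
  v <- tolower(as.vector(g))
  v[v %in% c("na", "")] <- NA_character_
  v[v == "ba"] <- "ab"
  out <- matrix(v, nrow = nrow(g), dimnames = dimnames(g))
  out
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@genotypes)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("individuals", "GenotypeMatrix", function(x) x@individuals)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerInfo", "GenotypeMatrix", function(x) x@markers)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) x@markers$marker_id)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("readDepth", "GenotypeMatrix", function(x) x@depth)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("families", "GenotypeMatrix",
          function(x) unique(x@individuals$family))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@genotypes))

setMethod("show", "GenotypeMatrix", function(object) {
  ind <- object@individuals
  cat(sprintf("GenotypeMatrix: %d markers x %d individuals\n",
              nrow(object@genotypes), ncol(object@genotypes)))
  for (fam in unique(ind$family)) {
    sub <- ind[ind$family == fam, ]
    cat(sprintf("  family %s: %d parent(s), %d offspring\n", fam,
                sum(sub$role != "offspring"), sum(sub$role == "offspring")))
  }
  miss <- mean(is.na(object@genotypes))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(NULL)
})

#' Column index of a family's mother or father
#'
#' @param x a \code{GenotypeMatrix}
#' @param family family identifier
#' @param role \code{"mother"} or \code{"father"}
#' @return integer column index, or NA if that parent is absent.
#' @export
parentColumn <- function(x, family, role = c("mother", "father")) {
  role <- match.arg(role)
  ind <- individuals(x)
  w <- which(ind$family == family & ind$role == role)
  if (length(w)) w[1] else NA_integer_
}

#' Column indices of a family's offspring
#' @inheritParams parentColumn
#' @export
offspringColumns <- function(x, family) {
  ind <- individuals(x)
  which(ind$family == family & ind$role == "offspring")
}

#' Subset a GenotypeMatrix by markers and/or individuals
#'
#' @param x a \code{GenotypeMatrix}
#' @param i marker index (integer/logical/character over marker ids)
#' @param j individual index (integer/logical/character over individual ids)
#' @param ... ignored
#' @param drop ignored; the result is always a \code{GenotypeMatrix}
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  if (is.character(i)) i <- match(i, x@markers$marker_id)
  if (is.character(j)) j <- match(j, x@individuals$id)
  new("GenotypeMatrix",
      genotypes   = x@genotypes[i, j, drop = FALSE],
      individuals = x@individuals[j, , drop = FALSE],
      markers     = x@markers[i, , drop = FALSE],
      depth       = if (length(x@depth)) x@depth[i, j, drop = FALSE]
                    else x@depth)
})

setMethod("show", "FilterLedger", function(object) {
  cat(sprintf("FilterLedger: %d step(s); start %d SNPs, %d individuals\n",
              nrow(object@steps), object@initialSnps, object@initialIndividuals))
  if (nrow(object@steps)) {
    print(object@steps, row.names = FALSE)
  }
  invisible(NULL)
})

#' @rdname ledgerSteps
#' @export
setMethod("ledgerSteps", "FilterLedger", function(x) x@steps)

setMethod("show", "TwoPointResult", function(object) {
  cat(sprintf("TwoPointResult: r = %.4f, LOD = %.3f, phase = %s, n = %d\n",
              object@rHat, object@lod, object@phase, object@nInformative))
  invisible(NULL)
})

setMethod("show", "ParentalMap", function(object) {
  cat(sprintf("ParentalMap: %s (%s), group %s: %d markers, %.1f cM%s\n",
              object@parent, object@sex, object@group, length(object@markers),
              mapLength(object),
              if (any(object@ambiguous)) sprintf(" (%d ambiguous)",
                                                 sum(object@ambiguous)) else ""))
  invisible(NULL)
})

#' @rdname mapLength
#' @export
setMethod("mapLength", "ParentalMap", function(x) {
  if (length(x@positions) < 2L) 0 else x@positions[length(x@positions)]
})

setMethod("show", "IntervalProfile", function(object) {
  cat(sprintf("IntervalProfile: %s (%s), group %s: %d intervals x %.2f cM\n",
              object@parent, object@sex, object@group,
              length(object@percent), object@width))
  invisible(NULL)
})

#' As-data.frame view of a ParentalMap
#'
#' @param x a \code{ParentalMap}
#' @param row.names,optional,... passed through for the generic's sake; unused.
#' @return data.frame with columns parent, sex, group, rank, marker_id,
#'   position_cM, ambiguous.
#' @export
as.data.frame.ParentalMap <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(parent = x@parent, sex = x@sex, group = x@group,
             rank = seq_along(x@markers), marker_id = x@markers,
             position_cM = round(x@positions, 2),
             ambiguous = x@ambiguous, stringsAsFactors = FALSE)
}
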