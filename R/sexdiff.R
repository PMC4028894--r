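#' Female:male map-length ratio
#'
#' Recombination-rate ratios between the sexes are estimated by comparing
#' total map lengths, since male and female maps share no markers.  The
#' ratio is reported to one decimal as 1:x with x on the longer (usually
#' female) side.
#'
#' @param female_len,male_len total map lengths in cM; must be positive.  A
#'   zero male length (all markers co-located) leaves the ratio undefined and
#'   returns NA.
#' @return numeric ratio rounded to 1 decimal, or NA when undefined.
#' @examples
#' mapLengthRatio(2807, 2170)  # 1.3
#' mapLengthRatio(2358, 1426)  # 1.7
#' @export
mapLengthRatio <- function(female_len, male_len) {
  if (female_len <= 0) stop("female map length must be positive")
  if (male_len <= 0) return(NA_real_)
  round(female_len / male_len, 1)
}

#' Split a map into marker-counting intervals
#'
#' The shorter parental map is split into \code{baseWidth}-cM intervals; the
#' interval count is floor(L / baseWidth) + 1, so a marker at the far end
#' always has an interval of its own (an 85 cM map yields 18 intervals at the
#' 5 cM base width).  If that count would not exceed \code{minIntervals}, the
#' map is instead split into exactly \code{minIntervals} equal intervals.
#'
#' @param map_length map length in cM (>= 0).
#' @param baseWidth base interval width in cM (default 5; must be positive).
#' @param minIntervals minimum interval count (default 5).
#' @return list with \code{n} (interval count), \code{width}, and
#'   \code{edges} (length n + 1 vector of interval boundaries starting at 0).
#' @examples
#' splitIntervals(85)$n    # 18
#' splitIntervals(12)      # five intervals of 2.4 cM
#' @export
splitIntervals <- function(map_length, baseWidth = 5, minIntervals = 5) {
  if (baseWidth <= 0) stop("baseWidth must be positive")
  if (map_length < 0) stop("map length must be non-negative")
  n <- floor(map_length / baseWidth) + 1L
  if (n > minIntervals) {
    list(n = as.integer(n), width = baseWidth,
         edges = seq(0, by = baseWidth, length.out = n + 1L))
  } else {
    w <- map_length / minIntervals
    list(n = as.integer(minIntervals), width = w,
         edges = seq(0, map_length, length.out = minIntervals + 1L))
  }
}

# percentage of markers per interval; markers on an interior edge belong to
# the higher interval
intervalPercentages <- function(positions, edges) {
  n <- length(edges) - 1L
  # [e_j, e_{j+1}) intervals: a marker on an interior edge goes up; the far
  # end of the last interval is closed
  idx <- findInterval(positions, edges)
  idx[positions <= edges[1L]] <- 1L   # incl. zero-length degenerate maps
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  counts <- tabulate(idx, nbins = n)
  100 * counts / max(length(positions), 1L)
}

#' Marker-clustering profiles for a female/male map pair
#'
#' The shorter of the two maps is split at the base width via
#' [splitIntervals()]; the longer map is split into the same number of equal
#' intervals.  Per-interval marker percentages are computed for both maps.
#'
#' @param femaleMap,maleMap [ParentalMap-class] objects for the same linkage
#'   group; both must contain at least one marker.
#' @param baseWidth,minIntervals passed to [splitIntervals()].
#' @return list with elements \code{female} and \code{male}, each an
#'   [IntervalProfile-class].
#' @export
clusteringProfile <- function(femaleMap, maleMap, baseWidth = 5,
                              minIntervals = 5) {
  if (!length(femaleMap@markers) || !length(maleMap@markers))
    stop("both maps must contain at least one marker")
  lf <- mapLength(femaleMap); lm <- mapLength(maleMap)
  shorter <- if (lm <= lf) maleMap else femaleMap
  longer  <- if (lm <= lf) femaleMap else maleMap
  sp <- splitIntervals(mapLength(shorter), baseWidth, minIntervals)
  edgesLong <- seq(0, max(mapLength(longer), 1e-9), length.out = sp$n + 1L)
  mkProfile <- function(map, edges, width) {
    pct <- intervalPercentages(map@positions, edges)
    new("IntervalProfile", parent = map@parent, sex = map@sex,
        group = map@group, width = width, percent = pct,
        topIntervals = as.integer(order(-pct)[1:5]))
  }
  out <- list(mkProfile(shorter, sp$edges, sp$width),
              mkProfile(longer, edgesLong, edgesLong[2L] - edgesLong[1L]))
  names(out) <- c(shorter@sex, longer@sex)
  out[c("female", "male")]
}

#' Average the five most populated intervals per sex
#'
#' For every profile, the five highest per-interval marker percentages are
#' ranked; rank-k percentages are then averaged across all profiles (linkage
#' groups and families) separately for each sex.
#'
#' @param profiles list of [IntervalProfile-class] objects (both sexes mixed).
#' @return matrix with rows \code{female}/\code{male} (those present) and
#'   five columns of averaged rank-1..5 percentages.
#' @export
topIntervalAverage <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  sexes <- vapply(profiles, function(p) p@sex, character(1))
  out <- lapply(split(profiles, sexes), function(ps) {
    tops <- t(vapply(ps, function(p) sort(p@percent, decreasing = TRUE)[1:5],
                     numeric(5)))
    colMeans(tops)
  })
  res <- do.call(rbind, out)
  colnames(res) <- paste0("rank", 1:5)
  res
}

#' Per-group and overall map-length ratio table
#'
#' @param maps list of [ParentalMap-class] objects (both sexes, one or more
#'   families); ratios are computed per family and group where both sexes
#'   have a map, and overall from summed lengths.  Groups with an undefined
#'   ratio (zero male length) are excluded from the overall sums.
#' @return data.frame with columns family, group, female_cM, male_cM, ratio;
#'   the last row is the overall ratio per family ("all" group).
#' @export
mapRatioTable <- function(maps) {
  key <- vapply(maps, function(m) paste(sub("_(mother|father)$", "", m@parent),
                                        m@group, sep = "\r"), character(1))
  rows <- list()
  for (k in unique(key)) {
    ms <- maps[key == k]
    fem <- Filter(function(m) m@sex == "female", ms)
    mal <- Filter(function(m) m@sex == "male", ms)
    if (!length(fem) || !length(mal)) next
    parts <- strsplit(k, "\r")[[1L]]
    lf <- mapLength(fem[[1L]]); lm <- mapLength(mal[[1L]])
    rows[[k]] <- data.frame(family = parts[1L], group = parts[2L],
                            female_cM = lf, male_cM = lm,
                            ratio = if (lm > 0) round(lf / lm, 1) else NA_real_,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(tab)
  for (fam in unique(tab$family)) {
    sub <- tab[tab$family == fam & !is.na(tab$ratio), ]
    tab <- rbind(tab, data.frame(family = fam, group = "all",
                                 female_cM = sum(sub$female_cM),
                                 male_cM = sum(sub$male_cM),
                                 ratio = mapLengthRatio(sum(sub$female_cM),
                                                        sum(sub$male_cM)),
                                 stringsAsFactors = FALSE))
  }
  rownames(tab) <- NULL
  tab
}
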