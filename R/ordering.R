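#' Haldane map function and its inverse
#'
#' Converts a recombination fraction to a map distance in centiMorgans under
#' the no-interference (Haldane) model, d = -50 ln(1 - 2r), and back,
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param r recombination fraction(s) in [0, 0.5); values at or above 0.5
#'   correspond to infinite distance and are rejected.
#' @param d map distance(s) in cM, >= 0.
#' @return \code{haldaneCM}: distance in cM; \code{haldaneR}: recombination
#'   fraction.
#' @examples
#' haldaneCM(0.2)            # 25.54 cM
#' haldaneR(haldaneCM(0.3))  # 0.3
#' @export
haldaneCM <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5); r >= 0.5 maps to infinite distance")
  -50 * log(1 - 2 * r)
}

#' @rdname haldaneCM
#' @export
haldaneR <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * d / 100)) / 2
}

# ---- multipoint likelihood engine -------------------------------------------
#
# The transmitted-haplotype indicators of one parent form, along the true
# marker order, a two-state Markov chain: the state switches between adjacent
# markers with the interval's recombination probability (no interference).
# Observed states are exact; missing states are summed out.  Because
# observations are noiseless, the likelihood factorises per meiosis over
# "gaps" between consecutive observed markers: a gap spanning intervals
# s..e mismatches with probability (1 - prod(1-2 r_k)) / 2.  Interval r_k are
# estimated by EM on these gap records.

# Extract gap records from a states matrix (markers in map order x meioses).
# Returns start interval, end interval, mismatch flag per gap, plus the number
# of meioses with at least one observed state.
gapRecords <- function(states) {
  obs <- which(!is.na(states), arr.ind = TRUE)
  if (nrow(obs) == 0L)
    return(list(gs = integer(), ge = integer(), mm = logical(), n0 = 0L))
  o <- order(obs[, 2L], obs[, 1L])
  rr <- obs[o, 1L]
  cc <- obs[o, 2L]
  n0 <- length(unique(cc))
  same <- cc[-1L] == cc[-length(cc)]
  if (!any(same))
    return(list(gs = integer(), ge = integer(), mm = logical(), n0 = n0))
  i1 <- rr[-length(rr)][same]
  i2 <- rr[-1L][same]
  c2 <- cc[-1L][same]
  mm <- states[cbind(i1, c2)] != states[cbind(i2, c2)]
  list(gs = i1, ge = i2 - 1L, mm = mm, n0 = n0)
}

# sum w over gaps covering each interval k (gs <= k <= ge); nInt intervals
intervalSums <- function(gs, ge, w, nInt) {
  acc <- numeric(nInt + 1L)
  if (length(gs)) {
    s1 <- rowsum(w, gs)
    i1 <- as.integer(rownames(s1))
    acc[i1] <- acc[i1] + s1[, 1L]
    s2 <- rowsum(w, ge + 1L)
    i2 <- as.integer(rownames(s2))
    acc[i2] <- acc[i2] - s2[, 1L]
  }
  cumsum(acc)[seq_len(nInt)]
}

# EM fit of per-interval recombination fractions from gap records
fitIntervalR <- function(gaps, nInt, tol = 1e-7, maxIter = 200L) {
  if (nInt < 1L) return(numeric(0))
  nk <- intervalSums(gaps$gs, gaps$ge, rep(1, length(gaps$gs)), nInt)
  r <- rep(0.1, nInt)
  r[nk == 0] <- 0.5          # no spanning meiosis: no information
  if (!length(gaps$gs)) return(r)
  rmax <- 0.5 - 1e-9
  for (it in seq_len(maxIter)) {
    q <- 1 - 2 * pmin(pmax(r, 1e-12), rmax)
    cl <- c(0, cumsum(log(q)))
    Qg <- exp(cl[gaps$ge + 1L] - cl[gaps$gs])
    Pg <- (1 - Qg) / 2
    Pg <- pmin(pmax(Pg, 1e-12), 1 - 1e-12)
    ag <- ifelse(gaps$mm, 1 / (2 * Pg), 1 / (2 * (1 - Pg)))
    tg <- ifelse(gaps$mm, 1, -1) * Qg * ag
    A <- intervalSums(gaps$gs, gaps$ge, ag, nInt)
    B <- intervalSums(gaps$gs, gaps$ge, tg, nInt)
    E <- r * (A + B / q)
    rnew <- ifelse(nk > 0, pmin(pmax(E / pmax(nk, 1), 0), rmax), 0.5)
    delta <- max(abs(rnew - r))
    r <- rnew
    if (delta < tol) break
  }
  r
}

gapLoglik10 <- function(gaps, r) {
  if (!length(gaps$gs)) return(gaps$n0 * log10(0.5))
  q <- 1 - 2 * pmin(pmax(r, 0), 0.5 - 1e-9)
  cl <- c(0, cumsum(log(q)))
  Qg <- exp(cl[gaps$ge + 1L] - cl[gaps$gs])
  Pg <- pmin(pmax((1 - Qg) / 2, 1e-300), 1 - 1e-16)
  sum(log10(ifelse(gaps$mm, Pg, 1 - Pg))) + gaps$n0 * log10(0.5)
}

#' Multipoint log-likelihood of a marker order
#'
#' Maximum log10 likelihood of one parent's transmitted-haplotype state
#' vectors under a two-state Markov chain along the given marker order, with
#' one free recombination probability per adjacent interval and missing states
#' summed out.  With complete data this reduces to a sum of per-interval
#' binomial terms at r = mismatches / meioses (plus the 1/2 prior for the
#' first transmitted allele of each meiosis).
#'
#' @param order integer vector: row order in which to chain the markers.
#' @param states matrix (markers x meioses) of transmitted states 0/1/NA, as
#'   returned by [transmittedStates()].
#' @param tol,maxIter EM convergence controls; order-search code uses a
#'   coarser tolerance since only likelihood differences matter there.
#' @return list with elements \code{loglik} (log10), \code{intervalR}
#'   (per-interval ML recombination fractions, in order).
#' @export
multipointLoglik <- function(order, states, tol = 1e-7, maxIter = 200L) {
  if (length(order) < 2L) stop("at least 2 markers are required")
  s <- states[order, , drop = FALSE]
  gaps <- gapRecords(s)
  r <- fitIntervalR(gaps, length(order) - 1L, tol = tol, maxIter = maxIter)
  list(loglik = gapLoglik10(gaps, r), intervalR = r)
}

# coarse likelihood for order comparison
searchLoglik <- function(order, states) {
  multipointLoglik(order, states, tol = 2e-4, maxIter = 60L)$loglik
}

# first-improvement 2-opt segment-reversal polish: repairs mis-oriented
# blocks that sequential insertion cannot revisit
reversalPolish <- function(ord, states, maxPasses = 20L) {
  m <- length(ord)
  if (m < 4L) return(ord)
  ll <- searchLoglik(ord, states)
  for (pass in seq_len(maxPasses)) {
    improved <- FALSE
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        o2 <- ord
        o2[i:j] <- rev(o2[i:j])
        l2 <- searchLoglik(o2, states)
        if (l2 > ll + 1e-6) { ord <- o2; ll <- l2; improved <- TRUE }
      }
    }
    if (!improved) break
  }
  ord
}

# all permutations of 1..n as a list (n small)
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

lexLess <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

# canonical representative of an order modulo reversal (reversal has the same
# likelihood by symmetry of the chain)
canonOrder <- function(ord) {
  rev_ord <- rev(ord)
  if (lexLess(rev_ord, ord)) rev_ord else ord
}

#' Order markers within a linkage group by multipoint likelihood
#'
#' The \code{nInit} markers with the most non-missing states are ordered
#' exhaustively by multipoint likelihood; the remaining markers are then
#' inserted one at a time at their maximum-likelihood position, taking at
#' each step the unplaced marker with the strongest two-point linkage to the
#' markers already placed (so the growing order stays contiguous).  A marker whose best position beats the
#' second-best by less than \code{thres} log10 units is still placed at the
#' best position but flagged ambiguous.  Likelihood ties are broken toward
#' the lexicographically smaller order; the returned order is the
#' lexicographically smaller of itself and its reversal.
#'
#' A final segment-reversal (2-opt) polish repairs mis-oriented blocks that
#' the sequential insertion cannot revisit (the seed order is estimated from
#' few, possibly distant, markers and all later placements condition on it).
#'
#' @param states matrix (markers x meioses) of transmitted states 0/1/NA.
#' @param nInit number of seed markers ordered exhaustively (default 5).
#' @param thres log10-likelihood ambiguity threshold (default 4).
#' @param polish logical: run the segment-reversal polish (default TRUE).
#' @return list with \code{order} (integer indices into the rows of
#'   \code{states}) and \code{ambiguous} (logical, parallel to \code{order}).
#' @export
orderMarkers <- function(states, nInit = 5, thres = 4, polish = TRUE) {
  m <- nrow(states)
  if (m < 2L) stop("at least 2 markers are required")
  if (m == 2L) return(list(order = 1:2, ambiguous = c(FALSE, FALSE)))
  info <- rowSums(!is.na(states))
  pref <- order(-info, seq_len(m))     # ties toward lower input index
  k <- min(nInit, m)
  seed <- sort(pref[seq_len(k)])
  rest <- pref[-seq_len(k)]

  perms <- Filter(function(p) !lexLess(rev(p), p), allPerms(k))
  cand <- lapply(perms, function(p) seed[p])
  ll <- vapply(cand, function(o) searchLoglik(o, states), numeric(1))
  best_i <- which(ll == max(ll))
  cur <- cand[[best_i[1L]]]
  if (length(best_i) > 1L)
    for (i in best_i[-1L]) if (lexLess(canonOrder(cand[[i]]), canonOrder(cur)))
      cur <- cand[[i]]
  seed_amb <- if (length(ll) > 1L) {
    (max(ll) - max(ll[-which.max(ll)])) < thres
  } else FALSE
  amb <- stats::setNames(rep(seed_amb, length(cur)), cur)

  # insertion sequence: always the unplaced marker with the strongest
  # two-point linkage to the markers already placed, so that the growing
  # order stays contiguous; ties toward more informative, then lower index
  pl <- pairwiseLod(states)$lod
  rest <- as.integer(rest)
  while (length(rest)) {
    bestlod <- apply(pl[rest, cur, drop = FALSE], 1L, max)
    pick <- order(-bestlod, -info[rest], rest)[1L]
    mk <- rest[pick]
    rest <- rest[-pick]
    npos <- length(cur) + 1L
    lls <- numeric(npos)
    for (p in seq_len(npos)) {
      o <- append(cur, mk, after = p - 1L)
      lls[p] <- searchLoglik(o, states)
    }
    bp <- which.max(lls)                     # first (lexicographically smaller)
    second <- if (npos > 1L) max(lls[-bp]) else -Inf
    amb <- c(amb, stats::setNames((lls[bp] - second) < thres, mk))
    cur <- append(cur, mk, after = bp - 1L)
  }
  if (polish) cur <- reversalPolish(cur, states)
  cur2 <- canonOrder(cur)
  list(order = cur2, ambiguous = unname(amb[as.character(cur2)]))
}

#' Ripple verification of a marker order
#'
#' Slides a window of \code{window} consecutive markers along the order; all
#' permutations of each window are scored by the full multipoint likelihood
#' and a strictly better permutation is adopted.  Passes repeat until a full
#' pass leaves the order unchanged.  Markers that move in any alternative
#' order scoring within \code{lodThresh} log10 units of the accepted one are
#' flagged ambiguous.
#'
#' @param order integer marker order (indices into rows of \code{states}).
#' @param states transmitted-state matrix as in [multipointLoglik()].
#' @param window window size (default 7); shrunk to the group size when
#'   larger; \code{window = 1} is a no-op.
#' @param lodThresh log10 ambiguity threshold (default 4).
#' @return list with \code{order} and \code{ambiguous} as in [orderMarkers()].
#' @export
rippleOrder <- function(order, states, window = 7, lodThresh = 4) {
  m <- length(order)
  window <- min(window, m)
  amb <- rep(FALSE, m)
  if (window <= 1L || m < 2L)
    return(list(order = order, ambiguous = amb))
  perms <- allPerms(window)
  repeat {
    changed <- FALSE
    amb_names <- character(0)
    for (w0 in seq_len(m - window + 1L)) {
      idx <- w0:(w0 + window - 1L)
      base_ll <- searchLoglik(order, states)
      best_ll <- base_ll
      best_order <- order
      near <- list()
      for (p in perms) {
        if (identical(p, seq_len(window))) next
        o <- order
        o[idx] <- order[idx][p]
        ll <- searchLoglik(o, states)
        if (ll > best_ll + 1e-9) { best_ll <- ll; best_order <- o }
        near[[length(near) + 1L]] <- list(o = o, ll = ll)
      }
      for (alt in near)
        if (alt$ll > best_ll - lodThresh && !identical(alt$o, best_order))
          amb_names <- c(amb_names, best_order[best_order != alt$o],
                         alt$o[best_order != alt$o])
      if (!identical(best_order, order)) { order <- best_order; changed <- TRUE }
    }
    if (!changed) break
  }
  amb <- order %in% unique(amb_names)
  list(order = order, ambiguous = amb)
}

#' Build one parent's linkage-group map
#'
#' Orders the markers ([orderMarkers()]), optionally verifies the order with
#' [rippleOrder()], estimates the adjacent-interval recombination fractions by
#' the multipoint fit, and accumulates Haldane cM positions from 0.
#'
#' @param states transmitted-state matrix (markers x meioses) for one parent's
#'   informative markers on one linkage group; rownames are marker ids.
#' @param parent,sex,group identifiers stored in the map.
#' @param nInit,thres passed to [orderMarkers()].
#' @param rippleWindow window for [rippleOrder()]; 0 (default) skips the
#'   ripple pass.
#' @param rippleLod LOD threshold for the ripple pass.
#' @return a [ParentalMap-class] object.
#' @export
buildParentalMap <- function(states, parent = "parent", sex = c("female", "male"),
                             group = "1", nInit = 5, thres = 4,
                             rippleWindow = 0, rippleLod = 4) {
  sex <- match.arg(sex)
  ids <- rownames(states)
  if (is.null(ids)) ids <- paste0("m", seq_len(nrow(states)))
  if (nrow(states) < 2L) {
    return(new("ParentalMap", parent = parent, sex = sex, group = as.character(group),
               markers = ids, positions = rep(0, nrow(states)),
               intervalR = numeric(0), ambiguous = rep(FALSE, nrow(states))))
  }
  os <- orderMarkers(states, nInit = nInit, thres = thres)
  if (rippleWindow > 1) {
    amb0 <- stats::setNames(os$ambiguous, os$order)
    rs <- rippleOrder(os$order, states, window = rippleWindow, lodThresh = rippleLod)
    newOrd <- canonOrder(rs$order)
    ambR <- stats::setNames(rs$ambiguous, rs$order)
    os$order <- newOrd
    os$ambiguous <- unname(ambR[as.character(newOrd)] | amb0[as.character(newOrd)])
  }
  fit <- multipointLoglik(os$order, states)
  r <- pmin(fit$intervalR, 0.5 - 1e-9)
  pos <- c(0, cumsum(haldaneCM(pmin(r, 0.4999))))
  new("ParentalMap", parent = parent, sex = sex, group = as.character(group),
      markers = ids[os$order], positions = pos,
      intervalR = pmin(r, 0.4999), ambiguous = os$ambiguous)
}

#' Trim spurious terminal markers from a map
#'
#' Genotyping errors inflate terminal map distances; terminal markers whose
#' gap to the neighbouring marker exceeds 30 cM (male maps) or 20 cM (female
#' maps) are removed, repeatedly from both ends, and positions re-zeroed to
#' the new first marker.  Internal gaps are untouched.
#'
#' @param map a [ParentalMap-class].
#' @param maleGap,femaleGap terminal-gap thresholds in cM.
#' @return the trimmed [ParentalMap-class].
#' @export
trimTerminal <- function(map, maleGap = 30, femaleGap = 20) {
  thr <- if (map@sex == "male") maleGap else femaleGap
  mk <- map@markers; pos <- map@positions; r <- map@intervalR; amb <- map@ambiguous
  repeat {
    n <- length(mk)
    if (n < 2L) break
    if (pos[2L] - pos[1L] > thr) {
      mk <- mk[-1L]; pos <- pos[-1L]; r <- r[-1L]; amb <- amb[-1L]
      pos <- pos - pos[1L]
      next
    }
    if (pos[n] - pos[n - 1L] > thr) {
      mk <- mk[-n]; pos <- pos[-n]; r <- r[-(n - 1L)]; amb <- amb[-n]
      next
    }
    break
  }
  new("ParentalMap", parent = map@parent, sex = map@sex, group = map@group,
      markers = mk, positions = pos - pos[1L], intervalR = r, ambiguous = amb)
}
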