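## Ring detection. Two complementary detectors run on the polar field:
##
##   * Multiple Conical Integration (MCI): peaks found independently in
##     several overlapping angular wedges; a peak recurring in at least a
##     quarter of the wedges is a ring. Robust for strong, possibly
##     anisotropic rings.
##   * Log-Central-Difference (LCD): a (-1, 2, -1) radial stencil (the
##     negative second finite difference) applied to I(theta, r), clipped
##     at zero, offset by a small eps and log-transformed; radii carrying
##     long contiguous azimuthal runs of high response are rings. Picks
##     up weak rings sitting next to strong ones.
##
## The two candidate lists are merged: nearby radii are averaged, the
## rest pass through.

#' Find local maxima of a 1D trace by prominence
#'
#' Simple peak picking used by the MCI detector: strict local maxima
#' whose topographic prominence exceeds `max(k * noise, floor)`, where
#' the noise scale is the median absolute deviation (scaled) of the
#' trace's first difference. Using a noise-relative threshold makes the
#' detection invariant to a global intensity rescale. Candidates that
#' survive only by noise are expected; the radial fitting stage prunes
#' them by amplitude significance.
#'
#' @param y numeric trace (NAs allowed; treated as gaps).
#' @param k prominence multiplier (default 3).
#' @param floor absolute prominence floor (default 0).
#' @return A data.frame with `index`, `value`, `prominence`, sorted by
#'   index.
#' @export
findProfilePeaks <- function(y, k = 3, floor = 0) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(), value = numeric(),
                                prominence = numeric()))
  yy <- y
  yy[is.na(yy)] <- -Inf
  isPeak <- which(yy[2:(n - 1)] > yy[1:(n - 2)] &
                  yy[2:(n - 1)] >= yy[3:n]) + 1L
  isPeak <- isPeak[is.finite(yy[isPeak])]
  if (!length(isPeak)) return(data.frame(index = integer(),
                                         value = numeric(),
                                         prominence = numeric()))
  prom <- vapply(isPeak, function(i) {
    h <- yy[i]
    # walk left/right to the nearest strictly higher point; the base on
    # each side is the minimum en route; prominence relative to the
    # higher of the two bases
    lmin <- h
    for (j in seq(i - 1L, 1L)) {
      if (yy[j] > h) break
      if (yy[j] < lmin && is.finite(yy[j])) lmin <- yy[j]
    }
    rmin <- h
    if (i < n) for (j in seq(i + 1L, n)) {
      if (yy[j] > h) break
      if (yy[j] < rmin && is.finite(yy[j])) rmin <- yy[j]
    }
    h - max(lmin, rmin)
  }, numeric(1))
  dy <- diff(y[is.finite(y)])
  noise <- if (length(dy) > 1) stats::mad(dy, na.rm = TRUE) else 0
  thr <- max(k * noise, floor)
  keep <- prom > thr & prom > 0
  data.frame(index = isPeak[keep], value = y[isPeak[keep]],
             prominence = prom[keep])
}

#' Ring detection by Multiple Conical Integration
#'
#' Integrates the pattern azimuthally within `nRanges` evenly spaced
#' angular wedges of width `rangeWidth` (with the defaults, 8 wedges of
#' 90 degrees overlapping at 45 degree spacing) and finds radial peaks
#' in each wedge's trace. Peaks are clustered across wedges by radius; a
#' cluster is reported as a ring candidate iff it appears in at least
#' one quarter of the wedges (`ceiling(nRanges / 4)`; with 8 wedges a
#' peak present in at least 2 qualifies). The candidate radius is the
#' mean of the member peak radii.
#'
#' @param polar a [PolarImage-class].
#' @param nRanges number of angular wedges (default 8).
#' @param rangeWidth wedge width in degrees (default 90).
#' @param clusterTol radius tolerance in pixels when clustering peaks
#'   across wedges (default 5).
#' @param peakK,peakFloor passed to [findProfilePeaks()].
#' @return A data.frame of candidates: `radius_px`, `source` ("MCI"),
#'   `support` (wedge count), `prominence` (mean member prominence).
#' @export
detectMCI <- function(polar, nRanges = 8L, rangeWidth = 90,
                      clusterTol = 5, peakK = 3, peakFloor = 0) {
  if (nRanges < 1L) stop("parameter error: nRanges must be >= 1")
  centers <- (seq_len(nRanges) - 1L) * 360 / nRanges
  peaks <- do.call(rbind, lapply(seq_len(nRanges), function(i) {
    prof <- azimuthalIntegrate(polar, c(centers[i], rangeWidth))
    pk <- findProfilePeaks(prof@intensity, k = peakK, floor = peakFloor)
    if (!nrow(pk)) return(NULL)
    data.frame(wedge = i, radius = prof@r[pk$index],
               prominence = pk$prominence)
  }))
  empty <- data.frame(radius_px = numeric(), source = character(),
                      support = numeric(), prominence = numeric())
  if (is.null(peaks) || !nrow(peaks)) return(empty)
  # single-linkage clustering on radius with tolerance clusterTol
  ord <- order(peaks$radius)
  peaks <- peaks[ord, ]
  grp <- cumsum(c(1, diff(peaks$radius) > clusterTol))
  supportMin <- ceiling(nRanges / 4)
  out <- do.call(rbind, lapply(split(peaks, grp), function(g) {
    support <- length(unique(g$wedge))
    if (support < supportMin) return(NULL)
    data.frame(radius_px = mean(g$radius), source = "MCI",
               support = support, prominence = mean(g$prominence))
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$radius_px), ]
}

#' MCI ring-classification support threshold
#'
#' A peak qualifies as a ring when it appears in at least one quarter of
#' the angular ranges: `ceiling(n / 4)` of `n` wedges (2 of 8 with the
#' defaults).
#'
#' @param nRanges number of angular wedges.
#' @return Integer minimal wedge support.
#' @export
mciSupportThreshold <- function(nRanges) as.integer(ceiling(nRanges / 4))

#' Log-Central-Difference field
#'
#' Applies the radial stencil `(-1, 2, -1)` at offset `q0` to the polar
#' field: `D(theta, r) = 2 I(theta, r) - I(theta, r - q0) -
#' I(theta, r + q0)`, the negative second finite difference along the
#' radius, which is large and positive at sharply peaked radii (rings)
#' and near zero in slowly varying regions (any background linear in r
#' is annihilated exactly). Negative values are clipped to zero, a small
#' `eps` is added and the log is taken: `L = log(max(D, 0) + eps)`.
#' Radii within `q0` of either border are flagged `NA`.
#'
#' @param polar a [PolarImage-class].
#' @param q0 radial stencil offset in pixels (default 10).
#' @param eps positive offset keeping the log finite (default 1e-6).
#' @return A list with matrices `D` and `L` `[theta, r]`, `q0`, `eps`,
#'   and `r` (bin centers), of class `"LCDField"`.
#' @export
computeLCD <- function(polar, q0 = 10, eps = 1e-6) {
  if (q0 <= 0) stop("parameter error: q0 must be > 0")
  if (eps <= 0) stop("parameter error: eps must be > 0")
  nR <- ncol(polar@values)
  q <- as.integer(round(q0 / polar@rStep))
  if (nR <= 2L * q) stop("rMax must exceed 2 * q0")
  I <- polar@values
  D <- matrix(NA_real_, nrow(I), nR)
  valid <- (q + 1L):(nR - q)
  D[, valid] <- 2 * I[, valid] - I[, valid - q] - I[, valid + q]
  L <- log(pmax(D, 0) + eps)
  structure(list(D = D, L = L, q0 = q0, eps = eps, r = rCenters(polar),
                 thetaStep = polar@thetaStep),
            class = "LCDField")
}

#' Ring detection on the Log-Central-Difference field
#'
#' Thresholds the L field at a quantile of its finite values, then scans
#' each radius (column) for maximal contiguous azimuthal runs above the
#' threshold, wrap-aware. A radius qualifies when its longest run is at
#' least `minRun` degrees; qualifying radii separated by at most
#' `groupGap` pixels are grouped into one ring, whose radius is the
#' run-length-weighted mean of the member radii.
#'
#' @param field an `"LCDField"` from [computeLCD()].
#' @param runThresholdQuantile quantile of finite L defining "high
#'   response" (default 0.90; scale-free across exposure levels).
#' @param minRun minimal contiguous run in degrees (default 30).
#' @param groupGap maximal radial gap within one ring in pixels
#'   (default 2).
#' @return A data.frame of candidates: `radius_px`, `source` ("LCD"),
#'   `support` (longest run, degrees), `prominence` (max L in group).
#' @export
detectLCD <- function(field, runThresholdQuantile = 0.90, minRun = 30,
                      groupGap = 2) {
  L <- field$L
  fin <- L[is.finite(L)]
  empty <- data.frame(radius_px = numeric(), source = character(),
                      support = numeric(), prominence = numeric())
  if (!length(fin)) return(empty)
  thr <- stats::quantile(fin, runThresholdQuantile, names = FALSE)
  if (max(fin) - min(fin) < 1e-12) return(empty)  # degenerate field
  nTheta <- nrow(L)
  runLen <- vapply(seq_len(ncol(L)), function(j) {
    col <- L[, j]
    hi <- is.finite(col) & col > thr
    if (!any(hi)) return(0)
    if (all(hi)) return(360)
    # rotate so the vector starts outside a run, making runs contiguous
    start <- which(!hi)[1]
    hi <- hi[c(start:nTheta, seq_len(start - 1L))]
    rl <- rle(hi)
    max(rl$lengths[rl$values]) * field$thetaStep
  }, numeric(1))
  qual <- which(runLen >= minRun)
  if (!length(qual)) return(empty)
  r <- field$r
  gapBins <- groupGap / (r[2] - r[1])
  grp <- cumsum(c(1, diff(qual) > gapBins))
  out <- do.call(rbind, lapply(split(qual, grp), function(g) {
    w <- runLen[g]
    data.frame(radius_px = sum(r[g] * w) / sum(w), source = "LCD",
               support = max(w),
               prominence = max(L[, g], na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out[order(out$radius_px), ]
}

#' Merge ring candidates from the two detectors
#'
#' Greedy nearest-pair matching between the MCI and LCD radius lists:
#' pairs within `tolerance` are replaced by their arithmetic mean (rings
#' with similar distances are averaged), each input radius contributing
#' to at most one output; unmatched radii pass through unchanged. For
#' example, MCI rings at 50, 80, 118 px merged with LCD rings at 82,
#' 120, 180 px give final rings at 50, 81, 119, 180 px.
#'
#' @param mci numeric vector of MCI candidate radii (pixels).
#' @param lcd numeric vector of LCD candidate radii (pixels).
#' @param tolerance maximal radius difference for a pair to merge
#'   (default 10 px).
#' @return Sorted numeric vector of merged radii.
#' @examples
#' mergeRings(c(50, 80, 118), c(82, 120, 180))  # 50 81 119 180
#' @export
mergeRings <- function(mci, lcd, tolerance = 10) {
  mci <- sort(as.numeric(mci)); lcd <- sort(as.numeric(lcd))
  if (!length(mci) || !length(lcd)) return(sort(c(mci, lcd)))
  d <- abs(outer(mci, lcd, "-"))
  usedM <- logical(length(mci)); usedL <- logical(length(lcd))
  merged <- numeric()
  repeat {
    d[usedM, ] <- Inf; d[, usedL] <- Inf
    if (all(!is.finite(d)) || min(d) > tolerance) break
    k <- arrayInd(which.min(d), dim(d))
    merged <- c(merged, (mci[k[1]] + lcd[k[2]]) / 2)
    usedM[k[1]] <- TRUE; usedL[k[2]] <- TRUE
  }
  sort(c(merged, mci[!usedM], lcd[!usedL]))
}

#' Run both detectors and merge
#'
#' Convenience wrapper: MCI and LCD detection on one polar field,
#' followed by [mergeRings()].
#'
#' @param polar a [PolarImage-class].
#' @param config a [diConfig()] parameter list.
#' @return A list with `radii` (merged, sorted), and the per-detector
#'   candidate data.frames `mci` and `lcd`.
#' @export
detectRings <- function(polar, config = diConfig()) {
  mci <- detectMCI(polar, nRanges = config$nRanges,
                   rangeWidth = config$rangeWidth,
                   clusterTol = config$clusterTol,
                   peakK = config$peakK, peakFloor = config$peakFloor)
  lcdOk <- ncol(polar@values) > 2 * round(config$q0 / polar@rStep)
  lcd <- if (lcdOk) {
    field <- computeLCD(polar, q0 = config$q0, eps = config$eps)
    detectLCD(field, runThresholdQuantile = config$runThresholdQuantile,
              minRun = config$minRun, groupGap = config$groupGap)
  } else data.frame(radius_px = numeric(), source = character(),
                    support = numeric(), prominence = numeric())
  list(radii = mergeRings(mci$radius_px, lcd$radius_px,
                          tolerance = config$mergeTol),
       mci = mci, lcd = lcd)
}
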