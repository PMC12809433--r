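# Shared fixtures and independent oracles used across the suite.

testGeometry <- function(size = c(192L, 192L)) defaultGeometry(size)

# Synthetic azimuthal profile of a centrosymmetric arc pair on a
# Poisson background, generated directly at the profile level (the
# image-level path is exercised separately). SNR is the arc peak
# amplitude over the background shot-noise sd.
simAzimuthalProfile <- function(phi0, sigmaTheta, snr = 10, baseline = 100,
                                seed = 1, n = 360, isotropic = FALSE) {
  th <- (seq_len(n) - 0.5) * 360 / n
  amp <- snr * sqrt(baseline)
  delta <- function(a, b) {
    d <- (a - b) %% 360
    ifelse(d > 180, d - 360, d)
  }
  shape <- if (isotropic) 0 else
    exp(-delta(th, phi0)^2 / (2 * sigmaTheta^2)) +
    exp(-delta(th, phi0 + 180)^2 / (2 * sigmaTheta^2))
  set.seed(seed)
  AzimuthalProfile(th, rpois(n, baseline + amp * shape), c(50, 70))
}

# One oriented single-ring pattern with the default study conditions
# (phi0 = 30 deg, sigma_theta = 10 deg, SNR 10 on baseline 100).
orientedPattern <- function(seed = 1, phi0 = 30, sigmaTheta = 10) {
  makePattern(rings = list(RingSpec(60, 100, sigmaR = 3,
                                    orientation = phi0,
                                    sigmaTheta = sigmaTheta)),
              seed = seed)
}

# Brute-force circle fit oracle: grid search of (cx, cy, r) minimizing
# the same rms residual, on a fine lattice around a coarse guess.
gridSearchCircle <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  scan <- function(cx0, cy0, span, step) {
    best <- c(NA, NA, NA); bestRms <- Inf
    for (cx in seq(cx0 - span, cx0 + span, by = step))
      for (cy in seq(cy0 - span, cy0 + span, by = step)) {
        d <- sqrt((x - cx)^2 + (y - cy)^2)
        r <- mean(d)  # optimal r for fixed center under rms
        rms <- sqrt(mean((d - r)^2))
        if (rms < bestRms) {
          bestRms <- rms
          best <- c(cx, cy, r)
        }
      }
    list(center = best[1:2], radius = best[3], rms = bestRms)
  }
  # coarse scan around the centroid, then refine on a fine lattice
  coarse <- scan(mean(x), mean(y), span = 60, step = 1)
  scan(coarse$center[1], coarse$center[2], span = 1.5, step = 0.02)
}

# Exhaustive merge-matching oracle: maximum-cardinality matching with
# pairs restricted to |a - b| <= tol, tie-broken by minimal total
# distance; merged pairs averaged, the rest passed through.
bruteForceMerge <- function(a, b, tol = 10) {
  a <- sort(a); b <- sort(b)
  bestPairs <- list(); bestCard <- -1L; bestDist <- Inf
  recurse <- function(i, used, pairs, dist) {
    if (i > length(a)) {
      card <- length(pairs)
      if (card > bestCard || (card == bestCard && dist < bestDist)) {
        bestPairs <<- pairs; bestCard <<- card; bestDist <<- dist
      }
      return(invisible())
    }
    recurse(i + 1L, used, pairs, dist)       # a[i] unmatched
    for (j in seq_along(b)) {
      if (used[j]) next
      d <- abs(a[i] - b[j])
      if (d <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, c(pairs, list(c(i, j))), dist + d)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(b)), list(), 0)
  usedA <- vapply(bestPairs, `[`, numeric(1), 1)
  usedB <- vapply(bestPairs, `[`, numeric(1), 2)
  merged <- vapply(bestPairs, function(p) (a[p[1]] + b[p[2]]) / 2,
                   numeric(1))
  sort(c(merged, a[setdiff(seq_along(a), usedA)],
         b[setdiff(seq_along(b), usedB)]))
}

# Random well-separated radius lists (distinct diffraction rings are
# at least ~2x the merge tolerance apart).
randomRadii <- function(n, minSep = 25, lo = 20, hi = 220) {
  repeat {
    r <- sort(runif(n, lo, hi))
    if (n < 2 || min(diff(r)) >= minSep) return(r)
  }
}

# Process the default synthetic scan once and cache the results for all
# tests that need an end-to-end folder (4 x 4 grid, brainlike preset).
.scanCache <- new.env(parent = emptyenv())
processedDefaultScan <- function() {
  if (is.null(.scanCache$res)) {
    dir <- tempfile("defaultscan")
    info <- makeScan(dir = dir, seed = 2024)
    res <- suppressWarnings(processFolder(dir))
    .scanCache$res <- list(dir = dir, info = info, res = res,
                           grid = info$grid)
  }
  .scanCache$res
}
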