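## Seeded generator of fiber-diffraction fixtures: single patterns and
## whole raster scans with known ground truth, emulating what a scanning
## microdiffraction experiment on partially oriented tissue produces --
## Gaussian rings (full rings when isotropic, centrosymmetric arc pairs
## when oriented) on a constant background with Poisson photon noise and
## a circular beamstop mask.

#' Specify one synthetic diffraction ring
#'
#' @param radius ring radius in pixels.
#' @param amplitude peak amplitude above baseline (counts).
#' @param sigmaR radial Gaussian width in pixels.
#' @param orientation arc azimuth phi0 in degrees, or `NA` for an
#'   isotropic (full) ring.
#' @param sigmaTheta azimuthal Gaussian width of each arc in degrees
#'   (ignored when isotropic).
#' @return A list of class `"RingSpec"`.
#' @export
RingSpec <- function(radius, amplitude, sigmaR = 3,
                     orientation = NA_real_, sigmaTheta = 15) {
  stopifnot(radius > 0, amplitude > 0, sigmaR > 0,
            is.na(orientation) || sigmaTheta > 0)
  structure(list(radius = radius, amplitude = amplitude, sigmaR = sigmaR,
                 orientation = orientation, sigmaTheta = sigmaTheta),
            class = "RingSpec")
}

#' Default synthetic detector geometry
#'
#' A small-angle configuration typical of a scanning diffraction
#' beamline: 2 m camera, 172 um pixels (Pilatus-class), 1.033 A
#' (12 keV) beam, beam center in the middle of a 192 x 192 px frame.
#' A ring at 60 px corresponds to a d-spacing of about 200 A.
#'
#' @param size integer(2) image dimension (rows, cols).
#' @return A [DetectorGeometry-class].
#' @export
defaultGeometry <- function(size = c(192L, 192L)) {
  DetectorGeometry(beamCenter = c((size[2] - 1) / 2, (size[1] - 1) / 2),
                   sdd = 2000, pixelSize = 0.172, wavelength = 1.033)
}

#' Generate one synthetic diffraction pattern
#'
#' The noiseless intensity is
#' `I(x, y) = baseline + sum_k A_k exp(-(rho - r_k)^2 / (2 sigmaR_k^2)) w_k(theta)`
#' with `w = 1` for isotropic rings and, for oriented rings, the sum of
#' two circular Gaussians at `phi0` and `phi0 + 180` (centrosymmetric
#' arc pair). Optional Poisson sampling emulates photon counting; a
#' central disk is masked as the beamstop shadow.
#'
#' @param size integer(2) image dimension (rows, cols).
#' @param geometry a [DetectorGeometry-class]; its beam center places
#'   the rings.
#' @param rings list of [RingSpec()] objects.
#' @param baseline constant background level in counts (default 100).
#' @param noise `"none"` or `"poisson"`.
#' @param beamstopRadius masked central disk radius in pixels
#'   (default 15; 0 disables).
#' @param seed RNG seed used for the Poisson draw (default 1).
#' @param name,index label and sequence index of the image.
#' @return A list with `image` (a [DiffractionImage-class]) and `truth`,
#'   a data.frame of the true ring parameters (radius, amplitude,
#'   widths, orientation, plus the d-spacing implied by `geometry`).
#' @examples
#' p <- makePattern(rings = list(RingSpec(60, 100, orientation = 30)))
#' p$truth
#' @export
makePattern <- function(size = c(192L, 192L), geometry = defaultGeometry(size),
                        rings = list(), baseline = 100,
                        noise = c("poisson", "none"), beamstopRadius = 15,
                        seed = 1L, name = "synthetic", index = 1L) {
  noise <- match.arg(noise)
  cx <- geometry@beamCenter[1]; cy <- geometry@beamCenter[2]
  maxR <- min(cx, size[2] - 1 - cx, cy, size[1] - 1 - cy)
  for (rs in rings)
    if (rs$radius >= maxR)
      stop("parameter error: ring radius ", rs$radius,
           " does not fit inside the image")
  xs <- matrix(rep(0:(size[2] - 1), each = size[1]), size[1], size[2])
  ys <- matrix(rep(0:(size[1] - 1), times = size[2]), size[1], size[2])
  rho <- sqrt((xs - cx)^2 + (ys - cy)^2)
  theta <- (atan2(cy - ys, xs - cx) * 180 / pi) %% 360
  I <- matrix(baseline, size[1], size[2])
  for (rs in rings) {
    w <- if (is.na(rs$orientation)) 1
    else gauss(circDiff(theta, rs$orientation), 0, rs$sigmaTheta) +
         gauss(circDiff(theta, rs$orientation + 180), 0, rs$sigmaTheta)
    I <- I + rs$amplitude * exp(-(rho - rs$radius)^2 / (2 * rs$sigmaR^2)) * w
  }
  if (noise == "poisson") {
    set.seed(as.integer(seed))
    I <- matrix(stats::rpois(length(I), I), size[1], size[2])
  }
  mask <- if (beamstopRadius > 0) rho <= beamstopRadius
          else matrix(FALSE, size[1], size[2])
  truth <- if (length(rings)) data.frame(
    ring_index = seq_along(rings),
    radius_px = vapply(rings, `[[`, numeric(1), "radius"),
    amplitude = vapply(rings, `[[`, numeric(1), "amplitude"),
    sigma_r_px = vapply(rings, `[[`, numeric(1), "sigmaR"),
    orientation_deg = vapply(rings, `[[`, numeric(1), "orientation"),
    sigma_theta_deg = vapply(rings, `[[`, numeric(1), "sigmaTheta")
  ) else data.frame(ring_index = integer(), radius_px = numeric(),
                    amplitude = numeric(), sigma_r_px = numeric(),
                    orientation_deg = numeric(), sigma_theta_deg = numeric())
  if (nrow(truth))
    truth$d_nm <- radiusToDspacing(truth$radius_px, geometry)$d_nm
  else truth$d_nm <- numeric()
  img <- new("DiffractionImage", data = I, mask = mask,
             name = name, index = as.integer(index))
  list(image = img, truth = truth)
}

#' Write a scan setup file
#'
#' Plain `key=value` text with keys `x_start`, `x_end`, `x_step`,
#' `y_start`, `y_end`, `y_step` and optionally `order`; the dialect read
#' back by [parseSetup()].
#'
#' @param grid a [ScanGrid-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSetup <- function(grid, path) {
  lines <- c(
    sprintf("x_start=%.10g", grid@xStart), sprintf("x_end=%.10g", grid@xEnd),
    sprintf("x_step=%.10g", grid@xStep),
    sprintf("y_start=%.10g", grid@yStart), sprintf("y_end=%.10g", grid@yEnd),
    sprintf("y_step=%.10g", grid@yStep),
    sprintf("order=%s", grid@order))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a whole synthetic raster scan on disk
#'
#' Writes one 16-bit TIFF per grid cell in raster order
#' (`image_0001.tif`, ...), a beamstop mask (`mask.tif`), the setup file
#' (`setup.txt`), a geometry settings file (`settings.json`) and a
#' ground-truth table (`truth.csv`, one row per true ring per cell) into
#' `dir`. The per-cell ring content is given by `field(row, col)`,
#' a function returning a list of [RingSpec()] (possibly empty).
#'
#' With a fixed seed the folder is byte-identical across runs.
#'
#' @param grid a [ScanGrid-class].
#' @param field `function(row, col)` returning a list of [RingSpec()];
#'   default: the "brainlike" preset of [presetField()].
#' @param dir output directory (created).
#' @param seed base RNG seed; image k uses `seed + k`.
#' @param size,geometry,baseline,noise,beamstopRadius as [makePattern()].
#' @return Invisibly, a list with `dir`, `grid`, `geometry` and the
#'   ground-truth data.frame.
#' @export
makeScan <- function(grid = ScanGrid(0, 0.9, 0.3, 0, 0.9, 0.3),
                     field = presetField("brainlike", grid),
                     dir = tempfile("scan"), seed = 1L,
                     size = c(192L, 192L), geometry = defaultGeometry(size),
                     baseline = 100, noise = "poisson",
                     beamstopRadius = 15) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nCols(grid) * nRows(grid)
  pos <- gridPosition(grid, seq_len(n))
  truth <- list()
  for (k in seq_len(n)) {
    rings <- field(pos$row[k], pos$col[k])
    nm <- sprintf("image_%04d.tif", k)
    pat <- makePattern(size = size, geometry = geometry, rings = rings,
                       baseline = baseline, noise = noise,
                       beamstopRadius = beamstopRadius,
                       seed = as.integer(seed) + k, name = nm, index = k)
    counts <- pmin(pmax(round(pat$image@data), 0), 65535)
    tiff::writeTIFF(counts / 65535, file.path(dir, nm),
                    bits.per.sample = 16L, compression = "none")
    if (nrow(pat$truth)) {
      pat$truth <- cbind(data.frame(image = nm, row = pos$row[k],
                                    col = pos$col[k]), pat$truth)
      truth[[length(truth) + 1L]] <- pat$truth
    }
  }
  maskImg <- makePattern(size = size, geometry = geometry, rings = list(),
                         baseline = 0, noise = "none",
                         beamstopRadius = beamstopRadius)$image
  tiff::writeTIFF(matrix(as.numeric(maskImg@mask), size[1], size[2]),
                  file.path(dir, "mask.tif"), bits.per.sample = 8L,
                  compression = "none")
  writeSetup(grid, file.path(dir, "setup.txt"))
  writeSettings(geometry, file.path(dir, "settings.json"))
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(image = character(), row = integer(), col = integer())
  utils::write.csv(truthDf, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(dir = dir, grid = grid, geometry = geometry,
                 truth = truthDf))
}

#' Preset per-cell ring fields for synthetic scans
#'
#' * `"single_ring"`: the same oriented ring (r = 60 px, phi0 = 30,
#'   sigma_theta = 10) in every cell.
#' * `"brainlike"`: tissue-map-like variation -- ring radius drifts
#'   linearly from 55 to 65 px across columns (a d-spacing gradient, as
#'   across a gray/white matter boundary), the left half of the grid is
#'   oriented with phi0 varying by row, the right half isotropic.
#' * `"isotropic"`: one isotropic ring (r = 60 px) everywhere.
#'
#' Amplitudes default to 100 counts on a baseline of 100, i.e. a
#' signal-to-noise ratio of 10 at the arc peak under Poisson noise.
#'
#' @param preset one of `"single_ring"`, `"brainlike"`, `"isotropic"`.
#' @param grid the [ScanGrid-class] the field will be used on.
#' @param amplitude arc peak amplitude in counts.
#' @return `function(row, col)` returning a list of [RingSpec()].
#' @export
presetField <- function(preset = c("brainlike", "single_ring", "isotropic"),
                        grid, amplitude = 100) {
  preset <- match.arg(preset)
  nc <- nCols(grid); nr <- nRows(grid)
  switch(preset,
    single_ring = function(row, col)
      list(RingSpec(60, amplitude, sigmaR = 3, orientation = 30,
                    sigmaTheta = 10)),
    isotropic = function(row, col)
      list(RingSpec(60, amplitude, sigmaR = 3)),
    brainlike = function(row, col) {
      radius <- if (nc > 1) 55 + 10 * (col - 1) / (nc - 1) else 60
      oriented <- col <= ceiling(nc / 2)
      if (oriented)
        list(RingSpec(radius, amplitude, sigmaR = 3,
                      orientation = (20 + 150 * (row - 1) /
                                       max(1, nr - 1)) %% 180,
                      sigmaTheta = 15))
      else
        list(RingSpec(radius, amplitude, sigmaR = 3))
    })
}
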