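## Image loading, masking, Cartesian -> polar resampling and the two 1D
## integrations (azimuthal and radial) that everything downstream consumes.
##
## Conventions: pixel coordinates are 0-based with x = column and y = row,
## pixel centers at integers. Azimuth theta is measured counter-clockwise
## from the +x axis of the displayed image (row 0 at top), i.e. a point at
## angle theta sits at x = cx + r cos(theta), y = cy - r sin(theta).

#' Load a diffraction image from disk
#'
#' Reads a single-frame TIFF (the numbered-series dialect written by area
#' detectors and by [makeScan()]). An optional blank (instrumental
#' background) image is subtracted with the result clipped at zero, and
#' an optional mask file (nonzero = excluded) is applied. Pixels whose
#' raw value is below `gapSentinel` (detector gap encoding) are masked.
#'
#' @param path path to a TIFF file.
#' @param blank optional blank image: a [DiffractionImage-class], a
#'   matrix, or a TIFF path. Subtracted from the data, clipped at 0.
#' @param mask optional mask: logical/numeric matrix or TIFF path;
#'   nonzero/`TRUE` pixels are excluded.
#' @param gapSentinel raw values strictly below this are detector gaps
#'   (default 0).
#' @param index 1-based sequence index recorded on the image.
#' @return A [DiffractionImage-class].
#' @export
loadImage <- function(path, blank = NULL, mask = NULL, gapSentinel = 0,
                      index = 1L) {
  if (grepl("\\.(h5|hdf5|nxs)$", path, ignore.case = TRUE))
    stop("HDF5 input is not supported by this build; ",
         "convert the stack to a numbered TIFF series")
  if (!file.exists(path)) stop("cannot read image: ", path)
  raw <- readImageMatrix(path)
  gap <- !is.na(raw) & raw < gapSentinel
  if (!is.null(blank)) {
    b <- if (is(blank, "DiffractionImage")) blank@data
         else if (is.character(blank)) readImageMatrix(blank)
         else as.matrix(blank)
    if (!identical(dim(b), dim(raw)))
      stop("blank image shape ", paste(dim(b), collapse = "x"),
           " does not match image shape ", paste(dim(raw), collapse = "x"))
    raw <- pmax(raw - b, 0)
  }
  m <- gap
  if (!is.null(mask)) {
    um <- if (is.character(mask)) readImageMatrix(mask) != 0
          else if (is.logical(mask)) mask
          else as.matrix(mask) != 0
    if (!identical(dim(um), dim(raw)))
      stop("mask shape does not match image shape")
    m <- m | um
  }
  new("DiffractionImage", data = raw, mask = m,
      name = basename(path), index = as.integer(index))
}

## Read a TIFF into a numeric matrix of raw counts (first channel).
readImageMatrix <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

## Vectorized bilinear sampling of `values` (NA = masked) at 0-based
## (x, y) positions. A sample is NA if any of its four neighbours is
## masked or out of bounds.
bilinearSample <- function(values, xs, ys) {
  nr <- nrow(values); nc <- ncol(values)
  out <- rep(NA_real_, length(xs))
  j0 <- floor(xs); i0 <- floor(ys)
  # clamp exact upper edge into the last cell
  j0[xs == nc - 1] <- nc - 2; i0[ys == nr - 1] <- nr - 2
  ok <- j0 >= 0 & j0 <= nc - 2 & i0 >= 0 & i0 <= nr - 2 &
        is.finite(xs) & is.finite(ys)
  if (!any(ok)) return(out)
  j0 <- j0[ok]; i0 <- i0[ok]
  fx <- xs[ok] - j0; fy <- ys[ok] - i0
  # R matrices are 1-based [row, col]
  idx <- function(i, j) i + 1L + nr * j
  v00 <- values[idx(i0, j0)];     v01 <- values[idx(i0, j0 + 1)]
  v10 <- values[idx(i0 + 1, j0)]; v11 <- values[idx(i0 + 1, j0 + 1)]
  out[ok] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
             fy       * ((1 - fx) * v10 + fx * v11)
  out
}

#' Resample a diffraction image onto a polar grid
#'
#' Builds the polar intensity field I(theta, r) about the beam center.
#' Each (theta, r) bin takes the mean of bilinear samples of unmasked
#' pixels spaced roughly one pixel apart along the bin's arc; the
#' fraction of valid samples is recorded as the bin weight. Bins with no
#' valid sample are `NA` with weight 0. Bin values are means (not sums),
#' so wedge width does not rescale profile amplitudes.
#'
#' @param image a [DiffractionImage-class].
#' @param geometry a [DetectorGeometry-class]; only the beam center is
#'   used here.
#' @param nTheta number of azimuthal bins over 360 degrees (default 360,
#'   i.e. 1 degree bins).
#' @param rMax maximal radius in pixels; defaults to the distance from
#'   the beam center to the nearest image edge (full circles only). Must
#'   not exceed the distance to the farthest corner.
#' @param rStep radial bin width in pixels (default 1).
#' @return A [PolarImage-class].
#' @export
toPolar <- function(image, geometry, nTheta = 360L, rMax = NULL,
                    rStep = 1) {
  d <- dim(image@data)
  cx <- geometry@beamCenter[1]; cy <- geometry@beamCenter[2]
  corners <- rbind(c(0, 0), c(d[2] - 1, 0), c(0, d[1] - 1),
                   c(d[2] - 1, d[1] - 1))
  farthest <- max(sqrt((corners[, 1] - cx)^2 + (corners[, 2] - cy)^2))
  diagpx <- sqrt((d[1] - 1)^2 + (d[2] - 1)^2)
  if (cx < -diagpx || cx > d[2] - 1 + diagpx ||
      cy < -diagpx || cy > d[1] - 1 + diagpx)
    stop("geometry error: beam center implausibly far outside the image")
  if (is.null(rMax))
    rMax <- floor(min(cx, d[2] - 1 - cx, cy, d[1] - 1 - cy))
  if (rMax > farthest)
    stop("rMax exceeds the distance to the farthest image corner")
  if (rMax < rStep) stop("rMax too small for the radial bin width")
  nR <- as.integer(ceiling(rMax / rStep))
  thetaStep <- 360 / nTheta
  dThetaRad <- thetaStep * pi / 180
  vals <- imageValues(image)
  out <- matrix(NA_real_, nTheta, nR)
  wgt <- matrix(0, nTheta, nR)
  thetaC <- (seq_len(nTheta) - 0.5) * thetaStep
  for (j in seq_len(nR)) {
    rc <- (j - 0.5) * rStep
    nS <- max(1L, as.integer(round(rc * dThetaRad / 1.0)))
    sub <- ((seq_len(nS) - 0.5) / nS - 0.5) * thetaStep  # offsets in deg
    th <- rep(thetaC, each = nS) + rep(sub, times = nTheta)
    rad <- th * pi / 180
    xs <- cx + rc * cos(rad)
    ys <- cy - rc * sin(rad)
    s <- bilinearSample(vals, xs, ys)
    sm <- matrix(s, nrow = nS)
    nOk <- colSums(!is.na(sm))
    tot <- colSums(sm, na.rm = TRUE)
    out[, j] <- ifelse(nOk > 0, tot / nOk, NA_real_)
    wgt[, j] <- nOk / nS
  }
  new("PolarImage", values = out, weight = wgt,
      thetaStep = thetaStep, rStep = rStep)
}

## Indices of theta bins whose centers fall inside a (center, width)
## wedge, wrap-aware.
wedgeBins <- function(polar, wedge) {
  thc <- thetaCenters(polar)
  dlt <- (thc - wedge[1] + 180) %% 360 - 180
  which(abs(dlt) <= wedge[2] / 2)
}

#' Azimuthal integration: intensity versus radius
#'
#' Averages the polar intensity field over the azimuthal bins of a wedge
#' (wrap-aware), producing the 1D intensity-versus-radius trace used for
#' ring detection and radial Gaussian fitting. The average weights each
#' bin by its unmasked-pixel fraction; missing bins are excluded. Radii
#' where every bin in the wedge is missing are flagged `NA`.
#'
#' @param polar a [PolarImage-class].
#' @param wedge numeric(2) `(center, width)` in degrees, width in
#'   `(0, 360]`. Default: the full circle.
#' @return A [RadialProfile-class].
#' @export
azimuthalIntegrate <- function(polar, wedge = c(0, 360)) {
  if (wedge[2] <= 0 || wedge[2] > 360)
    stop("wedge width must be in (0, 360]")
  sel <- wedgeBins(polar, wedge)
  v <- polar@values[sel, , drop = FALSE]
  w <- polar@weight[sel, , drop = FALSE]
  w[is.na(v)] <- 0
  v[is.na(v)] <- 0
  wsum <- colSums(w)
  prof <- ifelse(wsum > 0, colSums(v * w) / wsum, NA_real_)
  RadialProfile(rCenters(polar), prof, wedge)
}

#' Radial integration: intensity versus azimuth
#'
#' Sums the polar intensity field over the radial bins of a band,
#' producing the 1D intensity-versus-angle trace from which ring
#' orientation and angular spread are fitted.
#'
#' @param polar a [PolarImage-class].
#' @param band numeric(2) `(rLo, rHi)` in pixels, `0 <= rLo < rHi`.
#' @return An [AzimuthalProfile-class].
#' @export
radialIntegrate <- function(polar, band) {
  rc <- rCenters(polar)
  if (band[1] < 0 || band[2] <= band[1] || band[1] > max(rc))
    stop("empty or invalid radial band")
  sel <- which(rc >= band[1] & rc <= band[2])
  if (!length(sel)) stop("empty radial band")
  v <- polar@values[, sel, drop = FALSE]
  nOk <- rowSums(!is.na(v))
  s <- rowSums(v, na.rm = TRUE)
  # rescale partial sums so a few missing bins do not dent the trace
  s <- ifelse(nOk > 0, s * length(sel) / nOk, NA_real_)
  AzimuthalProfile(thetaCenters(polar), s, band)
}

#' Per-image background statistics
#'
#' Mean pixel value and pixel count outside the mask (or, when no mask is
#' given, outside radius `rmin` from the beam center). Detector gap
#' pixels never contribute. These numbers are written to
#' `BackgroundSummary.csv` and can later be used to scale intensities
#' across a series.
#'
#' @param image a [DiffractionImage-class].
#' @param mask optional logical matrix (`TRUE` = inside the masked area).
#' @param rmin radius in pixels; used when `mask` is absent.
#' @param geometry a [DetectorGeometry-class] (needed with `rmin`).
#' @return A list with `mean` (NA when no pixel qualifies) and `n`.
#' @export
backgroundSummary <- function(image, mask = NULL, rmin = NULL,
                              geometry = NULL) {
  vals <- imageValues(image)
  if (is.null(mask)) {
    if (is.null(rmin) || is.null(geometry))
      stop("either a mask or rmin + geometry must be given")
    d <- dim(vals)
    xs <- matrix(rep(0:(d[2] - 1), each = d[1]), d[1], d[2])
    ys <- matrix(rep(0:(d[1] - 1), times = d[2]), d[1], d[2])
    outside <- sqrt((xs - geometry@beamCenter[1])^2 +
                    (ys - geometry@beamCenter[2])^2) > rmin
  } else {
    if (!identical(dim(mask), dim(vals)))
      stop("mask shape does not match image shape")
    outside <- !mask
  }
  sel <- outside & !is.na(vals)
  n <- sum(sel)
  list(mean = if (n > 0) mean(vals[sel]) else NA_real_, n = n)
}
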