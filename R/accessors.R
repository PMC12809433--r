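## Constructors, accessors and show() methods for the core classes.

#' Construct a DetectorGeometry
#'
#' @param beamCenter numeric(2), beam center (x, y) in 0-based pixel
#'   coordinates.
#' @param sdd sample-to-detector distance in mm.
#' @param pixelSize pixel size in mm.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param imageDim optional integer(2) image dimension (rows, cols); if
#'   given, a beam center outside twice the image extent triggers a
#'   warning (not an error).
#' @return A [DetectorGeometry-class] object.
#' @examples
#' geo <- DetectorGeometry(c(96, 96), sdd = 2000, pixelSize = 0.172,
#'                         wavelength = 1.033)
#' radiusToDspacing(100, geo)
#' @export
DetectorGeometry <- function(beamCenter, sdd, pixelSize, wavelength,
                             imageDim = NULL) {
  obj <- new("DetectorGeometry", beamCenter = as.numeric(beamCenter),
             sdd = as.numeric(sdd), pixelSize = as.numeric(pixelSize),
             wavelength = as.numeric(wavelength))
  if (!is.null(imageDim)) {
    ext <- rev(as.numeric(imageDim))   # (x extent, y extent)
    if (any(beamCenter < -ext | beamCenter > 2 * ext))
      warning("beam center lies far outside the image bounds")
  }
  obj
}

#' @describeIn DetectorGeometry beam center (x, y) in pixels.
#' @param object,x a `DetectorGeometry`.
#' @export
beamCenter <- function(object) object@beamCenter

#' @describeIn DetectorGeometry sample-to-detector distance in mm.
#' @export
sdd <- function(object) object@sdd

#' @describeIn DetectorGeometry pixel size in mm.
#' @export
pixelSize <- function(object) object@pixelSize

#' @describeIn DetectorGeometry wavelength in Angstrom.
#' @export
wavelength <- function(object) object@wavelength

setMethod("show", "DetectorGeometry", function(object) {
  cat("DetectorGeometry\n")
  cat(sprintf("  beam center : (%.3f, %.3f) px\n",
              object@beamCenter[1], object@beamCenter[2]))
  cat(sprintf("  sdd         : %.4g mm\n", object@sdd))
  cat(sprintf("  pixel size  : %.4g mm\n", object@pixelSize))
  cat(sprintf("  wavelength  : %.6g A\n", object@wavelength))
})

#' Construct a DiffractionImage
#'
#' Wraps a numeric intensity matrix; pixels under `mask` or with values
#' below `gapSentinel` (detector gap encoding) are excluded from all
#' analysis.
#'
#' @param data numeric matrix `[row, col]` of intensities.
#' @param mask optional logical matrix (`TRUE` = excluded) of equal shape.
#' @param name source label.
#' @param index 1-based position in the scan sequence.
#' @param gapSentinel pixels with values strictly below this are treated
#'   as detector gaps and masked (default 0, i.e. any negative value).
#' @return A [DiffractionImage-class].
#' @export
DiffractionImage <- function(data, mask = NULL, name = "", index = 1L,
                             gapSentinel = 0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(mask)) mask <- matrix(FALSE, nrow(data), ncol(data))
  mask <- mask | (!is.na(data) & data < gapSentinel) | is.na(data)
  new("DiffractionImage", data = data, mask = mask,
      name = as.character(name), index = as.integer(index))
}

#' @describeIn DiffractionImage intensity matrix with `NA` at masked pixels.
#' @param object a `DiffractionImage`.
#' @export
imageValues <- function(object) {
  v <- object@data
  v[object@mask] <- NA_real_
  v
}

#' @describeIn DiffractionImage logical exclusion mask.
#' @export
imageMask <- function(object) object@mask

#' @describeIn DiffractionImage source name.
#' @export
imageName <- function(object) object@name

setMethod("show", "DiffractionImage", function(object) {
  cat(sprintf("DiffractionImage '%s' (#%d): %d x %d px, %d masked\n",
              object@name, object@index, nrow(object@data),
              ncol(object@data), sum(object@mask)))
})

setMethod("dim", "DiffractionImage", function(x) dim(x@data))

#' @describeIn PolarImage intensity matrix `[thetaBin, rBin]` (`NA` where
#'   the bin has no unmasked source pixel).
#' @param object a `PolarImage`.
#' @export
polarValues <- function(object) object@values

#' @describeIn PolarImage per-bin fraction of unmasked samples.
#' @export
polarWeight <- function(object) object@weight

#' @describeIn PolarImage azimuthal bin centers in degrees.
#' @export
thetaCenters <- function(object) {
  (seq_len(nrow(object@values)) - 0.5) * object@thetaStep
}

#' @describeIn PolarImage radial bin centers in pixels.
#' @export
rCenters <- function(object) {
  (seq_len(ncol(object@values)) - 0.5) * object@rStep
}

setMethod("show", "PolarImage", function(object) {
  cat(sprintf(
    "PolarImage: %d theta bins x %d r bins (%.3g deg x %.3g px), %d missing\n",
    nrow(object@values), ncol(object@values), object@thetaStep,
    object@rStep, sum(is.na(object@values))))
})

#' Construct a RadialProfile
#' @param r radial grid (pixels, strictly increasing).
#' @param intensity mean intensity per bin.
#' @param wedge numeric(2) `(center, width)` in degrees.
#' @return A [RadialProfile-class].
#' @export
RadialProfile <- function(r, intensity, wedge = c(0, 360)) {
  new("RadialProfile", r = as.numeric(r), intensity = as.numeric(intensity),
      wedge = as.numeric(wedge))
}

#' Construct an AzimuthalProfile
#' @param theta azimuthal grid (degrees in `[0, 360)`, strictly increasing).
#' @param intensity summed intensity per bin.
#' @param band numeric(2) radial band `(rLo, rHi)` in pixels.
#' @return An [AzimuthalProfile-class].
#' @export
AzimuthalProfile <- function(theta, intensity, band) {
  new("AzimuthalProfile", theta = as.numeric(theta),
      intensity = as.numeric(intensity), band = as.numeric(band))
}

setMethod("show", "RadialProfile", function(object) {
  cat(sprintf("RadialProfile: %d bins, r in [%.1f, %.1f] px, wedge %g +/- %g deg\n",
              length(object@r), min(object@r), max(object@r),
              object@wedge[1], object@wedge[2] / 2))
})

setMethod("show", "AzimuthalProfile", function(object) {
  cat(sprintf("AzimuthalProfile: %d bins, band [%.1f, %.1f] px\n",
              length(object@theta), object@band[1], object@band[2]))
})

#' Construct a ScanGrid
#'
#' @param xStart,xEnd,yStart,yEnd scan extents in mm.
#' @param xStep,yStep step sizes in mm.
#' @param order `"raster"` (row-major, default) or `"serpentine"`.
#' @return A [ScanGrid-class]. Column and row counts are
#'   `round((end - start)/step) + 1`; a warning is issued when the extent
#'   is not an integral number of steps.
#' @examples
#' g <- ScanGrid(0, 0.9, 0.3, 0, 0.3, 0.3)
#' nCols(g) * nRows(g)  # 8 positions
#' @export
ScanGrid <- function(xStart, xEnd, xStep, yStart, yEnd, yStep,
                     order = "raster") {
  if (xStep == 0 || yStep == 0) stop("step sizes must be nonzero")
  if ((xEnd - xStart) * xStep < 0 || (yEnd - yStart) * yStep < 0)
    stop("inverted range requires a negative step")
  nc <- (xEnd - xStart) / xStep
  nr <- (yEnd - yStart) / yStep
  if (abs(nc - round(nc)) > 1e-6 || abs(nr - round(nr)) > 1e-6)
    warning("scan extent is not an integral number of steps; rounding")
  new("ScanGrid", xStart = xStart, xEnd = xEnd, xStep = xStep,
      yStart = yStart, yEnd = yEnd, yStep = yStep,
      nCols = as.integer(round(nc)) + 1L, nRows = as.integer(round(nr)) + 1L,
      order = order)
}

#' @describeIn ScanGrid number of columns.
#' @param object a `ScanGrid`.
#' @export
nCols <- function(object) object@nCols

#' @describeIn ScanGrid number of rows.
#' @export
nRows <- function(object) object@nRows

#' @describeIn ScanGrid map a 1-based sequence index to grid/physical
#'   coordinates; returns a data.frame with `row`, `col` (1-based) and
#'   `x_mm`, `y_mm`.
#' @param index integer vector of 1-based image sequence indices.
#' @export
gridPosition <- function(object, index) {
  k <- as.integer(index) - 1L
  if (any(k < 0L) || any(k >= object@nCols * object@nRows))
    stop("sequence index outside the scan grid")
  row <- k %/% object@nCols
  col <- k %% object@nCols
  if (object@order == "serpentine") {
    rev <- row %% 2L == 1L
    col[rev] <- object@nCols - 1L - col[rev]
  }
  data.frame(
    row = row + 1L, col = col + 1L,
    x_mm = object@xStart + col * object@xStep,
    y_mm = object@yStart + row * object@yStep
  )
}

setMethod("show", "ScanGrid", function(object) {
  cat(sprintf("ScanGrid: %d cols x %d rows (%s order)\n", object@nCols,
              object@nRows, object@order))
  cat(sprintf("  x: %g to %g mm, step %g\n", object@xStart, object@xEnd,
              object@xStep))
  cat(sprintf("  y: %g to %g mm, step %g\n", object@yStart, object@yEnd,
              object@yStep))
})

#' @describeIn HeatmapLayer per-cell scalar values (`NA` = missing).
#' @param object a `HeatmapLayer`.
#' @export
mapValues <- function(object) object@values

#' @describeIn HeatmapLayer overlay list (`angle`, `magnitude`, `spread`)
#'   or an empty list.
#' @export
mapOverlay <- function(object) object@overlay

#' @describeIn HeatmapLayer the representation name.
#' @export
mapRepresentation <- function(object) object@representation

setMethod("show", "HeatmapLayer", function(object) {
  cat(sprintf("HeatmapLayer '%s': %d x %d cells (%d missing)%s\n",
              object@representation, nrow(object@values),
              ncol(object@values), sum(is.na(object@values)),
              if (length(object@overlay)) ", with orientation overlay"
              else ""))
})
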