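#' @import methods
NULL

#' Detector geometry for a scanning diffraction experiment
#'
#' Holds the experimental geometry that links a radial distance on the
#' detector (pixels) to a scattering angle and hence a d-spacing: beam
#' center, sample-to-detector distance, pixel size and X-ray wavelength.
#'
#' @slot beamCenter numeric(2), beam center (x, y) in 0-based pixel
#'   coordinates (x = column, y = row; pixel centers at integers).
#' @slot sdd numeric(1), sample-to-detector distance in mm.
#' @slot pixelSize numeric(1), detector pixel size in mm (square pixels).
#' @slot wavelength numeric(1), X-ray wavelength in Angstrom.
#'
#' @seealso [DetectorGeometry()], [radiusToDspacing()], [calibrateSdd()]
#' @exportClass DetectorGeometry
setClass("DetectorGeometry",
  representation(
    beamCenter = "numeric",
    sdd        = "numeric",
    pixelSize  = "numeric",
    wavelength = "numeric"
  )
)

setValidity("DetectorGeometry", function(object) {
  msg <- character()
  if (length(object@beamCenter) != 2L || any(!is.finite(object@beamCenter)))
    msg <- c(msg, "beamCenter must be two finite numbers (x, y)")
  if (length(object@sdd) != 1L || !is.finite(object@sdd) || object@sdd <= 0)
    msg <- c(msg, "sdd must be a single positive number (mm)")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (mm)")
  if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive number (Angstrom)")
  if (length(msg)) msg else TRUE
})

#' A single 2D diffraction image
#'
#' Detector intensities plus an exclusion mask. Pixels with intensities
#' below the gap sentinel (detector module gaps on photon-counting
#' detectors are conventionally encoded as negative values) are masked on
#' construction and never contribute to any downstream profile or summary.
#'
#' @slot data numeric matrix of intensities, indexed `[row, col]`.
#' @slot mask logical matrix of the same shape; `TRUE` = excluded.
#' @slot name character(1), source file name (or a label).
#' @slot index integer(1), 1-based position in the scan sequence.
#'
#' @seealso [loadImage()], [makePattern()]
#' @exportClass DiffractionImage
setClass("DiffractionImage",
  representation(
    data  = "matrix",
    mask  = "matrix",
    name  = "character",
    index = "integer"
  )
)

setValidity("DiffractionImage", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!identical(dim(object@data), dim(object@mask)))
    msg <- c(msg, "mask must have the same shape as data")
  if (length(msg)) msg else TRUE
})

#' Polar-resampled intensity field I(theta, r)
#'
#' The image resampled onto a regular azimuth-by-radius grid about the
#' beam center: the substrate for azimuthal/radial integration and for
#' both ring-detection methods. Bin (i, j) covers azimuth
#' `[(i-1)*thetaStep, i*thetaStep)` degrees and radius
#' `[(j-1)*rStep, j*rStep)` pixels; azimuth runs counter-clockwise from
#' the +x axis of the displayed image (row 0 at top). Bins with no
#' unmasked source pixel have weight 0 and value `NA` (missing, never a
#' silent zero).
#'
#' @slot values numeric matrix `[thetaBin, rBin]` of mean intensities.
#' @slot weight numeric matrix of the fraction of unmasked samples per bin.
#' @slot thetaStep numeric(1), azimuthal bin width in degrees.
#' @slot rStep numeric(1), radial bin width in pixels.
#'
#' @seealso [toPolar()], [azimuthalIntegrate()], [radialIntegrate()]
#' @exportClass PolarImage
setClass("PolarImage",
  representation(
    values    = "matrix",
    weight    = "matrix",
    thetaStep = "numeric",
    rStep     = "numeric"
  )
)

setValidity("PolarImage", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@weight)))
    msg <- c(msg, "values and weight must have the same shape")
  if (object@thetaStep <= 0 || object@rStep <= 0)
    msg <- c(msg, "bin widths must be positive")
  if (abs(nrow(object@values) * object@thetaStep - 360) > 1e-8)
    msg <- c(msg, "theta bins must cover exactly [0, 360) degrees")
  if (length(msg)) msg else TRUE
})

#' 1D radial intensity profile within an angular wedge
#'
#' @slot r numeric, radial bin centers in pixels (strictly increasing).
#' @slot intensity numeric, mean intensity per radial bin (NA = missing).
#' @slot wedge numeric(2), (center, width) of the angular wedge in degrees.
#' @exportClass RadialProfile
setClass("RadialProfile",
  representation(r = "numeric", intensity = "numeric", wedge = "numeric")
)

setValidity("RadialProfile", function(object) {
  msg <- character()
  if (length(object@r) != length(object@intensity))
    msg <- c(msg, "r and intensity lengths differ")
  if (any(diff(object@r) <= 0)) msg <- c(msg, "r must be strictly increasing")
  if (length(object@wedge) != 2L || object@wedge[2] <= 0 ||
      object@wedge[2] > 360)
    msg <- c(msg, "wedge must be (center, width) with width in (0, 360]")
  if (length(msg)) msg else TRUE
})

#' 1D azimuthal intensity profile over a radial band
#'
#' @slot theta numeric, azimuthal bin centers in degrees over [0, 360).
#' @slot intensity numeric, summed intensity per azimuthal bin.
#' @slot band numeric(2), radial band (rLo, rHi) in pixels.
#' @exportClass AzimuthalProfile
setClass("AzimuthalProfile",
  representation(theta = "numeric", intensity = "numeric", band = "numeric")
)

setValidity("AzimuthalProfile", function(object) {
  msg <- character()
  if (length(object@theta) != length(object@intensity))
    msg <- c(msg, "theta and intensity lengths differ")
  if (any(diff(object@theta) <= 0))
    msg <- c(msg, "theta must be strictly increasing")
  if (any(object@theta < 0 | object@theta >= 360))
    msg <- c(msg, "theta centers must lie in [0, 360)")
  if (length(object@band) != 2L || object@band[1] < 0 ||
      object@band[2] <= object@band[1])
    msg <- c(msg, "band must be (rLo, rHi) with 0 <= rLo < rHi")
  if (length(msg)) msg else TRUE
})

#' Raster-scan geometry
#'
#' Maps the 1-based image sequence index to a grid cell (row, col) and a
#' physical stage position (x, y) in mm. The default raster order is
#' row-major and non-serpentine; serpentine (boustrophedon) order is
#' available via `order = "serpentine"`.
#'
#' @slot xStart,xEnd,yStart,yEnd numeric(1), scan extents in mm.
#' @slot xStep,yStep numeric(1), step sizes in mm (sign matches direction).
#' @slot nCols,nRows integer(1), grid dimensions.
#' @slot order character(1), `"raster"` or `"serpentine"`.
#' @seealso [ScanGrid()], [parseSetup()], [gridPosition()]
#' @exportClass ScanGrid
setClass("ScanGrid",
  representation(
    xStart = "numeric", xEnd = "numeric", xStep = "numeric",
    yStart = "numeric", yEnd = "numeric", yStep = "numeric",
    nCols = "integer", nRows = "integer", order = "character"
  )
)

setValidity("ScanGrid", function(object) {
  msg <- character()
  if (object@nCols < 1L || object@nRows < 1L)
    msg <- c(msg, "grid must have at least one row and one column")
  if (object@xStep == 0 || object@yStep == 0)
    msg <- c(msg, "step sizes must be nonzero")
  if (!object@order %in% c("raster", "serpentine"))
    msg <- c(msg, "order must be 'raster' or 'serpentine'")
  if (length(msg)) msg else TRUE
})

#' One per-position scalar field of a scanned sample
#'
#' A heatmap layer in one of the five standard representations: total
#' intensity, d-spacing of the best ring, angular range (angle sigma) of
#' the best ring, orientation vector field over intensity, or elliptical
#' representation. Cells whose image had no qualifying ring are `NA`
#' (missing), never zero. The optional overlay carries per-cell
#' orientation glyph parameters (angle in display degrees, magnitude,
#' spread in radians); overlay entries are `NA` exactly where the best
#' ring is absent or excluded (isotropic diffraction).
#'
#' @slot values numeric matrix `[nRows, nCols]`.
#' @slot representation character(1), one of `"total_intensity"`,
#'   `"d_space"`, `"angular_range"`, `"vector_field"`, `"elliptical"`.
#' @slot overlay list with numeric matrices `angle`, `magnitude`, `spread`
#'   (empty list when the representation has no overlay).
#' @slot grid the [ScanGrid-class] the layer was built on.
#' @seealso [buildMap()], [rbfInterpolate()], [exportMap()]
#' @exportClass HeatmapLayer
setClass("HeatmapLayer",
  representation(
    values = "matrix",
    representation = "character",
    overlay = "list",
    grid = "ScanGrid"
  )
)

setValidity("HeatmapLayer", function(object) {
  msg <- character()
  reps <- c("total_intensity", "d_space", "angular_range", "vector_field",
            "elliptical")
  if (!object@representation %in% reps)
    msg <- c(msg, paste("representation must be one of:",
                        paste(reps, collapse = ", ")))
  if (length(object@overlay) &&
      !all(c("angle", "magnitude", "spread") %in% names(object@overlay)))
    msg <- c(msg, "overlay must have angle, magnitude and spread")
  for (nm in names(object@overlay))
    if (!identical(dim(object@overlay[[nm]]), dim(object@values)))
      msg <- c(msg, "overlay matrices must match the values shape")
  if (length(msg)) msg else TRUE
})
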