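## Detector calibration: circle fitting on clicked calibrant points,
## sample-to-detector distance from a calibrant ring, and pixel radius <->
## d-spacing conversion via Bragg's law. The full atan/asin forms are used
## throughout (no small-angle approximation), so the conversions remain
## valid at wide scattering angles.

#' Calibrant specification
#'
#' A calibration standard identified by the d-spacing of its first-order
#' (principal) reflection. The default is silver behenate, the standard
#' small-angle calibrant, with a first-order d of 58.38 Angstrom.
#'
#' @param name text label.
#' @param dSpacing first-order d-spacing in Angstrom.
#' @return A list with class `"CalibrantSpec"`.
#' @export
CalibrantSpec <- function(name = "silver behenate", dSpacing = 58.38) {
  stopifnot(is.numeric(dSpacing), dSpacing > 0)
  structure(list(name = name, dSpacing = dSpacing), class = "CalibrantSpec")
}

#' Least-squares circle fit
#'
#' Fits a circle to clicked points on a calibrant ring: an algebraic
#' (Kasa) fit followed by one Gauss-Newton refinement step of the
#' geometric residual. Used to locate the beam center and the calibrant
#' ring radius from at least three non-collinear points.
#'
#' @param points numeric matrix or data.frame with two columns (x, y), or
#'   a list of length-2 vectors; at least 3 non-collinear points.
#' @return A list with `center` (x, y), `radius` (px) and `rms`, the
#'   root-mean-square of the distances from the points to the fitted
#'   circle.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 6)[-6]
#' fitCircle(cbind(512 + 100 * cos(th), 512 + 100 * sin(th)))
#' @export
fitCircle <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, as.numeric))
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("calibration error: at least 3 points are required")
  x <- points[, 1]; y <- points[, 2]
  # Kasa fit: minimize || x^2 + y^2 - 2ax - 2by - c ||
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("calibration error: collinear points (singular system)"))
  qrA <- qr(A)
  if (qrA$rank < 3L)
    stop("calibration error: collinear points (singular system)")
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  # One Gauss-Newton step on the geometric residual d_i - r
  for (it in 1:2) {
    dx <- x - cx; dy <- y - cy
    d <- sqrt(dx^2 + dy^2)
    if (any(d < 1e-12)) break
    J <- cbind(-dx / d, -dy / d, -1)
    res <- d - r
    step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
    if (is.null(step)) break
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
  }
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  list(center = c(cx, cy), radius = r, rms = sqrt(mean((d - r)^2)))
}

#' Sample-to-detector distance from a calibrant ring
#'
#' Given the measured radius of the calibrant's first-order ring, the
#' distance follows from Bragg's law:
#' `sdd = r * pixelSize / tan(2 * asin(wavelength / (2 d)))`.
#'
#' @param ringRadiusPx measured ring radius in pixels.
#' @param calibrant a [CalibrantSpec()].
#' @param pixelSize pixel size in mm.
#' @param wavelength X-ray wavelength in Angstrom.
#' @return Sample-to-detector distance in mm.
#' @export
calibrateSdd <- function(ringRadiusPx, calibrant = CalibrantSpec(),
                         pixelSize, wavelength) {
  if (wavelength >= 2 * calibrant$dSpacing)
    stop("no solution: wavelength >= 2 * d (Bragg angle unsolvable)")
  if (ringRadiusPx == 0)
    warning("zero ring radius gives a degenerate sdd of 0")
  twoTheta <- 2 * asin(wavelength / (2 * calibrant$dSpacing))
  ringRadiusPx * pixelSize / tan(twoTheta)
}

#' Convert a pixel radius to a d-spacing
#'
#' `2theta = atan(r * pixelSize / sdd)`, `d = wavelength / (2 sin(theta))`.
#' d is strictly decreasing in r.
#'
#' @param r radius in pixels (> 0); vectorized.
#' @param geometry a [DetectorGeometry-class].
#' @return A data.frame with columns `d_A` (Angstrom) and `d_nm`.
#' @export
radiusToDspacing <- function(r, geometry) {
  if (any(r <= 0)) stop("undefined d-spacing: r must be > 0")
  twoTheta <- atan(r * geometry@pixelSize / geometry@sdd)
  dA <- geometry@wavelength / (2 * sin(twoTheta / 2))
  data.frame(d_A = dA, d_nm = dA / 10)
}

#' Convert a d-spacing to a pixel radius
#'
#' Inverse of [radiusToDspacing()].
#'
#' @param dA d-spacing in Angstrom (> wavelength/2); vectorized.
#' @param geometry a [DetectorGeometry-class].
#' @return Radius in pixels.
#' @export
dspacingToRadius <- function(dA, geometry) {
  if (any(dA <= geometry@wavelength / 2))
    stop("d-spacing below the Bragg limit wavelength/2")
  twoTheta <- 2 * asin(geometry@wavelength / (2 * dA))
  geometry@sdd * tan(twoTheta) / geometry@pixelSize
}

#' Calibrate a full geometry from clicked calibrant points
#'
#' Fits a circle through the points, takes its center as the beam center
#' and derives the sample-to-detector distance from the calibrant
#' d-spacing.
#'
#' @param points ring points as for [fitCircle()].
#' @param calibrant a [CalibrantSpec()].
#' @param pixelSize pixel size in mm.
#' @param wavelength wavelength in Angstrom.
#' @return A [DetectorGeometry-class].
#' @export
calibrateGeometry <- function(points, calibrant = CalibrantSpec(),
                              pixelSize, wavelength) {
  fit <- fitCircle(points)
  DetectorGeometry(
    beamCenter = fit$center,
    sdd = calibrateSdd(fit$radius, calibrant, pixelSize, wavelength),
    pixelSize = pixelSize, wavelength = wavelength
  )
}

#' Read/write geometry settings as JSON
#'
#' The settings file persists the detector geometry (and optionally the
#' calibrant) between sessions and between the command-line subcommands.
#' Keys: `sdd_mm`, `pixel_size_mm`, `wavelength_A`, `center_x`,
#' `center_y`, `calibrant_name`, `calibrant_d_A`, plus any extra
#' processing parameters passed through unchanged.
#'
#' @param geometry a [DetectorGeometry-class].
#' @param path file path of the JSON settings file.
#' @param calibrant optional [CalibrantSpec()].
#' @param extra named list of additional settings to persist.
#' @return `writeSettings` returns `path` invisibly; `readSettings`
#'   returns a list with `geometry`, `calibrant` and `extra`.
#' @export
writeSettings <- function(geometry, path, calibrant = NULL, extra = list()) {
  obj <- c(list(
    sdd_mm = geometry@sdd,
    pixel_size_mm = geometry@pixelSize,
    wavelength_A = geometry@wavelength,
    center_x = geometry@beamCenter[1],
    center_y = geometry@beamCenter[2]
  ), if (!is.null(calibrant)) list(calibrant_name = calibrant$name,
                                   calibrant_d_A = calibrant$dSpacing),
    extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSettings
#' @export
readSettings <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sdd_mm", "pixel_size_mm", "wavelength_A", "center_x", "center_y")
  if (!all(need %in% names(obj)))
    stop("settings file is missing keys: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  geometry <- DetectorGeometry(
    beamCenter = c(obj$center_x, obj$center_y),
    sdd = obj$sdd_mm, pixelSize = obj$pixel_size_mm,
    wavelength = obj$wavelength_A
  )
  calibrant <- if (!is.null(obj$calibrant_d_A))
    CalibrantSpec(obj$calibrant_name %||% "calibrant", obj$calibrant_d_A)
  list(geometry = geometry, calibrant = calibrant,
       extra = obj[setdiff(names(obj),
                           c(need, "calibrant_name", "calibrant_d_A"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
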