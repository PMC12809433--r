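## Folder-mode processing: walk a folder of numbered diffraction images,
## run detection + fitting on each image not yet processed, and append
## per-image and per-ring rows to the CSV result tables in di_results/.
## Reruns are idempotent: images already named in summary.csv are
## skipped, so a finished folder is left byte-identical.

#' Processing parameter set
#'
#' All tunable parameters of the pipeline with their defaults: polar
#' sampling (1 degree x 1 px bins), MCI (8 wedges of 90 degrees,
#' prominence multiplier 3), LCD (q0 = 10 px, eps = 1e-6, run quantile
#' 0.90, minimal run 30 degrees, group gap 2 px), ring merging
#' (tolerance 10 px), and the isotropy exclusion (threshold 1.0 on both
#' the angle fitting error and the angle sigma in radians).
#'
#' @param ... name = value overrides of any default.
#' @return A named list of class `"diConfig"`.
#' @examples
#' diConfig()$q0          # 10
#' diConfig(minRun = 45)$minRun
#' @export
diConfig <- function(...) {
  cfg <- list(
    nTheta = 360L, rStep = 1, rMax = NULL,
    nRanges = 8L, rangeWidth = 90, clusterTol = 5, peakK = 3, peakFloor = 0,
    q0 = 10, eps = 1e-6, runThresholdQuantile = 0.90, minRun = 30,
    groupGap = 2,
    mergeTol = 10,
    exclusionThreshold = 1.0, exclusionMode = "and",
    rotate90 = FALSE,
    gapSentinel = 0, rminBackground = 0,
    ringFilter = NULL, serpentine = FALSE,
    blank = NULL, maskFile = NULL
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(ov)) cfg[nm] <- list(ov[[nm]])  # NULL-preserving
  structure(cfg, class = "diConfig")
}

#' Parse a raster-scan setup file
#'
#' Reads the plain `key=value` dialect written by [writeSetup()]:
#' required keys `x_start`, `x_end`, `x_step`, `y_start`, `y_end`,
#' `y_step`, optional `order` (`raster`/`serpentine`). Column and row
#' counts are `round((end - start)/step) + 1`, with a warning when the
#' extent is not an integral number of steps.
#'
#' @param path path to the setup file.
#' @return A [ScanGrid-class].
#' @export
parseSetup <- function(path) {
  if (!file.exists(path)) stop("setup file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  names(vals) <- keys
  need <- c("x_start", "x_end", "x_step", "y_start", "y_end", "y_step")
  for (k in need)
    if (!k %in% keys) stop("parse error: missing key '", k, "'")
  num <- suppressWarnings(vapply(vals[need], as.numeric, numeric(1)))
  if (any(is.na(num))) stop("parse error: non-numeric value for '",
                            need[which(is.na(num))[1]], "'")
  if (num["x_step"] == 0) stop("parse error: zero step for 'x_step'")
  if (num["y_step"] == 0) stop("parse error: zero step for 'y_step'")
  ScanGrid(num["x_start"], num["x_end"], num["x_step"],
           num["y_start"], num["y_end"], num["y_step"],
           order = if ("order" %in% keys) vals[["order"]] else "raster")
}

## natural sort: order by the first integer embedded in the filename,
## then lexicographically
naturalSort <- function(x) {
  nums <- suppressWarnings(as.numeric(sub(".*?(\\d+)\\D*$", "\\1", x)))
  x[order(is.na(nums), nums, x)]
}

ringColumns <- c("image", "ring_index", "radius_px", "d_nm", "sigma_r_px",
                 "area", "orientation_deg", "orientation_rad",
                 "angle_sigma_rad", "angle_fit_error",
                 "ang_range_start_deg", "ang_range_end_deg", "excluded")

emptyRings <- function() {
  df <- as.data.frame(setNames(rep(list(numeric()), length(ringColumns)),
                               ringColumns))
  df$image <- character(); df$excluded <- logical()
  df$ring_index <- integer()
  df
}

## does a ring pass the rings-of-interest filter?
ringSelected <- function(rings, filter) {
  if (is.null(filter) || !nrow(rings)) return(rep(TRUE, nrow(rings)))
  value <- switch(filter$mode,
                  d_spacing = rings$d_nm,
                  radial_px = rings$radius_px,
                  stop("unknown ring filter mode: ", filter$mode))
  abs(value - filter$center) <= filter$bandwidth / 2
}

#' Analyze one diffraction image
#'
#' The per-image pipeline: polar resampling, ring detection (MCI + LCD,
#' merged), multi-Gaussian radial fit, per-ring orientation fit and
#' isotropy exclusion.
#'
#' @param image a [DiffractionImage-class].
#' @param geometry a [DetectorGeometry-class].
#' @param config a [diConfig()].
#' @return A list: `rings` (data.frame in the `rings.csv` schema),
#'   `summary` (one-row data.frame: image, total_intensity, n_rings),
#'   `background` (one-row data.frame: image, mean_background, n_pixels)
#'   and `detect` (the raw candidate lists).
#' @export
processImage <- function(image, geometry, config = diConfig()) {
  polar <- toPolar(image, geometry, nTheta = config$nTheta,
                   rMax = config$rMax, rStep = config$rStep)
  det <- detectRings(polar, config)
  rings <- emptyRings()
  if (length(det$radii)) {
    prof <- azimuthalIntegrate(polar)
    radial <- fitRadial(prof, det$radii, centerTol = config$mergeTol)
    rmax <- max(prof@r)
    if (nrow(radial)) for (i in seq_len(nrow(radial))) {
      lo <- max(0, radial$center_px[i] - 2 * radial$sigma_r_px[i])
      hi <- min(rmax, radial$center_px[i] + 2 * radial$sigma_r_px[i])
      az <- radialIntegrate(polar, c(lo, hi))
      fit <- fitOrientation(az)
      excl <- applyExclusion(fit$angle_fit_error, fit$angle_sigma_rad,
                             threshold = config$exclusionThreshold,
                             mode = config$exclusionMode)
      rings <- rbind(rings, data.frame(
        image = image@name, ring_index = i,
        radius_px = radial$center_px[i],
        d_nm = radiusToDspacing(radial$center_px[i], geometry)$d_nm,
        sigma_r_px = radial$sigma_r_px[i], area = radial$area[i],
        orientation_deg = fit$orientation_deg,
        orientation_rad = fit$orientation_deg * pi / 180,
        angle_sigma_rad = fit$angle_sigma_rad,
        angle_fit_error = fit$angle_fit_error,
        ang_range_start_deg = fit$angular_range_deg[1],
        ang_range_end_deg = fit$angular_range_deg[2],
        excluded = excl
      ))
    }
  }
  sel <- ringSelected(rings, config$ringFilter)
  total <- if (nrow(rings)) sum(rings$area[sel & !rings$excluded]) else 0
  bg <- backgroundSummary(image, rmin = config$rminBackground,
                          geometry = geometry)
  list(
    rings = rings,
    summary = data.frame(image = image@name, total_intensity = total,
                         n_rings = nrow(rings)),
    background = data.frame(image = image@name, mean_background = bg$mean,
                            n_pixels = bg$n),
    detect = det
  )
}

appendCsv <- function(df, path) {
  exists <- file.exists(path)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !exists, append = exists, qmethod = "double")
}

#' Process a folder of diffraction images
#'
#' Lists all TIFFs in the folder (natural filename order), skips images
#' already recorded in `di_results/summary.csv` (resume), and runs
#' [processImage()] on the rest, appending to `summary.csv`, `rings.csv`
#' and `BackgroundSummary.csv` under `di_results/`. If `summary.csv`
#' exists without `rings.csv` the result set is inconsistent and the
#' folder is reprocessed from scratch. Per-image failures are logged and
#' recorded as 0-ring rows; the run continues.
#'
#' Geometry is taken from `geometry`, or else from a `settings.json` in
#' the folder. A blank image and a mask named in `config` (or a
#' `mask.tif` present in the folder) are applied to every image.
#'
#' @param folder path containing the numbered TIFF series.
#' @param geometry optional [DetectorGeometry-class]; default: read from
#'   `settings.json` in the folder.
#' @param config a [diConfig()].
#' @param outDir results directory (default `folder/di_results`).
#' @return Invisibly, a list with data.frames `summary`, `rings`,
#'   `background` covering all processed images (old + new), plus
#'   `nProcessed`, the number processed in this call.
#' @export
processFolder <- function(folder, geometry = NULL, config = diConfig(),
                          outDir = file.path(folder, "di_results")) {
  if (is.null(geometry)) {
    sf <- file.path(folder, "settings.json")
    if (!file.exists(sf))
      stop("no geometry given and no settings.json in ", folder)
    geometry <- readSettings(sf)$geometry
  }
  imgs <- list.files(folder, pattern = "\\.tiff?$", ignore.case = TRUE)
  imgs <- setdiff(imgs, c("mask.tif", "mask.tiff", "blank.tif"))
  imgs <- naturalSort(imgs)
  if (!length(imgs)) stop("no supported images found in ", folder)
  maskFile <- config$maskFile %||%
    (if (file.exists(file.path(folder, "mask.tif")))
       file.path(folder, "mask.tif"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sumPath <- file.path(outDir, "summary.csv")
  ringPath <- file.path(outDir, "rings.csv")
  bgPath <- file.path(outDir, "BackgroundSummary.csv")
  if (file.exists(sumPath) && !file.exists(ringPath)) {
    warning("summary.csv present without rings.csv: ",
            "inconsistent results, reprocessing folder")
    file.remove(sumPath)
    if (file.exists(bgPath)) file.remove(bgPath)
  }
  done <- if (file.exists(sumPath))
    utils::read.csv(sumPath)$image else character()
  todo <- setdiff(imgs, done)
  for (nm in todo) {
    k <- match(nm, imgs)
    res <- tryCatch({
      img <- loadImage(file.path(folder, nm), blank = config$blank,
                       mask = maskFile, gapSentinel = config$gapSentinel,
                       index = k)
      processImage(img, geometry, config)
    }, error = function(e) {
      warning("image ", nm, " failed: ", conditionMessage(e))
      list(rings = emptyRings(),
           summary = data.frame(image = nm, total_intensity = 0,
                                n_rings = 0L),
           background = data.frame(image = nm, mean_background = NA_real_,
                                   n_pixels = 0L))
    })
    appendCsv(res$summary, sumPath)
    if (nrow(res$rings)) appendCsv(res$rings, ringPath)
    else if (!file.exists(ringPath)) appendCsv(emptyRings(), ringPath)
    appendCsv(res$background, bgPath)
  }
  if (!file.exists(ringPath)) appendCsv(emptyRings(), ringPath)
  invisible(list(
    summary = utils::read.csv(sumPath),
    rings = utils::read.csv(ringPath),
    background = utils::read.csv(bgPath),
    nProcessed = length(todo)
  ))
}

#' Read a folder's result tables
#'
#' @param folder the scan folder processed by [processFolder()].
#' @param outDir results directory (default `folder/di_results`).
#' @return A list with data.frames `summary`, `rings`, `background`.
#' @export
readResults <- function(folder, outDir = file.path(folder, "di_results")) {
  sumPath <- file.path(outDir, "summary.csv")
  if (!file.exists(sumPath))
    stop("no results found: ", sumPath, " does not exist")
  ringPath <- file.path(outDir, "rings.csv")
  list(summary = utils::read.csv(sumPath),
       rings = if (file.exists(ringPath)) utils::read.csv(ringPath)
               else emptyRings(),
       background = utils::read.csv(file.path(outDir,
                                              "BackgroundSummary.csv")))
}
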