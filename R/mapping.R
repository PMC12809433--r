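## Heatmap assembly: per-position results become 2D parameter maps of
## the scanned tissue in five representations, optionally RBF-
## interpolated, and exported as CSV, PNG or SVG.

#' Pick the best ring of one image
#'
#' Among the non-excluded rings passing the rings-of-interest filter,
#' the best ring is the one with the lowest angle fitting error (ties:
#' smaller radius).
#'
#' @param rings data.frame of one image's rings (the `rings.csv` schema).
#' @param filter optional list `(mode = "d_spacing"|"radial_px", center,
#'   bandwidth)`; a ring passes when `|value - center| <= bandwidth/2`
#'   (d in nm, radius in px).
#' @return A one-row data.frame, or `NULL` when none qualifies.
#' @export
bestRing <- function(rings, filter = NULL) {
  if (is.null(rings) || !nrow(rings)) return(NULL)
  ok <- !rings$excluded & ringSelected(rings, filter) &
        is.finite(rings$angle_fit_error)
  if (!any(ok)) return(NULL)
  cand <- rings[ok, , drop = FALSE]
  cand <- cand[order(cand$angle_fit_error, cand$radius_px), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Build a heatmap layer from scan results
#'
#' Places each image's value at its raster-grid cell:
#'
#' * `total_intensity` - total intensity from `summary.csv`;
#' * `d_space` - d-spacing (nm) of the best ring;
#' * `angular_range` - angle sigma (radians) of the best ring;
#' * `vector_field` - total intensity as color with the best ring's
#'   orientation as an overlay vector direction;
#' * `elliptical` - total intensity as color with the best ring's
#'   orientation as ellipse orientation and angle sigma as ellipse size.
#'
#' Cells whose image had no qualifying (non-excluded, filter-passing)
#' ring are missing (`NA`), and orientation overlays are absent exactly
#' there -- cells without an alignment glyph mark isotropic diffraction.
#'
#' @param result list with `summary` and `rings` data.frames (from
#'   [processFolder()] or [readResults()]).
#' @param grid a [ScanGrid-class].
#' @param representation one of the five names above.
#' @param filter optional ring filter, see [bestRing()].
#' @param rotate90 rotate displayed orientations by 90 degrees (lamellar
#'   assemblies; see [displayOrientation()]).
#' @return A [HeatmapLayer-class].
#' @export
buildMap <- function(result, grid,
                     representation = c("total_intensity", "d_space",
                                        "angular_range", "vector_field",
                                        "elliptical"),
                     filter = NULL, rotate90 = FALSE) {
  representation <- match.arg(representation)
  summary <- result$summary
  n <- nrow(summary)
  if (n > nCols(grid) * nRows(grid))
    stop("more images than scan-grid positions")
  pos <- gridPosition(grid, seq_len(n))
  vals <- matrix(NA_real_, nRows(grid), nCols(grid))
  needOverlay <- representation %in% c("vector_field", "elliptical")
  ang <- mag <- spr <- matrix(NA_real_, nRows(grid), nCols(grid))
  for (k in seq_len(n)) {
    rk <- result$rings[result$rings$image == summary$image[k], ,
                       drop = FALSE]
    best <- bestRing(rk, filter)
    i <- pos$row[k]; j <- pos$col[k]
    vals[i, j] <- switch(representation,
      total_intensity = summary$total_intensity[k],
      d_space = if (!is.null(best)) best$d_nm else NA_real_,
      angular_range = if (!is.null(best)) best$angle_sigma_rad else NA_real_,
      vector_field = ,
      elliptical = summary$total_intensity[k])
    if (needOverlay && !is.null(best)) {
      ang[i, j] <- displayOrientation(best$orientation_deg, rotate90)
      mag[i, j] <- summary$total_intensity[k]
      spr[i, j] <- best$angle_sigma_rad
    }
  }
  new("HeatmapLayer", values = vals, representation = representation,
      overlay = if (needOverlay)
        list(angle = ang, magnitude = mag, spread = spr) else list(),
      grid = grid)
}

## multiquadric kernel, shape parameter s in grid-index units
multiquadric <- function(r, s = 1) sqrt(1 + (s * r)^2)

#' Multiquadric RBF interpolation of a heatmap layer
#'
#' Fits a radial basis function interpolant through the non-missing
#' cell centers -- multiquadric kernel `phi(r) = sqrt(1 + (s r)^2)` with
#' shape parameter `s = 1` in grid-index units, zero smoothing, so the
#' surface passes exactly through the data -- and evaluates it on a grid
#' upsampled by an integer factor. Missing cells are excluded from the
#' node set (interpolation fills the gaps between measured points);
#' orientation overlays are never interpolated (angles on a half-circle
#' do not average linearly), so the result is a scalar layer.
#'
#' @param layer a [HeatmapLayer-class].
#' @param upsample integer >= 1; the output grid has
#'   `(n - 1) * upsample + 1` points along each axis, so every original
#'   cell center is an evaluation point.
#' @param shape shape parameter (default 1).
#' @return A dense [HeatmapLayer-class] (no overlay).
#' @export
rbfInterpolate <- function(layer, upsample = 4L, shape = 1) {
  v <- layer@values
  node <- which(!is.na(v), arr.ind = TRUE)
  if (nrow(node) < 2L)
    stop("at least 2 non-missing cells are required for interpolation")
  upsample <- as.integer(upsample)
  if (upsample < 1L) stop("upsample must be >= 1")
  y <- v[node]
  d <- sqrt(outer(node[, 1], node[, 1], "-")^2 +
            outer(node[, 2], node[, 2], "-")^2)
  w <- solve(multiquadric(d, shape), y)
  rows <- seq(1, nrow(v), by = 1 / upsample)
  cols <- seq(1, ncol(v), by = 1 / upsample)
  ev <- as.matrix(expand.grid(r = rows, c = cols))
  dd <- sqrt(outer(ev[, 1], node[, 1], "-")^2 +
             outer(ev[, 2], node[, 2], "-")^2)
  out <- matrix(multiquadric(dd, shape) %*% w,
                nrow = length(rows), ncol = length(cols))
  new("HeatmapLayer", values = out, representation = layer@representation,
      overlay = list(), grid = layer@grid)
}

## physical coordinates of the layer's cell centers (handles upsampled
## layers: indices map linearly onto the scan extent)
layerCoords <- function(layer) {
  g <- layer@grid
  nr <- nrow(layer@values); nc <- ncol(layer@values)
  xs <- if (nc == 1) g@xStart else
    g@xStart + (seq_len(nc) - 1) / (nc - 1) * (g@xEnd - g@xStart)
  ys <- if (nr == 1) g@yStart else
    g@yStart + (seq_len(nr) - 1) / (nr - 1) * (g@yEnd - g@yStart)
  list(x = xs, y = ys)
}

#' Export a heatmap layer
#'
#' * `csv`: one row per cell as visible on the map -- `row`, `col`,
#'   `x_mm`, `y_mm`, `value` and, when an orientation overlay is
#'   present, `orientation_deg`.
#' * `png`: raster image, `scale` x `scale` pixels per cell, viridis
#'   colormap (missing cells grey), with orientation glyphs drawn as
#'   white bars where the overlay is present. Deterministic bytes for
#'   fixed inputs.
#' * `svg`: the same map as a vector graphic.
#'
#' @param layer a [HeatmapLayer-class].
#' @param path output file path.
#' @param format `"csv"`, `"png"` or `"svg"` (default: from the file
#'   extension).
#' @param scale pixels (png) or user units (svg) per cell.
#' @param zlim optional numeric(2) color-scale clipping thresholds;
#'   default: the finite value range.
#' @return `path`, invisibly.
#' @export
exportMap <- function(layer, path,
                      format = c("auto", "csv", "png", "svg"),
                      scale = 16L, zlim = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("csv", "png", "svg"))
    stop("unsupported export format: ", format)
  v <- layer@values
  co <- layerCoords(layer)
  if (format == "csv") {
    df <- data.frame(
      row = rep(seq_len(nrow(v)), times = ncol(v)),
      col = rep(seq_len(ncol(v)), each = nrow(v)),
      x_mm = rep(co$x, each = nrow(v)),
      y_mm = rep(co$y, times = ncol(v)),
      value = as.vector(v))
    if (length(layer@overlay))
      df$orientation_deg <- as.vector(layer@overlay$angle)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  fin <- v[is.finite(v)]
  if (is.null(zlim))
    zlim <- if (length(fin)) range(fin) else c(0, 1)
  pal <- grDevices::hcl.colors(256, "viridis")
  rgbPal <- grDevices::col2rgb(pal) / 255
  naCol <- c(0.35, 0.35, 0.35)
  idx <- function(x) {
    z <- pmin(pmax((x - zlim[1]) / max(zlim[2] - zlim[1], 1e-300), 0), 1)
    as.integer(round(z * 255)) + 1L
  }
  nr <- nrow(v); nc <- ncol(v); s <- as.integer(scale)
  if (format == "png") {
    img <- array(0, dim = c(nr * s, nc * s, 3))
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      colr <- if (is.finite(v[i, j])) rgbPal[, idx(v[i, j])] else naCol
      img[(i - 1) * s + seq_len(s), (j - 1) * s + seq_len(s), ] <-
        rep(colr, each = s * s)
    }
    if (length(layer@overlay)) {
      ang <- layer@overlay$angle
      half <- 0.4 * s
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (!is.finite(ang[i, j])) next
        a <- ang[i, j] * pi / 180
        cxp <- (j - 0.5) * s; cyp <- (i - 0.5) * s
        t <- seq(-half, half, length.out = max(4L, 2L * s))
        px <- as.integer(round(cxp + t * cos(a)))
        # screen y grows downward; theta is ccw in display coordinates
        py <- as.integer(round(cyp - t * sin(a)))
        ok <- px >= 0 & px < nc * s & py >= 0 & py < nr * s
        for (ch in 1:3) img[cbind(py[ok] + 1L, px[ok] + 1L, ch)] <- 1
      }
    }
    png::writePNG(img, path)
  } else {
    hex <- function(x) if (is.finite(x)) pal[idx(x)] else "#595959"
    out <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
      nc * s, nr * s))
    for (i in seq_len(nr)) for (j in seq_len(nc))
      out <- c(out, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
        (j - 1L) * s, (i - 1L) * s, s, s, hex(v[i, j])))
    if (length(layer@overlay)) {
      ang <- layer@overlay$angle
      half <- 0.4 * s
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if (!is.finite(ang[i, j])) next
        a <- ang[i, j] * pi / 180
        cxp <- (j - 0.5) * s; cyp <- (i - 0.5) * s
        out <- c(out, sprintf(
          '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="white" stroke-width="1.5"/>',
          cxp - half * cos(a), cyp + half * sin(a),
          cxp + half * cos(a), cyp - half * sin(a)))
      }
    }
    out <- c(out, "</svg>")
    writeLines(out, path)
  }
  invisible(path)
}
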