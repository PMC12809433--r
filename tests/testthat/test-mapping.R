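# Hand-built result tables in the rings.csv schema for bookkeeping tests
fakeRing <- function(image, radius, d, err, excluded = FALSE,
                     orientation = 45, sigma = 0.2) {
  data.frame(image = image, ring_index = 1L, radius_px = radius,
             d_nm = d, sigma_r_px = 3, area = 100,
             orientation_deg = orientation,
             orientation_rad = orientation * pi / 180,
             angle_sigma_rad = sigma, angle_fit_error = err,
             ang_range_start_deg = 0, ang_range_end_deg = 90,
             excluded = excluded)
}

test_that("bestRing picks the lowest fitting error within the filter", {
  rings <- rbind(fakeRing("a", 50, 15.6, 0.3), fakeRing("a", 80, 10.0, 0.1),
                 fakeRing("a", 120, 6.7, 0.7))
  expect_equal(bestRing(rings)$angle_fit_error, 0.1)

  # d filter 16 +/- 1 nm keeps only the 15.6 nm ring
  rings2 <- rbind(fakeRing("a", 50, 15.6, 0.5), fakeRing("a", 95, 8.0, 0.1))
  best <- bestRing(rings2, list(mode = "d_spacing", center = 16,
                                bandwidth = 2))
  expect_equal(best$d_nm, 15.6)

  # all excluded -> none
  rings3 <- rbind(fakeRing("a", 50, 15.6, 1.4, excluded = TRUE))
  expect_null(bestRing(rings3))
  # tie on error -> smaller radius
  rings4 <- rbind(fakeRing("a", 80, 10, 0.2), fakeRing("a", 40, 20, 0.2))
  expect_equal(bestRing(rings4)$radius_px, 40)
})

test_that("buildMap lays out values in raster order", {
  grid <- ScanGrid(0, 0.1, 0.1, 0, 0.1, 0.1)  # 2 x 2
  result <- list(
    summary = data.frame(image = c("i1", "i2", "i3", "i4"),
                         total_intensity = c(10, 20, 30, 40),
                         n_rings = 1L),
    rings = rbind(fakeRing("i1", 60, 20, 0.1), fakeRing("i2", 60, 20, 0.2),
                  fakeRing("i3", 60, 20, 0.3), fakeRing("i4", 60, 20, 0.4)))
  m <- buildMap(result, grid, "total_intensity")
  expect_equal(mapValues(m), matrix(c(10, 30, 20, 40), 2, 2))
  expect_equal(length(mapOverlay(m)), 0)

  # d_space map with uniform radius is constant at that conversion
  geo <- testGeometry()
  dTrue <- radiusToDspacing(60, geo)$d_nm
  result$rings$d_nm <- dTrue
  md <- buildMap(result, grid, "d_space")
  expect_true(all(abs(mapValues(md) - dTrue) < 1e-12))

  ma <- buildMap(result, grid, "angular_range")
  expect_true(all(mapValues(ma) == 0.2))
})

test_that("overlays exist exactly where a best ring exists", {
  grid <- ScanGrid(0, 0.1, 0.1, 0, 0.1, 0.1)
  result <- list(
    summary = data.frame(image = c("i1", "i2", "i3", "i4"),
                         total_intensity = c(10, 20, 30, 40),
                         n_rings = 1L),
    rings = rbind(fakeRing("i1", 60, 20, 0.1, orientation = 30),
                  fakeRing("i2", 60, 20, 1.4, excluded = TRUE),
                  fakeRing("i3", 60, 20, 0.3, orientation = 150),
                  fakeRing("i4", 60, 20, 1.2, excluded = TRUE)))
  v <- buildMap(result, grid, "vector_field")
  ov <- mapOverlay(v)
  expect_equal(is.na(ov$angle), matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_equal(mapValues(v), matrix(c(10, 30, 20, 40), 2, 2))  # color kept
  expect_equal(ov$angle[1, 1], 30)

  # rotate-90 display semantics
  v90 <- buildMap(result, grid, "vector_field", rotate90 = TRUE)
  expect_equal(mapOverlay(v90)$angle[1, 1], 120)

  # all rings isotropic -> color but zero overlays
  resIso <- result
  resIso$rings$excluded <- TRUE
  vIso <- buildMap(resIso, grid, "elliptical")
  expect_true(all(is.na(mapOverlay(vIso)$angle)))
  expect_true(all(is.finite(mapValues(vIso))))
  # d_space cells with no qualifying ring are missing, not zero
  dIso <- buildMap(resIso, grid, "d_space")
  expect_true(all(is.na(mapValues(dIso))))
})

test_that("each map cell depends only on its own image", {
  grid <- ScanGrid(0, 0.1, 0.1, 0, 0.1, 0.1)
  mk <- function(err3) list(
    summary = data.frame(image = c("i1", "i2", "i3", "i4"),
                         total_intensity = c(10, 20, 30, 40),
                         n_rings = 1L),
    rings = rbind(fakeRing("i1", 60, 20, 0.1), fakeRing("i2", 61, 19, 0.2),
                  fakeRing("i3", 62, 18, err3), fakeRing("i4", 63, 17, 0.4)))
  mA <- mapValues(buildMap(mk(0.3), grid, "d_space"))
  mB <- mapValues(buildMap(mk(0.9), grid, "d_space"))
  expect_equal(mA, mB)  # value unchanged; only i3's error changed
})

test_that("RBF interpolation is exact at nodes and linear-accurate", {
  grid <- ScanGrid(0, 0.4, 0.1, 0, 0.4, 0.1)  # 5 x 5
  z <- outer(1:5, 1:5, function(r, c) 2 * c + 3 * r)
  layer <- new("HeatmapLayer", values = z,
               representation = "total_intensity", overlay = list(),
               grid = grid)
  up1 <- rbfInterpolate(layer, upsample = 1)
  expect_equal(mapValues(up1), z, tolerance = 1e-8)
  up2 <- rbfInterpolate(layer, upsample = 2)
  v <- mapValues(up2)
  expect_equal(dim(v), c(9L, 9L))
  expect_equal(v[seq(1, 9, 2), seq(1, 9, 2)], z, tolerance = 1e-8)
  # interior midpoints of the plane z = 2x + 3y stay within 1 percent
  # (the extrapolation-prone outer edge is excluded)
  truth <- outer(seq(1, 5, 0.5), seq(1, 5, 0.5),
                 function(r, c) 2 * c + 3 * r)
  relErr <- abs(v - truth) / truth
  expect_lt(max(relErr[3:7, 3:7]), 0.01)

  # missing cells are excluded from the node set but filled on output
  z2 <- z; z2[3, 3] <- NA
  layer2 <- new("HeatmapLayer", values = z2,
                representation = "total_intensity", overlay = list(),
                grid = grid)
  f <- rbfInterpolate(layer2, upsample = 1)
  expect_true(is.finite(mapValues(f)[3, 3]))
  sel <- !is.na(z2)
  expect_equal(mapValues(f)[sel], z2[sel], tolerance = 1e-8)

  expect_error(rbfInterpolate(new("HeatmapLayer",
    values = matrix(c(1, NA, NA, NA), 2, 2),
    representation = "total_intensity", overlay = list(),
    grid = ScanGrid(0, 0.1, 0.1, 0, 0.1, 0.1))), "2 non-missing")
})

test_that("a single row interpolates like an independent 1D solve", {
  grid <- ScanGrid(0, 0.4, 0.1, 0, 0, 0.1)  # 5 x 1
  z <- matrix(c(1, 4, 2, 8, 5), 1, 5)
  layer <- new("HeatmapLayer", values = z,
               representation = "total_intensity", overlay = list(),
               grid = grid)
  v <- mapValues(rbfInterpolate(layer, upsample = 2))
  # independent 1D multiquadric solve on node coordinates 1..5
  phi <- function(r) sqrt(1 + r^2)
  w <- solve(phi(abs(outer(1:5, 1:5, "-"))), as.numeric(z))
  xq <- seq(1, 5, by = 0.5)
  expected <- as.numeric(phi(abs(outer(xq, 1:5, "-"))) %*% w)
  expect_equal(as.numeric(v), expected, tolerance = 1e-10)
})

test_that("exports round-trip CSV and produce deterministic PNG bytes", {
  grid <- ScanGrid(0, 0.1, 0.1, 0, 0.1, 0.1)
  result <- list(
    summary = data.frame(image = c("i1", "i2", "i3", "i4"),
                         total_intensity = c(10.25, 20.5, 30.75, 40),
                         n_rings = 1L),
    rings = rbind(fakeRing("i1", 60, 20, 0.1, orientation = 30),
                  fakeRing("i2", 60, 20, 0.2, orientation = 60),
                  fakeRing("i3", 60, 20, 0.3, orientation = 90),
                  fakeRing("i4", 60, 20, 1.4, excluded = TRUE)))
  layer <- buildMap(result, grid, "vector_field")

  csvPath <- tempfile(fileext = ".csv")
  exportMap(layer, csvPath)
  df <- read.csv(csvPath)
  expect_equal(nrow(df), 4)
  expect_equal(length(readLines(csvPath)), 5)  # header + 4 rows
  got <- matrix(NA_real_, 2, 2)
  got[cbind(df$row, df$col)] <- df$value
  expect_equal(got, mapValues(layer))  # exact round-trip
  expect_true("orientation_deg" %in% names(df))
  expect_equal(df$x_mm[df$col == 2], c(0.1, 0.1))

  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  exportMap(layer, p1); exportMap(layer, p2)
  expect_equal(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  svgPath <- tempfile(fileext = ".svg")
  exportMap(layer, svgPath)
  svg <- readLines(svgPath)
  expect_equal(sum(grepl("<rect", svg)), 4)
  expect_equal(sum(grepl("<line", svg)), 3)  # one cell has no overlay
  expect_error(exportMap(layer, tempfile(fileext = ".bmp")), "format")
})
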