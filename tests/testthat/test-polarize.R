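test_that("loadImage subtracts blanks and masks gap pixels", {
  dir <- tempfile("img"); dir.create(dir)
  m <- matrix(50L, 32, 32)
  m[5, 7] <- 120L
  tiff::writeTIFF(m / 65535, file.path(dir, "a.tif"),
                  bits.per.sample = 16L, compression = "none")
  img <- loadImage(file.path(dir, "a.tif"))
  expect_equal(img@data[5, 7], 120)
  expect_equal(sum(imageMask(img)), 0)

  # blank equal to the image -> all zero
  img0 <- loadImage(file.path(dir, "a.tif"), blank = m)
  expect_true(all(imageValues(img0) == 0))

  # shape mismatch
  expect_error(loadImage(file.path(dir, "a.tif"), blank = matrix(0, 3, 3)),
               "shape")
  # HDF5 path rejected with a clear message
  expect_error(loadImage(file.path(dir, "a.h5")), "HDF5")
})

test_that("negative sentinel pixels are masked", {
  m <- matrix(10, 20, 20)
  m[c(3, 50, 399)] <- -1
  img <- DiffractionImage(m)
  expect_equal(sum(imageMask(img)), 3)
  expect_true(all(is.na(imageValues(img)[c(3, 50, 399)])))
})

test_that("toPolar reproduces a constant field and conserves flux", {
  geo <- DetectorGeometry(c(31.5, 31.5), 2000, 0.172, 1.033)
  img <- DiffractionImage(matrix(4.25, 64, 64))
  pol <- toPolar(img, geo)
  v <- polarValues(pol)
  w <- polarWeight(pol)
  expect_true(all(abs(v[w > 0] - 4.25) < 1e-9))
  expect_true(all(is.na(v[w == 0])))

  # flux conservation on a smooth image: sum over bins of
  # value * weight * bin area tracks the pixel sum over the sampled disk
  size <- 129L
  geo2 <- DetectorGeometry(c(64, 64), 2000, 0.172, 1.033)
  xs <- matrix(rep(0:(size - 1), each = size), size, size)
  ys <- matrix(rep(0:(size - 1), times = size), size, size)
  rho2 <- (xs - 64)^2 + (ys - 64)^2
  smooth <- 100 + 50 * exp(-rho2 / (2 * 30^2))
  img2 <- DiffractionImage(smooth)
  pol2 <- toPolar(img2, geo2)
  binArea <- outer(rep(pol2@thetaStep * pi / 180, 360), rCenters(pol2))
  v2 <- polarValues(pol2); v2[is.na(v2)] <- 0
  polarFlux <- sum(v2 * polarWeight(pol2) * binArea)
  inDisk <- rho2 <= max(rCenters(pol2))^2
  expect_lt(abs(polarFlux - sum(smooth[inDisk])) / sum(smooth[inDisk]),
            0.02)
})

test_that("an isotropic ring peaks at its radius in the polar field", {
  p <- makePattern(rings = list(RingSpec(60, 100, sigmaR = 3)),
                   noise = "none")
  pol <- toPolar(p$image, testGeometry())
  colMean <- colMeans(polarValues(pol), na.rm = TRUE)
  expect_equal(rCenters(pol)[which.max(colMean)], 60.5, tolerance = 1)
})

test_that("toPolar is consistent under 90-degree rotation", {
  size <- 101L
  geo <- DetectorGeometry(c(50, 50), 2000, 0.172, 1.033)
  xs <- matrix(rep(0:(size - 1), each = size), size, size)
  ys <- matrix(rep(0:(size - 1), times = size), size, size)
  th <- atan2(50 - ys, xs - 50)
  rho <- sqrt((xs - 50)^2 + (ys - 50)^2)
  smooth <- 100 + 40 * cos(th) * exp(-(rho - 30)^2 / 50)
  polA <- toPolar(DiffractionImage(smooth), geo)
  # rotate the source by 90 deg about the center (new[i, j] =
  # old[j, n + 1 - i]; clockwise in display coordinates since the row
  # axis points down), which shifts the polar field by -90 deg in theta
  rot <- t(smooth)[, size:1]
  polB <- toPolar(DiffractionImage(rot), geo)
  shift <- 270 / polA@thetaStep
  vA <- polarValues(polA)
  vB <- polarValues(polB)[c((shift + 1):360, 1:shift), ]
  sel <- !is.na(vA) & !is.na(vB) &
    col(vA) > 10  # skip tiny radii where resampling error dominates
  expect_lt(max(abs(vA[sel] - vB[sel])), 1.5)
})

test_that("masked pixels never contribute to profiles or summaries", {
  p <- makePattern(rings = list(RingSpec(60, 100, sigmaR = 3)),
                   noise = "none")
  geo <- testGeometry()
  base <- p$image
  poisoned <- base@data
  maskArea <- matrix(FALSE, nrow(poisoned), ncol(poisoned))
  maskArea[20:40, 100:130] <- TRUE
  poisoned[maskArea] <- 1e9
  imgP <- new("DiffractionImage", data = poisoned,
              mask = base@mask | maskArea, name = "p", index = 1L)
  imgC <- new("DiffractionImage", data = base@data,
              mask = base@mask | maskArea, name = "c", index = 1L)
  polP <- toPolar(imgP, geo)
  polC <- toPolar(imgC, geo)
  expect_equal(polarValues(polP), polarValues(polC))
  bgP <- backgroundSummary(imgP, rmin = 20, geometry = geo)
  bgC <- backgroundSummary(imgC, rmin = 20, geometry = geo)
  expect_equal(bgP, bgC)
})

test_that("azimuthal integration respects wedges and isotropy", {
  pIso <- makePattern(rings = list(RingSpec(60, 100, sigmaR = 3)),
                      noise = "none")
  geo <- testGeometry()
  pol <- toPolar(pIso$image, geo)
  full <- azimuthalIntegrate(pol, c(0, 360))
  quarter <- azimuthalIntegrate(pol, c(45, 90))
  sel <- is.finite(full@intensity) & is.finite(quarter@intensity)
  expect_lt(max(abs(full@intensity[sel] - quarter@intensity[sel])), 1)

  # constant image -> flat profile equal to the constant
  cImg <- DiffractionImage(matrix(3.5, 64, 64))
  cGeo <- DetectorGeometry(c(31.5, 31.5), 2000, 0.172, 1.033)
  cProf <- azimuthalIntegrate(toPolar(cImg, cGeo))
  expect_true(all(abs(cProf@intensity[is.finite(cProf@intensity)] - 3.5)
                  < 1e-9))

  # oriented ring: wedge on the arc sees a taller peak than orthogonal
  pOri <- makePattern(rings = list(RingSpec(60, 100, sigmaR = 3,
                                            orientation = 0,
                                            sigmaTheta = 15)),
                      noise = "none")
  polO <- toPolar(pOri$image, geo)
  onArc <- azimuthalIntegrate(polO, c(0, 90))
  offArc <- azimuthalIntegrate(polO, c(90, 90))
  expect_gt(max(onArc@intensity, na.rm = TRUE),
            max(offArc@intensity, na.rm = TRUE))
  expect_error(azimuthalIntegrate(pol, c(0, 0)), "width")
})

test_that("full-circle profile is the weighted mean of a wedge partition", {
  p <- makePattern(rings = list(RingSpec(60, 100, sigmaR = 3,
                                         orientation = 40,
                                         sigmaTheta = 20)), seed = 5)
  pol <- toPolar(p$image, testGeometry())
  full <- azimuthalIntegrate(pol, c(0, 360))
  centers <- c(45, 135, 225, 315)
  num <- 0; den <- 0
  for (cc in centers) {
    sel <- which(abs(((thetaCenters(pol) - cc + 180) %% 360) - 180) <= 45)
    w <- polarWeight(pol)[sel, , drop = FALSE]
    v <- polarValues(pol)[sel, , drop = FALSE]
    w[is.na(v)] <- 0; v[is.na(v)] <- 0
    num <- num + colSums(v * w); den <- den + colSums(w)
  }
  recombined <- ifelse(den > 0, num / den, NA)
  expect_equal(full@intensity, recombined, tolerance = 1e-9)
})

test_that("radial integration localizes arcs and flattens isotropy", {
  geo <- testGeometry()
  pIso <- makePattern(rings = list(RingSpec(60, 100, sigmaR = 3)),
                      seed = 2)
  polI <- toPolar(pIso$image, geo)
  azI <- radialIntegrate(polI, c(50, 70))
  cv <- sd(azI@intensity) / mean(azI@intensity)
  expect_lt(cv, 0.05)

  pOri <- makePattern(rings = list(RingSpec(60, 100, sigmaR = 3,
                                            orientation = 30,
                                            sigmaTheta = 10)),
                      noise = "none")
  polO <- toPolar(pOri$image, geo)
  azO <- radialIntegrate(polO, c(50, 70))
  top2 <- sort(azO@theta[order(azO@intensity, decreasing = TRUE)[1:2]])
  expect_lt(abs(top2[1] - 30), 1.5)
  expect_lt(abs(top2[2] - 210), 1.5)

  # band away from the ring: background only
  azBg <- radialIntegrate(polI, c(75, 90))
  perBin <- azBg@intensity / sum(rCenters(polI) >= 75 &
                                 rCenters(polI) <= 90)
  expect_equal(mean(perBin), 100, tolerance = 0.05)
  expect_error(radialIntegrate(polI, c(50, 50)), "band")
})

test_that("backgroundSummary matches brute-force pixel scans", {
  # full-true mask -> nothing qualifies
  img <- DiffractionImage(matrix(7, 10, 10))
  expect_equal(backgroundSummary(img, mask = matrix(TRUE, 10, 10))$n, 0)

  # no mask, rmin 0 -> every pixel
  geo10 <- DetectorGeometry(c(4.5, 4.5), 2000, 0.172, 1.033)
  bg <- backgroundSummary(img, rmin = 0, geometry = geo10)
  expect_equal(bg$mean, 7)
  expect_equal(bg$n, 100)

  # rmin 30 in a 100x100 image centered at (50, 50): brute force count
  set.seed(9)
  m <- matrix(runif(1e4), 100, 100)
  imgBig <- DiffractionImage(m)
  geoBig <- DetectorGeometry(c(50, 50), 2000, 0.172, 1.033)
  bgBig <- backgroundSummary(imgBig, rmin = 30, geometry = geoBig)
  cnt <- 0; tot <- 0
  for (i in 0:99) for (j in 0:99)
    if (sqrt((j - 50)^2 + (i - 50)^2) > 30) {
      cnt <- cnt + 1; tot <- tot + m[i + 1, j + 1]
    }
  expect_equal(bgBig$n, cnt)
  expect_equal(bgBig$mean, tot / cnt, tolerance = 1e-12)
  expect_error(backgroundSummary(img), "mask or rmin")
})
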