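# Wound masks from density, edge extraction, width profiles, closure curves.

test_that("density wound mask behaves at the degenerate extremes", {
  set.seed(61)
  # uniform monolayer, no wound -> empty mask
  p <- SimulationParams(fieldSize = c(1500, 1500), seedingDensity = 0.4e5,
                        nFrames = 1L, seed = 61L)
  cells <- seedMonolayer(p)
  m <- woundMaskFromPoints(cbind(cells$x, cells$y), p@fieldSize)
  expect_equal(sum(m@mask), 0L)

  # all nuclei removed -> full-frame mask (with a warning)
  expect_warning(full <- woundMaskFromPoints(matrix(numeric(0), 0, 2),
                                             c(1000, 1000)), "full-frame")
  expect_true(all(full@mask))
})

test_that("a cleared band is recovered with IoU >= 0.9", {
  p <- SimulationParams(fieldSize = c(2000, 2000), seedingDensity = 0.4e5,
                        nFrames = 1L, seed = 62L)
  cells <- seedMonolayer(p)
  inBand <- abs(cells$y - 1000) <= 150   # 300 um band
  pts <- cbind(cells$x, cells$y)[!inBand, ]
  # recovering absolute geometry of a 300 um feature needs a kernel bandwidth
  # well below the feature width (bias ~0.5 sigma per edge at threshold 0.4)
  # and boundary smoothing against density-sampling noise
  m <- woundMaskFromPoints(pts, p@fieldSize, gridStep = 10, bandwidth = 25,
                           threshold = 0.4, smoothing = 60)
  g <- m@pixelScale
  yy <- (row(m@mask) - 0.5) * g
  truthMask <- abs(yy - 1000) <= 150
  iou <- sum(m@mask & truthMask) / sum(m@mask | truthMask)
  expect_gte(iou, 0.9)
})

test_that("edges of a rectangular band are parallel lines; shape mode returns the polygon", {
  band <- syntheticBandMask(c(2000, 2000), 318, pixelScale = 5, angle = 0)
  e <- extractEdges(band$mask, "scratch")
  expect_s4_class(e[[1]], "EdgeLine")
  d1 <- e[[1]]@direction; d2 <- e[[2]]@direction
  ang <- acos(pmin(1, abs(sum(d1 * d2)))) * 180 / pi
  expect_lt(ang, 0.5)

  disc <- rasterizeWound(WoundShapeSpec("circle", size = 2), 5)
  poly <- extractEdges(disc, "shape")
  shoe <- abs(cfzkit:::shoelaceArea(poly)) / 1e6  # um^2 -> mm^2
  expect_equal(shoe, maskArea(disc), tolerance = 0.01)

  expect_error(extractEdges(WoundMask(matrix(FALSE, 10, 10), 5)), "empty")
})

test_that("sinusoidal edge roughness appears in the RMS residual as a/sqrt(2)", {
  # one straight edge, one sinusoidal edge of amplitude a
  a <- 30
  ps <- 5
  H <- 300; W <- 400
  xs <- (seq_len(W) - 1) * ps
  edgeY <- 600 + a * sin(2 * pi * xs / 500)
  m <- matrix(FALSE, H, W)
  yy <- (row(m) - 1) * ps
  ee <- matrix(edgeY, H, W, byrow = TRUE)
  m[yy >= 300 & yy <= ee] <- TRUE
  mask <- WoundMask(m, ps)
  e <- extractEdges(mask, "scratch")
  rms <- vapply(e, function(x) x@rmsResidual, numeric(1))
  wavy <- max(rms)  # the sinusoidal flank
  expect_equal(wavy, a / sqrt(2), tolerance = 0.1)
})

test_that("width profile: parallel, angled, and wavy bands", {
  # parallel edges: mean exact to half a pixel, sigma 0 (325 um puts both
  # edges on the half-pixel lattice, so no quantization offset is stacked on
  # top of the estimator's own error)
  band <- syntheticBandMask(c(2000, 2000), 325, pixelScale = 5, angle = 0)
  wp <- widthProfile(extractEdges(band$mask, "scratch"))
  expect_lt(abs(wp@meanWidth - 325), 2.5)
  expect_equal(wp@sdWidth, 0, tolerance = 1e-8)
  expect_equal(wp@sdWidth^2, var(wp@width), tolerance = 1e-12)

  # edges at relative angle theta: sd = L tan(theta) / sqrt(12)
  theta <- 2 * pi / 180
  ps <- 2
  W <- 500; H <- 400
  xs <- (seq_len(W) - 1) * ps
  m <- matrix(FALSE, H, W)
  yy <- (row(m) - 1) * ps
  top <- matrix(300 + xs * tan(theta), H, W, byrow = TRUE)
  m[yy >= 100 & yy <= top] <- TRUE
  wp2 <- widthProfile(extractEdges(WoundMask(m, ps), "scratch"), nSamples = 400L)
  L <- diff(range(wp2@s))
  expect_equal(wp2@sdWidth, L * tan(theta) / sqrt(12), tolerance = 0.05)

  # wavy band against its stored ground-truth width series
  wav <- syntheticBandMask(c(2000, 2000), 318, pixelScale = 5, angle = 8,
                           amplitude = 25, seed = 3L)
  wp3 <- widthProfile(extractEdges(wav$mask, "scratch"))
  expect_equal(wp3@meanWidth, mean(wav$width), tolerance = 0.05)
  expect_equal(wp3@sdWidth, sd(wav$width), tolerance = 0.2)
})

test_that("width sigma is invariant under rotation of the mask", {
  sds <- vapply(c(0, 25), function(angle) {
    b <- syntheticBandMask(c(2000, 2000), 318, pixelScale = 5, angle = angle,
                           amplitude = 30, seed = 9L)
    widthProfile(extractEdges(b$mask, "scratch"))@sdWidth
  }, numeric(1))
  expect_equal(sds[1], sds[2], tolerance = 0.02 + 0.03)  # 2% target + raster noise
})

test_that("closure curves follow the percent-closure arithmetic", {
  mk <- function(areaMm2) {
    n <- round(sqrt(areaMm2) / 0.01)
    m <- matrix(FALSE, 300, 300)
    if (n > 0) m[seq_len(n), seq_len(n)] <- TRUE
    WoundMask(m, 10)
  }
  cc <- closureCurve(list(mk(4.4), mk(2.2), mk(0)), frameIntervalMin = 960)
  expect_equal(cc@time, c(0, 16, 32))
  expect_equal(cc@percentClosure, c(0, 50, 100), tolerance = 0.01)
  expect_equal(cc@closureTime, 32)
  expect_equal(cc@percentClosure[1], 0)

  const <- closureCurve(list(mk(1), mk(1), mk(1)), 60)
  expect_true(all(const@percentClosure == 0))
  expect_equal(const@closureTime, Inf)

  expect_error(closureCurve(list(mk(0), mk(0)), 60), "zero")

  # monotone areas give monotone percent closure
  areas <- c(5, 4, 2.5, 1, 0.2)
  cc2 <- closureCurve(lapply(areas, mk), 30)
  expect_true(all(diff(cc2@percentClosure) >= -1e-9))
})
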