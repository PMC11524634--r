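# Preprocessing steps 1-5 and their composition.

rgbStack <- function(arr5) ImageStack(arr5, 5, 30)

test_that("flatten applies 709 luminance and passes gray through", {
  a <- array(0, dim = c(1, 1, 2, 2, 3))
  a[1, 1, 1, 1, ] <- c(80, 80, 80)     # gray fixed point
  a[1, 1, 1, 2, ] <- c(255, 0, 0)      # pure red
  a[1, 1, 2, 1, ] <- c(0, 255, 0)
  a[1, 1, 2, 2, ] <- c(0, 0, 255)
  fl <- flatten(rgbStack(a))
  expect_equal(dim(fl@data), c(1, 1, 2, 2))
  expect_equal(fl@data[1, 1, 1, 1], 80)
  expect_equal(fl@data[1, 1, 1, 2], 0.2125 * 255)
  expect_equal(fl@data[1, 1, 2, 1], 0.7154 * 255)
  expect_equal(fl@data[1, 1, 2, 2], 0.0721 * 255)

  flat <- ImageStack(array(runif(16), c(1, 1, 4, 4)), 5, 30)
  expect_warning(out <- flatten(flat), "no RGB axis")
  expect_identical(out@data, flat@data)
})

test_that("spatial rescale preserves constants, metadata and physical positions", {
  const <- ImageStack(array(7, c(1, 1, 40, 40)), 5, 30)
  expect_identical(rescaleSpatial(const, 1), const)
  half <- rescaleSpatial(const, 0.5)
  expect_equal(dim(half@data)[3:4], c(20L, 20L))
  expect_equal(max(abs(half@data - 7)), 0, tolerance = 1e-9)
  expect_equal(pixelScale(half), 10)  # um/px doubles

  # physical centroid bookkeeping: a rendered spot stays put within 1 px
  p <- tinyParams(1, field = 400, seed = 21L, noiseScale = 0)
  cells <- seedMonolayer(p)
  cells$x <- 200; cells$y <- 120
  fr <- renderFrame(cells, p)[1, , ]
  st <- ImageStack(array(fr, c(1, 1, dim(fr))), p@pixelScale, 30)
  for (f in c(0.5, 2)) {
    rs <- rescaleSpatial(st, f)
    m <- rs@data[1, 1, , ] - min(rs@data)
    cx <- (sum(col(m) * m) / sum(m) - 1) * pixelScale(rs)
    cy <- (sum(row(m) * m) / sum(m) - 1) * pixelScale(rs)
    m0 <- fr - min(fr)
    cx0 <- (sum(col(m0) * m0) / sum(m0) - 1) * p@pixelScale
    cy0 <- (sum(row(m0) * m0) / sum(m0) - 1) * p@pixelScale
    expect_lt(abs(cx - cx0), p@pixelScale)
    expect_lt(abs(cy - cy0), p@pixelScale)
  }
  expect_error(rescaleSpatial(const, 0.01), "below 1 px")
})

test_that("intensity rescale maps min/max to 0/255 linearly", {
  a <- array(0, c(1, 1, 1, 3))
  a[1, 1, 1, ] <- c(10, 15, 20)
  out <- rescaleIntensity(ImageStack(a, 5, 30))
  expect_equal(as.numeric(out@data[1, 1, 1, ]), c(0, 127.5, 255))

  const <- rescaleIntensity(ImageStack(array(42, c(1, 1, 2, 2)), 5, 30))
  expect_true(all(const@data == 0))

  span <- array(0, c(1, 1, 1, 2)); span[1, 1, 1, ] <- c(0, 255)
  expect_equal(rescaleIntensity(ImageStack(span, 5, 30))@data, span)
})

test_that("median filter matches a brute-force window median", {
  const <- ImageStack(array(3, c(1, 1, 8, 8)), 5, 30)
  expect_equal(medianFilterStack(const, 1)@data, const@data)
  expect_identical(medianFilterStack(const, 0), const)

  hot <- matrix(10, 9, 9); hot[5, 5] <- 1000
  st <- ImageStack(array(hot, c(1, 1, 9, 9)), 5, 30)
  expect_true(all(medianFilterStack(st, 1)@data == 10))

  # brute-force disc-window oracle on a random image (interior pixels)
  set.seed(31)
  m <- matrix(sample(0:9, 81, TRUE), 9, 9)
  got <- medianFilterStack(ImageStack(array(m, c(1, 1, 9, 9)), 5, 30), 1)@data[1, 1, , ]
  for (i in 2:8) for (j in 2:8) {
    win <- c(m[i, j], m[i - 1, j], m[i + 1, j], m[i, j - 1], m[i, j + 1])
    expect_equal(got[i, j], median(win))
  }
})

test_that("adaptive equalization respects range and expands contrast", {
  const <- ImageStack(array(5, c(1, 1, 32, 32)), 5, 30)
  eq <- adaptiveEqualize(const, 16)
  expect_equal(length(unique(as.numeric(eq@data))), 1L)

  set.seed(41)
  blob <- 100 + 5 * exp(-((row(matrix(0, 64, 64)) - 32)^2 +
                          (col(matrix(0, 64, 64)) - 32)^2) / 50)
  st <- ImageStack(array(blob, c(1, 1, 64, 64)), 5, 30)
  eq <- adaptiveEqualize(st, 32, clip = 0.05)
  expect_gte(min(eq@data), 0)
  expect_lte(max(eq@data), 255)
  expect_gte(diff(range(eq@data)), diff(range(blob)))
})

test_that("the composite pipeline preserves axes and honors step switches", {
  p <- tinyParams(40, field = 600, seed = 22L)
  sim <- simulateAssay(p)
  pre <- preprocess(sim$stack, PreprocessConfig())
  expect_equal(dim(pre@data)[1:2], dim(sim$stack@data)[1:2])
  expect_gte(min(pre@data), 0)
  expect_lte(max(pre@data), 255)

  off <- PreprocessConfig(doRescaleIntensity = FALSE, doMedian = FALSE,
                          doEqualize = FALSE)
  expect_identical(preprocess(sim$stack, off)@data, sim$stack@data)
  expect_identical(preprocess(sim$stack, PreprocessConfig())@data, pre@data)
})

test_that("image stacks round-trip through the TIFF writer", {
  p <- tinyParams(30, field = 400, seed = 23L)
  sim <- simulateAssay(SimulationParams(fieldSize = c(400, 400),
                                        seedingDensity = 0.3e5, nFrames = 2L,
                                        seed = 23L))
  f <- tempfile(fileext = ".tiff")
  writeImageStack(sim$stack, f)
  st2 <- readImageStack(f)
  expect_identical(st2@data, sim$stack@data)
  expect_equal(pixelScale(st2), pixelScale(sim$stack))
  expect_equal(frameInterval(st2), frameInterval(sim$stack))
  expect_equal(channelNames(st2), channelNames(sim$stack))

  wm <- rasterizeWound(WoundShapeSpec("circle", size = 1), 10)
  fm <- tempfile(fileext = ".tiff")
  writeWoundMask(wm, fm)
  wm2 <- readWoundMask(fm)
  expect_identical(wm2@mask, wm@mask)
  expect_equal(wm2@origin, wm@origin)
})
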