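# Plate calibration, toolpath planning, rasterization.

test_that("calibrateWells reproduces corners and interpolates bilinearly", {
  plate <- PlateSpec(2, 2, 15)
  cal <- cornersFrom(c(0, 0, 10), c(9, 0, 10), c(0, 9, 11), c(9, 9, 11))
  w <- calibrateWells(plate, cal)
  expect_equal(unlist(w[w$row == 1 & w$col == 1, c("x", "y", "z")]),
               c(x = 0, y = 0, z = 10))
  expect_equal(unlist(w[w$row == 2 & w$col == 2, c("x", "y", "z")]),
               c(x = 9, y = 9, z = 11))

  # 4 x 6 plate against the independent unit-square oracle; the spec well
  # (row 1, col 2) of a 0-based convention is (row 2, col 3) here
  plate <- PlateSpec(4, 6, 15.54)
  cal <- cornersFrom(c(0, 0, 10), c(95, 0, 10), c(0, 57, 10), c(95, 57, 10))
  w <- calibrateWells(plate, cal)
  got <- unlist(w[w$row == 2 & w$col == 3, c("x", "y", "z")])
  expect_equal(unname(got), c(38, 19, 10))
  for (k in sample(nrow(w), 5)) {
    u <- (w$col[k] - 1) / 5; v <- (w$row[k] - 1) / 3
    oracle <- bilinearOracle(c(0, 0, 10), c(95, 0, 10), c(0, 57, 10), c(95, 57, 10), u, v)
    expect_equal(unname(unlist(w[k, c("x", "y", "z")])), oracle)
  }
})

test_that("tilted-stage z interpolates as a plane in v only", {
  plate <- PlateSpec(4, 6, 15.54)
  cal <- cornersFrom(c(0, 0, 10), c(95, 0, 10), c(0, 57, 12), c(95, 57, 12))
  w <- calibrateWells(plate, cal)
  # closed-form plane: z = 10 + 2 * v
  expect_equal(w$z, 10 + 2 * (w$row - 1) / 3)
  # constant within a row (to rounding), strictly increasing across rows
  expect_true(all(vapply(split(w$z, w$row), function(z) diff(range(z)) < 1e-12,
                         logical(1))))
  expect_true(all(diff(vapply(split(w$z, w$row), mean, numeric(1))) > 0.1))
})

test_that("calibration is exact for affine well layouts (machine precision)", {
  set.seed(101)
  for (rep in 1:5) {
    A <- matrix(rnorm(4, sd = 10), 2, 2)
    while (abs(det(A)) < 1) A <- matrix(rnorm(4, sd = 10), 2, 2)
    b <- rnorm(2, sd = 50)
    zc <- rnorm(3, sd = 0.1)  # z affine in (u, v) too
    truth <- function(r, c) {
      uv <- c((c - 1) / 5, (r - 1) / 3)
      c(A %*% uv + b, zc[1] + zc[2] * uv[1] + zc[3] * uv[2])
    }
    cal <- cornersFrom(truth(1, 1), truth(1, 6), truth(4, 1), truth(4, 6))
    w <- calibrateWells(PlateSpec(4, 6, 15), cal)
    err <- max(abs(t(mapply(truth, w$row, w$col)) - as.matrix(w[, c("x", "y", "z")])))
    expect_lt(err, 1e-9)
  }
})

test_that("degenerate or mismatched calibrations are rejected", {
  expect_error(cornersFrom(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "degenerate")
  plate1 <- PlateSpec(1, 6, 15)
  cal <- cornersFrom(c(0, 0, 0), c(95, 0, 0), c(0, 57, 0), c(95, 57, 0))
  expect_error(calibrateWells(plate1, cal), "1 row")
})

test_that("line toolpath is one stroke with the stated swept area", {
  spec <- WoundShapeSpec("line", size = 8, tipWidth = 0.318)
  tp <- planToolpath(spec)
  expect_length(tp@strokes, 1L)
  expect_equal(nrow(tp@strokes[[1]]), 2L)
  expect_true(tp@penDown)
  # rectangle + end-cap oracle
  oracle <- 8 * 0.318 + pi * (0.318 / 2)^2
  expect_equal(maskArea(rasterizeWound(tp, 10)), oracle, tolerance = 0.02)
})

test_that("tip-sized shapes degenerate to a dwell point", {
  tp <- planToolpath(WoundShapeSpec("circle", size = 0.4, tipWidth = 0.4))
  expect_length(tp@strokes, 1L)
  expect_equal(nrow(tp@strokes[[1]]), 1L)
})

test_that("square infill has the prescribed pass count and coverage", {
  spec <- WoundShapeSpec("square", size = 4.2, tipWidth = 0.8)
  tp <- planToolpath(spec, overlap = 0.25)
  # nominal spacing 0.8 * 0.75 = 0.6 mm fixes ceiling(4.2/0.6) + 1 = 8 passes
  expect_length(tp@strokes, 1L + 8L)
  ext <- list(x = c(-3, 3), y = c(-3, 3))
  shape <- rasterizeWound(spec, 10, extent = ext)
  swept <- rasterizeWound(tp, 10, extent = ext)
  covered <- sum(shape@mask & swept@mask) / sum(shape@mask)
  expect_gte(covered, 0.99)
})

test_that("swept toolpaths reproduce their shapes (Jaccard >= 0.98)", {
  specs <- list(WoundShapeSpec("square", size = 4.2, tipWidth = 0.8),
                WoundShapeSpec("circle", size = 4.68, tipWidth = 0.5),
                WoundShapeSpec("triangle", size = 5, tipWidth = 0.5, rotation = 15),
                WoundShapeSpec("polygon",
                               vertices = rbind(c(-2, -1), c(2, -1.5), c(2.5, 1),
                                                c(0, 2), c(-2, 1.5)),
                               tipWidth = 0.5))
  ext <- list(x = c(-4, 4), y = c(-4, 4))
  for (spec in specs) {
    tp <- planToolpath(spec)
    expect_gte(maskJaccard(rasterizeWound(spec, 10, extent = ext),
                           rasterizeWound(tp, 10, extent = ext)), 0.98)
  }
})

test_that("rasterized areas match analytic formulas and improve with resolution", {
  circle <- WoundShapeSpec("circle", size = 2 * 2.340)
  expect_equal(maskArea(rasterizeWound(circle, 5)), pi * 2.340^2, tolerance = 0.005)

  sq <- WoundShapeSpec("square", size = 3.1, rotation = 20)
  m <- rasterizeWound(sq, 10)
  # shoelace oracle on the rotated square outline
  shoelace <- abs(cfzkit:::shoelaceArea(cfzkit:::shapePolygon(sq)))
  perimPx <- 4 * 3.1 * 0.010
  expect_lt(abs(maskArea(m) - shoelace), perimPx)

  # empty toolpath rasterizes to an all-zero mask
  empty <- Toolpath(list(matrix(c(0, 0), 1, 2)), FALSE, tipWidth = 0.3)
  expect_equal(sum(rasterizeWound(empty, 10)@mask), 0)

  # quartering the pixel scale improves the total absolute error
  shapes <- list(circle, sq, WoundShapeSpec("triangle", size = 4, rotation = 7))
  analytic <- c(pi * 2.34^2, 3.1^2, sqrt(3) / 4 * 16)
  errAt <- function(ps) sum(abs(vapply(seq_along(shapes), function(i)
    maskArea(rasterizeWound(shapes[[i]], ps)) - analytic[i], numeric(1))))
  expect_lte(errAt(5), errAt(20))
})

test_that("invalid specs are rejected", {
  expect_error(WoundShapeSpec("blob", size = 1), "shape")
  expect_error(WoundShapeSpec("circle", size = -1), "size")
  expect_error(WoundShapeSpec("polygon",
                              vertices = rbind(c(0, 0), c(2, 0), c(1, 1),
                                               c(2, 2), c(0, 2))),
               "convex")
  big <- WoundShapeSpec("circle", size = 20)
  expect_error(planToolpath(big, wellDiameter = 15.5), "does not fit")
})

test_that("design objects round-trip through JSON/CSV", {
  spec <- WoundShapeSpec("triangle", size = 3, center = c(0.5, -0.2),
                         rotation = 30, well = c(2L, 5L), tipWidth = 0.4)
  f <- tempfile(fileext = ".json")
  writeWoundSpec(spec, f)
  spec2 <- readWoundSpec(f)
  expect_equal(spec2@shape, "triangle")
  expect_equal(spec2@size, 3)
  expect_equal(spec2@center, c(0.5, -0.2))
  expect_equal(spec2@well, c(2L, 5L))

  cal <- cornersFrom(c(0, 0, 10), c(95, 0, 10), c(0, 57, 12), c(95, 57, 12))
  fc <- tempfile(fileext = ".json")
  writeCornerCalibration(cal, fc)
  expect_equal(readCornerCalibration(fc)@corners, cal@corners)

  tp <- planToolpath(WoundShapeSpec("square", size = 2, tipWidth = 0.5))
  ft <- tempfile(fileext = ".json")
  writeToolpathJSON(tp, ft)
  tp2 <- readToolpathJSON(ft)
  expect_equal(tp2@strokes, tp@strokes)
  expect_equal(tp2@penDown, tp@penDown)
  fcsv <- tempfile(fileext = ".csv")
  writeToolpathCSV(tp, fcsv)
  csv <- read.csv(fcsv)
  expect_named(csv, c("stroke_id", "point_index", "x_mm", "y_mm", "pen_down"))
  expect_equal(nrow(csv), sum(vapply(tp@strokes, nrow, integer(1))))
})
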