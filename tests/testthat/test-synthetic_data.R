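# Monolayer simulator: seeding, wounding, dynamics, rendering, assay-level
# properties.

test_that("seeding realizes the requested density with the minimum spacing", {
  expect_equal(nrow(seedMonolayer(tinyParams(0))), 0L)

  # unit-conversion oracle: 0.40e5 cells/cm^2 x (2 x 2 mm = 0.04 cm^2) = 1600
  p <- SimulationParams(fieldSize = c(2000, 2000), seedingDensity = 0.40e5,
                        seed = 4L)
  cells <- seedMonolayer(p)
  expect_equal(nrow(cells), 1600L)
  expect_gte(min(dist(cbind(cells$x, cells$y))), p@minDist)

  # deterministic given the seed
  expect_identical(seedMonolayer(p), seedMonolayer(p))

  # beyond close packing the parameters are rejected outright
  expect_error(SimulationParams(fieldSize = c(1000, 1000), seedingDensity = 300,
                                minDist = 900, seed = 1L), "close-packing")
  # feasible by close packing but beyond the random-sequential-adsorption
  # jamming limit: dart throwing must give up after bounded attempts
  expect_error(seedMonolayer(SimulationParams(fieldSize = c(1000, 1000),
                                              seedingDensity = 9.5e3,
                                              minDist = 100, seed = 1L)),
               "infeasible")
})

test_that("applyWound removes exactly the cells inside the mask", {
  p <- tinyParams(150, seed = 2L)
  cells <- seedMonolayer(p)
  ps <- 10
  empty <- WoundMask(matrix(FALSE, 100, 100), ps)
  expect_identical(applyWound(cells, empty), cells)
  full <- WoundMask(matrix(TRUE, 100, 100), ps)
  expect_equal(nrow(applyWound(cells, full)), 0L)
  # half-plane: columns covering x >= 500 um
  half <- WoundMask(cbind(matrix(FALSE, 100, 50), matrix(TRUE, 100, 50)), ps)
  kept <- applyWound(cells, half)
  # brute-force point-in-mask check on centres
  expectKept <- cells[round(cells$x / ps) + 1 <= 50, ]
  expect_equal(sort(kept$id), sort(expectKept$id))
})

test_that("dynamics are frozen with zero speed and zero division", {
  p <- tinyParams(120, seed = 3L, speedMean = 0, speedSd = 0, divisionProb = 0)
  cells <- seedMonolayer(p)
  out <- stepDynamics(cells, p, seed = 11L)
  expect_equal(out$cells$x, cells$x)
  expect_equal(out$cells$y, cells$y)
  expect_equal(nrow(out$lineage), 0L)
})

test_that("division follows the branching-process expectation", {
  pdiv <- 0.02; Tn <- 15L; n0 <- 100L
  counts <- vapply(1:20, function(s) {
    p <- tinyParams(n0, seed = s, speedMean = 0, speedSd = 0, divisionProb = pdiv)
    cells <- seedMonolayer(p)
    for (t in seq_len(Tn)) cells <- stepDynamics(cells, p, frame = t + 1L)$cells
    nrow(cells)
  }, numeric(1))
  expected <- n0 * (1 + pdiv)^Tn
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * max(se, 1e-9))
})

test_that("strong edge bias points displacement at the wound", {
  p <- tinyParams(1, seed = 5L, biasStrength = 50, persistence = 0,
                  divisionProb = 0)
  # one cell at (500, 500); compact wound disc centred at (700, 520)
  cells <- seedMonolayer(p)
  cells$x <- 500; cells$y <- 500; cells$vx <- 0; cells$vy <- 0
  m <- matrix(FALSE, 100, 100)
  ctr <- c(700, 520) / 10 + 1
  for (i in 1:100) for (j in 1:100)
    if ((i - ctr[2])^2 + (j - ctr[1])^2 <= 9) m[i, j] <- TRUE
  wound <- WoundMask(m, 10)
  out <- stepDynamics(cells, p, wound = wound, seed = 6L)$cells
  disp <- c(out$x - 500, out$y - 500)
  target <- c(200, 20) / sqrt(sum(c(200, 20)^2))
  ang <- acos(sum(disp / sqrt(sum(disp^2)) * target)) * 180 / pi
  expect_lt(ang, 15)
})

test_that("rendering is additive with symmetric peaks and exact background", {
  p <- tinyParams(1, field = 500, seed = 7L, noiseScale = 0)
  none <- seedMonolayer(tinyParams(0, field = 500, noiseScale = 0))
  fr0 <- renderFrame(none, p)
  expect_true(all(fr0[1, , ] == p@background))

  one <- seedMonolayer(p)
  one$x <- 250; one$y <- 250
  fr1 <- renderFrame(one, p)[1, , ]
  pk <- which(fr1 == max(fr1), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(pk - (250 / p@pixelScale + 1))), 1)

  # two well-separated cells integrate to ~2x one cell
  two <- rbind(one, one)
  two$id <- 1:2; two$x <- c(120, 380); two$y <- c(120, 380)
  two$radius <- one$radius; two$aspect <- one$aspect
  two$theta <- one$theta; two$stain <- one$stain
  fr2 <- renderFrame(two, p)[1, , ]
  bg <- p@background * length(fr1)
  expect_equal(sum(fr2) - bg, 2 * (sum(fr1) - bg), tolerance = 0.01)
})

test_that("a one-frame assay equals wounded seeding, bit-identically reproducible", {
  p <- SimulationParams(fieldSize = c(1000, 1000), seedingDensity = 0.3e5,
                        nFrames = 1L, seed = 9L)
  spec <- WoundShapeSpec("line", size = 0.8, tipWidth = 0.318)
  sim <- simulateAssay(p, spec)
  expect_equal(dim(sim$stack@data)[2], 1L)

  set.seed(p@seed)
  cells <- seedMonolayer(p, seed = NA)
  cells <- applyWound(cells, cfzkit:::fieldWoundMask(spec, p))
  expect_equal(sim$truth@cells$x, cells$x)
  expect_equal(sim$truth@cells$id, cells$id)

  sim2 <- simulateAssay(p, spec)
  expect_identical(sim$stack@data, sim2$stack@data)
  expect_identical(sim$truth@cells, sim2$truth@cells)
})

test_that("cells are conserved: created only by division, removed only by wounding", {
  p <- SimulationParams(fieldSize = c(1000, 1000), seedingDensity = 0.3e5,
                        nFrames = 8L, seed = 10L, divisionProb = 0.01)
  spec <- WoundShapeSpec("line", size = 0.8, tipWidth = 0.318)
  sim <- simulateAssay(p, spec)
  gt <- sim$truth@cells
  for (t in 2:8) {
    prev <- gt$id[gt$frame == t - 1]
    cur <- gt$id[gt$frame == t]
    expect_true(all(prev %in% cur))  # nobody disappears
    born <- setdiff(cur, prev)
    expect_setequal(born, sim$truth@lineage$child[sim$truth@lineage$frame == t])
  }
})

test_that("a strongly biased line wound closes almost completely", {
  p <- SimulationParams(fieldSize = c(1500, 1500), seedingDensity = 0.4e5,
                        nFrames = 25L, seed = 12L, biasStrength = 1)
  spec <- WoundShapeSpec("line", size = 1.1, tipWidth = 0.318)
  sim <- simulateAssay(p, spec)
  a <- sim$truth@area
  expect_gt(a[1], 0)
  expect_lt(a[length(a)], 0.05 * a[1])
})

test_that("median wound area is non-increasing across frames (10 seeds, smoothed)", {
  spec <- WoundShapeSpec("line", size = 0.8, tipWidth = 0.318)
  areas <- sapply(1:10, function(s) {
    p <- SimulationParams(fieldSize = c(1000, 1000), seedingDensity = 0.35e5,
                          nFrames = 12L, seed = s, biasStrength = 0.2,
                          divisionProb = 0.002)
    simulateAssay(p, spec)$truth@area
  })
  med <- apply(areas, 1, median)
  sm <- stats::filter(med, rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-9))
})
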