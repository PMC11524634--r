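# Frame-to-frame linking, assignment optimality, property merging, lineage.

test_that("static nuclei produce full-length zero-displacement tracks", {
  set.seed(71)
  pos <- cbind(runif(20, 0, 500), runif(20, 0, 500))
  nuc <- do.call(rbind, lapply(1:6, function(t)
    data.frame(frame = t, label = 1:20, x_um = pos[, 1], y_um = pos[, 2])))
  tr <- linkTracks(nuc, TrackConfig(divisionLinking = FALSE))
  lens <- table(tr$track)
  expect_equal(length(lens), 20L)
  expect_true(all(lens == 6))
  disp <- tapply(seq_len(nrow(tr)), tr$track, function(ix) {
    d <- tr[ix, ]
    sqrt((d$x_um[6] - d$x_um[1])^2 + (d$y_um[6] - d$y_um[1])^2)
  })
  expect_true(all(disp == 0))
})

test_that("a constant-velocity nucleus yields exact per-frame displacement", {
  v <- c(8, -5)
  nuc <- do.call(rbind, lapply(1:8, function(t)
    data.frame(frame = t, label = 1L, x_um = 100 + v[1] * (t - 1),
               y_um = 200 + v[2] * (t - 1))))
  tr <- linkTracks(nuc, TrackConfig())
  expect_equal(length(unique(tr$track)), 1L)
  expect_equal(diff(tr$x_um), rep(v[1], 7))
  expect_equal(diff(tr$y_um), rep(v[2], 7))
})

test_that("two crossing nuclei match the exhaustive assignment oracle", {
  # 90 degree crossing; constant-velocity model should carry identity through
  tmax <- 9
  mk <- function(t) data.frame(
    frame = t, label = 1:2,
    x_um = c(100 + 10 * (t - 1), 140),
    y_um = c(140, 100 + 10 * (t - 1)))
  nuc <- do.call(rbind, lapply(1:tmax, mk))
  tr <- linkTracks(nuc, TrackConfig(divisionLinking = FALSE))
  expect_equal(length(unique(tr$track)), 2L)

  # exhaustive oracle: at each transition pick the pairing minimising total
  # squared prediction error under a constant-velocity extrapolation
  oracleTracks <- list(`1` = mk(1)[1, c("x_um", "y_um")],
                       `2` = mk(1)[2, c("x_um", "y_um")])
  assignPrev <- c(1L, 2L)
  for (t in 2:tmax) {
    obs <- mk(t)
    pred <- lapply(oracleTracks, function(h) {
      n <- nrow(h)
      if (n == 1) unlist(h[1, ]) else unlist(2 * h[n, ] - h[n - 1, ])
    })
    cost <- function(perm) sum(vapply(1:2, function(i)
      sum((unlist(obs[perm[i], c("x_um", "y_um")]) - pred[[i]])^2), numeric(1)))
    perm <- if (cost(c(1, 2)) <= cost(c(2, 1))) c(1L, 2L) else c(2L, 1L)
    for (i in 1:2)
      oracleTracks[[i]] <- rbind(oracleTracks[[i]], obs[perm[i], c("x_um", "y_um")])
  }
  for (i in 1:2) {
    got <- tr[tr$track == i, c("x_um", "y_um")]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(oracleTracks[[i]])))
  }
})

test_that("within-frame row order does not change the linking", {
  set.seed(72)
  p <- tinyParams(60, field = 600, seed = 73L, divisionProb = 0)
  p2 <- SimulationParams(fieldSize = c(600, 600), seedingDensity = 60 / (600 * 600 / 1e8),
                         nFrames = 6L, seed = 73L, divisionProb = 0)
  sim <- simulateAssay(p2)
  nuc <- gtAsNuclei(sim$truth)
  perm <- do.call(rbind, lapply(split(nuc, nuc$frame), function(d)
    d[sample(nrow(d)), , drop = FALSE]))
  t1 <- linkTracks(nuc, TrackConfig(divisionLinking = FALSE))
  t2 <- linkTracks(perm, TrackConfig(divisionLinking = FALSE))
  k1 <- t1[order(t1$frame, t1$label), c("frame", "label", "track")]
  k2 <- t2[order(t2$frame, t2$label), c("frame", "label", "track")]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})

test_that("track bookkeeping conserves births, deaths and frame ordering", {
  p <- SimulationParams(fieldSize = c(600, 600), seedingDensity = 0.2e5,
                        nFrames = 8L, seed = 74L, divisionProb = 0.01)
  sim <- simulateAssay(p)
  nuc <- gtAsNuclei(sim$truth)
  tr <- linkTracks(nuc, TrackConfig())
  expect_equal(nrow(tr), nrow(nuc))  # r = sum of track lengths
  byTrack <- split(tr$frame, tr$track)
  expect_true(all(vapply(byTrack, function(f) all(diff(f) >= 1), logical(1))))
  births <- length(byTrack)
  endsAtLast <- sum(vapply(byTrack, function(f) max(f) == max(nuc$frame), logical(1)))
  deaths <- births - endsAtLast
  expect_equal(births - deaths, endsAtLast)
})

test_that("divisions are recovered as parent-child lineage edges", {
  p <- SimulationParams(fieldSize = c(900, 900), seedingDensity = 0.25e5,
                        nFrames = 12L, seed = 75L, divisionProb = 0.012)
  sim <- simulateAssay(p)
  truthEdges <- sim$truth@lineage
  expect_gt(nrow(truthEdges), 3)
  nuc <- gtAsNuclei(sim$truth)
  tr <- linkTracks(nuc, TrackConfig(divisionLinking = TRUE))
  lin <- attr(tr, "lineage")
  # daughters are interchangeable after a division, so a division (mother m at
  # frame f) counts as recovered when a track birth at frame f is linked to
  # the track that held m at frame f - 1
  idOf <- setNames(nuc$id, paste(nuc$frame, nuc$label))
  tr$id <- idOf[paste(tr$frame, tr$label)]
  recovered <- vapply(seq_len(nrow(truthEdges)), function(k) {
    f <- truthEdges$frame[k]
    motherRow <- tr[tr$id == truthEdges$parent[k] & tr$frame == f - 1, ]
    if (nrow(motherRow) == 0) return(FALSE)
    any(lin$frame == f & lin$parent_track == motherRow$track[1])
  }, logical(1))
  expect_gte(mean(recovered), 0.8)
})

test_that("mergeProperties joins every row and rejects orphans", {
  nuc <- data.frame(frame = rep(1:3, each = 2), label = rep(1:2, 3),
                    x_um = runif(6), y_um = runif(6),
                    area_um2 = seq(100, 600, 100), eccentricity = runif(6))
  tr <- linkTracks(nuc, TrackConfig(maxLinkDist = 10))
  merged <- mergeProperties(tr, nuc)
  expect_equal(nrow(merged), nrow(tr))
  # spot check one (track, frame) row against its (frame, label) source
  k <- 3
  src <- nuc[nuc$frame == merged$frame[k] & nuc$label == merged$label[k], ]
  expect_equal(merged$area_um2[k], src$area_um2)

  bad <- tr
  bad$label <- bad$label + 100L
  expect_error(mergeProperties(bad, nuc), "no matching nucleus")
})

test_that("empty input produces an empty track table", {
  tr <- linkTracks(data.frame(frame = integer(0), label = integer(0),
                              x_um = numeric(0), y_um = numeric(0)))
  expect_equal(nrow(tr), 0L)
  expect_equal(nrow(attr(tr, "lineage")), 0L)
})
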