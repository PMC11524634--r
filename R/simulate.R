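# Agent-based monolayer simulator: dart-throwing seeding, wounding, persistent
# biased random-walk migration with contact separation and division, Gaussian
# spot rendering with Poisson noise, and complete ground truth.
#
# Field coordinates are image coordinates in um: x right, y down, origin at
# the top-left pixel centre; rendered pixel (i, j) (1-based) has its centre at
# ((j - 1) * pixelScale, (i - 1) * pixelScale).

newCellColumns <- function(n, params, ids, parent = rep(NA_integer_, n),
                           birthFrame = rep(1L, n)) {
  data.frame(id = ids,
             x = numeric(n), y = numeric(n), vx = numeric(n), vy = numeric(n),
             radius = pmax(1, rnorm(n, params@radiusMean, params@radiusSd)),
             aspect = pmax(1, rnorm(n, 1.15, 0.08)),
             theta = runif(n, 0, pi),
             stain = pmax(0, rnorm(n, params@stainLevel, 0.1 * params@stainLevel)),
             parent = parent, birthFrame = birthFrame)
}

#' Seed a confluent monolayer by dart throwing
#'
#' Places round(seedingDensity x field area) cells uniformly at random,
#' rejecting candidates closer than the minimum inter-nucleus distance to any
#' accepted cell. Errors out after a bounded number of rejections when the
#' requested density is infeasible for the minimum distance.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param seed random seed; default the params seed; NA uses the ambient RNG
#'   state (for use inside \code{\link{simulateAssay}}).
#' @return data.frame of cell states (id, x, y, vx, vy, radius, aspect,
#'   theta, stain, parent, birthFrame); positions in um.
#' @export
seedMonolayer <- function(params, seed = params@seed) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  if (!is.na(seed)) set.seed(seed)
  W <- params@fieldSize[1]; H <- params@fieldSize[2]
  n <- round(params@seedingDensity * (W * H / 1e8))
  cells <- newCellColumns(n, params, ids = seq_len(n))
  if (n == 0) return(cells)
  mind <- params@minDist
  if (mind > 0 && n >= 2 && mind > sqrt(W^2 + H^2))
    stop("infeasible: minDist exceeds the field diagonal")
  cell <- max(mind, 1)
  nx <- max(1L, ceiling(W / cell)); ny <- max(1L, ceiling(H / cell))
  bins <- vector("list", nx * ny)
  px <- numeric(n); py <- numeric(n)
  placed <- 0L
  attempts <- 0L
  maxAttempts <- 300L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop(sprintf("infeasible seeding: placed %d of %d cells after %d attempts",
                   placed, n, attempts))
    cx <- runif(1, 0, W); cy <- runif(1, 0, H)
    bx <- min(nx, max(1L, ceiling(cx / cell)))
    by <- min(ny, max(1L, ceiling(cy / cell)))
    ok <- TRUE
    if (mind > 0) {
      for (ox in max(1L, bx - 1L):min(nx, bx + 1L)) {
        for (oy in max(1L, by - 1L):min(ny, by + 1L)) {
          for (q in bins[[(oy - 1L) * nx + ox]]) {
            if ((px[q] - cx)^2 + (py[q] - cy)^2 < mind^2) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (!ok) break
      }
    }
    if (ok) {
      placed <- placed + 1L
      px[placed] <- cx; py[placed] <- cy
      b <- (by - 1L) * nx + bx
      bins[[b]] <- c(bins[[b]], placed)
    }
  }
  cells$x <- px; cells$y <- py
  cells
}

#' Remove the cells whose centre lies inside a wound mask
#'
#' @param cells cell-state data.frame (positions in um, field frame).
#' @param mask a \linkS4class{WoundMask} on the field frame.
#' @return the surviving cells, otherwise unaltered.
#' @export
applyWound <- function(cells, mask) {
  stopifnot(is.data.frame(cells), is(mask, "WoundMask"))
  if (nrow(cells) == 0) return(cells)
  s <- mask@pixelScale / 1000
  # the mask is assumed to cover the field: border cells clamp to edge pixels
  j <- pmin(ncol(mask@mask), pmax(1L, round((cells$x / 1000 - mask@origin[1]) / s) + 1L))
  i <- pmin(nrow(mask@mask), pmax(1L, round((cells$y / 1000 - mask@origin[2]) / s) + 1L))
  hit <- mask@mask[cbind(i, j)]
  out <- cells[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Advance the monolayer by one frame
#'
#' Each cell's velocity follows an AR(1) persistent random walk whose
#' stationary speed distribution has mean \code{speedMean}; cells within
#' \code{biasRadius} of the current wound additionally receive a bias of
#' magnitude \code{biasStrength x speedMean} pointing at their nearest wound
#' pixel. Positions advance by v x dt, are reflected at the field borders, and
#' overlapping cells are pushed apart to the minimum distance. Each cell then
#' divides with probability \code{divisionProb}, placing the daughter at the
#' minimum distance with a new id and a parent link.
#'
#' @param cells cell-state data.frame.
#' @param params a \linkS4class{SimulationParams}.
#' @param wound optional \linkS4class{WoundMask} (current cell-free region)
#'   driving the edge bias; NULL disables the bias.
#' @param frame frame index recorded as birthFrame of daughters.
#' @param seed optional seed (NA = ambient RNG).
#' @return list(cells = updated data.frame, lineage = data.frame(parent,
#'   child, frame) of this step's divisions).
#' @export
stepDynamics <- function(cells, params, wound = NULL, frame = 1L, seed = NA) {
  stopifnot(is.data.frame(cells), is(params, "SimulationParams"))
  if (!is.na(seed)) set.seed(seed)
  lineage <- data.frame(parent = integer(0), child = integer(0), frame = integer(0))
  n <- nrow(cells)
  if (n == 0) return(list(cells = cells, lineage = lineage))
  W <- params@fieldSize[1]; H <- params@fieldSize[2]
  dt <- params@frameInterval / 60
  p <- params@persistence
  sigComp <- params@speedMean / sqrt(pi / 2)
  noiseSd <- sigComp * sqrt(1 - p^2)
  vx <- p * cells$vx + rnorm(n, 0, noiseSd)
  vy <- p * cells$vy + rnorm(n, 0, noiseSd)
  if (!is.null(wound) && params@biasStrength > 0 && any(wound@mask)) {
    s <- wound@pixelScale / 1000
    pts <- cbind((cells$x / 1000 - wound@origin[1]) / s + 1,
                 (cells$y / 1000 - wound@origin[2]) / s + 1)
    nd <- nearest_mask_dist_cpp(wound@mask, pts)
    distUm <- nd[, 1] * wound@pixelScale
    inRange <- is.finite(distUm) & distUm > 0 & distUm <= params@biasRadius
    mag <- params@biasStrength * params@speedMean
    vx[inRange] <- vx[inRange] + mag * nd[inRange, 2]
    vy[inRange] <- vy[inRange] + mag * nd[inRange, 3]
  }
  x <- cells$x + vx * dt
  y <- cells$y + vy * dt
  x <- ifelse(x < 0, -x, ifelse(x > W, 2 * W - x, x))
  y <- ifelse(y < 0, -y, ifelse(y > H, 2 * H - y, y))
  x <- pmin(pmax(x, 0), W); y <- pmin(pmax(y, 0), H)
  if (params@minDist > 0 && n > 1) {
    sep <- resolve_overlaps_cpp(x, y, params@minDist, 4L, W, H)
    x <- sep[, 1]; y <- sep[, 2]
  }
  cells$x <- x; cells$y <- y; cells$vx <- vx; cells$vy <- vy
  if (params@divisionProb > 0) {
    divides <- which(runif(n) < params@divisionProb)
    if (length(divides)) {
      m <- length(divides)
      ids <- max(cells$id) + seq_len(m)
      kids <- newCellColumns(m, params, ids = ids,
                             parent = cells$id[divides],
                             birthFrame = rep(as.integer(frame), m))
      ang <- runif(m, 0, 2 * pi)
      d0 <- max(params@minDist, 1)
      kids$x <- pmin(pmax(cells$x[divides] + d0 * cos(ang), 0), W)
      kids$y <- pmin(pmax(cells$y[divides] + d0 * sin(ang), 0), H)
      kids$vx <- cells$vx[divides]; kids$vy <- cells$vy[divides]
      cells <- rbind(cells, kids)
      lineage <- data.frame(parent = kids$parent, child = kids$id,
                            frame = as.integer(frame))
    }
  }
  rownames(cells) <- NULL
  list(cells = cells, lineage = lineage)
}

#' Render one frame of the nuclear channel (plus optional channels)
#'
#' The nuclear channel is the sum of anisotropic Gaussian spots (peak
#' amplitude = per-cell stain level, sd = nucleus radius) over a constant
#' background, with Poisson noise applied to the expected counts when
#' \code{noiseScale > 0}. Output is integer-valued.
#'
#' @param cells cell-state data.frame.
#' @param params a \linkS4class{SimulationParams}.
#' @param seed optional seed (NA = ambient RNG).
#' @return numeric array (channels, y, x); channel 1 is "nuclear", an
#'   "oblique" pseudo-brightfield channel is appended when configured.
#' @export
renderFrame <- function(cells, params, seed = NA) {
  stopifnot(is(params, "SimulationParams"))
  if (!is.na(seed)) set.seed(seed)
  ps <- params@pixelScale
  H <- max(1L, round(params@fieldSize[2] / ps))
  W <- max(1L, round(params@fieldSize[1] / ps))
  base <- matrix(params@background, H, W)
  if (nrow(cells)) {
    sdpx <- cells$radius / ps
    spots <- cbind(cells$x / ps + 1, cells$y / ps + 1,
                   sdpx * sqrt(cells$aspect), sdpx / sqrt(cells$aspect),
                   cells$theta, cells$stain)
    nuclear <- render_spots_cpp(base, spots)
  } else nuclear <- base
  if (params@noiseScale > 0) {
    lam <- pmax(nuclear, 0) / params@noiseScale
    nuclear <- matrix(rpois(length(lam), lam) * params@noiseScale, H, W)
  } else nuclear <- round(nuclear)
  nc <- if (params@obliqueChannel) 2L else 1L
  out <- array(0, dim = c(nc, H, W))
  out[1, , ] <- nuclear
  if (nc == 2L) {
    tex <- gauss_blur_cpp(matrix(rnorm(H * W, 0, 20), H, W), 3)
    out[2, , ] <- round(pmax(100 + tex, 0))
  }
  out
}

# rasterize a wound spec onto the field grid at the given pixel scale so that
# pixel (1, 1) centre sits at field coordinate (0, 0) um (the well centre maps
# to the field centre)
fieldWoundMask <- function(spec, params, pixelScale = params@pixelScale) {
  W <- params@fieldSize[1]; H <- params@fieldSize[2]
  ext <- list(x = (c(0, W) - W / 2 - pixelScale / 2) / 1000,
              y = (c(0, H) - H / 2 - pixelScale / 2) / 1000)
  m <- rasterizeWound(spec, pixelScale, extent = ext)
  WoundMask(m@mask, pixelScale, origin = c(0, 0))
}

#' Simulate a complete wounded-monolayer assay
#'
#' Seeds the monolayer, removes the cells under the wound, then alternates
#' rendering and dynamics for \code{nFrames} frames. Ground truth contains
#' the per-frame cell table, the lineage, and a per-frame true wound mask
#' (cell-free region recomputed from the true positions by the same density
#' thresholding the analysis pipeline uses) with its area series; for line
#' wounds, the true width profile statistics per frame are stored as well.
#' All outputs are a pure function of (params, wound, seed).
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param wound a \linkS4class{WoundShapeSpec}, a field-frame
#'   \linkS4class{WoundMask}, or NULL for an unwounded monolayer.
#' @param gridStep grid step (um) of the ground-truth wound masks.
#' @return list(stack = \linkS4class{ImageStack},
#'   truth = \linkS4class{GroundTruth}).
#' @export
simulateAssay <- function(params, wound = NULL, gridStep = 20) {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  set.seed(params@seed)
  cells <- seedMonolayer(params, seed = NA)
  isLine <- is(wound, "WoundShapeSpec") && wound@shape == "line"
  woundMask <- NULL
  locus <- NULL
  if (is(wound, "WoundShapeSpec")) {
    woundMask <- fieldWoundMask(wound, params)
    locus <- fieldWoundMask(wound, params, pixelScale = gridStep)
  } else if (is(wound, "WoundMask")) {
    woundMask <- wound
    locus <- wound
  } else if (!is.null(wound)) stop("wound must be a WoundShapeSpec, WoundMask or NULL")
  if (!is.null(woundMask)) cells <- applyWound(cells, woundMask)

  nf <- params@nFrames
  ps <- params@pixelScale
  H <- max(1L, round(params@fieldSize[2] / ps))
  W <- max(1L, round(params@fieldSize[1] / ps))
  nc <- if (params@obliqueChannel) 2L else 1L
  arr <- array(0, dim = c(nc, nf, H, W))
  gtRows <- vector("list", nf)
  masks <- vector("list", nf)
  area <- numeric(nf)
  wMean <- rep(NA_real_, nf); wSd <- rep(NA_real_, nf)
  lineage <- data.frame(parent = integer(0), child = integer(0), frame = integer(0))
  curWound <- NULL
  for (t in seq_len(nf)) {
    gtRows[[t]] <- data.frame(frame = t, id = cells$id, x = cells$x, y = cells$y,
                              radius = cells$radius)
    gm <- woundMaskFromPoints(cbind(cells$x, cells$y), params@fieldSize,
                              gridStep = gridStep, locus = locus)
    masks[[t]] <- gm
    area[t] <- maskArea(gm)
    if (isLine && any(gm@mask) && !all(gm@mask)) {
      wp <- tryCatch(widthProfile(extractEdges(gm, mode = "scratch")),
                     error = function(e) NULL)
      if (!is.null(wp)) { wMean[t] <- wp@meanWidth; wSd[t] <- wp@sdWidth }
    }
    arr[, t, , ] <- renderFrame(cells, params, seed = NA)
    curWound <- gm
    if (t < nf) {
      st <- stepDynamics(cells, params, wound = curWound, frame = t + 1L, seed = NA)
      cells <- st$cells
      if (nrow(st$lineage)) lineage <- rbind(lineage, st$lineage)
    }
  }
  stack <- ImageStack(arr, ps, params@frameInterval,
                      channelNames = c("nuclear", "oblique")[seq_len(nc)])
  truth <- new("GroundTruth", cells = do.call(rbind, gtRows), lineage = lineage,
               masks = masks, area = area, widthMean = wMean, widthSd = wSd)
  list(stack = stack, truth = truth)
}
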