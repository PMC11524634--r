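# Wound quantification: density-based wound masks, contour wound edges with
# total-least-squares fits, width profiles, areas and closure curves.

#' Wound mask from a point pattern by density thresholding
#'
#' Point centroids are binned onto a grid and smoothed with a Gaussian kernel
#' (bandwidth = 2 x grid step); pixels whose density falls below
#' \code{threshold} x the median (monolayer) density are wound candidates.
#' The largest candidate component overlapping the designed wound locus (or
#' the largest overall when no locus is given) is returned, after dropping
#' components smaller than \code{minComponentCells} missing cells' worth of
#' area and filling holes smaller than one nucleus.
#'
#' @param points n x 2 matrix of (x, y) positions in um (field frame).
#' @param fieldSize (width, height) of the field, um.
#' @param gridStep grid step, um.
#' @param threshold fraction of the median density below which a pixel is
#'   wound (default 0.3).
#' @param bandwidth Gaussian kernel sd, um (default 2 x gridStep).
#' @param locus optional \linkS4class{WoundMask} marking where the wound was
#'   designed.
#' @param minComponentCells minimum component size in units of missing cells
#'   (default 20).
#' @param holeArea holes up to this area (um^2, default 400: about one
#'   nucleus) inside the wound are filled.
#' @param smoothing boundary-regularization scale, um (default = bandwidth):
#'   the selected component is smoothed by a Gaussian of this sd and
#'   re-thresholded at 0.5, suppressing edge wiggle from density-sampling
#'   noise without biasing the edge position; 0 disables.
#' @return a \linkS4class{WoundMask} on the density grid (pixel (1,1) centre
#'   at (gridStep/2, gridStep/2) um).
#' @export
woundMaskFromPoints <- function(points, fieldSize, gridStep = 20, threshold = 0.3,
                                bandwidth = 2 * gridStep, locus = NULL,
                                minComponentCells = 20, holeArea = 400,
                                smoothing = bandwidth) {
  W <- max(1L, round(fieldSize[1] / gridStep))
  H <- max(1L, round(fieldSize[2] / gridStep))
  origin <- c(gridStep / 2, gridStep / 2) / 1000
  points <- as.matrix(points)
  if (nrow(points) == 0) {
    warning("no points: returning a full-frame wound mask")
    return(WoundMask(matrix(TRUE, H, W), gridStep, origin))
  }
  j <- pmin(W, pmax(1L, floor(points[, 1] / gridStep) + 1L))
  i <- pmin(H, pmax(1L, floor(points[, 2] / gridStep) + 1L))
  counts <- matrix(0, H, W)
  for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1
  dens <- gauss_blur_cpp(counts, bandwidth / gridStep)
  med <- median(dens)
  if (med <= 0) {
    warning("degenerate density (median 0): returning a full-frame wound mask")
    return(WoundMask(matrix(TRUE, H, W), gridStep, origin))
  }
  cand <- dens < threshold * med
  if (!any(cand)) return(WoundMask(matrix(FALSE, H, W), gridStep, origin))
  lab <- conn_comp_cpp(cand)
  sizes <- tabulate(lab[lab > 0])
  densityPerUm2 <- nrow(points) / (fieldSize[1] * fieldSize[2])
  minPix <- (minComponentCells / densityPerUm2) / gridStep^2
  keep <- which(sizes >= minPix)
  if (length(keep) == 0) return(WoundMask(matrix(FALSE, H, W), gridStep, origin))
  chosen <- if (!is.null(locus)) {
    lm <- locus@mask
    hh <- min(nrow(lm), H); ww <- min(ncol(lm), W)
    ov <- vapply(keep, function(l)
      sum(lab[seq_len(hh), seq_len(ww)] == l & lm[seq_len(hh), seq_len(ww)]), numeric(1))
    if (max(ov) > 0) keep[which.max(ov)] else keep[which.max(sizes[keep])]
  } else keep[which.max(sizes[keep])]
  wound <- lab == chosen
  # fill interior holes smaller than one nucleus
  holes <- conn_comp_cpp(!wound)
  if (max(holes) > 0) {
    border <- unique(c(holes[1, ], holes[H, ], holes[, 1], holes[, W]))
    hs <- tabulate(holes[holes > 0])
    for (h in setdiff(which(hs * gridStep^2 <= holeArea), border))
      wound[holes == h] <- TRUE
  }
  if (smoothing > 0 && any(wound))
    wound <- gauss_blur_cpp(wound + 0, smoothing / gridStep) > 0.5
  WoundMask(wound, gridStep, origin)
}

#' Wound mask from a segmented-nuclei table
#'
#' Applies \code{\link{woundMaskFromPoints}} to the centroids of one frame of
#' a nuclei table. With zero nuclei, a full-frame mask is returned with a
#' warning.
#'
#' @param rows nuclei table rows for one frame (columns x_um, y_um).
#' @param fieldSize (width, height) in um.
#' @param ... passed to \code{\link{woundMaskFromPoints}}.
#' @export
woundMaskFromDensity <- function(rows, fieldSize, ...) {
  woundMaskFromPoints(cbind(rows$x_um, rows$y_um), fieldSize, ...)
}

# contours of a mask at the 0.5 level, in um (image frame), via marching
# squares (grDevices::contourLines). Returns a list of n x 2 matrices with a
# "closed" attribute.
maskContours <- function(mask) {
  m <- mask@mask
  ps <- mask@pixelScale
  ys <- mask@origin[2] * 1000 + (seq_len(nrow(m)) - 1) * ps
  xs <- mask@origin[1] * 1000 + (seq_len(ncol(m)) - 1) * ps
  cl <- contourLines(x = ys, y = xs, z = m + 0, levels = 0.5)
  lapply(cl, function(cc) {
    pts <- cbind(x = cc$y, y = cc$x)
    # marching squares on a binary raster may close a loop with a coarse last
    # step, so closedness is judged relative to the contour length
    gap <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
    len <- contourLength(pts)
    attr(pts, "closed") <- gap <= max(3 * ps, 0.06 * len)
    pts
  })
}

contourLength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

fitEdgeLine <- function(pts) {
  ctr <- colMeans(pts)
  sc <- sweep(pts, 2, ctr)
  sv <- svd(sc, nu = 0, nv = 2)
  dir <- sv$v[, 1]
  resid <- sc %*% sv$v[, 2]
  new("EdgeLine", point = as.numeric(ctr), direction = as.numeric(dir),
      nPoints = nrow(pts), rmsResidual = sqrt(mean(resid^2)),
      contour = unname(pts))
}

#' Extract wound edges from a wound mask
#'
#' Boundary contours are traced by marching squares at the 0.5 level. In
#' scratch mode the two longest flank contours are each fit by orthogonal
#' (total-least-squares) regression, giving two \linkS4class{EdgeLine}s; a
#' single closed contour (a band not touching the frame) is split at the two
#' extremes of its principal axis into two flanks first. In shape mode the
#' longest closed contour is returned as a polygon for area work.
#'
#' @param mask a non-empty \linkS4class{WoundMask}.
#' @param mode "scratch" or "shape".
#' @return scratch: list of two \linkS4class{EdgeLine}; shape: n x 2 matrix
#'   (um).
#' @export
extractEdges <- function(mask, mode = c("scratch", "shape")) {
  mode <- match.arg(mode)
  stopifnot(is(mask, "WoundMask"))
  if (!any(mask@mask)) stop("empty wound mask: no edges to extract")
  cont <- maskContours(mask)
  if (length(cont) == 0) stop("no contours found")
  len <- vapply(cont, contourLength, numeric(1))
  # drop minor contours (holes, speckles) relative to the dominant one
  keep <- len >= 0.15 * max(len)
  cont <- cont[keep]; len <- len[keep]
  closed <- vapply(cont, function(p) isTRUE(attr(p, "closed")), logical(1))
  if (mode == "shape") {
    if (!any(closed)) stop("no closed contour; is this a border-spanning scratch?")
    return(cont[closed][[which.max(len[closed])]][, 1:2, drop = FALSE])
  }
  longest <- which.max(len)
  open <- which(!closed)
  if (!closed[longest] && length(open) >= 2) {
    pick <- open[order(len[open], decreasing = TRUE)][1:2]
    return(list(fitEdgeLine(cont[[pick[1]]]), fitEdgeLine(cont[[pick[2]]])))
  }
  if (any(closed)) {
    # band fully inside the frame: split its boundary at the principal-axis
    # extremes into the two flanks
    pts <- cont[closed][[which.max(len[closed])]]
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr), nu = 0, nv = 1)
    proj <- as.numeric(sweep(pts, 2, ctr) %*% sv$v[, 1])
    iMin <- which.min(proj); iMax <- which.max(proj)
    lo <- min(iMin, iMax); hi <- max(iMin, iMax)
    a <- pts[lo:hi, , drop = FALSE]
    b <- rbind(pts[hi:nrow(pts), , drop = FALSE], pts[seq_len(lo), , drop = FALSE])
    if (nrow(a) >= 2 && nrow(b) >= 2) return(list(fitEdgeLine(a), fitEdgeLine(b)))
  }
  stop("fewer than two flank contours found in scratch mode; try mode = 'shape'")
}

#' Wound width profile between two wound edges
#'
#' The scratch axis is the bisector of the two fitted edge lines; at uniform
#' arc positions along the overlap of the two contours' projections onto that
#' axis, the local width is the distance between the two actual contours
#' measured perpendicular to the axis. The fitted lines define only the axis;
#' the raw contours carry the edge roughness into sigma.
#'
#' @param edges list of two \linkS4class{EdgeLine} from
#'   \code{\link{extractEdges}}.
#' @param nSamples number of arc positions (default 100).
#' @return a \linkS4class{WidthProfile}.
#' @export
widthProfile <- function(edges, nSamples = 100L) {
  stopifnot(is.list(edges), length(edges) == 2L,
            is(edges[[1]], "EdgeLine"), is(edges[[2]], "EdgeLine"))
  d1 <- edges[[1]]@direction
  d2 <- edges[[2]]@direction
  if (sum(d1 * d2) < 0) d2 <- -d2
  axis <- d1 + d2
  axis <- axis / sqrt(sum(axis^2))
  perp <- c(-axis[2], axis[1])
  p0 <- (edges[[1]]@point + edges[[2]]@point) / 2
  proj <- lapply(edges, function(e) {
    rel <- sweep(e@contour, 2, p0)
    list(s = as.numeric(rel %*% axis), o = as.numeric(rel %*% perp))
  })
  lo <- max(min(proj[[1]]$s), min(proj[[2]]$s))
  hi <- min(max(proj[[1]]$s), max(proj[[2]]$s))
  if (hi <= lo) stop("edge contours do not overlap along the scratch axis")
  s <- seq(lo, hi, length.out = nSamples)
  off <- lapply(proj, function(p)
    stats::approx(p$s, p$o, xout = s, ties = mean, rule = 2)$y)
  w <- abs(off[[1]] - off[[2]])
  new("WidthProfile", s = s, width = w, meanWidth = mean(w),
      sdWidth = if (length(w) > 1) sd(w) else 0)
}

#' Wound closure curve from per-frame wound masks
#'
#' area(t) is the mask pixel count times the pixel area (mm^2); percent
#' closure is 100 x (1 - area(t)/area(0)); the closure time is the first time
#' the area falls to <= epsilon x the initial area (epsilon absorbs stray
#' discretization pixels), reported at frame resolution, or Inf ("not closed
#' by the horizon") otherwise.
#'
#' @param masks list of \linkS4class{WoundMask}, one per frame.
#' @param frameIntervalMin minutes between frames.
#' @param epsilon closed-fraction threshold (default 0.005).
#' @return a \linkS4class{ClosureCurve}.
#' @export
closureCurve <- function(masks, frameIntervalMin, epsilon = 0.005) {
  stopifnot(length(masks) >= 1)
  areas <- vapply(masks, maskArea, numeric(1))
  if (areas[1] == 0) stop("initial wound area is zero: percent closure undefined")
  tt <- (seq_along(areas) - 1) * frameIntervalMin / 60
  pct <- 100 * (1 - areas / areas[1])
  closedAt <- which(areas <= epsilon * areas[1])
  new("ClosureCurve", time = tt, area = areas, percentClosure = pct,
      closureTime = if (length(closedAt)) tt[closedAt[1]] else Inf,
      horizon = tt[length(tt)], epsilon = epsilon)
}

#' Synthetic scratch band mask with a stored ground-truth width series
#'
#' Builds a band (scratch) mask crossing the whole field at a given angle,
#' with smooth pseudo-random sinusoidal perturbations of both edges, and
#' returns the exact width series used to draw it. Used to exercise the width
#' estimator against known truth.
#'
#' @param fieldSize (width, height) um.
#' @param width nominal band width, um.
#' @param pixelScale um/px.
#' @param angle band angle, degrees.
#' @param amplitude edge perturbation amplitude, um (0 = parallel edges).
#' @param nWaves number of sinusoidal components per edge.
#' @param seed random seed for the perturbation phases/wavelengths.
#' @return list(mask = \linkS4class{WoundMask}, s = axis positions (um),
#'   width = true width at s (um)).
#' @export
syntheticBandMask <- function(fieldSize, width, pixelScale = 5, angle = 0,
                              amplitude = 0, nWaves = 3L, seed = 1L) {
  set.seed(seed)
  W <- round(fieldSize[1] / pixelScale); H <- round(fieldSize[2] / pixelScale)
  th <- angle * pi / 180
  ax <- c(cos(th), sin(th))
  ctr <- fieldSize / 2
  mkEdge <- function() {
    lam <- runif(nWaves, fieldSize[1] / 6, fieldSize[1] / 2)
    phi <- runif(nWaves, 0, 2 * pi)
    amp <- amplitude * runif(nWaves, 0.5, 1) / nWaves
    function(u) {
      if (amplitude == 0) return(rep(0, length(u)))
      rowSums(vapply(seq_len(nWaves),
                     function(k) amp[k] * sin(2 * pi * u / lam[k] + phi[k]),
                     numeric(length(u))))
    }
  }
  e1 <- mkEdge(); e2 <- mkEdge()
  xs <- (seq_len(W) - 1) * pixelScale
  ys <- (seq_len(H) - 1) * pixelScale
  gx <- matrix(xs, H, W, byrow = TRUE) - ctr[1]
  gy <- matrix(ys, H, W) - ctr[2]
  u <- gx * ax[1] + gy * ax[2]
  p <- -gx * ax[2] + gy * ax[1]
  ev1 <- matrix(e1(as.numeric(u)), H, W)
  ev2 <- matrix(e2(as.numeric(u)), H, W)
  mask <- p <= width / 2 + ev1 & p >= -(width / 2 + ev2)
  sGrid <- seq(min(u), max(u), length.out = 200L)
  list(mask = WoundMask(mask, pixelScale, origin = c(0, 0)),
       s = sGrid, width = width + e1(sGrid) + e2(sGrid))
}
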