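# Wound geometry: shape outlines, toolpath planning, rasterization.

# Boundary polygon of a filled shape spec, in well-centric mm (rotation and
# centre offset applied). Line specs have no filled outline; see lineSegment().
shapePolygon <- function(spec, nCircle = 96L) {
  base <- switch(spec@shape,
    circle = {
      r <- spec@size / 2
      th <- seq(0, 2 * pi, length.out = nCircle + 1L)[-(nCircle + 1L)]
      cbind(r * cos(th), r * sin(th))
    },
    square = {
      h <- spec@size / 2
      cbind(c(-h, h, h, -h), c(-h, -h, h, h))
    },
    triangle = {
      # equilateral, centroid at origin
      s <- spec@size
      R <- s / sqrt(3)
      th <- pi / 2 + c(0, 2, 4) * pi / 3
      cbind(R * cos(th), R * sin(th))
    },
    polygon = sweep(spec@vertices, 2, colMeans(spec@vertices)),
    line = stop("a line has no filled outline"))
  center <- if (spec@shape == "polygon") colMeans(spec@vertices) else c(0, 0)
  sweep(rotate2d(base, spec@rotation), 2, -(center + spec@center))
}

lineSegment <- function(spec) {
  h <- spec@size / 2
  ends <- rbind(c(-h, 0), c(h, 0))
  sweep(rotate2d(ends, spec@rotation), 2, -spec@center)
}

shapeBoundingRadius <- function(spec) {
  if (spec@shape == "line") {
    p <- lineSegment(spec)
  } else {
    p <- shapePolygon(spec)
  }
  max(sqrt(rowSums(p^2)))
}

checkFitsWell <- function(spec, wellDiameter) {
  r <- shapeBoundingRadius(spec) + spec@tipWidth / 2
  if (2 * r > wellDiameter)
    stop(sprintf("shape (bounding circle %.2f mm incl. tip) does not fit a %.2f mm well",
                 2 * r, wellDiameter))
  invisible(TRUE)
}

#' Plan the tip toolpath that sweeps out a wound shape
#'
#' A line becomes a single straight pen-down stroke. Filled shapes (circle,
#' square, triangle, convex polygon) become a boundary stroke along the
#' half-tip-inset outline followed by serpentine infill passes. The nominal
#' pass spacing is \code{tipWidth * (1 - overlap)}; it fixes the pass count
#' \code{ceiling(span / spacing) + 1} over the full shape span, and the passes
#' are then placed evenly across the half-tip-eroded span so the swept region
#' (every pass dilated by half the tip width) reproduces the shape without
#' overshooting its boundary.
#'
#' Shapes smaller than the tip (e.g. a circle whose diameter equals the tip
#' width) degenerate to a single dwell point at the shape centre.
#'
#' @param spec a \linkS4class{WoundShapeSpec}.
#' @param overlap fractional overlap of adjacent passes (default 0.25).
#' @param wellDiameter optional well diameter (mm) to validate fit against.
#' @return a \linkS4class{Toolpath}.
#' @export
planToolpath <- function(spec, overlap = 0.25, wellDiameter = NULL) {
  stopifnot(is(spec, "WoundShapeSpec"))
  validObject(spec)
  if (!is.null(wellDiameter)) checkFitsWell(spec, wellDiameter)
  tip <- spec@tipWidth
  if (spec@shape == "line")
    return(Toolpath(list(lineSegment(spec)), TRUE, tip))

  poly <- shapePolygon(spec)
  eroded <- insetConvexPolygon(poly, tip / 2)
  if (!is.null(eroded)) {
    ctr <- colMeans(eroded)
    if (max(sqrt(rowSums(sweep(eroded, 2, ctr)^2))) < 0.02 * tip) eroded <- NULL
  }
  if (is.null(eroded)) {
    # shape no larger than the tip: a single dwell point suffices
    centroid <- matrix(colMeans(poly), 1, 2)
    return(Toolpath(list(centroid), TRUE, tip))
  }
  strokes <- list(rbind(eroded, eroded[1, , drop = FALSE]))  # closed boundary
  d <- tip * (1 - overlap)
  spanFull <- diff(range(poly[, 2]))
  ylo <- min(eroded[, 2]); yhi <- max(eroded[, 2])
  n <- ceiling(spanFull / d) + 1L
  ys <- if (n == 1L) (ylo + yhi) / 2 else seq(ylo, yhi, length.out = n)
  flip <- FALSE
  for (y in ys) {
    xs <- convexLineCrossings(eroded, y)
    if (is.null(xs)) next
    pts <- rbind(c(xs[1], y), c(xs[2], y))
    if (flip) pts <- pts[2:1, , drop = FALSE]
    strokes[[length(strokes) + 1L]] <- pts
    flip <- !flip
  }
  Toolpath(strokes, rep(TRUE, length(strokes)), tip)
}

# x interval where the horizontal line y = y0 crosses a convex polygon
convexLineCrossings <- function(poly, y0) {
  n <- nrow(poly)
  xs <- numeric(0)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1, ]
    if ((a[2] <= y0 && b[2] > y0) || (b[2] <= y0 && a[2] > y0)) {
      t <- (y0 - a[2]) / (b[2] - a[2])
      xs <- c(xs, a[1] + t * (b[1] - a[1]))
    } else if (a[2] == y0 && b[2] == y0) {
      xs <- c(xs, a[1], b[1])
    }
  }
  if (length(xs) < 2) return(NULL)
  range(xs)
}

#' Rasterize a wound shape or toolpath into a binary mask
#'
#' For a \linkS4class{WoundShapeSpec}, the mask is the analytic shape (a line
#' is the stadium of its tip-width sweep). For a \linkS4class{Toolpath}, the
#' mask is the union of all pen-down strokes dilated by half the tip width.
#' Mask area converges to the analytic area as the pixel scale decreases.
#'
#' @param x a \linkS4class{WoundShapeSpec} or \linkS4class{Toolpath}.
#' @param pixelScale um/px (> 0).
#' @param extent optional list(x = c(min, max), y = c(min, max)) in mm fixing
#'   the raster frame; default is the object bounding box plus a tip-width
#'   margin.
#' @return a \linkS4class{WoundMask} (origin = well-centric mm of pixel (1,1)).
#' @export
rasterizeWound <- function(x, pixelScale, extent = NULL) {
  stopifnot(pixelScale > 0)
  s <- pixelScale / 1000  # mm per px
  if (is(x, "WoundShapeSpec")) {
    validObject(x)
    pts <- if (x@shape == "line") lineSegment(x) else shapePolygon(x)
    margin <- x@tipWidth
  } else if (is(x, "Toolpath")) {
    validObject(x)
    down <- x@strokes[x@penDown]
    if (length(down) == 0) {
      ext <- extent %||% list(x = c(0, 1), y = c(0, 1))
      H <- max(1L, round(diff(ext$y) / s)); W <- max(1L, round(diff(ext$x) / s))
      return(WoundMask(matrix(FALSE, H, W), pixelScale,
                       origin = c(ext$x[1] + s / 2, ext$y[1] + s / 2)))
    }
    pts <- do.call(rbind, down)
    margin <- x@tipWidth
  } else stop("x must be a WoundShapeSpec or a Toolpath")

  ext <- extent %||% list(x = range(pts[, 1]) + c(-margin, margin),
                          y = range(pts[, 2]) + c(-margin, margin))
  W <- max(1L, round(diff(ext$x) / s))
  H <- max(1L, round(diff(ext$y) / s))
  origin <- c(ext$x[1] + s / 2, ext$y[1] + s / 2)
  toPx <- function(m) cbind((m[, 1] - origin[1]) / s + 1, (m[, 2] - origin[2]) / s + 1)

  if (is(x, "WoundShapeSpec")) {
    if (x@shape == "line") {
      seg <- toPx(lineSegment(x))
      mk <- sweep_segments_cpp(H, W, matrix(c(seg[1, ], seg[2, ]), 1, 4),
                               (x@tipWidth / 2) / s)
    } else if (x@shape == "circle") {
      # analytic disc: exact membership test at pixel centres
      ctr <- toPx(matrix(x@center, 1, 2))  # shape centre in px
      jj <- matrix(seq_len(W), H, W, byrow = TRUE)
      ii <- matrix(seq_len(H), H, W)
      r <- (x@size / 2) / s
      mk <- (jj - ctr[1, 1])^2 + (ii - ctr[1, 2])^2 <= r^2
    } else {
      p <- toPx(shapePolygon(x))
      mk <- fill_polygon_cpp(H, W, p[, 1], p[, 2])
    }
  } else {
    segs <- do.call(rbind, lapply(x@strokes[x@penDown], function(st) {
      st <- toPx(st)
      if (nrow(st) == 1) return(matrix(c(st[1, ], st[1, ]), 1, 4))
      cbind(st[-nrow(st), 1], st[-nrow(st), 2], st[-1, 1], st[-1, 2])
    }))
    mk <- sweep_segments_cpp(H, W, segs, (x@tipWidth / 2) / s)
  }
  WoundMask(matrix(as.logical(mk), H, W), pixelScale, origin)
}

#' Jaccard overlap of two equally-sized wound masks
#' @param a,b \linkS4class{WoundMask} objects on the same raster frame.
#' @export
maskJaccard <- function(a, b) {
  stopifnot(identical(dim(a@mask), dim(b@mask)))
  u <- sum(a@mask | b@mask)
  if (u == 0) return(1)
  sum(a@mask & b@mask) / u
}
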