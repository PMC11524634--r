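#' @include cfzkit-package.R
NULL

# ---- wound design ----------------------------------------------------------

#' Multi-well plate specification
#'
#' Describes the geometry of a multi-well plate: number of rows and columns
#' and the well diameter in mm.
#'
#' @slot rows,cols integer, plate dimensions (>= 1).
#' @slot wellDiameter numeric, well diameter in mm (> 0).
#' @slot name character label.
#' @export
setClass("PlateSpec",
  representation(rows = "integer", cols = "integer",
                 wellDiameter = "numeric", name = "character"),
  validity = function(object) {
    if (length(object@rows) != 1L || object@rows < 1L) return("rows must be a single integer >= 1")
    if (length(object@cols) != 1L || object@cols < 1L) return("cols must be a single integer >= 1")
    if (length(object@wellDiameter) != 1L || !is.finite(object@wellDiameter) ||
        object@wellDiameter <= 0) return("wellDiameter must be > 0")
    TRUE
  })

#' @param rows,cols plate dimensions.
#' @param wellDiameter well diameter (mm).
#' @param name plate label.
#' @rdname PlateSpec-class
#' @export
PlateSpec <- function(rows, cols, wellDiameter, name = sprintf("%dx%d", rows, cols)) {
  new("PlateSpec", rows = as.integer(rows), cols = as.integer(cols),
      wellDiameter = as.numeric(wellDiameter), name = name)
}

#' Corner-well calibration of a plate in the stage frame
#'
#' Stage-frame (x, y, z) coordinates, in mm, of the centres of the four corner
#' wells, keyed \code{r1c1} (well A1), \code{r1cC} (first row, last column),
#' \code{rRc1} and \code{rRcC}, plus the measured tip-to-stage z offset.
#'
#' @slot corners 4 x 3 numeric matrix, rows named r1c1, r1cC, rRc1, rRcC;
#'   columns x, y, z (mm).
#' @slot tipOffsetZ numeric, measured tip offset (mm).
#' @export
setClass("CornerCalibration",
  representation(corners = "matrix", tipOffsetZ = "numeric"),
  validity = function(object) {
    m <- object@corners
    if (!is.numeric(m) || !identical(dim(m), c(4L, 3L))) return("corners must be a 4 x 3 numeric matrix")
    need <- c("r1c1", "r1cC", "rRc1", "rRcC")
    if (!identical(rownames(m), need)) return("corner rows must be named r1c1, r1cC, rRc1, rRcC")
    if (any(!is.finite(m))) return("corner coordinates must be finite")
    if (length(object@tipOffsetZ) != 1L || !is.finite(object@tipOffsetZ))
      return("tipOffsetZ must be a single finite number")
    # affine non-degeneracy: quadrilateral r1c1, r1cC, rRcC, rRc1 has area > 0
    q <- m[c("r1c1", "r1cC", "rRcC", "rRc1"), 1:2, drop = FALSE]
    a <- shoelaceArea(q)
    if (abs(a) < 1e-9) return("corner wells are degenerate (zero-area quadrilateral)")
    TRUE
  })

#' @param corners 4 x 3 numeric matrix (rows r1c1, r1cC, rRc1, rRcC).
#' @param tipOffsetZ tip-to-stage z offset (mm).
#' @rdname CornerCalibration-class
#' @export
CornerCalibration <- function(corners, tipOffsetZ = 0) {
  corners <- as.matrix(corners)
  colnames(corners) <- c("x", "y", "z")
  new("CornerCalibration", corners = corners, tipOffsetZ = as.numeric(tipOffsetZ))
}

#' Declarative wound (cell-free zone) geometry
#'
#' Describes one wound: its shape, size and placement inside a well, and the
#' tip parameters used to create it. Coordinates are well-centric mm (x right,
#' y down, origin at the well centre).
#'
#' The default effective tip width is 0.66 x the tip outer diameter of a
#' 0.48 mm precision dispensing tip, i.e. ~0.318 mm: the width actually swept
#' by a tip differs from its outer diameter because of tip deformation, and
#' the 0.48 mm tip produces ~318 um scratches.
#'
#' @slot shape one of "line", "circle", "square", "triangle", "polygon".
#' @slot size numeric: line length, circle diameter, or square/triangle side
#'   (mm). Ignored for polygon.
#' @slot vertices n x 2 matrix of polygon vertices (mm, well-centric), used
#'   only when shape == "polygon"; must be convex.
#' @slot center numeric length 2, offset of the shape centre from the well
#'   centre (mm).
#' @slot rotation rotation angle in degrees.
#' @slot well integer length 2, (row, col) well index (1-based).
#' @slot tipWidth effective tip width (mm).
#' @slot tipSpeed,tipAccel tip kinematics metadata (mm/s, mm/s^2); carried but
#'   not simulated.
#' @export
setClass("WoundShapeSpec",
  representation(shape = "character", size = "numeric", vertices = "matrix",
                 center = "numeric", rotation = "numeric", well = "integer",
                 tipWidth = "numeric", tipSpeed = "numeric", tipAccel = "numeric"),
  validity = function(object) {
    shapes <- c("line", "circle", "square", "triangle", "polygon")
    if (length(object@shape) != 1L || !object@shape %in% shapes)
      return(sprintf("shape must be one of %s", paste(shapes, collapse = ", ")))
    if (object@shape == "polygon") {
      v <- object@vertices
      if (!is.numeric(v) || ncol(v) != 2 || nrow(v) < 3)
        return("polygon needs an n x 2 vertex matrix with n >= 3")
      if (!isConvexPolygon(v)) return("polygon vertices must describe a convex polygon")
    } else {
      if (length(object@size) != 1L || !is.finite(object@size) || object@size <= 0)
        return("size must be a single number > 0")
    }
    if (length(object@center) != 2L || any(!is.finite(object@center)))
      return("center must be (x, y) in mm")
    if (length(object@tipWidth) != 1L || object@tipWidth <= 0)
      return("tipWidth must be > 0")
    TRUE
  })

#' @param shape,size,vertices,center,rotation,well,tipWidth,tipSpeed,tipAccel
#'   see slots.
#' @rdname WoundShapeSpec-class
#' @export
WoundShapeSpec <- function(shape, size = NA_real_, vertices = matrix(numeric(0), 0, 2),
                           center = c(0, 0), rotation = 0, well = c(1L, 1L),
                           tipWidth = 0.66 * 0.48, tipSpeed = 3, tipAccel = 10) {
  new("WoundShapeSpec", shape = shape, size = as.numeric(size),
      vertices = as.matrix(vertices), center = as.numeric(center),
      rotation = as.numeric(rotation), well = as.integer(well),
      tipWidth = as.numeric(tipWidth), tipSpeed = as.numeric(tipSpeed),
      tipAccel = as.numeric(tipAccel))
}

#' Tip toolpath for creating a wound
#'
#' Ordered strokes, each an ordered n x 2 matrix of (x, y) points in mm, with
#' a pen-down flag per stroke. Pen-down strokes are swept by a round tip of
#' width \code{tipWidth}; pen-up strokes are travel moves.
#'
#' @slot strokes list of n x 2 numeric matrices.
#' @slot penDown logical vector, one flag per stroke.
#' @slot tipWidth effective tip width (mm) used when sweeping.
#' @export
setClass("Toolpath",
  representation(strokes = "list", penDown = "logical", tipWidth = "numeric"),
  validity = function(object) {
    if (length(object@strokes) != length(object@penDown))
      return("one penDown flag per stroke required")
    ok <- vapply(object@strokes, function(s) is.matrix(s) && ncol(s) == 2 && nrow(s) >= 1,
                 logical(1))
    if (!all(ok)) return("each stroke must be an n x 2 matrix with n >= 1")
    if (object@tipWidth <= 0) return("tipWidth must be > 0")
    TRUE
  })

#' @param strokes,penDown,tipWidth see slots.
#' @rdname Toolpath-class
#' @export
Toolpath <- function(strokes, penDown = rep(TRUE, length(strokes)), tipWidth) {
  new("Toolpath", strokes = strokes, penDown = penDown, tipWidth = as.numeric(tipWidth))
}

#' Binary wound mask raster
#'
#' @slot mask logical matrix (TRUE = wound / cell-free).
#' @slot pixelScale pixel scale in um/px.
#' @slot origin numeric length 2: (x, y) coordinate, in mm, of the centre of
#'   pixel (1, 1); x grows with column index, y with row index (y down).
#' @export
setClass("WoundMask",
  representation(mask = "matrix", pixelScale = "numeric", origin = "numeric"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be a logical matrix")
    if (length(object@pixelScale) != 1L || object@pixelScale <= 0)
      return("pixelScale must be > 0 (um/px)")
    if (length(object@origin) != 2L) return("origin must be (x, y) in mm")
    TRUE
  })

#' @param mask,pixelScale,origin see slots.
#' @rdname WoundMask-class
#' @export
WoundMask <- function(mask, pixelScale, origin = c(0, 0)) {
  mode(mask) <- "logical"
  new("WoundMask", mask = mask, pixelScale = as.numeric(pixelScale),
      origin = as.numeric(origin))
}

# ---- imaging ---------------------------------------------------------------

#' Multi-channel time-series image stack
#'
#' Dense raster with axes (c, t, y, x) and optionally a trailing RGB axis q.
#' Physical metadata (pixel scale, frame interval) ride along so that all
#' downstream measurements can be reported in micrometres and hours.
#'
#' @slot data numeric array, dim (c, t, y, x) or (c, t, y, x, 3).
#' @slot pixelScale um/px.
#' @slot frameInterval minutes between frames.
#' @slot channelNames character vector, length c.
#' @export
setClass("ImageStack",
  representation(data = "array", pixelScale = "numeric",
                 frameInterval = "numeric", channelNames = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (!(length(d) %in% c(4L, 5L))) return("data must have axes (c, t, y, x[, q])")
    if (any(d[1:4] < 1L)) return("all of c, t, y, x must be >= 1")
    if (length(d) == 5L && d[5] != 3L) return("q axis, when present, must have length 3 (RGB)")
    if (object@pixelScale <= 0) return("pixelScale must be > 0")
    if (object@frameInterval <= 0) return("frameInterval must be > 0")
    if (length(object@channelNames) != d[1]) return("one channel name per channel required")
    TRUE
  })

#' @param data array with axes (c, t, y, x) or (c, t, y, x, 3).
#' @param pixelScale um/px.
#' @param frameInterval minutes.
#' @param channelNames character vector.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(data, pixelScale, frameInterval,
                       channelNames = paste0("ch", seq_len(dim(data)[1]))) {
  new("ImageStack", data = data, pixelScale = as.numeric(pixelScale),
      frameInterval = as.numeric(frameInterval), channelNames = channelNames)
}

# ---- simulation ------------------------------------------------------------

#' Parameters of the monolayer/wound simulator
#'
#' Defaults describe the emulated experiment: BJ-fibroblast-like monolayers
#' seeded in the 0.22-0.63e5 cells/cm^2 range (default 0.40e5), imaged every
#' 30 min at ~5x-magnification pixel scale, nuclei rendered as bright
#' anisotropic Gaussian spots over a dim background with Poisson noise.
#' Motility defaults (20 um/h persistent biased walk, division probability
#' 0.002 per cell per 30-min frame) are placeholders tuned so a ~0.3 mm line
#' wound closes in roughly 30 h; no claim of biological fidelity is made.
#'
#' @slot fieldSize (width, height) of the simulated field, um.
#' @slot pixelScale um/px of rendered frames.
#' @slot seedingDensity cells/cm^2.
#' @slot minDist minimum inter-nucleus distance, um.
#' @slot frameInterval minutes between frames.
#' @slot nFrames number of frames.
#' @slot speedMean,speedSd stationary migration speed mean/sd, um/h.
#' @slot persistence AR(1) velocity persistence in [0, 1).
#' @slot biasStrength dimensionless strength of the wound-directed bias
#'   (multiplies speedMean).
#' @slot biasRadius cells within this distance (um) of the wound feel the bias.
#' @slot divisionProb probability a cell divides per frame.
#' @slot radiusMean,radiusSd nucleus radius (Gaussian sd of the rendered spot), um.
#' @slot stainLevel mean peak intensity of a rendered nucleus (counts).
#' @slot background constant background level (counts).
#' @slot noiseScale 0 disables noise; 1 applies Poisson noise to expected counts.
#' @slot obliqueChannel logical; add a flat textured pseudo-brightfield channel.
#' @slot seed integer random seed.
#' @export
setClass("SimulationParams",
  representation(fieldSize = "numeric", pixelScale = "numeric",
                 seedingDensity = "numeric", minDist = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 speedMean = "numeric", speedSd = "numeric", persistence = "numeric",
                 biasStrength = "numeric", biasRadius = "numeric",
                 divisionProb = "numeric", radiusMean = "numeric", radiusSd = "numeric",
                 stainLevel = "numeric", background = "numeric", noiseScale = "numeric",
                 obliqueChannel = "logical", seed = "integer"),
  validity = function(object) {
    pos <- c(fieldSize = all(object@fieldSize > 0), pixelScale = object@pixelScale > 0,
             frameInterval = object@frameInterval > 0, nFrames = object@nFrames >= 1)
    if (!all(pos)) return(sprintf("invalid (non-positive) %s",
                                  paste(names(pos)[!pos], collapse = ", ")))
    nonneg <- c(object@seedingDensity, object@minDist, object@speedMean, object@speedSd,
                object@biasStrength, object@biasRadius, object@divisionProb,
                object@radiusMean, object@radiusSd, object@background, object@noiseScale)
    if (any(nonneg < 0)) return("rates and scales must be >= 0")
    if (object@persistence < 0 || object@persistence >= 1)
      return("persistence must be in [0, 1)")
    if (object@divisionProb > 1) return("divisionProb must be <= 1")
    # close packing of discs at radius minDist/2
    if (object@minDist > 0) {
      limit <- 0.9069 / (pi * (object@minDist / 2)^2) * 1e8  # cells/cm^2
      if (object@seedingDensity > limit)
        return("seedingDensity exceeds the close-packing limit for minDist")
    }
    TRUE
  })

#' @param ... slot values overriding the defaults (see slots).
#' @rdname SimulationParams-class
#' @export
SimulationParams <- function(...) {
  args <- list(...)
  defaults <- list(fieldSize = c(2000, 2000), pixelScale = 5,
                   seedingDensity = 0.40e5, minDist = 15,
                   frameInterval = 30, nFrames = 60L,
                   speedMean = 20, speedSd = 5, persistence = 0.7,
                   biasStrength = 0.03, biasRadius = 200,
                   divisionProb = 0.002, radiusMean = 8, radiusSd = 1,
                   stainLevel = 300, background = 20, noiseScale = 1,
                   obliqueChannel = FALSE, seed = 1L)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  defaults$nFrames <- as.integer(defaults$nFrames)
  defaults$seed <- as.integer(defaults$seed)
  defaults$obliqueChannel <- as.logical(defaults$obliqueChannel)
  do.call(new, c(list("SimulationParams"), defaults))
}

#' Complete ground truth of a simulated assay
#'
#' @slot cells data.frame (frame, id, x, y, radius) with positions in um
#'   (field/image coordinates).
#' @slot lineage data.frame (parent, child, frame).
#' @slot masks list of per-frame \linkS4class{WoundMask} objects (true wound,
#'   recomputed per frame by density thresholding of the true positions).
#' @slot area numeric, true wound area per frame, mm^2.
#' @slot widthMean,widthSd numeric per frame (um); NA when no scratch-like
#'   wound geometry is measurable for that frame.
#' @export
setClass("GroundTruth",
  representation(cells = "data.frame", lineage = "data.frame", masks = "list",
                 area = "numeric", widthMean = "numeric", widthSd = "numeric"))

# ---- configs ---------------------------------------------------------------

#' Preprocessing configuration (pipeline steps 1-5)
#'
#' @slot doFlatten,doRescaleSpatial,doRescaleIntensity,doMedian,doEqualize
#'   logical step switches.
#' @slot spatialFactor spatial rescale factor (> 0).
#' @slot medianRadius median filter disc radius, px (0 = identity).
#' @slot equalizeKernel CLAHE tile size, px.
#' @slot equalizeClip CLAHE clip limit (fraction of tile pixels per bin).
#' @slot intensityMode "global" (per channel over all frames) or "frame".
#' @export
setClass("PreprocessConfig",
  representation(doFlatten = "logical", doRescaleSpatial = "logical",
                 doRescaleIntensity = "logical", doMedian = "logical",
                 doEqualize = "logical", spatialFactor = "numeric",
                 medianRadius = "integer", equalizeKernel = "integer",
                 equalizeClip = "numeric", intensityMode = "character"),
  validity = function(object) {
    if (object@spatialFactor <= 0) return("spatialFactor must be > 0")
    if (object@medianRadius < 0) return("medianRadius must be >= 0")
    if (object@equalizeKernel < 1) return("equalizeKernel must be >= 1")
    if (!object@intensityMode %in% c("global", "frame"))
      return("intensityMode must be 'global' or 'frame'")
    TRUE
  })

#' @param ... slot values overriding the defaults.
#' @rdname PreprocessConfig-class
#' @export
PreprocessConfig <- function(...) {
  args <- list(...)
  defaults <- list(doFlatten = TRUE, doRescaleSpatial = FALSE, doRescaleIntensity = TRUE,
                   doMedian = TRUE, doEqualize = TRUE, spatialFactor = 1,
                   medianRadius = 1L, equalizeKernel = 64L, equalizeClip = 0.01,
                   intensityMode = "global")
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) stop("unknown preprocess parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  defaults$medianRadius <- as.integer(defaults$medianRadius)
  defaults$equalizeKernel <- as.integer(defaults$equalizeKernel)
  do.call(new, c(list("PreprocessConfig"), defaults))
}

#' Nucleus detection and isolation-filter configuration
#'
#' @slot radiusRange expected nucleus radius range, um (the rendered/imaged
#'   nucleus is treated as a Gaussian spot; radius = its sd).
#' @slot threshold detection threshold on the scale-normalized
#'   Laplacian-of-Gaussian response of the [0, 1]-normalized frame.
#' @slot minArea,maxArea retained object area range, um^2.
#' @slot k number of nearest neighbours for the isolation filter.
#' @slot isolationThreshold distance threshold, um; NA = scale-free default
#'   (4 x median nearest-neighbour spacing of the frame).
#' @slot isolationMode "mean" or "max" of the k neighbour distances.
#' @export
setClass("DetectionConfig",
  representation(radiusRange = "numeric", threshold = "numeric",
                 minArea = "numeric", maxArea = "numeric", k = "integer",
                 isolationThreshold = "numeric", isolationMode = "character"),
  validity = function(object) {
    r <- object@radiusRange
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) return("invalid radiusRange")
    if (object@threshold <= 0) return("threshold must be > 0")
    if (object@minArea < 0 || object@maxArea <= object@minArea) return("invalid area range")
    if (object@k < 1L) return("k must be >= 1")
    if (!is.na(object@isolationThreshold) && object@isolationThreshold <= 0)
      return("isolationThreshold must be > 0 (or NA for the scale-free default)")
    if (!object@isolationMode %in% c("mean", "max"))
      return("isolationMode must be 'mean' or 'max'")
    TRUE
  })

#' @param ... slot values overriding the defaults.
#' @rdname DetectionConfig-class
#' @export
DetectionConfig <- function(...) {
  args <- list(...)
  defaults <- list(radiusRange = c(4, 12), threshold = 0.05,
                   minArea = 30, maxArea = 4000, k = 3L,
                   isolationThreshold = NA_real_, isolationMode = "mean")
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) stop("unknown detection parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  defaults$k <- as.integer(defaults$k)
  do.call(new, c(list("DetectionConfig"), defaults))
}

#' Tracking configuration
#'
#' @slot maxLinkDist Euclidean gate, um.
#' @slot maxGap frames a track may go unobserved before termination.
#' @slot motionModel "cv" (constant velocity) or "brownian".
#' @slot processNoise,obsNoise Kalman noise scales, um.
#' @slot divisionLinking logical; link track births to nearby live tracks as
#'   parent -> child.
#' @slot divisionMaxDist um.
#' @export
setClass("TrackConfig",
  representation(maxLinkDist = "numeric", maxGap = "integer",
                 motionModel = "character", processNoise = "numeric",
                 obsNoise = "numeric", divisionLinking = "logical",
                 divisionMaxDist = "numeric"),
  validity = function(object) {
    if (object@maxLinkDist <= 0) return("maxLinkDist (gate) must be > 0")
    if (object@maxGap < 0L) return("maxGap must be >= 0")
    if (!object@motionModel %in% c("cv", "brownian"))
      return("motionModel must be 'cv' or 'brownian'")
    if (object@processNoise <= 0 || object@obsNoise <= 0)
      return("noise scales must be > 0")
    TRUE
  })

#' @param ... slot values overriding the defaults.
#' @rdname TrackConfig-class
#' @export
TrackConfig <- function(...) {
  args <- list(...)
  defaults <- list(maxLinkDist = 30, maxGap = 1L, motionModel = "cv",
                   processNoise = 3, obsNoise = 1.5, divisionLinking = TRUE,
                   divisionMaxDist = 30)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) stop("unknown tracking parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  defaults$maxGap <- as.integer(defaults$maxGap)
  do.call(new, c(list("TrackConfig"), defaults))
}

# ---- metrics ---------------------------------------------------------------

#' Fitted wound-edge line
#'
#' Total-least-squares line through one wound-edge contour: the line of best
#' fit serves as the wound edge; the supporting contour points are kept for
#' local width measurements.
#'
#' @slot point point on the line (um).
#' @slot direction unit direction (um frame).
#' @slot nPoints number of supporting contour points.
#' @slot rmsResidual RMS orthogonal residual of the contour about the line (um).
#' @slot contour n x 2 matrix of the supporting contour (um).
#' @export
setClass("EdgeLine",
  representation(point = "numeric", direction = "numeric", nPoints = "integer",
                 rmsResidual = "numeric", contour = "matrix"),
  validity = function(object) {
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8) return("direction must be unit length")
    if (object@nPoints < 2L) return("an edge line needs >= 2 supporting points")
    TRUE
  })

#' Wound width profile along the scratch axis
#'
#' @slot s arc positions along the scratch axis (um).
#' @slot width local widths w(s) (um).
#' @slot meanWidth,sdWidth summary statistics (um); sdWidth^2 is the sample
#'   variance of w(s).
#' @export
setClass("WidthProfile",
  representation(s = "numeric", width = "numeric",
                 meanWidth = "numeric", sdWidth = "numeric"),
  validity = function(object) {
    if (length(object@s) != length(object@width)) return("s and width lengths differ")
    if (any(object@width < 0)) return("widths must be >= 0")
    TRUE
  })

#' Wound closure curve
#'
#' @slot time hours since the first frame.
#' @slot area wound area per frame, mm^2.
#' @slot percentClosure 100 * (1 - area(t)/area(0)).
#' @slot closureTime first time (h) the area falls to <= epsilon * area(0);
#'   Inf when not closed within the observation horizon.
#' @slot horizon observation horizon (h).
#' @slot epsilon closed-fraction threshold.
#' @export
setClass("ClosureCurve",
  representation(time = "numeric", area = "numeric", percentClosure = "numeric",
                 closureTime = "numeric", horizon = "numeric", epsilon = "numeric"),
  validity = function(object) {
    n <- length(object@time)
    if (length(object@area) != n || length(object@percentClosure) != n)
      return("time, area and percentClosure must have equal length")
    TRUE
  })
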