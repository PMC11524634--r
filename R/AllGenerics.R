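#' @include AllClasses.R
NULL

#' Pixel scale accessor
#' @param x an \linkS4class{ImageStack} or \linkS4class{WoundMask}.
#' @return pixel scale in um/px.
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))

#' @rdname pixelScale
#' @export
setMethod("pixelScale", "ImageStack", function(x) x@pixelScale)

#' @rdname pixelScale
#' @export
setMethod("pixelScale", "WoundMask", function(x) x@pixelScale)

#' Frame interval accessor
#' @param x an \linkS4class{ImageStack}.
#' @return minutes between frames.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname frameInterval
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@frameInterval)

#' Channel names accessor
#' @param x an \linkS4class{ImageStack}.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "ImageStack", function(x) x@channelNames)

#' Area of a wound mask in mm^2
#' @param x a \linkS4class{WoundMask}.
#' @return area in mm^2 (pixel count x pixel area).
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))

#' @rdname maskArea
#' @export
setMethod("maskArea", "WoundMask", function(x) sum(x@mask) * (x@pixelScale / 1000)^2)

#' Extract one frame of one channel as a numeric matrix
#' @param x an \linkS4class{ImageStack}.
#' @param channel channel index or name.
#' @param t frame index.
#' @return numeric (y, x) matrix.
#' @export
setGeneric("getFrame", function(x, channel = 1L, t = 1L) standardGeneric("getFrame"))

#' @rdname getFrame
#' @export
setMethod("getFrame", "ImageStack", function(x, channel = 1L, t = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, x@channelNames)
    if (is.na(channel)) stop("unknown channel name")
  }
  d <- dim(x@data)
  if (length(d) == 5L) stop("stack has an RGB axis; flatten() it first")
  matrix(x@data[channel, t, , ], d[3], d[4])
})

setMethod("show", "PlateSpec", function(object) {
  cat(sprintf("PlateSpec '%s': %d x %d wells, diameter %.2f mm\n",
              object@name, object@rows, object@cols, object@wellDiameter))
})

setMethod("show", "WoundShapeSpec", function(object) {
  sz <- if (object@shape == "polygon") sprintf("%d vertices", nrow(object@vertices))
        else sprintf("size %.3g mm", object@size)
  cat(sprintf("WoundShapeSpec: %s (%s), well (%d, %d), tip %.3f mm\n",
              object@shape, sz, object@well[1], object@well[2], object@tipWidth))
})

setMethod("show", "Toolpath", function(object) {
  np <- sum(vapply(object@strokes, nrow, integer(1)))
  cat(sprintf("Toolpath: %d strokes (%d pen-down), %d points, tip %.3f mm\n",
              length(object@strokes), sum(object@penDown), np, object@tipWidth))
})

setMethod("show", "WoundMask", function(object) {
  cat(sprintf("WoundMask: %d x %d px at %.3g um/px, area %.4g mm^2\n",
              nrow(object@mask), ncol(object@mask), object@pixelScale,
              maskArea(object)))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  q <- if (length(d) == 5L) " x 3 (RGB)" else ""
  cat(sprintf("ImageStack: c=%d t=%d, %d x %d px%s, %.3g um/px, dt %.3g min [%s]\n",
              d[1], d[2], d[3], d[4], q, object@pixelScale, object@frameInterval,
              paste(object@channelNames, collapse = ", ")))
})

setMethod("show", "GroundTruth", function(object) {
  nf <- length(unique(object@cells$frame))
  cat(sprintf("GroundTruth: %d frames, %d cell-frame rows, %d divisions\n",
              nf, nrow(object@cells), nrow(object@lineage)))
})

setMethod("show", "EdgeLine", function(object) {
  cat(sprintf("EdgeLine through (%.1f, %.1f) um, direction (%.3f, %.3f), %d pts, RMS %.2f um\n",
              object@point[1], object@point[2], object@direction[1],
              object@direction[2], object@nPoints, object@rmsResidual))
})

setMethod("show", "WidthProfile", function(object) {
  cat(sprintf("WidthProfile: %d samples, mean %.1f um, sd %.2f um\n",
              length(object@s), object@meanWidth, object@sdWidth))
})

setMethod("show", "ClosureCurve", function(object) {
  ct <- if (is.finite(object@closureTime)) sprintf("%.3g h", object@closureTime)
        else sprintf("> %.3g h", object@horizon)
  cat(sprintf("ClosureCurve: %d frames over %.3g h, area0 %.4g mm^2, closure %s\n",
              length(object@time), object@horizon, object@area[1], ct))
})

#' @export
#' @method as.data.frame WidthProfile
as.data.frame.WidthProfile <- function(x, ...) {
  data.frame(s_um = x@s, width_um = x@width)
}

#' @export
#' @method as.data.frame ClosureCurve
as.data.frame.ClosureCurve <- function(x, ...) {
  data.frame(time_h = x@time, area_mm2 = x@area, percent_closure = x@percentClosure)
}
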