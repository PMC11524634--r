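# Preprocessing: flatten -> spatial rescale -> intensity rescale -> median
# filter -> adaptive equalization. Each step preserves the (c, t) axes and
# frame order and can be disabled individually.

#' Flatten an RGB axis to grayscale luminance
#'
#' Applies the ITU-R 709 luminance weights (0.2125 R + 0.7154 G + 0.0721 B)
#' per pixel. A stack without an RGB axis is returned unchanged with a warning.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @return an \linkS4class{ImageStack} with axes (c, t, y, x).
#' @export
flatten <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@data)
  if (length(d) == 4L) {
    warning("stack has no RGB axis; returning unchanged")
    return(stack)
  }
  w <- c(0.2125, 0.7154, 0.0721)
  out <- stack@data[, , , , 1] * w[1] + stack@data[, , , , 2] * w[2] +
    stack@data[, , , , 3] * w[3]
  dim(out) <- d[1:4]
  initialize(stack, data = out)
}

#' Rescale the spatial (y, x) axes of a stack
#'
#' Anti-aliased (Gaussian prefilter for downscaling) bilinear resampling of
#' every frame of every channel. The pixel-scale metadata is updated
#' (um/px divided by the factor) so physical coordinates are preserved.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param factor spatial scale factor (> 0); 0.5 halves y and x.
#' @export
rescaleSpatial <- function(stack, factor) {
  stopifnot(is(stack, "ImageStack"), factor > 0)
  d <- dim(stack@data)
  if (length(d) == 5L) stop("flatten() the RGB axis first")
  if (factor == 1) return(stack)
  H <- max(1L, round(d[3] * factor)); W <- max(1L, round(d[4] * factor))
  if (round(d[3] * factor) < 1 || round(d[4] * factor) < 1)
    stop("rescale factor collapses the image below 1 px")
  sigma <- if (factor < 1) sqrt((1 / factor)^2 - 1) / 2 else 0
  out <- array(0, dim = c(d[1], d[2], H, W))
  for (c in seq_len(d[1])) for (t in seq_len(d[2])) {
    fr <- matrix(stack@data[c, t, , ], d[3], d[4])
    if (sigma > 0) fr <- gauss_blur_cpp(fr, sigma)
    out[c, t, , ] <- resize_bilinear_cpp(fr, H, W)
  }
  initialize(stack, data = out, pixelScale = stack@pixelScale / factor)
}

#' Rescale intensities to [0, 255]
#'
#' Linear min-max rescale per channel, either over the whole time series
#' (mode "global", the default: preserves temporal intensity trends) or per
#' frame. A constant channel maps to 0.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param mode "global" or "frame".
#' @export
rescaleIntensity <- function(stack, mode = c("global", "frame")) {
  stopifnot(is(stack, "ImageStack"))
  mode <- match.arg(mode)
  d <- dim(stack@data)
  if (length(d) == 5L) stop("flatten() the RGB axis first")
  out <- stack@data
  for (c in seq_len(d[1])) {
    if (mode == "global") {
      v <- out[c, , , ]
      rng <- range(v)
      out[c, , , ] <- if (diff(rng) == 0) 0 else (v - rng[1]) / diff(rng) * 255
    } else {
      for (t in seq_len(d[2])) {
        v <- out[c, t, , ]
        rng <- range(v)
        out[c, t, , ] <- if (diff(rng) == 0) 0 else (v - rng[1]) / diff(rng) * 255
      }
    }
  }
  initialize(stack, data = out)
}

#' Median-filter every frame with a disc footprint
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param radius disc radius in pixels; 0 is the identity.
#' @export
medianFilterStack <- function(stack, radius = 1L) {
  stopifnot(is(stack, "ImageStack"), radius >= 0)
  if (radius == 0) return(stack)
  d <- dim(stack@data)
  if (length(d) == 5L) stop("flatten() the RGB axis first")
  out <- stack@data
  for (c in seq_len(d[1])) for (t in seq_len(d[2]))
    out[c, t, , ] <- median_filter_cpp(matrix(stack@data[c, t, , ], d[3], d[4]),
                                       as.integer(radius))
  initialize(stack, data = out)
}

#' Contrast-limited adaptive histogram equalization per frame
#'
#' Frames are linearly mapped to [0, 255] for binning (256 bins), equalized
#' with tiles of \code{kernel} px and the given clip limit, and returned in
#' [0, 255].
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param kernel tile size in pixels.
#' @param clip clip limit as the fraction of tile pixels allowed per histogram
#'   bin before redistribution (default 0.01).
#' @export
adaptiveEqualize <- function(stack, kernel = 64L, clip = 0.01) {
  stopifnot(is(stack, "ImageStack"), kernel >= 1)
  d <- dim(stack@data)
  if (length(d) == 5L) stop("flatten() the RGB axis first")
  out <- stack@data
  for (c in seq_len(d[1])) for (t in seq_len(d[2])) {
    fr <- matrix(stack@data[c, t, , ], d[3], d[4])
    rng <- range(fr)
    fr255 <- if (diff(rng) == 0) fr * 0 else (fr - rng[1]) / diff(rng) * 255
    if (diff(rng) == 0) {
      out[c, t, , ] <- fr255
    } else {
      out[c, t, , ] <- pmin(pmax(clahe_cpp(fr255, as.integer(kernel), clip), 0), 255)
    }
  }
  initialize(stack, data = out)
}

#' Run the preprocessing pipeline (steps 1-5)
#'
#' Applies, in order: grayscale flattening, spatial rescale, intensity rescale
#' to [0, 255], median filtering, adaptive histogram equalization. Steps are
#' controlled by a \linkS4class{PreprocessConfig}; the composite is
#' deterministic.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param config a \linkS4class{PreprocessConfig}.
#' @export
preprocess <- function(stack, config = PreprocessConfig()) {
  stopifnot(is(stack, "ImageStack"), is(config, "PreprocessConfig"))
  validObject(config)
  if (config@doFlatten && length(dim(stack@data)) == 5L) stack <- flatten(stack)
  if (config@doRescaleSpatial && config@spatialFactor != 1)
    stack <- rescaleSpatial(stack, config@spatialFactor)
  if (config@doRescaleIntensity) stack <- rescaleIntensity(stack, config@intensityMode)
  if (config@doMedian && config@medianRadius > 0)
    stack <- medianFilterStack(stack, config@medianRadius)
  if (config@doEqualize)
    stack <- adaptiveEqualize(stack, config@equalizeKernel, config@equalizeClip)
  stack
}
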