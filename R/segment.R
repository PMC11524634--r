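# Nuclear segmentation: multi-scale Laplacian-of-Gaussian blob detection,
# marker-controlled watershed delineation, region properties, and the
# nearest-neighbour isolation filter that removes stray detections from the
# wound bed.

#' Segment nuclei in a single frame
#'
#' The frame is normalized to [0, 1]; bright blobs are detected as local
#' maxima of the scale-normalized Laplacian-of-Gaussian response maximized
#' over a log-spaced set of scales spanning the expected nucleus radius range.
#' Detected maxima seed a marker-controlled watershed on the smoothed image,
#' restricted to a robust foreground (median + 3 x MAD of the smoothed frame),
#' which delineates touching nuclei. Objects outside the configured area range
#' are discarded.
#'
#' Any external detector can be substituted upstream as long as it produces
#' the same contract: an integer label mask plus one property row per label
#' (see \code{\link{regionProperties}}).
#'
#' @param frame numeric (y, x) matrix: the nuclear channel of one frame.
#' @param config a \linkS4class{DetectionConfig}.
#' @param pixelScale um/px of the frame.
#' @param intensityFrames optional named list of same-sized matrices whose
#'   per-object mean intensities are added as \code{mean_intensity_<name>}
#'   columns (defaults to the detection frame as channel "ch1").
#' @return list with \code{labels} (integer matrix) and \code{table}
#'   (data.frame, one row per retained nucleus; see
#'   \code{\link{regionProperties}} for columns).
#' @export
segmentNuclei <- function(frame, config = DetectionConfig(), pixelScale = 1,
                          intensityFrames = NULL) {
  stopifnot(is.matrix(frame), is(config, "DetectionConfig"))
  validObject(config)
  if (is.null(intensityFrames)) intensityFrames <- list(ch1 = frame)
  empty <- regionProperties(matrix(0L, nrow(frame), ncol(frame)),
                            intensityFrames, pixelScale)
  rng <- range(frame)
  if (diff(rng) == 0)
    return(list(labels = matrix(0L, nrow(frame), ncol(frame)), table = empty))
  im <- (frame - rng[1]) / diff(rng)

  sigmas <- exp(seq(log(config@radiusRange[1] / pixelScale),
                    log(config@radiusRange[2] / pixelScale), length.out = 4L))
  sigmas <- pmax(sigmas, 0.6)
  resp <- NULL
  smoothMin <- NULL
  for (s in sigmas) {
    g <- gauss_blur_cpp(im, s)
    if (is.null(smoothMin)) smoothMin <- g
    r <- -s^2 * laplacian_cpp(g)
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  minDistPx <- max(1L, as.integer(floor(config@radiusRange[1] / pixelScale)))
  peaks <- local_maxima_cpp(resp, minDistPx, config@threshold)
  if (nrow(peaks) == 0)
    return(list(labels = matrix(0L, nrow(frame), ncol(frame)), table = empty))

  # robust foreground; the absolute floor keeps noise-free frames (MAD = 0)
  # from flooding the background
  med <- median(smoothMin)
  fg <- smoothMin > med + max(3 * mad(smoothMin), 0.02 * (max(smoothMin) - med))
  markers <- matrix(0L, nrow(frame), ncol(frame))
  keep <- fg[peaks]
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) == 0)
    return(list(labels = matrix(0L, nrow(frame), ncol(frame)), table = empty))
  markers[peaks] <- seq_len(nrow(peaks))
  labels <- watershed_cpp(-smoothMin, markers, fg)

  tab <- regionProperties(labels, intensityFrames, pixelScale)
  bad <- tab$area_um2 < config@minArea | tab$area_um2 > config@maxArea
  if (any(bad)) {
    drop <- tab$label[bad]
    labels[labels %in% drop] <- 0L
    tab <- tab[!bad, , drop = FALSE]
    rownames(tab) <- NULL
  }
  list(labels = labels, table = tab)
}

#' Region properties of a label mask
#'
#' One row per label: centroid (0-based pixel coordinates and um), area
#' (px^2 and um^2), major/minor axis lengths (um), eccentricity, and the mean
#' intensity over each supplied channel. Centroid um = 0-based px x pixel
#' scale. Axis lengths follow the normalized-second-moment ellipse convention
#' (length = 4 sqrt(eigenvalue)).
#'
#' @param labels integer matrix of labels (0 = background).
#' @param intensityFrames named list of numeric matrices.
#' @param pixelScale um/px.
#' @return data.frame with columns label, x_px, y_px, x_um, y_um, area_px,
#'   area_um2, major_axis_um, minor_axis_um, eccentricity,
#'   mean_intensity_<channel>...
#' @export
regionProperties <- function(labels, intensityFrames = list(), pixelScale = 1) {
  idx <- which(labels > 0L)
  cols <- c("label", "x_px", "y_px", "x_um", "y_um", "area_px", "area_um2",
            "major_axis_um", "minor_axis_um", "eccentricity",
            paste0("mean_intensity_", names(intensityFrames)))
  if (length(idx) == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$label <- integer(0)
    return(out)
  }
  lv <- labels[idx]
  H <- nrow(labels)
  rows <- ((idx - 1L) %% H) + 1L
  colsIx <- ((idx - 1L) %/% H) + 1L
  ulab <- sort(unique(lv))
  f <- factor(lv, levels = ulab)
  area <- as.integer(table(f))
  cx <- tapply(colsIx, f, mean) - 1  # 0-based pixel centroid
  cy <- tapply(rows, f, mean) - 1
  # central second moments
  dx <- colsIx - 1 - cx[f]
  dy <- rows - 1 - cy[f]
  mu20 <- tapply(dx * dx, f, mean)
  mu02 <- tapply(dy * dy, f, mean)
  mu11 <- tapply(dx * dy, f, mean)
  tr <- mu20 + mu02
  det <- sqrt(pmax(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (tr + det) / 2
  l2 <- pmax(0, (tr - det) / 2)
  major <- 4 * sqrt(l1) * pixelScale
  minor <- 4 * sqrt(l2) * pixelScale
  ecc <- ifelse(l1 > 0, sqrt(pmax(0, 1 - l2 / l1)), 0)
  out <- data.frame(label = ulab, x_px = as.numeric(cx), y_px = as.numeric(cy),
                    x_um = as.numeric(cx) * pixelScale, y_um = as.numeric(cy) * pixelScale,
                    area_px = area, area_um2 = area * pixelScale^2,
                    major_axis_um = as.numeric(major), minor_axis_um = as.numeric(minor),
                    eccentricity = as.numeric(ecc))
  for (nm in names(intensityFrames))
    out[[paste0("mean_intensity_", nm)]] <-
      as.numeric(tapply(intensityFrames[[nm]][idx], f, mean))
  rownames(out) <- NULL
  out
}

#' Segment every frame of a stack into a nuclei table
#'
#' @param stack an \linkS4class{ImageStack} (no RGB axis).
#' @param config a \linkS4class{DetectionConfig}.
#' @param nuclearChannel channel index or name used for detection.
#' @param keepLabels logical; also return the per-frame label masks.
#' @return data.frame with a \code{frame} column prepended to the
#'   \code{\link{regionProperties}} columns (and \code{labels} list attribute
#'   when \code{keepLabels}).
#' @export
segmentStack <- function(stack, config = DetectionConfig(), nuclearChannel = 1L,
                         keepLabels = FALSE) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@data)
  if (length(d) == 5L) stop("flatten() the RGB axis first")
  tabs <- vector("list", d[2])
  labs <- if (keepLabels) vector("list", d[2]) else NULL
  for (t in seq_len(d[2])) {
    fr <- getFrame(stack, nuclearChannel, t)
    intensity <- setNames(lapply(seq_len(d[1]), function(c) getFrame(stack, c, t)),
                          stack@channelNames)
    seg <- segmentNuclei(fr, config, stack@pixelScale, intensity)
    if (nrow(seg$table)) seg$table <- cbind(frame = t, seg$table)
    else seg$table <- cbind(data.frame(frame = integer(0)), seg$table)
    tabs[[t]] <- seg$table
    if (keepLabels) labs[[t]] <- seg$labels
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  if (keepLabels) attr(out, "labels") <- labs
  out
}

#' Remove isolated detections by the k-nearest-neighbour rule
#'
#' For each nucleus of one frame, the mean (or max) distance to its k nearest
#' neighbours is computed; nuclei whose statistic exceeds the isolation
#' threshold are removed. With the threshold unset (NA) a scale-free default
#' of 4 x the median nearest-neighbour spacing of the frame is used. When
#' k >= number of nuclei, all rows are retained. Raising the threshold never
#' removes more nuclei. Row order is preserved.
#'
#' @param rows data.frame for one frame with x_um / y_um columns (as produced
#'   by \code{\link{segmentNuclei}}).
#' @param config a \linkS4class{DetectionConfig}.
#' @return the retained rows (original order).
#' @export
filterIsolated <- function(rows, config = DetectionConfig()) {
  stopifnot(is.data.frame(rows), is(config, "DetectionConfig"))
  n <- nrow(rows)
  if (n <= 1L || config@k >= n) return(rows)
  p <- cbind(rows$x_um, rows$y_um)
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  sorted <- apply(d, 1, sort)  # columns = points, rows = sorted distances
  knn <- sorted[seq_len(config@k), , drop = FALSE]
  stat <- if (config@isolationMode == "mean") colMeans(knn) else apply(knn, 2, max)
  thr <- config@isolationThreshold
  if (is.na(thr)) thr <- 4 * median(sorted[1, ])
  rows[stat <= thr, , drop = FALSE]
}

#' Apply the isolation filter frame by frame
#' @param nuclei data.frame with a \code{frame} column.
#' @param config a \linkS4class{DetectionConfig}.
#' @export
filterIsolatedByFrame <- function(nuclei, config = DetectionConfig()) {
  parts <- split(nuclei, nuclei$frame)
  out <- do.call(rbind, lapply(parts, filterIsolated, config = config))
  rownames(out) <- NULL
  out
}
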