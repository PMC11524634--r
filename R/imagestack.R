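# Minimal baseline TIFF (little-endian, uncompressed, grayscale, 16-bit,
# multi-page) with a JSON ImageDescription carrying physical metadata. No TIFF
# library is available in this environment, so the subset needed for the
# package's own round trips is implemented here; readers accept exactly this
# subset (one or more strips, 8 or 16 bits, no compression).

u16raw <- function(v) {
  v <- pmin(pmax(round(v), 0), 65535)
  as.raw(as.vector(rbind(v %% 256, v %/% 256)))
}
u32raw <- function(v) {
  v <- round(v)
  as.raw(as.vector(rbind(v %% 256, (v %/% 256) %% 256,
                         (v %/% 65536) %% 256, (v %/% 16777216) %% 256)))
}

# one IFD entry: tag, type (3=SHORT, 4=LONG, 2=ASCII), count, value-or-offset
ifdEntry <- function(tag, type, count, value) {
  val <- if (type == 3 && count == 1) c(u16raw(value), as.raw(c(0, 0)))
         else u32raw(value)
  c(u16raw(tag), u16raw(type), u32raw(count), val)
}

writeTiffPages <- function(path, pages, description = "") {
  np <- length(pages)
  stopifnot(np >= 1)
  Hs <- vapply(pages, nrow, integer(1)); Ws <- vapply(pages, ncol, integer(1))
  pos <- 8
  stripOffsets <- integer(np)
  for (p in seq_len(np)) { stripOffsets[p] <- pos; pos <- pos + Hs[p] * Ws[p] * 2 }
  desc <- charToRaw(description)
  desc <- c(desc, as.raw(0))
  if (length(desc) %% 2 == 1) desc <- c(desc, as.raw(0))
  descOffset <- pos
  pos <- pos + length(desc)
  nEntries <- c(10L, rep(9L, np - 1L))
  ifdSize <- 2 + nEntries * 12 + 4
  ifdOffsets <- pos + c(0, cumsum(ifdSize))[seq_len(np)]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(u16raw(42), con)
  writeBin(u32raw(ifdOffsets[1]), con)
  for (p in seq_len(np)) writeBin(u16raw(as.vector(t(pages[[p]]))), con)
  writeBin(desc, con)
  for (p in seq_len(np)) {
    entries <- list(
      ifdEntry(256, 4, 1, Ws[p]),
      ifdEntry(257, 4, 1, Hs[p]),
      ifdEntry(258, 3, 1, 16),
      ifdEntry(259, 3, 1, 1),
      ifdEntry(262, 3, 1, 1))
    if (p == 1L)
      entries <- c(entries, list(ifdEntry(270, 2, length(desc), descOffset)))
    entries <- c(entries, list(
      ifdEntry(273, 4, 1, stripOffsets[p]),
      ifdEntry(277, 3, 1, 1),
      ifdEntry(278, 4, 1, Hs[p]),
      ifdEntry(279, 4, 1, Hs[p] * Ws[p] * 2)))
    writeBin(u16raw(length(entries)), con)
    for (e in entries) writeBin(e, con)
    nxt <- if (p < np) ifdOffsets[p + 1] else 0
    writeBin(u32raw(nxt), con)
  }
  invisible(path)
}

readTiffPages <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  getU16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  getU32 <- function(off) as.integer(raw[off + 1]) + 256 * as.integer(raw[off + 2]) +
    65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
  if (rawToChar(raw[1:2]) != "II" || getU16(2) != 42L)
    stop("not a little-endian TIFF")
  ifd <- getU32(4)
  pages <- list()
  description <- ""
  while (ifd != 0) {
    n <- getU16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- getU16(off); type <- getU16(off + 2); count <- getU32(off + 4)
      value <- if (type == 3 && count == 1) getU16(off + 8) else getU32(off + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = value,
                                        off = off + 8)
    }
    W <- tags[["256"]]$value; H <- tags[["257"]]$value
    bits <- if (!is.null(tags[["258"]])) tags[["258"]]$value else 1L
    if (!is.null(tags[["259"]]) && tags[["259"]]$value != 1L)
      stop("compressed TIFF not supported")
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit grayscale TIFF supported")
    nStrips <- tags[["273"]]$count
    offs <- if (nStrips == 1) tags[["273"]]$value
            else vapply(seq_len(nStrips) - 1L, function(k) getU32(tags[["273"]]$value + 4 * k), numeric(1))
    cnts <- if (nStrips == 1) tags[["279"]]$value
            else vapply(seq_len(nStrips) - 1L, function(k) getU32(tags[["279"]]$value + 4 * k), numeric(1))
    data <- unlist(lapply(seq_len(nStrips), function(k)
      as.integer(raw[(offs[k] + 1):(offs[k] + cnts[k])])), use.names = FALSE)
    v <- if (bits == 16L) data[c(TRUE, FALSE)] + 256L * data[c(FALSE, TRUE)] else data
    pages[[length(pages) + 1L]] <- matrix(v, H, W, byrow = TRUE)
    if (!is.null(tags[["270"]]) && description == "") {
      d <- tags[["270"]]
      bytes <- raw[(d$value + 1):(d$value + d$count)]
      bytes <- bytes[bytes != as.raw(0)]
      description <- rawToChar(bytes)
    }
    ifd <- getU32(ifd + 2 + n * 12)
  }
  list(pages = pages, description = description)
}

#' Write an ImageStack to a multi-page TIFF
#'
#' Pages are ordered frame-major (frame 1 channel 1, frame 1 channel 2, ...).
#' Pixel scale, frame interval and channel names are stored as JSON in the
#' ImageDescription tag. Values are clamped to the unsigned 16-bit range.
#'
#' @param stack an \linkS4class{ImageStack} without an RGB axis.
#' @param path output file.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@data)
  if (length(d) == 5L) stop("flatten() the RGB axis before writing")
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (t in seq_len(d[2])) for (c in seq_len(d[1])) {
    k <- k + 1L
    pages[[k]] <- matrix(stack@data[c, t, , ], d[3], d[4])
  }
  meta <- jsonlite::toJSON(list(pixelScale = stack@pixelScale,
                                frameInterval = stack@frameInterval,
                                channelNames = stack@channelNames,
                                nChannels = d[1], nFrames = d[2]),
                           auto_unbox = TRUE, digits = NA)
  writeTiffPages(path, pages, as.character(meta))
}

#' Read an ImageStack written by \code{\link{writeImageStack}}
#' @param path TIFF file.
#' @return an \linkS4class{ImageStack}.
#' @export
readImageStack <- function(path) {
  r <- readTiffPages(path)
  meta <- jsonlite::fromJSON(r$description)
  nC <- meta$nChannels; nT <- meta$nFrames
  H <- nrow(r$pages[[1]]); W <- ncol(r$pages[[1]])
  arr <- array(0, dim = c(nC, nT, H, W))
  k <- 0L
  for (t in seq_len(nT)) for (c in seq_len(nC)) {
    k <- k + 1L
    arr[c, t, , ] <- r$pages[[k]]
  }
  ImageStack(arr, meta$pixelScale, meta$frameInterval, as.character(meta$channelNames))
}

#' Write a WoundMask as a single-page TIFF (0/65535)
#' @param mask a \linkS4class{WoundMask}.
#' @param path output file.
#' @export
writeWoundMask <- function(mask, path) {
  stopifnot(is(mask, "WoundMask"))
  meta <- jsonlite::toJSON(list(pixelScale = mask@pixelScale, origin = mask@origin,
                                kind = "wound_mask"), auto_unbox = TRUE, digits = NA)
  writeTiffPages(path, list(ifelse(mask@mask, 65535, 0)), as.character(meta))
}

#' Read a WoundMask written by \code{\link{writeWoundMask}}
#' @param path TIFF file.
#' @export
readWoundMask <- function(path) {
  r <- readTiffPages(path)
  meta <- jsonlite::fromJSON(r$description)
  WoundMask(r$pages[[1]] > 0, meta$pixelScale, as.numeric(meta$origin))
}

#' Write per-frame 16-bit label masks
#' @param labels list of integer label matrices (one per frame).
#' @param dir output directory; files are named frame_0001.tiff, ...
#' @export
writeLabelMasks <- function(labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(labels))
    writeTiffPages(file.path(dir, sprintf("frame_%04d.tiff", t)),
                   list(labels[[t]]), sprintf("{\"kind\":\"labels\",\"frame\":%d}", t))
  invisible(dir)
}
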