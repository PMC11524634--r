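# JSON / CSV serialization of design objects and parameters.

#' Write / read a WoundShapeSpec as JSON
#' @param spec a \linkS4class{WoundShapeSpec}.
#' @param path file path.
#' @export
writeWoundSpec <- function(spec, path) {
  stopifnot(is(spec, "WoundShapeSpec"))
  x <- list(shape = spec@shape, size = spec@size,
            vertices = if (nrow(spec@vertices)) unname(apply(spec@vertices, 1, as.numeric, simplify = FALSE)) else NULL,
            center = spec@center, rotation = spec@rotation, well = spec@well,
            tip_width = spec@tipWidth, tip_speed = spec@tipSpeed,
            tip_accel = spec@tipAccel)
  jsonlite::write_json(x[!vapply(x, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeWoundSpec
#' @export
readWoundSpec <- function(path) {
  x <- jsonlite::fromJSON(path)
  WoundShapeSpec(shape = x$shape,
                 size = x$size %||% NA_real_,
                 vertices = if (!is.null(x$vertices)) matrix(unlist(x$vertices), ncol = 2, byrow = TRUE)
                            else matrix(numeric(0), 0, 2),
                 center = as.numeric(x$center %||% c(0, 0)),
                 rotation = x$rotation %||% 0,
                 well = as.integer(x$well %||% c(1L, 1L)),
                 tipWidth = x$tip_width %||% (0.66 * 0.48),
                 tipSpeed = x$tip_speed %||% 3,
                 tipAccel = x$tip_accel %||% 10)
}

#' Write / read a CornerCalibration as JSON
#' @param cal a \linkS4class{CornerCalibration}.
#' @param path file path.
#' @export
writeCornerCalibration <- function(cal, path) {
  stopifnot(is(cal, "CornerCalibration"))
  x <- list(corners = setNames(lapply(rownames(cal@corners),
                                      function(k) as.numeric(cal@corners[k, ])),
                               rownames(cal@corners)),
            tip_offset_z = cal@tipOffsetZ)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCornerCalibration
#' @export
readCornerCalibration <- function(path) {
  x <- jsonlite::fromJSON(path)
  m <- do.call(rbind, x$corners[c("r1c1", "r1cC", "rRc1", "rRcC")])
  CornerCalibration(m, x$tip_offset_z %||% 0)
}

#' Export a toolpath as JSON or flat CSV
#'
#' The CSV has columns stroke_id, point_index, x_mm, y_mm, pen_down.
#'
#' @param path a \linkS4class{Toolpath}.
#' @param file output file.
#' @export
writeToolpathJSON <- function(path, file) {
  stopifnot(is(path, "Toolpath"))
  x <- list(tip_width = path@tipWidth,
            strokes = lapply(seq_along(path@strokes), function(i)
              list(pen_down = path@penDown[i],
                   points = unname(apply(path@strokes[[i]], 1, as.numeric, simplify = FALSE)))))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeToolpathJSON
#' @export
readToolpathJSON <- function(file) {
  x <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  strokes <- lapply(x$strokes, function(s)
    matrix(unlist(s$points), ncol = 2, byrow = TRUE))
  pen <- vapply(x$strokes, function(s) isTRUE(s$pen_down), logical(1))
  Toolpath(strokes, pen, x$tip_width)
}

#' @rdname writeToolpathJSON
#' @export
writeToolpathCSV <- function(path, file) {
  stopifnot(is(path, "Toolpath"))
  rows <- do.call(rbind, lapply(seq_along(path@strokes), function(i) {
    st <- path@strokes[[i]]
    data.frame(stroke_id = i, point_index = seq_len(nrow(st)),
               x_mm = st[, 1], y_mm = st[, 2], pen_down = path@penDown[i])
  }))
  write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Write / read SimulationParams as JSON
#' @param params a \linkS4class{SimulationParams}.
#' @param path file path.
#' @export
writeSimulationParams <- function(params, path) {
  stopifnot(is(params, "SimulationParams"))
  sl <- slotNames("SimulationParams")
  x <- setNames(lapply(sl, function(s) slot(params, s)), sl)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSimulationParams
#' @export
readSimulationParams <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(SimulationParams, x)
}

#' Write ground truth tables (cells per frame + lineage) as CSV
#' @param gt a \linkS4class{GroundTruth}.
#' @param dir output directory.
#' @export
writeGroundTruth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(gt@cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(gt@lineage, file.path(dir, "lineage.csv"), row.names = FALSE)
  write.csv(data.frame(frame = seq_along(gt@area), area_mm2 = gt@area,
                       width_mean_um = gt@widthMean, width_sd_um = gt@widthSd),
            file.path(dir, "wound.csv"), row.names = FALSE)
  invisible(dir)
}
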