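#' Compute all well centres of a plate from four calibrated corner wells
#'
#' The four corner wells of the plate are measured in the stage frame; every
#' other well centre is obtained by bilinear interpolation of the corners in
#' normalized grid coordinates u = (col - 1)/(cols - 1), v = (row - 1)/(rows - 1).
#' The z coordinate is interpolated the same way, so a tilted plate is
#' reproduced exactly as long as the true centres are an affine image of the
#' integer grid. One-row or one-column plates degenerate to linear
#' interpolation along the remaining axis.
#'
#' @param plate a \linkS4class{PlateSpec}.
#' @param cal a \linkS4class{CornerCalibration}; corners keyed r1c1, r1cC,
#'   rRc1, rRcC must match the plate dimensions (for a 1-row plate the rRc*
#'   corners must coincide with the r1c* corners, and similarly for 1 column).
#' @return data.frame with columns row, col (1-based), x, y, z (mm), in
#'   row-major order.
#' @export
calibrateWells <- function(plate, cal) {
  stopifnot(is(plate, "PlateSpec"), is(cal, "CornerCalibration"))
  validObject(plate); validObject(cal)
  m <- cal@corners
  if (plate@rows == 1L) {
    if (max(abs(m["rRc1", ] - m["r1c1", ]), abs(m["rRcC", ] - m["r1cC", ])) > 1e-6)
      stop("plate has 1 row but the rRc* corners differ from the r1c* corners")
  }
  if (plate@cols == 1L) {
    if (max(abs(m["r1cC", ] - m["r1c1", ]), abs(m["rRcC", ] - m["rRc1", ])) > 1e-6)
      stop("plate has 1 column but the *cC corners differ from the *c1 corners")
  }
  grid <- expand.grid(col = seq_len(plate@cols), row = seq_len(plate@rows))
  u <- if (plate@cols > 1L) (grid$col - 1) / (plate@cols - 1) else rep(0, nrow(grid))
  v <- if (plate@rows > 1L) (grid$row - 1) / (plate@rows - 1) else rep(0, nrow(grid))
  w <- cbind((1 - u) * (1 - v), u * (1 - v), (1 - u) * v, u * v)
  xyz <- w %*% m[c("r1c1", "r1cC", "rRc1", "rRcC"), , drop = FALSE]
  out <- data.frame(row = grid$row, col = grid$col,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  out[order(out$row, out$col), , drop = FALSE]
}
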