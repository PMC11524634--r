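# shared fixtures: small simulations and geometry helpers used across tests

# independent bilinear interpolation oracle on the unit square
bilinearOracle <- function(c00, c01, c10, c11, u, v) {
  (1 - u) * (1 - v) * c00 + u * (1 - v) * c01 + (1 - u) * v * c10 + u * v * c11
}

cornersFrom <- function(p1, p2, p3, p4) {
  m <- rbind(r1c1 = p1, r1cC = p2, rRc1 = p3, rRcC = p4)
  CornerCalibration(m)
}

# tiny simulation: n cells on a small field, one frame, quiet defaults
tinyParams <- function(n = 100, field = 1000, seed = 1L, ...) {
  SimulationParams(fieldSize = c(field, field),
                   seedingDensity = n / (field * field / 1e8),
                   nFrames = 1L, seed = seed, ...)
}

# per-frame link accuracy of a track table against true ids carried in nuclei
linkAccuracy <- function(tracks, nuclei) {
  idOf <- setNames(nuclei$id, paste(nuclei$frame, nuclei$label))
  tracks$id <- idOf[paste(tracks$frame, tracks$label)]
  frames <- sort(unique(nuclei$frame))
  good <- 0; tot <- 0
  for (t in frames[-length(frames)]) {
    a <- tracks[tracks$frame == t, ]
    b <- tracks[tracks$frame == t + 1, ]
    mm <- merge(a[, c("track", "id")], b[, c("track", "id")], by = "track")
    tot <- tot + sum(nuclei$frame == t & nuclei$id %in% nuclei$id[nuclei$frame == t + 1])
    good <- good + sum(mm$id.x == mm$id.y)
  }
  good / tot
}

# ground-truth cells of frame 1 as a nuclei table with per-frame labels
gtAsNuclei <- function(truth) {
  do.call(rbind, lapply(split(truth@cells, truth@cells$frame), function(d)
    data.frame(frame = d$frame, label = seq_len(nrow(d)),
               x_um = d$x, y_um = d$y, id = d$id)))
}
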