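# Single-cell tracking: linear-Gaussian (Kalman) motion prediction per track,
# frame-to-frame global assignment (Hungarian, with dummy rows/columns for
# track birth and death), gap closing, and division linking. A transparent
# simplification of Bayesian multi-hypothesis trackers: one global
# minimum-cost assignment per frame transition, costs are negative
# log-likelihoods of observations under each track's predicted observation
# density.

kfMatrices <- function(model, dt, q, r) {
  if (model == "cv") {
    F <- diag(4); F[1, 3] <- dt; F[2, 4] <- dt
    G <- matrix(c(dt^2 / 2, 0, 0, dt^2 / 2, dt, 0, 0, dt), 4, 2, byrow = TRUE)
    Q <- q^2 * (G %*% t(G))
    H <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 2, 4, byrow = TRUE)
  } else {
    F <- diag(2)
    Q <- q^2 * dt * diag(2)
    H <- diag(2)
  }
  list(F = F, Q = Q, H = H, R = r^2 * diag(2))
}

#' Link segmented nuclei over time into tracks
#'
#' For each frame transition, every live track's position is predicted by its
#' motion model; a cost matrix of observation negative log-likelihoods
#' (Mahalanobis distance under the predicted observation covariance, plus the
#' normalization term) is gated at the Euclidean \code{maxLinkDist} and solved
#' as a global assignment with dummy rows/columns so tracks may die and
#' observations may start new tracks. Tracks unobserved for more than
#' \code{maxGap} frames terminate. With division linking on, a track born
#' next to a track present in the previous frame is recorded as that track's
#' child.
#'
#' Within-frame observation order does not affect the result: observations
#' are processed in label order and the assignment is the global cost
#' minimum (ties broken toward lower labels).
#'
#' @param nuclei data.frame with columns frame, label, x_um, y_um (extra
#'   columns are ignored here; see \code{\link{mergeProperties}}).
#' @param config a \linkS4class{TrackConfig}.
#' @return data.frame (track, frame, label, x_um, y_um, parent_track) with
#'   one row per (track, frame), ordered by (track, frame); the division
#'   edge list is attached as attribute "lineage" (data.frame parent_track,
#'   child_track, frame).
#' @export
linkTracks <- function(nuclei, config = TrackConfig()) {
  stopifnot(is.data.frame(nuclei), is(config, "TrackConfig"))
  validObject(config)
  cols <- c("frame", "label", "x_um", "y_um")
  missing <- setdiff(cols, names(nuclei))
  if (length(missing)) stop("nuclei table lacks column(s): ", paste(missing, collapse = ", "))
  empty <- data.frame(track = integer(0), frame = integer(0), label = integer(0),
                      x_um = numeric(0), y_um = numeric(0), parent_track = integer(0))
  attr(empty, "lineage") <- data.frame(parent_track = integer(0),
                                       child_track = integer(0), frame = integer(0))
  if (nrow(nuclei) == 0) return(empty)
  if (is.unsorted(nuclei$frame)) nuclei <- nuclei[order(nuclei$frame), , drop = FALSE]

  gate <- config@maxLinkDist
  q <- config@processNoise; r <- config@obsNoise
  model <- config@motionModel
  BIG <- 1e9

  tracks <- list()   # each: id, x (state), P, lastFrame
  nextId <- 1L
  rows <- vector("list", 2048L); nRows <- 0L
  births <- list()   # id -> c(frame, x, y)
  addRow <- function(row) {
    nRows <<- nRows + 1L
    if (nRows > length(rows)) length(rows) <<- 2L * nRows
    rows[[nRows]] <<- row
  }
  newTrack <- function(f, x, y, label) {
    st <- if (model == "cv") c(x, y, 0, 0) else c(x, y)
    P <- if (model == "cv") diag(c(r^2, r^2, (gate / 2)^2, (gate / 2)^2))
         else diag(c(r^2, r^2))
    id <- nextId; nextId <<- nextId + 1L
    tracks[[length(tracks) + 1L]] <<- list(id = id, x = st, P = P, lastFrame = f)
    births[[as.character(id)]] <<- c(f, x, y)
    addRow(data.frame(track = id, frame = f, label = label, x_um = x, y_um = y))
  }

  frames <- sort(unique(nuclei$frame))
  byFrame <- split(nuclei, nuclei$frame)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    obs <- byFrame[[as.character(f)]]
    obs <- obs[order(obs$label), , drop = FALSE]
    nO <- nrow(obs)
    # drop tracks out of gap range
    if (length(tracks))
      tracks <- Filter(function(tr) f - tr$lastFrame <= config@maxGap + 1L, tracks)
    nT <- length(tracks)
    if (fi == 1L || nT == 0L) {
      for (k in seq_len(nO)) newTrack(f, obs$x_um[k], obs$y_um[k], obs$label[k])
      next
    }
    # predict
    preds <- lapply(tracks, function(tr) {
      dt <- f - tr$lastFrame
      M <- kfMatrices(model, dt, q, r)
      xp <- as.numeric(M$F %*% tr$x)
      Pp <- M$F %*% tr$P %*% t(M$F) + M$Q
      S <- M$H %*% Pp %*% t(M$H) + M$R
      list(xp = xp, Pp = Pp, S = S, Sinv = solve(S), ldet = determinant(S)$modulus[1],
           M = M)
    })
    n <- nT + nO
    A <- matrix(BIG, n, n)
    A[(nT + 1):n, (nO + 1):n] <- 0  # dummy-dummy
    ox <- obs$x_um; oy <- obs$y_um
    for (i in seq_len(nT)) {
      pr <- preds[[i]]
      S <- pr$S
      lmax <- 0.5 * (S[1, 1] + S[2, 2] +
                     sqrt((S[1, 1] - S[2, 2])^2 + 4 * S[1, 2]^2))
      A[i, nO + i] <- 0.5 * gate^2 / lmax + 0.5 * pr$ldet + log(2 * pi)  # death
      dx <- ox - pr$xp[1]; dy <- oy - pr$xp[2]
      within <- which(dx * dx + dy * dy <= gate^2)
      if (length(within)) {
        Si <- pr$Sinv
        maha2 <- Si[1, 1] * dx[within]^2 + 2 * Si[1, 2] * dx[within] * dy[within] +
          Si[2, 2] * dy[within]^2
        A[i, within] <- 0.5 * maha2 + 0.5 * pr$ldet + log(2 * pi)
      }
    }
    S0 <- (r^2 + q^2) # nominal birth covariance scale
    birthCost <- 0.5 * gate^2 / (S0 * 4) + 0.5 * log(S0^2) + log(2 * pi)
    for (j in seq_len(nO)) A[nT + j, j] <- birthCost
    sol <- as.integer(clue::solve_LSAP(A - min(A)))
    matchedObs <- logical(nO)
    for (i in seq_len(nT)) {
      j <- sol[i]
      if (j <= nO && A[i, j] < BIG) {
        matchedObs[j] <- TRUE
        pr <- preds[[i]]
        z <- c(obs$x_um[j], obs$y_um[j])
        K <- pr$Pp %*% t(pr$M$H) %*% pr$Sinv
        xn <- pr$xp + as.numeric(K %*% (z - pr$M$H %*% pr$xp))
        Pn <- (diag(nrow(pr$Pp)) - K %*% pr$M$H) %*% pr$Pp
        tracks[[i]]$x <- xn; tracks[[i]]$P <- Pn; tracks[[i]]$lastFrame <- f
        addRow(data.frame(track = tracks[[i]]$id, frame = f, label = obs$label[j],
                          x_um = z[1], y_um = z[2]))
      }
    }
    for (j in which(!matchedObs)) newTrack(f, obs$x_um[j], obs$y_um[j], obs$label[j])
  }

  out <- do.call(rbind, rows[seq_len(nRows)])
  out <- out[order(out$track, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out$parent_track <- NA_integer_

  lineage <- data.frame(parent_track = integer(0), child_track = integer(0),
                        frame = integer(0))
  if (config@divisionLinking && length(births)) {
    firstFrame <- min(out$frame)
    trackStart <- tapply(out$frame, out$track, min)
    for (id in names(births)) {
      b <- births[[id]]
      if (b[1] <= firstFrame) next
      # candidate parents existed before the birth frame; measure the distance
      # at the birth frame itself when the candidate is present there (the
      # mother has already moved by frame f), else at f - 1
      candTracks <- as.integer(names(trackStart)[trackStart <= b[1] - 1L])
      candTracks <- setdiff(candTracks, as.integer(id))
      if (!length(candTracks)) next
      cand <- out[out$track %in% candTracks & out$frame %in% c(b[1], b[1] - 1L), ,
                  drop = FALSE]
      if (!nrow(cand)) next
      cand <- cand[order(cand$track, -cand$frame), , drop = FALSE]
      cand <- cand[!duplicated(cand$track), , drop = FALSE]
      d <- sqrt((cand$x_um - b[2])^2 + (cand$y_um - b[3])^2)
      k <- which.min(d)
      if (d[k] <= config@divisionMaxDist) {
        lineage <- rbind(lineage, data.frame(parent_track = cand$track[k],
                                             child_track = as.integer(id),
                                             frame = b[1]))
        out$parent_track[out$track == as.integer(id)] <- cand$track[k]
      }
    }
  }
  attr(out, "lineage") <- lineage
  out
}

#' Merge nuclear properties onto a track table
#'
#' Joins every (frame, label) track row with its full property row from the
#' nuclei table; the output has exactly one row per input track row. Track
#' rows without a property row are an error (all orphans are listed).
#'
#' @param tracks output of \code{\link{linkTracks}}.
#' @param nuclei the nuclei table the tracks were built from.
#' @return track table with all nuclei-table columns appended.
#' @export
mergeProperties <- function(tracks, nuclei) {
  stopifnot(is.data.frame(tracks), is.data.frame(nuclei))
  lineage <- attr(tracks, "lineage")
  orphan <- !paste(tracks$frame, tracks$label) %in% paste(nuclei$frame, nuclei$label)
  if (any(orphan))
    stop("track rows with no matching nucleus: ",
         paste(sprintf("(frame %s, label %s)", tracks$frame[orphan],
                       tracks$label[orphan]), collapse = ", "))
  extra <- setdiff(names(nuclei), c("frame", "label", "x_um", "y_um"))
  merged <- merge(tracks, nuclei[, c("frame", "label", extra), drop = FALSE],
                  by = c("frame", "label"), all.x = TRUE, sort = FALSE)
  merged <- merged[order(merged$track, merged$frame), , drop = FALSE]
  rownames(merged) <- NULL
  attr(merged, "lineage") <- lineage
  merged
}
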