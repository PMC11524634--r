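# internal helpers: small geometry, seeds, matching

`%||%` <- function(a, b) if (is.null(a)) b else a

# signed area of a polygon (shoelace); vertices as n x 2 matrix, no repeat
shoelaceArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

isConvexPolygon <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  s <- 0
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[(i %% n) + 1, ]; c <- v[((i + 1) %% n) + 1, ]
    cr <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

rotate2d <- function(pts, degrees) {
  th <- degrees * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts %*% t(R)
}

# inward offset of a convex polygon by d: shift every edge toward the interior
# and intersect consecutive edge lines. Returns NULL when the offset collapses.
insetConvexPolygon <- function(v, d) {
  n <- nrow(v)
  if (n < 3) return(NULL)
  orient <- sign(shoelaceArea(v))
  if (orient == 0) return(NULL)
  p <- matrix(NA_real_, n, 2)  # shifted edge anchor
  dir <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[(i %% n) + 1, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < 1e-12) return(NULL)
    e <- e / len
    nrm <- orient * c(-e[2], e[1])  # interior normal
    p[i, ] <- a + d * nrm
    dir[i, ] <- e
  }
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    j <- (i %% n) + 1
    # intersect line i with line j
    A <- cbind(dir[i, ], -dir[j, ])
    rhs <- p[j, ] - p[i, ]
    det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    if (abs(det) < 1e-12) return(NULL)
    t <- (rhs[1] * A[2, 2] - rhs[2] * A[1, 2]) / det
    out[j, ] <- p[i, ] + t * dir[i, ]
  }
  if (sign(shoelaceArea(out)) != orient) return(NULL)
  if (abs(shoelaceArea(out)) < 1e-9) return(NULL)
  out
}

# stable small integer derived from a master seed and a label, via md5 of the
# string; keeps results < 2^31
deriveSeed <- function(seed, label) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste0(seed, "/", label), f)
  h <- tools::md5sum(f)[[1]]
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% .Machine$integer.max)
}

#' Match two point sets by global nearest assignment
#'
#' One-to-one matching of rows of \code{a} to rows of \code{b} minimising the
#' total Euclidean distance (Hungarian assignment), keeping only pairs closer
#' than \code{maxDist}. Used to score detections against ground truth.
#'
#' @param a,b n x 2 / m x 2 matrices of (x, y) points.
#' @param maxDist maximum distance for a valid match (same units as points).
#' @return data.frame with columns \code{i} (row of a), \code{j} (row of b),
#'   \code{dist}.
#' @export
matchCentroids <- function(a, b, maxDist = Inf) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  d <- outer(seq_len(na), seq_len(nb), function(i, j)
    sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
  big <- if (is.finite(maxDist)) 10 * maxDist + max(d) else max(d) + 1
  cost <- d
  cost[cost > maxDist] <- big
  # pad to square for solve_LSAP
  n <- max(na, nb)
  sq <- matrix(big, n, n)
  sq[seq_len(na), seq_len(nb)] <- cost
  sol <- clue::solve_LSAP(sq)
  i <- seq_len(na)
  j <- as.integer(sol)[seq_len(na)]
  ok <- j <= nb & d[cbind(i, pmin(j, nb))] <= maxDist
  data.frame(i = i[ok], j = j[ok], dist = d[cbind(i[ok], j[ok])])
}
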