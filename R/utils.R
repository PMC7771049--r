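# Small numeric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rowNorms <- function(m) sqrt(rowSums(m * m))

vecNorm <- function(v) sqrt(sum(v * v))

normalizeVec <- function(v) {
  n <- vecNorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Mean of a truncated normal distribution
#'
#' Closed-form mean of a Normal(mu, sigma) distribution truncated to
#' `[lo, hi]`. Used as the recovery target for phantom angle groups, whose
#' generator draws are truncated to anatomical ranges that may be
#' asymmetric about the nominal mean.
#'
#' @param mu,sigma Mean and standard deviation of the parent normal.
#' @param lo,hi Truncation bounds.
#' @return The mean of the truncated distribution.
#' @export
truncnormMean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sigma * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Inverse-CDF sampling from a truncated normal; deterministic under a seed.
rtruncnorm <- function(n, mu, sigma, lo, hi) {
  pa <- stats::pnorm(lo, mu, sigma)
  pb <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(stats::runif(n, pa, pb), mu, sigma)
}

# Resample a polyline (n x 2 or n x 3 matrix) at fixed arc-length steps,
# always keeping both endpoints.
resamplePolyline <- function(pts, step = 0.5) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) return(pts)
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(len))
  total <- s[length(s)]
  if (total == 0) return(pts[1, , drop = FALSE])
  at <- unique(c(seq(0, total, by = step), total))
  out <- matrix(0, length(at), ncol(pts))
  for (j in seq_len(ncol(pts))) {
    out[, j] <- stats::approx(s, pts[, j], xout = at)$y
  }
  out
}

polylineLength <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Minimum distance from each point in `p` (m x d) to segment a->b.
pointSegDist <- function(p, a, b) {
  ab <- b - a
  ab2 <- sum(ab * ab)
  if (ab2 == 0) return(rowNorms(sweep(p, 2, a)))
  t <- pmin(1, pmax(0, as.vector(sweep(p, 2, a) %*% ab) / ab2))
  proj <- matrix(a, nrow(p), length(a), byrow = TRUE) + outer(t, ab)
  rowNorms(p - proj)
}

# Minimum distance from each point in `p` to a polyline.
pointPolylineDist <- function(p, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) == 1) return(rowNorms(sweep(p, 2, poly[1, ])))
  d <- rep(Inf, nrow(p))
  for (i in seq_len(nrow(poly) - 1)) {
    d <- pmin(d, pointSegDist(p, poly[i, ], poly[i + 1, ]))
  }
  d
}

#' Mean symmetric distance between two polylines
#'
#' Average of the two directed mean point-to-polyline distances, each
#' polyline resampled at fixed arc-length steps. Zero exactly when the
#' traces coincide; used as the match score for vein-section pairing.
#'
#' @param a,b Polylines as n x 2 matrices (mm).
#' @param step Resampling step in mm.
#' @return Mean symmetric distance in mm.
#' @export
meanSymmetricDistance <- function(a, b, step = 0.5) {
  ra <- resamplePolyline(a, step)
  rb <- resamplePolyline(b, step)
  (mean(pointPolylineDist(ra, b)) + mean(pointPolylineDist(rb, a))) / 2
}

# Simple non-self-intersection check for a closed polygon (n x 2).
polygonSimple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  closed <- rbind(poly, poly[1, ])
  segInt <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (j == 1 && i == n)) next
      if (segInt(closed[i, ], closed[i + 1, ], closed[j, ], closed[j + 1, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}
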