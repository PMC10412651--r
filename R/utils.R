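# Internal helpers: seeded evaluation, disk geometry, polygon rasterization.

# Evaluate expr under a fixed RNG state without disturbing the caller's stream.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Offsets (dr, dc) of a filled disk of radius r (in pixels, centre included).
.diskOffsets <- function(r) {
  rr <- ceiling(r)
  d <- seq.int(-rr, rr)
  g <- expand.grid(dr = d, dc = d)
  g <- g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

# Linear indices of a disk clipped to an H x W image.
.diskIndices <- function(row, col, r, H, W) {
  o <- .diskOffsets(r)
  rr <- row + o[, 1L]; cc <- col + o[, 2L]
  keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  rr[keep] + (cc[keep] - 1L) * H
}

.assertFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(x)
}

# round() uses banker's rounding; percentages are reported half-away-from-zero.
.roundHalfUp <- function(x) floor(x + 0.5)

# ---- polygon helpers (manual ROI import) ----

# Even-odd point-in-polygon, vectorized over query points, with points on the
# boundary counted as inside (tolerance eps in pixel units).
.pointsInPolygon <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py[crosses] - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      upd <- which(crosses)[px[crosses] < xint]
      inside[upd] <- !inside[upd]
    }
    j <- i
  }
  # boundary inclusion
  onb <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    ex <- vx[i] - vx[j]; ey <- vy[i] - vy[j]
    len2 <- ex^2 + ey^2
    if (len2 == 0) { j <- i; next }
    t <- ((px - vx[j]) * ex + (py - vy[j]) * ey) / len2
    t <- pmin(1, pmax(0, t))
    d2 <- (px - (vx[j] + t * ex))^2 + (py - (vy[j] + t * ey))^2
    onb <- onb | d2 <= eps
    j <- i
  }
  inside | onb
}

# Do two closed segments properly intersect (excluding shared endpoints)?
.segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.polygonSelfIntersects <- function(vx, vy) {
  n <- length(vx)
  if (n < 4) return(FALSE)
  pts <- cbind(vx, vy)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    for (j in seq_len(n)) {
      j2 <- if (j == n) 1L else j + 1L
      # skip identical and adjacent edges
      if (i == j || i2 == j || j2 == i) next
      if (j < i) next
      if (.segmentsIntersect(pts[i, ], pts[i2, ], pts[j, ], pts[j2, ]))
        return(TRUE)
    }
  }
  FALSE
}

# Rasterize a polygon given in 0-based pixel coordinates (x = column, y = row)
# into linear indices of an H x W matrix. Pixel (x, y) is matrix[y+1, x+1];
# pixel centres on the polygon boundary are included.
.rasterizePolygon <- function(vx, vy, H, W) {
  r0 <- max(1L, floor(min(vy)) + 1L); r1 <- min(H, ceiling(max(vy)) + 1L)
  c0 <- max(1L, floor(min(vx)) + 1L); c1 <- min(W, ceiling(max(vx)) + 1L)
  if (r0 > r1 || c0 > c1) return(integer(0))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  keep <- .pointsInPolygon(g$col - 1, g$row - 1, vx, vy)
  g$row[keep] + (g$col[keep] - 1L) * H
}

# Per-label pixel counts of mask within a label matrix (label ids 1..n).
.areaByLabel <- function(labels, n, mask = NULL) {
  v <- if (is.null(mask)) labels[labels != 0L] else labels[mask & labels != 0L]
  tabulate(v, nbins = n)
}
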