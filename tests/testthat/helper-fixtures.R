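# Shared fixtures and independent oracles for the test suite.

unitSquare <- function(cx = 0, cy = 0, side = 1) {
  h <- side / 2
  cbind(c(-h, h, h, -h) + cx + h, c(-h, -h, h, h) + cy + h)
}

regularPolygon <- function(n, r = 1, cx = 0, cy = 0) {
  th <- 2 * pi * (0:(n - 1)) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

ellipsePolygon <- function(a, b, n = 64, cx = 0, cy = 0) {
  th <- 2 * pi * (0:(n - 1)) / n
  cbind(cx + a * cos(th), cy + b * sin(th))
}

rotatePolygon <- function(poly, deg, about = c(0, 0)) {
  r <- deg * pi / 180
  rot <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  sweep(sweep(poly, 2, about, "-") %*% t(rot), 2, about, "+")
}

# A plus sign made of 5 unit squares inside a 3x3 bounding box.
plusPolygon <- function() {
  cbind(c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
        c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1))
}

# Independent even-odd point-in-polygon test (oracle for rasterization and
# IoU), evaluated on an arbitrary point set.
oraclePointsInPolygon <- function(poly, px, py) {
  inside <- logical(length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cr <- ((yi > py) != (yj > py)) & (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cr)
    j <- i
  }
  inside
}

# Brute-force IoU on a fine subpixel grid.
oracleIoU <- function(a, b, step = 0.2) {
  xr <- range(c(a[, 1], b[, 1])); yr <- range(c(a[, 2], b[, 2]))
  gx <- seq(xr[1] - step, xr[2] + step, by = step)
  gy <- seq(yr[1] - step, yr[2] + step, by = step)
  px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
  ia <- oraclePointsInPolygon(a, px, py)
  ib <- oraclePointsInPolygon(b, px, py)
  if (!any(ia | ib)) return(0)
  sum(ia & ib) / sum(ia | ib)
}

# Exhaustive-permutation assignment oracle (n <= 8).
oracleAssignmentMin <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  best <- Inf
  perm <- integer(n)
  used <- logical(n)
  rec <- function(i, acc) {
    if (acc >= best) return()
    if (i > n) { best <<- acc; return() }
    for (j in seq_len(n)) if (!used[j]) {
      used[j] <<- TRUE
      rec(i + 1L, acc + cost[i, j])
      used[j] <<- FALSE
    }
  }
  rec(1L, 0)
  best
}

# A minimal synthetic grayscale frame with rectangular blobs; blobs is a
# list of c(x0, y0, w, h) in 0-based pixel coords, value 1 on 0 background.
blobImage <- function(width, height, blobs) {
  img <- matrix(0, height, width)
  for (b in blobs)
    img[(b[2] + 1):(b[2] + b[4]), (b[1] + 1):(b[1] + b[3])] <- 1
  img
}

# Straight-line trajectory fixture.
lineTrajectory <- function(n = 10, step = 1) {
  trajectory(x = step * (0:(n - 1)), y = rep(0, n))
}
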