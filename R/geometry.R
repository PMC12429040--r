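#' Polygon geometry and static morphometric descriptors
#'
#' Polygons are plain numeric matrices with two columns (x, y) giving vertex
#' coordinates in pixels: x grows rightwards, y downwards, origin at the
#' top-left corner of the image, 0-based. The polygon is implicitly closed
#' (the last vertex connects back to the first).
#'
#' @name polygon-geometry
NULL

.polyTol <- 1e-12

# Validate a polygon matrix; returns it with any duplicated closing vertex
# dropped. Degenerate (collinear / zero-area) input is an error.
checkPolygon <- function(poly) {
  if (is.data.frame(poly)) poly <- as.matrix(poly)
  if (!is.matrix(poly) || ncol(poly) != 2L || !is.numeric(poly))
    stop("invalid geometry: a polygon must be a numeric n x 2 matrix", call. = FALSE)
  if (anyNA(poly) || any(!is.finite(poly)))
    stop("invalid geometry: polygon vertices must be finite", call. = FALSE)
  n <- nrow(poly)
  if (n >= 2L && all(abs(poly[n, ] - poly[1L, ]) < .polyTol)) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L)
    stop("invalid geometry: a polygon needs at least 3 vertices", call. = FALSE)
  if (abs(shoelaceArea(poly)) <= .polyTol)
    stop("invalid geometry: polygon has zero area (degenerate/collinear)", call. = FALSE)
  dimnames(poly) <- NULL
  poly
}

# Signed shoelace area; positive for counter-clockwise vertex order in a
# standard (y-up) frame.
shoelaceArea <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area
#'
#' Unsigned enclosed area of a polygon by the shoelace formula, in square
#' pixels (or square calibrated units if the vertices are calibrated).
#'
#' @param poly numeric n x 2 vertex matrix (see \link{polygon-geometry}).
#' @return scalar area.
#' @export
polygonArea <- function(poly) {
  poly <- checkPolygon(poly)
  abs(shoelaceArea(poly))
}

#' Polygon perimeter
#'
#' Length of the closed vertex chain.
#'
#' @inheritParams polygonArea
#' @return scalar perimeter.
#' @export
polygonPerimeter <- function(poly) {
  poly <- checkPolygon(poly)
  d <- poly[c(seq_len(nrow(poly))[-1L], 1L), , drop = FALSE] - poly
  sum(sqrt(rowSums(d^2)))
}

#' Centroid of a polygon
#'
#' The default is the area centroid of the filled region (first moments).
#' `method = "boundary"` instead averages the boundary vertices, matching
#' pipelines that compute centroids as the mean of boundary pixels; it is
#' sensitive to vertex density and provided for compatibility only.
#'
#' @inheritParams polygonArea
#' @param method `"area"` (default) or `"boundary"`.
#' @return length-2 numeric (x, y).
#' @export
polygonCentroid <- function(poly, method = c("area", "boundary")) {
  method <- match.arg(method)
  poly <- checkPolygon(poly)
  if (method == "boundary") return(colMeans(poly))
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Area, perimeter and circularity of a cell outline
#'
#' Converts pixel measurements to physical units with the supplied
#' calibration and reports the dimensionless circularity
#' \eqn{4\pi A / P^2}, which is 1 for a perfect circle and decreases for
#' elongated or irregular outlines.
#'
#' @inheritParams polygonArea
#' @param calib micrometres per pixel (default 1: stay in pixel units).
#' @return named list with `area` (calib units squared), `perimeter`
#'   (calib units) and `circularity`.
#' @export
polygonMetrics <- function(poly, calib = 1) {
  assertScalarNumeric(calib, "calib", lower = .Machine$double.eps)
  a <- polygonArea(poly)
  p <- polygonPerimeter(poly)
  list(area = a * calib^2, perimeter = p * calib,
       circularity = 4 * pi * a / p^2)
}

.polyToClip <- function(poly) list(x = poly[, 1L], y = poly[, 2L])

.clipArea <- function(contours) {
  if (length(contours) == 0L) return(0)
  sum(vapply(contours, function(cc)
    abs(shoelaceArea(cbind(cc$x, cc$y))), numeric(1)))
}

#' Intersection over union of two polygons
#'
#' Exact polygon clipping; the union area is computed as
#' \eqn{A + B - A\cap B}.
#'
#' @param a,b polygons (numeric n x 2 matrices).
#' @return IoU ratio in `[0, 1]`; symmetric in its arguments.
#' @export
polygonIoU <- function(a, b) {
  a <- checkPolygon(a); b <- checkPolygon(b)
  # cheap reject: disjoint bounding boxes
  if (max(a[, 1L]) < min(b[, 1L]) || max(b[, 1L]) < min(a[, 1L]) ||
      max(a[, 2L]) < min(b[, 2L]) || max(b[, 2L]) < min(a[, 2L]))
    return(0)
  inter <- .clipArea(polyclip::polyclip(.polyToClip(a), .polyToClip(b),
                                        op = "intersection"))
  aa <- abs(shoelaceArea(a)); ab <- abs(shoelaceArea(b))
  un <- aa + ab - inter
  if (un <= .polyTol) return(0)
  min(max(inter / un, 0), 1)
}

#' Union of two polygons
#'
#' Merges two overlapping polygons into the boundary of their union. When
#' the union has several disjoint parts, the largest is returned.
#'
#' @param a,b polygons.
#' @return polygon matrix of the union boundary.
#' @export
polygonUnion <- function(a, b) {
  a <- checkPolygon(a); b <- checkPolygon(b)
  u <- polyclip::polyclip(.polyToClip(a), .polyToClip(b), op = "union")
  if (length(u) == 0L) stop("invalid geometry: empty union", call. = FALSE)
  areas <- vapply(u, function(cc) abs(shoelaceArea(cbind(cc$x, cc$y))), numeric(1))
  cc <- u[[which.max(areas)]]
  cbind(cc$x, cc$y)
}

# Exact second-order central moments of the filled polygon (Green's theorem).
# Returns mu20, mu02, mu11 (not normalized by area), area and centroid.
polygonSecondMoments <- function(poly) {
  poly <- checkPolygon(poly)
  if (shoelaceArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(area = a, cx = cx, cy = cy,
       mu20 = ixx - a * cx^2, mu02 = iyy - a * cy^2, mu11 = ixy - a * cx * cy)
}

#' Equivalent-ellipse fit of a polygon
#'
#' Fits the ellipse with the same second-order central moments as the filled
#' polygon region (computed exactly via Green's theorem). Eccentricity is
#' \eqn{\sqrt{1 - (b/a)^2}} for semi-axes \eqn{a \ge b}; orientation is the
#' angle of the major axis to the image x-axis in degrees, wrapped to
#' `[0, 180)`. Isotropic regions (a circle) report eccentricity 0 and
#' orientation 0 by convention.
#'
#' @inheritParams polygonArea
#' @return named list `eccentricity`, `orientation` (degrees), `major`,
#'   `minor` (semi-axis lengths, pixels).
#' @export
ellipseFit <- function(poly) {
  m <- polygonSecondMoments(poly)
  if (m$area <= .polyTol) stop("invalid geometry: zero-area region", call. = FALSE)
  u20 <- m$mu20 / m$area; u02 <- m$mu02 / m$area; u11 <- m$mu11 / m$area
  tr <- u20 + u02
  disc <- sqrt(max((u20 - u02)^2 + 4 * u11^2, 0))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  l2 <- max(l2, 0)
  major <- 2 * sqrt(l1); minor <- 2 * sqrt(l2)
  if (minor <= .polyTol)
    stop("invalid geometry: degenerate (zero-thickness) region", call. = FALSE)
  iso <- disc <= 1e-9 * max(tr, .polyTol)
  theta <- if (iso) 0 else atan2(2 * u11, u20 - u02) / 2
  deg <- (theta * 180 / pi) %% 180
  ecc <- sqrt(max(1 - (minor / major)^2, 0))
  if (iso) { ecc <- 0; deg <- 0 }
  list(eccentricity = ecc, orientation = deg, major = major, minor = minor)
}

#' Shape ratio descriptors
#'
#' Solidity (area / convex-hull area), aspect ratio (major / minor semi-axis
#' of the equivalent ellipse), fill factor (area / axis-aligned bounding-box
#' area) and boundary smoothness (convex-hull perimeter / polygon perimeter;
#' 1 for convex outlines, smaller for protrusive ones).
#'
#' @inheritParams polygonArea
#' @return named list `solidity`, `aspect_ratio`, `fill_factor`,
#'   `boundary_smoothness`.
#' @export
shapeRatios <- function(poly) {
  poly <- checkPolygon(poly)
  a <- abs(shoelaceArea(poly))
  hullIdx <- grDevices::chull(poly[, 1L], poly[, 2L])
  hull <- poly[hullIdx, , drop = FALSE]
  hullA <- abs(shoelaceArea(hull))
  hullP <- polygonPerimeter(hull)
  ef <- ellipseFit(poly)
  bbox <- (max(poly[, 1L]) - min(poly[, 1L])) * (max(poly[, 2L]) - min(poly[, 2L]))
  list(solidity = min(a / hullA, 1),
       aspect_ratio = ef$major / ef$minor,
       fill_factor = min(a / bbox, 1),
       boundary_smoothness = min(hullP / polygonPerimeter(poly), 1))
}

#' Rasterize a polygon to pixel coordinates
#'
#' Pixel-center-in-polygon rule (even-odd): a pixel at integer coordinates
#' (x, y) belongs to the region when its center lies inside the polygon.
#'
#' @inheritParams polygonArea
#' @return two-column integer matrix of inside-pixel (x, y) coordinates.
#' @export
rasterizePolygon <- function(poly) {
  poly <- checkPolygon(poly)
  xs <- seq.int(floor(min(poly[, 1L])), ceiling(max(poly[, 1L])))
  ys <- seq.int(floor(min(poly[, 2L])), ceiling(max(poly[, 2L])))
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- logical(length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  cbind(x = px[inside], y = py[inside])
}

# Raster central moments up to third order for unit-weight pixels.
rasterCentralMoments <- function(px) {
  n <- nrow(px)
  cx <- mean(px[, 1L]); cy <- mean(px[, 2L])
  dx <- px[, 1L] - cx; dy <- px[, 2L] - cy
  list(m00 = n,
       mu20 = sum(dx^2), mu02 = sum(dy^2), mu11 = sum(dx * dy),
       mu30 = sum(dx^3), mu03 = sum(dy^3),
       mu21 = sum(dx^2 * dy), mu12 = sum(dx * dy^2))
}

# Scale-normalized central moments eta_pq = mu_pq / m00^(1 + (p+q)/2).
normalizedMoments <- function(mom) {
  s2 <- mom$m00^2; s25 <- mom$m00^2.5
  list(eta11 = mom$mu11 / s2, eta20 = mom$mu20 / s2, eta02 = mom$mu02 / s2,
       eta21 = mom$mu21 / s25, eta12 = mom$mu12 / s25,
       eta30 = mom$mu30 / s25, eta03 = mom$mu03 / s25)
}

# The seven Hu invariant moments from normalized central moments.
huMoments <- function(eta) {
  n20 <- eta$eta20; n02 <- eta$eta02; n11 <- eta$eta11
  n30 <- eta$eta30; n03 <- eta$eta03; n21 <- eta$eta21; n12 <- eta$eta12
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

# Population moment intensity statistics; skewness and excess kurtosis are 0
# for constant patches by convention.
intensityStats <- function(v) {
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  sk <- if (m2 > 0) mean(d^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean(d^4) / m2^2 - 3 else 0
  c(mean = m, sd = sqrt(m2), min = min(v), max = max(v),
    median = median(v), skewness = sk, kurtosis = ku)
}

#' 24-dimension appearance descriptor of a segmented cell
#'
#' Concatenates 7 intensity statistics over the pixels inside the rasterized
#' polygon (mean, sd, min, max, median, skewness, excess kurtosis), the 7 Hu
#' invariant moments, 7 scale-normalized central moments (eta11, eta20,
#' eta02, eta21, eta12, eta30, eta03) and the three shape ratios solidity,
#' aspect ratio and fill factor, then L2-normalizes the 24-vector. Shape
#' moments are computed on the rasterized mask (pixel-center rule) so that
#' intensity and shape statistics share the same pixel support. Without an
#' image the intensity slots are zero before normalization. All quantities
#' are in pixel space, so the descriptor is independent of the micrometre
#' calibration and invariant to integer translation.
#'
#' @inheritParams polygonArea
#' @param image optional grayscale frame as a numeric matrix indexed
#'   `image[y + 1, x + 1]` (row = y, 0-based pixel coordinates); must cover
#'   the polygon's bounding box.
#' @return numeric vector of length 24 with unit Euclidean norm.
#' @export
appearanceVector <- function(poly, image = NULL) {
  poly <- checkPolygon(poly)
  px <- rasterizePolygon(poly)
  if (nrow(px) == 0L)
    stop("polygon rasterizes to zero pixels", call. = FALSE)
  if (!is.null(image)) {
    if (!is.matrix(image) || !is.numeric(image))
      stop("'image' must be a numeric matrix", call. = FALSE)
    ii <- cbind(px[, 2L] + 1L, px[, 1L] + 1L)
    if (any(ii < 1L) || any(ii[, 1L] > nrow(image)) || any(ii[, 2L] > ncol(image)))
      stop("image does not cover the polygon's bounding box", call. = FALSE)
    istats <- intensityStats(image[ii])
  } else {
    istats <- rep(0, 7)
  }
  mom <- rasterCentralMoments(px)
  eta <- normalizedMoments(mom)
  hu <- huMoments(eta)
  sr <- shapeRatios(poly)
  v <- c(istats, hu,
         eta$eta11, eta$eta20, eta$eta02, eta$eta21, eta$eta12,
         eta$eta30, eta$eta03,
         sr$solidity, sr$aspect_ratio, sr$fill_factor)
  names(v) <- NULL
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("all-zero appearance vector", call. = FALSE)
  v / nv
}
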