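#' Detection ingest: YOLO polygon text, classical segmentation, tile stitching
#'
#' A Detection is a plain list with elements `poly` (vertex matrix, pixels),
#' `class` (integer id), `confidence` (in `[0,1]` or `NA`) and `source`
#' (tile/file identifier). A FrameDetections is a list with elements `frame`
#' (0-based index) and `detections` (list of Detection).
#'
#' @name detection-ingest
NULL

detection <- function(poly, class = 0L, confidence = NA_real_, source = "") {
  list(poly = poly, class = as.integer(class),
       confidence = confidence, source = source)
}

#' Bundle detections for one frame
#'
#' @param frame 0-based frame index.
#' @param detections list of detections (see \link{detection-ingest}).
#' @return FrameDetections list.
#' @export
frameDetections <- function(frame, detections = list()) {
  list(frame = as.integer(frame), detections = detections)
}

#' Read YOLO-format segmentation polygons
#'
#' Each line holds a class id followed by an even number (>= 6) of
#' normalized coordinates `x1 y1 x2 y2 ...` in `[0, 1]`; coordinates are
#' scaled to pixels by the image size. An empty file yields an empty list.
#'
#' @param path text file path.
#' @param imageSize integer `(W, H)` in pixels.
#' @param source source label stored on each detection (default the file
#'   basename).
#' @return list of detections.
#' @examples
#' f <- system.file("extdata", "example_yolo.txt", package = "trackmorph")
#' dets <- readYoloPolygons(f, imageSize = c(200, 100))
#' length(dets)
#' dets[[1]]$poly
#' @export
readYoloPolygons <- function(path, imageSize, source = basename(path)) {
  stopifnot(length(imageSize) == 2L, all(imageSize > 0))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d of %s: non-numeric token", i, path),
           call. = FALSE)
    coords <- vals[-1L]
    if (length(coords) < 6L || length(coords) %% 2L != 0L)
      stop(sprintf("parse error at line %d of %s: odd or insufficient coordinate count (%d)",
                   i, path, length(coords)), call. = FALSE)
    if (any(coords < 0 | coords > 1))
      stop(sprintf("parse error at line %d of %s: coordinate outside [0, 1]",
                   i, path), call. = FALSE)
    xs <- coords[seq(1L, length(coords), by = 2L)] * imageSize[1L]
    ys <- coords[seq(2L, length(coords), by = 2L)] * imageSize[2L]
    out[[i]] <- detection(cbind(xs, ys), class = vals[1L], source = source)
  }
  out
}

#' Write detections as YOLO-format segmentation text
#'
#' Inverse of [readYoloPolygons()]; coordinates are normalized by the image
#' size and printed with enough digits for a 1e-6 relative round-trip.
#'
#' @param detections list of detections.
#' @param path output file.
#' @param imageSize integer `(W, H)`.
#' @export
writeYoloPolygons <- function(detections, path, imageSize) {
  stopifnot(length(imageSize) == 2L, all(imageSize > 0))
  lines <- vapply(detections, function(d) {
    xs <- d$poly[, 1L] / imageSize[1L]
    ys <- d$poly[, 2L] / imageSize[2L]
    paste(c(d$class, sprintf("%.9f", as.vector(rbind(xs, ys)))),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
}

#' Classical segmentation of a grayscale frame
#'
#' Fallback mask pipeline when no detector output is available: optional
#' flatfield correction (division by a heavily Gaussian-smoothed background
#' estimate), adaptive thresholding against a local mean, morphological
#' closing, connected components, and removal of small artifacts with pixel
#' area strictly below `minAreaPx2` (a component of exactly `minAreaPx2`
#' pixels is kept). Surviving components are returned as boundary polygons.
#'
#' @param image numeric matrix indexed `image[y + 1, x + 1]` (2-D grayscale).
#' @param minAreaPx2 area filter threshold in square pixels (default 100).
#' @param flatfield apply flatfield correction first (default FALSE).
#' @param window odd local-window width of the adaptive threshold (default 31).
#' @param offset intensity offset above the local mean (default 0.02).
#' @param closingSize diameter of the disc brush for morphological closing
#'   (default 3).
#' @return list of polygon matrices (0-based pixel coordinates), with
#'   attribute `areas_px2` holding the surviving components' pixel areas.
#' @export
segmentClassical <- function(image, minAreaPx2 = 100, flatfield = FALSE,
                             window = 31, offset = 0.02, closingSize = 3) {
  if (!is.matrix(image) || !is.numeric(image) || length(dim(image)) != 2L)
    stop("'image' must be a 2-D numeric matrix", call. = FALSE)
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("segmentClassical requires the EBImage package", call. = FALSE)
  img <- EBImage::Image(t(image))          # EBImage dims are (x, y)
  if (flatfield) {
    sigma <- max(dim(image)) / 8
    bg <- EBImage::gblur(img, sigma = sigma)
    img <- img / pmax(bg, 1e-6)
  }
  half <- max(1L, (as.integer(window) - 1L) %/% 2L)
  mask <- EBImage::thresh(img, w = half, h = half, offset = offset)
  if (closingSize >= 2)
    mask <- EBImage::closing(mask, EBImage::makeBrush(closingSize, shape = "disc"))
  lab <- EBImage::bwlabel(mask)
  labm <- EBImage::imageData(lab)
  if (max(labm) == 0) return(list())
  areas <- tabulate(labm[labm > 0], nbins = max(labm))
  keep <- which(areas >= minAreaPx2)       # strict '<' removal
  if (length(keep) == 0L) return(list())
  ctr <- EBImage::ocontour(lab)
  polys <- list()
  pxAreas <- numeric(0)
  for (k in keep) {
    cc <- ctr[[k]]
    if (is.null(cc) || nrow(cc) < 3L) next
    # ocontour returns 0-based (x, y) boundary pixels in EBImage's (x, y)
    # layout, which matches the package's pixel convention directly.
    polys[[length(polys) + 1L]] <- unname(cbind(cc[, 1L], cc[, 2L]))
    pxAreas <- c(pxAreas, areas[k])
  }
  attr(polys, "areas_px2") <- pxAreas
  polys
}

#' Stitch tiled detections into one per-frame detection set
#'
#' Translates tile-local detections into global pixel coordinates, greedily
#' suppresses duplicate observations of the same object (IoU >=
#' `dupIou`, keeping the higher-confidence one, ties broken by larger area
#' then lower tile index) and union-merges cross-tile fragment pairs with
#' `mergeIou <= IoU < dupIou`.
#'
#' @param imageSize integer `(W, H)` of the full frame.
#' @param tiles list of `list(offset = c(x, y), detections = list(...))`
#'   with tile-local pixel coordinates.
#' @param dupIou duplicate-suppression threshold (default 0.8).
#' @param mergeIou merge threshold for cross-tile fragments (default 0.3).
#' @param frame 0-based frame index recorded on the output (default 0).
#' @return FrameDetections whose detection list contains no pair with IoU
#'   >= `dupIou`.
#' @export
tileStitch <- function(imageSize, tiles, dupIou = 0.8, mergeIou = 0.3,
                       frame = 0L) {
  stopifnot(length(imageSize) == 2L, all(imageSize > 0))
  pool <- list()
  for (ti in seq_along(tiles)) {
    off <- tiles[[ti]]$offset
    if (length(off) != 2L || any(off < 0) || any(off > imageSize))
      stop(sprintf("tile %d offset outside the image", ti), call. = FALSE)
    for (d in tiles[[ti]]$detections) {
      d$poly <- sweep(d$poly, 2L, off, "+")
      d$tile <- ti
      pool[[length(pool) + 1L]] <- d
    }
  }
  if (length(pool) == 0L) return(frameDetections(frame))
  conf <- vapply(pool, function(d) ifelse(is.na(d$confidence), 1, d$confidence),
                 numeric(1))
  area <- vapply(pool, function(d) polygonArea(d$poly), numeric(1))
  tile <- vapply(pool, function(d) d$tile, numeric(1))
  ord <- order(-conf, -area, tile)
  pool <- pool[ord]
  # greedy duplicate suppression
  kept <- list()
  for (d in pool) {
    dup <- FALSE
    for (k in kept) if (polygonIoU(d$poly, k$poly) >= dupIou) { dup <- TRUE; break }
    if (!dup) kept[[length(kept) + 1L]] <- d
  }
  # union-merge cross-tile fragment pairs; repeat until stable
  repeat {
    merged <- FALSE
    n <- length(kept)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- kept[[i]]; b <- kept[[j]]
        if (a$tile == b$tile) next
        iou <- polygonIoU(a$poly, b$poly)
        if (iou >= mergeIou && iou < dupIou) {
          a$poly <- polygonUnion(a$poly, b$poly)
          a$confidence <- max(a$confidence, b$confidence, na.rm = TRUE)
          kept[[i]] <- a
          kept[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  kept <- lapply(kept, function(d) { d$tile <- NULL; d })
  frameDetections(frame, kept)
}

#' Serialize frame detections to JSON
#'
#' @param frames list of FrameDetections.
#' @param path output JSON file.
#' @export
writeDetectionsJSON <- function(frames, path) {
  payload <- lapply(frames, function(fd) {
    list(frame = fd$frame,
         detections = lapply(fd$detections, function(d) {
           list(class = d$class, confidence = d$confidence,
                source = d$source,
                vertices = unname(apply(d$poly, 1L, function(r) c(r[1L], r[2L]),
                                        simplify = FALSE)))
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
}

#' Read frame detections from JSON written by [writeDetectionsJSON()]
#'
#' @param path JSON file.
#' @return list of FrameDetections.
#' @export
readDetectionsJSON <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(fd) {
    dets <- lapply(fd$detections, function(d) {
      poly <- do.call(rbind, lapply(d$vertices, function(v)
        c(as.numeric(v[[1L]]), as.numeric(v[[2L]]))))
      detection(poly, class = d$class %||% 0L,
                confidence = if (is.null(d$confidence)) NA_real_
                             else as.numeric(d$confidence),
                source = d$source %||% "")
    })
    frameDetections(fd$frame, dets)
  })
}
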