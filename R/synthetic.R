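#' Synthetic scenes, trajectories and metric panels
#'
#' Ground-truth generators used to validate the tracker, the motility suite
#' and the statistics engine: single trajectories under specified motion
#' laws, multi-cell rendered polygon scenes with divisions and detection
#' dropouts, and grouped AR(1) metric panels. All generators are
#' deterministic given a seed (Mersenne-Twister, pinned by the package's
#' seeding wrapper).
#'
#' @name synthetic-scenes
NULL

#' Specify a motion model
#'
#' Supported kinds (units px/frame):
#' \describe{
#' \item{brownian}{isotropic Gaussian steps with per-axis deviation
#'   `sigma`.}
#' \item{persistent}{constant-`speed` steps whose heading is perturbed each
#'   frame by wrapped Gaussian noise scaled by `1 - phi`; `phi = 1` is a
#'   straight run, `phi = 0` a fully random heading walk.}
#' \item{directed}{deterministic steps along the vector `v`.}
#' \item{arrested}{two-state Markov switch between Brownian movement
#'   (deviation `sigma`) and zero steps, with per-frame stop probability
#'   `pStop` and resume probability `pGo`, emulating episodic bursts of
#'   movement on an arrested baseline.}
#' }
#'
#' @param kind one of `"brownian"`, `"persistent"`, `"directed"`,
#'   `"arrested"`.
#' @param sigma per-axis step standard deviation (brownian/arrested).
#' @param speed step length (persistent).
#' @param phi heading persistence in `[0, 1]` (persistent).
#' @param v step vector (directed).
#' @param pStop,pGo Markov transition probabilities (arrested).
#' @param turnSd base heading-noise standard deviation in radians
#'   (persistent; default pi).
#' @return a `MotionModel` list.
#' @export
motionModel <- function(kind = c("brownian", "persistent", "directed", "arrested"),
                        sigma = 1, speed = 2, phi = 0.8, v = c(2, 0),
                        pStop = 0.1, pGo = 0.1, turnSd = pi) {
  kind <- match.arg(kind)
  if (sigma < 0 || speed < 0) stop("sigma and speed must be >= 0", call. = FALSE)
  if (phi < 0 || phi > 1) stop("phi must be in [0, 1]", call. = FALSE)
  if (any(c(pStop, pGo) < 0) || any(c(pStop, pGo) > 1))
    stop("transition probabilities must be in [0, 1]", call. = FALSE)
  if (length(v) != 2L) stop("v must be a 2-vector", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, speed = speed, phi = phi,
                 v = v, pStop = pStop, pGo = pGo, turnSd = turnSd),
            class = "MotionModel")
}

# One trajectory as a T x 2 position matrix; assumes the RNG is already
# seeded by the caller.
simPositions <- function(model, T, start = c(0, 0)) {
  pos <- matrix(0, T, 2L)
  pos[1L, ] <- start
  switch(model$kind,
    brownian = {
      steps <- matrix(rnorm(2L * (T - 1L), 0, model$sigma), T - 1L, 2L)
      pos[-1L, ] <- sweep(apply(steps, 2L, cumsum), 2L, start, "+")
    },
    directed = {
      for (t in 2:T) pos[t, ] <- pos[t - 1L, ] + model$v
    },
    persistent = {
      theta <- runif(1L, 0, 2 * pi)
      for (t in 2:T) {
        theta <- (theta + (1 - model$phi) * rnorm(1L, 0, model$turnSd) + pi) %%
          (2 * pi) - pi
        pos[t, ] <- pos[t - 1L, ] + model$speed * c(cos(theta), sin(theta))
      }
    },
    arrested = {
      moving <- TRUE
      for (t in 2:T) {
        moving <- if (moving) runif(1L) >= model$pStop else runif(1L) < model$pGo
        step <- if (moving) rnorm(2L, 0, model$sigma) else c(0, 0)
        pos[t, ] <- pos[t - 1L, ] + step
      }
    })
  pos
}

#' Generate a trajectory under a motion model
#'
#' @param model a [motionModel()].
#' @param T number of frames (>= 2).
#' @param seed RNG seed.
#' @param start starting position.
#' @return a [trajectory()] in model units.
#' @export
genTrajectory <- function(model, T, seed = NULL, start = c(0, 0)) {
  if (!inherits(model, "MotionModel")) stop("invalid motion model", call. = FALSE)
  if (T < 2L) stop("T must be >= 2", call. = FALSE)
  pos <- withSeed(seed, simPositions(model, as.integer(T), start))
  trajectory(x = pos[, 1L], y = pos[, 2L])
}

# A 16-vertex noisy ellipse outline centered at the origin; returns the
# vertex offsets and the unit major-axis direction.
cellShape <- function(radius, ratio, orientation, noiseSd = 0.05) {
  a <- radius * sqrt(ratio)
  b <- radius / sqrt(ratio)
  ang <- 2 * pi * (0:15) / 16
  rad <- 1 + rnorm(16L, 0, noiseSd)
  ex <- a * cos(ang) * rad
  ey <- b * sin(ang) * rad
  rot <- matrix(c(cos(orientation), sin(orientation),
                  -sin(orientation), cos(orientation)), 2L, 2L)
  offsets <- cbind(ex, ey) %*% t(rot)
  list(offsets = offsets, major = c(cos(orientation), sin(orientation)),
       a = a)
}

reflectInto <- function(p, lo, hi) {
  L <- hi - lo
  z <- (p - lo) %% (2 * L)
  lo + ifelse(z > L, 2 * L - z, z)
}

#' Generate a multi-cell scene with ground truth
#'
#' Cells are seeded on a jittered grid without initial overlap and rendered
#' as 16-vertex noisy ellipses (axis ratio 1.2-3) following trajectories
#' drawn from the motion model. With `divisionProb` a living cell splits
#' into two daughters at 60 percent of the parent area, offset by +/- 0.6
#' major semi-axes along the parent's major axis (the parent track ends,
#' two new true ids start, and a lineage event is recorded). With
#' `dropoutProb` a cell's detection is withheld for a run of 1-3 frames;
#' withheld observations are enumerated in the truth and absent from the
#' detections.
#'
#' @param nCells number of cells.
#' @param model a [motionModel()].
#' @param T number of frames.
#' @param divisionProb per-cell per-frame division probability (default 0).
#' @param dropoutProb per-cell per-frame probability of starting a 1-3
#'   frame detection dropout (default 0).
#' @param imageSize `(W, H)` pixels (default `c(512, 512)`).
#' @param seed RNG seed (default 1).
#' @param cellRadiusPx equivalent cell radius in pixels (default 12).
#' @param forcedDivisions optional data.frame `id`, `frame` forcing
#'   divisions of specific cells at specific frames.
#' @return list with `detections` (list of [frameDetections()]) and `truth`
#'   (a [SceneTruth]).
#' @export
genScene <- function(nCells, model, T, divisionProb = 0, dropoutProb = 0,
                     imageSize = c(512, 512), seed = 1, cellRadiusPx = 12,
                     forcedDivisions = NULL) {
  stopifnot(nCells >= 1L, T >= 2L)
  margin <- 4 * cellRadiusPx
  cols <- ceiling(sqrt(nCells * imageSize[1L] / imageSize[2L]))
  rowsN <- ceiling(nCells / cols)
  spacing <- min((imageSize[1L] - 2 * margin) / max(cols - 1L, 1L),
                 (imageSize[2L] - 2 * margin) / max(rowsN - 1L, 1L))
  if (spacing < 4 * cellRadiusPx && nCells > 1L)
    stop("image too small for the requested number of cells", call. = FALSE)
  lo <- c(margin, margin)
  hi <- c(imageSize[1L], imageSize[2L]) - margin
  # keep every trajectory inside the renderable area by reflecting at the
  # margins as soon as it is generated, so that division geometry and
  # rendering agree on positions
  simBounded <- function(T, start) {
    pos <- simPositions(model, T, start)
    pos[, 1L] <- reflectInto(pos[, 1L], lo[1L], hi[1L])
    pos[, 2L] <- reflectInto(pos[, 2L], lo[2L], hi[2L])
    pos
  }
  withSeed(seed, {
    cells <- list()   # id, shape, pos (T x 2 from birth), birth, death, parent
    for (i in seq_len(nCells)) {
      gx <- (i - 1L) %% cols
      gy <- (i - 1L) %/% cols
      start <- c(margin + gx * spacing, margin + gy * spacing) +
        runif(2L, -0.05, 0.05) * spacing
      shape <- cellShape(cellRadiusPx, runif(1L, 1.2, 3), runif(1L, 0, pi))
      pos <- simBounded(T, start)
      cells[[i]] <- list(id = i, shape = shape, pos = pos, birth = 0L,
                         death = T - 1L, parent = NA_integer_, scale = 1)
    }
    nextId <- nCells + 1L
    lineage <- list()
    # divisions
    ci <- 1L
    while (ci <= length(cells)) {
      cell <- cells[[ci]]
      f <- cell$birth + 1L
      while (f <= cell$death) {
        forced <- !is.null(forcedDivisions) &&
          any(forcedDivisions$id == cell$id & forcedDivisions$frame == f)
        if (forced || (divisionProb > 0 && runif(1L) < divisionProb)) {
          relF <- f - cell$birth + 1L
          center <- cell$pos[relF, ]
          off <- 0.6 * cell$shape$a * cell$scale * cell$shape$major
          childScale <- cell$scale * sqrt(0.6)
          for (sgn in c(-1, 1)) {
            cstart <- c(reflectInto(center[1L] + sgn * off[1L], lo[1L], hi[1L]),
                        reflectInto(center[2L] + sgn * off[2L], lo[2L], hi[2L]))
            cpos <- simBounded(T - f, cstart)
            cells[[length(cells) + 1L]] <- list(
              id = nextId, shape = cell$shape, pos = cpos, birth = f,
              death = T - 1L, parent = cell$id, scale = childScale)
            nextId <- nextId + 1L
          }
          lineage[[length(lineage) + 1L]] <- data.frame(
            frame = f, parent_id = cell$id, child1 = nextId - 2L,
            child2 = nextId - 1L)
          cell$death <- f - 1L
          cells[[ci]] <- cell
          break
        }
        f <- f + 1L
      }
      ci <- ci + 1L
    }
    # dropouts
    drops <- list()   # per cell: logical vector over its frames
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      span <- cell$death - cell$birth + 1L
      dropped <- rep(FALSE, span)
      if (dropoutProb > 0 && span > 2L) {
        t <- 2L
        while (t <= span - 1L) {
          if (runif(1L) < dropoutProb) {
            len <- sample.int(3L, 1L)
            idx <- t:min(t + len - 1L, span - 1L)
            dropped[idx] <- TRUE
            t <- t + len
          }
          t <- t + 1L
        }
      }
      drops[[ci]] <- dropped
    }
    # assemble frames
    detFrames <- vector("list", T)
    polysByFrame <- vector("list", T)
    objRows <- list()
    for (f in seq_len(T) - 1L) {
      dets <- list()
      polys <- list()
      for (ci in seq_along(cells)) {
        cell <- cells[[ci]]
        if (f < cell$birth || f > cell$death) next
        relF <- f - cell$birth + 1L
        center <- cell$pos[relF, ]
        poly <- sweep(cell$shape$offsets * cell$scale, 2L, center, "+")
        dropped <- drops[[ci]][relF]
        objRows[[length(objRows) + 1L]] <- data.frame(
          frame = f, id = cell$id, parent_id = cell$parent,
          centroid_x_px = center[1L], centroid_y_px = center[2L],
          area_px2 = polygonArea(poly), dropped = dropped)
        polys[[as.character(cell$id)]] <- poly
        if (!dropped)
          dets[[length(dets) + 1L]] <- detection(poly, source = "synthetic")
      }
      detFrames[[f + 1L]] <- frameDetections(f, dets)
      polysByFrame[[f + 1L]] <- polys
    }
    truth <- new("SceneTruth",
                 objects = do.call(rbind, objRows),
                 polygons = polysByFrame,
                 lineage = if (length(lineage)) do.call(rbind, lineage) else
                   data.frame(frame = integer(0), parent_id = integer(0),
                              child1 = integer(0), child2 = integer(0)),
                 nFrames = as.integer(T))
    list(detections = detFrames, truth = truth)
  })
}

#' Generate a grouped AR(1) series panel
#'
#' \eqn{X_g(t) = \mu_g(t) + \phi (X_g(t-1) - \mu_g(t-1)) + \epsilon_t},
#' \eqn{\epsilon \sim N(0, noiseSd^2)}, with a stationary start. The group
#' mean \eqn{\mu_g} is `groupOffsets[g]`, optionally stepping by
#' `changeOffsets[g]` from the `changepoint` frame onwards.
#'
#' @param k number of series (>= 2).
#' @param T number of frames (>= 30).
#' @param groupOffsets baseline mean per series (default all 0).
#' @param ar1Phi AR(1) coefficient, `|phi| < 1` (default 0).
#' @param noiseSd innovation standard deviation (default 1).
#' @param changepoint optional 0-based frame at which means step.
#' @param changeOffsets per-series step sizes applied from the changepoint.
#' @param seed RNG seed (default 1).
#' @return a [seriesPanel()].
#' @export
genGroupedSeries <- function(k, T, groupOffsets = rep(0, k), ar1Phi = 0,
                             noiseSd = 1, changepoint = NULL,
                             changeOffsets = rep(0, k), seed = 1) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (T < 30L) stop("T must be >= 30", call. = FALSE)
  if (abs(ar1Phi) >= 1) stop("|phi| must be < 1", call. = FALSE)
  stopifnot(length(groupOffsets) == k, length(changeOffsets) == k)
  vals <- withSeed(seed, {
    m <- matrix(0, T, k)
    for (g in seq_len(k)) {
      mu <- rep(groupOffsets[g], T)
      if (!is.null(changepoint))
        mu[seq_len(T) - 1L >= changepoint] <- groupOffsets[g] + changeOffsets[g]
      x <- numeric(T)
      x[1L] <- mu[1L] + rnorm(1L, 0, noiseSd / sqrt(1 - ar1Phi^2))
      for (t in 2:T)
        x[t] <- mu[t] + ar1Phi * (x[t - 1L] - mu[t - 1L]) + rnorm(1L, 0, noiseSd)
      m[, g] <- x
    }
    m
  })
  seriesPanel(vals, metric = "synthetic")
}
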