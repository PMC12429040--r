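#' Trajectory linking and motility metrics
#'
#' A trajectory is a data.frame with columns `track_id`, `frame` (strictly
#' increasing, 0-based), `x`, `y` (micrometres), optionally `area` (square
#' micrometres) and `interpolated` (logical).
#'
#' @name motility
NULL

#' Construct a trajectory
#'
#' @param x,y calibrated positions in micrometres.
#' @param frame 0-based frame indices (default consecutive).
#' @param area optional per-frame areas (square micrometres).
#' @param track_id track identifier.
#' @param interpolated logical flags for gap-bridged positions.
#' @return trajectory data.frame.
#' @export
trajectory <- function(x, y, frame = seq_along(x) - 1L, area = NA_real_,
                       track_id = 1L, interpolated = FALSE) {
  stopifnot(length(x) == length(y))
  if (any(diff(frame) <= 0)) stop("frames must be strictly increasing", call. = FALSE)
  data.frame(track_id = track_id, frame = as.integer(frame), x = x, y = y,
             area = area, interpolated = interpolated)
}

#' Baseline nearest-neighbour trajectory linking
#'
#' Links per-frame centroids by greedy mutual nearest neighbours subject to
#' a maximum displacement per time step (default the 10 um used for
#' calibrated microscopy at this frame rate). A track silent for up to
#' `maxGap` frames may re-link when the reappearance lies within the
#' per-step budget scaled by the elapsed steps; the missing positions are
#' filled by linear interpolation and flagged. Otherwise a new track starts.
#'
#' @param centroids list (by frame) of two-column matrices of calibrated
#'   centroid positions in micrometres (possibly with an `area` attribute
#'   column as third column).
#' @param maxStepUm maximum displacement per time step, micrometres
#'   (default 10).
#' @param maxGap maximum number of missing frames bridged (default 2).
#' @return list of trajectory data.frames.
#' @export
linkTrajectories <- function(centroids, maxStepUm = 10, maxGap = 2) {
  if (maxStepUm < 0) stop("maxStepUm must be non-negative", call. = FALSE)
  open <- list()    # each: id, frame (last seen), x, y, rows (list)
  done <- list()
  nextId <- 1L
  for (f in seq_along(centroids)) {
    frame <- f - 1L
    pts <- centroids[[f]]
    if (is.null(pts)) pts <- matrix(numeric(0), 0L, 2L)
    pts <- as.matrix(pts)
    np <- nrow(pts)
    usedPt <- rep(FALSE, np)
    if (length(open) && np > 0L) {
      lastPos <- do.call(rbind, lapply(open, function(tr) c(tr$x, tr$y)))
      lastFrame <- vapply(open, `[[`, integer(1), "frame")
      gap <- frame - lastFrame
      d <- outer(seq_along(open), seq_len(np), Vectorize(function(i, j)
        sqrt(sum((lastPos[i, ] - pts[j, 1:2])^2))))
      budget <- gap * maxStepUm
      feas <- d <= matrix(budget, length(open), np)
      usedTr <- rep(FALSE, length(open))
      while (any(feas & !outer(usedTr, usedPt, `|`))) {
        dd <- d
        dd[!feas | outer(usedTr, usedPt, `|`)] <- Inf
        ij <- which(dd == min(dd), arr.ind = TRUE)[1L, ]
        i <- ij[1L]; j <- ij[2L]
        tr <- open[[i]]
        g <- frame - tr$frame
        if (g > 1L) {
          # bridge the gap by linear interpolation
          for (m in seq_len(g - 1L)) {
            t <- m / g
            tr$rows[[length(tr$rows) + 1L]] <- c(tr$frame + m,
                                                 tr$x + t * (pts[j, 1L] - tr$x),
                                                 tr$y + t * (pts[j, 2L] - tr$y),
                                                 NA_real_, 1)
          }
        }
        ar <- if (ncol(pts) >= 3L) pts[j, 3L] else NA_real_
        tr$rows[[length(tr$rows) + 1L]] <- c(frame, pts[j, 1L], pts[j, 2L], ar, 0)
        tr$frame <- frame; tr$x <- pts[j, 1L]; tr$y <- pts[j, 2L]
        open[[i]] <- tr
        usedTr[i] <- TRUE
        usedPt[j] <- TRUE
      }
    }
    # retire tracks whose gap exceeded the bridgeable window
    if (length(open)) {
      stale <- vapply(open, function(tr) frame - tr$frame > maxGap, logical(1))
      done <- c(done, open[stale])
      open <- open[!stale]
    }
    # new tracks
    for (j in which(!usedPt)) {
      ar <- if (ncol(pts) >= 3L) pts[j, 3L] else NA_real_
      open[[length(open) + 1L]] <- list(id = nextId, frame = frame,
                                        x = pts[j, 1L], y = pts[j, 2L],
                                        rows = list(c(frame, pts[j, 1L],
                                                      pts[j, 2L], ar, 0)))
      nextId <- nextId + 1L
    }
  }
  done <- c(done, open)
  done <- done[order(vapply(done, `[[`, integer(1), "id"))]
  lapply(done, function(tr) {
    m <- do.call(rbind, tr$rows)
    trajectory(x = m[, 2L], y = m[, 3L], frame = m[, 1L], area = m[, 4L],
               track_id = tr$id, interpolated = m[, 5L] == 1)
  })
}

#' Per-step kinematics of a trajectory
#'
#' Frame-to-frame displacement (Euclidean distance between consecutive
#' centroids), instantaneous speed and instantaneous acceleration (change in
#' speed between consecutive steps). The canonical speed unit is um/frame;
#' the physical frame interval is carried as metadata for conversion to
#' um/s.
#'
#' @param traj a [trajectory()].
#' @param frameIntervalS frame interval in seconds (metadata; default 350).
#' @return list with `displacement` (length n-1), `speed` (um/frame, length
#'   n-1), `acceleration` (um/frame^2, length n-2) and `frame_interval_s`.
#' @export
kinematics <- function(traj, frameIntervalS = 350) {
  n <- nrow(traj)
  if (n < 2L) stop("kinematics needs at least 2 points", call. = FALSE)
  dx <- diff(traj$x); dy <- diff(traj$y)
  disp <- sqrt(dx^2 + dy^2)
  dfr <- diff(traj$frame)
  speed <- disp / dfr
  list(displacement = disp, speed = speed, acceleration = diff(speed),
       frame_interval_s = frameIntervalS)
}

# Turning angles (radians, in [0, pi]) between successive step vectors;
# zero-length steps have undefined direction and contribute no angle.
turningAngles <- function(traj) {
  dx <- diff(traj$x); dy <- diff(traj$y)
  len <- sqrt(dx^2 + dy^2)
  keep <- len > 0
  dx <- dx[keep]; dy <- dy[keep]; len <- len[keep]
  if (length(len) < 2L) return(numeric(0))
  n <- length(len)
  dots <- dx[-n] * dx[-1L] + dy[-n] * dy[-1L]
  cosang <- pmin(pmax(dots / (len[-n] * len[-1L]), -1), 1)
  acos(cosang)
}

#' Twelve-metric motility summary of a trajectory
#'
#' The dynamic descriptor suite of one calibrated trajectory:
#' \describe{
#' \item{msd}{mean squared displacement from the initial location,
#'   \eqn{(1/T)\sum_{k=1}^{T}\|r_k - r_0\|^2} (um^2).}
#' \item{directional_persistence}{mean cosine of consecutive turning
#'   angles.}
#' \item{meandering_index}{net start-to-end displacement over total path
#'   length.}
#' \item{mean_turning_angle_deg}{mean absolute angular deviation between
#'   successive velocity vectors, degrees.}
#' \item{radius_of_gyration}{RMS distance of positions from the trajectory
#'   center of mass (um).}
#' \item{arrest_coefficient}{fraction of steps with instantaneous speed
#'   strictly below `arrestThresholdUm` (default 0.2 um/frame).}
#' \item{shape_motion_coupling}{Pearson correlation of per-frame area and
#'   instantaneous speed.}
#' \item{relative_motion_change}{mean absolute speed change between
#'   consecutive steps over the mean speed.}
#' \item{velocity_cross_correlation}{Pearson correlation of the x and y
#'   components of the step vectors.}
#' \item{directionality_ratio}{computed by the same net-over-total formula
#'   as the meandering index and reported under both names for schema
#'   fidelity.}
#' \item{mean_speed}{um/frame.}
#' \item{mean_acceleration}{um/frame^2.}
#' }
#' Angle metrics on an all-stationary trajectory are undefined and reported
#' as `NA`, as is `relative_motion_change` at zero mean speed.
#'
#' @param traj a [trajectory()].
#' @param arrestThresholdUm arrest speed threshold, um/frame (default 0.2).
#' @param turnThresholdDeg sharp-turn threshold in degrees used for the
#'   `sharp_turn_fraction` attribute (default 90).
#' @return named list of the twelve metrics (plus attribute
#'   `sharp_turn_fraction`).
#' @export
motilityMetrics <- function(traj, arrestThresholdUm = 0.2,
                            turnThresholdDeg = 90) {
  n <- nrow(traj)
  if (n < 2L) stop("motility metrics need at least 2 points", call. = FALSE)
  kin <- kinematics(traj)
  r0 <- c(traj$x[1L], traj$y[1L])
  dsq <- (traj$x - r0[1L])^2 + (traj$y - r0[2L])^2
  msd <- mean(dsq[-1L])
  net <- sqrt(sum((c(traj$x[n], traj$y[n]) - r0)^2))
  pathLen <- sum(kin$displacement)
  meander <- if (pathLen > 0) net / pathLen else NA_real_
  ang <- turningAngles(traj)
  persistence <- if (length(ang)) mean(cos(ang)) else NA_real_
  meanTurn <- if (length(ang)) mean(ang) * 180 / pi else NA_real_
  sharpFrac <- if (length(ang)) mean(ang > turnThresholdDeg * pi / 180) else NA_real_
  cx <- mean(traj$x); cy <- mean(traj$y)
  rgyr <- sqrt(mean((traj$x - cx)^2 + (traj$y - cy)^2))
  arrest <- mean(kin$speed < arrestThresholdUm)
  areas <- traj$area[-1L]
  coupling <- if (length(kin$speed) >= 3L && !anyNA(areas) &&
                  sd(kin$speed) > 0 && sd(areas) > 0)
    cor(areas, kin$speed) else NA_real_
  meanSpeed <- mean(kin$speed)
  relChange <- if (meanSpeed > 0 && length(kin$speed) >= 2L)
    mean(abs(diff(kin$speed))) / meanSpeed else NA_real_
  dx <- diff(traj$x); dy <- diff(traj$y)
  vcc <- if (length(dx) >= 3L && sd(dx) > 0 && sd(dy) > 0)
    cor(dx, dy) else NA_real_
  out <- list(msd = msd,
              directional_persistence = persistence,
              meandering_index = meander,
              mean_turning_angle_deg = meanTurn,
              radius_of_gyration = rgyr,
              arrest_coefficient = arrest,
              shape_motion_coupling = coupling,
              relative_motion_change = relChange,
              velocity_cross_correlation = vcc,
              directionality_ratio = meander,
              mean_speed = meanSpeed,
              mean_acceleration = if (length(kin$acceleration))
                mean(kin$acceleration) else NA_real_)
  attr(out, "sharp_turn_fraction") <- sharpFrac
  out
}

#' Lag-resolved time-averaged mean squared displacement
#'
#' \eqn{MSD(\tau) = \langle \|r_{t+\tau} - r_t\|^2 \rangle_t} for lags
#' `1..maxLag`; used for random-walk diagnostics (for an isotropic walk with
#' per-axis step deviation sigma the slope is `2 sigma^2` per lag).
#'
#' @param traj a [trajectory()] with consecutive frames.
#' @param maxLag maximum lag (default a quarter of the track length).
#' @return data.frame `lag`, `msd`.
#' @export
msdLag <- function(traj, maxLag = max(1L, nrow(traj) %/% 4L)) {
  n <- nrow(traj)
  if (n < 2L) stop("msdLag needs at least 2 points", call. = FALSE)
  maxLag <- min(maxLag, n - 1L)
  out <- vapply(seq_len(maxLag), function(l) {
    dx <- traj$x[(1L + l):n] - traj$x[1L:(n - l)]
    dy <- traj$y[(1L + l):n] - traj$y[1L:(n - l)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  data.frame(lag = seq_len(maxLag), msd = out)
}

#' Static and dynamic aggregation of instantaneous values
#'
#' Dynamic aggregates average each cell's instantaneous displacement, speed
#' and acceleration over the lifespan of its trajectory (one row per track);
#' static aggregates average the instantaneous values across all cells
#' present at each frame (one row per frame), a cross-sectional snapshot of
#' the ensemble.
#'
#' @param trajs list of [trajectory()] data.frames.
#' @param mode `"dynamic"` or `"static"`.
#' @return data.frame (see Details).
#' @export
aggregateTracks <- function(trajs, mode = c("dynamic", "static")) {
  mode <- match.arg(mode)
  if (length(trajs) == 0L) stop("empty track list", call. = FALSE)
  if (mode == "dynamic") {
    rows <- lapply(trajs, function(tr) {
      kin <- kinematics(tr)
      data.frame(track_id = tr$track_id[1L], n_frames = nrow(tr),
                 mean_displacement = mean(kin$displacement),
                 mean_speed = mean(kin$speed),
                 mean_acceleration = if (length(kin$acceleration))
                   mean(kin$acceleration) else NA_real_)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  # static: instantaneous speed at the arrival frame of each step
  pieces <- lapply(trajs, function(tr) {
    if (nrow(tr) < 2L) return(NULL)
    kin <- kinematics(tr)
    acc <- c(kin$acceleration, NA_real_)
    data.frame(frame = tr$frame[-1L], displacement = kin$displacement,
               speed = kin$speed, acceleration = acc[seq_along(kin$speed)])
  })
  long <- do.call(rbind, pieces)
  if (is.null(long) || nrow(long) == 0L) stop("no kinematic steps to aggregate", call. = FALSE)
  frames <- sort(unique(long$frame))
  out <- do.call(rbind, lapply(frames, function(f) {
    sub <- long[long$frame == f, , drop = FALSE]
    data.frame(frame = f, n_cells = nrow(sub),
               mean_displacement = mean(sub$displacement),
               mean_speed = mean(sub$speed),
               mean_acceleration = if (all(is.na(sub$acceleration))) NA_real_
               else mean(sub$acceleration, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
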