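#' Multi-object cell tracking by cost-matrix assignment
#'
#' Frame-to-frame identity maintenance: a two-stage Hungarian assignment on
#' a cost matrix balancing appearance, shape overlap and spatial proximity,
#' with adaptive velocity gating, division (split) and merge recovery,
#' re-identification of occluded tracks and lineage bookkeeping.
#'
#' @name tracker
NULL

# Internal per-track state. `poly`/`centroid` are the last observed polygon
# and its area centroid; `vel` is the EWMA velocity estimate in px/frame.
newTrackState <- function(id, frame, det, gen = 0L, parent = NA_integer_,
                          vel = c(0, 0)) {
  list(id = id, status = "active", poly = det$poly, feat = det$feat,
       areaEwma = det$area, vel = vel, age = 1L, missed = 0L,
       gen = as.integer(gen), parent = as.integer(parent),
       lastFrame = as.integer(frame), centroid = det$centroid)
}

# Detection preprocessing: centroid, pixel area and appearance vector.
prepDetections <- function(fd, cfg, image = NULL) {
  dets <- list()
  for (d in fd$detections) {
    poly <- checkPolygon(d$poly)
    area <- polygonArea(poly)
    if (area < cfg@minAreaPx2) next
    d$poly <- poly
    d$area <- area
    d$centroid <- polygonCentroid(poly)
    d$feat <- appearanceVector(poly, image)
    dets[[length(dets) + 1L]] <- d
  }
  dets
}

predictedPolygon <- function(tr, frame) {
  gap <- max(frame - tr$lastFrame, 1L)
  sweep(tr$poly, 2L, tr$vel * gap, "+")
}

trackGate <- function(tr, cfg) {
  cfg@baseGatePx + cfg@velocityGateGain * sqrt(sum(tr$vel^2))
}

#' Build the assignment cost matrix between tracks and detections
#'
#' Cost of pairing track t with detection d:
#' \deqn{w_{iou}(1 - IoU) + w_{dist}\min(dist/gate_t, 1) +
#'       w_{feat}(1 - \cos(f_t, f_d)) + w_{area}|A_t - A_d|/\max(A_t, A_d)}
#' where the track polygon is translated by its velocity estimate before the
#' IoU, and \eqn{gate_t = baseGatePx + velocityGateGain \cdot \|v_t\|}.
#' Pairs whose centroid distance exceeds the gate are masked infeasible.
#'
#' @param tracks list of internal track states (as produced by the tracking
#'   loop; each needs `poly`, `feat`, `areaEwma`, `vel`, `centroid`,
#'   `lastFrame`).
#' @param dets list of preprocessed detections (each with `poly`, `feat`,
#'   `centroid`, `area`).
#' @param cfg a [trackerConfig()].
#' @param frame current 0-based frame index (for gap-aware prediction).
#' @param gateScale multiplier on the gate radius (the fallback stage
#'   doubles it).
#' @return list with `cost` (tracks x detections matrix) and `feasible`
#'   (logical matrix).
#' @export
buildCostMatrix <- function(tracks, dets, cfg, frame = NULL, gateScale = 1) {
  nt <- length(tracks); nd <- length(dets)
  cost <- matrix(Inf, nt, nd)
  feasible <- matrix(FALSE, nt, nd)
  if (nt == 0L || nd == 0L) return(list(cost = cost, feasible = feasible))
  w <- cfg@weights
  for (i in seq_len(nt)) {
    tr <- tracks[[i]]
    f <- frame %||% (tr$lastFrame + 1L)
    gate <- trackGate(tr, cfg) * gateScale
    gap <- max(f - tr$lastFrame, 1L)
    predC <- tr$centroid + tr$vel * gap
    predP <- predictedPolygon(tr, f)
    for (j in seq_len(nd)) {
      d <- dets[[j]]
      if (length(tr$feat) != length(d$feat))
        stop("feature vector dimension mismatch", call. = FALSE)
      dist <- sqrt(sum((predC - d$centroid)^2))
      if (dist > gate) next
      iou <- polygonIoU(predP, d$poly)
      cost[i, j] <- w[["iou"]] * (1 - iou) +
        w[["dist"]] * min(dist / gate, 1) +
        w[["feat"]] * (1 - cosineSimilarity(tr$feat, d$feat)) +
        w[["area"]] * abs(tr$areaEwma - d$area) / max(tr$areaEwma, d$area)
      feasible[i, j] <- TRUE
    }
  }
  list(cost = cost, feasible = feasible)
}

#' Solve the rectangular assignment problem
#'
#' Minimum-total-cost one-to-one matching (Hungarian method via the linear
#' sum assignment solver in \pkg{clue}); infeasible pairs are never matched.
#' An all-infeasible matrix yields an empty matching.
#'
#' @param cost numeric cost matrix (rows = tracks, columns = detections).
#' @param feasible optional logical matrix; `FALSE` (or a non-finite cost)
#'   marks a forbidden pair.
#' @return list with `pairs` (two-column matrix of row/column indices of the
#'   matching, ordered by row) and `total` (summed cost of the matching).
#' @export
solveAssignment <- function(cost, feasible = NULL) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  if (is.null(feasible)) feasible <- is.finite(cost)
  feasible <- feasible & is.finite(cost)
  empty <- list(pairs = matrix(integer(0), 0L, 2L,
                               dimnames = list(NULL, c("row", "col"))),
                total = 0)
  if (nrow(cost) == 0L || ncol(cost) == 0L || !any(feasible)) return(empty)
  big <- max(cost[feasible]) * (max(dim(cost)) + 1) + 1
  work <- cost
  work[!feasible] <- big
  transposed <- nrow(work) > ncol(work)
  if (transposed) work <- t(work)
  sol <- clue::solve_LSAP(work, maximum = FALSE)
  rows <- seq_len(nrow(work))
  cols <- as.integer(sol)
  if (transposed) { tmp <- rows; rows <- cols; cols <- tmp }
  keep <- feasible[cbind(rows, cols)]
  pairs <- cbind(row = rows[keep], col = cols[keep])
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  list(pairs = pairs, total = sum(cost[pairs]))
}

# Apply an observation to a track state.
observeTrack <- function(tr, det, frame, cfg) {
  alpha <- cfg@ewmaAlpha
  gap <- max(frame - tr$lastFrame, 1L)
  instVel <- (det$centroid - tr$centroid) / gap
  tr$vel <- (1 - alpha) * tr$vel + alpha * instVel
  f <- (1 - alpha) * tr$feat + alpha * det$feat
  nf <- sqrt(sum(f^2))
  tr$feat <- if (nf > 0) f / nf else det$feat
  tr$areaEwma <- (1 - alpha) * tr$areaEwma + alpha * det$area
  tr$poly <- det$poly
  tr$centroid <- det$centroid
  tr$lastFrame <- as.integer(frame)
  tr$missed <- 0L
  tr$age <- tr$age + 1L
  tr$status <- "active"
  tr
}

newTrackerState <- function() {
  list(tracks = list(), nextId = 1L)
}

#' Advance the tracker by one frame
#'
#' Runs the full per-frame update: primary assignment among active tracks
#' (cost cap `costMaxStage1`), a fallback pass over the leftovers with
#' doubled gates (`costMaxStage2`), division recovery (an unmatched
#' detection pair overlapping one track's prediction: the better-IoU
#' detection keeps the parent id, the other spawns a child with generation
#' + 1), merge bookkeeping (a track losing a shared detection becomes
#' occluded), re-identification of occluded tracks by EWMA appearance
#' similarity within the tolerated gap, EWMA/velocity updates, archiving of
#' stale tracks and creation of new tracks for leftover detections.
#'
#' @param state tracker state (from [newTrackerState()] internally, or a
#'   previous call); pass `NULL` to start.
#' @param fd a [frameDetections()] for the current frame.
#' @param cfg a [trackerConfig()].
#' @param image optional grayscale frame matrix for intensity features.
#' @return list with `state` (updated), `events` (data.frame of lineage
#'   events this frame), `matches` (data.frame track_id/detection index/IoU),
#'   `unmatchedDetections` (indices into `fd$detections` that started new
#'   tracks), `newTrackIds`.
#' @export
updateTracks <- function(state, fd, cfg, image = NULL) {
  if (is.null(state)) state <- newTrackerState()
  frame <- fd$frame
  dets <- prepDetections(fd, cfg, image)
  nd <- length(dets)
  tracks <- state$tracks
  statuses <- vapply(tracks, `[[`, character(1), "status")
  activeIdx <- which(statuses == "active")
  occlIdx <- which(statuses == "occluded")

  detMatched <- rep(FALSE, nd)
  trackMatchDet <- setNames(rep(NA_integer_, length(activeIdx)),
                            as.character(activeIdx))
  events <- list()
  matchIoU <- numeric(0)
  matchedTrackIds <- integer(0)

  assignStage <- function(trIdx, detIdx, gateScale, costMax) {
    if (length(trIdx) == 0L || length(detIdx) == 0L) return(NULL)
    cm <- buildCostMatrix(tracks[trIdx], dets[detIdx], cfg,
                          frame = frame, gateScale = gateScale)
    feas <- cm$feasible & cm$cost <= costMax
    sol <- solveAssignment(cm$cost, feas)
    if (nrow(sol$pairs) == 0L) return(NULL)
    cbind(track = trIdx[sol$pairs[, 1L]], det = detIdx[sol$pairs[, 2L]])
  }

  # Stage 1: primary assignment among active tracks
  p1 <- assignStage(activeIdx, seq_len(nd), 1, cfg@costMaxStage1)
  # Stage 2 (fallback): unmatched x unmatched, doubled gates, looser cap
  m1t <- if (is.null(p1)) integer(0) else p1[, "track"]
  m1d <- if (is.null(p1)) integer(0) else p1[, "det"]
  p2 <- assignStage(setdiff(activeIdx, m1t), setdiff(seq_len(nd), m1d),
                    2, cfg@costMaxStage2)
  pairs <- rbind(p1, p2)

  applyMatch <- function(ti, di) {
    iou <- polygonIoU(predictedPolygon(tracks[[ti]], frame), dets[[di]]$poly)
    tracks[[ti]] <<- observeTrack(tracks[[ti]], dets[[di]], frame, cfg)
    detMatched[di] <<- TRUE
    matchIoU <<- c(matchIoU, iou)
    matchedTrackIds <<- c(matchedTrackIds, tracks[[ti]]$id)
  }

  matchedBy <- rep(NA_integer_, nd)   # det index -> track index
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) matchedBy[pairs[r, "det"]] <- pairs[r, "track"]
  }

  # Split recovery before observations are applied: examine each active
  # track's predicted polygon against unmatched detections.
  splitSpawns <- list()   # list of (parentTrackIdx, childDetIdx)
  unmatchedDets <- which(!seq_len(nd) %in% (if (is.null(pairs)) integer(0) else pairs[, "det"]))
  if (length(unmatchedDets) && length(activeIdx)) {
    claimed <- rep(FALSE, nd)
    for (ti in activeIdx) {
      pred <- predictedPolygon(tracks[[ti]], frame)
      cand <- unmatchedDets[!claimed[unmatchedDets]]
      if (length(cand) == 0L) next
      ious <- vapply(cand, function(di) polygonIoU(pred, dets[[di]]$poly),
                     numeric(1))
      ok <- cand[ious >= cfg@splitIouMin]
      iousOk <- ious[ious >= cfg@splitIouMin]
      if (length(ok) == 0L) next
      mdet <- if (!is.null(pairs) && ti %in% pairs[, "track"])
        pairs[pairs[, "track"] == ti, "det"][1L] else NA_integer_
      if (!is.na(mdet)) {
        # parent already matched: the unmatched overlapper becomes a
        # daughter unless it overlaps the prediction better, in which case
        # it inherits the parent id and the previously matched detection
        # spawns the child.
        best <- ok[which.max(iousOk)]
        iouM <- polygonIoU(pred, dets[[mdet]]$poly)
        if (max(iousOk) > iouM) {
          pairs[pairs[, "track"] == ti, "det"] <- best
          matchedBy[best] <- ti; matchedBy[mdet] <- NA_integer_
          childDet <- mdet
        } else childDet <- best
        splitSpawns[[length(splitSpawns) + 1L]] <- list(parent = ti, det = childDet)
        claimed[childDet] <- TRUE
      } else if (length(ok) >= 2L) {
        # parent unmatched but two daughters overlap its prediction
        ordIoU <- order(-iousOk)
        keepDet <- ok[ordIoU[1L]]
        childDet <- ok[ordIoU[2L]]
        pairs <- rbind(pairs, cbind(track = ti, det = keepDet))
        matchedBy[keepDet] <- ti
        splitSpawns[[length(splitSpawns) + 1L]] <- list(parent = ti, det = childDet)
        claimed[keepDet] <- TRUE
        claimed[childDet] <- TRUE
      }
    }
  }

  # Merge bookkeeping: an unmatched active track whose feasible detections
  # were all won by other tracks competed and lost; it becomes occluded.
  mergeLosers <- integer(0)
  stillUnmatchedTr <- setdiff(activeIdx,
                              if (is.null(pairs)) integer(0) else pairs[, "track"])
  if (length(stillUnmatchedTr) && nd > 0L) {
    cmAll <- buildCostMatrix(tracks[stillUnmatchedTr], dets, cfg,
                             frame = frame, gateScale = 2)
    for (k in seq_along(stillUnmatchedTr)) {
      feas <- which(cmAll$feasible[k, ] & cmAll$cost[k, ] <= cfg@costMaxStage2)
      if (length(feas) && all(!is.na(matchedBy[feas]))) {
        ti <- stillUnmatchedTr[k]
        winner <- tracks[[matchedBy[feas[which.min(cmAll$cost[k, feas])]]]]$id
        mergeLosers <- c(mergeLosers, ti)
        events[[length(events) + 1L]] <- data.frame(
          frame = frame, parent_id = tracks[[ti]]$id,
          child1 = winner, child2 = tracks[[ti]]$id, kind = "merge")
      }
    }
  }

  # Apply matched observations
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) applyMatch(pairs[r, "track"], pairs[r, "det"])
  }

  # Spawn split children and record events
  newIds <- integer(0)
  for (sp in splitSpawns) {
    parent <- tracks[[sp$parent]]
    child <- newTrackState(state$nextId, frame, dets[[sp$det]],
                           gen = parent$gen + 1L, parent = parent$id,
                           vel = parent$vel)
    tracks[[length(tracks) + 1L]] <- child
    newIds <- c(newIds, state$nextId)
    detMatched[sp$det] <- TRUE
    events[[length(events) + 1L]] <- data.frame(
      frame = frame, parent_id = parent$id,
      child1 = parent$id, child2 = child$id, kind = "split")
    state$nextId <- state$nextId + 1L
  }

  # Re-identification: occluded tracks within the tolerated gap rematch to
  # leftover detections on appearance similarity within a gap-scaled gate.
  freeDets <- which(!detMatched)
  if (length(occlIdx) && length(freeDets)) {
    cand <- list()
    for (ti in occlIdx) {
      tr <- tracks[[ti]]
      gap <- frame - tr$lastFrame
      if (gap > cfg@maxGapFrames) next
      gate <- trackGate(tr, cfg) * gap
      predC <- tr$centroid + tr$vel * gap
      for (di in freeDets) {
        sim <- cosineSimilarity(tr$feat, dets[[di]]$feat)
        dist <- sqrt(sum((predC - dets[[di]]$centroid)^2))
        if (sim >= cfg@reidSimilarityMin && dist <= gate)
          cand[[length(cand) + 1L]] <- c(ti, di, sim)
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(-cand[, 3L], cand[, 1L]), , drop = FALSE]
      usedT <- integer(0); usedD <- integer(0)
      for (r in seq_len(nrow(cand))) {
        ti <- cand[r, 1L]; di <- cand[r, 2L]
        if (ti %in% usedT || di %in% usedD) next
        usedT <- c(usedT, ti); usedD <- c(usedD, di)
        events[[length(events) + 1L]] <- data.frame(
          frame = frame, parent_id = tracks[[ti]]$id,
          child1 = tracks[[ti]]$id, child2 = tracks[[ti]]$id, kind = "reid")
        tracks[[ti]] <- observeTrack(tracks[[ti]], dets[[di]], frame, cfg)
        matchedTrackIds <- c(matchedTrackIds, tracks[[ti]]$id)
        detMatched[di] <- TRUE
      }
    }
  }

  # Age out the unmatched
  for (ti in seq_along(tracks)) {
    tr <- tracks[[ti]]
    if (tr$status == "archived") next
    if (tr$lastFrame < frame) {
      tr$missed <- frame - tr$lastFrame
      tr$status <- if (tr$missed > cfg@maxGapFrames) "archived" else "occluded"
      tracks[[ti]] <- tr
    }
  }

  # Leftover detections start new tracks (generation 0)
  starters <- which(!detMatched)
  for (di in starters) {
    tracks[[length(tracks) + 1L]] <- newTrackState(state$nextId, frame, dets[[di]])
    newIds <- c(newIds, state$nextId)
    state$nextId <- state$nextId + 1L
  }

  state$tracks <- tracks
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(frame = integer(0), parent_id = integer(0),
               child1 = integer(0), child2 = integer(0), kind = character(0))
  list(state = state, events = ev,
       matches = data.frame(track_id = matchedTrackIds,
                            iou = c(matchIoU, rep(NA_real_,
                                    length(matchedTrackIds) - length(matchIoU)))),
       dets = dets,
       prevActiveIds = vapply(state$tracks[activeIdx], `[[`, integer(1), "id"),
       unmatchedDetections = starters,
       newTrackIds = newIds)
}

#' Per-frame tracking quality metrics
#'
#' @param prevActiveIds track ids active before the frame update.
#' @param matchedIds track ids matched during the frame update.
#' @param activeCount number of active tracks after the update.
#' @param meanIoU mean IoU of matched (prediction, detection) pairs.
#' @param events lineage events of the frame.
#' @param frame frame index.
#' @return one-row data.frame: `frame`, `track_count`, `mean_iou`, `splits`,
#'   `merges`, `reid_events`, `continuity`. Continuity is the fraction of
#'   previously active tracks matched this frame (1 when there were none).
#' @export
computeFrameMetrics <- function(frame, prevActiveIds, matchedIds, activeCount,
                                meanIoU, events) {
  continuity <- if (length(prevActiveIds) == 0L) 1 else
    sum(prevActiveIds %in% matchedIds) / length(prevActiveIds)
  data.frame(frame = frame, track_count = activeCount,
             mean_iou = meanIoU,
             splits = sum(events$kind == "split"),
             merges = sum(events$kind == "merge"),
             reid_events = sum(events$kind == "reid"),
             continuity = continuity)
}

polyToJSON <- function(poly) {
  jsonlite::toJSON(unname(round(poly, 4)), digits = NA)
}

#' Track cells across a sequence of frame detections
#'
#' Runs [updateTracks()] over all frames and assembles the track table, the
#' lineage event log and the per-frame quality metrics into a [TrackSet].
#' Identical inputs and configuration yield identical output.
#'
#' @param detFrames list of [frameDetections()], ordered by frame.
#' @param cfg a [trackerConfig()].
#' @param images optional list of grayscale matrices parallel to
#'   `detFrames` for intensity features.
#' @return a [TrackSet].
#' @examples
#' sq <- function(cx) cbind(c(-5, 5, 5, -5) + cx, c(-5, -5, 5, 5) + 20)
#' frames <- lapply(0:5, function(f)
#'   frameDetections(f, list(list(poly = sq(20 + 2 * f)))))
#' ts <- trackCells(frames, trackerConfig(minAreaPx2 = 10))
#' ts
#' @export
trackCells <- function(detFrames, cfg = trackerConfig(), images = NULL) {
  state <- NULL
  rows <- list()
  allEvents <- list()
  metrics <- list()
  polysByFrame <- vector("list", length(detFrames))
  for (k in seq_along(detFrames)) {
    fd <- detFrames[[k]]
    img <- if (!is.null(images)) images[[k]] else NULL
    up <- updateTracks(state, fd, cfg, image = img)
    state <- up$state
    statuses <- vapply(state$tracks, `[[`, character(1), "status")
    activeNow <- which(statuses == "active")
    # observation rows: every track observed at this frame
    framePolys <- list()
    for (ti in activeNow) {
      tr <- state$tracks[[ti]]
      if (tr$lastFrame != fd$frame) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fd$frame, track_id = tr$id, parent_id = tr$parent,
        generation = tr$gen, status = tr$status,
        centroid_x_px = tr$centroid[1L], centroid_y_px = tr$centroid[2L],
        area_px2 = polygonArea(tr$poly),
        polygon = as.character(polyToJSON(tr$poly)))
      framePolys[[as.character(tr$id)]] <- tr$poly
    }
    polysByFrame[[k]] <- framePolys
    meanIoU <- if (nrow(up$matches)) mean(up$matches$iou, na.rm = TRUE) else NA_real_
    metrics[[k]] <- computeFrameMetrics(fd$frame, up$prevActiveIds,
                                        up$matches$track_id,
                                        sum(vapply(state$tracks, function(t)
                                          t$status == "active" &&
                                            t$lastFrame == fd$frame, logical(1))),
                                        meanIoU, up$events)
    if (nrow(up$events)) allEvents[[length(allEvents) + 1L]] <- up$events
  }
  tracksDf <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), track_id = integer(0),
               parent_id = integer(0), generation = integer(0),
               status = character(0), centroid_x_px = numeric(0),
               centroid_y_px = numeric(0), area_px2 = numeric(0),
               polygon = character(0))
  lineageDf <- if (length(allEvents)) do.call(rbind, allEvents) else
    data.frame(frame = integer(0), parent_id = integer(0),
               child1 = integer(0), child2 = integer(0), kind = character(0))
  rownames(tracksDf) <- NULL
  rownames(lineageDf) <- NULL
  new("TrackSet", tracks = tracksDf, lineage = lineageDf,
      frameMetrics = do.call(rbind, metrics), config = cfg,
      polygons = polysByFrame)
}

#' Evaluate tracking output against ground truth
#'
#' Associates predicted to true objects per frame by IoU (Hungarian,
#' feasible when IoU >= `assocIou`) and reports MOT-style identity metrics:
#' `id_switches` counts true objects whose associated predicted id changes
#' between consecutive matched frames; `identity_preservation` is the
#' fraction of true tracks whose single most frequent predicted id covers at
#' least 90 percent of their matched frames (a never-matched true track is
#' not preserved); `split_recall` is the fraction of true divisions for
#' which a predicted split event occurs within one frame and involves the
#' predicted id associated with the true parent or a daughter.
#'
#' @param trackSet a [TrackSet].
#' @param truth a [SceneTruth].
#' @param assocIou association threshold (default 0.5).
#' @return named list `identity_preservation`, `id_switches`,
#'   `split_recall` (NA when the truth has no divisions).
#' @export
evaluateTracking <- function(trackSet, truth, assocIou = 0.5) {
  stopifnot(is(trackSet, "TrackSet"), is(truth, "SceneTruth"))
  nF <- truth@nFrames
  if (length(trackSet@polygons) != nF)
    stop("tracks and truth cover different frame ranges", call. = FALSE)
  # per-frame association: assoc[[f]] maps true id -> predicted id
  assoc <- vector("list", nF)
  for (f in seq_len(nF)) {
    tp <- truth@polygons[[f]]
    pp <- trackSet@polygons[[f]]
    if (length(tp) == 0L || length(pp) == 0L) { assoc[[f]] <- list(); next }
    cost <- matrix(Inf, length(tp), length(pp))
    for (i in seq_along(tp)) for (j in seq_along(pp)) {
      iou <- polygonIoU(tp[[i]], pp[[j]])
      if (iou >= assocIou) cost[i, j] <- 1 - iou
    }
    sol <- solveAssignment(cost)
    m <- list()
    if (nrow(sol$pairs)) {
      for (r in seq_len(nrow(sol$pairs))) {
        m[[names(tp)[sol$pairs[r, 1L]]]] <- as.integer(names(pp)[sol$pairs[r, 2L]])
      }
    }
    assoc[[f]] <- m
  }
  trueIds <- unique(truth@objects$id)
  switches <- 0L
  preserved <- 0L
  for (tid in trueIds) {
    seqIds <- integer(0)
    for (f in seq_len(nF)) {
      pid <- assoc[[f]][[as.character(tid)]]
      if (!is.null(pid)) seqIds <- c(seqIds, pid)
    }
    if (length(seqIds) >= 2L)
      switches <- switches + sum(diff(seqIds) != 0L)
    tFrames <- sum(truth@objects$id == tid)
    if (length(seqIds) > 0L) {
      cover <- max(table(seqIds)) / length(seqIds)
      if (cover >= 0.9) preserved <- preserved + 1L
    }
  }
  preservation <- if (length(trueIds)) preserved / length(trueIds) else NA_real_
  # split recall
  tl <- truth@lineage
  recall <- NA_real_
  if (nrow(tl)) {
    pl <- trackSet@lineage
    pl <- pl[pl$kind == "split", , drop = FALSE]
    usedPred <- rep(FALSE, nrow(pl))
    hits <- 0L
    for (r in seq_len(nrow(tl))) {
      f <- tl$frame[r]
      relevant <- integer(0)
      for (ff in max(f - 1L, 0L):min(f + 1L, nF - 1L)) {
        for (id in c(tl$parent_id[r], tl$child1[r], tl$child2[r])) {
          pid <- assoc[[ff + 1L]][[as.character(id)]]
          if (!is.null(pid)) relevant <- c(relevant, pid)
        }
      }
      if (f >= 1L) {
        pid <- assoc[[f]][[as.character(tl$parent_id[r])]]
        if (!is.null(pid)) relevant <- c(relevant, pid)
      }
      cand <- which(!usedPred & abs(pl$frame - f) <= 1L &
                      (pl$parent_id %in% relevant | pl$child1 %in% relevant |
                         pl$child2 %in% relevant))
      if (length(cand)) { hits <- hits + 1L; usedPred[cand[1L]] <- TRUE }
    }
    recall <- hits / nrow(tl)
  }
  list(identity_preservation = preservation, id_switches = switches,
       split_recall = recall)
}
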