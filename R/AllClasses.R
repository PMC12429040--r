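#' @import methods
NULL

#' Tracker configuration
#'
#' Global constants governing the tracking loop: cost weights, gates, cost
#' caps for the two assignment stages, EWMA smoothing, the maximum tolerated
#' detection gap, the re-identification appearance threshold and the
#' division-overlap threshold.
#'
#' @slot weights named numeric of length 4 (`iou`, `dist`, `feat`, `area`),
#'   non-negative, summing to 1.
#' @slot baseGatePx spatial gate radius at zero velocity (pixels).
#' @slot velocityGateGain gate growth per unit speed (pixels per px/frame).
#' @slot costMaxStage1 maximal accepted cost in the primary assignment.
#' @slot costMaxStage2 maximal accepted cost in the fallback pass
#'   (must be >= `costMaxStage1`).
#' @slot ewmaAlpha smoothing weight of new observations in the appearance,
#'   area and velocity histories, in (0, 1].
#' @slot maxGapFrames frames a track may stay unseen before it is archived.
#' @slot reidSimilarityMin minimal cosine similarity of EWMA appearance
#'   vectors for re-identification.
#' @slot splitIouMin minimal IoU between a candidate daughter detection and
#'   a parent's predicted polygon for division recovery.
#' @slot minAreaPx2 minimal detectable object area (square pixels).
#' @export
setClass("TrackerConfig", representation(
  weights = "numeric",
  baseGatePx = "numeric",
  velocityGateGain = "numeric",
  costMaxStage1 = "numeric",
  costMaxStage2 = "numeric",
  ewmaAlpha = "numeric",
  maxGapFrames = "integer",
  reidSimilarityMin = "numeric",
  splitIouMin = "numeric",
  minAreaPx2 = "numeric"
))

setValidity("TrackerConfig", function(object) {
  w <- object@weights
  msgs <- character(0)
  if (length(w) != 4L || is.null(names(w)) ||
      !identical(sort(names(w)), sort(c("iou", "dist", "feat", "area"))))
    msgs <- c(msgs, "weights must be named iou, dist, feat, area")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    msgs <- c(msgs, "weights must be non-negative and sum to 1")
  if (object@costMaxStage1 > object@costMaxStage2)
    msgs <- c(msgs, "costMaxStage1 must be <= costMaxStage2")
  if (object@ewmaAlpha <= 0 || object@ewmaAlpha > 1)
    msgs <- c(msgs, "ewmaAlpha must be in (0, 1]")
  if (object@maxGapFrames < 1L) msgs <- c(msgs, "maxGapFrames must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TrackerConfig
#'
#' @param weights cost weights for IoU, centroid distance, appearance and
#'   area terms (must sum to 1).
#' @param baseGatePx,velocityGateGain adaptive gate: a detection is feasible
#'   for a track when its centroid lies within
#'   `baseGatePx + velocityGateGain * speed` pixels of the predicted
#'   position.
#' @param costMaxStage1,costMaxStage2 cost caps of the primary and fallback
#'   assignment stages.
#' @param ewmaAlpha exponential smoothing weight for appearance/area/velocity.
#' @param maxGapFrames maximum tolerated gap before a track is archived.
#' @param reidSimilarityMin cosine threshold for re-identification.
#' @param splitIouMin IoU threshold for division recovery.
#' @param minAreaPx2 minimum detectable object area, px^2.
#' @return a `TrackerConfig` object.
#' @examples
#' cfg <- trackerConfig()
#' cfg
#' @export
trackerConfig <- function(weights = c(iou = 0.4, dist = 0.3, feat = 0.2, area = 0.1),
                          baseGatePx = 50, velocityGateGain = 2,
                          costMaxStage1 = 0.6, costMaxStage2 = 0.8,
                          ewmaAlpha = 0.3, maxGapFrames = 30L,
                          reidSimilarityMin = 0.9, splitIouMin = 0.2,
                          minAreaPx2 = 100) {
  new("TrackerConfig", weights = weights, baseGatePx = baseGatePx,
      velocityGateGain = velocityGateGain, costMaxStage1 = costMaxStage1,
      costMaxStage2 = costMaxStage2, ewmaAlpha = ewmaAlpha,
      maxGapFrames = as.integer(maxGapFrames),
      reidSimilarityMin = reidSimilarityMin, splitIouMin = splitIouMin,
      minAreaPx2 = minAreaPx2)
}

setMethod("show", "TrackerConfig", function(object) {
  cat("TrackerConfig\n")
  cat("  weights      :", paste(sprintf("%s=%.2f", names(object@weights),
                                        object@weights), collapse = " "), "\n")
  cat(sprintf("  gate         : %.0f px + %.1f px per px/frame\n",
              object@baseGatePx, object@velocityGateGain))
  cat(sprintf("  cost caps    : stage1 %.2f, stage2 %.2f\n",
              object@costMaxStage1, object@costMaxStage2))
  cat(sprintf("  ewma alpha   : %.2f   max gap: %d frames\n",
              object@ewmaAlpha, object@maxGapFrames))
  cat(sprintf("  reid cos >=  : %.2f   split IoU >= %.2f   min area %.0f px^2\n",
              object@reidSimilarityMin, object@splitIouMin, object@minAreaPx2))
})

#' Tracking result container
#'
#' Holds the per-frame track table, the lineage event log, the per-frame
#' quality metrics and the configuration that produced them.
#'
#' @slot tracks data.frame with columns `frame`, `track_id`, `parent_id`,
#'   `generation`, `status`, `centroid_x_px`, `centroid_y_px`, `area_px2`,
#'   `polygon` (JSON vertex list).
#' @slot lineage data.frame with columns `frame`, `parent_id`, `child1`,
#'   `child2`, `kind` (`split`, `merge` or `reid`).
#' @slot frameMetrics data.frame with columns `frame`, `track_count`,
#'   `mean_iou`, `splits`, `merges`, `reid_events`, `continuity`.
#' @slot config the `TrackerConfig` used.
#' @slot polygons list (by frame) of lists of polygon matrices for matched
#'   tracks, used by the evaluation harness and overlay rendering.
#' @export
setClass("TrackSet", representation(
  tracks = "data.frame",
  lineage = "data.frame",
  frameMetrics = "data.frame",
  config = "TrackerConfig",
  polygons = "list"
))

setValidity("TrackSet", function(object) {
  need <- c("frame", "track_id", "parent_id", "generation", "status",
            "centroid_x_px", "centroid_y_px", "area_px2", "polygon")
  if (!all(need %in% names(object@tracks)))
    return("tracks table is missing required columns")
  TRUE
})

setMethod("show", "TrackSet", function(object) {
  tr <- object@tracks
  cat("TrackSet\n")
  cat(sprintf("  %d track(s) over %d frame(s); %d observation rows\n",
              length(unique(tr$track_id)),
              length(unique(tr$frame)), nrow(tr)))
  le <- object@lineage
  if (nrow(le))
    cat(sprintf("  lineage events: %d split, %d merge, %d reid\n",
                sum(le$kind == "split"), sum(le$kind == "merge"),
                sum(le$kind == "reid")))
  else cat("  lineage events: none\n")
})

#' @describeIn TrackSet-class the per-frame track observation table.
#' @param x a `TrackSet`.
#' @export
trackTable <- function(x) {
  stopifnot(is(x, "TrackSet"))
  x@tracks
}

#' @describeIn TrackSet-class the lineage event log.
#' @export
lineageEvents <- function(x) {
  stopifnot(is(x, "TrackSet"))
  x@lineage
}

#' @describeIn TrackSet-class per-frame tracking quality metrics.
#' @export
frameMetrics <- function(x) {
  stopifnot(is(x, "TrackSet"))
  x@frameMetrics
}

#' Ground truth of a synthetic scene
#'
#' @slot objects data.frame: `frame`, `id`, `parent_id`, `centroid_x_px`,
#'   `centroid_y_px`, `area_px2`, `dropped` (logical: detection withheld).
#' @slot polygons list (by frame, 1-based over 0-based frame index) of named
#'   lists mapping true id to polygon matrix (all objects, including
#'   withheld ones).
#' @slot lineage data.frame: `frame`, `parent_id`, `child1`, `child2`.
#' @slot nFrames integer.
#' @export
setClass("SceneTruth", representation(
  objects = "data.frame",
  polygons = "list",
  lineage = "data.frame",
  nFrames = "integer"
))

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth\n")
  cat(sprintf("  %d true track(s), %d frame(s), %d division(s), %d withheld detection(s)\n",
              length(unique(object@objects$id)), object@nFrames,
              nrow(object@lineage), sum(object@objects$dropped)))
})

#' Panel of aligned metric series
#'
#' One metric observed across `k >= 2` experimental series (treatments) over
#' aligned frames. The statistical engine treats each frame position within
#' a sliding window as a block and each series as a treatment.
#'
#' @slot values numeric T x k matrix (rows = frames, columns = series).
#' @slot frames integer frame indices (0-based, aligned).
#' @slot seriesIds character series labels.
#' @slot metric character name of the underlying metric.
#' @export
setClass("SeriesPanel", representation(
  values = "matrix",
  frames = "integer",
  seriesIds = "character",
  metric = "character"
))

setValidity("SeriesPanel", function(object) {
  msgs <- character(0)
  if (ncol(object@values) < 2L) msgs <- c(msgs, "need k >= 2 series")
  if (length(object@frames) != nrow(object@values))
    msgs <- c(msgs, "frames length must match row count")
  if (length(object@seriesIds) != ncol(object@values))
    msgs <- c(msgs, "seriesIds length must match column count")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SeriesPanel
#'
#' @param values T x k numeric matrix of one metric: rows are frames,
#'   columns are experimental series.
#' @param frames optional 0-based frame indices (default `0:(T-1)`).
#' @param seriesIds optional series labels.
#' @param metric metric name (metadata only).
#' @return a `SeriesPanel`.
#' @export
seriesPanel <- function(values, frames = NULL, seriesIds = NULL,
                        metric = "metric") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(frames)) frames <- seq_len(nrow(values)) - 1L
  if (is.null(seriesIds))
    seriesIds <- colnames(values) %||% paste0("series", seq_len(ncol(values)))
  new("SeriesPanel", values = unname(values), frames = as.integer(frames),
      seriesIds = as.character(seriesIds), metric = metric)
}

setMethod("show", "SeriesPanel", function(object) {
  cat(sprintf("SeriesPanel: metric '%s', %d series x %d frames\n",
              object@metric, ncol(object@values), nrow(object@values)))
})

#' @describeIn SeriesPanel-class the T x k value matrix.
#' @param x a `SeriesPanel`.
#' @export
panelValues <- function(x) {
  stopifnot(is(x, "SeriesPanel"))
  v <- x@values
  colnames(v) <- x@seriesIds
  v
}

#' Sliding-window scan result
#'
#' @slot windows data.frame with one row per window: `window_start`,
#'   `window_end` (frame indices into the smoothed series), `n_blocks`,
#'   `panel_q`, `n_eff`, `friedman_stat`, `df`, `p_asymptotic`,
#'   `p_permutation`, `n_significant_pairs`.
#' @slot posthoc list of Holm-adjusted pairwise p-value matrices (NULL when
#'   the omnibus test was not significant or untestable).
#' @slot pairSignificance data.frame in long form: `window_start`, `pair`,
#'   `p_adjusted`, `significant`.
#' @slot params list of scan parameters (ma width, window width, step, B,
#'   alpha, seed).
#' @export
setClass("WindowScan", representation(
  windows = "data.frame",
  posthoc = "list",
  pairSignificance = "data.frame",
  params = "list"
))

setMethod("show", "WindowScan", function(object) {
  w <- object@windows
  nsig <- sum(!is.na(w$p_asymptotic) & w$p_asymptotic < object@params$alpha)
  cat(sprintf("WindowScan: %d window(s) (width %d, step %d), %d significant at alpha=%.2f\n",
              nrow(w), object@params$window_w, object@params$step, nsig,
              object@params$alpha))
})

#' @describeIn WindowScan-class the per-window result table.
#' @param x a `WindowScan`.
#' @export
scanWindows <- function(x) {
  stopifnot(is(x, "WindowScan"))
  x@windows
}

#' @describeIn WindowScan-class long-form pairwise significance table (the
#'   heatmap data).
#' @export
pairSignificance <- function(x) {
  stopifnot(is(x, "WindowScan"))
  x@pairSignificance
}
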