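#' Staged analysis pipeline
#'
#' Orchestrates the package modules as a file-based pipeline with stages
#' `simulate`, `detect`, `track`, `analyse`, `stats` and `evaluate`. Each
#' stage reads the previous stage's documented files, writes its own
#' tables, and drops a run manifest (configuration hash, seed, input
#' checksums, package version) so every output directory is self-describing
#' and reproducible: a given configuration and seed fully determine every
#' output byte.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @slot calibration micrometres per pixel (default 0.5199).
#' @slot frameIntervalS frame interval in seconds (default 350).
#' @slot tracker a [TrackerConfig-class].
#' @slot arrestThresholdUm arrest speed threshold, um/frame (default 0.2).
#' @slot turnThresholdDeg sharp-turn threshold, degrees (default 90).
#' @slot maxStepUm baseline-linker displacement bound, um/step (default 10).
#' @slot maxGapLink baseline-linker bridgeable gap, frames (default 2).
#' @slot maW moving-average width (default 15).
#' @slot windowW Friedman window width (default 15).
#' @slot bPerm Friedman permutations (default 1000).
#' @slot bBoot bootstrap resamples (default 10000).
#' @slot alpha significance level (default 0.05).
#' @slot seed RNG seed (default 1).
#' @slot options named list of stage-specific options (simulation size,
#'   overlay flag, ...).
#' @export
setClass("PipelineConfig", representation(
  calibration = "numeric", frameIntervalS = "numeric",
  tracker = "TrackerConfig",
  arrestThresholdUm = "numeric", turnThresholdDeg = "numeric",
  maxStepUm = "numeric", maxGapLink = "integer",
  maW = "integer", windowW = "integer",
  bPerm = "integer", bBoot = "integer", alpha = "numeric",
  seed = "integer", options = "list"
))

setValidity("PipelineConfig", function(object) {
  msgs <- character(0)
  if (object@calibration <= 0) msgs <- c(msgs, "calibration must be > 0")
  if (object@frameIntervalS <= 0) msgs <- c(msgs, "frameIntervalS must be > 0")
  if (object@alpha <= 0 || object@alpha >= 1) msgs <- c(msgs, "alpha must be in (0,1)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PipelineConfig
#'
#' All defaults match the package's canonical analysis settings: 0.5199
#' um/px calibration, 350 s frame interval, 0.2 um/frame arrest threshold,
#' 90 degree sharp-turn threshold, 10 um/step baseline linking with 2-frame
#' gap bridging, 15/15 moving-average and test windows, 1000 permutations,
#' 10,000 bootstrap resamples and alpha 0.05.
#'
#' @param calibration,frameIntervalS,arrestThresholdUm,turnThresholdDeg
#'   analysis constants (see slots).
#' @param tracker a [trackerConfig()].
#' @param maxStepUm,maxGapLink baseline-linker constants.
#' @param maW,windowW,bPerm,bBoot,alpha statistics constants.
#' @param seed RNG seed.
#' @param options named list of stage options.
#' @return a `PipelineConfig`.
#' @export
pipelineConfig <- function(calibration = 0.5199, frameIntervalS = 350,
                           tracker = trackerConfig(),
                           arrestThresholdUm = 0.2, turnThresholdDeg = 90,
                           maxStepUm = 10, maxGapLink = 2L,
                           maW = 15L, windowW = 15L, bPerm = 1000L,
                           bBoot = 10000L, alpha = 0.05, seed = 1L,
                           options = list()) {
  new("PipelineConfig", calibration = calibration,
      frameIntervalS = frameIntervalS, tracker = tracker,
      arrestThresholdUm = arrestThresholdUm,
      turnThresholdDeg = turnThresholdDeg, maxStepUm = maxStepUm,
      maxGapLink = as.integer(maxGapLink), maW = as.integer(maW),
      windowW = as.integer(windowW), bPerm = as.integer(bPerm),
      bBoot = as.integer(bBoot), alpha = alpha, seed = as.integer(seed),
      options = options)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat(sprintf("  calibration : %.4f um/px   frame interval: %.0f s\n",
              object@calibration, object@frameIntervalS))
  cat(sprintf("  arrest      : %.2f um/frame   sharp turn: %.0f deg\n",
              object@arrestThresholdUm, object@turnThresholdDeg))
  cat(sprintf("  linker      : %.0f um/step, gap <= %d frames\n",
              object@maxStepUm, object@maxGapLink))
  cat(sprintf("  stats       : ma %d, window %d, B_perm %d, B_boot %d, alpha %.2f\n",
              object@maW, object@windowW, object@bPerm, object@bBoot,
              object@alpha))
  cat(sprintf("  seed        : %d\n", object@seed))
})

configToList <- function(cfg) {
  tr <- cfg@tracker
  c(list(calibration = cfg@calibration, frame_interval_s = cfg@frameIntervalS,
         arrest_threshold_um = cfg@arrestThresholdUm,
         turn_threshold_deg = cfg@turnThresholdDeg,
         max_step_um = cfg@maxStepUm, max_gap_link = cfg@maxGapLink,
         ma_w = cfg@maW, window_w = cfg@windowW, b_perm = cfg@bPerm,
         b_boot = cfg@bBoot, alpha = cfg@alpha, seed = cfg@seed),
    list(w_iou = unname(tr@weights[["iou"]]), w_dist = unname(tr@weights[["dist"]]),
         w_feat = unname(tr@weights[["feat"]]), w_area = unname(tr@weights[["area"]]),
         base_gate_px = tr@baseGatePx, velocity_gate_gain = tr@velocityGateGain,
         cost_max_stage1 = tr@costMaxStage1, cost_max_stage2 = tr@costMaxStage2,
         ewma_alpha = tr@ewmaAlpha, max_gap_frames = tr@maxGapFrames,
         reid_similarity_min = tr@reidSimilarityMin,
         split_iou_min = tr@splitIouMin, min_area_px2 = tr@minAreaPx2),
    cfg@options)
}

#' Read a pipeline configuration from a flat key-value file
#'
#' The file is flat YAML (`key: value` per line); any subset of keys may be
#' present and overrides the defaults of [pipelineConfig()]. Unknown keys
#' are kept as stage options. An invalid value aborts naming the field.
#'
#' @param path config file; `NULL` gives the defaults.
#' @param overrides named list applied after the file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
    kv <- yaml::read_yaml(path)
    if (!is.list(kv)) stop("config must be a flat key-value file", call. = FALSE)
  }
  kv[names(overrides)] <- overrides
  num <- function(key, default) {
    v <- kv[[key]] %||% default
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("invalid config value for '%s'", key), call. = FALSE)
    v
  }
  tracker <- trackerConfig(
    weights = c(iou = num("w_iou", 0.4), dist = num("w_dist", 0.3),
                feat = num("w_feat", 0.2), area = num("w_area", 0.1)),
    baseGatePx = num("base_gate_px", 50),
    velocityGateGain = num("velocity_gate_gain", 2),
    costMaxStage1 = num("cost_max_stage1", 0.6),
    costMaxStage2 = num("cost_max_stage2", 0.8),
    ewmaAlpha = num("ewma_alpha", 0.3),
    maxGapFrames = num("max_gap_frames", 30),
    reidSimilarityMin = num("reid_similarity_min", 0.9),
    splitIouMin = num("split_iou_min", 0.2),
    minAreaPx2 = num("min_area_px2", 100))
  known <- c("calibration", "frame_interval_s", "arrest_threshold_um",
             "turn_threshold_deg", "max_step_um", "max_gap_link", "ma_w",
             "window_w", "b_perm", "b_boot", "alpha", "seed", "w_iou",
             "w_dist", "w_feat", "w_area", "base_gate_px",
             "velocity_gate_gain", "cost_max_stage1", "cost_max_stage2",
             "ewma_alpha", "max_gap_frames", "reid_similarity_min",
             "split_iou_min", "min_area_px2")
  pipelineConfig(
    calibration = num("calibration", 0.5199),
    frameIntervalS = num("frame_interval_s", 350),
    tracker = tracker,
    arrestThresholdUm = num("arrest_threshold_um", 0.2),
    turnThresholdDeg = num("turn_threshold_deg", 90),
    maxStepUm = num("max_step_um", 10),
    maxGapLink = num("max_gap_link", 2),
    maW = num("ma_w", 15), windowW = num("window_w", 15),
    bPerm = num("b_perm", 1000), bBoot = num("b_boot", 10000),
    alpha = num("alpha", 0.05), seed = num("seed", 1),
    options = kv[setdiff(names(kv), known)])
}

pipeLog <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), sprintf(...))
}

#' Write pipeline tables to an output directory
#'
#' Data frames become CSV files (header-only when empty); lists become
#' JSON. Used by every stage for its canonical outputs.
#'
#' @param tables named list of data.frames and/or lists.
#' @param dir writable output directory (created if absent).
#' @return invisible character vector of written paths.
#' @export
writeOutputs <- function(tables, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      write.csv(x, p, row.names = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null")
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}

writeManifest <- function(dir, stage, cfg, inputs) {
  cfgPath <- file.path(dir, "config.yaml")
  cl <- configToList(cfg)
  yaml::write_yaml(cl[order(names(cl))], cfgPath)
  checks <- list()
  for (p in inputs) if (file.exists(p) && !dir.exists(p))
    checks[[basename(p)]] <- unname(tools::md5sum(p))
  manifest <- list(stage = stage,
                   config_hash = unname(tools::md5sum(cfgPath)),
                   seed = cfg@seed,
                   inputs = checks,
                   package_version = as.character(utils::packageVersion("trackmorph")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

truthToJSON <- function(truth, path) {
  payload <- list(
    n_frames = truth@nFrames,
    objects = truth@objects,
    lineage = truth@lineage,
    polygons = lapply(truth@polygons, function(pl)
      lapply(pl, function(p) unname(round(p, 4)))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
}

truthFromJSON <- function(path) {
  raw <- jsonlite::read_json(path)
  toDf <- function(rows, cols) {
    if (length(rows) == 0L)
      return(as.data.frame(setNames(rep(list(integer(0)), length(cols)), cols)))
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v))))
  }
  polys <- lapply(raw$polygons, function(pl)
    lapply(pl, function(p) do.call(rbind, lapply(p, function(v)
      c(as.numeric(v[[1L]]), as.numeric(v[[2L]]))))))
  new("SceneTruth",
      objects = toDf(raw$objects,
                     c("frame", "id", "parent_id", "centroid_x_px",
                       "centroid_y_px", "area_px2", "dropped")),
      polygons = polys,
      lineage = toDf(raw$lineage, c("frame", "parent_id", "child1", "child2")),
      nFrames = as.integer(raw$n_frames))
}

trackSetFromFiles <- function(tracksCsv, lineageCsv, metricsCsv, cfg, nFrames) {
  tr <- read.csv(tracksCsv, stringsAsFactors = FALSE)
  li <- read.csv(lineageCsv, stringsAsFactors = FALSE)
  fm <- read.csv(metricsCsv, stringsAsFactors = FALSE)
  polys <- vector("list", nFrames)
  for (f in seq_len(nFrames)) polys[[f]] <- list()
  for (r in seq_len(nrow(tr))) {
    m <- jsonlite::fromJSON(tr$polygon[r])
    polys[[tr$frame[r] + 1L]][[as.character(tr$track_id[r])]] <- m
  }
  new("TrackSet", tracks = tr, lineage = li, frameMetrics = fm,
      config = cfg@tracker, polygons = polys)
}

# Minimal deterministic overlay rendering: polygon contours burned into a
# grayscale frame, one PNG per frame.
writeOverlays <- function(polysByFrame, imageSize, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in seq_along(polysByFrame)) {
    img <- matrix(0, imageSize[2L], imageSize[1L])
    for (poly in polysByFrame[[f]]) {
      n <- nrow(poly)
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        len <- max(abs(poly[j, ] - poly[i, ]))
        ts <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
        xs <- round(poly[i, 1L] + ts * (poly[j, 1L] - poly[i, 1L])) + 1L
        ys <- round(poly[i, 2L] + ts * (poly[j, 2L] - poly[i, 2L])) + 1L
        ok <- xs >= 1L & xs <= imageSize[1L] & ys >= 1L & ys <= imageSize[2L]
        img[cbind(ys[ok], xs[ok])] <- 1
      }
    }
    png::writePNG(img, file.path(dir, sprintf("overlay_%04d.png", f - 1L)))
  }
  invisible(NULL)
}

requireInput <- function(inputs, key, stage) {
  p <- inputs[[key]]
  if (is.null(p) || !file.exists(p))
    stop(sprintf("stage '%s' requires input '%s' (missing path: %s)",
                 stage, key, p %||% "<unset>"), call. = FALSE)
  p
}

#' Run one pipeline stage
#'
#' Stages and their files (all under `outDir`):
#' \describe{
#' \item{simulate}{writes `detections.json` and `truth.json` for a seeded
#'   synthetic scene (options `n_cells`, `frames`, `motion`, `sigma`,
#'   `division_prob`, `dropout_prob`, `image_w`, `image_h`).}
#' \item{detect}{classical segmentation of grayscale PNG frames in
#'   `inputs$images` (a directory); writes `detections.json`.}
#' \item{track}{reads `inputs$detections`; writes `tracks.csv`,
#'   `frame_metrics.csv`, `lineage_events.csv` (and overlay PNGs when
#'   option `overlays` is TRUE).}
#' \item{analyse}{reads `inputs$tracks`; writes `trajectories.csv`,
#'   `track_metrics.csv` (the twelve-metric table), `dynamic_aggregate.csv`
#'   and `static_aggregate.csv` in calibrated units.}
#' \item{stats}{reads the long-format panel `inputs$panel` (columns
#'   `series_id`, `frame`, `value`); writes `windows.csv` and
#'   `pair_significance.csv`.}
#' \item{evaluate}{reads `inputs$tracks` directory and `inputs$truth`;
#'   writes `evaluation.json`.}
#' }
#' Every stage writes `config.yaml` and `manifest.json`.
#'
#' @param stage stage name.
#' @param config a [pipelineConfig()].
#' @param inputs named list of input paths (stage-specific).
#' @param outDir output directory.
#' @return invisible list of the stage's primary results.
#' @export
runPipeline <- function(stage = c("simulate", "detect", "track", "analyse",
                                  "stats", "evaluate"),
                        config = pipelineConfig(), inputs = list(),
                        outDir = ".") {
  stage <- match.arg(stage)
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir, call. = FALSE)
  opt <- config@options
  res <- switch(stage,
    simulate = {
      model <- motionModel(opt$motion %||% "brownian",
                           sigma = opt$sigma %||% 2,
                           speed = opt$speed %||% 2,
                           phi = opt$phi %||% 0.8,
                           pStop = opt$p_stop %||% 0.1,
                           pGo = opt$p_go %||% 0.1)
      scene <- genScene(nCells = opt$n_cells %||% 20L,
                        model = model,
                        T = opt$frames %||% 100L,
                        divisionProb = opt$division_prob %||% 0,
                        dropoutProb = opt$dropout_prob %||% 0,
                        imageSize = c(opt$image_w %||% 1280L,
                                      opt$image_h %||% 1024L),
                        seed = config@seed)
      writeDetectionsJSON(scene$detections, file.path(outDir, "detections.json"))
      truthToJSON(scene$truth, file.path(outDir, "truth.json"))
      pipeLog("simulate: %d cells, %d frames -> %s",
              opt$n_cells %||% 20L, opt$frames %||% 100L, outDir)
      scene
    },
    detect = {
      imgDir <- requireInput(inputs, "images", stage)
      files <- sort(list.files(imgDir, pattern = "\\.png$", full.names = TRUE))
      frames <- lapply(seq_along(files), function(i) {
        arr <- png::readPNG(files[[i]])
        if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
        polys <- segmentClassical(arr, minAreaPx2 = config@tracker@minAreaPx2)
        frameDetections(i - 1L, lapply(polys, detection, source = basename(files[[i]])))
      })
      writeDetectionsJSON(frames, file.path(outDir, "detections.json"))
      frames
    },
    track = {
      detPath <- requireInput(inputs, "detections", stage)
      frames <- readDetectionsJSON(detPath)
      ts <- trackCells(frames, config@tracker)
      writeOutputs(list(tracks = trackTable(ts),
                        frame_metrics = frameMetrics(ts),
                        lineage_events = lineageEvents(ts)), outDir)
      if (isTRUE(opt$overlays))
        writeOverlays(ts@polygons,
                      c(opt$image_w %||% 1280L, opt$image_h %||% 1024L),
                      file.path(outDir, "overlays"))
      pipeLog("track: %d tracks over %d frames",
              length(unique(trackTable(ts)$track_id)), length(frames))
      ts
    },
    analyse = {
      trPath <- requireInput(inputs, "tracks", stage)
      tr <- read.csv(trPath, stringsAsFactors = FALSE)
      calib <- config@calibration
      trajs <- lapply(split(tr, tr$track_id), function(d) {
        d <- d[order(d$frame), ]
        trajectory(x = d$centroid_x_px * calib, y = d$centroid_y_px * calib,
                   frame = d$frame, area = d$area_px2 * calib^2,
                   track_id = d$track_id[1L])
      })
      kin <- trajs[vapply(trajs, nrow, integer(1)) >= 2L]
      metricsRows <- lapply(kin, function(tj) {
        mm <- motilityMetrics(tj, arrestThresholdUm = config@arrestThresholdUm,
                              turnThresholdDeg = config@turnThresholdDeg)
        cbind(data.frame(track_id = tj$track_id[1L], n_frames = nrow(tj)),
              as.data.frame(mm))
      })
      trajDf <- do.call(rbind, trajs)
      names(trajDf) <- c("track_id", "frame", "x_um", "y_um", "area_um2",
                         "interpolated")
      out <- list(trajectories = trajDf,
                  track_metrics = if (length(metricsRows))
                    do.call(rbind, metricsRows) else data.frame(),
                  dynamic_aggregate = if (length(kin))
                    aggregateTracks(kin, "dynamic") else data.frame(),
                  static_aggregate = if (length(kin))
                    aggregateTracks(kin, "static") else data.frame())
      writeOutputs(out, outDir)
      pipeLog("analyse: %d trajectories", length(trajs))
      out
    },
    stats = {
      panelPath <- requireInput(inputs, "panel", stage)
      long <- read.csv(panelPath, stringsAsFactors = FALSE)
      need <- c("series_id", "frame", "value")
      if (!all(need %in% names(long)))
        stop("panel CSV must have columns series_id, frame, value", call. = FALSE)
      wide <- stats::reshape(long[need], idvar = "frame",
                             timevar = "series_id", direction = "wide")
      wide <- wide[order(wide$frame), ]
      vals <- as.matrix(wide[, -1L, drop = FALSE])
      ids <- sub("^value\\.", "", colnames(vals))
      panel <- seriesPanel(vals, frames = wide$frame, seriesIds = ids)
      scan <- slidingScan(panel, maW = config@maW, windowW = config@windowW,
                          B = config@bPerm, alpha = config@alpha,
                          seed = config@seed)
      writeOutputs(list(windows = scanWindows(scan),
                        pair_significance = pairSignificance(scan)), outDir)
      pipeLog("stats: %d windows scanned", nrow(scanWindows(scan)))
      scan
    },
    evaluate = {
      trDir <- requireInput(inputs, "tracks", stage)
      truthPath <- requireInput(inputs, "truth", stage)
      truth <- truthFromJSON(truthPath)
      ts <- trackSetFromFiles(file.path(trDir, "tracks.csv"),
                              file.path(trDir, "lineage_events.csv"),
                              file.path(trDir, "frame_metrics.csv"),
                              config, truth@nFrames)
      ev <- evaluateTracking(ts, truth)
      jsonlite::write_json(ev, file.path(outDir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      pipeLog("evaluate: preservation %.3f, %d id switches",
              ev$identity_preservation, ev$id_switches)
      ev
    })
  writeManifest(outDir, stage, config,
                unlist(inputs[vapply(inputs, is.character, logical(1))]))
  invisible(res)
}
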