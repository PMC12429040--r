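# Helpers building tracker inputs from plain polygons.
mkFrames <- function(polyLists) {
  lapply(seq_along(polyLists), function(i)
    frameDetections(i - 1L, lapply(polyLists[[i]], function(p) list(poly = p))))
}
smallCfg <- function(...) trackerConfig(minAreaPx2 = 10, ...)

test_that("cost matrix terms behave at their extremes", {
  cfg <- smallCfg()
  sq <- unitSquare(side = 10)
  det <- trackmorph:::prepDetections(frameDetections(1, list(list(poly = sq))),
                                     cfg)[[1]]
  tr <- trackmorph:::newTrackState(1L, 0L, det)
  cm <- buildCostMatrix(list(tr), list(det), cfg, frame = 1L)
  expect_true(cm$feasible[1, 1])
  expect_equal(cm$cost[1, 1], 0, tolerance = 1e-12)
  # detection beyond the gate is masked infeasible
  far <- trackmorph:::prepDetections(
    frameDetections(1, list(list(poly = unitSquare(cx = 500, side = 10)))), cfg)[[1]]
  cm2 <- buildCostMatrix(list(tr), list(far), cfg, frame = 1L)
  expect_false(cm2$feasible[1, 1])
  # degenerate weighting (1,0,0,0): cost is exactly 1 - IoU
  cfgIou <- trackerConfig(weights = c(iou = 1, dist = 0, feat = 0, area = 0),
                          minAreaPx2 = 10)
  shifted <- trackmorph:::prepDetections(
    frameDetections(1, list(list(poly = unitSquare(cx = 5, side = 10)))), cfg)[[1]]
  cm3 <- buildCostMatrix(list(tr), list(shifted), cfgIou, frame = 1L)
  expect_equal(cm3$cost[1, 1], 1 - polygonIoU(sq, shifted$poly), tolerance = 1e-12)
})

test_that("assignment solves small canonical cases", {
  s1 <- solveAssignment(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))
  expect_equal(s1$pairs, cbind(row = 1:2, col = 1:2))
  expect_equal(s1$total, 2)
  s2 <- solveAssignment(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_equal(s2$total, 0)
  # all-infeasible matrix gives an empty matching, not an error
  s3 <- solveAssignment(matrix(1, 2, 2), feasible = matrix(FALSE, 2, 2))
  expect_equal(nrow(s3$pairs), 0)
  # rectangular: unmatched columns are simply absent
  s4 <- solveAssignment(matrix(c(5, 1, 9, 2, 8, 3), 2, 3, byrow = TRUE))
  expect_equal(nrow(s4$pairs), 2)
})

test_that("assignment equals the exhaustive-permutation optimum", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(2:7, 1)
    cm <- matrix(runif(n * n), n)
    expect_equal(solveAssignment(cm)$total, oracleAssignmentMin(cm),
                 tolerance = 1e-12)
  }
})

test_that("a single moving cell keeps one id with increasing age", {
  frames <- mkFrames(lapply(0:9, function(f) list(unitSquare(cx = 2 * f, side = 10))))
  ts <- trackCells(frames, smallCfg())
  tt <- trackTable(ts)
  expect_equal(unique(tt$track_id), 1L)
  expect_equal(nrow(tt), 10)
  expect_equal(frameMetrics(ts)$continuity, rep(1, 10))
  expect_equal(frameMetrics(ts)$track_count, rep(1L, 10))
})

test_that("a division spawns a child with generation parent + 1", {
  # one cell splits into two overlapping daughters at frame 5
  parent <- function(f) ellipsePolygon(12, 6, cx = 50 + f, cy = 50)
  d1 <- function(f) ellipsePolygon(9, 5, cx = 50 + f - 7, cy = 50)
  d2 <- function(f) ellipsePolygon(9, 5, cx = 50 + f + 7, cy = 50)
  polys <- c(lapply(0:4, function(f) list(parent(f))),
             lapply(5:9, function(f) list(d1(f), d2(f))))
  ts <- trackCells(mkFrames(polys), smallCfg())
  le <- lineageEvents(ts)
  expect_equal(sum(le$kind == "split"), 1)
  expect_equal(le$frame[le$kind == "split"], 5)
  tt <- trackTable(ts)
  childId <- le$child2[le$kind == "split"]
  parentId <- le$parent_id[le$kind == "split"]
  expect_equal(tt$generation[tt$track_id == childId][1],
               tt$generation[tt$track_id == parentId][1] + 1L)
  expect_equal(tt$parent_id[tt$track_id == childId][1], parentId)
})

test_that("a 3-frame dropout is re-identified under the original id", {
  present <- c(0:4, 8:12)
  polys <- lapply(0:12, function(f)
    if (f %in% present) list(ellipsePolygon(10, 6, cx = 60, cy = 60)) else list())
  ts <- trackCells(mkFrames(polys), smallCfg(maxGapFrames = 5L))
  tt <- trackTable(ts)
  expect_equal(unique(tt$track_id), 1L)
  le <- lineageEvents(ts)
  expect_equal(sum(le$kind == "reid"), 1)
  expect_equal(le$frame[le$kind == "reid"], 8)
})

test_that("frame metrics report continuity as the matched fraction", {
  fm5 <- computeFrameMetrics(3L, prevActiveIds = 1:5, matchedIds = 1:5,
                             activeCount = 5L, meanIoU = 0.9,
                             events = data.frame(kind = character(0)))
  expect_equal(fm5$continuity, 1)
  expect_equal(fm5$track_count, 5L)
  fm4 <- computeFrameMetrics(3L, prevActiveIds = 1:5, matchedIds = 1:4,
                             activeCount = 5L, meanIoU = 0.9,
                             events = data.frame(kind = "split"))
  expect_equal(fm4$continuity, 0.8)
  expect_equal(fm4$splits, 1)
  fm0 <- computeFrameMetrics(0L, prevActiveIds = integer(0),
                             matchedIds = integer(0), activeCount = 2L,
                             meanIoU = NA_real_,
                             events = data.frame(kind = character(0)))
  expect_equal(fm0$continuity, 1)
})

test_that("evaluation harness scores perfect, swapped and empty predictions", {
  scene <- genScene(6, motionModel("brownian", sigma = 1.5), T = 12,
                    imageSize = c(512, 512), seed = 21)
  ts <- trackCells(scene$detections, trackerConfig())
  ev <- evaluateTracking(ts, scene$truth)
  expect_equal(ev$identity_preservation, 1)
  expect_equal(ev$id_switches, 0L)
  # swap two predicted ids from frame 6 onwards: exactly 2 switches
  swapped <- ts
  ids <- sort(unique(trackTable(ts)$track_id))[1:2]
  tt <- swapped@tracks
  sel <- tt$frame >= 6 & tt$track_id %in% ids
  tt$track_id[sel] <- ifelse(tt$track_id[sel] == ids[1], ids[2], ids[1])
  swapped@tracks <- tt
  for (f in 7:12) {
    pl <- swapped@polygons[[f]]
    nm <- names(pl)
    nm[nm == as.character(ids[1])] <- "tmp"
    nm[nm == as.character(ids[2])] <- as.character(ids[1])
    nm[nm == "tmp"] <- as.character(ids[2])
    names(pl) <- nm
    swapped@polygons[[f]] <- pl
  }
  ev2 <- evaluateTracking(swapped, scene$truth)
  expect_equal(ev2$id_switches, 2L)
  expect_lt(ev2$identity_preservation, 1)
  # empty predictions: defined, no crash
  empty <- new("TrackSet", tracks = trackTable(ts)[0, ],
               lineage = lineageEvents(ts)[0, ],
               frameMetrics = frameMetrics(ts)[0, ],
               config = trackerConfig(),
               polygons = replicate(12, list(), simplify = FALSE))
  ev3 <- evaluateTracking(empty, scene$truth)
  expect_equal(ev3$identity_preservation, 0)
  expect_equal(ev3$id_switches, 0L)
})

test_that("track ids are never reused and lineage is consistent", {
  fd <- data.frame(id = c(1, 3), frame = c(4, 8))
  scene <- genScene(6, motionModel("brownian", sigma = 1.5), T = 15,
                    imageSize = c(640, 512), seed = 33, forcedDivisions = fd,
                    dropoutProb = 0.02)
  ts <- trackCells(scene$detections, trackerConfig())
  tt <- trackTable(ts)
  # each id appears in one contiguous run per frame (no duplicate id in a frame)
  perFrame <- split(tt$track_id, tt$frame)
  for (ids in perFrame) expect_equal(anyDuplicated(ids), 0)
  # every child's parent exists; generation increments along lineage
  withParent <- tt[!is.na(tt$parent_id), ]
  if (nrow(withParent)) {
    for (r in which(!duplicated(withParent$track_id))) {
      pid <- withParent$parent_id[r]
      expect_true(pid %in% tt$track_id)
      expect_equal(withParent$generation[r],
                   tt$generation[tt$track_id == pid][1] + 1L)
    }
  }
})

test_that("tracking is deterministic for identical inputs", {
  scene <- genScene(8, motionModel("persistent", speed = 2, phi = 0.8),
                    T = 20, imageSize = c(640, 512), seed = 77)
  a <- trackCells(scene$detections, trackerConfig())
  b <- trackCells(scene$detections, trackerConfig())
  expect_identical(trackTable(a), trackTable(b))
  expect_identical(lineageEvents(a), lineageEvents(b))
  expect_identical(frameMetrics(a), frameMetrics(b))
})

test_that("well-separated cells track perfectly", {
  # inter-cell spacing far above twice the gate, no divisions or dropouts
  scene <- genScene(9, motionModel("brownian", sigma = 2), T = 30,
                    imageSize = c(1024, 1024), seed = 55)
  ts <- trackCells(scene$detections, trackerConfig())
  ev <- evaluateTracking(ts, scene$truth)
  expect_equal(ev$identity_preservation, 1)
  expect_equal(ev$id_switches, 0L)
})
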