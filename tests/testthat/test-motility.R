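test_that("nearest-neighbour linking honours the per-step displacement bound", {
  # consecutive centroids 5.2 um apart: linked into one track
  two <- function(d) list(matrix(c(0, 0), 1), matrix(c(d, 0), 1))
  t1 <- linkTrajectories(two(5.2), maxStepUm = 10)
  expect_length(t1, 1)
  expect_equal(nrow(t1[[1]]), 2)
  # 10.4 um exceeds the bound: two tracks
  t2 <- linkTrajectories(two(10.4), maxStepUm = 10)
  expect_length(t2, 2)
  # exactly at the bound: still linked (constraint is 'within')
  t3 <- linkTrajectories(two(10), maxStepUm = 10)
  expect_length(t3, 1)
  expect_error(linkTrajectories(two(1), maxStepUm = -1), "non-negative")
})

test_that("gaps up to two frames are bridged by collinear interpolation", {
  pts <- lapply(0:5, function(f)
    if (f %in% c(2, 3)) matrix(numeric(0), 0, 2) else matrix(c(3 * f, 0), 1))
  tr <- linkTrajectories(pts, maxStepUm = 10, maxGap = 2)
  expect_length(tr, 1)
  tj <- tr[[1]]
  expect_equal(nrow(tj), 6)
  expect_equal(tj$x, 3 * (0:5))            # interpolated points on the segment
  expect_equal(tj$interpolated, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  # a 3-frame gap is beyond the bridgeable window: two tracks
  pts3 <- lapply(0:6, function(f)
    if (f %in% 2:4) matrix(numeric(0), 0, 2) else matrix(c(2 * f, 0), 1))
  expect_length(linkTrajectories(pts3, maxStepUm = 10, maxGap = 2), 2)
})

test_that("kinematics: displacements, speeds, accelerations", {
  k <- kinematics(trajectory(x = c(0, 3), y = c(0, 4)))
  expect_equal(k$displacement, 5)
  expect_equal(k$speed, 5)
  expect_length(k$acceleration, 0)
  expect_equal(k$frame_interval_s, 350)
  # constant position
  k0 <- kinematics(trajectory(x = rep(1, 5), y = rep(2, 5)))
  expect_equal(k0$speed, rep(0, 4))
  # x_k = k^2: speeds 1, 3, 5, ...; accelerations all 2
  n <- 8
  kq <- kinematics(trajectory(x = (0:(n - 1))^2, y = rep(0, n)))
  expect_equal(kq$speed, seq(1, by = 2, length.out = n - 1))
  expect_equal(kq$acceleration, rep(2, n - 2))
  expect_error(kinematics(trajectory(x = 1, y = 1)), "at least 2")
})

test_that("straight runs and closed loops bracket the angle metrics", {
  line <- lineTrajectory(n = 8, step = 2)
  m <- motilityMetrics(line)
  expect_equal(m$directional_persistence, 1)
  expect_equal(m$meandering_index, 1)
  expect_equal(m$directionality_ratio, 1)
  expect_equal(m$mean_turning_angle_deg, 0)
  # closed unit-square loop: net displacement 0, three right-angle turns
  sqr <- trajectory(x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  ms <- motilityMetrics(sqr)
  expect_equal(ms$meandering_index, 0)
  expect_equal(ms$mean_turning_angle_deg, 90)
  expect_equal(ms$directional_persistence, 0, tolerance = 1e-12)
})

test_that("from-origin MSD matches the closed form", {
  # unit-speed 1-D path, T = 3 steps: (1 + 4 + 9) / 3
  tj <- trajectory(x = 0:3, y = rep(0, 4))
  expect_equal(motilityMetrics(tj)$msd, 14 / 3)
})

test_that("arrest coefficient counts sub-threshold steps", {
  # speeds 0.1, 0.1, 0.3, 0.3 at the printed 0.2 um/frame threshold
  x <- cumsum(c(0, 0.1, 0.1, 0.3, 0.3))
  tj <- trajectory(x = x, y = rep(0, 5))
  expect_equal(motilityMetrics(tj)$arrest_coefficient, 0.5)
  # monotone non-decreasing in the threshold
  set.seed(4)
  rw <- trajectory(x = cumsum(rnorm(40, 0, 0.3)), y = cumsum(rnorm(40, 0, 0.3)))
  ths <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  arr <- vapply(ths, function(th)
    motilityMetrics(rw, arrestThresholdUm = th)$arrest_coefficient, numeric(1))
  expect_true(all(diff(arr) >= 0))
})

test_that("radius of gyration equals a for two points at +/- a", {
  tj <- trajectory(x = c(-3.5, 3.5), y = c(0, 0))
  expect_equal(motilityMetrics(tj)$radius_of_gyration, 3.5)
})

test_that("stationary trajectories report angle metrics as missing", {
  tj <- trajectory(x = rep(0, 6), y = rep(0, 6))
  m <- motilityMetrics(tj)
  expect_true(is.na(m$directional_persistence))
  expect_true(is.na(m$mean_turning_angle_deg))
  expect_true(is.na(m$meandering_index))
  expect_true(is.na(m$relative_motion_change))
  expect_equal(m$arrest_coefficient, 1)
})

test_that("metrics are invariant to rigid motions of the trajectory", {
  set.seed(12)
  x <- cumsum(rnorm(30)); y <- cumsum(rnorm(30))
  tj <- trajectory(x = x, y = y)
  m0 <- motilityMetrics(tj)
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y + 100
  yr <- sin(th) * x + cos(th) * y - 50
  m1 <- motilityMetrics(trajectory(x = xr, y = yr))
  for (f in c("msd", "directional_persistence", "meandering_index",
              "mean_turning_angle_deg", "radius_of_gyration",
              "arrest_coefficient", "mean_speed", "mean_acceleration"))
    expect_equal(m1[[f]], m0[[f]], tolerance = 1e-9, label = f)
})

test_that("lag-resolved MSD of a Brownian walk grows linearly", {
  # modest in-suite version of the random-walk diagnostic
  sigma <- 1.5
  curves <- withr::with_seed(99, {
    vapply(1:150, function(i) {
      tj <- trajectory(x = cumsum(c(0, rnorm(63, 0, sigma))),
                       y = cumsum(c(0, rnorm(63, 0, sigma))))
      msdLag(tj, maxLag = 16)$msd
    }, numeric(16))
  })
  avg <- rowMeans(curves)
  slope <- coef(lm(avg ~ seq_len(16)))[[2]]
  expect_equal(slope, 2 * sigma^2, tolerance = 0.1)
})

test_that("dynamic and static aggregation summarize per track and per frame", {
  # one track at constant speed v
  v <- 2.5
  t1 <- trajectory(x = v * (0:5), y = rep(0, 6), track_id = 1L)
  dyn <- aggregateTracks(list(t1), "dynamic")
  expect_equal(dyn$mean_speed, v)
  stat <- aggregateTracks(list(t1), "static")
  expect_equal(stat$mean_speed, rep(v, 5))
  # two fully overlapping tracks with speeds 1 and 3: static mean 2
  t2 <- trajectory(x = 1 * (0:5), y = rep(0, 6), track_id = 2L)
  t3 <- trajectory(x = 3 * (0:5), y = rep(1, 6), track_id = 3L)
  st <- aggregateTracks(list(t2, t3), "static")
  expect_equal(st$mean_speed, rep(2, 5))
  expect_equal(st$n_cells, rep(2L, 5))
  # staggered tracks: frames where only one cell moves use that cell alone
  t4 <- trajectory(x = c(0, 1, 2), y = c(0, 0, 0), frame = 0:2, track_id = 4L)
  t5 <- trajectory(x = c(0, 5, 10), y = c(5, 5, 5), frame = 2:4, track_id = 5L)
  st2 <- aggregateTracks(list(t4, t5), "static")
  expect_equal(st2$frame, c(1, 2, 3, 4))
  expect_equal(st2$mean_speed, c(1, 1, 5, 5))
  expect_error(aggregateTracks(list(), "dynamic"), "empty")
})
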