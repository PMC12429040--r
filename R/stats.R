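#' Autocorrelation-corrected non-parametric statistics for metric series
#'
#' Tools for comparing k experimental series of one frame-level metric:
#' moving-average smoothing, lag-1 autocorrelation and Bartlett effective
#' sample size, the effective-sample-size-corrected and permutation Friedman
#' tests over sliding windows, Conover-Holm post hoc comparisons, bootstrap
#' confidence intervals and distributional distances.
#'
#' @name timeseries-stats
NULL

#' Centered moving average
#'
#' Only positions with a full window are emitted, so the output has length
#' `length(x) - w + 1`.
#'
#' @param x numeric series.
#' @param w window length (default 15 frames).
#' @return smoothed series.
#' @export
movingAverage <- function(x, w = 15) {
  w <- as.integer(w)
  if (w < 1L) stop("window length must be >= 1", call. = FALSE)
  if (w > length(x)) stop("window length exceeds series length", call. = FALSE)
  as.numeric(zoo::rollmean(zoo::zoo(x), w, align = "center"))
}

#' Lag-1 autocorrelation
#'
#' The ratio of the sum of adjacent products about the mean to the sum of
#' squares about the mean:
#' \deqn{Q = \frac{\sum_{t=1}^{N-1}(X_t - \bar X)(X_{t+1} - \bar X)}
#'            {\sum_{t=1}^{N}(X_t - \bar X)^2}}
#'
#' @param x numeric series of length >= 3 with nonzero variance.
#' @return Q in `[-1, 1]`.
#' @export
lag1Autocorrelation <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  d <- x - mean(x)
  den <- sum(d^2)
  if (den <= 0) stop("undefined autocorrelation: zero variance", call. = FALSE)
  sum(d[-n] * d[-1L]) / den
}

#' Bartlett effective sample size
#'
#' \eqn{N_{eff} = N (1 - Q) / (1 + Q)} for an approximate AR(1) process
#' with lag-1 autocorrelation Q. Q is clamped to `[0, 0.99]` first: a
#' negative Q would inflate the sample size (anti-conservative), and the
#' upper clamp keeps the result positive.
#'
#' @param N number of blocks (>= 2).
#' @param Q lag-1 autocorrelation.
#' @return effective sample size, monotone decreasing in Q.
#' @export
effectiveSampleSize <- function(N, Q) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  Q <- min(max(Q, 0), 0.99)
  N * (1 - Q) / (1 + Q)
}

# Classical Friedman statistic with mid-ranks and tie correction, matching
# stats::friedman.test.
friedmanStatistic <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  r <- t(apply(mat, 1L, rank))
  ties <- tapply(r, row(r), table)
  denom <- n * k * (k + 1) -
    sum(unlist(lapply(ties, function(u) u^3 - u))) / (k - 1)
  if (denom <= 0) return(list(stat = 0, colsums = colSums(r), ranks = r,
                              denom = denom))
  stat <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  list(stat = stat, colsums = colSums(r), ranks = r, denom = denom)
}

# Per-series lag-1 Q of a window, averaged over series and clamped to
# [0, 0.99]; series with zero variance contribute nothing.
panelLag1Q <- function(mat) {
  qs <- apply(mat, 2L, function(x)
    tryCatch(lag1Autocorrelation(x), error = function(e) NA_real_))
  q <- mean(qs, na.rm = TRUE)
  if (!is.finite(q)) q <- 0
  min(max(q, 0), 0.99)
}

#' Effective-sample-size-corrected Friedman test
#'
#' Treats each frame position within the window as a block and each series
#' as a treatment. The classical (tie-corrected, mid-rank) Friedman
#' statistic over the N blocks is scaled by `N_eff / N` before the
#' chi-square lookup with `k - 1` degrees of freedom, the standard
#' variance-inflation remedy for serial dependence; at Q = 0 it reduces to
#' the classical test. Windows with `N_eff < 3` are reported as untestable
#' (`p_asymptotic = NA`).
#'
#' @param mat numeric N x k matrix: N blocks (frames) by k treatments
#'   (series), k >= 2, N >= 3.
#' @param Q optional panel lag-1 autocorrelation; by default the mean of
#'   the per-series lag-1 values of the window, clamped to `[0, 0.99]`.
#' @return list `stat` (classical), `stat_corrected`, `df`, `p_asymptotic`,
#'   `n`, `n_eff`, `panel_q`.
#' @export
friedmanNeff <- function(mat, Q = NULL) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop("need k >= 2 treatments", call. = FALSE)
  if (n < 3L) stop("need N >= 3 blocks", call. = FALSE)
  fr <- friedmanStatistic(mat)
  q <- if (is.null(Q)) panelLag1Q(mat) else min(max(Q, 0), 0.99)
  neff <- effectiveSampleSize(n, q)
  statc <- fr$stat * neff / n
  p <- if (neff < 3) NA_real_ else pchisq(statc, df = k - 1, lower.tail = FALSE)
  list(stat = fr$stat, stat_corrected = statc, df = k - 1L,
       p_asymptotic = p, n = n, n_eff = neff, panel_q = q)
}

#' Permutation Friedman test
#'
#' Empirical null distribution from `B` independent uniform permutations of
#' the k treatment labels within each block;
#' \eqn{p = (1 + \#\{stat^* \ge stat\}) / (B + 1)} (add-one estimator, so
#' the attainable minimum is `1/(B+1)`). Seeded and reproducible.
#'
#' @inheritParams friedmanNeff
#' @param B number of permutations (default 1000).
#' @param seed RNG seed.
#' @return permutation p-value.
#' @export
friedmanPermutation <- function(mat, B = 1000, seed = NULL) {
  mat <- as.matrix(mat)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop("need k >= 2 treatments", call. = FALSE)
  fr <- friedmanStatistic(mat)
  if (fr$denom <= 0) return(1)   # fully tied panel: every permutation ties
  obs <- fr$stat
  center <- n * (k + 1) / 2
  nB <- n * as.integer(B)
  stats <- withSeed(seed, {
    u <- matrix(runif(nB * k), nB, k)
    # per-row ranks of u = uniformly random permutations of 1..k
    p <- matrix(1L, nB, k)
    for (a in seq_len(k)) for (b in seq_len(k)) if (b != a)
      p[, a] <- p[, a] + (u[, b] < u[, a])
    block <- rep.int(seq_len(n), as.integer(B))
    v <- matrix(fr$ranks[cbind(rep(block, k), as.vector(p))], nB, k)
    rj <- rowsum(v, rep(seq_len(as.integer(B)), each = n))
    12 * rowSums((rj - center)^2) / fr$denom
  })
  (1 + sum(stats >= obs - 1e-9)) / (B + 1)
}

#' Conover post hoc comparisons with Holm correction
#'
#' Conover-Iman pairwise rank comparisons on the within-block ranks for all
#' `k(k-1)/2` treatment pairs, with Holm step-down family-wise error
#' control. Intended to be run only when the omnibus Friedman test is
#' significant (the sliding scan enforces this).
#'
#' @inheritParams friedmanNeff
#' @param alpha significance level recorded on the result (default 0.05).
#' @return k x k symmetric matrix of Holm-adjusted p-values (diagonal NA),
#'   with attribute `raw` holding the unadjusted matrix.
#' @export
conoverHolm <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop("need k >= 2 treatments", call. = FALSE)
  fr <- friedmanStatistic(mat)
  r <- fr$ranks
  Rsum <- colSums(r)
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  raw <- matrix(NA_real_, k, k, dimnames = list(colnames(mat), colnames(mat)))
  if (A1 - C1 <= 1e-12) {
    # all blocks fully tied: no discrimination possible
    praw <- rep(1, nrow(pairs))
  } else {
    T2 <- (k - 1) * sum((Rsum - n * (k + 1) / 2)^2) / (A1 - C1)
    fac <- 1 - T2 / (n * (k - 1))
    dfree <- (n - 1) * (k - 1)
    se2 <- (A1 - C1) * 2 * n / dfree * fac
    praw <- vapply(seq_len(nrow(pairs)), function(idx) {
      i <- pairs[idx, 1L]; j <- pairs[idx, 2L]
      dif <- abs(Rsum[i] - Rsum[j])
      if (se2 <= 0) return(if (dif > 1e-9) 0 else 1)
      2 * pt(dif / sqrt(se2), df = dfree, lower.tail = FALSE)
    }, numeric(1))
  }
  padj <- stats::p.adjust(praw, method = "holm")
  for (idx in seq_len(nrow(pairs))) {
    i <- pairs[idx, 1L]; j <- pairs[idx, 2L]
    raw[i, j] <- raw[j, i] <- padj[idx]
  }
  attr(raw, "raw") <- praw
  attr(raw, "alpha") <- alpha
  raw
}

#' Sliding-window Friedman scan of a series panel
#'
#' Smooths each series with a centered moving average and slides a window
#' of `windowW` blocks across the panel. Each window is tested twice: the
#' effective-sample-size-corrected Friedman test runs on the smoothed
#' values (whose serial dependence the Bartlett correction absorbs, often
#' by declaring heavily smoothed windows untestable), while the
#' permutation Friedman test runs on the raw values at the centers of the
#' same moving-average spans - smoothing makes blocks within a window
#' strongly dependent, which would break the within-block permutation
#' null, so the exact test must see the raw frames. Where the permutation
#' omnibus p is significant, Conover-Holm pairwise comparisons (on the
#' same raw window) are added. The long-form pairwise table (the heatmap
#' data) marks the windows in which treatment pairs reject.
#'
#' @param panel a [seriesPanel()].
#' @param maW moving-average width (default 15 frames).
#' @param windowW test window width in smoothed frames (default 15).
#' @param step window step (default 1).
#' @param B permutations per window (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed for the permutation tests.
#' @return a [WindowScan].
#' @export
slidingScan <- function(panel, maW = 15, windowW = 15, step = 1, B = 1000,
                        alpha = 0.05, seed = 1) {
  stopifnot(is(panel, "SeriesPanel"))
  vals <- panel@values
  Tn <- nrow(vals); k <- ncol(vals)
  need <- maW + windowW - 1
  if (Tn < need)
    stop(sprintf("series too short: %d frames given, >= %d required (maW + windowW - 1)",
                 Tn, need), call. = FALSE)
  sm <- apply(vals, 2L, movingAverage, w = maW)
  Ts <- nrow(sm)
  center <- (maW - 1L) %/% 2L   # raw frame at the center of an MA span
  starts <- seq(1L, Ts - windowW + 1L, by = step)
  rows <- vector("list", length(starts))
  posthoc <- vector("list", length(starts))
  sig <- list()
  pairIdx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pairNames <- paste(panel@seriesIds[pairIdx[, 1L]],
                     panel@seriesIds[pairIdx[, 2L]], sep = "-")
  for (wi in seq_along(starts)) {
    s <- starts[wi]
    win <- sm[s:(s + windowW - 1L), , drop = FALSE]
    raw <- vals[(s + center):(s + center + windowW - 1L), , drop = FALSE]
    ft <- friedmanNeff(win)
    pp <- friedmanPermutation(raw, B = B, seed = childSeed(seed, wi))
    # Window-level significance is decided by the raw-window permutation
    # p: within-block label permutation is exact for raw frames, whereas
    # smoothed blocks are mutually dependent (the corrected asymptotic
    # test on the smoothed window absorbs that dependence via N_eff,
    # typically by declaring such windows untestable).
    omnibus <- if (B >= 1) pp else ft$p_asymptotic
    nsig <- 0L
    if (!is.na(omnibus) && omnibus < alpha) {
      ph <- conoverHolm(raw, alpha = alpha)
      posthoc[[wi]] <- ph
      padj <- ph[pairIdx]
      nsig <- sum(padj < alpha, na.rm = TRUE)
      sig[[length(sig) + 1L]] <- data.frame(
        window_start = s - 1L, pair = pairNames, p_adjusted = padj,
        significant = padj < alpha)
    }
    rows[[wi]] <- data.frame(
      window_start = s - 1L, window_end = s + windowW - 2L,
      frame_start = panel@frames[s],
      frame_end = panel@frames[s + windowW - 1L + maW - 1L],
      n_blocks = ft$n, panel_q = ft$panel_q, n_eff = ft$n_eff,
      friedman_stat = ft$stat, friedman_stat_corrected = ft$stat_corrected,
      df = ft$df, p_asymptotic = ft$p_asymptotic, p_permutation = pp,
      n_significant_pairs = nsig)
  }
  sigDf <- if (length(sig)) do.call(rbind, sig) else
    data.frame(window_start = integer(0), pair = character(0),
               p_adjusted = numeric(0), significant = logical(0))
  rownames(sigDf) <- NULL
  new("WindowScan", windows = do.call(rbind, rows), posthoc = posthoc,
      pairSignificance = sigDf,
      params = list(ma_w = maW, window_w = windowW, step = step, B = B,
                    alpha = alpha, seed = seed))
}

#' Distributional distance between two samples
#'
#' Kolmogorov-Smirnov distance (supremum of the absolute ECDF difference)
#' or the 1-D Wasserstein (earth mover) distance computed as the integral
#' of the absolute ECDF difference.
#'
#' @param a,b numeric samples (nonempty).
#' @param kind `"ks"` or `"wasserstein"`.
#' @return non-negative distance.
#' @export
distributionDistance <- function(a, b, kind = c("ks", "wasserstein")) {
  kind <- match.arg(kind)
  if (length(a) == 0L || length(b) == 0L)
    stop("samples must be nonempty", call. = FALSE)
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  if (kind == "ks") return(max(abs(Fa - Fb)))
  ng <- length(grid)
  if (ng < 2L) return(0)
  sum(abs(Fa[-ng] - Fb[-ng]) * diff(grid))
}

#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples with replacement `B` times (default 10,000) and reports the
#' percentile interval of the resampled means. `level = 0` degenerates to
#' the point estimate.
#'
#' @param values numeric sample (length >= 2).
#' @param B number of resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list `estimate`, `lower`, `upper`, `B`, `level`, `seed`.
#' @export
bootstrapCI <- function(values, B = 10000, level = 0.95, seed = NULL) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (length(values) < 2L) stop("need at least 2 observations", call. = FALSE)
  est <- mean(values)
  if (level <= 0)
    return(list(estimate = est, lower = est, upper = est, B = as.integer(B),
                level = level, seed = seed))
  n <- length(values)
  means <- withSeed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), as.integer(B), n)
    rowMeans(matrix(values[idx], as.integer(B), n))
  })
  qq <- quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(estimate = est, lower = qq[1L], upper = qq[2L], B = as.integer(B),
       level = level, seed = seed)
}
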