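# Chromosome partitioning: sliding-window density tracks with Z-scores,
# named region assignment, Gaussian mean-change binary segmentation with a
# BIC penalty, per-region feature comparisons (Welch), and centromere
# gradients (Spearman).

#' Default region table
#'
#' Five named regions (R1, R2a, C, R2b, R3) at boundaries proportional to
#' the canonical wheat-3B partitioning (1/68/265/387/715/774.4 Mb on a
#' 774.4 Mb chromosome), rescaled to the requested chromosome length. C is
#' the centromeric-pericentromeric core.
#'
#' @param chrom_length chromosome length in bp.
#' @return data.frame(name, start, end) in bp; regions tile `[0, L]`.
#' @export
default_regions <- function(chrom_length = 774.4e6) {
  b <- c(0, 68, 265, 387, 715, 774.4) / 774.4 * chrom_length
  data.frame(name = c("R1", "R2a", "C", "R2b", "R3"),
             start = b[-6L], end = b[-1L], stringsAsFactors = FALSE)
}

#' Sliding-window feature density track
#'
#' Windows start at 0 and advance by `step`; the window count is
#' `floor((L - window) / step) + 1`. A feature is assigned to a window when
#' its midpoint falls in the half-open interval `[w_start, w_start +
#' window)`, so a midpoint on a boundary counts in the right-hand window
#' only. Value = features per Mb of window.
#'
#' @param intervals data.frame with `start`, `end` (bp, 1-based inclusive);
#'   midpoints are `floor((start + end) / 2)`.
#' @param chrom_length chromosome length L in bp.
#' @param window,step window and step sizes in bp (defaults 10 Mb / 1 Mb).
#' @param chrom chromosome name for the track.
#' @return data.frame(chrom, start, end, n, value) — a window track; pass
#'   through [track_zscore()] to add Z-scores.
#' @export
windowed_density <- function(intervals, chrom_length, window = 1e7,
                             step = 1e6, chrom = "chr") {
  if (any(intervals$start < 1 | intervals$end > chrom_length))
    stopf("interval outside [1, %s]", format(chrom_length))
  if (window > chrom_length) {
    warnf("window larger than the chromosome: using one whole-chromosome window")
    window <- chrom_length
    step <- chrom_length
  }
  n_win <- floor((chrom_length - window) / step) + 1
  ws <- (seq_len(n_win) - 1) * step
  mid <- floor((intervals$start + intervals$end) / 2)
  n <- vapply(ws, function(w) sum(mid >= w & mid < w + window), 0)
  data.frame(chrom = chrom, start = ws, end = ws + window, n = n,
             value = n / (window / 1e6), stringsAsFactors = FALSE)
}

#' Add Z-scores to a window track
#'
#' `z = (v - mean) / sd` over windows, with the sample (n-1) standard
#' deviation; a zero-variance track gets all-zero Z-scores.
#'
#' @param track data.frame with a `value` column (>= 2 rows).
#' @return the track with a `zscore` column appended.
#' @export
track_zscore <- function(track) {
  v <- track$value
  if (length(v) < 2L) stopf("need at least 2 windows")
  s <- stats::sd(v)
  track$zscore <- if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  track
}

#' Assign positions to named regions
#'
#' Membership is half-open `[start, end)` except the last region, which is
#' right-closed so the chromosome end belongs to it.
#'
#' @param position numeric vector of bp positions in `[0, L]`.
#' @param regions data.frame(name, start, end) tiling `[0, L]`.
#' @return character vector of region names.
#' @export
assign_region <- function(position, regions) {
  L <- max(regions$end)
  if (any(position < min(regions$start) | position > L))
    stopf("position outside the chromosome [%s, %s]",
          format(min(regions$start)), format(L))
  idx <- findInterval(position, regions$start)
  idx[position >= L] <- nrow(regions)
  regions$name[idx]
}

#' Binary-segmentation changepoint detection (mean change, BIC penalty)
#'
#' Recursively finds the split minimizing the residual sum of squares under
#' a two-mean Gaussian model; a split is accepted when twice the
#' log-likelihood improvement exceeds `beta = 2 * log(n)` (BIC for one
#' additional mean parameter plus the changepoint location). The noise
#' variance is estimated once, globally, from first differences
#' (`sum(diff(x)^2) / (2 (n-1))`), which is robust to the mean shifts
#' themselves. Changepoints are therefore invariant under affine transforms
#' of the series.
#'
#' @param series numeric vector (length >= 4).
#' @param min_seg minimum segment length (default 2).
#' @return list(changepoints, segment_means, penalty, sigma2, method):
#'   `changepoints` are the last indices of each segment but the final one
#'   (strictly increasing, interior).
#' @export
binary_segmentation <- function(series, min_seg = 2L) {
  n <- length(series)
  empty <- function(s2) list(changepoints = integer(0),
                             segment_means = mean(series),
                             penalty = 2 * log(n), sigma2 = s2,
                             method = "BinSeg mean-change BIC")
  if (n < 4L) return(empty(NA_real_))
  sigma2 <- sum(diff(series)^2) / (2 * (n - 1))
  if (sigma2 == 0) return(empty(0))
  beta <- 2 * log(n)

  best_split <- function(lo, hi) {
    x <- series[lo:hi]
    m <- length(x)
    if (m < 2L * min_seg) return(NULL)
    cs <- cumsum(x); tot <- cs[m]
    k <- min_seg:(m - min_seg)                 # last index of the left part
    rss1 <- (cumsum(x^2)[m]) - cs[k]^2 / k - (tot - cs[k])^2 / (m - k)
    rss0 <- sum(x^2) - tot^2 / m
    gain <- (rss0 - rss1) / sigma2             # 2 * delta logLik
    i <- which.max(gain)
    if (gain[i] > beta) lo + k[i] - 1L else NULL
  }
  cps <- integer(0)
  recurse <- function(lo, hi) {
    k <- best_split(lo, hi)
    if (is.null(k)) return()
    cps <<- c(cps, k)
    recurse(lo, k)
    recurse(k + 1L, hi)
  }
  recurse(1L, n)
  cps <- sort(cps)
  bounds <- c(0L, cps, n)
  means <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(series[(bounds[i] + 1L):bounds[i + 1L]]), 0)
  list(changepoints = cps, segment_means = means, penalty = beta,
       sigma2 = sigma2, method = "BinSeg mean-change BIC")
}

#' Segment a window track
#'
#' Runs [binary_segmentation()] on the track values (the overlapping-window
#' series itself, so windows are autocorrelated — segment borders are
#' interpreted at window resolution) and reports changepoints in bp as the
#' start of the window following each changepoint.
#'
#' @param track data.frame from [windowed_density()].
#' @param column which column to segment (default `"value"`).
#' @return list as in [binary_segmentation()] plus `changepoint_bp`.
#' @export
segment_track <- function(track, column = "value") {
  res <- binary_segmentation(track[[column]])
  res$changepoint_bp <- track$start[res$changepoints + 1L]
  res
}

#' Per-region feature summaries and pairwise Welch tests
#'
#' Genes are assigned to regions by their midpoint. For every feature
#' column, reports per-region n, mean, SD and quartiles, plus the Welch
#' two-sample t statistic and two-sided p for every region pair. Regions
#' with fewer than 2 genes are summarised but excluded from testing.
#'
#' @param features data.frame with `start`, `end` and numeric feature
#'   columns (any other non-numeric columns are ignored).
#' @param regions data.frame(name, start, end).
#' @return list(summary, tests) data.frames.
#' @export
region_feature_stats <- function(features, regions) {
  mid <- (features$start + features$end) / 2
  reg <- assign_region(mid, regions)
  feat_cols <- names(features)[vapply(features, is.numeric, NA)]
  feat_cols <- setdiff(feat_cols, c("start", "end"))
  summ <- list(); tests <- list()
  for (f in feat_cols) {
    for (r in regions$name) {
      v <- features[[f]][reg == r]
      q <- if (length(v)) stats::quantile(v, c(.25, .5, .75), names = FALSE,
                                          type = 7) else rep(NA_real_, 3L)
      summ[[length(summ) + 1L]] <- data.frame(
        feature = f, region = r, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        q1 = q[1L], median = q[2L], q3 = q[3L], stringsAsFactors = FALSE)
    }
    rn <- regions$name
    for (a in seq_len(length(rn) - 1L)) for (b in (a + 1L):length(rn)) {
      va <- features[[f]][reg == rn[a]]
      vb <- features[[f]][reg == rn[b]]
      if (length(va) < 2L || length(vb) < 2L) {
        tests[[length(tests) + 1L]] <- data.frame(
          feature = f, region_a = rn[a], region_b = rn[b],
          t = NA_real_, p = NA_real_, note = "skipped: n < 2",
          stringsAsFactors = FALSE)
        next
      }
      if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
        eq <- mean(va) == mean(vb)
        tests[[length(tests) + 1L]] <- data.frame(
          feature = f, region_a = rn[a], region_b = rn[b],
          t = if (eq) 0 else Inf, p = if (eq) 1 else 0, note = "degenerate",
          stringsAsFactors = FALSE)
        next
      }
      tt <- stats::t.test(va, vb, var.equal = FALSE)
      tests[[length(tests) + 1L]] <- data.frame(
        feature = f, region_a = rn[a], region_b = rn[b],
        t = unname(tt$statistic), p = tt$p.value, note = "",
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summ), tests = do.call(rbind, tests))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranked values; p is the two-sided
#' t approximation with n-2 degrees of freedom. A constant input vector
#' yields an undefined rho, flagged with a warning.
#'
#' @param values,distances paired numeric vectors (n >= 4), e.g. a window
#'   density and the window distance to the centromere.
#' @return list(rho, p, n).
#' @export
spearman_gradient <- function(values, distances) {
  n <- length(values)
  if (n < 4L || length(distances) != n)
    stopf("need paired vectors of length >= 4")
  if (stats::sd(values) == 0 || stats::sd(distances) == 0) {
    warnf("constant vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(values), rank(distances))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2), n = n)
}

#' Goodness-of-fit of one windowed count track to another
#'
#' Chi-square goodness-of-fit of observed window counts (e.g. expressed
#' genes) to the proportions of a reference track (e.g. predicted genes)
#' over the same windows. Windows where the reference is empty are dropped.
#'
#' @param obs_counts,ref_counts non-negative integer vectors per window.
#' @return list(statistic, df, p).
#' @export
window_count_gof <- function(obs_counts, ref_counts) {
  keep <- ref_counts > 0
  obs <- obs_counts[keep]; ref <- ref_counts[keep]
  ct <- suppressWarnings(stats::chisq.test(obs, p = ref / sum(ref)))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
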