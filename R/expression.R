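# Expression profiles: breadth, level classes, organ specificity, the
# 30-bin expression-vs-structure analysis with inflexion detection, and the
# quartile-based outlier statistic.

#' Per-locus expression profiles
#'
#' Breadth is the number of conditions with FPKM above the floor; the mean
#' expression level averages only the conditions where the locus is
#' expressed. Level classes follow the FPKM scale commonly used for
#' semi-quantitative RNA-seq work: low `< 5`, medium `[5, 200)`, high
#' `>= 200` FPKM. A locus is organ-specific when all its expressed
#' conditions belong to a single organ.
#'
#' @param mat FPKM matrix (loci x conditions).
#' @param level_cuts numeric length 2: low/medium and medium/high FPKM cuts
#'   (default `c(5, 200)`).
#' @param fpkm_floor expression floor (default 0, i.e. expressed means
#'   FPKM > 0).
#' @return data.frame(locus_id, breadth, expressed, mean_expr, level_class,
#'   organ_specific).
#' @export
profile_expression <- function(mat, level_cuts = c(5, 200), fpkm_floor = 0) {
  ci <- condition_info(mat)
  pos <- mat > fpkm_floor
  breadth <- rowSums(pos)
  mean_expr <- vapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, pos[i, ]]
    if (length(v)) mean(v) else 0
  }, 0)
  level_class <- rep(NA_character_, nrow(mat))
  expressed <- breadth > 0
  level_class[expressed & mean_expr < level_cuts[1L]] <- "low"
  level_class[expressed & mean_expr >= level_cuts[1L] &
                mean_expr < level_cuts[2L]] <- "medium"
  level_class[expressed & mean_expr >= level_cuts[2L]] <- "high"
  organ_specific <- vapply(seq_len(nrow(mat)), function(i) {
    if (!expressed[i]) return(NA_character_)
    organs <- unique(ci$organ[pos[i, ]])
    if (length(organs) == 1L && !is.na(organs)) organs else NA_character_
  }, "")
  data.frame(locus_id = rownames(mat), breadth = as.integer(breadth),
             expressed = expressed, mean_expr = mean_expr,
             level_class = level_class, organ_specific = organ_specific,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Breadth distribution by gene category
#'
#' For each category (a named list of locus ids: e.g. full genes,
#' pseudogenes, syntenic, non-syntenic, cis-NAT genes), the percentage of
#' expressed loci at each breadth 1..n_conditions. Percentages sum to 100
#' within a category; empty categories are omitted with a warning.
#'
#' @param profiles data.frame from [profile_expression()].
#' @param categories named list of character vectors of locus ids.
#' @param n_conditions number of conditions (default: max breadth observed).
#' @return long data.frame(category, breadth, n, pct).
#' @export
breadth_distribution <- function(profiles, categories, n_conditions = NULL) {
  n_conditions <- n_conditions %||% max(profiles$breadth, 1L)
  out <- list()
  for (nm in names(categories)) {
    sel <- profiles[profiles$locus_id %in% categories[[nm]] &
                      profiles$breadth >= 1L, , drop = FALSE]
    if (!nrow(sel)) {
      warnf("category '%s' has no expressed loci; omitted", nm)
      next
    }
    tab <- tabulate(sel$breadth, nbins = n_conditions)
    out[[nm]] <- data.frame(category = nm, breadth = seq_len(n_conditions),
                            n = tab, pct = pct1(tab, nrow(sel)),
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Equal-size expression bins with per-bin structural feature statistics
#'
#' Expressed loci are ranked by mean expression level (ties broken by stable
#' locus-id order) and split into `n_bins` contiguous rank blocks whose
#' sizes differ by at most one. For every structural feature column the
#' per-bin mean and standard deviation are reported, along with the per-bin
#' mean expression and breadth.
#'
#' @param profiles data.frame from [profile_expression()] (expressed loci
#'   are selected internally).
#' @param structures data.frame from [structure_features()] keyed by
#'   `gene_id`; every expressed locus must be present.
#' @param n_bins number of bins (default 30).
#' @return long data.frame(bin, n, feature, mean, sd) plus rows for
#'   `mean_expr` and `breadth`; attribute `members` holds the per-bin locus
#'   ids.
#' @export
bin_by_expression <- function(profiles, structures, n_bins = 30) {
  pr <- profiles[profiles$expressed, , drop = FALSE]
  pr <- pr[pr$locus_id %in% structures$gene_id, , drop = FALSE]
  n <- nrow(pr)
  if (n < n_bins)
    stopf("fewer expressed loci (%d) than bins (%d)", n, n_bins)
  pr <- pr[order(pr$mean_expr, pr$locus_id, method = "radix"), , drop = FALSE]
  base <- n %/% n_bins; rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin <- rep(seq_len(n_bins), times = sizes)
  st <- structures[match(pr$locus_id, structures$gene_id), , drop = FALSE]
  feats <- setdiff(names(st), "gene_id")
  vals <- cbind(st[feats], mean_expr = pr$mean_expr, breadth = pr$breadth)
  out <- list()
  for (f in names(vals)) {
    m <- tapply(vals[[f]], bin, mean)
    s <- tapply(vals[[f]], bin, stats::sd)
    out[[f]] <- data.frame(bin = as.integer(names(m)), n = as.integer(sizes),
                           feature = f, mean = as.numeric(m),
                           sd = as.numeric(s), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  attr(df, "members") <- split(pr$locus_id, bin)
  df
}

#' Locate the inflexion (maximum) of a binned feature curve
#'
#' Smooths the per-bin means with a 3-bin moving average (shorter at the
#' edges) and returns the argmax bin. When the maximum sits on the first or
#' last bin there is no interior maximum and the curve is flagged monotone.
#'
#' @param bins data.frame from [bin_by_expression()].
#' @param feature feature name to analyse.
#' @return list(bin, monotone, smoothed).
#' @export
detect_inflexion <- function(bins, feature) {
  sel <- bins[bins$feature == feature, , drop = FALSE]
  if (!nrow(sel)) stopf("feature '%s' not present in bins", feature)
  sel <- sel[order(sel$bin), , drop = FALSE]
  y <- sel$mean
  n <- length(y)
  if (n < 5L) stopf("need at least 5 bins, got %d", n)
  sm <- vapply(seq_len(n), function(i)
    mean(y[max(1L, i - 1L):min(n, i + 1L)]), 0)
  idx <- which.max(sm)
  list(bin = sel$bin[idx], monotone = idx == 1L || idx == n, smoothed = sm)
}

#' Quartile-based outlier statistic
#'
#' Reports the first and third quartiles (type-7 linear interpolation; the
#' statistic depends on the quartile method, so it is fixed and documented),
#' the spread statistic `(Q3 - Q1) * 3 / Q3`, and a conventional flagging
#' rule: values above `Q3 + 3 * (Q3 - Q1)` are marked as outliers.
#'
#' @param values numeric vector with at least 4 positive values.
#' @return list(q1, q3, statistic, fence, outlier) where `outlier` is a
#'   logical vector aligned with `values`.
#' @export
outlier_statistic <- function(values) {
  if (sum(values > 0, na.rm = TRUE) < 4L)
    stopf("need at least 4 positive values")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  q1 <- q[1L]; q3 <- q[2L]
  statistic <- if (q3 == 0) {
    warnf("Q3 = 0: outlier statistic undefined")
    NA_real_
  } else (q3 - q1) * 3 / q3
  fence <- q3 + 3 * (q3 - q1)
  list(q1 = q1, q3 = q3, statistic = statistic, fence = fence,
       outlier = !is.na(values) & values > fence)
}
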