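# Co-expression clustering, gene islands (insulae), co-expressed neighbour
# pairs with orientation classes, cluster-by-region composition tests, and
# generic Fisher term enrichment.

#' Critical Pearson correlation at a significance level
#'
#' The two-sided critical value `r = t / sqrt(t^2 + n - 2)` with `t` the
#' `1 - alpha/2` Student-t quantile at `n - 2` degrees of freedom. With 15
#' conditions and alpha 0.01 this is 0.641 — the similarity cut used for
#' profile clustering.
#'
#' @param n number of paired observations (>= 4).
#' @param alpha two-sided significance level.
#' @return the critical correlation coefficient.
#' @export
critical_pearson <- function(n, alpha = 0.01) {
  if (n < 4L) stopf("need n >= 4")
  tq <- stats::qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(tq^2 + n - 2)
}

#' Hierarchical co-expression clustering with a similarity cut
#'
#' Agglomerative complete-linkage clustering on distance `1 - Pearson`
#' between expression profiles, with the dendrogram cut at distance
#' `1 - cut_similarity` (default similarity 0.641, the critical Pearson at
#' alpha 0.01 for 15 conditions). Complete linkage at that cut implies
#' every within-cluster pair correlates at least at the cut. Rows are
#' processed in locus-id order so the result is deterministic. Loci with
#' zero-variance profiles (Pearson undefined) are placed in a reserved
#' cluster 0 and excluded from similarity computations.
#'
#' @param mat FPKM matrix (expressed loci x conditions).
#' @param cut_similarity minimum within-cluster similarity.
#' @return data.frame(locus_id, cluster); attribute `k` holds the number of
#'   non-reserved clusters.
#' @export
cluster_profiles <- function(mat, cut_similarity = 0.641) {
  mat <- mat[id_order(rownames(mat)), , drop = FALSE]
  if (nrow(mat) < 2L) {
    out <- data.frame(locus_id = rownames(mat),
                      cluster = rep(1L, nrow(mat)), stringsAsFactors = FALSE)
    attr(out, "k") <- nrow(mat)
    return(out)
  }
  sds <- apply(mat, 1L, stats::sd)
  const <- sds == 0
  cluster <- integer(nrow(mat))
  if (sum(!const) == 1L) {
    cluster[!const] <- 1L
  } else if (sum(!const) >= 2L) {
    cm <- stats::cor(t(mat[!const, , drop = FALSE]))
    d <- stats::as.dist(1 - cm)
    hc <- stats::hclust(d, method = "complete")
    cluster[!const] <- stats::cutree(hc, h = 1 - cut_similarity)
  }
  out <- data.frame(locus_id = rownames(mat), cluster = cluster,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "k") <- length(unique(cluster[cluster > 0L]))
  out
}

#' Detect insulae (gene islands)
#'
#' Maximal runs of two or more consecutive genes whose intergenic distances
#' (`start(next) - end(previous) - 1`) are at or below the gap threshold
#' (default 30 kb, the median intergenic distance scale). Singletons are not
#' insulae. Overlapping genes get distance 0 (clamped, with a warning) and
#' join the same island.
#'
#' @param genes_df data.frame(gene_id, chrom, start, end), one chromosome.
#' @param gap_threshold maximum intragenic-island gap in bp.
#' @return list(insulae, membership, stats): insulae as
#'   data.frame(insula_id, chrom, start, end, n_genes), membership mapping
#'   gene_id to insula_id (NA for isolated genes, in genomic order), and
#'   summary statistics from [insula_summary_stats()].
#' @export
detect_insulae <- function(genes_df, gap_threshold = 30000) {
  g <- genes_df[order(genes_df$start, genes_df$gene_id, method = "radix"), ,
                drop = FALSE]
  n <- nrow(g)
  gap <- if (n > 1L) g$start[-1L] - g$end[-n] - 1 else numeric(0)
  if (any(gap < 0)) {
    warnf("%d overlapping gene pair(s): distance clamped to 0", sum(gap < 0))
    gap[gap < 0] <- 0
  }
  linked <- gap <= gap_threshold
  run_id <- cumsum(c(1L, as.integer(!linked)))      # island id per gene
  sizes <- table(run_id)
  keep <- names(sizes)[sizes >= 2L]
  membership <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
    insula_id = ifelse(run_id %in% as.integer(keep),
                       paste0("insula_", match(run_id, as.integer(keep))),
                       NA_character_),
    stringsAsFactors = FALSE, row.names = NULL)
  ins <- membership[!is.na(membership$insula_id), , drop = FALSE]
  insulae <- if (nrow(ins)) {
    agg <- do.call(rbind, lapply(split(ins, ins$insula_id), function(d)
      data.frame(insula_id = d$insula_id[1L], chrom = d$chrom[1L],
                 start = min(d$start), end = max(d$end), n_genes = nrow(d),
                 stringsAsFactors = FALSE)))
    agg <- agg[order(agg$start), , drop = FALSE]
    rownames(agg) <- NULL
    agg
  } else data.frame(insula_id = character(0), chrom = character(0),
                    start = numeric(0), end = numeric(0),
                    n_genes = integer(0), stringsAsFactors = FALSE)
  list(insulae = insulae, membership = membership,
       stats = insula_summary_stats(nrow(ins), nrow(insulae), n))
}

#' Insula summary statistics from counts
#'
#' @param n_genes_in_insulae genes organised in islands.
#' @param n_insulae island count.
#' @param n_genes_total total (expressed) gene count, for the percentage.
#' @return list with mean island size (1 decimal) and the genes-in-insulae
#'   fraction.
#' @export
insula_summary_stats <- function(n_genes_in_insulae, n_insulae,
                                 n_genes_total = NA) {
  list(n_genes_in_insulae = n_genes_in_insulae, n_insulae = n_insulae,
       n_genes_total = n_genes_total,
       mean_insula_size = if (n_insulae > 0)
         round(n_genes_in_insulae / n_insulae, 1) else NA_real_,
       pct_genes_in_insulae = if (is.na(n_genes_total)) NA_real_ else
         pct1(n_genes_in_insulae, n_genes_total))
}

#' Co-expressed neighbour pairs within insulae
#'
#' Every genomically adjacent gene pair inside an island is examined: the
#' pair is co-expressed when both members carry the same expression cluster.
#' Orientation of the (left, right) pair: divergent for (-,+) (5' ends
#' facing), convergent for (+,-), tandem otherwise.
#'
#' @param membership data.frame from [detect_insulae()] (`membership`).
#' @param strands named character vector gene_id -> strand.
#' @param clusters data.frame from [cluster_profiles()].
#' @param duplication_flags optional named logical vector gene_id -> member
#'   of a duplicated (paralogous) pair; a pair is flagged duplicated when
#'   both members are.
#' @return list(pairs, stats): pairs as data.frame(gene_a, gene_b,
#'   insula_id, distance_bp, orientation, same_cluster, duplicated_pair);
#'   stats from [pair_summary_stats()].
#' @export
coexpressed_pairs <- function(membership, strands, clusters,
                              duplication_flags = NULL) {
  cl <- stats::setNames(clusters$cluster, clusters$locus_id)
  m <- membership[!is.na(membership$insula_id), , drop = FALSE]
  pairs <- list()
  for (iid in unique(m$insula_id)) {
    d <- m[m$insula_id == iid, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    for (i in seq_len(nrow(d) - 1L)) {
      a <- d$gene_id[i]; b <- d$gene_id[i + 1L]
      sa <- unname(strands[a]); sb <- unname(strands[b])
      orientation <- if (identical(sa, "-") && identical(sb, "+")) "divergent"
        else if (identical(sa, "+") && identical(sb, "-")) "convergent"
        else "tandem"
      same <- !is.na(cl[a]) && !is.na(cl[b]) && cl[a] == cl[b] && cl[a] > 0L
      dup <- !is.null(duplication_flags) &&
        isTRUE(duplication_flags[a]) && isTRUE(duplication_flags[b])
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = a, gene_b = b, insula_id = iid,
        distance_bp = max(0, d$start[i + 1L] - d$end[i] - 1),
        orientation = orientation, same_cluster = same,
        duplicated_pair = dup, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(0), gene_b = character(0),
               insula_id = character(0), distance_bp = numeric(0),
               orientation = character(0), same_cluster = logical(0),
               duplicated_pair = logical(0), stringsAsFactors = FALSE)
  co <- pairs[pairs$same_cluster, , drop = FALSE]
  genes_co <- unique(c(co$gene_a, co$gene_b))
  stats <- pair_summary_stats(
    n_genes_coexpressed = length(genes_co),
    n_genes_in_insulae = nrow(m),
    n_coexpressed_pairs = nrow(co),
    n_duplicated_pairs = sum(co$duplicated_pair),
    n_adjacent_pairs = nrow(pairs),
    n_divergent_pairs = sum(co$orientation == "divergent"),
    mean_coexpressed_distance_kb = if (nrow(co))
      round(mean(co$distance_bp) / 1000, 1) else NA_real_)
  list(pairs = pairs, stats = stats)
}

#' Neighbour-pair summary statistics from counts
#'
#' Chains explain why the distinct-gene count can be below twice the pair
#' count: an island of three same-cluster genes yields two pairs but three
#' genes.
#'
#' @param n_genes_coexpressed distinct genes in same-cluster adjacent pairs.
#' @param n_genes_in_insulae genes organised in islands (denominator).
#' @param n_coexpressed_pairs same-cluster adjacent pairs.
#' @param n_duplicated_pairs co-expressed pairs of duplicated genes.
#' @param n_adjacent_pairs,n_divergent_pairs,mean_coexpressed_distance_kb
#'   optional extras carried through.
#' @return list with the co-clustered-gene and duplicated-pair percentages.
#' @export
pair_summary_stats <- function(n_genes_coexpressed, n_genes_in_insulae,
                               n_coexpressed_pairs, n_duplicated_pairs,
                               n_adjacent_pairs = NA, n_divergent_pairs = NA,
                               mean_coexpressed_distance_kb = NA) {
  list(n_genes_coexpressed = n_genes_coexpressed,
       n_genes_in_insulae = n_genes_in_insulae,
       n_coexpressed_pairs = n_coexpressed_pairs,
       n_duplicated_pairs = n_duplicated_pairs,
       n_adjacent_pairs = n_adjacent_pairs,
       n_divergent_pairs = n_divergent_pairs,
       pct_genes_coexpressed = pct1(n_genes_coexpressed, n_genes_in_insulae),
       pct_duplicated_pairs = pct1(n_duplicated_pairs, n_coexpressed_pairs),
       mean_coexpressed_distance_kb = mean_coexpressed_distance_kb)
}

#' Cluster composition across chromosome regions
#'
#' Builds the clusters-by-regions contingency table and, per cluster, a
#' chi-square test of homogeneity (the cluster's genes vs all others across
#' regions, df = regions - 1). Tests with more than 20% of expected counts
#' below 1 are flagged unreliable.
#'
#' @param clusters data.frame from [cluster_profiles()].
#' @param positions data.frame(gene_id, start, end) of the clustered genes.
#' @param regions data.frame(name, start, end).
#' @return list(composition, pct, tests).
#' @export
cluster_region_composition <- function(clusters, positions, regions) {
  pos <- positions[match(clusters$locus_id, positions$gene_id), , drop = FALSE]
  reg <- assign_region((pos$start + pos$end) / 2, regions)
  tab <- table(cluster = clusters$cluster,
               region = factor(reg, levels = regions$name))
  pct <- round(100 * sweep(tab, 2L, colSums(tab), "/"), 1)
  tests <- lapply(rownames(tab), function(cl) {
    two <- rbind(tab[cl, ], colSums(tab) - tab[cl, ])
    exp_counts <- outer(rowSums(two), colSums(two)) / sum(two)
    unreliable <- mean(exp_counts < 1) > 0.2
    ct <- suppressWarnings(stats::chisq.test(two, correct = FALSE))
    data.frame(cluster = cl, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value,
               unreliable = unreliable, stringsAsFactors = FALSE)
  })
  list(composition = tab, pct = pct, tests = do.call(rbind, tests))
}

#' Fisher exact term enrichment with BH correction
#'
#' One 2x2 Fisher exact test per term (query vs rest of the universe,
#' in-term vs not), two-sided, with Benjamini-Hochberg adjustment across
#' terms.
#'
#' @param query character vector of gene ids (must be a subset of
#'   `universe`, non-empty).
#' @param universe character vector of all gene ids.
#' @param term_map data.frame(gene_id, term).
#' @return data.frame(term, n_query, n_universe, odds_ratio, p, q) ordered
#'   by p.
#' @export
fisher_enrichment <- function(query, universe, term_map) {
  if (!length(query)) stopf("empty query set")
  if (length(setdiff(query, universe)))
    stopf("query contains ids outside the universe")
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- unique(term_map$term)
  rows <- lapply(terms, function(tm) {
    in_term <- unique(term_map$gene_id[term_map$term == tm])
    a <- length(intersect(query, in_term))
    b <- length(setdiff(query, in_term))
    c_ <- length(setdiff(in_term, query))
    d <- length(universe) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L), alternative = "two.sided")
    data.frame(term = tm, n_query = a, n_universe = length(in_term),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$q <- stats::p.adjust(df$p, method = "BH")
  df <- df[order(df$p, df$term), , drop = FALSE]
  rownames(df) <- NULL
  df
}
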