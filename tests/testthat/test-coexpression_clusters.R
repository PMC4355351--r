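test_that("critical Pearson matches the t-quantile form and a permutation null", {
  expect_equal(round(critical_pearson(15, 0.01), 3), 0.641)
  expect_equal(critical_pearson(15, 1), 0)
  expect_error(critical_pearson(3, 0.01), "n >= 4")

  # permutation oracle at n = 100: 99th percentile of |r| under the null
  set.seed(8)
  n <- 100
  x <- rnorm(n); y <- rnorm(n)
  perm <- replicate(20000, abs(cor(x, sample(y))))
  expect_lt(abs(critical_pearson(n, 0.01) -
                  unname(quantile(perm, 0.99, type = 7))), 0.01)
})

test_that("profile clustering groups by correlation under a deterministic cut", {
  cond <- paste0("c", 1:15)
  m <- rbind(a = 1:15, b = (1:15) * 2,       # r = 1
             c = 15:1,                       # r = -1 with a
             z = rep(3, 15))                 # constant -> reserved cluster
  colnames(m) <- cond
  cl <- cluster_profiles(m)
  cv <- setNames(cl$cluster, cl$locus_id)
  expect_equal(cv[["a"]], cv[["b"]])
  expect_false(cv[["a"]] == cv[["c"]])
  expect_equal(cv[["z"]], 0L)
  expect_equal(attr(cl, "k"), 2L)

  # anti-correlated profiles split at any positive cut
  cl2 <- cluster_profiles(m[c("a", "c"), ], cut_similarity = 0.01)
  expect_equal(attr(cl2, "k"), 2L)
})

test_that("template-structured matrices are recovered exactly", {
  set.seed(9)
  k <- 5
  tpl <- matrix(0, k, 15)
  for (i in seq_len(k)) tpl[i, ((i - 1) * 3 + 1):(i * 3)] <- c(1, 2, 3)
  m <- do.call(rbind, lapply(seq_len(k), function(i)
    t(sapply(1:12, function(j) tpl[i, ] * exp(rnorm(15, 0, 0.1))))))
  rownames(m) <- sprintf("L%02d", seq_len(nrow(m)))
  colnames(m) <- paste0("c", 1:15)
  truth <- rep(seq_len(k), each = 12)
  cl <- cluster_profiles(m)
  expect_equal(attr(cl, "k"), k)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)
})

test_that("cluster count is monotone in the similarity cut", {
  set.seed(10)
  m <- matrix(rexp(40 * 15), 40, dimnames = list(paste0("L", 1:40),
                                                 paste0("c", 1:15)))
  ks <- vapply(c(0.95, 0.8, 0.641, 0.4, 0.1, -0.5), function(cut)
    attr(cluster_profiles(m, cut_similarity = cut), "k"), 0L)
  expect_true(all(diff(ks) <= 0))
})

test_that("insulae are maximal runs of close genes; singletons excluded", {
  g <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                  start = c(1, 11001, 62001), end = c(1000, 12000, 63000))
  r <- detect_insulae(g, gap_threshold = 30000)
  expect_equal(nrow(r$insulae), 1L)
  expect_equal(r$insulae$n_genes, 2L)
  expect_true(is.na(r$membership$insula_id[r$membership$gene_id == "g3"]))
  expect_equal(r$stats$mean_insula_size, 2)

  far <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                    start = c(1, 90000), end = c(100, 90100))
  expect_equal(nrow(detect_insulae(far)$insulae), 0L)

  over <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                     start = c(1, 500), end = c(1000, 1500))
  expect_warning(ro <- detect_insulae(over), "clamped")
  expect_equal(nrow(ro$insulae), 1L)
})

test_that("published insula and pair arithmetic replays", {
  expect_equal(insula_summary_stats(3465, 1199, 5185)$mean_insula_size, 2.9)
  expect_equal(insula_summary_stats(3465, 1199, 5185)$pct_genes_in_insulae, 66.8)
  p <- pair_summary_stats(1218, 3465, 718, 46)
  expect_equal(p$pct_genes_coexpressed, 35.2)
  expect_equal(p$pct_duplicated_pairs, 6.4)
})

test_that("raising the gap threshold never decreases genes in insulae", {
  set.seed(12)
  pos <- sort(round(runif(60, 1, 2e6)))
  g <- data.frame(gene_id = sprintf("g%02d", 1:60), chrom = "chr1",
                  start = pos, end = pos + 500)
  g <- g[!duplicated(g$start), ]
  counts <- vapply(c(1e3, 1e4, 3e4, 1e5, 1e6), function(th)
    suppressWarnings(detect_insulae(g, gap_threshold = th))$stats$n_genes_in_insulae,
    0)  # random placement may overlap; clamping is exercised elsewhere
  expect_true(all(diff(counts) >= 0))
})

test_that("neighbour pairs: orientation classes and chain counting", {
  g <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                  start = c(1, 2001, 4001), end = c(1000, 3000, 5000))
  ins <- detect_insulae(g, gap_threshold = 5000)
  clusters <- data.frame(locus_id = c("g1", "g2", "g3"), cluster = c(1L, 1L, 1L))
  strands <- c(g1 = "-", g2 = "+", g3 = "-")
  cp <- coexpressed_pairs(ins$membership, strands, clusters)
  expect_equal(nrow(cp$pairs), 2L)                       # 3 genes, 2 pairs
  expect_equal(cp$stats$n_genes_coexpressed, 3L)
  expect_equal(cp$pairs$orientation, c("divergent", "convergent"))
  expect_equal(cp$pairs$distance_bp, c(1000, 1000))
  # tandem when both strands agree
  cp2 <- coexpressed_pairs(ins$membership, c(g1 = "+", g2 = "+", g3 = "+"),
                           clusters)
  expect_true(all(cp2$pairs$orientation == "tandem"))
  # pair count bounded by adjacency within insulae
  expect_lte(cp$stats$n_coexpressed_pairs, cp$stats$n_adjacent_pairs)
  expect_lte(cp$stats$n_adjacent_pairs,
             sum(ins$insulae$n_genes - 1L))
})

test_that("cluster-by-region composition tests flag concentrated clusters", {
  reg <- data.frame(name = c("A", "B"), start = c(0, 1e6), end = c(1e6, 2e6))
  pos <- data.frame(gene_id = sprintf("g%02d", 1:40),
                    start = c(runif(20, 1, 9e5), runif(20, 1.1e6, 1.9e6)))
  pos$end <- pos$start
  # cluster 1 uniform across both regions; cluster 2 only in region B
  cl <- data.frame(locus_id = pos$gene_id,
                   cluster = c(rep(1L, 20), rep(2L, 20)))
  comp <- cluster_region_composition(cl, pos, reg)
  expect_lt(comp$tests$p[comp$tests$cluster == "2"], 0.01)

  cl_u <- data.frame(locus_id = pos$gene_id, cluster = rep(1:2, 20))
  comp_u <- cluster_region_composition(cl_u, pos, reg)
  expect_gt(min(comp_u$tests$p), 0.5)
  expect_true(all(comp_u$tests$df == 1))
})

test_that("Fisher enrichment matches hypergeometric enumeration with BH", {
  universe <- sprintf("g%02d", 1:20)
  tmap <- data.frame(gene_id = universe[1:10], term = "T1")
  query <- universe[c(1:8, 11, 12)]        # a=8, b=2, c=2, d=8
  fe <- fisher_enrichment(query, universe, tmap)
  # oracle: two-sided Fisher p by enumerating the hypergeometric support
  probs <- dhyper(0:10, 10, 10, 10)
  p_oracle <- sum(probs[probs <= dhyper(8, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(fe$p, p_oracle, tolerance = 1e-10)
  expect_equal(round(fe$p, 3), 0.023)

  # query = universe: every term has p 1
  fe2 <- fisher_enrichment(universe, universe, tmap)
  expect_true(all(fe2$p == 1))

  # a term covering the full query and nothing else is the most enriched
  tmap3 <- rbind(tmap, data.frame(gene_id = query, term = "T2"))
  fe3 <- fisher_enrichment(query, universe, tmap3)
  expect_equal(fe3$term[1], "T2")
  expect_true(fe3$q[1] <= fe3$q[2])
  expect_error(fisher_enrichment(character(0), universe, tmap), "empty")
  expect_error(fisher_enrichment("nope", universe, tmap), "outside")
})
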