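# Shared fixtures: exon-chain builders and cached synthetic bundles so the
# generator and full pipeline run once per suite, not once per test.

tx <- function(id, exons, gene = "g1") transcript_model(id, gene, exons)

ex_mat <- function(...) {
  v <- c(...)
  matrix(v, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("start", "end")))
}

one_gene <- function(txs, strand = "+", gene_id = "g1", chrom = "chr1",
                     category = "full") {
  sp <- range(unlist(lapply(txs, function(t) t$exons)))
  gene_model(gene_id, chrom, sp[1L], sp[2L], strand, txs, category = category)
}

# random multi-exon chain with roomy introns (uses the session RNG)
random_chain <- function(n_exons, exon_len = c(60, 200), intron_len = c(200, 800)) {
  el <- round(runif(n_exons, exon_len[1L], exon_len[2L]))
  il <- if (n_exons > 1L) round(runif(n_exons - 1L, intron_len[1L], intron_len[2L]))
        else numeric(0)
  starts <- cumsum(c(1, if (n_exons > 1L) el[-n_exons] + il else numeric(0)))
  cbind(start = starts, end = starts + el - 1)
}

reflect_exons <- function(exons, K) {
  m <- cbind(start = K + 1 - exons[, 2L], end = K + 1 - exons[, 1L])
  m[order(m[, 1L]), , drop = FALSE]
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, expr, envir = .fixture_cache)
  .fixture_cache[[key]]
}

# small chromosome (~50 Mb, ~340 genes): generator/unit tests
small_bundle <- function() cached("small", generate_chromosome(
  synthetic_config(scale = 50 / 774.4, seed = 1)))

# medium chromosome (~155 Mb, ~1050 genes): pipeline recovery tests
medium_bundle <- function() cached("medium", generate_chromosome(
  synthetic_config(scale = 0.2, seed = 1)))

medium_run <- function() cached("medium_run", {
  b <- medium_bundle()
  sc <- 0.2
  run_all(b, chrom_length = b$config$chrom_length,
          config = run_config(window_bp = round(1e7 * sc),
                              step_bp = round(1e6 * sc)))
})
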