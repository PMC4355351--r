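mk_mat <- function(rows, n_cond = 15) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0(rep(c("root", "leaf", "stem", "spike", "grain"),
                            each = 3), "_s", 1:3)[seq_len(ncol(m))]
  m
}

test_that("longest-ORF scan matches hand-translated oracles on both strands", {
  # ATG AAA TAG: start + one codon before the stop -> 2 AA
  expect_equal(find_longest_orf("ATGAAATAG"), 2L)
  expect_equal(find_longest_orf("CCCCCCGGG"), 0L)           # no ATG
  expect_equal(find_longest_orf("ATGAAACCC"), 0L)           # no in-frame stop
  # 10-codon ORF (ATG + 9 codons) then TAA; strand symmetry via revcomp
  orf <- paste0("ATG", strrep("GCA", 9), "TAA")
  expect_equal(find_longest_orf(orf), 10L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
  expect_equal(find_longest_orf(rc), 10L)
  # frame offset: leading base shifts the frame but the ORF is still found
  expect_equal(find_longest_orf(paste0("C", orf)), 10L)
  expect_warning(out <- find_longest_orf(""), "empty")
  expect_equal(out, 0L)
})

test_that("TAR calling emits one TAR per expressed locus with its class", {
  g <- list(
    a = one_gene(list(tx("a.1", ex_mat(1, 1000), gene = "a")), gene_id = "a"),
    b = gene_model("b", "chr1", 101000, 102000, "-",
                   list(transcript_model("b.1", "b", ex_mat(101000, 102000))),
                   category = "pseudogene_fragment"),
    c = one_gene(list(tx("c.1", ex_mat(201000, 202000), gene = "c")),
                 gene_id = "c"))
  ntr <- data.frame(ntr_id = "n1", chrom = "chr1", start = 301000,
                    end = 302000, strand = NA)
  mat <- mk_mat(list(a = c(1, rep(0, 14)), b = rep(2, 15),
                     c = rep(0, 15), n1 = c(rep(0, 14), 5)))
  tars <- call_tars(g, mat, ntr)
  expect_equal(nrow(tars), 3L)                 # c is silent -> no TAR
  expect_false("c" %in% tars$tar_id)
  expect_equal(tars$class[tars$tar_id == "a"], "gene_full")
  expect_equal(tars$class[tars$tar_id == "b"], "gene_pseudo")
  expect_equal(tars$class[tars$tar_id == "n1"], "NTR")
  expect_equal(tars$breadth[tars$tar_id == "b"], 15L)

  # 3 expressed genes + 1 NTR on a 400 kb chromosome: spacing 100 kb
  mat2 <- mk_mat(list(a = rep(1, 15), b = rep(1, 15), c = rep(1, 15),
                      n1 = rep(1, 15)))
  s <- summarize_tars(call_tars(g, mat2, ntr), g, 400000)
  expect_equal(s$n_tars, 4L)
  expect_equal(s$mean_tar_spacing_kb, 100)

  bad <- mk_mat(list(a = rep(1, 15), zz = rep(1, 15)))
  expect_error(call_tars(g, bad, ntr), "zz")
})

test_that("summary arithmetic reproduces the published headline percentages", {
  s <- tar_summary_stats(
    n_predicted = 7264, n_expressed = 5185,
    n_predicted_full = 5326, n_expressed_full = 4125,
    n_predicted_pseudo = 1938, n_expressed_pseudo = 1060,
    n_ntr = 3692, chrom_length_bp = 774.4e6,
    n_multicopy_pseudo = 511, n_cis_nat = 635, n_lincRNA = 596)
  expect_equal(s$pct_expressed, 71.4)
  expect_equal(s$pct_full_expressed, 77.5)
  expect_equal(s$pct_pseudo_expressed, 54.7)
  expect_equal(s$n_tars, 8877)
  expect_equal(round(s$mean_tar_spacing_kb), 87)
  expect_equal(s$pct_multicopy_pseudo, 48.2)
  expect_equal(s$pct_cis_nat, 12.2)

  z <- tar_summary_stats(10, 0, 5, 0, 5, 0, 0, 1e6)
  expect_equal(z$pct_expressed, 0)            # no division error
  expect_true(is.na(z$mean_tar_spacing_kb))
})

test_that("lincRNA filters are conjunctive with the stated boundaries", {
  ntr <- data.frame(tar_id = c("n1", "n2", "n3", "n4", "n5"))
  seqs <- c(n1 = orf_seq <- strrep("C", 300),       # 300 nt, no ORF
            n2 = strrep("C", 150),                  # too short
            n3 = paste0(strrep("C", 100), "ATG", strrep("GCA", 301), "TAA"),
            n4 = paste0(strrep("C", 100), "ATG", strrep("GCA", 299), "TAA"),
            n5 = strrep("C", 500))
  sim <- c(n1 = FALSE, n2 = FALSE, n3 = FALSE, n4 = FALSE, n5 = TRUE)
  calls <- classify_lincRNAs(ntr, seqs, sim)
  got <- setNames(calls$is_lincRNA, calls$tar_id)
  expect_true(got["n1"])                        # length > 200, ORF 0
  expect_false(got["n2"])                       # length filter strict
  expect_equal(calls$orf_aa[calls$tar_id == "n3"], 302L)
  expect_false(got["n3"])                       # ORF > 300 AA fails
  expect_equal(calls$orf_aa[calls$tar_id == "n4"], 300L)
  expect_true(got["n4"])                        # exactly 300 AA passes
  expect_false(got["n5"])                       # protein similarity fails

  expect_warning(
    u <- classify_lincRNAs(data.frame(tar_id = "nx"), seqs, sim),
    "uncallable")
  expect_false(u$callable)
  expect_false(u$is_lincRNA)
})

test_that("cis-NAT calls require sense expression and enough overlap", {
  g <- list(
    a = one_gene(list(tx("a.1", ex_mat(1000, 2000), gene = "a")), gene_id = "a"),
    b = one_gene(list(tx("b.1", ex_mat(5000, 6000), gene = "b")), gene_id = "b"))
  mat <- mk_mat(list(a = rep(1, 15), b = rep(0, 15)))
  anti <- data.frame(chrom = "chr1",
                     start = c(1200, 5000), end = c(1800, 6000),
                     strand = c("-", "-"))
  nat <- detect_cis_nats(g, anti, mat)
  expect_true(nat$is_cis_nat[nat$gene_id == "a"])
  expect_false(nat$is_cis_nat[nat$gene_id == "b"])   # not expressed

  # 10 bp overlap below a 50 bp floor
  anti2 <- data.frame(chrom = "chr1", start = 1991, end = 2300, strand = "-")
  nat2 <- detect_cis_nats(g, anti2, mat, min_overlap_bp = 50)
  expect_equal(nat2$antisense_overlap_bp[nat2$gene_id == "a"], 10)
  expect_false(nat2$is_cis_nat[nat2$gene_id == "a"])

  expect_error(detect_cis_nats(
    g, data.frame(chrom = "chrZ", start = 1, end = 2, strand = "-"), mat),
    "unknown chromosome")
})

test_that("tightening any filter never increases the call count", {
  set.seed(42)
  n <- 40
  seqs <- setNames(vapply(round(runif(n, 50, 1500)), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), ""),
    paste0("n", 1:n))
  ntr <- data.frame(tar_id = names(seqs))
  sim <- setNames(runif(n) < 0.3, names(seqs))
  counts <- vapply(c(0, 100, 200, 400, 800), function(minlen)
    sum(classify_lincRNAs(ntr, seqs, sim, min_length_nt = minlen)$is_lincRNA), 0)
  expect_true(all(diff(counts) <= 0))
  counts2 <- vapply(c(500, 300, 100, 10, 0), function(maxorf)
    sum(classify_lincRNAs(ntr, seqs, sim, max_orf_aa = maxorf)$is_lincRNA), 0)
  expect_true(all(diff(counts2) <= 0))

  g <- list(a = one_gene(list(tx("a.1", ex_mat(1000, 2000), gene = "a")),
                         gene_id = "a"))
  mat <- mk_mat(list(a = rep(1, 15)))
  anti <- data.frame(chrom = "chr1", start = 1500, end = 1700, strand = "-")
  nats <- vapply(c(1, 100, 201, 5000), function(mo)
    sum(detect_cis_nats(g, anti, mat, min_overlap_bp = mo)$is_cis_nat), 0)
  expect_true(all(diff(nats) <= 0))
})
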