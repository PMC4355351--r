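test_that("generation is byte-identical for a fixed seed", {
  cfg <- synthetic_config(scale = 20 / 774.4, seed = 99)
  b1 <- generate_chromosome(cfg)
  b2 <- generate_chromosome(cfg)
  expect_identical(b1$matrix, b2$matrix)
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(b1$truth$events, b2$truth$events)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gff3(b1$genes, f1); write_gff3(b2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated annotation passes full model validation", {
  b <- small_bundle()
  expect_true(validate_genes(b$genes))
  expect_equal(nrow(b$truth$loci), nrow(b$matrix))    # one truth row per locus
  expect_false(anyDuplicated(b$truth$loci$locus_id) > 0)
})

test_that("the configured density gradient is realised (R1 and R3 above C)", {
  b <- small_bundle()
  reg <- default_regions(b$config$chrom_length)
  gt <- gene_table(b$genes)
  r <- assign_region((gt$start + gt$end) / 2, reg)
  mb <- setNames((reg$end - reg$start) / 1e6, reg$name)
  dens <- table(factor(r, reg$name)) / mb
  expect_gt(dens[["R1"]], dens[["R2a"]])
  expect_gt(dens[["R2a"]], dens[["C"]])
  expect_gt(dens[["R3"]], dens[["R2b"]])
  expect_gt(dens[["R2b"]], dens[["C"]])
})

test_that("every injected AS event is recovered with its exact signature", {
  b <- small_bundle()
  ev <- classify_as_events_all(b$genes[unique(b$truth$events$gene_id)])
  canon <- ev[ev$type != "complex", ]
  expect_identical(sort(paste(canon$gene_id, canon$detail)),
                   sort(paste(b$truth$events$gene_id, b$truth$events$detail)))
})

test_that("a degenerate AS mixture yields only that type", {
  cfg <- synthetic_config(scale = 20 / 774.4, seed = 2,
                          as_props = c(IR = 1, A3SS = 0, ES = 0,
                                       A5SS = 0, MXE = 0))
  b <- generate_chromosome(cfg)
  expect_gt(nrow(b$truth$events), 10)
  expect_true(all(b$truth$events$type == "IR"))
  ev <- classify_as_events_all(b$genes[unique(b$truth$events$gene_id)])
  expect_true(all(ev$type[ev$type != "complex"] == "IR"))
})

test_that("lincRNA loci carry no ORF and ORF loci carry long ones", {
  b <- small_bundle()
  tl <- b$truth$loci
  linc_ids <- tl$locus_id[tl$class == "ntr" & tl$lincRNA]
  expect_gt(length(linc_ids), 3)
  expect_true(all(vapply(b$sequences[linc_ids], find_longest_orf, 0L) == 0L))
  expect_true(all(nchar(b$sequences[linc_ids]) > 200))
  # the classifier therefore recovers the truth exactly
  tars <- call_tars(b$genes, b$matrix, b$ntr_intervals)
  ntr_tars <- tars[tars$class == "NTR", ]
  calls <- classify_lincRNAs(ntr_tars, b$sequences, b$similarity_flags)
  truth_flag <- setNames(tl$lincRNA[tl$class == "ntr"],
                         tl$locus_id[tl$class == "ntr"])
  expect_equal(setNames(calls$is_lincRNA, calls$tar_id),
               truth_flag[calls$tar_id])
})

test_that("TAR classes and cis-NAT flags match the truth labels exactly", {
  b <- small_bundle()
  tl <- b$truth$loci
  tars <- call_tars(b$genes, b$matrix, b$ntr_intervals)
  expect_setequal(tars$tar_id, tl$locus_id[tl$expressed])
  got <- setNames(tars$class, tars$tar_id)
  want <- setNames(ifelse(tl$class == "ntr", "NTR", tl$class), tl$locus_id)
  expect_equal(got, want[names(got)])

  nats <- detect_cis_nats(b$genes, b$antisense, b$matrix)
  expect_equal(setNames(nats$is_cis_nat, nats$gene_id),
               setNames(tl$cis_nat[match(nats$gene_id, tl$locus_id)],
                        nats$gene_id))
})

test_that("dropout lowers expression breadth monotonically", {
  mean_breadth <- vapply(c(0, 0.15, 0.4), function(d) {
    b <- generate_chromosome(synthetic_config(scale = 20 / 774.4, seed = 5,
                                              dropout = d))
    p <- profile_expression(b$matrix)
    gene_rows <- p$locus_id %in% b$truth$loci$locus_id[
      b$truth$loci$class != "ntr"]
    mean(p$breadth[gene_rows & p$expressed])
  }, 0)
  expect_true(all(diff(mean_breadth) < 0))
})

test_that("over-dense configurations fail with a capacity error", {
  expect_error(generate_chromosome(synthetic_config(
    scale = 0.01, seed = 1,
    gene_density = c(R1 = 500, R2a = 500, C = 500, R2b = 500, R3 = 500))),
    "capacity")
})

test_that("region boundaries are recovered from a non-overlapping density track", {
  b <- medium_bundle()
  gt <- gene_table(b$genes)
  tars <- call_tars(b$genes, b$matrix, b$ntr_intervals)
  expr <- gt[gt$gene_id %in% tars$tar_id, ]
  w <- 2e6
  trk <- windowed_density(expr, b$config$chrom_length, window = w, step = w)
  seg <- binary_segmentation(trk$value)
  for (bnd in b$truth$region_boundaries_bp / w) {
    expect_true(any(abs(seg$changepoints - bnd) <= 1),
                info = sprintf("boundary at window %.1f", bnd))
  }
})

test_that("expression couplings: breadth rises with level; size falls with
           breadth under strong negative coupling", {
  b <- small_bundle()
  p <- profile_expression(b$matrix)
  pe <- p[p$expressed, ]
  expect_gt(cor(pe$breadth, pe$mean_expr, method = "spearman"), 0.3)

  bneg <- generate_chromosome(synthetic_config(
    scale = 20 / 774.4, seed = 4, size_breadth_coupling = -1))
  pn <- profile_expression(bneg$matrix)
  st <- structure_features(bneg$genes)
  keep <- pn$expressed & pn$locus_id %in% st$gene_id
  expect_lt(cor(st$transcript_length[match(pn$locus_id[keep], st$gene_id)],
                pn$breadth[keep], method = "spearman"), 0)
})
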