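test_that("each canonical event type is called from its defining pattern", {
  # IR: the second isoform retains the intron
  g <- one_gene(list(tx("t1", ex_mat(1, 100, 201, 300)),
                     tx("t2", ex_mat(1, 300))))
  ev <- classify_as_events(g)
  expect_equal(ev$type, "IR")
  expect_equal(c(ev$start, ev$end), c(101, 200))

  # A5SS on + strand: donor 100 vs 120, downstream acceptor 201 shared
  g <- one_gene(list(tx("t1", ex_mat(1, 100, 201, 300)),
                     tx("t2", ex_mat(1, 120, 201, 300))))
  ev <- classify_as_events(g)
  expect_equal(ev$type, "A5SS")
  expect_equal(c(ev$start, ev$end), c(100, 120))
  # same structure on - strand is an acceptor shift
  gm <- one_gene(list(tx("t1", ex_mat(1, 100, 201, 300)),
                      tx("t2", ex_mat(1, 120, 201, 300))), strand = "-")
  expect_equal(classify_as_events(gm)$type, "A3SS")

  # ES: internal exon skipped, flanks shared
  g <- one_gene(list(tx("t1", ex_mat(1, 100, 201, 250, 301, 400)),
                     tx("t2", ex_mat(1, 100, 301, 400))))
  ev <- classify_as_events(g)
  expect_equal(ev$type, "ES")
  expect_equal(c(ev$start, ev$end), c(201, 250))

  # MXE: mutually exclusive internal exons between shared flanks
  g <- one_gene(list(tx("t1", ex_mat(1, 100, 201, 250, 401, 500)),
                     tx("t2", ex_mat(1, 100, 301, 350, 401, 500))))
  ev <- classify_as_events(g)
  expect_equal(ev$type, "MXE")
  expect_equal(ev$detail, "MXE:201-250|301-350")
})

test_that("a retained intron is never miscalled as a splice-site shift", {
  g <- one_gene(list(tx("t1", ex_mat(1, 100, 201, 300, 401, 500)),
                     tx("t2", ex_mat(1, 300, 401, 500))))
  ev <- classify_as_events(g)
  expect_equal(ev$type, "IR")
  expect_equal(nrow(ev), 1L)
})

test_that("event calling is symmetric and deduplicates across isoform pairs", {
  a <- tx("t1", ex_mat(1, 100, 201, 300))
  b <- tx("t2", ex_mat(1, 300))
  ev_ab <- classify_as_events(one_gene(list(a, b)))
  ev_ba <- classify_as_events(one_gene(list(b, a)))
  expect_equal(ev_ab$detail, ev_ba$detail)

  # adding a duplicate isoform never changes the event set
  b2 <- tx("t3", ex_mat(1, 300))
  ev3 <- classify_as_events(one_gene(list(a, b, b2)))
  expect_equal(sort(ev3$detail), sort(ev_ab$detail))
})

test_that("single-isoform genes and pure terminal shifts yield no events", {
  g <- one_gene(list(tx("t1", ex_mat(1, 100, 201, 300))))
  expect_equal(nrow(classify_as_events(g)), 0L)
  # TSS/TES shifts only: same splice sites, no event (not even complex)
  g2 <- one_gene(list(tx("t1", ex_mat(1, 100, 201, 300)),
                      tx("t2", ex_mat(20, 100, 201, 340))))
  expect_equal(nrow(classify_as_events(g2)), 0L)
})

test_that("reflection swaps A5SS and A3SS; reflection plus strand flip fixes all types", {
  set.seed(7)
  K <- 100000
  types <- c("IR", "ES", "A5SS", "A3SS", "MXE")
  for (ty in types) {
    base <- tx("t1", random_chain(6))
    alt <- inject_as_event(base, ty, strand = "+", new_id = "t2")
    fwd <- classify_as_events(one_gene(list(base, alt), strand = "+"))
    refl <- lapply(list(base, alt), function(t)
      tx(t$tx_id, reflect_exons(t$exons, K)))
    same_strand <- classify_as_events(one_gene(refl, strand = "+"))
    flipped <- classify_as_events(one_gene(refl, strand = "-"))
    swap <- c(IR = "IR", ES = "ES", MXE = "MXE", A5SS = "A3SS", A3SS = "A5SS")
    expect_equal(fwd$type, ty)
    expect_equal(same_strand$type, unname(swap[ty]))
    expect_equal(flipped$type, ty)
  }
})

test_that("AS summaries report rates, isoform means and type proportions", {
  expect_equal(as_summary_stats(30232, 5185)$mean_isoforms_per_gene, 5.8)

  genes <- list(
    g1 = one_gene(list(tx("g1.1", ex_mat(1, 100, 201, 300), gene = "g1"),
                       tx("g1.2", ex_mat(1, 300), gene = "g1")),
                  gene_id = "g1"),
    g2 = one_gene(list(tx("g2.1", ex_mat(1000, 1100, 1301, 1400), gene = "g2")),
                  gene_id = "g2"),
    g3 = one_gene(list(tx("g3.1", ex_mat(2000, 2400), gene = "g3")),
                  gene_id = "g3"))
  ev <- classify_as_events_all(genes)
  s <- as_summary(genes, ev)
  expect_equal(s$n_genes, 3L)
  expect_equal(s$n_as_genes, 1L)
  expect_equal(s$pct_as_genes, 33.3)
  expect_equal(s$n_multiexonic, 2L)
  expect_equal(s$pct_as_multiexonic, 50)
  expect_equal(s$type_table$n[s$type_table$type == "IR"], 1L)
  expect_equal(s$type_table$pct[s$type_table$type == "IR"], 100)

  # all genes single-isoform: AS rate 0, empty event table
  solo <- genes["g2"]
  s0 <- as_summary(solo, classify_as_events_all(solo))
  expect_equal(s0$pct_as_genes, 0)
  expect_equal(s0$n_events, 0L)
})

test_that("injected events are recovered exactly, one per isoform", {
  set.seed(11)
  for (rep in 1:25) {
    ty <- sample(c("IR", "ES", "A5SS", "A3SS", "MXE"), 1)
    strand <- sample(c("+", "-"), 1)
    base <- tx("t1", random_chain(sample(4:8, 1)))
    alt <- inject_as_event(base, ty, strand = strand, new_id = "t2")
    ev <- classify_as_events(one_gene(list(base, alt), strand = strand))
    expect_equal(ev$type, ty)
    expect_equal(ev$detail, attr(alt, "event_detail"))
  }
  # structurally impossible requests error
  two_exon <- tx("t1", ex_mat(1, 100, 201, 300))
  expect_error(inject_as_event(two_exon, "MXE"), "cannot host")
  expect_error(inject_as_event(tx("t1", ex_mat(1, 100)), "IR"), "cannot host")
})
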