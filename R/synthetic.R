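# Synthetic chromosome generator.
#
# Emits an annotation (gene models with isoforms carrying injected AS
# events), an FPKM matrix over 15 organ-by-stage conditions with cluster
# structure, NTR loci with sequences (lincRNA-like loci carry no start
# codon on either strand by construction), an antisense-transcription
# table, and truth labels for every locus, event, cluster and region
# boundary — so each downstream stage can be validated by recovery tests.

#' Configuration for the synthetic chromosome
#'
#' Defaults emulate the canonical wheat-3B study conditions: a 774.4 Mb
#' chromosome with five regions (R1/R2a/C/R2b/R3), a centromere-to-telomere
#' gene-density gradient (about 18 genes/Mb at the short-arm telomere down
#' to 1 in the centromeric core), ~27% of gene models annotated as
#' pseudogenes/fragments, 77.5% / 54.7% of full genes / pseudogenes
#' expressed, NTRs at ~4.8/Mb, AS event-type proportions IR .35 / A3SS .27 /
#' ES .21 / A5SS .16 / MXE .009, a 12.2% cis-NAT rate among expressed genes,
#' 15 conditions (5 organs x 3 stages), an island model around a 30 kb gap
#' scale (about two thirds of genes in islands of mean size ~3), and a
#' bell-shaped coupling between expression rank and gene structure peaking
#' near bin 22 of 30. `scale` shrinks the chromosome (and hence gene
#' counts) proportionally; analyses at reduced scale use a window/step
#' scaled by the same factor.
#'
#' @param scale linear scale factor on the chromosome length.
#' @param seed RNG seed (set inside [generate_chromosome()]).
#' @param chrom chromosome name.
#' @param chrom_length length in bp.
#' @param gene_density genes/Mb per region (named: R1, R2a, C, R2b, R3).
#' @param pseudogene_fraction fraction of gene models annotated as
#'   pseudogene/fragment.
#' @param expressed_fraction_full,expressed_fraction_pseudo expressed
#'   fractions by category.
#' @param ntr_density NTR loci per Mb.
#' @param ntr_protein_similar_fraction fraction of NTRs with (simulated)
#'   protein similarity.
#' @param lincrna_fraction fraction of non-similar NTRs built as lincRNAs
#'   (length > 200 nt, no ORF).
#' @param cisnat_fraction fraction of expressed genes given an antisense
#'   record.
#' @param as_props AS event-type proportions (IR, A3SS, ES, A5SS, MXE).
#' @param as_gene_fraction fraction of expressed multi-exon genes receiving
#'   extra isoforms.
#' @param iso_lambda Poisson rate scale for extra isoforms (modulated by the
#'   structure bell).
#' @param max_isoforms cap on isoforms per gene.
#' @param n_clusters number of expression cluster templates (2 constitutive,
#'   5 organ-specific, 1 condition-specific when 8).
#' @param noise_sdlog multiplicative log-normal FPKM noise (log sd).
#' @param dropout per-condition dropout probability inside active
#'   conditions of non-constitutive clusters (default 0: zeros are carried
#'   by the activity patterns).
#' @param inflexion_bin,n_bins,bell_width location (bin of `n_bins`) and
#'   width (rank fraction) of the structure bell.
#' @param exon_gain Poisson gain of exon count at the bell peak.
#' @param size_breadth_coupling log-scale coefficient tying exon length to
#'   standardised breadth (negative: broadly expressed genes are more
#'   compact).
#' @param island_singleton_p,island_extra_lambda island size model:
#'   singleton with probability `island_singleton_p`, else
#'   `2 + Poisson(island_extra_lambda)` genes.
#' @param insula_gap_max intra-island gap ceiling in bp (the 30 kb scale).
#' @param syntenic_fraction_expressed,syntenic_fraction_silent synteny
#'   probabilities by expression status.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(scale = 1, seed = 1L, chrom = "chrS",
                             chrom_length = round(774.4e6 * scale),
                             gene_density = c(R1 = 18, R2a = 7, C = 1,
                                              R2b = 5, R3 = 15),
                             pseudogene_fraction = 0.267,
                             expressed_fraction_full = 0.775,
                             expressed_fraction_pseudo = 0.547,
                             ntr_density = 4.8,
                             ntr_protein_similar_fraction = 0.28,
                             lincrna_fraction = 0.224,
                             cisnat_fraction = 0.122,
                             as_props = c(IR = 0.35, A3SS = 0.27, ES = 0.21,
                                          A5SS = 0.16, MXE = 0.009),
                             as_gene_fraction = 0.614,
                             iso_lambda = 3, max_isoforms = 8,
                             n_clusters = 8, noise_sdlog = 0.15,
                             dropout = 0,
                             inflexion_bin = 22, n_bins = 30,
                             bell_width = 0.22, exon_gain = 7,
                             size_breadth_coupling = -0.15,
                             island_singleton_p = 0.6,
                             island_extra_lambda = 1.0,
                             insula_gap_max = 30000,
                             syntenic_fraction_expressed = 0.75,
                             syntenic_fraction_silent = 0.45) {
  stopifnot(all(as_props >= 0), abs(sum(as_props) - 1) < 0.05 || sum(as_props) > 0,
            all(gene_density > 0), chrom_length > 0)
  cfg <- as.list(environment())
  cfg$as_props <- as_props / sum(as_props)
  cfg$regions <- default_regions(chrom_length)
  class(cfg) <- "synthetic_config"
  cfg
}

# --- expression templates ---------------------------------------------------

# 15-condition cluster templates: strong, distinct organ/stage modulation so
# that within-cluster Pearson stays well above the 0.641 cut and clusters
# stay mutually separable under complete linkage.
cluster_templates <- function(organs = c("root", "leaf", "stem", "spike", "grain"),
                              n_stages = 3) {
  cond_organ <- rep(organs, each = n_stages)
  conditions <- paste(cond_organ, paste0("s", rep(seq_len(n_stages), length(organs))),
                      sep = "_")
  organ_mod <- c(root = 2.2, leaf = 0.5, stem = 1.0, spike = 0.35, grain = 1.6)
  stage_soft <- c(0.8, 1.0, 1.25)
  stage_hard <- c(0.35, 1.0, 2.6)
  stage_organ <- c(0.55, 1.0, 1.9)
  tpl <- list()
  tpl[["const_broad"]] <- organ_mod[cond_organ] * rep(stage_soft, length(organs))
  tpl[["const_stage"]] <- rep(stage_hard, length(organs))
  for (o in organs) {
    v <- numeric(length(conditions))
    v[cond_organ == o] <- stage_organ
    tpl[[paste0("organ_", o)]] <- v
  }
  v <- numeric(length(conditions))
  v[conditions == "spike_s2"] <- 1
  tpl[["single_cond"]] <- v
  m <- do.call(rbind, tpl)
  colnames(m) <- conditions
  m
}

# base level (FPKM) per cluster template, log scale
cluster_meanlog <- function(template_names) {
  v <- ifelse(template_names == "const_broad", log(350),
       ifelse(template_names == "const_stage", log(120),
       ifelse(template_names == "single_cond", log(6), log(25))))
  stats::setNames(v, template_names)
}

# cluster mixture weights, modulated by region: the centromeric core is
# enriched in the broad constitutive cluster, R1 in leaf-preferential genes,
# R3 in spike/grain-preferential genes.
cluster_weights_for_region <- function(template_names, region) {
  w <- stats::setNames(rep(1, length(template_names)), template_names)
  w["const_broad"] <- 2.4
  w["const_stage"] <- 2.6
  w["single_cond"] <- 0.9
  if (region == "C") w["const_broad"] <- w["const_broad"] * 4
  if (region == "R1") w["organ_leaf"] <- w["organ_leaf"] * 2.5
  if (region == "R3") {
    w["organ_spike"] <- w["organ_spike"] * 2
    w["organ_grain"] <- w["organ_grain"] * 2
  }
  w / sum(w)
}

bell_factor <- function(u, peak, width) exp(-(u - peak)^2 / (2 * width^2))

# --- sequence helpers -------------------------------------------------------

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# sequence with no start codon on either strand (no ATG, no CAT substring),
# hence longest ORF 0 by construction
orf_free_dna <- function(n) {
  s <- random_dna(n)
  repeat {
    s2 <- gsub("CAT", "CTT", gsub("ATG", "ATT", s, fixed = TRUE), fixed = TRUE)
    if (identical(s2, s)) return(s)
    s <- s2
  }
}

# sequence of length n embedding an ORF of orf_codons codons (start + body,
# then a stop)
dna_with_orf <- function(n, orf_codons) {
  body_len <- 3 * (orf_codons - 1)
  need <- 3 + body_len + 3
  stopifnot(n >= need)
  codons <- c("ATG")
  if (body_len > 0) {
    pool <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1L, paste, collapse = "")
    pool <- setdiff(pool, c("TAA", "TAG", "TGA"))
    codons <- c(codons, sample(pool, orf_codons - 1, replace = TRUE))
  }
  core <- paste(c(codons, "TAA"), collapse = "")
  pre <- orf_free_dna(max(0, floor((n - need) / 2)))
  post <- orf_free_dna(n - nchar(core) - nchar(pre))
  paste0(pre, core, post)
}

# --- AS event injection -----------------------------------------------------

# Render an event signature in the classifier's coordinate format, with an
# optional coordinate offset (used when relative gene builds are placed on
# the chromosome).
render_detail <- function(type, tag, nums, off = 0) {
  nums <- nums + off
  if (type %in% c("IR", "ES"))
    sprintf("%s:%.0f-%.0f", type, nums[1L], nums[2L])
  else if (type %in% c("A5SS", "A3SS"))
    sprintf("%s:%s%.0f|%.0f", type, tag, nums[1L], nums[2L])
  else
    sprintf("MXE:%.0f-%.0f|%.0f-%.0f", nums[1L], nums[2L], nums[3L], nums[4L])
}

# Inject one event of `type` into an exon chain, restricted to introns in
# `free_introns` (index set). Returns NULL when structurally impossible,
# else list(exons, consumed, type, tag, nums).
inject_event_core <- function(exons, strand, type, free_introns) {
  m <- nrow(exons)
  introns <- introns_of(exons)
  pickable <- function(idx) idx[idx %in% free_introns]
  if (type == "IR") {
    if (m < 2L) return(NULL)
    cand <- pickable(seq_len(m - 1L))
    if (!length(cand)) return(NULL)
    i <- if (length(cand) == 1L) cand else sample(cand, 1L)
    new <- exons[-(i + 1L), , drop = FALSE]
    new[i, 2L] <- exons[i + 1L, 2L]
    list(exons = new, consumed = i, type = "IR", tag = "",
         nums = c(introns[i, 1L], introns[i, 2L]))
  } else if (type == "ES") {
    if (m < 3L) return(NULL)
    cand <- Filter(function(j) all(c(j - 1L, j) %in% free_introns), 2:(m - 1L))
    if (!length(cand)) return(NULL)
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    list(exons = exons[-j, , drop = FALSE], consumed = c(j - 1L, j),
         type = "ES", tag = "", nums = c(exons[j, 1L], exons[j, 2L]))
  } else if (type %in% c("A5SS", "A3SS")) {
    if (m < 2L) return(NULL)
    # the boundary to move: donor = end on '+', start on '-'; acceptor is the
    # mirror. A5SS moves a donor, A3SS moves an acceptor.
    move_end <- (type == "A5SS") == (strand == "+")
    if (move_end) {
      cand <- pickable(seq_len(m - 1L))          # exon j's end bounds intron j
      if (!length(cand)) return(NULL)
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      exon_len <- exons[j, 2L] - exons[j, 1L] + 1
      intron_len <- introns[j, 2L] - introns[j, 1L] + 1
      dirs <- c(if (intron_len >= 30) "extend", if (exon_len >= 30) "shrink")
      if (!length(dirs)) return(NULL)
      dir <- if (length(dirs) == 1L) dirs else sample(dirs, 1L)
      dmax <- if (dir == "extend") intron_len - 20 else exon_len - 20
      delta <- sample(10:max(10, dmax), 1L)
      old <- exons[j, 2L]
      new_b <- if (dir == "extend") old + delta else old - delta
      new <- exons
      new[j, 2L] <- new_b
      # consume both introns around the modified exon so no second shift can
      # land on it (two opposite shifts on one exon would mimic an MXE)
      list(exons = new, consumed = intersect(c(j - 1L, j), seq_len(m - 1L)),
           type = type, tag = "e", nums = c(min(old, new_b), max(old, new_b)))
    } else {
      cand <- pickable(seq_len(m - 1L)) + 1L     # exon j's start bounds intron j-1
      if (!length(cand)) return(NULL)
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      exon_len <- exons[j, 2L] - exons[j, 1L] + 1
      intron_len <- introns[j - 1L, 2L] - introns[j - 1L, 1L] + 1
      dirs <- c(if (intron_len >= 30) "extend", if (exon_len >= 30) "shrink")
      if (!length(dirs)) return(NULL)
      dir <- if (length(dirs) == 1L) dirs else sample(dirs, 1L)
      dmax <- if (dir == "extend") intron_len - 20 else exon_len - 20
      delta <- sample(10:max(10, dmax), 1L)
      old <- exons[j, 1L]
      new_b <- if (dir == "extend") old - delta else old + delta
      new <- exons
      new[j, 1L] <- new_b
      list(exons = new, consumed = intersect(c(j - 1L, j), seq_len(m - 1L)),
           type = type, tag = "s", nums = c(min(old, new_b), max(old, new_b)))
    }
  } else if (type == "MXE") {
    if (m < 3L) return(NULL)
    cand <- Filter(function(j) all(c(j - 1L, j) %in% free_introns), 2:(m - 1L))
    cand <- Filter(function(j) {
      any(introns[c(j - 1L, j), 2L] - introns[c(j - 1L, j), 1L] + 1 >= 80)
    }, cand)
    if (!length(cand)) return(NULL)
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    side_ok <- which(introns[c(j - 1L, j), 2L] - introns[c(j - 1L, j), 1L] + 1 >= 80)
    side <- if (length(side_ok) == 1L) side_ok else sample(side_ok, 1L)
    intr <- introns[j - 2L + side, , drop = FALSE]
    glen <- intr[1L, 2L] - intr[1L, 1L] + 1
    ylen <- sample(40:min(120, glen - 30), 1L)
    ys <- intr[1L, 1L] + sample(10:(glen - ylen - 10), 1L)
    y <- c(ys, ys + ylen - 1)
    new <- exons
    new[j, ] <- y
    new <- new[order(new[, 1L]), , drop = FALSE]
    x <- exons[j, ]
    first <- if (x[1L] <= y[1L]) x else y
    second <- if (x[1L] <= y[1L]) y else x
    list(exons = new, consumed = c(j - 1L, j), type = "MXE", tag = "",
         nums = c(first[1L], first[2L], second[1L], second[2L]))
  } else stopf("unknown AS type '%s'", type)
}

#' Inject an alternative-splicing event into a transcript
#'
#' Returns a new isoform differing from the input by exactly one event of
#' the requested type (IR merges two exons across an intron; ES drops an
#' internal exon; A5SS/A3SS shift a donor/acceptor boundary, strand-aware;
#' MXE replaces an internal exon with a non-overlapping one in a flanking
#' intron). Errors when the transcript cannot host the requested type (IR
#' needs >= 2 exons, ES/MXE need >= 3).
#'
#' @param tx a [transcript_model()].
#' @param type one of `"IR"`, `"ES"`, `"A5SS"`, `"A3SS"`, `"MXE"`.
#' @param strand gene strand (affects A5SS/A3SS).
#' @param new_id id for the new isoform.
#' @return a `transcript_model`; attribute `event_detail` records the event
#'   signature in the classifier's coordinate format.
#' @export
inject_as_event <- function(tx, type, strand = "+",
                            new_id = paste0(tx$tx_id, ".", type)) {
  res <- inject_event_core(tx$exons, strand, type,
                           free_introns = seq_len(max(0L, nrow(tx$exons) - 1L)))
  if (is.null(res))
    stopf("transcript '%s' (%d exons) cannot host a %s event",
          tx$tx_id, nrow(tx$exons), type)
  out <- transcript_model(new_id, tx$gene_id, res$exons)
  attr(out, "event_detail") <- render_detail(res$type, res$tag, res$nums)
  out
}

# --- gene structure ---------------------------------------------------------

# Build one gene's primary exon chain (relative coordinates starting at 1).
build_exon_chain <- function(exon_n, exon_meanlog, intron_meanlog = log(300)) {
  elens <- pmax(30, round(stats::rlnorm(exon_n, exon_meanlog, 0.30)))
  ilens <- if (exon_n > 1L)
    pmax(150, round(stats::rlnorm(exon_n - 1L, intron_meanlog, 0.5))) else numeric(0)
  increments <- if (exon_n > 1L) elens[-exon_n] + ilens else numeric(0)
  starts <- cumsum(c(1, increments))
  cbind(start = starts, end = starts + elens - 1)
}

# --- the generator ----------------------------------------------------------

#' Generate a synthetic chromosome with truth labels
#'
#' See [synthetic_config()] for the emulated conditions. Deterministic for
#' a fixed seed: two runs with the same config are identical.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `genes` (gene models), `matrix` (FPKM, gene +
#'   NTR rows, 15 conditions), `ntr_intervals`, `sequences` (named vector:
#'   NTR loci and gene primary transcripts), `antisense` (stranded
#'   intervals), `similarity_flags`, `truth` (per-locus labels, AS events,
#'   cluster ids, region boundaries), and `config`.
#' @export
generate_chromosome <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  regions <- cfg$regions
  tpl <- cluster_templates()
  mlog <- cluster_meanlog(rownames(tpl))
  conditions <- colnames(tpl)

  # -- per-region gene counts
  reg_mb <- (regions$end - regions$start) / 1e6
  n_per_region <- round(cfg$gene_density[regions$name] * reg_mb)
  n_genes <- sum(n_per_region)
  if (n_genes < 2L) stopf("configuration yields fewer than 2 genes")
  gene_region <- rep(regions$name, times = n_per_region)

  gene_id <- sprintf("G%05d", seq_len(n_genes))
  pseudo <- stats::runif(n_genes) < cfg$pseudogene_fraction
  expressed <- ifelse(pseudo,
                      stats::runif(n_genes) < cfg$expressed_fraction_pseudo,
                      stats::runif(n_genes) < cfg$expressed_fraction_full)
  syntenic <- stats::runif(n_genes) <
    ifelse(expressed, cfg$syntenic_fraction_expressed, cfg$syntenic_fraction_silent)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  # -- cluster assignment (expressed genes only) and FPKM rows
  cluster <- rep(NA_character_, n_genes)
  for (r in regions$name) {
    idx <- which(gene_region == r & expressed)
    if (!length(idx)) next
    w <- cluster_weights_for_region(rownames(tpl), r)
    cluster[idx] <- sample(rownames(tpl), length(idx), replace = TRUE, prob = w)
  }
  level <- rep(NA_real_, n_genes)
  level[expressed] <- stats::rlnorm(sum(expressed),
                                    mlog[cluster[expressed]], 0.7)
  fpkm <- matrix(0, n_genes, length(conditions),
                 dimnames = list(gene_id, conditions))
  for (i in which(expressed)) {
    t_i <- tpl[cluster[i], ]
    active <- t_i > 0
    v <- level[i] * t_i * exp(stats::rnorm(length(t_i), 0, cfg$noise_sdlog))
    v[!active] <- 0
    if (cfg$dropout > 0 && !startsWith(cluster[i], "const")) {
      drop <- active & stats::runif(length(t_i)) < cfg$dropout
      if (all(drop[active])) drop[which(active)[1L]] <- FALSE
      v[drop] <- 0
    }
    fpkm[i, ] <- v
  }
  breadth <- rowSums(fpkm > 0)
  mean_expr <- vapply(seq_len(n_genes), function(i) {
    v <- fpkm[i, fpkm[i, ] > 0]
    if (length(v)) mean(v) else 0
  }, 0)

  # -- expression rank drives gene structure (bell-shaped coupling)
  u <- rep(NA_real_, n_genes)
  ei <- which(expressed)
  u[ei] <- (rank(mean_expr[ei], ties.method = "first") - 0.5) / length(ei)
  u[!expressed] <- stats::runif(sum(!expressed))
  peak <- (cfg$inflexion_bin - 0.5) / cfg$n_bins
  bell <- bell_factor(u, peak, cfg$bell_width)
  zb <- ifelse(expressed, (breadth - mean(breadth[ei])) /
                 max(1e-9, stats::sd(breadth[ei])), 0)
  exon_n <- 1L + stats::rpois(n_genes, 1 + cfg$exon_gain * bell)
  # exon length carries part of the bell too, so spliced transcript length
  # (exon count x exon length) expresses the configured inflexion clearly
  exon_meanlog <- log(120) + 0.7 * bell + cfg$size_breadth_coupling * zb

  # -- build genes (relative coordinates), inject isoforms
  genes <- vector("list", n_genes)
  events <- list()
  as_types <- names(cfg$as_props)
  for (i in seq_len(n_genes)) {
    ex <- build_exon_chain(exon_n[i], exon_meanlog[i])
    tx0 <- transcript_model(paste0(gene_id[i], ".1"), gene_id[i], ex)
    txs <- list(tx0)
    if (expressed[i] && !pseudo[i] && exon_n[i] >= 2L &&
        stats::runif(1) < cfg$as_gene_fraction) {
      n_extra <- min(1L + stats::rpois(1L, cfg$iso_lambda * bell[i]),
                     cfg$max_isoforms - 1L)
      free <- seq_len(exon_n[i] - 1L)
      made <- 0L
      tries <- 0L
      while (made < n_extra && tries < 20L && length(free)) {
        tries <- tries + 1L
        ty <- sample(as_types, 1L, prob = cfg$as_props)
        res <- inject_event_core(ex, strand[i], ty, free)
        if (is.null(res)) next
        made <- made + 1L
        free <- setdiff(free, res$consumed)
        new_tx <- transcript_model(sprintf("%s.%d", gene_id[i], made + 1L),
                                   gene_id[i], res$exons)
        txs[[length(txs) + 1L]] <- new_tx
        events[[length(events) + 1L]] <- data.frame(
          gene_id = gene_id[i], type = ty, tag = res$tag,
          nums = I(list(res$nums)),
          tx_a = tx0$tx_id, tx_b = new_tx$tx_id, stringsAsFactors = FALSE)
      }
    }
    genes[[i]] <- list(txs = txs,
                       span = max(vapply(txs, function(t) t$exons[nrow(t$exons), 2L], 0)))
  }

  # -- place genes along the chromosome: island model per region
  placed_start <- numeric(n_genes)
  for (rix in seq_len(nrow(regions))) {
    r <- regions$name[rix]
    idx <- which(gene_region == r)
    if (!length(idx)) next
    spans <- vapply(idx, function(i) genes[[i]]$span, 0)
    # island sizes
    sizes <- integer(0)
    while (sum(sizes) < length(idx)) {
      s <- if (stats::runif(1) < cfg$island_singleton_p) 1L
           else 2L + stats::rpois(1L, cfg$island_extra_lambda)
      sizes <- c(sizes, s)
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - length(idx))
    sizes <- sizes[sizes > 0L]
    intra <- round(stats::runif(length(idx) - length(sizes), 500,
                                cfg$insula_gap_max - 5000))
    min_inter <- cfg$insula_gap_max + 5000
    reg_len <- regions$end[rix] - regions$start[rix]
    need <- sum(spans) + sum(intra) + length(sizes) * min_inter
    if (need > 0.98 * reg_len)
      stopf("region %s: configured densities exceed chromosome capacity", r)
    slack <- 0.98 * reg_len - need
    wts <- stats::rexp(length(sizes))
    inter <- min_inter + slack * wts / sum(wts)
    cursor <- regions$start[rix]
    k <- 0L
    intra_k <- 0L
    for (s in seq_along(sizes)) {
      cursor <- cursor + inter[s]
      for (j in seq_len(sizes[s])) {
        k <- k + 1L
        i <- idx[k]
        placed_start[i] <- round(cursor)
        cursor <- cursor + spans[k] - 1
        if (j < sizes[s]) {
          intra_k <- intra_k + 1L
          cursor <- cursor + intra[intra_k] + 1
        }
      }
    }
  }

  gene_models <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    off <- placed_start[i] - 1
    txs <- lapply(genes[[i]]$txs, function(t)
      transcript_model(t$tx_id, t$gene_id, t$exons + off))
    gene_models[[i]] <- gene_model(
      gene_id[i], cfg$chrom, placed_start[i], placed_start[i] + genes[[i]]$span - 1,
      strand = strand[i], transcripts = txs,
      category = if (pseudo[i]) "pseudogene_fragment" else "full",
      syntenic = syntenic[i])
  }
  names(gene_models) <- gene_id

  # -- NTR loci
  n_ntr <- round(cfg$ntr_density * sum(reg_mb))
  ntr_id <- sprintf("NTR%05d", seq_len(n_ntr))
  ntr_region <- sample(regions$name, n_ntr, replace = TRUE,
                       prob = (regions$end - regions$start))
  similar <- stats::runif(n_ntr) < cfg$ntr_protein_similar_fraction
  linc <- !similar & stats::runif(n_ntr) < cfg$lincrna_fraction
  subtype <- ifelse(similar, "similar",
             ifelse(linc, "lincRNA",
             ifelse(stats::runif(n_ntr) < 0.5, "short", "orf")))
  ntr_len <- integer(n_ntr)
  ntr_len[subtype == "similar"] <- round(stats::runif(sum(subtype == "similar"), 300, 2000))
  ntr_len[subtype == "lincRNA"] <- round(stats::runif(sum(subtype == "lincRNA"), 250, 1500))
  ntr_len[subtype == "short"] <- round(stats::runif(sum(subtype == "short"), 80, 200))
  ntr_len[subtype == "orf"] <- round(stats::runif(sum(subtype == "orf"), 1200, 2500))

  gene_iv <- cbind(placed_start, placed_start + vapply(genes, `[[`, 0, "span") - 1)
  ntr_start <- numeric(n_ntr)
  for (j in seq_len(n_ntr)) {
    rix <- match(ntr_region[j], regions$name)
    for (try in 1:50) {
      cand <- round(stats::runif(1, regions$start[rix] + 1,
                                 regions$end[rix] - ntr_len[j]))
      hit <- any(gene_iv[, 1L] <= cand + ntr_len[j] - 1 & gene_iv[, 2L] >= cand)
      if (!hit) break
    }
    ntr_start[j] <- cand
  }
  ntr_intervals <- data.frame(ntr_id = ntr_id, chrom = cfg$chrom,
                              start = ntr_start, end = ntr_start + ntr_len - 1,
                              strand = NA_character_, stringsAsFactors = FALSE)

  # NTR FPKM rows: low level, specific profiles
  ntr_fpkm <- matrix(0, n_ntr, length(conditions),
                     dimnames = list(ntr_id, conditions))
  ntr_tpl_pool <- grep("^organ_|single_cond", rownames(tpl), value = TRUE)
  ntr_cluster <- sample(ntr_tpl_pool, n_ntr, replace = TRUE)
  ntr_level <- stats::rlnorm(n_ntr, log(8), 0.7)
  for (j in seq_len(n_ntr)) {
    t_j <- tpl[ntr_cluster[j], ]
    v <- ntr_level[j] * t_j * exp(stats::rnorm(length(t_j), 0, cfg$noise_sdlog))
    v[t_j == 0] <- 0
    ntr_fpkm[j, ] <- v
  }

  # -- sequences
  sequences <- character(0)
  for (j in seq_len(n_ntr)) {
    sequences[ntr_id[j]] <- switch(
      subtype[j],
      lincRNA = orf_free_dna(ntr_len[j]),
      short = orf_free_dna(ntr_len[j]),
      orf = dna_with_orf(ntr_len[j], 320),
      similar = random_dna(ntr_len[j]))
  }
  for (i in seq_len(n_genes)) {
    tx <- primary_transcript(gene_models[[i]])
    tlen <- as.integer(tx_length(tx))
    codons <- max(2L, min(floor(tlen / 3) - 3L, floor(tlen * 0.8 / 3)))
    sequences[tx$tx_id] <- if (tlen >= 3 * codons + 6)
      dna_with_orf(tlen, codons) else random_dna(tlen)
  }
  similarity_flags <- stats::setNames(similar, ntr_id)

  # -- antisense table (cis-NATs among expressed genes, biased to full and
  # syntenic genes)
  wts <- ifelse(pseudo, 1, 3) * ifelse(syntenic, 2, 1)
  n_nat <- round(cfg$cisnat_fraction * sum(expressed))
  nat_idx <- sample(which(expressed), n_nat, prob = wts[expressed])
  antisense <- do.call(rbind, lapply(nat_idx, function(i) {
    g <- gene_models[[i]]
    w <- g$end - g$start + 1
    s <- g$start + round(stats::runif(1, 0, 0.3) * w)
    e <- min(g$end, s + max(50, round(stats::runif(1, 0.3, 0.9) * w)))
    data.frame(chrom = g$chrom, start = s, end = e,
               strand = if (g$strand == "+") "-" else "+",
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  }))
  if (is.null(antisense))
    antisense <- data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0), strand = character(0),
                            gene_id = character(0), stringsAsFactors = FALSE)

  # -- truth labels
  loci <- rbind(
    data.frame(locus_id = gene_id,
               class = ifelse(pseudo, "gene_pseudo", "gene_full"),
               region = gene_region, expressed = expressed,
               cluster = cluster, syntenic = syntenic,
               cis_nat = gene_id %in% antisense$gene_id,
               lincRNA = FALSE, protein_similar = FALSE,
               stringsAsFactors = FALSE),
    data.frame(locus_id = ntr_id, class = "ntr", region = ntr_region,
               expressed = TRUE, cluster = NA_character_, syntenic = NA,
               cis_nat = FALSE, lincRNA = subtype == "lincRNA",
               protein_similar = similar, stringsAsFactors = FALSE))
  # events were injected in relative gene coordinates; render their
  # signatures in placed (chromosome) coordinates
  events_df <- if (length(events)) {
    ed <- do.call(rbind, events)
    off <- placed_start[match(ed$gene_id, gene_id)] - 1
    ed$detail <- vapply(seq_len(nrow(ed)), function(r)
      render_detail(ed$type[r], ed$tag[r], ed$nums[[r]], off[r]), "")
    ed[c("gene_id", "type", "detail", "tx_a", "tx_b")]
  } else data.frame(gene_id = character(0), type = character(0),
                    detail = character(0), tx_a = character(0),
                    tx_b = character(0), stringsAsFactors = FALSE)
  truth <- list(
    loci = loci,
    events = events_df,
    region_boundaries_bp = regions$end[-nrow(regions)],
    n_conditions = length(conditions))

  list(genes = gene_models,
       matrix = structure(rbind(fpkm, ntr_fpkm),
                          conditions = parse_conditions(conditions)),
       ntr_intervals = ntr_intervals, sequences = sequences,
       similarity_flags = similarity_flags, antisense = antisense,
       truth = truth, config = cfg)
}
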