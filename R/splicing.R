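# Alternative-splicing event classification.
#
# Events are called between every unordered pair of isoforms of a gene by
# purely structural, strand-aware tests, then deduplicated by (type,
# coordinates) across pairs:
#
#   IR   an intron of one isoform lies strictly inside a single exon of the
#        other (the retaining isoform's exon extends past both intron ends);
#   ES   an exon of one isoform lies fully within a single intron of the
#        other, and both isoforms share the flanking exons' inner
#        boundaries;
#   A5SS two overlapping exons share their acceptor-side boundary but differ
#        at the donor-side boundary (donor = exon end on '+', exon start on
#        '-'), and the flanking exon on the differing side exists in both
#        isoforms with the same facing boundary (so a retained intron is
#        never miscalled as a splice-site shift);
#   A3SS the mirror case (acceptor differs, donor-side flank shared);
#   MXE  exons x (only in isoform A) and y (only in isoform B),
#        non-overlapping, both immediately between the same shared flanking
#        exon pair.
#
# Terminal-exon differences (TSS/TES shifts, alternative first/last exons)
# are not events: only internal boundaries participate. Pairs whose splice
# sites differ without matching any canonical pattern are reported once as
# type "complex" and excluded from the five-type proportion denominator.

introns_of <- function(ex) {
  n <- nrow(ex)
  if (n < 2L)
    return(matrix(numeric(0), ncol = 2L))
  cbind(ex[-n, 2L] + 1, ex[-1L, 1L] - 1)
}

splice_sites_of <- function(ex) {
  n <- nrow(ex)
  if (n < 2L) return(numeric(0))
  sort(c(ex[-n, 2L], ex[-1L, 1L]))
}

# All canonical events between one ordered pair of exon chains.
pair_as_events <- function(exA, exB, strand) {
  events <- list()
  add <- function(type, start, end, detail)
    events[[length(events) + 1L]] <<- data.frame(
      type = type, start = start, end = end, detail = detail,
      stringsAsFactors = FALSE)

  intrA <- introns_of(exA)
  intrB <- introns_of(exB)

  # IR: intron of X strictly inside an exon of Y
  ir_scan <- function(intr, exY) {
    for (r in seq_len(nrow(intr))) {
      is <- intr[r, 1L]; ie <- intr[r, 2L]
      if (any(exY[, 1L] < is & exY[, 2L] > ie))
        add("IR", is, ie, sprintf("IR:%.0f-%.0f", is, ie))
    }
  }
  ir_scan(intrA, exB)
  ir_scan(intrB, exA)

  # ES: exon of Y inside an intron of X, flanking inner boundaries shared
  es_scan <- function(intrX, exY) {
    for (r in seq_len(nrow(intrX))) {
      is <- intrX[r, 1L]; ie <- intrX[r, 2L]
      inside <- which(exY[, 1L] >= is & exY[, 2L] <= ie)
      has_left <- any(exY[, 2L] == is - 1)
      has_right <- any(exY[, 1L] == ie + 1)
      if (has_left && has_right)
        for (j in inside)
          add("ES", exY[j, 1L], exY[j, 2L],
              sprintf("ES:%.0f-%.0f", exY[j, 1L], exY[j, 2L]))
    }
  }
  es_scan(intrA, exB)
  es_scan(intrB, exA)

  # A5SS / A3SS: overlapping exon pairs differing on exactly one side, with
  # the flank on the differing side present and shared in both isoforms.
  nA <- nrow(exA); nB <- nrow(exB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    as_ <- exA[i, 1L]; ae <- exA[i, 2L]
    bs <- exB[j, 1L]; be <- exB[j, 2L]
    if (ae < bs || be < as_) next            # no overlap
    if (as_ == bs && ae != be) {             # differ at the end side
      if (i < nA && j < nB && exA[i + 1L, 1L] == exB[j + 1L, 1L]) {
        type <- if (strand == "+") "A5SS" else "A3SS"
        lo <- min(ae, be); hi <- max(ae, be)
        add(type, lo, hi, sprintf("%s:e%.0f|%.0f", type, lo, hi))
      }
    } else if (ae == be && as_ != bs) {      # differ at the start side
      if (i > 1L && j > 1L && exA[i - 1L, 2L] == exB[j - 1L, 2L]) {
        type <- if (strand == "+") "A3SS" else "A5SS"
        lo <- min(as_, bs); hi <- max(as_, bs)
        add(type, lo, hi, sprintf("%s:s%.0f|%.0f", type, lo, hi))
      }
    }
  }

  # MXE: exon unique to A and exon unique to B, non-overlapping, immediately
  # between the same shared flanking exon pair.
  keyA <- paste(exA[, 1L], exA[, 2L])
  keyB <- paste(exB[, 1L], exB[, 2L])
  uA <- which(!(keyA %in% keyB))
  uB <- which(!(keyB %in% keyA))
  for (i in uA) {
    if (i == 1L || i == nA) next
    for (j in uB) {
      if (j == 1L || j == nB) next
      x <- exA[i, ]; y <- exB[j, ]
      if (x[2L] >= y[1L] && y[2L] >= x[1L]) next  # must not overlap
      if (exA[i - 1L, 2L] == exB[j - 1L, 2L] &&
          exA[i + 1L, 1L] == exB[j + 1L, 1L]) {
        first <- if (x[1L] <= y[1L]) x else y
        second <- if (x[1L] <= y[1L]) y else x
        add("MXE", first[1L], second[2L],
            sprintf("MXE:%.0f-%.0f|%.0f-%.0f", first[1L], first[2L],
                    second[1L], second[2L]))
      }
    }
  }

  if (!length(events))
    return(data.frame(type = character(0), start = numeric(0),
                      end = numeric(0), detail = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}

#' Classify alternative-splicing events among a gene's isoforms
#'
#' Pairwise structural comparison of all isoforms with set-level
#' deduplication; see the module header for the five canonical type
#' definitions. A single-isoform gene yields an empty event list.
#'
#' @param gene a [gene_model()].
#' @param include_complex also report isoform pairs whose splice sites
#'   differ without matching any canonical pattern (type `"complex"`).
#' @return data.frame(gene_id, type, start, end, detail, tx_a, tx_b); one
#'   row per distinct (type, coordinates) event, witnessed by the first
#'   isoform pair that exhibits it.
#' @export
classify_as_events <- function(gene, include_complex = TRUE) {
  empty <- data.frame(gene_id = character(0), type = character(0),
                      start = numeric(0), end = numeric(0),
                      detail = character(0), tx_a = character(0),
                      tx_b = character(0), stringsAsFactors = FALSE)
  txs <- gene$transcripts
  if (length(txs) < 2L) return(empty)
  ids <- names(txs)[id_order(names(txs))]
  out <- list()
  for (a in seq_len(length(ids) - 1L)) for (b in (a + 1L):length(ids)) {
    exA <- txs[[ids[a]]]$exons
    exB <- txs[[ids[b]]]$exons
    evs <- pair_as_events(exA, exB, gene$strand)
    if (!nrow(evs) && include_complex) {
      ssA <- splice_sites_of(exA); ssB <- splice_sites_of(exB)
      if (!setequal(ssA, ssB)) {
        dif <- c(setdiff(ssA, ssB), setdiff(ssB, ssA))
        evs <- data.frame(type = "complex", start = min(dif), end = max(dif),
                          detail = sprintf("complex:%.0f-%.0f", min(dif), max(dif)),
                          stringsAsFactors = FALSE)
      }
    }
    if (nrow(evs)) {
      evs$tx_a <- ids[a]; evs$tx_b <- ids[b]
      out[[length(out) + 1L]] <- evs
    }
  }
  if (!length(out)) return(empty)
  ev <- do.call(rbind, out)
  ev <- ev[!duplicated(ev$detail), , drop = FALSE]
  ev <- cbind(gene_id = gene$gene_id, ev, stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev
}

#' Classify AS events for a list of genes
#' @param genes list of [gene_model()] objects.
#' @inheritParams classify_as_events
#' @return row-bound data.frame of events over all genes.
#' @export
classify_as_events_all <- function(genes, include_complex = TRUE) {
  parts <- lapply(genes, classify_as_events, include_complex = include_complex)
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) out <- classify_as_events(list())  # empty-typed frame
  rownames(out) <- NULL
  out
}

#' Mean isoform count from transcript and gene totals
#'
#' The arithmetic behind the "alternative transcripts per gene" headline:
#' total transcripts divided by total genes, reported to 1 decimal.
#'
#' @param n_transcripts,n_genes totals.
#' @export
as_summary_stats <- function(n_transcripts, n_genes) {
  list(n_transcripts = n_transcripts, n_genes = n_genes,
       mean_isoforms_per_gene = round(n_transcripts / n_genes, 1))
}

#' Summarize alternative splicing over a gene set
#'
#' Per-type event proportions (among the five canonical types; `complex`
#' events are excluded from the denominator), the fraction of genes with
#' multiple isoforms overall and among multiexonic genes, and isoform
#' counts. When a transcript-level FPKM matrix is supplied, the fraction of
#' transcripts expressed in all conditions is reported as well.
#'
#' @param genes list of [gene_model()] objects (typically the expressed set).
#' @param events data.frame from [classify_as_events_all()].
#' @param tx_matrix optional transcript-level FPKM matrix.
#' @param fpkm_floor expression floor for the transcript-breadth statistic.
#' @return list of counts, percentages, and a per-type proportion table.
#' @export
as_summary <- function(genes, events, tx_matrix = NULL, fpkm_floor = 0) {
  n_genes <- length(genes)
  n_iso <- vapply(genes, function(g) length(g$transcripts), 0L)
  # multiexonic = at least one isoform with an intron (not primary-only:
  # an intron-retaining isoform can be the longest one)
  multiexonic <- vapply(genes, function(g)
    any(vapply(g$transcripts, function(t) nrow(t$exons), 0L) >= 2L), NA)
  as_gene <- n_iso >= 2L
  canonical <- c("IR", "A3SS", "ES", "A5SS", "MXE")
  type_n <- table(factor(events$type[events$type %in% canonical],
                         levels = canonical))
  type_tab <- data.frame(type = canonical, n = as.integer(type_n),
                         pct = pct1(as.integer(type_n), sum(type_n)),
                         stringsAsFactors = FALSE)
  pct_tx_all_conditions <- NA_real_
  if (!is.null(tx_matrix)) {
    full <- rowSums(tx_matrix > fpkm_floor) == ncol(tx_matrix)
    pct_tx_all_conditions <- pct1(sum(full), nrow(tx_matrix))
  }
  c(as_summary_stats(sum(n_iso), n_genes),
    list(
      n_as_genes = sum(as_gene),
      pct_as_genes = pct1(sum(as_gene), n_genes),
      n_multiexonic = sum(multiexonic),
      pct_as_multiexonic = pct1(sum(as_gene & multiexonic), sum(multiexonic)),
      mean_isoforms_per_as_gene = if (any(as_gene))
        round(sum(n_iso[as_gene]) / sum(as_gene), 1) else NA_real_,
      n_events = sum(type_n),
      n_complex = sum(events$type == "complex"),
      type_table = type_tab,
      pct_tx_all_conditions = pct_tx_all_conditions))
}
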