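# Internal data model: genes and transcripts.
#
# All coordinates are 1-based inclusive (GFF3 convention) everywhere inside
# the package; conversion to BED's 0-based half-open happens only when a BED
# file is written.

#' Construct a transcript model
#'
#' A transcript is an ordered chain of genomic exons on one strand. Introns
#' are derived as the gaps between consecutive exons, so a transcript with
#' `n` exons has `n - 1` introns and its length is the sum of exon widths.
#'
#' @param tx_id transcript identifier.
#' @param gene_id identifier of the parent gene.
#' @param exons two-column numeric matrix (start, end), 1-based inclusive.
#'   Rows may be given in any order; they are sorted and validated: every
#'   exon must have `start <= end` and consecutive exons must be separated
#'   by at least one intronic base.
#' @param sequence optional nucleotide string (spliced transcript sequence).
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(tx_id, gene_id, exons, sequence = NULL) {
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L || nrow(exons) < 1L)
    stopf("transcript '%s': exons must be a matrix with 2 columns and >= 1 row", tx_id)
  storage.mode(exons) <- "double"
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  dimnames(exons) <- list(NULL, c("start", "end"))
  if (any(exons[, 2L] < exons[, 1L]))
    stopf("transcript '%s': exon with end < start", tx_id)
  if (nrow(exons) > 1L) {
    gap <- exons[-1L, 1L] - exons[-nrow(exons), 2L]
    if (any(gap < 2))
      stopf("transcript '%s': exons overlap or abut (no intron between them)", tx_id)
  }
  structure(
    list(tx_id = as.character(tx_id), gene_id = as.character(gene_id),
         exons = exons, sequence = sequence),
    class = "transcript_model")
}

#' Introns of a transcript
#'
#' @param tx a `transcript_model`.
#' @return two-column matrix (start, end) of introns; 0 rows for a
#'   single-exon transcript.
#' @export
tx_introns <- function(tx) {
  e <- tx$exons
  n <- nrow(e)
  if (n < 2L)
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  cbind(start = e[-n, 2L] + 1, end = e[-1L, 1L] - 1)
}

#' Spliced length of a transcript (sum of exon widths)
#' @param tx a `transcript_model`.
#' @export
tx_length <- function(tx) sum(tx$exons[, 2L] - tx$exons[, 1L] + 1)

#' Genomic span of a transcript
#' @param tx a `transcript_model`.
#' @return numeric vector `c(start, end)`.
#' @export
tx_span <- function(tx) c(tx$exons[1L, 1L], tx$exons[nrow(tx$exons), 2L])

#' Construct a gene model
#'
#' A located, stranded gene with a category flag (`full` or
#' `pseudogene_fragment`), a synteny flag, and one or more transcripts.
#' Defaults (`category = "full"`, `syntenic = FALSE`) are always materialised
#' so downstream code never meets a missing flag.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param start,end gene span, 1-based inclusive, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list of [transcript_model()] objects, all lying within
#'   `[start, end]`.
#' @param category `"full"` or `"pseudogene_fragment"`.
#' @param syntenic logical; whether the gene is positionally conserved with
#'   related grass genomes.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand, transcripts,
                       category = c("full", "pseudogene_fragment"),
                       syntenic = FALSE) {
  category <- match.arg(category)
  if (!strand %in% c("+", "-"))
    stopf("gene '%s': strand must be '+' or '-'", gene_id)
  if (end < start)
    stopf("gene '%s': end < start", gene_id)
  if (length(transcripts) < 1L)
    stopf("gene '%s': at least one transcript required", gene_id)
  for (tx in transcripts) {
    sp <- tx_span(tx)
    if (sp[1L] < start || sp[2L] > end)
      stopf("gene '%s': transcript '%s' lies outside the gene span",
            gene_id, tx$tx_id)
  }
  names(transcripts) <- vapply(transcripts, `[[`, "", "tx_id")
  structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         start = as.numeric(start), end = as.numeric(end), strand = strand,
         category = category, syntenic = isTRUE(syntenic),
         transcripts = transcripts),
    class = "gene_model")
}

#' Primary transcript of a gene
#'
#' The representative isoform used for all structural statistics: the
#' longest transcript by spliced length, ties broken by lowest transcript id.
#'
#' @param gene a `gene_model`.
#' @export
primary_transcript <- function(gene) {
  ids <- names(gene$transcripts)[id_order(names(gene$transcripts))]
  lens <- vapply(gene$transcripts[ids], tx_length, 0)
  gene$transcripts[[ids[which.max(lens)]]]
}

#' Gene-level table from a list of gene models
#'
#' @param genes list of `gene_model` objects.
#' @return data.frame with one row per gene (id, coordinates, strand,
#'   category, synteny, transcript count).
#' @export
gene_table <- function(genes) {
  df <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chrom = vapply(genes, `[[`, "", "chrom"),
    start = vapply(genes, `[[`, 0, "start"),
    end = vapply(genes, `[[`, 0, "end"),
    strand = vapply(genes, `[[`, "", "strand"),
    category = vapply(genes, `[[`, "", "category"),
    syntenic = vapply(genes, function(g) isTRUE(g$syntenic), NA),
    n_transcripts = vapply(genes, function(g) length(g$transcripts), 0L),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Structural features of genes (primary-transcript based)
#'
#' Computes, per gene, the features used by the expression-vs-structure
#' analysis: spliced transcript length, exon number, cumulative and mean
#' intron length, mean exon length, and isoform count. All features are
#' taken from the primary (longest) transcript.
#'
#' @param genes list of `gene_model` objects.
#' @return data.frame keyed by `gene_id`.
#' @export
structure_features <- function(genes) {
  rows <- lapply(genes, function(g) {
    tx <- primary_transcript(g)
    e <- tx$exons
    introns <- tx_introns(tx)
    ilen <- if (nrow(introns)) introns[, 2L] - introns[, 1L] + 1 else numeric(0)
    data.frame(
      gene_id = g$gene_id,
      transcript_length = sum(e[, 2L] - e[, 1L] + 1),
      exon_n = nrow(e),
      cum_intron_length = sum(ilen),
      mean_exon_length = mean(e[, 2L] - e[, 1L] + 1),
      mean_intron_length = if (length(ilen)) mean(ilen) else 0,
      n_isoforms = length(g$transcripts),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Validate a list of gene models
#'
#' Re-checks every invariant of the data model (spans, strand, exon order,
#' flags). Used by the synthetic generator's self-test and after file import.
#'
#' @param genes list of `gene_model` objects.
#' @return invisibly `TRUE`; errors on the first violation.
#' @export
validate_genes <- function(genes) {
  ids <- vapply(genes, `[[`, "", "gene_id")
  if (anyDuplicated(ids))
    stopf("duplicated gene ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (g in genes) {
    stopifnot(inherits(g, "gene_model"))
    # reconstruct to re-run all constructor checks
    gene_model(g$gene_id, g$chrom, g$start, g$end, g$strand, g$transcripts,
               category = g$category, syntenic = g$syntenic)
  }
  invisible(TRUE)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %s%s, %d transcript(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, x$category,
              if (x$syntenic) " syntenic" else "", length(x$transcripts)))
  invisible(x)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s), %d exon(s), length %d\n",
              x$tx_id, x$gene_id, nrow(x$exons), as.integer(tx_length(x))))
  invisible(x)
}
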