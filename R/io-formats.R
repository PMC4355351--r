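# File formats: GFF3 gene models, TSV FPKM matrices, BED6 output, FASTA.
#
# GFF3 parsing is delegated to rtracklayer; this module only validates the
# coordinates up front (to report the offending line) and assembles the
# internal gene/transcript model from the parsed features.

#' Read gene models from a GFF3 file
#'
#' Expects `gene`, `mRNA` (or `transcript`) and `exon` features linked by
#' `ID`/`Parent` attributes. Gene category and synteny are read from
#' configurable attribute keys and default to `full` / `FALSE` when absent.
#' Unknown feature types are ignored with a warning. Multi-chromosome files
#' are accepted.
#'
#' @param path GFF3 file.
#' @param category_key,syntenic_key attribute keys carrying the gene
#'   category (`full` / `pseudogene_fragment`) and synteny flag.
#' @return named list of [gene_model()] objects.
#' @export
read_gff3 <- function(path, category_key = "category", syntenic_key = "syntenic") {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) stopf("GFF3 line %d: fewer than 9 columns", i)
    s <- suppressWarnings(as.numeric(f[4L])); e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e)) stopf("GFF3 line %d: non-numeric coordinates", i)
    if (e < s) stopf("GFF3 line %d: end (%s) < start (%s)", i, f[5L], f[4L])
  }

  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  known <- c("gene", "mRNA", "transcript", "exon")
  if (any(!type %in% known))
    warnf("ignoring %d feature(s) of unknown type: %s",
          sum(!type %in% known),
          paste(unique(type[!type %in% known]), collapse = ", "))

  md <- as.data.frame(GenomicRanges::mcols(gr))
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, "")

  gi <- which(type == "gene")
  ti <- which(type %in% c("mRNA", "transcript"))
  ei <- which(type == "exon")
  if (any(is.na(parents[ei])))
    stopf("exon feature without a Parent attribute (feature %d in file)",
          ei[which(is.na(parents[ei]))][1L])
  tx_parent_gene <- stats::setNames(parents[ti], ids[ti])
  if (any(is.na(tx_parent_gene)))
    stopf("mRNA feature without a Parent gene")
  orphan <- setdiff(parents[ei], ids[ti])
  if (length(orphan))
    stopf("exon(s) with unknown parent transcript: %s",
          paste(orphan, collapse = ", "))

  exon_by_tx <- split(ei, parents[ei])
  genes <- vector("list", length(gi))
  starts <- GenomicRanges::start(gr); ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  for (k in seq_along(gi)) {
    i <- gi[k]
    gid <- ids[i]
    my_tx <- ids[ti][tx_parent_gene == gid]
    if (!length(my_tx))
      stopf("gene '%s' has no mRNA children", gid)
    txs <- lapply(my_tx, function(tid) {
      exi <- exon_by_tx[[tid]]
      if (is.null(exi)) stopf("transcript '%s' has no exons", tid)
      transcript_model(tid, gid, cbind(starts[exi], ends[exi]))
    })
    cat_val <- if (category_key %in% names(md) && !is.na(md[i, category_key]))
      as.character(md[i, category_key]) else "full"
    syn_raw <- if (syntenic_key %in% names(md) && !is.na(md[i, syntenic_key]))
      as.character(md[i, syntenic_key]) else "false"
    genes[[k]] <- gene_model(
      gid, chroms[i], starts[i], ends[i],
      strand = if (strands[i] %in% c("+", "-")) strands[i] else "+",
      transcripts = txs,
      category = if (identical(cat_val, "pseudogene_fragment"))
        "pseudogene_fragment" else "full",
      syntenic = tolower(syn_raw) %in% c("true", "1", "yes"))
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  genes
}

#' Write gene models to a GFF3 file
#'
#' Emits gene/mRNA/exon features with `ID`/`Parent` links plus the
#' `category` and `syntenic` gene attributes, so that
#' `read_gff3(write_gff3(x))` round-trips coordinates, strands, parent links
#' and flags exactly.
#'
#' @param genes list of [gene_model()] objects.
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, s, e, strand, attrs)
    sprintf("%s\ttxatlas\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, as.integer(s), as.integer(e), strand, attrs)
  for (g in genes) {
    writeLines(fmt(g$chrom, "gene", g$start, g$end, g$strand,
                   sprintf("ID=%s;category=%s;syntenic=%s", g$gene_id,
                           g$category, tolower(g$syntenic))), con)
    for (tx in g$transcripts) {
      sp <- tx_span(tx)
      writeLines(fmt(g$chrom, "mRNA", sp[1L], sp[2L], g$strand,
                     sprintf("ID=%s;Parent=%s", tx$tx_id, g$gene_id)), con)
      ex <- tx$exons
      for (r in seq_len(nrow(ex)))
        writeLines(fmt(g$chrom, "exon", ex[r, 1L], ex[r, 2L], g$strand,
                       sprintf("ID=%s.e%d;Parent=%s", tx$tx_id, r, tx$tx_id)),
                   con)
    }
  }
  invisible(path)
}

# --- expression matrix ------------------------------------------------------

#' Read an FPKM expression matrix from TSV
#'
#' First column holds locus ids; the header holds condition ids, optionally
#' tagged `organ:stage` (or `organ_stage`), which is parsed into condition
#' metadata retrievable with [condition_info()].
#'
#' @param path TSV file.
#' @return numeric matrix (loci x conditions) with a `conditions` attribute.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("expression matrix needs a locus column plus >= 1 condition")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stopf("duplicated locus id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      stopf("non-numeric FPKM at row '%s', column '%s'", ids[bad[1L]],
            names(vals)[j])
    if (anyNA(v))
      stopf("missing FPKM at row '%s', column '%s'", ids[which(is.na(v))[1L]],
            names(vals)[j])
    if (any(v < 0))
      stopf("negative FPKM at row '%s', column '%s'", ids[which(v < 0)[1L]],
            names(vals)[j])
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  attr(m, "conditions") <- parse_conditions(colnames(m))
  m
}

#' Write an FPKM matrix to TSV
#' @param mat numeric matrix with locus-id rownames.
#' @param path output file.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(locus_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse condition ids into organ/stage metadata
#'
#' Accepts `organ:stage` or `organ_stage` ids; anything else yields NA organ.
#'
#' @param ids character vector of condition ids.
#' @return data.frame(condition, organ, stage).
#' @export
parse_conditions <- function(ids) {
  parts <- regmatches(ids, regexec("^([A-Za-z]+)[:_](.+)$", ids))
  organ <- vapply(parts, function(p) if (length(p) == 3L) p[2L] else NA_character_, "")
  stage <- vapply(parts, function(p) if (length(p) == 3L) p[3L] else NA_character_, "")
  data.frame(condition = ids, organ = organ, stage = stage,
             stringsAsFactors = FALSE)
}

#' Condition metadata of an expression matrix
#' @param mat matrix returned by [read_expression_matrix()] (or any matrix;
#'   metadata is derived from column names if the attribute is absent).
#' @export
condition_info <- function(mat) {
  attr(mat, "conditions") %||% parse_conditions(colnames(mat))
}

# --- BED --------------------------------------------------------------------

#' Write intervals as BED6
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention (`start - 1`, `end`) at this boundary only.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path output file.
#' @param chrom_length optional chromosome length; intervals outside
#'   `[1, chrom_length]` raise an error.
#' @export
write_bed <- function(intervals, path, chrom_length = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (!nrow(intervals)) return(invisible(path))
  if (any(intervals$start < 1))
    stopf("interval start < 1 (internal coordinates are 1-based)")
  if (!is.null(chrom_length) && any(intervals$end > chrom_length))
    stopf("interval end beyond chromosome length %s", format(chrom_length))
  if (any(intervals$end < intervals$start)) stopf("interval with end < start")
  name <- intervals$name %||% rep(".", nrow(intervals))
  score <- intervals$score %||% rep(".", nrow(intervals))
  strand <- intervals$strand %||% rep(".", nrow(intervals))
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", intervals$chrom,
                     as.integer(intervals$start - 1), as.integer(intervals$end),
                     as.character(name), as.character(score), strand), con)
  invisible(path)
}

# --- FASTA ------------------------------------------------------------------

#' Read transcript sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta_sequences <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
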