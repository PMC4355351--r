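# Transcriptionally active regions (TARs): identification, classification
# into expressed genes / expressed pseudogenes / novel transcribed regions,
# lincRNA and cis-NAT calling, and the summary table.
#
# "Expressed" means FPKM > 0 in at least one condition; a configurable floor
# exists but defaults to 0.

#' Longest open reading frame of a nucleotide sequence
#'
#' Scans all six frames (both strands). An ORF is an `ATG` followed by an
#' in-frame stop codon; its length is counted in codons from the start codon
#' up to (excluding) the stop. Returns 0 when no complete ORF exists.
#'
#' @param sequence nucleotide string over `A`,`C`,`G`,`T`,`N`.
#' @return longest ORF length in amino acids (codons, stop excluded).
#' @export
find_longest_orf <- function(sequence) {
  if (is.null(sequence) || is.na(sequence) || !nzchar(sequence)) {
    warnf("empty sequence: ORF length 0")
    return(0L)
  }
  s <- toupper(sequence)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (str in c(s, rc)) {
    n <- nchar(str)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 2L) next
      at <- off + (seq_len(ncod) - 1L) * 3L + 1L
      codons <- substring(str, at, at + 2L)
      open_at <- NA_integer_
      for (i in seq_len(ncod)) {
        cd <- codons[i]
        if (is.na(open_at)) {
          if (cd == "ATG") open_at <- i
        } else if (cd %in% stops) {
          best <- max(best, i - open_at)
          open_at <- NA_integer_
        }
      }
    }
  }
  as.integer(best)
}

#' Identify and classify transcriptionally active regions
#'
#' One TAR is emitted per locus (annotated gene or novel transcribed region)
#' with FPKM above the floor in at least one condition. TAR class follows the
#' annotation: `gene_full`, `gene_pseudo` (pseudogenes and gene fragments),
#' or `NTR` for expressed loci with no annotated gene.
#'
#' @param genes list of [gene_model()] objects.
#' @param mat FPKM matrix (rows: gene and NTR locus ids).
#' @param ntr_intervals data.frame(ntr_id, chrom, start, end, strand) of
#'   novel transcribed region loci; strand may be NA (unstranded assembly).
#' @param fpkm_floor expression floor; a locus is expressed when any
#'   condition exceeds it (default 0, i.e. FPKM > 0).
#' @return data.frame of TARs (tar_id, chrom, start, end, strand, class,
#'   gene_id, breadth).
#' @export
call_tars <- function(genes, mat, ntr_intervals = NULL, fpkm_floor = 0) {
  gt <- gene_table(genes)
  ntr <- ntr_intervals
  if (is.null(ntr))
    ntr <- data.frame(ntr_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  known <- c(gt$gene_id, ntr$ntr_id)
  orphans <- setdiff(rownames(mat), known)
  if (length(orphans))
    stopf("matrix rows without annotation or NTR interval: %s",
          paste(utils::head(orphans, 5L), collapse = ", "))

  expressed <- rownames(mat)[rowSums(mat > fpkm_floor) > 0]
  breadth <- rowSums(mat > fpkm_floor)

  gsel <- gt[gt$gene_id %in% expressed, , drop = FALSE]
  nsel <- ntr[ntr$ntr_id %in% expressed, , drop = FALSE]
  g_tars <- data.frame(
    tar_id = gsel$gene_id, chrom = gsel$chrom, start = gsel$start,
    end = gsel$end, strand = gsel$strand,
    class = ifelse(gsel$category == "pseudogene_fragment", "gene_pseudo", "gene_full"),
    gene_id = gsel$gene_id, stringsAsFactors = FALSE)
  n_tars <- data.frame(
    tar_id = nsel$ntr_id, chrom = nsel$chrom, start = nsel$start,
    end = nsel$end,
    strand = if (is.null(nsel$strand)) rep(NA_character_, nrow(nsel))
             else as.character(nsel$strand),
    class = rep("NTR", nrow(nsel)),
    gene_id = rep(NA_character_, nrow(nsel)), stringsAsFactors = FALSE)
  tars <- rbind(g_tars, n_tars)
  tars <- tars[id_order(tars$tar_id), , drop = FALSE]
  tars$breadth <- as.integer(breadth[tars$tar_id])
  rownames(tars) <- NULL
  tars
}

#' Classify putative lincRNAs among NTR TARs
#'
#' Applies the three filters conjunctively: transcript length strictly
#' greater than `min_length_nt` (default 200 nt), longest ORF at most
#' `max_orf_aa` (default 300 AA; 300 itself passes), and no protein
#' similarity (an externally supplied flag; homology search is out of
#' scope). NTRs without a sequence are marked uncallable.
#'
#' @param ntr_tars data.frame of NTR TARs (needs `tar_id`).
#' @param sequences named character vector of NTR transcript sequences.
#' @param similarity_flags named logical vector: TRUE when the NTR has
#'   protein similarity.
#' @param min_length_nt,max_orf_aa filter thresholds.
#' @return data.frame(tar_id, length_nt, orf_aa, has_protein_similarity,
#'   callable, is_lincRNA) retaining all intermediate values.
#' @export
classify_lincRNAs <- function(ntr_tars, sequences, similarity_flags,
                              min_length_nt = 200, max_orf_aa = 300) {
  ids <- ntr_tars$tar_id
  callable <- ids %in% names(sequences) &
    !is.na(sequences[ids]) & nzchar(sequences[ids])
  if (any(!callable))
    warnf("%d NTR(s) without sequence marked uncallable", sum(!callable))
  len <- ifelse(callable, nchar(sequences[ids]), NA_integer_)
  orf <- rep(NA_integer_, length(ids))
  orf[callable] <- vapply(sequences[ids[callable]], find_longest_orf, 0L)
  sim <- as.logical(similarity_flags[ids])
  sim[is.na(sim)] <- FALSE
  is_linc <- callable & len > min_length_nt & orf <= max_orf_aa & !sim
  data.frame(tar_id = ids, length_nt = as.integer(len), orf_aa = orf,
             has_protein_similarity = sim, callable = callable,
             is_lincRNA = is_linc, stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect cis-natural antisense transcripts
#'
#' A gene carries a cis-NAT when it is expressed on its sense strand and
#' overlapped by opposite-strand transcription over at least
#' `min_overlap_bp` bases (largest single antisense interval overlap).
#'
#' @param genes list of [gene_model()] objects.
#' @param antisense_table data.frame(chrom, start, end, strand) of stranded
#'   antisense transcription intervals.
#' @param mat FPKM matrix used to establish sense-strand expression.
#' @param min_overlap_bp minimum overlap (default 1 bp).
#' @param fpkm_floor expression floor.
#' @return data.frame(gene_id, antisense_overlap_bp, is_cis_nat).
#' @export
detect_cis_nats <- function(genes, antisense_table, mat,
                            min_overlap_bp = 1, fpkm_floor = 0) {
  gt <- gene_table(genes)
  at <- antisense_table
  bad <- setdiff(unique(at$chrom), unique(gt$chrom))
  if (length(bad))
    stopf("antisense interval(s) on unknown chromosome: %s",
          paste(bad, collapse = ", "))
  expressed <- rownames(mat)[rowSums(mat > fpkm_floor) > 0]
  ov <- numeric(nrow(gt))
  for (k in seq_len(nrow(gt))) {
    opp <- at[at$chrom == gt$chrom[k] & at$strand != gt$strand[k], , drop = FALSE]
    if (!nrow(opp)) next
    o <- pmin(opp$end, gt$end[k]) - pmax(opp$start, gt$start[k]) + 1
    ov[k] <- max(0, o)
  }
  data.frame(gene_id = gt$gene_id, antisense_overlap_bp = ov,
             is_cis_nat = gt$gene_id %in% expressed & ov >= min_overlap_bp,
             stringsAsFactors = FALSE)
}

#' Summary statistics from TAR class counts
#'
#' The arithmetic core of the TAR summary table: takes class counts (either
#' computed by [summarize_tars()] or transcribed from a published table) and
#' derives the headline percentages (reported to 1 decimal) and the mean TAR
#' spacing in kb.
#'
#' @param n_predicted,n_expressed predicted and expressed gene-model counts
#'   (full genes plus pseudogenes/fragments).
#' @param n_predicted_full,n_expressed_full same, full genes only.
#' @param n_predicted_pseudo,n_expressed_pseudo same, pseudogenes/fragments.
#' @param n_ntr expressed novel transcribed regions.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_multicopy_pseudo optional: expressed pseudogenes with additional
#'   genomic copies (input count; copy detection is out of scope).
#' @param n_cis_nat optional: expressed genes with antisense transcription.
#' @param n_lincRNA optional: putative lincRNA count among NTRs.
#' @return list of counts and derived statistics.
#' @export
tar_summary_stats <- function(n_predicted, n_expressed,
                              n_predicted_full, n_expressed_full,
                              n_predicted_pseudo, n_expressed_pseudo,
                              n_ntr, chrom_length_bp,
                              n_multicopy_pseudo = NA, n_cis_nat = NA,
                              n_lincRNA = NA) {
  n_tars <- n_expressed + n_ntr
  list(
    n_predicted = n_predicted, n_expressed = n_expressed,
    n_predicted_full = n_predicted_full, n_expressed_full = n_expressed_full,
    n_predicted_pseudo = n_predicted_pseudo,
    n_expressed_pseudo = n_expressed_pseudo,
    n_ntr = n_ntr, n_tars = n_tars,
    pct_expressed = pct1(n_expressed, n_predicted),
    pct_full_expressed = pct1(n_expressed_full, n_predicted_full),
    pct_pseudo_expressed = pct1(n_expressed_pseudo, n_predicted_pseudo),
    mean_tar_spacing_kb = if (n_tars > 0)
      round(chrom_length_bp / 1000 / n_tars, 1) else NA_real_,
    n_multicopy_pseudo = n_multicopy_pseudo,
    pct_multicopy_pseudo = if (is.na(n_multicopy_pseudo)) NA_real_ else
      pct1(n_multicopy_pseudo, n_expressed_pseudo),
    n_cis_nat = n_cis_nat,
    pct_cis_nat = if (is.na(n_cis_nat)) NA_real_ else pct1(n_cis_nat, n_expressed),
    n_lincRNA = n_lincRNA,
    pct_ntr_of_tars = pct1(n_ntr, n_tars))
}

#' Summarize a TAR set against its annotation
#'
#' Counts expressed loci per class, relates them to the predicted annotation
#' and derives the headline percentages via [tar_summary_stats()].
#'
#' @param tars data.frame from [call_tars()].
#' @param genes list of [gene_model()] objects (the predicted annotation).
#' @param chrom_length_bp chromosome length in bp.
#' @param cis_nat_calls optional data.frame from [detect_cis_nats()].
#' @param lincRNA_calls optional data.frame from [classify_lincRNAs()].
#' @return list of counts and percentages (see [tar_summary_stats()]).
#' @export
summarize_tars <- function(tars, genes, chrom_length_bp,
                           cis_nat_calls = NULL, lincRNA_calls = NULL) {
  gt <- gene_table(genes)
  tar_summary_stats(
    n_predicted = nrow(gt),
    n_expressed = sum(tars$class %in% c("gene_full", "gene_pseudo")),
    n_predicted_full = sum(gt$category == "full"),
    n_expressed_full = sum(tars$class == "gene_full"),
    n_predicted_pseudo = sum(gt$category == "pseudogene_fragment"),
    n_expressed_pseudo = sum(tars$class == "gene_pseudo"),
    n_ntr = sum(tars$class == "NTR"),
    chrom_length_bp = chrom_length_bp,
    n_cis_nat = if (is.null(cis_nat_calls)) NA else sum(cis_nat_calls$is_cis_nat),
    n_lincRNA = if (is.null(lincRNA_calls)) NA else
      sum(lincRNA_calls$is_lincRNA, na.rm = TRUE))
}
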