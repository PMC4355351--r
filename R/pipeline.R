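# End-to-end orchestration: one config, all stages, a report bundle.
#
# Every threshold the analysis uses is a config default here, never
# hard-coded inside stage logic.

#' Run configuration
#'
#' Collects every tunable constant of the pipeline: the FPKM floor (0), the
#' lincRNA filters (200 nt / 300 AA), the cis-NAT minimum overlap (1 bp),
#' the insula gap (30 kb), the cluster similarity cut (0.641), the sliding
#' window (10 Mb / 1 Mb step, rescaled for shrunken synthetic chromosomes),
#' the 30 expression bins and the 5/200 FPKM level cuts, and the region
#' table.
#'
#' @param fpkm_floor expression floor.
#' @param lincrna_min_length_nt,lincrna_max_orf_aa lincRNA filters.
#' @param cisnat_min_overlap_bp minimum antisense overlap.
#' @param insula_gap_bp intergenic gap threshold.
#' @param cluster_cut_similarity dendrogram cut similarity.
#' @param window_bp,step_bp sliding-window geometry.
#' @param n_bins number of expression bins.
#' @param level_cuts low/medium and medium/high FPKM cuts.
#' @param regions region table (data.frame name/start/end) or NULL to derive
#'   from the chromosome length.
#' @param seed seed for any stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(fpkm_floor = 0, lincrna_min_length_nt = 200,
                       lincrna_max_orf_aa = 300, cisnat_min_overlap_bp = 1,
                       insula_gap_bp = 30000, cluster_cut_similarity = 0.641,
                       window_bp = 1e7, step_bp = 1e6, n_bins = 30,
                       level_cuts = c(5, 200), regions = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Generate a synthetic input bundle on disk
#'
#' Runs [generate_chromosome()] and writes the files [run_all()] reads:
#' annotation GFF3, FPKM TSV, NTR intervals TSV, transcript FASTA,
#' antisense TSV, similarity flags TSV, truth labels JSON and the config as
#' YAML.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the in-memory bundle.
#' @export
simulate <- function(config = synthetic_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- generate_chromosome(config)
  write_gff3(bundle$genes, file.path(out_dir, "annotation.gff3"))
  write_expression_matrix(bundle$matrix, file.path(out_dir, "fpkm.tsv"))
  utils::write.table(bundle$ntr_intervals, file.path(out_dir, "ntr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta_sequences(bundle$sequences, file.path(out_dir, "transcripts.fa"))
  utils::write.table(bundle$antisense, file.path(out_dir, "antisense.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(ntr_id = names(bundle$similarity_flags),
               protein_similar = unname(bundle$similarity_flags)),
    file.path(out_dir, "similarity.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- bundle$config
  cfg$regions <- NULL
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(bundle)
}

#' Read an input bundle written by [simulate()]
#'
#' @param in_dir directory with `annotation.gff3`, `fpkm.tsv`, `ntr.tsv` and
#'   optionally `transcripts.fa`, `antisense.tsv`, `similarity.tsv`.
#' @return list shaped like the output of [generate_chromosome()] (without
#'   truth labels).
#' @export
read_bundle <- function(in_dir) {
  p <- function(f) file.path(in_dir, f)
  ntr <- utils::read.delim(p("ntr.tsv"), stringsAsFactors = FALSE)
  list(
    genes = read_gff3(p("annotation.gff3")),
    matrix = read_expression_matrix(p("fpkm.tsv")),
    ntr_intervals = ntr,
    sequences = if (file.exists(p("transcripts.fa")))
      read_fasta_sequences(p("transcripts.fa")) else NULL,
    antisense = if (file.exists(p("antisense.tsv")))
      utils::read.delim(p("antisense.tsv"), stringsAsFactors = FALSE) else NULL,
    similarity_flags = if (file.exists(p("similarity.tsv"))) {
      sf <- utils::read.delim(p("similarity.tsv"), stringsAsFactors = FALSE)
      stats::setNames(as.logical(sf$protein_similar), sf$ntr_id)
    } else NULL)
}

#' Run the full transcriptome-map analysis
#'
#' Executes the stages in order — TAR classification, expression profiles
#' and binning, AS event typing, window tracks with segmentation and region
#' statistics, clustering with insulae and neighbour pairs — and returns a
#' report bundle plus a machine-readable summary. Stages whose optional
#' inputs are absent (e.g. no FASTA for the lincRNA filters) are skipped
#' with an explicit status rather than failing the run.
#'
#' @param bundle input list: `genes`, `matrix`, `ntr_intervals`, and
#'   optionally `sequences`, `antisense`, `similarity_flags` (from
#'   [generate_chromosome()] or [read_bundle()]).
#' @param chrom_length chromosome length in bp (default: max annotated end).
#' @param config a [run_config()].
#' @param out_dir optional directory for the TSV/BED/JSON report files.
#' @return list with per-stage results and `summary` (all headline counts
#'   and percentages).
#' @export
run_all <- function(bundle, chrom_length = NULL, config = run_config(),
                    out_dir = NULL) {
  genes <- bundle$genes
  mat <- bundle$matrix
  gt <- gene_table(genes)
  chrom_length <- chrom_length %||%
    max(gt$end, bundle$ntr_intervals$end %||% 0)
  regions <- config$regions %||% default_regions(chrom_length)
  set.seed(config$seed)

  # stage 1: TARs ------------------------------------------------------------
  tars <- call_tars(genes, mat, bundle$ntr_intervals,
                    fpkm_floor = config$fpkm_floor)
  ntr_tars <- tars[tars$class == "NTR", , drop = FALSE]
  linc <- NULL
  linc_status <- "skipped: no sequences"
  if (!is.null(bundle$sequences)) {
    linc <- classify_lincRNAs(
      ntr_tars, bundle$sequences,
      bundle$similarity_flags %||%
        stats::setNames(rep(FALSE, nrow(ntr_tars)), ntr_tars$tar_id),
      min_length_nt = config$lincrna_min_length_nt,
      max_orf_aa = config$lincrna_max_orf_aa)
    linc_status <- "ok"
  }
  nats <- NULL
  if (!is.null(bundle$antisense) && nrow(bundle$antisense))
    nats <- detect_cis_nats(genes, bundle$antisense, mat,
                            min_overlap_bp = config$cisnat_min_overlap_bp,
                            fpkm_floor = config$fpkm_floor)
  tar_summary <- summarize_tars(tars, genes, chrom_length,
                                cis_nat_calls = nats, lincRNA_calls = linc)

  # stage 2: expression profiles and structure bins ---------------------------
  profiles <- profile_expression(mat, level_cuts = config$level_cuts,
                                 fpkm_floor = config$fpkm_floor)
  structures <- structure_features(genes)
  expressed_gene_ids <- tars$tar_id[tars$class %in% c("gene_full", "gene_pseudo")]
  categories <- list(
    full = gt$gene_id[gt$category == "full"],
    pseudogene = gt$gene_id[gt$category == "pseudogene_fragment"],
    syntenic = gt$gene_id[gt$syntenic],
    non_syntenic = gt$gene_id[!gt$syntenic])
  if (!is.null(nats))
    categories$cis_nat <- nats$gene_id[nats$is_cis_nat]
  breadth_dist <- suppressWarnings(
    breadth_distribution(profiles, categories, n_conditions = ncol(mat)))
  bins <- NULL; inflexion <- NULL
  expr_full <- profiles[profiles$expressed &
                          profiles$locus_id %in% expressed_gene_ids, , drop = FALSE]
  if (nrow(expr_full) >= config$n_bins) {
    bins <- bin_by_expression(expr_full, structures, n_bins = config$n_bins)
    inflexion <- lapply(
      stats::setNames(nm = c("transcript_length", "exon_n",
                             "cum_intron_length", "n_isoforms")),
      function(f) detect_inflexion(bins, f)[c("bin", "monotone")])
  }

  # stage 3: alternative splicing --------------------------------------------
  expressed_genes <- genes[intersect(names(genes), expressed_gene_ids)]
  events <- classify_as_events_all(expressed_genes)
  splice_summary <- as_summary(expressed_genes, events)

  # stage 4: chromosome partitioning -----------------------------------------
  mk_track <- function(df) if (nrow(df))
    track_zscore(windowed_density(df, chrom_length, config$window_bp,
                                  config$step_bp, chrom = gt$chrom[1L]))
    else NULL
  expressed_tab <- gt[gt$gene_id %in% expressed_gene_ids, , drop = FALSE]
  tracks <- list(
    predicted_genes = mk_track(gt),
    expressed_genes = mk_track(expressed_tab),
    non_expressed_genes = mk_track(gt[!gt$gene_id %in% expressed_gene_ids, ,
                                      drop = FALSE]),
    ntr = mk_track(bundle$ntr_intervals))
  if (!is.null(nats))
    tracks$cis_nat <- mk_track(gt[gt$gene_id %in%
                                    nats$gene_id[nats$is_cis_nat], , drop = FALSE])
  tracks <- Filter(Negate(is.null), tracks)
  segmentation <- lapply(tracks, segment_track)
  # gradient: expressed-gene density vs distance to the centromere (midpoint
  # of the C region)
  centromere <- mean(unlist(regions[regions$name == "C", c("start", "end")]))
  tr <- tracks$expressed_genes
  gradient <- spearman_gradient(
    tr$value, abs((tr$start + tr$end) / 2 - centromere))
  feat_tab <- merge(cbind(gt[c("gene_id", "start", "end")],
                          mean_expr = profiles$mean_expr[match(gt$gene_id,
                                                               profiles$locus_id)],
                          breadth = profiles$breadth[match(gt$gene_id,
                                                           profiles$locus_id)]),
                    structures, by = "gene_id")
  region_stats <- region_feature_stats(
    feat_tab[feat_tab$gene_id %in% expressed_gene_ids, , drop = FALSE], regions)

  # stage 5: co-expression ----------------------------------------------------
  full_expr_ids <- tars$tar_id[tars$class == "gene_full"]
  clusters <- cluster_profiles(mat[full_expr_ids, , drop = FALSE],
                               cut_similarity = config$cluster_cut_similarity)
  ins <- detect_insulae(gt[gt$gene_id %in% expressed_gene_ids,
                           c("gene_id", "chrom", "start", "end")],
                        gap_threshold = config$insula_gap_bp)
  pairs <- coexpressed_pairs(ins$membership,
                             stats::setNames(gt$strand, gt$gene_id), clusters)
  composition <- cluster_region_composition(
    clusters, gt[c("gene_id", "start", "end")], regions)

  summary <- list(
    chrom_length_bp = chrom_length,
    tar = tar_summary,
    lincRNA_status = linc_status,
    n_lincRNA = if (is.null(linc)) NA else sum(linc$is_lincRNA, na.rm = TRUE),
    expression = list(
      n_expressed = sum(profiles$expressed),
      mean_breadth = round(mean(profiles$breadth[profiles$expressed &
                                                   profiles$locus_id %in%
                                                   expressed_gene_ids]), 1),
      pct_all_conditions = pct1(
        sum(profiles$breadth[profiles$locus_id %in% expressed_gene_ids] ==
              ncol(mat)),
        length(expressed_gene_ids)),
      inflexion = lapply(inflexion %||% list(), `[[`, "bin")),
    splicing = splice_summary[c("n_transcripts", "n_genes",
                                "mean_isoforms_per_gene", "pct_as_genes",
                                "pct_as_multiexonic")],
    as_type_pct = stats::setNames(splice_summary$type_table$pct,
                                  splice_summary$type_table$type),
    gradient = gradient,
    n_changepoints = vapply(segmentation, function(s)
      length(s$changepoints), 0L),
    clustering = list(k = attr(clusters, "k")),
    insulae = ins$stats,
    pairs = pairs$stats)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(cbind(tars, name = tars$tar_id, score = "."),
              file.path(out_dir, "tars.bed"), chrom_length)
    utils::write.table(profiles, file.path(out_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bins))
      utils::write.table(bins, file.path(out_dir, "expression_bins.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(events, file.path(out_dir, "as_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(tracks))
      utils::write.table(tracks[[nm]],
                         file.path(out_dir, paste0("track_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clusters, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pairs$pairs, file.path(out_dir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  list(tars = tars, lincRNA = linc, cis_nats = nats, profiles = profiles,
       breadth_distribution = breadth_dist, bins = bins,
       inflexion = inflexion, events = events, tracks = tracks,
       gradient = gradient, segmentation = segmentation,
       region_stats = region_stats,
       clusters = clusters, insulae = ins, pairs = pairs,
       composition = composition, summary = summary)
}
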