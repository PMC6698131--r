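# The two integrative workflows: sequence->structure->function (method 1)
# and function->structure->sequence (method 2), plus the run manifest.

default_config <- function(config = list()) {
  defaults <- list(
    min_precursor = 60L, max_precursor = 150L, spacer_min = 1L,
    conservation_threshold = 0.8, specificity_threshold = 2,
    saturation_cap = NULL,
    sweep_from = 11.5, sweep_to = 0.5, sweep_by = 0.5,
    fine_cutoff = 1.5, coarse_cutoff = 3,
    keywords = c("defense", "resistance"),
    top_fraction = 0.30, min_cluster_size = 3L,
    seed = 1L)
  defaults[names(config)] <- config
  defaults
}

run_manifest <- function(config, inputs) {
  list(tool = "nsltp",
       version = as.character(packageVersion("nsltp")),
       config = config[order(names(config))],
       inputs = inputs)
}

write_manifest <- function(manifest, outdir) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(NULL)
}

#' Integrative method 1: sequence -> structure -> function
#'
#' Filters the sequence set on the nsLTP membership criteria, builds the
#' alignment consensus (overall and per tree clade), computes the FAST
#' specificity/conservation tables and the conserved-core and SDP reports.
#'
#' @param sequences named character vector of mature sequences.
#' @param aln [nsltp_alignment()] of (a subset of) those sequences.
#' @param tree rooted guide tree over the alignment ids.
#' @param config named list overriding the defaults (thresholds, precursor
#'   bounds, saturation cap, seed).
#' @param precursor_lengths optional named precursor lengths for the length
#'   criterion.
#' @param outdir optional directory; when given, reports, consensus FASTA,
#'   colored SVG and a run manifest are written there.
#' @return list with `filter_report`, `consensus` (overall string),
#'   `clade_consensus` (per-clade strings), `scores` ([fast_scores()]),
#'   `reports` ([report_positions()]), `colors` ([colorize()]) and
#'   `manifest`.
#' @export
run_method1 <- function(sequences, aln, tree, config = list(),
                        precursor_lengths = NULL, outdir = NULL) {
  cfg <- default_config(config)
  filter_report <- filter_sequences(
    sequences, precursor_lengths = precursor_lengths,
    min_precursor = cfg$min_precursor, max_precursor = cfg$max_precursor,
    spacer_min = cfg$spacer_min)
  clades <- enumerate_tree_clusters(tree, expected_ids = rownames(aln))
  clade_consensus <- vapply(clades, function(ids)
    build_consensus(subset_alignment(aln, ids)), character(1L))
  scores <- fast_scores(aln, tree)
  reports <- report_positions(scores,
                              conservation_threshold = cfg$conservation_threshold,
                              specificity_threshold = cfg$specificity_threshold)
  leaf_order <- tree$tip.label
  colors <- colorize(aln, leaf_order, scores,
                     saturation_cap = cfg$saturation_cap)
  manifest <- run_manifest(cfg, list(
    n_sequences = length(sequences), n_aligned = nrow(aln),
    n_columns = ncol(aln)))
  if (!is.null(outdir)) {
    write_manifest(manifest, outdir)
    write.table(filter_report, file.path(outdir, "filter_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(c(consensus = build_consensus(aln), clade_consensus),
                file.path(outdir, "consensus.fasta"))
    write_fast_tsv(scores, file.path(outdir, "fast_scores.tsv"))
    write.table(reports$sdp, file.path(outdir, "sdp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(reports$conserved_core,
                file.path(outdir, "conserved_core.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    render_alignment_svg(aln, colors,
                         file.path(outdir, "alignment.svg"))
  }
  list(filter_report = filter_report, consensus = build_consensus(aln),
       clade_consensus = clade_consensus, scores = scores,
       reports = reports, colors = colors, manifest = manifest)
}

#' Integrative method 2: function -> structure -> sequence
#'
#' Pairwise Kabsch RMSD matrix, structural distance tree, cutoff-sweep
#' clustering, annotation enrichment, medoid selection and rvET traces for
#' three groups mirroring the defense-cluster analysis: (i) the
#' best-enriched cluster at the fine cutoff, (ii) the cluster containing it
#' at the coarse cutoff, and (iii) the set of all annotated structures.
#' The trace of group (i) is the reference in the cross-cluster comparison.
#'
#' @param structures list of [coordinate_set()] objects.
#' @param master_aln master alignment containing all structure ids (columns
#'   shared across all traces).
#' @param annotations annotation table (`id`, `keywords`).
#' @param correspondences optional correspondence table for the RMSD
#'   computation; by default derived from the master alignment's shared
#'   non-gap columns.
#' @param config named list overriding the defaults (sweep bounds, fine and
#'   coarse cutoffs, keywords, top fraction, minimum cluster size, seed).
#' @param outdir optional output directory (matrix, tree, cluster report,
#'   traces, comparison TSV, JSON tree export, manifest).
#' @return list with `rmsd`, `tree`, `sweep` (all partitions), `enrichment`
#'   (at the fine cutoff), `groups` (member-id lists), `medoids`, `traces`
#'   (named `nsltp_trace` list), `comparison` and `manifest`.
#' @export
run_method2 <- function(structures, master_aln, annotations,
                        correspondences = NULL, config = list(),
                        outdir = NULL) {
  cfg <- default_config(config)
  ids <- vapply(structures, `[[`, character(1L), "id")
  if (is.null(correspondences))
    correspondences <- correspondences_from_alignment(
      subset_alignment(master_aln, ids))
  rmsd <- pairwise_rmsd_matrix(structures, correspondences)
  tree <- build_distance_tree(rmsd)
  sweep <- sweep_clusters(rmsd, cfg$sweep_from, cfg$sweep_to, cfg$sweep_by)

  fine <- cut_clusters(rmsd, cfg$fine_cutoff)
  enrichment <- annotation_enrichment(fine, annotations, cfg$keywords)
  eligible <- enrichment$size >= cfg$min_cluster_size
  if (!any(eligible)) stop_nsltp("no cluster of size >= %d at cutoff %.2f",
                                 cfg$min_cluster_size, cfg$fine_cutoff)
  pick <- which(eligible)[order(-enrichment$annotated_fraction[eligible],
                                -enrichment$size[eligible])][1L]
  defense_like <- fine[[pick]]$member_ids

  coarse <- cut_clusters(rmsd, cfg$coarse_cutoff)
  containing <- Filter(function(cl) all(defense_like %in% cl$member_ids),
                       coarse)
  broad <- if (length(containing) > 0L) containing[[1L]]$member_ids
           else rownames(rmsd)
  annotated <- intersect(annotated_ids(annotations, cfg$keywords),
                         rownames(rmsd))

  groups <- list(fine = defense_like, broad = broad)
  if (length(annotated) >= 2L) groups$annotated <- sort(annotated)
  medoids <- lapply(groups, select_medoid, m = rmsd)
  ref_id <- medoids$fine
  traces <- lapply(groups, function(mem) {
    sub <- subset_alignment(master_aln, mem)
    compute_trace(sub, ref_id = if (ref_id %in% mem) ref_id
                  else select_medoid(mem, rmsd))
  })
  comparison <- compare_traces(traces$fine, traces[-1L],
                               fraction = cfg$top_fraction)
  manifest <- run_manifest(cfg, list(
    n_structures = length(structures),
    n_columns = ncol(master_aln),
    n_annotated = length(annotated)))
  if (!is.null(outdir)) {
    write_manifest(manifest, outdir)
    write_rmsd_tsv(rmsd, file.path(outdir, "rmsd_matrix.tsv"))
    ape::write.tree(tree, file.path(outdir, "structure_tree.nwk"))
    write_cluster_tsv(fine, file.path(outdir, "clusters_fine.tsv"),
                      annotations = annotations, keywords = cfg$keywords)
    export_tree_json(tree, file.path(outdir, "structure_tree.json"),
                     annotations = annotations, keywords = cfg$keywords)
    for (nm in names(traces))
      write_trace_tsv(traces[[nm]],
                      file.path(outdir, sprintf("trace_%s.tsv", nm)))
    write.table(comparison, file.path(outdir, "trace_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(rmsd = rmsd, tree = tree, sweep = sweep, enrichment = enrichment,
       groups = groups, medoids = medoids, traces = traces,
       comparison = comparison, manifest = manifest)
}
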