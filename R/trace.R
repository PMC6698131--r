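# Structural Trace Display: real-valued evolutionary-trace (rvET) residue
# ranking of a cluster's alignment, tie-aware rank/coverage/variability
# tables and cross-cluster comparison.
#
# The rvET score of column i is
#   rho_i = 1 + sum_{n=1}^{N-1} (1/n) * sum_{g=1}^{n} H(g, i)
# where the n-group partition cuts the grouping tree below its n-1 highest
# internal nodes and H(g, i) is the natural-log Shannon entropy of column i
# within group g over 21 states (20 amino acids + gap).  Invariant columns
# score exactly 1 (most conserved); every score is >= 1.

# symbol ordering used for deterministic tie-breaks ('.' sorts first)
symbol_rank <- function(sym) match(sym, c(GAP, sort(AA20)))

aln_to_int <- function(aln) {
  m <- matrix(match(unclass(aln), ALPHABET21), nrow = nrow(aln),
              dimnames = dimnames(aln))
  m
}

#' UPGMA grouping tree from pairwise sequence identity
#'
#' Distances are fractional mismatches over the columns where both
#' sequences are ungapped (distance 1 when no column is shared); the tree
#' is built by UPGMA (average linkage), giving a rooted ultrametric tree.
#' Ids are processed in lexicographic order so ties resolve
#' deterministically.
#'
#' @inheritParams n_columns
#' @return a rooted `phylo` tree with branch lengths.
#' @export
identity_distance_tree <- function(aln) {
  stopifnot(inherits(aln, "nsltp_aln"))
  if (nrow(aln) < 2L) stop_nsltp("grouping tree needs at least 2 sequences")
  aln <- subset_alignment(aln, sort(rownames(aln)))
  ids <- rownames(aln)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  gapm <- unclass(aln) == GAP
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    shared <- !gapm[a, ] & !gapm[b, ]
    d[a, b] <- d[b, a] <- if (!any(shared)) 1 else
      mean(aln[a, shared] != aln[b, shared])
  }
  hc <- hclust(as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  # as.phylo.hclust halves merge heights into edge lengths; heights only
  # order the partition schedule, so the factor is immaterial
  tr
}

# Partition schedule of a rooted grouping tree: internal nodes ordered by
# distance from the root (ascending; the "highest" nodes of a dendrogram
# drawn root-up), ties by pre-order.  Returns the node order plus per-node
# tip sets; polytomies are resolved to binary with zero-length branches so
# cutting below j nodes always yields j+1 groups.
tree_schedule <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop_nsltp("grouping tree must be rooted")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  pre <- unique(reorder(tree, "cladewise")$edge[, 1L])  # pre-order internals
  ord <- pre[order(depth[pre], match(pre, pre))]
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  tips_of <- function(node) {
    if (node <= ntip) tree$tip.label[node] else labels[parts[[node - ntip]]]
  }
  children_of <- function(node) tree$edge[tree$edge[, 1L] == node, 2L]
  list(tree = tree, ntip = ntip, order = ord,
       tips_of = tips_of, children_of = children_of)
}

#' Real-valued evolutionary-trace scores of alignment columns
#'
#' @inheritParams n_columns
#' @param tree optional rooted grouping tree (leaves = alignment ids); by
#'   default the [identity_distance_tree()] of the alignment.
#' @return numeric vector of one score per alignment column, each >= 1;
#'   exactly 1 for invariant columns.
#' @export
rvet_scores <- function(aln, tree = NULL) {
  stopifnot(inherits(aln, "nsltp_aln"))
  if (is.null(tree)) tree <- identity_distance_tree(aln)
  if (!setequal(tree$tip.label, rownames(aln)) ||
      length(tree$tip.label) != nrow(aln))
    stop_nsltp("tree leaves do not match alignment ids")
  N <- nrow(aln)
  L <- ncol(aln)
  if (N < 2L) return(rep(1, L))
  sched <- tree_schedule(tree)
  int <- aln_to_int(aln)
  col_entropy <- function(ids) {
    sub <- int[ids, , drop = FALSE]
    vapply(seq_len(L), function(j)
      shannon_entropy(tabulate(sub[, j], 21L)), numeric(1L))
  }
  node_H <- lapply(sched$order, function(v) col_entropy(sched$tips_of(v)))
  names(node_H) <- as.character(sched$order)
  H_of <- function(v) {
    if (v <= sched$ntip) rep(0, L) else node_H[[as.character(v)]]
  }
  rho <- rep(1, L)
  Tn <- H_of(sched$order[1L])  # level 1: one group, the root's tips
  for (n in seq_len(N - 1L)) {
    rho <- rho + Tn / n
    w <- sched$order[n]        # nth node in the schedule splits next
    kids <- sched$children_of(w)
    Tn <- Tn - H_of(w)
    for (k in kids) Tn <- Tn + H_of(k)
  }
  rho
}

#' Distinct symbols of a column, most frequent first
#'
#' @inheritParams column_profile
#' @return single string, e.g. `"AV"` or `".AD"`; ties break with `"."`
#'   first then alphabetically.
#' @export
column_variability <- function(aln, col) {
  prof <- column_profile(aln, col)
  syms <- names(prof)[order(-prof, symbol_rank(names(prof)))]
  paste(syms, collapse = "")
}

#' Tie-aware rank and coverage table over reference residues
#'
#' Residues are sorted by ascending rvET score (ties by residue number);
#' exactly tied scores share the minimal rank of their block, and coverage
#' is the fraction of reference residues scoring at most the row's score,
#' so the last row always has coverage 1.
#'
#' @param scores per-alignment-column rvET scores (see [rvet_scores()]).
#' @param mapping a [map_to_reference()] data.frame selecting the reference
#'   residues and their columns.
#' @param aln optional alignment used to fill `residue` and `variability`.
#' @param ref_id reference sequence id (required when `aln` is given).
#' @return data.frame of class `nsltp_trace` with columns `rank`,
#'   `residue_number`, `alignment_position`, `residue`, `coverage`,
#'   `variability`, `rvet_score`; attributes `reference_id` and `L`.
#' @export
rank_coverage <- function(scores, mapping, aln = NULL, ref_id = NULL) {
  L <- nrow(mapping)
  if (L == 0L) stop_nsltp("mapping covers no residues")
  s <- scores[mapping$alignment_position + 1L]
  ord <- order(s, mapping$residue_number)
  s <- s[ord]
  res_no <- mapping$residue_number[ord]
  col0 <- mapping$alignment_position[ord]
  rank <- rank(s, ties.method = "min")
  coverage <- vapply(s, function(x) sum(s <= x), numeric(1L)) / L
  residue <- rep(NA_character_, L)
  variability <- rep(NA_character_, L)
  if (!is.null(aln)) {
    if (is.null(ref_id)) stop_nsltp("ref_id required when aln is given")
    residue <- unclass(aln)[ref_id, col0 + 1L]
    variability <- vapply(col0, function(j) column_variability(aln, j),
                          character(1L))
  }
  out <- data.frame(rank = as.integer(rank), residue_number = res_no,
                    alignment_position = col0, residue = residue,
                    coverage = coverage, variability = variability,
                    rvet_score = s)
  attr(out, "reference_id") <- ref_id
  attr(out, "L") <- L
  class(out) <- c("nsltp_trace", "data.frame")
  out
}

#' Compute the full trace of a cluster alignment
#'
#' Convenience wrapper: rvET scores of the (sub-)alignment, mapped onto the
#' reference sequence's residues.
#'
#' @inheritParams rvet_scores
#' @param ref_id reference (representative) sequence id.
#' @return an `nsltp_trace` table (see [rank_coverage()]).
#' @export
compute_trace <- function(aln, ref_id, tree = NULL) {
  scores <- rvet_scores(aln, tree)
  mapping <- map_to_reference(aln, ref_id)
  rank_coverage(scores, mapping, aln = aln, ref_id = ref_id)
}

#' Top fraction of a trace
#'
#' Selects the `round(fraction * L)` most conserved residues (round half to
#' even), in score order with residue-number tie-breaks.
#'
#' @param trace an `nsltp_trace` table.
#' @param fraction in (0, 1].
#' @return the selected rows.
#' @export
top_fraction <- function(trace, fraction = 0.30) {
  if (fraction <= 0 || fraction > 1) stop_nsltp("fraction must be in (0,1]")
  L <- attr(trace, "L") %||% nrow(trace)
  n_sel <- round(fraction * L)
  trace[seq_len(min(n_sel, nrow(trace))), , drop = FALSE]
}

#' Cross-cluster trace comparison
#'
#' Restricts the reference trace to its top fraction and reports, for each
#' other trace, the rank, coverage, variability and rvET score found at the
#' same alignment position (alignment columns are shared across cluster
#' subsets because [subset_alignment()] never re-compacts columns).
#'
#' @param reference an `nsltp_trace` for the reference cluster.
#' @param others named list of `nsltp_trace` tables.
#' @param fraction top fraction of the reference trace (default 0.30).
#' @return data.frame: the reference rows plus, per other trace `x`,
#'   columns `rank_x`, `coverage_x`, `variability_x`, `rvet_score_x`
#'   (`NA` when the position is absent from that trace).
#' @export
compare_traces <- function(reference, others, fraction = 0.30) {
  if (is.null(names(others)) || any(names(others) == ""))
    stop_nsltp("others must be a named list of traces")
  out <- as.data.frame(top_fraction(reference, fraction))
  for (nm in names(others)) {
    other <- others[[nm]]
    idx <- match(out$alignment_position, other$alignment_position)
    out[[paste0("rank_", nm)]] <- other$rank[idx]
    out[[paste0("coverage_", nm)]] <- other$coverage[idx]
    out[[paste0("variability_", nm)]] <- other$variability[idx]
    out[[paste0("rvet_score_", nm)]] <- other$rvet_score[idx]
  }
  out
}

#' Write a trace table as TSV
#'
#' Column layout `Rank`, `Residue number`, `Alignment position`, `Residue`,
#' `Coverage`, `Variability`, `rvET score`; scores printed with 2 decimals
#' and coverage with 5.
#'
#' @param trace an `nsltp_trace` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  out <- data.frame(
    Rank = trace$rank,
    `Residue number` = trace$residue_number,
    `Alignment position` = trace$alignment_position,
    Residue = trace$residue,
    Coverage = sprintf("%.5f", trace$coverage),
    Variability = trace$variability,
    `rvET score` = sprintf("%.2f", trace$rvet_score),
    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-residue trace scores for 3D coloring
#'
#' Two-column TSV (`residue_number`, `score`) consumable by molecular
#' viewers.
#'
#' @inheritParams write_trace_tsv
#' @return `path`, invisibly.
#' @export
write_residue_scores <- function(trace, path) {
  out <- trace[order(trace$residue_number),
               c("residue_number", "rvet_score")]
  names(out) <- c("residue_number", "score")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
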