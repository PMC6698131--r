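# Seeded fixture generators with planted ground truth.  All generators are
# pure functions of their parameters and seed (local RNG state, restored on
# exit), so the same call is byte-identical across sessions.
#
# Background residues are drawn uniformly over the 20 amino acids: the
# statistics exercised downstream (hypergeometric enrichment, entropies,
# RMSD geometry) do not require substitution-matrix realism, and a uniform
# background makes planted signal/noise levels exact.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

balanced_newick <- function(ids) {
  build <- function(v) {
    if (length(v) == 1L) return(v)
    h <- ceiling(length(v) / 2)
    sprintf("(%s:1,%s:1)", build(v[seq_len(h)]), build(v[-seq_len(h)]))
  }
  paste0(build(ids), ";")
}

#' Alignment with planted specificity-determining positions
#'
#' Generates `n_clades` monophyletic groups of `seqs_per_clade` sequences
#' each.  Planted conserved columns are invariant across all sequences;
#' each planted SDP column carries one fixed symbol inside its assigned
#' clade and per-clade different symbols outside; the remaining background
#' columns are uniform over the 20 amino acids.  Per-cell mutation noise is
#' then applied at `noise_rate` (never touching a cell twice).  The guide
#' tree is balanced with unit branch lengths: clade structure, not branch
#' length, is what drives the specificity statistic.
#'
#' @param n_clades,seqs_per_clade clade structure (defaults 2 x 8).
#' @param n_columns alignment width.
#' @param n_sdp,n_conserved numbers of planted SDP and conserved columns.
#' @param noise_rate per-cell substitution probability in `[0, 0.5)`.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return list with `alignment` (an [nsltp_alignment()]), `tree` (`phylo`,
#'   balanced, clades monophyletic) and `truth` (list: `sdp_columns`
#'   data.frame of 0-based `column`, `clade`, `symbol`; `conserved_columns`
#'   0-based; `clades` id list).
#' @export
make_sdp_alignment <- function(n_clades = 2L, seqs_per_clade = 8L,
                               n_columns = 60L, n_sdp = 4L,
                               n_conserved = 8L, noise_rate = 0,
                               seed = 1L) {
  if (n_sdp + n_conserved > n_columns)
    stop_nsltp("n_sdp + n_conserved exceeds n_columns")
  if (noise_rate < 0 || noise_rate >= 0.5)
    stop_nsltp("noise_rate must be in [0, 0.5)")
  if (n_clades < 2L || seqs_per_clade < 1L)
    stop_nsltp("need at least 2 clades of at least 1 sequence")
  with_local_seed(seed, {
    n_seq <- n_clades * seqs_per_clade
    ids <- sprintf("s%02d", seq_len(n_seq))
    clade_of <- rep(seq_len(n_clades), each = seqs_per_clade)
    clades <- split(ids, clade_of)
    names(clades) <- paste0("clade", seq_len(n_clades))
    mat <- matrix(sample(AA20, n_seq * n_columns, replace = TRUE),
                  nrow = n_seq, dimnames = list(ids, NULL))
    special <- sample(n_columns, n_sdp + n_conserved)
    cons_cols <- sort(special[seq_len(n_conserved)])
    sdp_cols <- sort(special[n_conserved + seq_len(n_sdp)])
    for (j in cons_cols) mat[, j] <- sample(AA20, 1L)
    sdp_truth <- list()
    for (i in seq_along(sdp_cols)) {
      j <- sdp_cols[i]
      target <- ((i - 1L) %% n_clades) + 1L
      # one distinct symbol per clade so the in-clade symbol is absent outside
      syms <- sample(AA20, n_clades)
      for (cl in seq_len(n_clades)) mat[clade_of == cl, j] <- syms[cl]
      sdp_truth[[i]] <- data.frame(column = j - 1L,
                                   clade = names(clades)[target],
                                   symbol = syms[target])
    }
    if (noise_rate > 0) {
      hit <- which(runif(length(mat)) < noise_rate)
      mat[hit] <- sample(AA20, length(hit), replace = TRUE)
    }
    tree <- ape::read.tree(text = balanced_newick_clades(clades))
    list(
      alignment = nsltp_alignment(apply(mat, 1L, paste, collapse = "")),
      tree = tree,
      truth = list(sdp_columns = do.call(rbind, sdp_truth),
                   conserved_columns = cons_cols - 1L,
                   clades = clades))
  })
}

balanced_newick_clades <- function(clades) {
  sub <- vapply(clades, function(ids) {
    sub_nwk <- balanced_newick(ids)
    substr(sub_nwk, 1L, nchar(sub_nwk) - 1L)  # strip ';'
  }, character(1L), USE.NAMES = FALSE)
  join <- function(v) {
    if (length(v) == 1L) return(v)
    h <- ceiling(length(v) / 2)
    sprintf("(%s:1,%s:1)", join(v[seq_len(h)]), join(v[-seq_len(h)]))
  }
  paste0(join(sub), ";")
}

#' Helical coordinate bundles with planted structural clusters
#'
#' Each cluster derives from an ideal alpha-helical CA curve (2.3 Å radius,
#' 1.5 Å rise, 100 degrees per residue); cluster `j > 1` additionally
#' displaces the last third of the residues by `between_shift` Å in a
#' cluster-specific direction.  Members are the cluster base plus isotropic
#' Gaussian jitter of `within_sigma` Å per coordinate, so intra-cluster
#' RMSDs scale with `within_sigma` and inter-cluster RMSDs with
#' `between_shift`.
#'
#' @param n_clusters,members_per_cluster bundle layout (defaults 2 x 5).
#' @param n_residues residues per structure.
#' @param within_sigma jitter standard deviation (Å) per coordinate; the
#'   default 0.3 yields intra-cluster RMSDs around 0.8 Å, well inside a
#'   1.5 Å cutoff.
#' @param between_shift deformation magnitude (Å) separating clusters; must
#'   exceed `within_sigma`.  The default 12 yields inter-cluster RMSDs
#'   around 3 Å after superposition, the scale at which the two nsLTP fold
#'   families separate.
#' @param seed integer seed.
#' @return list with `structures` (list of [coordinate_set()]s, ids
#'   `"m01"`, ...) and `truth` (list: `cluster_assignment` named integer
#'   vector, `within_sigma`, `between_shift`).
#' @export
make_helix_bundle <- function(n_clusters = 2L, members_per_cluster = 5L,
                              n_residues = 60L, within_sigma = 0.3,
                              between_shift = 12, seed = 1L) {
  if (n_clusters < 1L || members_per_cluster < 1L || n_residues < 3L)
    stop_nsltp("non-positive bundle sizes")
  if (within_sigma >= between_shift)
    stop_nsltp("within_sigma must be smaller than between_shift")
  with_local_seed(seed, {
    t <- seq_len(n_residues)
    base <- cbind(2.3 * cos(t * 100 * pi / 180),
                  2.3 * sin(t * 100 * pi / 180),
                  1.5 * t)
    deform_idx <- seq.int(floor(2 * n_residues / 3) + 1L, n_residues)
    structures <- list()
    assignment <- integer(0L)
    k <- 0L
    for (cl in seq_len(n_clusters)) {
      centre <- base
      if (cl > 1L) {
        ang <- 2 * pi * (cl - 1L) / n_clusters
        dir <- c(cos(ang), sin(ang), 0)
        centre[deform_idx, ] <- centre[deform_idx, ] +
          rep(between_shift * dir, each = length(deform_idx))
      }
      for (mem in seq_len(members_per_cluster)) {
        k <- k + 1L
        id <- sprintf("m%02d", k)
        jitter <- if (within_sigma > 0)
          matrix(rnorm(3L * n_residues, sd = within_sigma), ncol = 3L)
        else 0
        structures[[k]] <- coordinate_set(id, centre + jitter)
        assignment[id] <- cl
      }
    }
    list(structures = structures,
         truth = list(cluster_assignment = assignment,
                      within_sigma = within_sigma,
                      between_shift = between_shift))
  })
}

#' Annotation table with planted keyword placement
#'
#' Exactly `n_in_cluster` annotated ids inside `target_cluster` and
#' `n_outside` annotated ids elsewhere, sampled without replacement.
#'
#' @param ids all ids.
#' @param target_cluster ids forming the cluster of interest.
#' @param n_in_cluster,n_outside annotated counts inside/outside it.
#' @param keyword annotation keyword (default `"defense"`).
#' @param seed integer seed.
#' @return data.frame with columns `id` and `keywords` (empty string when
#'   unannotated), one row per id.
#' @export
make_annotations <- function(ids, target_cluster, n_in_cluster, n_outside,
                             keyword = "defense", seed = 1L) {
  target_cluster <- intersect(target_cluster, ids)
  outside <- setdiff(ids, target_cluster)
  if (n_in_cluster > length(target_cluster) || n_outside > length(outside) ||
      n_in_cluster < 0L || n_outside < 0L)
    stop_nsltp("infeasible annotation counts")
  with_local_seed(seed, {
    hit <- c(sample(target_cluster, n_in_cluster),
             sample(outside, n_outside))
    data.frame(id = ids,
               keywords = ifelse(ids %in% hit, keyword, ""))
  })
}
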