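# Structural classification: Kabsch superposition RMSD, pairwise matrices,
# distance trees, cutoff clustering, medoids and annotation enrichment.

#' Read C-alpha coordinates from a PDB file
#'
#' ATOM records only, CA atoms, first model, first alternate location.
#'
#' @param path PDB-format file.
#' @param id identifier for the coordinate set; defaults to the file name
#'   without extension.
#' @return list with `id`, `ca_coordinates` (n x 3 matrix, ångströms) and
#'   `residue_numbers` (1-based integers, strictly increasing).
#' @export
read_ca_coordinates <- function(path, id = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety == "CA" &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno)), , drop = FALSE]
  if (nrow(at) == 0L) stop_nsltp("no CA ATOM records in %s", path)
  coordinate_set(
    id = id %||% sub("\\.[^.]*$", "", basename(path)),
    ca_coordinates = as.matrix(at[, c("x", "y", "z")]),
    residue_numbers = as.integer(at$resno))
}

#' Construct a C-alpha coordinate set
#'
#' @param id identifier.
#' @param ca_coordinates n x 3 numeric matrix of CA positions (Å).
#' @param residue_numbers strictly increasing 1-based residue numbers;
#'   defaults to `1:n`.
#' @return list of class `nsltp_coords`.
#' @export
coordinate_set <- function(id, ca_coordinates,
                           residue_numbers = seq_len(nrow(ca_coordinates))) {
  ca_coordinates <- as.matrix(ca_coordinates)
  dimnames(ca_coordinates) <- NULL
  if (ncol(ca_coordinates) != 3L || !all(is.finite(ca_coordinates)))
    stop_nsltp("coordinates must be a finite n x 3 matrix")
  if (length(residue_numbers) != nrow(ca_coordinates) ||
      any(diff(residue_numbers) <= 0L))
    stop_nsltp("residue_numbers must be strictly increasing, one per atom")
  structure(list(id = id, ca_coordinates = ca_coordinates,
                 residue_numbers = as.integer(residue_numbers)),
            class = "nsltp_coords")
}

#' Write a coordinate set as a minimal PDB file
#'
#' CA-only ATOM records (poly-alanine), fixed-width PDB columns.
#'
#' @param coords an `nsltp_coords` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(coords, path) {
  xyz <- coords$ca_coordinates
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)), coords$residue_numbers,
    xyz[, 1L], xyz[, 2L], xyz[, 3L])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation mapping the paired atoms of
#' `B` onto `A` with minimal RMSD: both point sets are centered on the
#' paired-atom centroids and the optimal rotation is obtained from the SVD
#' of the cross-covariance matrix, with the usual sign correction so the
#' rotation is never a reflection.
#'
#' @param A,B `nsltp_coords` objects (see [coordinate_set()]).
#' @param pairs two-column integer matrix of paired atom indices
#'   (`A` index, `B` index); defaults to the identity pairing when both
#'   sets have equal length.  At least 3 non-collinear pairs are required.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3
#'   vector) and `rmsd` (Å): a `B` atom `x` maps to `rotation %*% x +
#'   translation` in `A`'s frame.
#' @export
kabsch_superpose <- function(A, B, pairs = NULL) {
  if (is.null(pairs)) {
    if (nrow(A$ca_coordinates) != nrow(B$ca_coordinates))
      stop_nsltp("no correspondence given and lengths differ (%s: %d, %s: %d)",
                 A$id, nrow(A$ca_coordinates), B$id, nrow(B$ca_coordinates))
    pairs <- cbind(seq_len(nrow(A$ca_coordinates)),
                   seq_len(nrow(A$ca_coordinates)))
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3L)
    stop_nsltp("superposition needs at least 3 paired atoms, got %d",
               nrow(pairs))
  if (anyDuplicated(pairs[, 1L]) || anyDuplicated(pairs[, 2L]))
    stop_nsltp("correspondence repeats an atom index")
  P <- A$ca_coordinates[pairs[, 1L], , drop = FALSE]  # target
  Q <- B$ca_coordinates[pairs[, 2L], , drop = FALSE]  # moving
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Qc, Pc)  # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) stop_nsltp("degenerate geometry: singular cross-covariance")
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- as.numeric(cp - R %*% cq)
  moved <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Pc)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Read a residue correspondence table
#'
#' TSV with columns `idA`, `idxA`, `idB`, `idxB` (1-based atom indices into
#' the respective coordinate sets), e.g. the shared non-gap columns of a
#' structure-based alignment.
#'
#' @param path TSV path.
#' @return data.frame with those four columns.
#' @export
read_correspondences <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("idA", "idxA", "idB", "idxB")
  if (!all(need %in% names(tab)))
    stop_nsltp("correspondence table must have columns %s",
               paste(need, collapse = ", "))
  tab
}

#' Correspondences from an alignment's shared non-gap columns
#'
#' For every pair of alignment rows, pairs up the atom indices (ungapped
#' residue ranks) of columns where neither sequence has a gap — the way a
#' structure-based alignment feeds the RMSD computation.
#'
#' @inheritParams n_columns
#' @return data.frame `idA`, `idxA`, `idB`, `idxB` covering all unordered
#'   id pairs.
#' @export
correspondences_from_alignment <- function(aln) {
  stopifnot(inherits(aln, "nsltp_aln"))
  ids <- rownames(aln)
  ranks <- lapply(ids, function(id) cumsum(aln[id, ] != GAP))
  names(ranks) <- ids
  out <- list()
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    shared <- which(aln[a, ] != GAP & aln[b, ] != GAP)
    if (length(shared) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      idA = ids[a], idxA = ranks[[a]][shared],
      idB = ids[b], idxB = ranks[[b]][shared])
  }
  do.call(rbind, out)
}

pairs_for <- function(correspondences, idA, idB) {
  fwd <- correspondences$idA == idA & correspondences$idB == idB
  if (any(fwd))
    return(cbind(correspondences$idxA[fwd], correspondences$idxB[fwd]))
  rev <- correspondences$idA == idB & correspondences$idB == idA
  if (any(rev))
    return(cbind(correspondences$idxB[rev], correspondences$idxA[rev]))
  NULL
}

#' Pairwise Kabsch RMSD matrix
#'
#' @param structures list of `nsltp_coords` objects.
#' @param correspondences data.frame as in [read_correspondences()]; when
#'   `NULL`, all structures must have equal length and the identity pairing
#'   is used.
#' @return symmetric non-negative matrix (Å) with zero diagonal, dimnames =
#'   structure ids.
#' @export
pairwise_rmsd_matrix <- function(structures, correspondences = NULL) {
  ids <- vapply(structures, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop_nsltp("duplicated structure ids")
  names(structures) <- ids
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b) next
    pairs <- if (is.null(correspondences)) NULL
             else pairs_for(correspondences, ids[a], ids[b])
    if (!is.null(correspondences) && is.null(pairs))
      stop_nsltp("no correspondence for pair (%s, %s)", ids[a], ids[b])
    r <- kabsch_superpose(structures[[a]], structures[[b]], pairs)$rmsd
    m[a, b] <- m[b, a] <- r
  }
  validate_rmsd_matrix(m)
  m
}

validate_rmsd_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop_nsltp("RMSD matrix must be square with matching id dimnames")
  if (max(abs(m - t(m))) > 1e-9) stop_nsltp("RMSD matrix is not symmetric")
  if (any(diag(m) != 0)) stop_nsltp("RMSD matrix diagonal must be zero")
  if (any(m < 0)) stop_nsltp("RMSD matrix must be non-negative")
  invisible(m)
}

#' Neighbor-joining distance tree from an RMSD matrix
#'
#' Minimum-evolution style tree; on an exactly additive distance matrix the
#' leaf-to-leaf path lengths reproduce the input distances.
#'
#' @param m symmetric RMSD matrix with id dimnames.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
build_distance_tree <- function(m) {
  validate_rmsd_matrix(m)
  if (nrow(m) < 3L) stop_nsltp("distance tree needs at least 3 structures")
  ape::nj(as.dist(m))
}

#' Complete-linkage cutoff clustering of an RMSD matrix
#'
#' Agglomerative complete linkage: starting from singletons, the two
#' clusters at smallest complete-linkage distance (their maximum pairwise
#' member distance) are merged while that distance stays within the cutoff,
#' so every resulting cluster has all pairwise member distances <= cutoff.
#' Merge ties break by the lexicographically smallest member id.
#'
#' @param m symmetric RMSD matrix with id dimnames.
#' @param cutoff maximum allowed intra-cluster pairwise distance (Å), > 0.
#' @return list of clusters, each a list with `member_ids` (sorted),
#'   `cutoff` and `medoid_id` (see [select_medoid()]); clusters ordered by
#'   decreasing size then first member id.
#' @export
cut_clusters <- function(m, cutoff) {
  validate_rmsd_matrix(m)
  if (cutoff <= 0) stop_nsltp("cutoff must be positive")
  ids <- rownames(m)
  clusters <- as.list(ids)
  # complete-linkage distance between current clusters
  link <- m
  repeat {
    nc <- length(clusters)
    if (nc == 1L) break
    best <- NULL
    for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
      d <- link[a, b]
      if (d > cutoff) next
      key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
        best <- list(a = a, b = b, d = d, key = key)
      }
    }
    if (is.null(best)) break
    merged <- c(clusters[[best$a]], clusters[[best$b]])
    keep <- setdiff(seq_len(nc), c(best$a, best$b))
    clusters <- c(clusters[keep], list(merged))
    if (length(keep) == 0L) {
      link <- matrix(0, 1L, 1L)
    } else {
      new_row <- pmax(link[best$a, keep], link[best$b, keep])
      link <- link[keep, keep, drop = FALSE]
      link <- rbind(cbind(link, new_row, deparse.level = 0),
                    c(new_row, 0))
    }
  }
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1L), 1L))
  lapply(clusters[ord], function(mem) {
    list(member_ids = mem, cutoff = cutoff,
         medoid_id = select_medoid(mem, m))
  })
}

#' Cutoff sweep clustering
#'
#' @inheritParams cut_clusters
#' @param from,to,by sweep bounds and step in Å (defaults 11.5 down to 0.5
#'   in 0.5 Å steps).
#' @return named list of [cut_clusters()] partitions, one per cutoff, names
#'   formatted as the cutoff value.
#' @export
sweep_clusters <- function(m, from = 11.5, to = 0.5, by = 0.5) {
  cutoffs <- seq(from, to, by = -abs(by))
  out <- lapply(cutoffs, function(co) cut_clusters(m, co))
  names(out) <- format(cutoffs, trim = TRUE)
  out
}

#' Medoid of a cluster
#'
#' The member with the smallest summed RMS distance to all other members;
#' ties break lexicographically by id.
#'
#' @param member_ids cluster member ids.
#' @param m RMSD matrix containing all members.
#' @return the medoid id.
#' @export
select_medoid <- function(member_ids, m) {
  if (length(member_ids) == 0L) stop_nsltp("empty cluster")
  missing <- setdiff(member_ids, rownames(m))
  if (length(missing) > 0L)
    stop_nsltp("members absent from matrix: %s",
               paste(missing, collapse = ", "))
  if (length(member_ids) == 1L) return(member_ids)
  sums <- rowSums(m[member_ids, member_ids, drop = FALSE])
  member_ids[order(sums, member_ids)][1L]
}

#' Annotation enrichment of a partition
#'
#' @param partition a [cut_clusters()] result (list of clusters with
#'   `member_ids`).
#' @param annotations data.frame with columns `id` and `keywords`
#'   (semicolon- or comma-separated keyword list per id).
#' @param keywords keywords of interest (default `c("defense",
#'   "resistance")`); an id is "annotated" when it carries any of them
#'   (case-insensitive).
#' @return data.frame per cluster: `cluster`, `cutoff`, `size`, `medoid`,
#'   `annotated_count` (members carrying a keyword), `annotated_fraction`
#'   (of the cluster) and `captured_fraction` (of all annotated ids).
#' @export
annotation_enrichment <- function(partition, annotations,
                                  keywords = c("defense", "resistance")) {
  if (length(keywords) == 0L) stop_nsltp("keyword list must be non-empty")
  annotated <- annotated_ids(annotations, keywords)
  rows <- lapply(seq_along(partition), function(i) {
    cl <- partition[[i]]
    hit <- sum(cl$member_ids %in% annotated)
    data.frame(
      cluster = i,
      cutoff = cl$cutoff %||% NA_real_,
      size = length(cl$member_ids),
      medoid = cl$medoid_id %||% NA_character_,
      annotated_count = hit,
      annotated_fraction = if (length(cl$member_ids) > 0)
        hit / length(cl$member_ids) else 0,
      captured_fraction = if (length(annotated) > 0)
        hit / length(annotated) else 0)
  })
  do.call(rbind, rows)
}

annotated_ids <- function(annotations, keywords) {
  if (is.null(annotations) || nrow(annotations) == 0L) return(character(0L))
  kw <- tolower(keywords)
  hit <- vapply(annotations$keywords, function(s) {
    terms <- tolower(trimws(strsplit(s, "[;,]")[[1L]]))
    any(terms %in% kw)
  }, logical(1L), USE.NAMES = FALSE)
  unique(annotations$id[hit])
}

#' Distance between two residues after superposition
#'
#' Euclidean distance between a residue of `A` (in its own frame) and a
#' residue of `B` mapped into `A`'s frame by a [kabsch_superpose()] result.
#'
#' @param A,B `nsltp_coords` objects.
#' @param superposition result of `kabsch_superpose(A, B, ...)`.
#' @param residueA,residueB residue numbers (as in `residue_numbers`).
#' @return distance in Å.
#' @export
residue_pair_distance <- function(A, B, superposition, residueA, residueB) {
  ia <- match(residueA, A$residue_numbers)
  ib <- match(residueB, B$residue_numbers)
  if (is.na(ia)) stop_nsltp("residue %s not in %s", residueA, A$id)
  if (is.na(ib)) stop_nsltp("residue %s not in %s", residueB, B$id)
  xa <- A$ca_coordinates[ia, ]
  xb <- as.numeric(superposition$rotation %*% B$ca_coordinates[ib, ] +
                     superposition$translation)
  sqrt(sum((xa - xb)^2))
}

#' Write an RMSD matrix as square TSV
#' @param m RMSD matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rmsd_tsv <- function(m, path) {
  write.table(cbind(id = rownames(m), as.data.frame(m)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square RMSD TSV written by [write_rmsd_tsv()]
#' @param path TSV path.
#' @return RMSD matrix with id dimnames.
#' @export
read_rmsd_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$id
  storage.mode(m) <- "double"
  validate_rmsd_matrix(m)
  m
}

#' Write a cluster report as TSV
#'
#' @param partition a [cut_clusters()] result.
#' @param path output path.
#' @param annotations,keywords optional; when given, enrichment columns are
#'   included (see [annotation_enrichment()]).
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(partition, path, annotations = NULL,
                              keywords = c("defense", "resistance")) {
  base <- data.frame(
    cluster = seq_along(partition),
    cutoff = vapply(partition, function(cl) cl$cutoff %||% NA_real_,
                    numeric(1L)),
    size = lengths(lapply(partition, `[[`, "member_ids")),
    medoid = vapply(partition, `[[`, character(1L), "medoid_id"),
    members = vapply(partition, function(cl)
      paste(cl$member_ids, collapse = ","), character(1L)))
  if (!is.null(annotations)) {
    enr <- annotation_enrichment(partition, annotations, keywords)
    base <- cbind(base, enr[, c("annotated_count", "annotated_fraction",
                                "captured_fraction")])
  }
  write.table(base, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a distance tree with per-leaf annotation flags as JSON
#'
#' @param tree a `phylo` tree.
#' @param path output JSON path.
#' @param annotations,keywords optional annotation table; each leaf gets an
#'   `annotated` flag.
#' @return `path`, invisibly.
#' @export
export_tree_json <- function(tree, path, annotations = NULL,
                             keywords = c("defense", "resistance")) {
  flagged <- if (is.null(annotations)) character(0L)
             else annotated_ids(annotations, keywords)
  obj <- list(
    newick = ape::write.tree(tree),
    leaves = lapply(tree$tip.label, function(id)
      list(id = id, annotated = id %in% flagged)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
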