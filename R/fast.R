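# FAST column statistic: per-cell Fisher specificity against tree clades,
# per-column conservation, and the hue/saturation/value coloring model.
#
# An amino-acid "cluster" at a position is the set of sequences sharing the
# identical symbol there (gap '.' counts as a 21st symbol).  Its specificity
# is the smallest one-sided hypergeometric upper-tail probability of the
# overlap between that set and any clade of the guide tree; the displayed
# score is -log10 of that probability.

#' Enumerate the monophyletic clusters of a rooted tree
#'
#' One clade per internal node, excluding singletons and the full leaf set,
#' ordered by tree pre-order.
#'
#' @param tree an [ape::read.tree()] phylo object (rooted).
#' @param expected_ids optional ids that must equal the tree's leaf set;
#'   a mismatch raises an error listing the symmetric difference.
#' @return named list of leaf-id character vectors (class `nsltp_clades`),
#'   names `"c1"`, `"c2"`, ... in pre-order.
#' @export
enumerate_tree_clusters <- function(tree, expected_ids = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(expected_ids)) {
    extra <- setdiff(tree$tip.label, expected_ids)
    miss <- setdiff(expected_ids, tree$tip.label)
    if (length(extra) > 0L || length(miss) > 0L)
      stop_nsltp(
        "tree/alignment id mismatch; only in tree: {%s}; only in alignment: {%s}",
        paste(extra, collapse = ","), paste(miss, collapse = ","))
  }
  ntip <- length(tree$tip.label)
  if (is.null(tree$Nnode) || tree$Nnode < 1L || ntip < 2L)
    return(structure(list(), class = "nsltp_clades"))
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  # pre-order rank of internal nodes from cladewise edge ordering
  ord <- unique(reorder(tree, "cladewise")$edge[, 1L])
  clades <- list()
  for (node in ord) {
    tips <- labels[parts[[node - ntip]]]
    if (length(tips) >= 2L && length(tips) <= ntip - 1L)
      clades[[length(clades) + 1L]] <- sort(tips)
  }
  names(clades) <- if (length(clades) > 0L)
    paste0("c", seq_along(clades)) else character(0L)
  structure(clades, class = "nsltp_clades")
}

#' One-sided hypergeometric enrichment probability
#'
#' Probability that a uniformly random `n`-subset of an `N`-population
#' overlaps a fixed `K`-subset in at least `k` elements, i.e. the upper-tail
#' Fisher exact probability for enrichment.
#'
#' @param k observed overlap.
#' @param n size of the symbol cluster (draws).
#' @param K clade size.
#' @param N total number of sequences.
#' @return probability in (0, 1].
#' @export
fisher_enrichment_p <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0L) || n > N || K > N || k > min(n, K))
    stop_nsltp("inconsistent counts: k=%d n=%d K=%d N=%d", k, n, K, N)
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Best clade specificity of a symbol at an alignment column
#'
#' @inheritParams column_profile
#' @param symbol amino-acid letter or `"."`; must occur in the column.
#' @param clades an [enumerate_tree_clusters()] result.
#' @return list with `column`, `symbol`, `best_clade` (clade name or `NA`),
#'   `fisher_p` (minimum over clades; 1 by convention for an empty clade
#'   set) and `spec_score` (`-log10(fisher_p)`).  Ties among clades break
#'   toward the smallest clade, then tree pre-order.
#' @export
best_specificity <- function(aln, col, symbol, clades) {
  stopifnot(inherits(aln, "nsltp_aln"))
  colv <- aln[, col + 1L]
  members <- rownames(aln)[colv == symbol]
  if (length(members) == 0L)
    stop_nsltp("symbol '%s' absent from column %d", symbol, col)
  n <- length(members)
  N <- nrow(aln)
  best <- list(p = 1, size = Inf, idx = NA_integer_)
  for (i in seq_along(clades)) {
    K <- length(clades[[i]])
    k <- sum(members %in% clades[[i]])
    p <- fisher_enrichment_p(k, n, K, N)
    if (p < best$p - 1e-15 ||
        (abs(p - best$p) <= 1e-15 && K < best$size)) {
      best <- list(p = p, size = K, idx = i)
    }
  }
  list(column = col, symbol = symbol,
       best_clade = if (is.na(best$idx)) NA_character_ else names(clades)[best$idx],
       fisher_p = best$p,
       spec_score = -log10(best$p))
}

#' Column conservation score
#'
#' `1 - H / log(21)` where `H` is the Shannon entropy (natural log) of the
#' 21-state symbol distribution (20 amino acids + gap).  Invariant columns
#' score 1; a column uniform over all 21 symbols scores 0.
#'
#' @inheritParams column_profile
#' @return conservation in `[0, 1]`.
#' @export
column_conservation <- function(aln, col) {
  prof <- column_profile(aln, col)
  p <- prof / sum(prof)
  H <- -sum(p * log(p))
  1 - H / log(21)
}

shannon_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1L) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Compute the full FAST score tables of an alignment
#'
#' @inheritParams n_columns
#' @param tree rooted guide tree whose leaves are the alignment ids.
#' @return list with `cells` — a data.frame of one row per (column, symbol)
#'   pair observed in the alignment (`column` 0-based, `symbol`,
#'   `best_clade`, `fisher_p`, `spec_score`) — and `columns` — a data.frame
#'   of per-column `conservation`.
#' @export
fast_scores <- function(aln, tree) {
  clades <- enumerate_tree_clusters(tree, expected_ids = rownames(aln))
  cells <- list()
  cons <- numeric(ncol(aln))
  for (j in seq_len(ncol(aln))) {
    col0 <- j - 1L
    cons[j] <- column_conservation(aln, col0)
    for (sym in sort(unique(aln[, j]))) {
      cells[[length(cells) + 1L]] <-
        as.data.frame(best_specificity(aln, col0, sym, clades))
    }
  }
  list(cells = do.call(rbind, cells),
       columns = data.frame(column = seq_len(ncol(aln)) - 1L,
                            conservation = cons),
       clades = clades)
}

#' HSV coloring of an alignment
#'
#' Sequences, sorted in tree-leaf order, receive base hues on a 270-degree
#' rainbow gradient.  Each cell takes the base hue of the median member (by
#' tree order; lower median on even counts) of its symbol cluster, a
#' saturation proportional to the cell's specificity score (capped at
#' `saturation_cap`) and a value darkening with column conservation
#' (`1 - 0.8 * conservation`, floor 0.2), so conserved columns render dark
#' and clade-specific clusters render saturated.
#'
#' @inheritParams n_columns
#' @param leaf_order sequence ids in tree order (all alignment rows).
#' @param scores a [fast_scores()] result.
#' @param saturation_cap spec-score mapped to full saturation; default the
#'   99th percentile of the observed spec scores.
#' @return list of numeric matrices `hue` (degrees), `saturation`, `value`,
#'   rows following `leaf_order`.
#' @export
colorize <- function(aln, leaf_order, scores, saturation_cap = NULL) {
  stopifnot(inherits(aln, "nsltp_aln"))
  if (!setequal(leaf_order, rownames(aln)) ||
      length(leaf_order) != nrow(aln))
    stop_nsltp("leaf_order must be a permutation of the alignment ids")
  aln <- subset_alignment(aln, leaf_order)
  N <- nrow(aln)
  base_hue <- if (N == 1L) 0 else 270 * (seq_len(N) - 1L) / (N - 1L)
  if (is.null(saturation_cap))
    saturation_cap <- stats::quantile(scores$cells$spec_score, 0.99,
                                      names = FALSE)
  spec <- scores$cells
  key <- paste(spec$column, spec$symbol, sep = "\r")
  spec_of <- setNames(spec$spec_score, key)
  hue <- sat <- val <- matrix(0, nrow = N, ncol = ncol(aln),
                              dimnames = list(leaf_order, NULL))
  for (j in seq_len(ncol(aln))) {
    colv <- aln[, j]
    cons <- scores$columns$conservation[j]
    for (sym in unique(colv)) {
      members <- which(colv == sym)           # indices in tree order
      med <- members[ceiling(length(members) / 2)]  # lower median
      s <- spec_of[[paste(j - 1L, sym, sep = "\r")]]
      sat_v <- if (saturation_cap > 0) min(1, s / saturation_cap)
               else as.numeric(s > 0)
      hue[members, j] <- base_hue[med]
      sat[members, j] <- sat_v
      val[members, j] <- 1 - 0.8 * cons
    }
  }
  list(hue = hue, saturation = sat, value = val)
}

#' Conserved-core and specificity-determining-position tables
#'
#' @param scores a [fast_scores()] result.
#' @param conservation_threshold minimum conservation for the conserved-core
#'   table.
#' @param specificity_threshold minimum spec score for the SDP table.
#' @return list with `conserved_core` (data.frame `column`, `conservation`)
#'   and `sdp` (data.frame `column`, `symbol`, `best_clade`, `fisher_p`,
#'   `spec_score`, sorted by score descending).
#' @export
report_positions <- function(scores, conservation_threshold = 0.8,
                             specificity_threshold = 2) {
  cons <- scores$columns
  core <- cons[cons$conservation >= conservation_threshold, , drop = FALSE]
  sdp <- scores$cells[scores$cells$spec_score >= specificity_threshold, ,
                      drop = FALSE]
  sdp <- sdp[order(-sdp$spec_score, sdp$column, sdp$symbol), , drop = FALSE]
  rownames(core) <- rownames(sdp) <- NULL
  list(conserved_core = core, sdp = sdp)
}

#' Write FAST score tables as TSV
#'
#' @param scores a [fast_scores()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fast_tsv <- function(scores, path) {
  tab <- merge(scores$cells, scores$columns, by = "column")
  tab <- tab[order(tab$column, tab$symbol), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a colored alignment as SVG
#'
#' One rectangle per cell, filled with the [colorize()] HSV color; residue
#' letters are drawn in a contrasting gray.
#'
#' @inheritParams n_columns
#' @param colors a [colorize()] result.
#' @param path output SVG path.
#' @param cell_w,cell_h cell size in pixels.
#' @return `path`, invisibly.
#' @export
render_alignment_svg <- function(aln, colors, path, cell_w = 12, cell_h = 16) {
  leaf_order <- rownames(colors$hue)
  aln <- subset_alignment(aln, leaf_order)
  n <- nrow(aln); m <- ncol(aln)
  label_w <- 10 + 7 * max(nchar(leaf_order))
  w <- label_w + m * cell_w
  h <- (n + 1) * cell_h
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" font-family="monospace" font-size="%d">',
    ceiling(w), ceiling(h), round(cell_h * 0.7)), con)
  for (i in seq_len(n)) {
    y <- i * cell_h
    writeLines(sprintf('<text x="4" y="%d">%s</text>', y - 3, leaf_order[i]),
               con)
    for (j in seq_len(m)) {
      fill <- hsv(colors$hue[i, j] / 360, colors$saturation[i, j],
                  colors$value[i, j])
      x <- label_w + (j - 1) * cell_w
      txt_col <- if (colors$value[i, j] < 0.5) "#dddddd" else "#222222"
      writeLines(sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/><text x="%d" y="%d" fill="%s">%s</text>',
        x, y - cell_h, cell_w, cell_h, fill,
        x + 2, y - 3, txt_col, aln[i, j]), con)
    }
  }
  writeLines("</svg>", con)
  invisible(path)
}
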