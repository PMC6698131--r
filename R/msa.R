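# Alignment container, consensus construction and column/reference plumbing.
#
# An alignment is stored as a character matrix (sequences x columns) with
# unique rownames; the two common gap characters '-' and '.' are normalized
# to '.' on construction so every downstream tally sees a single gap state.

#' Construct a multiple sequence alignment object
#'
#' @param rows character vector of equal-length gapped residue strings.
#' @param ids unique sequence identifiers, one per row; defaults to
#'   `names(rows)`.
#' @return An object of class `nsltp_aln`: a character matrix with one row
#'   per sequence and one column per alignment position, gaps normalized to
#'   `"."`.
#' @examples
#' aln <- nsltp_alignment(c(s1 = "AC-", s2 = "AD."))
#' n_columns(aln)
#' @export
nsltp_alignment <- function(rows, ids = names(rows)) {
  if (length(rows) == 0L) stop_nsltp("empty alignment: no sequences supplied")
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop_nsltp("every alignment row needs an id")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop_nsltp("duplicated sequence ids: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1L]][1L]
    stop_nsltp("ragged alignment: row '%s' has length %d, expected %d",
               bad, nchar(rows[ids == bad][1L]), widths[1L])
  }
  if (widths[1L] == 0L) stop_nsltp("empty alignment: zero columns")
  mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  mat[mat == "-"] <- GAP
  rownames(mat) <- ids
  bad <- !(mat %in% ALPHABET21) & mat != GAP
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_nsltp("invalid character '%s' in sequence '%s' at column %d",
               mat[bad][1L], ids[idx[1L]], idx[2L])
  }
  structure(mat, class = c("nsltp_aln", "matrix", "array"))
}

#' @export
print.nsltp_aln <- function(x, ...) {
  cat(sprintf("nsltp alignment: %d sequences x %d columns\n", nrow(x), ncol(x)))
  shown <- head(seq_len(nrow(x)), 6L)
  for (i in shown) {
    row <- paste(x[i, seq_len(min(ncol(x), 60L))], collapse = "")
    if (ncol(x) > 60L) row <- paste0(row, "...")
    cat(sprintf("  %-15s %s\n", rownames(x)[i], row))
  }
  if (nrow(x) > 6L) cat(sprintf("  ... %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Number of alignment columns
#' @param aln an [nsltp_alignment()] object.
#' @return integer column count.
#' @export
n_columns <- function(aln) ncol(aln)

#' Sequence ids of an alignment
#' @inheritParams n_columns
#' @return character vector of ids in row order.
#' @export
aln_ids <- function(aln) rownames(aln)

#' Ungapped sequence strings
#' @inheritParams n_columns
#' @return named character vector of residue strings with gaps removed.
#' @export
ungap_rows <- function(aln) {
  vapply(seq_len(nrow(aln)), function(i) {
    paste(aln[i, aln[i, ] != GAP], collapse = "")
  }, character(1L), USE.NAMES = FALSE) |> setNames(rownames(aln))
}

#' Read an aligned FASTA file
#'
#' Reads plain or gzipped aligned FASTA; all records must have equal length.
#'
#' @param path path to an aligned FASTA file.
#' @return an [nsltp_alignment()] object.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_nsltp("empty alignment file: %s", path)
  rows <- as.character(set)
  names(rows) <- sub("\\s.*$", "", names(set))
  nsltp_alignment(rows)
}

#' Write an alignment (or any named sequence set) as FASTA
#'
#' @param x an `nsltp_aln` object or a named character vector of sequences.
#' @param path output file path (`.gz` suffix triggers compression).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "nsltp_aln")) {
    setNames(apply(unclass(x), 1L, paste, collapse = ""), rownames(x))
  } else x
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Symbol counts of one alignment column
#'
#' @inheritParams n_columns
#' @param col 0-based column index (alignment positions are reported 0-based
#'   throughout the package).
#' @return named integer vector of counts over the symbols observed in the
#'   column (amino acids and `"."`); counts sum to the number of sequences.
#' @export
column_profile <- function(aln, col) {
  stopifnot(inherits(aln, "nsltp_aln"))
  if (col < 0L || col >= ncol(aln))
    stop_nsltp("column %d out of range [0, %d]", col, ncol(aln) - 1L)
  tab <- table(aln[, col + 1L])
  setNames(as.integer(tab), names(tab))
}

#' Majority consensus of an alignment
#'
#' Per column, the consensus symbol is the most frequent amino acid (gaps do
#' not vote); ties are broken alphabetically.  The consensus becomes a gap
#' when strictly more than half of the sequences carry a gap in that column.
#'
#' @inheritParams n_columns
#' @return single gapped character string of length `n_columns(aln)`.
#' @export
build_consensus <- function(aln) {
  stopifnot(inherits(aln, "nsltp_aln"))
  n <- nrow(aln)
  out <- vapply(seq_len(ncol(aln)), function(j) {
    colv <- aln[, j]
    n_gap <- sum(colv == GAP)
    if (n_gap > n / 2) return(GAP)
    aa <- colv[colv != GAP]
    if (length(aa) == 0L) return(GAP)
    tab <- table(aa)
    # which.max on a table sorted by name gives the alphabetical tie-break
    names(tab)[which.max(tab)]
  }, character(1L))
  paste(out, collapse = "")
}

#' Map alignment columns to reference residue numbers
#'
#' @inheritParams n_columns
#' @param ref_id id of the reference sequence.
#' @return data.frame with columns `alignment_position` (0-based) and
#'   `residue_number` (1-based over the ungapped reference), one row per
#'   non-gap reference column.
#' @export
map_to_reference <- function(aln, ref_id) {
  stopifnot(inherits(aln, "nsltp_aln"))
  if (!ref_id %in% rownames(aln))
    stop_nsltp("unknown reference id '%s'", ref_id)
  row <- aln[ref_id, ]
  cols <- which(row != GAP)
  data.frame(
    alignment_position = cols - 1L,
    residue_number = seq_along(cols)
  )
}

#' Extract a sub-alignment by sequence id
#'
#' Columns are kept verbatim (never re-compacted), so alignment positions
#' remain comparable across subsets — required when traces from different
#' structural clusters are compared at shared column numbers.
#'
#' @inheritParams n_columns
#' @param ids ids to keep, in the requested order.
#' @return an `nsltp_aln` with the selected rows and unchanged width.
#' @export
subset_alignment <- function(aln, ids) {
  stopifnot(inherits(aln, "nsltp_aln"))
  missing <- setdiff(ids, rownames(aln))
  if (length(missing) > 0L)
    stop_nsltp("unknown ids: %s", paste(missing, collapse = ", "))
  out <- unclass(aln)[ids, , drop = FALSE]
  structure(out, class = c("nsltp_aln", "matrix", "array"))
}

#' Write a column-to-residue mapping as TSV
#' @param mapping result of [map_to_reference()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mapping_tsv <- function(mapping, path) {
  write.table(mapping, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
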