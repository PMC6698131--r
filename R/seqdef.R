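# Family-membership filtering on the eight-cysteine motif (8CM).
#
# The 8CM is C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C: eight cysteines of which the
# 3rd/4th are adjacent (CC) and the 5th/6th are separated by exactly one
# residue (CXC).  Every other spacer must hold at least `spacer_min`
# residues (default 1) so that the CC and CXC groups stay unambiguous.

# residue classes for the CXC fold-type heuristic; overridable per call
CXC_HYDROPHILIC <- c("S", "T", "N", "Q", "D", "E", "K", "R", "H")
CXC_APOLAR <- c("A", "V", "L", "I", "F", "M", "W")

validate_residues <- function(residues) {
  if (length(residues) != 1L || is.na(residues) || nchar(residues) < 1L)
    stop_nsltp("residue string must be a single non-empty string")
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA20)
  if (length(bad) > 0L)
    stop_nsltp("non-amino-acid character '%s' at position %d",
               chars[bad[1L]], bad[1L])
  chars
}

#' Locate the eight-cysteine motif in a mature sequence
#'
#' @param residues mature (gap-free) protein sequence over the 20 standard
#'   one-letter amino-acid codes.
#' @param spacer_min minimum length of each `Xn` spacer segment (between
#'   C1-C2, C2-C3, C4-C5, C6-C7 and C7-C8); the CC pair and the CXC triplet
#'   are fixed by definition.
#' @return `NULL` when the sequence does not carry the motif; otherwise a
#'   list with `cys_positions` (eight 0-based indices, strictly increasing),
#'   `cxc_central_residue` (the single residue between the 5th and 6th
#'   cysteine) and `spacer_lengths` (the seven inter-cysteine segment
#'   lengths).
#' @details A match requires *exactly* eight cysteines in the sequence; the
#'   motif is then tested on those positions.  Terminal cysteines may sit at
#'   the sequence ends.
#' @examples
#' find_8cm("CACACCACACACAC")$cys_positions
#' @export
find_8cm <- function(residues, spacer_min = 1L) {
  chars <- validate_residues(residues)
  pos <- which(chars == "C")  # 1-based
  if (length(pos) != 8L) return(NULL)
  gaps <- diff(pos) - 1L  # residues strictly between consecutive cysteines
  ok <- gaps[3L] == 0L &&                       # CC pair
    gaps[5L] == 1L &&                           # CXC
    all(gaps[c(1L, 2L, 4L, 6L, 7L)] >= spacer_min)
  if (!ok) return(NULL)
  list(
    cys_positions = pos - 1L,
    cxc_central_residue = chars[pos[5L] + 1L],
    spacer_lengths = gaps
  )
}

#' Test a sequence against the nsLTP family-membership criteria
#'
#' Membership requires (i) a precursor between 60 and 150 residues
#' (evaluated only when `precursor_length` is supplied — the toolkit works
#' on mature sequences and cannot recover the signal peptide), (ii) exactly
#' eight cysteines in the mature sequence and (iii) those cysteines arranged
#' in the 8CM pattern.
#'
#' @inheritParams find_8cm
#' @param precursor_length optional residue count of the full precursor
#'   (signal peptide included).
#' @param min_precursor,max_precursor inclusive precursor-length bounds.
#' @return list with `passed` (TRUE iff no rule failed), `reasons`
#'   (character vector among `"length_bounds"`, `"cys_count"`, `"pattern"`),
#'   `length_evaluated` (FALSE when `precursor_length` was absent) and
#'   `match` (the [find_8cm()] result or `NULL`).
#' @export
passes_nsltp_criteria <- function(residues, precursor_length = NULL,
                                  min_precursor = 60L, max_precursor = 150L,
                                  spacer_min = 1L) {
  chars <- validate_residues(residues)
  reasons <- character(0L)
  length_evaluated <- !is.null(precursor_length) && !is.na(precursor_length)
  if (length_evaluated &&
      (precursor_length < min_precursor || precursor_length > max_precursor))
    reasons <- c(reasons, "length_bounds")
  n_cys <- sum(chars == "C")
  match <- NULL
  if (n_cys != 8L) {
    reasons <- c(reasons, "cys_count")
  } else {
    match <- find_8cm(residues, spacer_min = spacer_min)
    if (is.null(match)) reasons <- c(reasons, "pattern")
  }
  list(passed = length(reasons) == 0L, reasons = reasons,
       length_evaluated = length_evaluated, match = match)
}

#' Fold-type hint from the CXC central residue
#'
#' Type I nsLTPs typically carry a hydrophilic residue between the 5th and
#' 6th cysteine while type II proteins carry an apolar one; the remaining
#' residues (G, P, C, Y by default) give no signal.
#'
#' @param match a [find_8cm()] result (or any list with
#'   `cxc_central_residue`).
#' @param hydrophilic,apolar residue classes used for the call; defaults are
#'   the standard charged/polar vs aliphatic/aromatic-apolar split.
#' @return one of `"type1_like"`, `"type2_like"`, `"indeterminate"`.
#' @export
cxc_fold_hint <- function(match, hydrophilic = CXC_HYDROPHILIC,
                          apolar = CXC_APOLAR) {
  res <- match$cxc_central_residue
  if (is.null(res)) stop_nsltp("match carries no cxc_central_residue")
  if (res %in% hydrophilic) "type1_like"
  else if (res %in% apolar) "type2_like"
  else "indeterminate"
}

#' Read mature sequences from FASTA
#'
#' @param path plain or gzipped FASTA of ungapped protein sequences.
#' @return named character vector of residue strings.
#' @export
read_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Filter a sequence set and build a membership report
#'
#' @param sequences named character vector of mature sequences (see
#'   [read_sequences()]).
#' @param precursor_lengths optional named integer vector of precursor
#'   lengths (ids matching `sequences`).
#' @inheritParams passes_nsltp_criteria
#' @return data.frame with columns `id`, `passed`, `reasons`
#'   (comma-joined), `cys_positions` (comma-joined 0-based),
#'   `cxc_central_residue` and `fold_hint`.
#' @export
filter_sequences <- function(sequences, precursor_lengths = NULL,
                             min_precursor = 60L, max_precursor = 150L,
                             spacer_min = 1L) {
  ids <- names(sequences)
  if (is.null(ids)) stop_nsltp("sequences must be named by id")
  rows <- lapply(ids, function(id) {
    dec <- passes_nsltp_criteria(
      sequences[[id]],
      precursor_length = if (!is.null(precursor_lengths))
        precursor_lengths[[id]] else NULL,
      min_precursor = min_precursor, max_precursor = max_precursor,
      spacer_min = spacer_min)
    data.frame(
      id = id,
      passed = dec$passed,
      reasons = paste(dec$reasons, collapse = ","),
      cys_positions = if (!is.null(dec$match))
        paste(dec$match$cys_positions, collapse = ",") else "",
      cxc_central_residue = if (!is.null(dec$match))
        dec$match$cxc_central_residue else "",
      fold_hint = if (!is.null(dec$match)) cxc_fold_hint(dec$match) else ""
    )
  })
  do.call(rbind, rows)
}
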