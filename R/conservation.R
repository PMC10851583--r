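#' Read an aligned protein FASTA
#'
#' @param path Aligned FASTA; all records must have equal length (gaps
#'   as `-`).
#' @return A tibble with columns `id` and `seq` (uppercase). The first
#'   record is conventionally the reference.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  aln <- tibble::tibble(id = names(set),
                        seq = unname(toupper(as.character(set))))
  validate_alignment(aln)
  aln
}

#' @rdname read_alignment
#' @param alignment Alignment tibble (`id`, `seq`).
#' @export
write_alignment <- function(alignment, path) {
  validate_alignment(alignment)
  set <- Biostrings::AAStringSet(alignment$seq)
  names(set) <- alignment$id
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

validate_alignment <- function(alignment) {
  stopifnot(all(c("id", "seq") %in% names(alignment)))
  if (nrow(alignment) < 2L) {
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  }
  widths <- nchar(alignment$seq)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(widths)), collapse = ", "), call. = FALSE)
  }
  invisible(alignment)
}

#' Map reference residue indices to alignment columns (and back)
#'
#' The reference sequence may carry gaps; residue k of the ungapped
#' reference corresponds to the k-th non-gap column.
#'
#' @param ref_seq Reference row of the alignment (possibly gapped).
#' @param residue 1-based residue indices in the ungapped reference.
#' @return Integer alignment column indices.
#' @export
ref_residue_to_column <- function(ref_seq, residue) {
  non_gap <- which(strsplit(ref_seq, "")[[1]] != "-")
  residue <- as.integer(residue)
  if (any(residue < 1L | residue > length(non_gap))) {
    stop("residue index out of range 1..", length(non_gap), call. = FALSE)
  }
  non_gap[residue]
}

#' @rdname ref_residue_to_column
#' @param column 1-based alignment column indices; must be non-gap in
#'   the reference.
#' @export
column_to_ref_residue <- function(ref_seq, column) {
  chars <- strsplit(ref_seq, "")[[1]]
  column <- as.integer(column)
  if (any(column < 1L | column > length(chars))) {
    stop("column index out of range 1..", length(chars), call. = FALSE)
  }
  if (any(chars[column] == "-")) {
    stop("reference has a gap at the requested column", call. = FALSE)
  }
  cumsum(chars != "-")[column]
}

#' Conservation of alignment columns at reference residues
#'
#' For each requested residue of the (first, by default) reference
#' sequence, computes the fraction of the other sequences whose residue
#' at that alignment column matches the reference residue; a column is
#' `strict` when the fraction is exactly 1.
#'
#' @param alignment Alignment tibble from [read_alignment()] (or built
#'   in code); the reference is the row named by `ref`.
#' @param residue Integer vector of 1-based reference residue indices.
#' @param ref Reference row index or `id`; default first row.
#' @return A tibble: `residue`, `column`, `ref_aa`, `n_compared`,
#'   `n_identical`, `fraction_identical`, `strict`.
#' @examples
#' aln <- tibble::tibble(id = c("ref", "s1", "s2"),
#'                       seq = c("MARK", "MARK", "MTRK"))
#' column_conservation(aln, residue = 1:4)
#' @export
column_conservation <- function(alignment, residue, ref = 1L) {
  validate_alignment(alignment)
  if (is.character(ref)) ref <- match(ref, alignment$id)
  stopifnot(!is.na(ref), ref >= 1L, ref <= nrow(alignment))
  ref_seq <- alignment$seq[ref]
  others <- alignment$seq[-ref]
  cols <- ref_residue_to_column(ref_seq, residue)
  purrr::map2_dfr(as.integer(residue), cols, function(k, col) {
    ref_aa <- substr(ref_seq, col, col)
    other_aa <- substr(others, col, col)
    n_id <- sum(other_aa == ref_aa)
    tibble::tibble(
      residue = k, column = col, ref_aa = ref_aa,
      n_compared = length(other_aa), n_identical = n_id,
      fraction_identical = n_id / length(other_aa),
      strict = n_id == length(other_aa)
    )
  })
}
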