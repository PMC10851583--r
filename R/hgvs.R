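#' Parse HGVS coding-DNA (c.) descriptions
#'
#' Parses a restricted HGVS subset covering the variant classes seen in
#' clinical resequencing tables: single-nucleotide substitutions
#' (`c.553G>T`), simple insertions (`c.544_545insGGTGC`) and simple
#' deletions (`c.100del`, `c.100_102del`, optionally with the deleted
#' bases spelled out). Whitespace inside the description is tolerated on
#' input and stripped from the canonical form. Coding-nucleotide
#' numbering starts at the A of the initiator ATG (position 1).
#'
#' @param x Character vector of HGVS c. strings.
#' @return A tibble with one row per input: `hgvs` (canonical string),
#'   `kind` (`"substitution"`, `"insertion"` or `"deletion"`), `position`
#'   (1-based start), `end` (end coordinate; equals `position` for
#'   substitutions), `ref_base`, `alt_base`, `inserted_seq`,
#'   `deleted_len`. Fields that do not apply to a class are `NA`.
#' @examples
#' parse_cdna_hgvs(c("c.553G>T", "c.544_545insGGTGC"))
#' @seealso [parse_protein_hgvs()], [format_cdna_hgvs()]
#' @export
parse_cdna_hgvs <- function(x) {
  stopifnot(is.character(x))
  purrr::map_dfr(x, parse_cdna_one)
}

parse_cdna_one <- function(text) {
  raw <- text
  s <- gsub("[[:space:]]+", "", text)
  if (startsWith(s, "p.")) {
    stop("protein (p.) description passed to the cDNA parser: '", raw, "'",
         call. = FALSE)
  }
  if (!startsWith(s, "c.")) {
    stop("not an HGVS c. description: '", raw, "'", call. = FALSE)
  }
  body <- substr(s, 3L, nchar(s))

  row <- function(kind, position, end = position, ref_base = NA_character_,
                  alt_base = NA_character_, inserted_seq = NA_character_,
                  deleted_len = NA_integer_) {
    tibble::tibble(
      hgvs = format_cdna_row(kind, position, end, ref_base, alt_base,
                             inserted_seq, deleted_len),
      kind = kind, position = as.integer(position), end = as.integer(end),
      ref_base = ref_base, alt_base = alt_base,
      inserted_seq = inserted_seq, deleted_len = deleted_len
    )
  }

  m <- regmatches(body, regexec("^([0-9]+)([A-Za-z])>([A-Za-z])$", body))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2])
    ref <- toupper(m[3]); alt <- toupper(m[4])
    check_nuc(c(ref, alt), raw)
    if (pos < 1L) stop("cDNA position must be >= 1 in '", raw, "'", call. = FALSE)
    if (ref == alt) {
      stop("reference and alternate base are identical in '", raw, "'",
           call. = FALSE)
    }
    return(row("substitution", pos, pos, ref_base = ref, alt_base = alt))
  }

  m <- regmatches(body, regexec("^([0-9]+)_([0-9]+)ins([A-Za-z]+)$", body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2]); end <- as.integer(m[3])
    seq <- toupper(m[4])
    check_nuc(strsplit(seq, "")[[1]], raw)
    if (end != start + 1L) {
      stop("insertion flanks must be consecutive, got ", start, "_", end,
           " in '", raw, "'", call. = FALSE)
    }
    if (start < 1L) stop("cDNA position must be >= 1 in '", raw, "'", call. = FALSE)
    return(row("insertion", start, end, inserted_seq = seq))
  }

  m <- regmatches(body, regexec("^([0-9]+)(?:_([0-9]+))?del([A-Za-z]*)$", body))[[1]]
  if (length(m)) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    if (start < 1L || end < start) {
      stop("invalid deletion range ", start, "_", end, " in '", raw, "'",
           call. = FALSE)
    }
    len <- end - start + 1L
    if (nzchar(m[4])) {
      seq <- toupper(m[4])
      check_nuc(strsplit(seq, "")[[1]], raw)
      if (nchar(seq) != len) {
        stop("deleted sequence length ", nchar(seq),
             " does not match range length ", len, " in '", raw, "'",
             call. = FALSE)
      }
    }
    return(row("deletion", start, end, deleted_len = len))
  }

  stop("cannot parse HGVS c. description: '", raw, "'", call. = FALSE)
}

check_nuc <- function(bases, raw) {
  bad <- setdiff(bases, c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("non-nucleotide letter '", bad[1], "' in '", raw, "'", call. = FALSE)
  }
  invisible(TRUE)
}

format_cdna_row <- function(kind, position, end, ref_base, alt_base,
                            inserted_seq, deleted_len) {
  switch(kind,
    substitution = paste0("c.", position, ref_base, ">", alt_base),
    insertion    = paste0("c.", position, "_", end, "ins", inserted_seq),
    deletion     = if (end > position) {
      paste0("c.", position, "_", end, "del")
    } else {
      paste0("c.", position, "del")
    },
    stop("unknown cDNA change kind: ", kind, call. = FALSE)
  )
}

#' Format parsed cDNA changes back to canonical HGVS
#'
#' @param x A tibble as returned by [parse_cdna_hgvs()].
#' @return Character vector of canonical HGVS c. strings.
#' @export
format_cdna_hgvs <- function(x) {
  purrr::pmap_chr(
    x[c("kind", "position", "end", "ref_base", "alt_base", "inserted_seq",
        "deleted_len")],
    format_cdna_row
  )
}

#' Parse HGVS protein (p.) descriptions
#'
#' Accepts one-letter substitutions (`p.G185C`; called synonymous when the
#' two residues agree), frameshifts anchored at a residue (`p.H182fs`),
#' stopgains written with `*` or `X` as the alternate residue
#' (`p.W100*`), and stoploss (`p.*367W`).
#'
#' @param x Character vector of HGVS p. strings.
#' @return A tibble with `hgvs` (canonical form), `kind` (`missense`,
#'   `synonymous`, `frameshift`, `stopgain`, `stoploss`), `position`
#'   (1-based residue index), `ref_aa`, `alt_aa`.
#' @examples
#' parse_protein_hgvs(c("p.G185C", "p.H182fs"))
#' @export
parse_protein_hgvs <- function(x) {
  stopifnot(is.character(x))
  purrr::map_dfr(x, parse_protein_one)
}

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
         "Q", "R", "S", "T", "V", "W", "Y")

parse_protein_one <- function(text) {
  raw <- text
  s <- gsub("[[:space:]]+", "", text)
  if (!startsWith(s, "p.")) {
    stop("not an HGVS p. description: '", raw, "'", call. = FALSE)
  }
  body <- substr(s, 3L, nchar(s))

  row <- function(kind, position, ref_aa, alt_aa = NA_character_) {
    tibble::tibble(
      hgvs = format_protein_row(kind, position, ref_aa, alt_aa),
      kind = kind, position = as.integer(position),
      ref_aa = ref_aa, alt_aa = alt_aa
    )
  }

  m <- regmatches(body, regexec("^([A-Za-z*])([0-9]+)fs$", body))[[1]]
  if (length(m)) {
    ref <- toupper(m[2])
    check_aa(ref, raw)
    return(row("frameshift", as.integer(m[3]), ref_aa = ref))
  }

  m <- regmatches(body, regexec("^([A-Za-z*])([0-9]+)([A-Za-z*])$", body))[[1]]
  if (length(m)) {
    ref <- toupper(m[2]); alt <- toupper(m[4])
    pos <- as.integer(m[3])
    if (pos < 1L) stop("residue position must be >= 1 in '", raw, "'", call. = FALSE)
    if (ref == "*") {
      check_aa(alt, raw)
      return(row("stoploss", pos, ref_aa = ref, alt_aa = alt))
    }
    check_aa(ref, raw)
    if (alt %in% c("*", "X")) {
      return(row("stopgain", pos, ref_aa = ref, alt_aa = "*"))
    }
    check_aa(alt, raw)
    kind <- if (ref == alt) "synonymous" else "missense"
    return(row(kind, pos, ref_aa = ref, alt_aa = alt))
  }

  stop("cannot parse HGVS p. description: '", raw, "'", call. = FALSE)
}

check_aa <- function(aa, raw) {
  bad <- setdiff(aa, AA1)
  if (length(bad)) {
    stop("'", bad[1], "' is not a standard one-letter amino acid in '",
         raw, "'", call. = FALSE)
  }
  invisible(TRUE)
}

format_protein_row <- function(kind, position, ref_aa, alt_aa) {
  switch(kind,
    frameshift = paste0("p.", ref_aa, position, "fs"),
    stopgain   = paste0("p.", ref_aa, position, "*"),
    paste0("p.", ref_aa, position, alt_aa)
  )
}

#' Format parsed protein changes back to canonical HGVS
#'
#' @param x A tibble as returned by [parse_protein_hgvs()].
#' @return Character vector of canonical HGVS p. strings.
#' @export
format_protein_hgvs <- function(x) {
  purrr::pmap_chr(x[c("kind", "position", "ref_aa", "alt_aa")],
                  format_protein_row)
}
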