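#' Codon number containing a coding-nucleotide position
#'
#' @param cds_position Integer vector of 1-based coding-nucleotide
#'   indices (position 1 is the A of the initiator ATG).
#' @return Integer vector of 1-based codon numbers, `ceiling(pos / 3)`.
#' @examples
#' codon_index(553) # codon 185
#' @export
codon_index <- function(cds_position) {
  cds_position <- as.integer(cds_position)
  if (any(is.na(cds_position)) || any(cds_position < 1L)) {
    stop("cds_position must be a positive 1-based coordinate", call. = FALSE)
  }
  as.integer(ceiling(cds_position / 3))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

genetic_code <- function() {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- gsub("U", "T", names(Biostrings::GENETIC_CODE))
  gc
}

split_codons <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Validate a coding sequence
#'
#' A valid CDS is an uppercase A/C/G/T string whose length is a multiple
#' of three, starting with ATG and ending with its single stop codon.
#'
#' @param nt Nucleotide string.
#' @return The string, invisibly, if valid; otherwise an error.
#' @export
validate_cds <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  if (grepl("[^ACGT]", nt)) stop("CDS contains non-ACGT characters", call. = FALSE)
  if (nchar(nt) %% 3L != 0L) {
    stop("CDS length ", nchar(nt), " is not a multiple of 3", call. = FALSE)
  }
  codons <- split_codons(nt)
  if (codons[1] != "ATG") stop("CDS must start with ATG", call. = FALSE)
  stops <- which(codons %in% STOP_CODONS)
  if (length(stops) == 0L || stops[length(stops)] != length(codons)) {
    stop("CDS must end with a stop codon", call. = FALSE)
  }
  if (length(stops) > 1L) {
    stop("internal stop codon at codon ", stops[1], call. = FALSE)
  }
  invisible(nt)
}

#' Translate a coding sequence
#'
#' Standard-code translation of a validated CDS; the terminal stop is
#' excluded, so the result has `nchar(cds)/3 - 1` residues.
#'
#' @param cds Validated coding sequence (see [validate_cds()]).
#' @return Single amino-acid string.
#' @examples
#' translate_cds("ATGGGCTAA") # "MG"
#' @export
translate_cds <- function(cds) {
  cds <- validate_cds(cds)
  codons <- split_codons(cds)
  aa <- unname(genetic_code()[codons])
  paste(aa[-length(aa)], collapse = "")
}

# Translate without CDS validity checks; internal stops rendered "*".
# Trailing incomplete codon dropped. Used by the frameshift machinery and
# by the brute-force oracle in the test suite.
translate_raw <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n == 0L) return("")
  codons <- split_codons(substr(nt, 1L, n))
  paste(unname(genetic_code()[codons]), collapse = "")
}

apply_cdna_change <- function(cds, change) {
  pos <- change$position
  switch(change$kind,
    substitution = {
      paste0(substr(cds, 1L, pos - 1L), change$alt_base,
             substr(cds, pos + 1L, nchar(cds)))
    },
    insertion = {
      paste0(substr(cds, 1L, pos), change$inserted_seq,
             substr(cds, pos + 1L, nchar(cds)))
    },
    deletion = {
      paste0(substr(cds, 1L, pos - 1L),
             substr(cds, change$end + 1L, nchar(cds)))
    }
  )
}

#' Call the protein consequence of a coding-DNA change
#'
#' Maps a parsed cDNA change (or an HGVS c. string) onto a coding
#' sequence. Substitutions are resolved codon-locally against the
#' reference codon (missense / synonymous / stopgain / stoploss); indels
#' whose length is not a multiple of three are frameshifts anchored at
#' the codon containing the first shifted nucleotide (for an insertion
#' between i and i+1, the codon of i+1), and in-frame indels are
#' reported as `inframe`.
#'
#' @param cds Validated coding sequence.
#' @param change One-row tibble from [parse_cdna_hgvs()], or an HGVS
#'   c. string.
#' @return One-row tibble: `kind`, `position` (residue), `ref_aa`,
#'   `alt_aa`, `hgvs_p` (canonical protein description; `NA` for
#'   in-frame indels).
#' @examples
#' cds <- build_synthetic_cds(length = 10, codon_constraints = c("5" = "GGC"))
#' call_consequence(cds, "c.13G>T")
#' @export
call_consequence <- function(cds, change) {
  cds <- validate_cds(cds)
  if (is.character(change)) change <- parse_cdna_hgvs(change)
  stopifnot(nrow(change) == 1L)
  n <- nchar(cds)
  protein_len <- n / 3L - 1L
  if (change$end > n || change$position > n) {
    stop("change at cDNA position ", change$position,
         " lies beyond the ", n, " nt CDS", call. = FALSE)
  }
  code <- genetic_code()

  if (change$kind == "substitution") {
    pos <- change$position
    have <- substr(cds, pos, pos)
    if (have != change$ref_base) {
      stop("reference-base mismatch at c.", pos, ": change expects ",
           change$ref_base, " but the CDS holds ", have, call. = FALSE)
    }
    ci <- codon_index(pos)
    cstart <- (ci - 1L) * 3L + 1L
    ref_codon <- substr(cds, cstart, cstart + 2L)
    off <- pos - cstart + 1L
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- change$alt_base
    ref_aa <- unname(code[ref_codon])
    alt_aa <- unname(code[alt_codon])
    kind <-
      if (ci > protein_len) {           # terminal stop codon
        if (alt_aa == "*") "synonymous" else "stoploss"
      } else if (alt_aa == "*") {
        "stopgain"
      } else if (ref_aa == alt_aa) {
        "synonymous"
      } else {
        "missense"
      }
    return(consequence_row(kind, ci, ref_aa, alt_aa))
  }

  # indels
  shift_len <- if (change$kind == "insertion") {
    nchar(change$inserted_seq)
  } else {
    change$deleted_len
  }
  first_shifted <- if (change$kind == "insertion") {
    change$position + 1L
  } else {
    change$position
  }
  anchor <- codon_index(first_shifted)
  ref_aa <- unname(code[split_codons(cds)[anchor]])
  if (shift_len %% 3L == 0L) {
    return(consequence_row("inframe", anchor, ref_aa, NA_character_))
  }
  consequence_row("frameshift", anchor, ref_aa, NA_character_)
}

consequence_row <- function(kind, position, ref_aa, alt_aa) {
  hgvs_p <- switch(kind,
    missense   = paste0("p.", ref_aa, position, alt_aa),
    synonymous = paste0("p.", ref_aa, position, "="),
    stopgain   = paste0("p.", ref_aa, position, "*"),
    stoploss   = paste0("p.*", position, alt_aa),
    frameshift = paste0("p.", ref_aa, position, "fs"),
    NA_character_
  )
  tibble::tibble(
    kind = kind, position = as.integer(position),
    ref_aa = ref_aa, alt_aa = alt_aa, hgvs_p = hgvs_p
  )
}

#' Read / write a single-record coding-sequence FASTA
#'
#' Thin wrappers over Biostrings FASTA IO that enforce the single-record,
#' uppercase convention used for coding sequences.
#'
#' @param path File path.
#' @return `read_cds_fasta()` returns the validated nucleotide string.
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("expected a single-record FASTA, found ", length(set), " records",
         call. = FALSE)
  }
  validate_cds(toupper(as.character(set[[1]])))
  toupper(as.character(set[[1]]))
}

#' @rdname read_cds_fasta
#' @param cds Validated coding sequence.
#' @param name FASTA record name.
#' @export
write_cds_fasta <- function(cds, path, name = "cds") {
  cds <- validate_cds(cds)
  set <- Biostrings::DNAStringSet(cds)
  names(set) <- name
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}
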