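SENSE_CODONS <- local({
  all <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                               paste0),
                         c("A", "C", "G", "T"), paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Build a synthetic coding sequence under residue/codon constraints
#'
#' Produces a random CDS of `length` codons plus a terminal TAA stop,
#' with no internal stop codons, whose translation satisfies every
#' constraint. `codon_constraints` pin exact codons (so that specific
#' nucleotide substitutions produce specific residue changes);
#' `residue_constraints` pin a residue and draw a synonymous codon for
#' it. Codon 1 is always ATG.
#'
#' @param length Protein length in codons (excluding the stop).
#' @param residue_constraints Named character vector, names = 1-based
#'   codon numbers, values = one-letter residues.
#' @param codon_constraints Named character vector, names = codon
#'   numbers, values = exact codons.
#' @param seed Optional integer seed (local RNG).
#' @return A validated CDS string of `3 * (length + 1)` nucleotides.
#' @examples
#' cds <- build_synthetic_cds(length = 20, seed = 1)
#' nchar(cds) # 63
#' @export
build_synthetic_cds <- function(length, residue_constraints = NULL,
                                codon_constraints = NULL, seed = NULL) {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  body <- function() {
    code <- genetic_code()
    codons <- sample(SENSE_CODONS, length, replace = TRUE)
    codons[1] <- "ATG"
    if (!is.null(residue_constraints)) {
      pos <- as.integer(names(residue_constraints))
      if (any(is.na(pos)) || any(pos < 1L) || any(pos > length)) {
        stop("residue constraint outside codon range 1..", length,
             call. = FALSE)
      }
      if (anyDuplicated(pos)) {
        stop("conflicting constraints: one residue per codon", call. = FALSE)
      }
      for (j in seq_along(pos)) {
        aa <- toupper(residue_constraints[j])
        if (!aa %in% AA1) {
          stop("constraint at codon ", pos[j], " names an impossible ",
               "residue '", residue_constraints[j], "'", call. = FALSE)
        }
        if (pos[j] == 1L && aa != "M") {
          stop("codon 1 must encode Met", call. = FALSE)
        }
        syn <- SENSE_CODONS[code[SENSE_CODONS] == aa]
        codons[pos[j]] <- if (length(syn) == 1L) syn else sample(syn, 1L)
      }
    }
    if (!is.null(codon_constraints)) {
      pos <- as.integer(names(codon_constraints))
      if (any(is.na(pos)) || any(pos < 1L) || any(pos > length)) {
        stop("codon constraint outside codon range 1..", length,
             call. = FALSE)
      }
      cod <- toupper(codon_constraints)
      if (any(!cod %in% SENSE_CODONS)) {
        stop("codon constraint is not a sense codon: ",
             cod[!cod %in% SENSE_CODONS][1], call. = FALSE)
      }
      if (any(pos == 1L & cod != "ATG")) {
        stop("codon 1 must be ATG", call. = FALSE)
      }
      codons[pos] <- cod
    }
    validate_cds(paste(c(codons, "TAA"), collapse = ""))
    paste(c(codons, "TAA"), collapse = "")
  }
  if (is.null(seed)) body() else with_local_seed(seed, body())
}

# Codons pinned so each printed APOA5 nucleotide change yields its
# printed residue change (e.g. GGC at 185 so c.553G>T gives Gly185Cys;
# AAA at 188 so c.563A>T gives Lys188Ile).
APOA5_CODON_CONSTRAINTS <- c(
  "26" = "GGC", "35" = "AGC", "153" = "GTG", "167" = "GAC",
  "180" = "GTG", "182" = "CAC", "185" = "GGC", "188" = "AAA",
  "223" = "CGC", "263" = "GGC"
)

#' A synthetic apoA-V-like coding sequence
#'
#' A 366-codon stand-in for the (unpublished) APOA5 transcript used to
#' validate consequence names: wild-type residues at every tabulated
#' variant position are pinned via exact codons, the remainder is random
#' but seed-deterministic.
#'
#' @param seed Integer seed.
#' @return A 1101-nt CDS string.
#' @export
apoa5_synthetic_cds <- function(seed = 1L) {
  build_synthetic_cds(length = APOA5_PROTEIN_LENGTH,
                      codon_constraints = APOA5_CODON_CONSTRAINTS,
                      seed = seed)
}

#' Simulate a small cross-species protein alignment
#'
#' Builds an alignment of the reference protein against simulated
#' orthologs: at each non-conserved column, each non-reference sequence
#' is substituted with probability `variability`; the listed conserved
#' columns are never touched, so they are strictly conserved by
#' construction. No gaps are introduced, so alignment columns coincide
#' with reference residues.
#'
#' @param ref_protein Reference amino-acid string.
#' @param ids Sequence names; the first names the reference.
#' @param conserved Residue columns kept strictly conserved.
#' @param variability Per-column substitution probability for
#'   non-reference sequences.
#' @param seed Integer seed.
#' @return An alignment tibble (`id`, `seq`).
#' @export
simulate_alignment <- function(ref_protein,
                               ids = c("HUMAN", "RAT", "MOUSE", "NEOSC",
                                       "ACIJB", "PHOVI"),
                               conserved = c(35L, 167L, 223L),
                               variability = 0.2, seed = 1L) {
  stopifnot(length(ids) >= 2L, variability >= 0, variability <= 1)
  n <- nchar(ref_protein)
  if (any(conserved < 1L | conserved > n)) {
    stop("conserved column outside 1..", n, call. = FALSE)
  }
  with_local_seed(seed, {
    ref_chars <- strsplit(ref_protein, "")[[1]]
    seqs <- c(ref_protein, vapply(ids[-1], function(id) {
      chars <- ref_chars
      mutable <- setdiff(seq_len(n), conserved)
      hit <- mutable[stats::runif(length(mutable)) < variability]
      for (j in hit) {
        chars[j] <- sample(setdiff(AA1, chars[j]), 1L)
      }
      paste(chars, collapse = "")
    }, character(1)))
    tibble::tibble(id = ids, seq = unname(seqs))
  })
}

#' The packaged-style conservation fixture alignment
#'
#' Six-species apoA-V-like alignment built from the synthetic CDS
#' translation, strictly conserved at residues 35, 167 and 223.
#'
#' @param seed Integer seed (drives both the CDS and the orthologs).
#' @param variability Per-column substitution probability.
#' @return An alignment tibble.
#' @export
apoa5_alignment_fixture <- function(seed = 1L, variability = 0.2) {
  simulate_alignment(translate_cds(apoa5_synthetic_cds(seed)),
                     variability = variability, seed = seed + 1L)
}
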