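PREDICTOR_LEVELS <- list(
  sift = c("D", "T"),
  polyphen_hdiv = c("D", "P", "B"),
  lrt = c("D", "N", "U"),
  mutation_taster = c("D", "N", "P", "A"),
  mutation_assessor = c("H", "M", "L", "N")
)

VARIANT_TABLE_COLS <- c(
  "gene", "exon", "cdna", "protein", "rsid", "status",
  names(PREDICTOR_LEVELS), "cadd", "af_all", "af_eas", "af_amr",
  "phylo_hmm", "n_het_hlap", "n_hom_hlap", "n_het_bap", "n_hom_bap"
)

#' Read a variant annotation table
#'
#' Reads a tab-delimited table of coding variants with their in-silico
#' predictor categories, CADD scores, allele frequencies, conservation
#' scores and per-arm carrier counts. The literal string `"na"` marks a
#' missing value in any annotation column; missing values are preserved
#' as `NA` and never coerced to zero. HGVS strings and predictor
#' categories are validated row by row, and a `variant_id` column
#' (canonical `gene:c.` string) is added.
#'
#' @param path Path to a TSV file with columns `gene, exon, cdna,
#'   protein, rsid, status, sift, polyphen_hdiv, lrt, mutation_taster,
#'   mutation_assessor, cadd, af_all, af_eas, af_amr, phylo_hmm,
#'   n_het_hlap, n_hom_hlap, n_het_bap, n_hom_bap`.
#' @return A tibble with one row per variant, the validated columns
#'   above plus `variant_id` and the parsed consequence `kind` from the
#'   protein description.
#' @export
read_variant_table <- function(path) {
  raw <- readr::read_tsv(
    path, na = "na", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  unknown <- setdiff(names(raw), VARIANT_TABLE_COLS)
  if (length(unknown)) {
    stop("unknown column(s) in variant table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(VARIANT_TABLE_COLS, names(raw))
  if (length(missing_cols)) {
    stop("variant table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(empty_variant_table())
  }
  out <- purrr::imap_dfr(split(raw, seq_len(nrow(raw))), function(r, i) {
    line <- as.integer(i) + 1L  # header is line 1
    tryCatch(validate_variant_row(r), error = function(e) {
      stop("variant table line ", line, ": ", conditionMessage(e),
           call. = FALSE)
    })
  })
  dup <- out$variant_id[duplicated(out$variant_id)]
  if (length(dup)) {
    stop("duplicate variant annotation for ", dup[1],
         "; conflicting duplicates are rejected", call. = FALSE)
  }
  out
}

empty_variant_table <- function() {
  tibble::tibble(
    variant_id = character(), gene = character(), exon = integer(),
    cdna = character(), protein = character(), kind = character(),
    rsid = character(), status = character(),
    sift = character(), polyphen_hdiv = character(), lrt = character(),
    mutation_taster = character(), mutation_assessor = character(),
    cadd = double(), af_all = double(), af_eas = double(),
    af_amr = double(), phylo_hmm = double(),
    n_het_hlap = integer(), n_hom_hlap = integer(),
    n_het_bap = integer(), n_hom_bap = integer()
  )
}

validate_variant_row <- function(r, arms = c("hlap", "bap")) {
  cdna <- parse_cdna_hgvs(r$cdna)
  prot <- parse_protein_hgvs(r$protein)
  for (p in names(PREDICTOR_LEVELS)) {
    v <- r[[p]]
    if (!is.na(v) && !v %in% PREDICTOR_LEVELS[[p]]) {
      stop("'", v, "' is not a valid ", p, " category (expected one of ",
           paste(PREDICTOR_LEVELS[[p]], collapse = "/"), ")")
    }
  }
  num <- function(x, what, lo = -Inf, hi = Inf) {
    if (is.na(x)) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("non-numeric ", what, ": '", x, "'")
    if (v < lo || v > hi) stop(what, " out of range [", lo, ", ", hi, "]: ", v)
    v
  }
  cnt <- function(x, what) {
    v <- num(x, what, lo = 0)
    if (is.na(v)) stop(what, " must not be missing")
    as.integer(v)
  }
  status <- r$status
  if (!status %in% c("known", "novel")) {
    stop("status must be 'known' or 'novel', got '", status, "'")
  }
  if (status == "novel" && !is.na(r$rsid)) {
    stop("novel variant must not carry an rsid (got '", r$rsid, "')")
  }
  if (status == "known" && is.na(r$rsid)) {
    stop("known variant must carry an rsid")
  }
  tibble::tibble(
    variant_id = paste0(r$gene, ":", cdna$hgvs),
    gene = r$gene,
    exon = as.integer(num(r$exon, "exon", lo = 1)),
    cdna = cdna$hgvs,
    protein = prot$hgvs,
    kind = prot$kind,
    rsid = r$rsid,
    status = status,
    sift = r$sift, polyphen_hdiv = r$polyphen_hdiv, lrt = r$lrt,
    mutation_taster = r$mutation_taster,
    mutation_assessor = r$mutation_assessor,
    cadd = num(r$cadd, "cadd", lo = 0),
    af_all = num(r$af_all, "af_all", 0, 1),
    af_eas = num(r$af_eas, "af_eas", 0, 1),
    af_amr = num(r$af_amr, "af_amr", 0, 1),
    phylo_hmm = num(r$phylo_hmm, "phylo_hmm"),
    n_het_hlap = cnt(r$n_het_hlap, "n_het_hlap"),
    n_hom_hlap = cnt(r$n_hom_hlap, "n_hom_hlap"),
    n_het_bap = cnt(r$n_het_bap, "n_het_bap"),
    n_hom_bap = cnt(r$n_hom_bap, "n_hom_bap")
  )
}

#' The packaged apoA-V variant annotation table
#'
#' Ten coding APOA5 variants from a two-arm acute-pancreatitis
#' resequencing study: six in the pathogenic section (five missense plus
#' the frameshift insertion c.544_545insGGTGC) and four benign, with the
#' categorical outputs of five predictors, CADD scores, gnomAD allele
#' frequencies, phylo-HMM residue conservation, and carrier counts by
#' arm and zygosity.
#'
#' @return A validated variant tibble (see [read_variant_table()]).
#' @examples
#' apoa5_variants()
#' @export
apoa5_variants <- function() {
  read_variant_table(
    system.file("extdata", "apoa5_variant_table.tsv", package = "varprio",
                mustWork = TRUE)
  )
}
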