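APOA5_PROTEIN_LENGTH <- 366L

DOMAIN_CLASSES <- c("signal_peptide", "helix", "lipid_binding",
                    "receptor_binding", "heparin_binding", "lpl_activation")

#' The apoA-V functional domain map
#'
#' Named residue intervals of the 366-residue apoA-V precursor
#' (full-length numbering, Met1 = 1, both ends inclusive): the signal
#' peptide (1-23), four AlphaFold-supported amphipathic helices, three
#' lipid-binding regions, nine positively charged receptor-binding
#' domains (RBD1-RBD9), the heparin-binding region (209-250) and the
#' LPL-activation region (215-261). Intervals of different classes
#' overlap freely.
#'
#' @return A tibble with columns `name`, `class`, `start`, `end`.
#' @examples
#' apoa5_domains()
#' @export
apoa5_domains <- function() {
  read_domain_map(
    system.file("extdata", "apoa5_domains.tsv", package = "varprio",
                mustWork = TRUE)
  )
}

#' Read / write a domain map TSV
#'
#' BED-like but 1-based and inclusive on both ends (columns `name`,
#' `class`, `start`, `end`), matching the residue numbering used
#' throughout.
#'
#' @param path File path.
#' @param protein_length Protein length used to validate intervals.
#' @return A validated domain-map tibble.
#' @export
read_domain_map <- function(path, protein_length = APOA5_PROTEIN_LENGTH) {
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = "ccii")
  validate_domain_map(map, protein_length)
  map
}

#' @rdname read_domain_map
#' @param map A domain-map tibble.
#' @export
write_domain_map <- function(map, path) {
  validate_domain_map(map)
  readr::write_tsv(map, path)
  invisible(path)
}

validate_domain_map <- function(map, protein_length = APOA5_PROTEIN_LENGTH) {
  stopifnot(all(c("name", "class", "start", "end") %in% names(map)))
  bad_class <- setdiff(map$class, DOMAIN_CLASSES)
  if (length(bad_class)) {
    stop("unknown domain class: ", bad_class[1], call. = FALSE)
  }
  with(map, {
    if (any(start < 1L | end > protein_length | start > end)) {
      stop("domain intervals must satisfy 1 <= start <= end <= ",
           protein_length, call. = FALSE)
    }
  })
  invisible(map)
}

#' Domains overlapping given residue positions
#'
#' @param position Integer vector of 1-based residue indices.
#' @param map Domain map tibble (default [apoa5_domains()]).
#' @param protein_length Upper bound for valid positions.
#' @return A tibble of `(position, name, class, start, end)` rows, one
#'   per overlapping interval, in map order within each position.
#'   Positions overlapping nothing contribute no rows.
#' @examples
#' domains_at(223) # helix 3, lipid binding 2, heparin binding, LPL activation
#' @export
domains_at <- function(position, map = apoa5_domains(),
                       protein_length = APOA5_PROTEIN_LENGTH) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L | position > protein_length)) {
    stop("residue position out of range 1..", protein_length, call. = FALSE)
  }
  validate_domain_map(map, protein_length)
  purrr::map_dfr(position, function(p) {
    hit <- map[map$start <= p & p <= map$end, ]
    if (nrow(hit) == 0L) return(tibble::tibble())
    tibble::tibble(position = p, hit)
  })
}

# Charge at physiological pH (His counted +1), polarity and a
# hydropathy binarization (Kyte-Doolittle > 0 = hydrophobic). A plain
# tibble constant so an alternative convention is a one-line change.
AA_PROPERTIES <- tibble::tibble(
  aa = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
         "P", "Q", "R", "S", "T", "V", "W", "Y"),
  charge = c(0, 0, -1, -1, 0, 0, 1, 0, 1, 0, 0, 0,
             0, 0, 1, 0, 0, 0, 0, 0),
  polarity = c("nonpolar", "nonpolar", "polar", "polar", "nonpolar",
               "nonpolar", "polar", "nonpolar", "polar", "nonpolar",
               "nonpolar", "polar", "nonpolar", "polar", "polar",
               "polar", "polar", "nonpolar", "nonpolar", "polar"),
  hydropathy = c("hydrophobic", "hydrophobic", "hydrophilic", "hydrophilic",
                 "hydrophobic", "hydrophilic", "hydrophilic", "hydrophobic",
                 "hydrophilic", "hydrophobic", "hydrophobic", "hydrophilic",
                 "hydrophilic", "hydrophilic", "hydrophilic", "hydrophilic",
                 "hydrophilic", "hydrophobic", "hydrophilic", "hydrophilic")
)

#' Residue property table
#'
#' The built-in per-residue property constants used by
#' [property_change()]: formal charge at physiological pH (Asp/Glu -1;
#' Lys/Arg/His +1), polar/nonpolar classification, and hydropathy
#' binarized from the Kyte-Doolittle scale at threshold 0.
#'
#' @return A tibble with columns `aa`, `charge`, `polarity`,
#'   `hydropathy`.
#' @export
aa_property_table <- function() AA_PROPERTIES

#' Describe the physicochemical change of a residue substitution
#'
#' @param ref_aa,alt_aa One-letter amino acids (vectorized).
#' @return A tibble per substitution: `ref_aa`, `alt_aa`,
#'   `charge_before/after`, `polarity_before/after`,
#'   `hydropathy_before/after` and logical `charge_changed`,
#'   `polarity_changed`, `hydropathy_changed`.
#' @examples
#' property_change("D", "V") # loses charge, polarity and hydrophilicity
#' @export
property_change <- function(ref_aa, alt_aa) {
  bad <- setdiff(c(ref_aa, alt_aa), AA_PROPERTIES$aa)
  if (length(bad)) {
    stop("'", bad[1], "' is not a standard one-letter amino acid",
         call. = FALSE)
  }
  before <- AA_PROPERTIES[match(ref_aa, AA_PROPERTIES$aa), ]
  after <- AA_PROPERTIES[match(alt_aa, AA_PROPERTIES$aa), ]
  tibble::tibble(
    ref_aa = ref_aa, alt_aa = alt_aa,
    charge_before = before$charge, charge_after = after$charge,
    polarity_before = before$polarity, polarity_after = after$polarity,
    hydropathy_before = before$hydropathy,
    hydropathy_after = after$hydropathy,
    charge_changed = before$charge != after$charge,
    polarity_changed = before$polarity != after$polarity,
    hydropathy_changed = before$hydropathy != after$hydropathy
  )
}

#' Plot a domain map
#'
#' Draws the residue intervals of a domain map as stacked segments, one
#' track per domain class, optionally marking residue positions of
#' interest (e.g. mutated sites).
#'
#' @param map Domain map tibble (default [apoa5_domains()]).
#' @param highlight Optional integer vector of residue positions to mark.
#' @return A ggplot object.
#' @export
plot_domain_map <- function(map = apoa5_domains(), highlight = NULL) {
  validate_domain_map(map)
  map$class <- factor(map$class, levels = DOMAIN_CLASSES)
  p <- ggplot2::ggplot(map) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$class, yend = .data$class,
                   colour = .data$class),
      linewidth = 4, lineend = "butt", show.legend = FALSE
    ) +
    ggplot2::labs(x = "residue (full-length numbering)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_vline(xintercept = highlight, linetype = "dotted")
  }
  p
}
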