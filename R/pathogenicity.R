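DAMAGING_CATEGORIES <- list(
  sift = "D",
  polyphen_hdiv = c("D", "P"),
  lrt = "D",
  mutation_taster = c("D", "A"),
  mutation_assessor = c("H", "M")
)

CADD_DELETERIOUS_GT <- 15

#' Is a single predictor output damaging?
#'
#' Encodes the per-program damaging conventions of the six predictors:
#' SIFT `D`; PolyPhen2-HDIV `D` or `P`; LRT `D`; MutationTaster `D` (or
#' the automatic `A`); MutationAssessor `H` or `M`; CADD strictly
#' greater than 15. A missing value is never damaging.
#'
#' @param program One of `"sift"`, `"polyphen_hdiv"`, `"lrt"`,
#'   `"mutation_taster"`, `"mutation_assessor"`, `"cadd"`.
#' @param value Category character (or numeric score for CADD); may be
#'   `NA`.
#' @return Logical vector.
#' @examples
#' predictor_damaging("mutation_assessor", "M")
#' predictor_damaging("cadd", 3.66)
#' @export
predictor_damaging <- function(program, value) {
  program <- match.arg(program, c(names(DAMAGING_CATEGORIES), "cadd"))
  if (program == "cadd") {
    value <- as.numeric(value)
    if (any(!is.na(value) & value < 0)) {
      stop("CADD scores must be non-negative", call. = FALSE)
    }
    return(!is.na(value) & value > CADD_DELETERIOUS_GT)
  }
  levels <- PREDICTOR_LEVELS[[program]]
  bad <- !is.na(value) & !value %in% levels
  if (any(bad)) {
    stop("'", value[bad][1], "' is not a valid ", program, " category",
         call. = FALSE)
  }
  !is.na(value) & value %in% DAMAGING_CATEGORIES[[program]]
}

AUTO_PATHOGENIC_KINDS <- c("frameshift", "stopgain", "stoploss")

#' Classify variants as pathogenic or benign by the SIFT-anchored consensus
#'
#' Applies the consensus rule: a variant is called pathogenic when at
#' least two of the six in-silico programs judge it damaging and one of
#' the damaging votes is SIFT's; frameshift, stopgain and stoploss
#' variants are pathogenic outright regardless of predictor output
#' (their `auto_rule` records why). Missing predictor values never count
#' as damaging. Allele frequencies, conservation scores and database
#' status do not enter the verdict.
#'
#' @param variants A variant tibble as returned by
#'   [read_variant_table()] / [apoa5_variants()]: one row per variant
#'   with a resolved consequence `kind` and the six predictor columns.
#' @return The input tibble, with class `pathogenicity_calls`, gaining
#'   per-program logical columns (`sift_damaging`, ...,
#'   `cadd_damaging`), `damaging_votes` (0-6), `auto_rule` (`"none"`,
#'   `"frameshift"`, `"stopgain"`, `"stoploss"`), `verdict`
#'   (`"pathogenic"`/`"benign"`) and a human-readable `rationale`.
#' @examples
#' classify_variants(apoa5_variants())
#' @export
classify_variants <- function(variants) {
  required <- c("variant_id", "kind", names(DAMAGING_CATEGORIES), "cadd")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variants table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate annotations for variant ",
         variants$variant_id[duplicated(variants$variant_id)][1],
         call. = FALSE)
  }
  out <- variants |>
    dplyr::mutate(
      sift_damaging = predictor_damaging("sift", .data$sift),
      polyphen_hdiv_damaging =
        predictor_damaging("polyphen_hdiv", .data$polyphen_hdiv),
      lrt_damaging = predictor_damaging("lrt", .data$lrt),
      mutation_taster_damaging =
        predictor_damaging("mutation_taster", .data$mutation_taster),
      mutation_assessor_damaging =
        predictor_damaging("mutation_assessor", .data$mutation_assessor),
      cadd_damaging = predictor_damaging("cadd", .data$cadd),
      damaging_votes = .data$sift_damaging + .data$polyphen_hdiv_damaging +
        .data$lrt_damaging + .data$mutation_taster_damaging +
        .data$mutation_assessor_damaging + .data$cadd_damaging,
      auto_rule = dplyr::if_else(.data$kind %in% AUTO_PATHOGENIC_KINDS,
                                 .data$kind, "none"),
      verdict = dplyr::if_else(
        .data$auto_rule != "none" |
          (.data$sift_damaging & .data$damaging_votes >= 2L),
        "pathogenic", "benign"
      )
    )
  out$rationale <- purrr::pmap_chr(
    out[c("auto_rule", "verdict", "damaging_votes", "sift_damaging", "cadd")],
    call_rationale
  )
  class(out) <- c("pathogenicity_calls", class(tibble::tibble()))
  out
}

call_rationale <- function(auto_rule, verdict, damaging_votes,
                           sift_damaging, cadd) {
  if (auto_rule != "none") {
    return(paste0("pathogenic by protein-truncating rule (", auto_rule, ")"))
  }
  base <- paste0(damaging_votes, "/6 programs damaging, SIFT ",
                 if (sift_damaging) "damaging" else "tolerated/missing",
                 "; verdict ", verdict)
  if (!is.na(cadd) && cadd >= 20) {
    base <- paste0(base, "; CADD ", cadd,
                   " places it in the top 1% most deleterious")
  }
  base
}

#' @export
print.pathogenicity_calls <- function(x, ...) {
  cat("Pathogenicity calls (SIFT-anchored consensus, 6 programs):",
      sum(x$verdict == "pathogenic"), "pathogenic /",
      sum(x$verdict == "benign"), "benign\n")
  NextMethod()
}

#' Tidy pathogenicity calls
#'
#' @param x A `pathogenicity_calls` object.
#' @param ... Unused.
#' @return A tibble with one row per variant: identifiers, consequence
#'   kind, per-program damaging flags, vote count, auto rule, verdict
#'   and rationale.
#' @export
tidy.pathogenicity_calls <- function(x, ...) {
  tibble::as_tibble(x)[, c(
    "variant_id", "gene", "cdna", "protein", "kind",
    "sift_damaging", "polyphen_hdiv_damaging", "lrt_damaging",
    "mutation_taster_damaging", "mutation_assessor_damaging",
    "cadd_damaging", "damaging_votes", "auto_rule", "verdict", "rationale"
  )]
}

#' Summarize pathogenicity calls
#'
#' @param x A `pathogenicity_calls` object.
#' @param ... Unused.
#' @return One-row tibble: numbers of variants, pathogenic and benign
#'   calls, auto-rule calls, and the median vote count among pathogenic
#'   missense calls.
#' @export
glance.pathogenicity_calls <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x),
    n_pathogenic = sum(x$verdict == "pathogenic"),
    n_benign = sum(x$verdict == "benign"),
    n_auto_rule = sum(x$auto_rule != "none"),
    median_votes_pathogenic_missense = stats::median(
      x$damaging_votes[x$verdict == "pathogenic" & x$auto_rule == "none"]
    )
  )
}

#' Plot pathogenicity calls as a vote chart
#'
#' Bar chart of damaging votes per variant, filled by verdict, with
#' auto-rule (protein-truncating) calls marked.
#'
#' @param object A `pathogenicity_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathogenicity_calls <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- paste0(df$protein, ifelse(df$auto_rule != "none", " (auto)", ""))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, .data$damaging_votes),
    y = .data$damaging_votes, fill = .data$verdict
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "damaging votes (of 6 programs)",
                  fill = "verdict") +
    ggplot2::theme_minimal()
}

#' Write per-variant classification reports as JSON
#'
#' @param calls A `pathogenicity_calls` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls_json <- function(calls, path) {
  jsonlite::write_json(tidy(calls), path, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
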