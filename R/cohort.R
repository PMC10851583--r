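#' Round half away from zero
#'
#' Percentage rendering used in clinical burden tables (32 = 52/163,
#' not banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator
#'
#' @param n,total Numerator and denominator counts.
#' @param digits Decimal places (0 for the integer style of burden
#'   tables, 1 for the severity style).
#' @return Numeric percentage, rounded half away from zero.
#' @export
pct <- function(n, total, digits = 0) {
  round_half_up(100 * n / total, digits)
}

check_genotypes <- function(genotypes, variants) {
  stopifnot(all(c("patient_id", "gene", "variant_id", "zygosity") %in%
                  names(genotypes)))
  unknown <- setdiff(genotypes$variant_id, variants$variant_id)
  if (length(unknown)) {
    stop("genotype references unclassified variant ", unknown[1],
         call. = FALSE)
  }
  bad_z <- setdiff(genotypes$zygosity, c("het", "hom"))
  if (length(bad_z)) {
    stop("zygosity must be het/hom, got '", bad_z[1], "'", call. = FALSE)
  }
  invisible(genotypes)
}

pathogenic_ids <- function(calls) {
  calls$variant_id[calls$verdict == "pathogenic"]
}

#' Per-gene carrier burden by arm
#'
#' For each gene, counts distinct patients carrying any variant and
#' distinct patients carrying at least one pathogenic variant, per arm,
#' with integer-rounded percentages of the arm size. A patient with
#' several mutations in one gene counts once.
#'
#' @param patients Patient tibble with `patient_id` and `arm`
#'   (`"HLAP"`/`"BAP"`).
#' @param genotypes Long genotype tibble (`patient_id`, `gene`,
#'   `variant_id`, `zygosity`).
#' @param calls Classified variants ([classify_variants()]); every
#'   genotyped variant must appear.
#' @return A `gene_burden` tibble: `gene`, `n_any_hlap`, `pct_any_hlap`,
#'   `n_any_bap`, `pct_any_bap`, `n_path_hlap`, `pct_path_hlap`,
#'   `n_path_bap`, `pct_path_bap`, sorted by descending HLAP pathogenic
#'   burden.
#' @export
gene_burden_table <- function(patients, genotypes, calls) {
  check_genotypes(genotypes, calls)
  n_hlap <- sum(patients$arm == "HLAP")
  n_bap <- sum(patients$arm == "BAP")
  path_ids <- pathogenic_ids(calls)

  g <- genotypes |>
    dplyr::left_join(patients[c("patient_id", "arm")], by = "patient_id") |>
    dplyr::mutate(pathogenic = .data$variant_id %in% path_ids)
  if (any(is.na(g$arm))) {
    stop("genotype references unknown patient ",
         g$patient_id[is.na(g$arm)][1], call. = FALSE)
  }

  count_arm <- function(df, arm) {
    df |>
      dplyr::filter(.data$arm == {{ arm }}) |>
      dplyr::distinct(.data$gene, .data$patient_id) |>
      dplyr::count(.data$gene)
  }
  # the gene universe comes from the classified variants, so genes with
  # no carrier still get an all-zero row
  genes <- tibble::tibble(gene = sort(unique(c(calls$gene, genotypes$gene))))
  tab <- genes |>
    dplyr::left_join(count_arm(g, "HLAP") |>
                       dplyr::rename(n_any_hlap = "n"), by = "gene") |>
    dplyr::left_join(count_arm(g, "BAP") |>
                       dplyr::rename(n_any_bap = "n"), by = "gene") |>
    dplyr::left_join(count_arm(dplyr::filter(g, .data$pathogenic), "HLAP") |>
                       dplyr::rename(n_path_hlap = "n"), by = "gene") |>
    dplyr::left_join(count_arm(dplyr::filter(g, .data$pathogenic), "BAP") |>
                       dplyr::rename(n_path_bap = "n"), by = "gene") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                \(x) dplyr::coalesce(x, 0L))) |>
    dplyr::mutate(
      pct_any_hlap = pct(.data$n_any_hlap, n_hlap),
      pct_any_bap = pct(.data$n_any_bap, n_bap),
      pct_path_hlap = pct(.data$n_path_hlap, n_hlap),
      pct_path_bap = pct(.data$n_path_bap, n_bap)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_path_hlap), .data$gene) |>
    dplyr::select("gene", "n_any_hlap", "pct_any_hlap", "n_any_bap",
                  "pct_any_bap", "n_path_hlap", "pct_path_hlap",
                  "n_path_bap", "pct_path_bap")
  class(tab) <- c("gene_burden", class(tab))
  tab
}

#' Partition HLAP patients by pathogenic-mutation burden
#'
#' Group I: carriers of at least one pathogenic APOA5 mutation (takes
#' precedence). Group II: no pathogenic APOA5 mutation but at least one
#' pathogenic mutation in the designated gene set. Group III: the
#' remaining patients. The partition is exhaustive and disjoint.
#'
#' @param patients HLAP patients only (`arm == "HLAP"` throughout;
#'   passing a BAP patient is an error).
#' @param genotypes,calls As in [gene_burden_table()].
#' @param group2_genes Character vector of the group-II gene symbols
#'   (default: the 25 group-II genes of the packaged configuration).
#' @return Tibble `patient_id`, `group` (factor `I`/`II`/`III`).
#' @export
assign_groups <- function(patients, genotypes, calls,
                          group2_genes = default_group2_genes()) {
  if (any(patients$arm != "HLAP")) {
    stop("assign_groups() expects HLAP patients only; found arm '",
         patients$arm[patients$arm != "HLAP"][1], "'", call. = FALSE)
  }
  check_genotypes(genotypes, calls)
  path_ids <- pathogenic_ids(calls)
  g <- genotypes[genotypes$variant_id %in% path_ids &
                   genotypes$patient_id %in% patients$patient_id, ]
  apoa5_carriers <- unique(g$patient_id[g$gene == "APOA5"])
  group2_carriers <- unique(g$patient_id[g$gene %in% group2_genes])
  tibble::tibble(
    patient_id = patients$patient_id,
    group = factor(
      dplyr::case_when(
        patients$patient_id %in% apoa5_carriers ~ "I",
        patients$patient_id %in% group2_carriers ~ "II",
        TRUE ~ "III"
      ),
      levels = c("I", "II", "III")
    )
  )
}

#' @rdname assign_groups
#' @export
default_group2_genes <- function() {
  gc <- default_gene_counts()
  gc$gene[gc$group2]
}

#' Patient-by-gene pathogenic mutation count matrix
#'
#' Each cell counts the distinct pathogenic mutations of a gene carried
#' by a patient (the quantity shown in per-patient mutation heat maps).
#'
#' @inheritParams gene_burden_table
#' @return A wide `carrier_matrix` tibble: `patient_id`, `arm`, one
#'   integer column per gene. Non-carriers have all-zero rows.
#' @export
carrier_matrix <- function(patients, genotypes, calls) {
  check_genotypes(genotypes, calls)
  path_ids <- pathogenic_ids(calls)
  g <- genotypes[genotypes$variant_id %in% path_ids, ]
  genes <- sort(unique(c(genotypes$gene, calls$gene)))
  counts <- g |>
    dplyr::distinct(.data$patient_id, .data$gene, .data$variant_id) |>
    dplyr::count(.data$patient_id, .data$gene) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "n",
                       values_fill = 0L)
  out <- patients[c("patient_id", "arm")] |>
    dplyr::left_join(counts, by = "patient_id")
  for (gn in genes) {
    if (!gn %in% names(out)) out[[gn]] <- 0L
    out[[gn]] <- dplyr::coalesce(out[[gn]], 0L)
  }
  out <- out[c("patient_id", "arm", genes)]
  class(out) <- c("carrier_matrix", class(out))
  out
}

#' Heat map of a carrier matrix
#'
#' @param object A [carrier_matrix()] result.
#' @param drop_empty Drop genes with no pathogenic carrier.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carrier_matrix <- function(object, drop_empty = TRUE, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-c("patient_id", "arm"), names_to = "gene",
                        values_to = "n_mutations")
  if (drop_empty) {
    keep <- long |>
      dplyr::summarise(tot = sum(.data$n_mutations), .by = "gene") |>
      dplyr::filter(.data$tot > 0L)
    long <- long[long$gene %in% keep$gene, ]
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$patient_id, y = .data$gene,
                                     fill = .data$n_mutations)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(. ~ arm, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient(low = "grey95", high = "indianred4") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mutations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
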