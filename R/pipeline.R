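#' Run the full simulate - classify - aggregate pipeline
#'
#' Generates (or accepts) a cohort, classifies every variant with the
#' SIFT-anchored consensus rule, and writes the report bundle under
#' `out_dir`: `calls.json` (per-variant verdicts), `burden.tsv`
#' (per-gene carrier counts by arm), `groups.tsv` (HLAP pathogenic-
#' burden partition), `matrix.tsv` (patient x gene pathogenic-mutation
#' counts), `cohort.tsv`/`genotypes.tsv`/`variants.tsv` (the inputs) and
#' `summary.json` (headline numbers, seed and config hash). Progress is
#' logged to stderr; data go to files only.
#'
#' @param config A [cohort_config()] (or path handled by
#'   [read_cohort_config()] upstream).
#' @param seed Integer seed controlling every random draw.
#' @param out_dir Output directory, created if missing.
#' @param cohort Optional pre-built `synthetic_cohort`; when supplied,
#'   `config`/`seed` are taken from it.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `calls`, `burden`, `groups`, `matrix`, `summary`).
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1L,
                         out_dir = "varprio-run", cohort = NULL) {
  log_msg <- function(...) message("[varprio] ", ...)
  if (is.null(cohort)) {
    log_msg("simulating cohort (seed ", seed, ")")
    cohort <- generate_cohort(config, seed = seed)
  } else {
    config <- cohort$config
    seed <- cohort$seed
  }
  log_msg("classifying ", nrow(cohort$variants), " variants")
  calls <- classify_variants(cohort$variants)

  log_msg("aggregating burden, groups and carrier matrix")
  burden <- gene_burden_table(cohort$patients, cohort$genotypes, calls)
  hlap <- cohort$patients[cohort$patients$arm == "HLAP", ]
  groups <- assign_groups(hlap, cohort$genotypes, calls)
  cmat <- carrier_matrix(cohort$patients, cohort$genotypes, calls)

  apoa5 <- burden[burden$gene == "APOA5", ]
  summary <- list(
    seed = seed,
    config_hash = rlang::hash(config),
    n_hlap = nrow(hlap),
    n_bap = sum(cohort$patients$arm == "BAP"),
    n_variants = nrow(calls),
    n_pathogenic_variants = sum(calls$verdict == "pathogenic"),
    apoa5_pathogenic_carriers_hlap = apoa5$n_path_hlap,
    apoa5_pathogenic_pct_hlap = apoa5$pct_path_hlap,
    apoa5_pathogenic_carriers_bap = apoa5$n_path_bap,
    apoa5_pathogenic_pct_bap = apoa5$pct_path_bap,
    group_sizes = as.list(table(groups$group))
  )

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_cohort(cohort, out_dir)
  write_calls_json(calls, file.path(out_dir, "calls.json"))
  readr::write_tsv(burden, file.path(out_dir, "burden.tsv"))
  readr::write_tsv(groups, file.path(out_dir, "groups.tsv"))
  readr::write_tsv(cmat, file.path(out_dir, "matrix.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("report bundle written to ", out_dir)

  invisible(list(cohort = cohort, calls = calls, burden = burden,
                 groups = groups, matrix = cmat, summary = summary))
}
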