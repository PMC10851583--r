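#' Configuration for the synthetic two-arm cohort generator
#'
#' Defaults reproduce the published study conditions: 163
#' hyperlipidemic-pancreatitis (HLAP) and 30 biliary-pancreatitis (BAP)
#' patients; clinical covariate moments and comorbidity/severity counts
#' per arm; per-variant APOA5 carrier counts by zygosity; per-gene
#' carrier totals for all 53 candidate genes; and the three pinned
#' carriers (A10, A15, A46) that resolve the overlap between
#' carrier-events and distinct carriers. Counts are assigned exactly
#' (sampling decides only who, never how many); continuous covariates
#' are the only stochastic quantities.
#'
#' @param n_hlap,n_bap Arm sizes.
#' @param moments Clinical moments/counts table (columns `variable`,
#'   `type` in `truncnorm`/`lognormal`/`flag`, per-arm mean/sd or
#'   counts).
#' @param gene_counts Per-gene carrier totals (columns `gene`, `group2`,
#'   `n_any_hlap`, `n_any_bap`, `n_path_hlap`, `n_path_bap`).
#' @param variants APOA5 per-variant annotation + carrier-count table
#'   (see [apoa5_variants()]).
#' @param n_group2 Number of HLAP patients whose only pathogenic burden
#'   lies in the 25 group-II genes.
#' @param pinned_carriers Tibble `(patient_id, variant_id, zygosity)` of
#'   deterministically placed genotypes.
#' @param tg_carrier_shift Additive TG shift (mmol/L) for carriers of a
#'   pathogenic APOA5 variant; off (0) by default.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_hlap = 163L, n_bap = 30L,
                          moments = default_clinical_moments(),
                          gene_counts = default_gene_counts(),
                          variants = apoa5_variants(),
                          n_group2 = 50L,
                          pinned_carriers = default_pinned_carriers(),
                          tg_carrier_shift = 0) {
  cfg <- structure(
    list(n_hlap = as.integer(n_hlap), n_bap = as.integer(n_bap),
         moments = moments, gene_counts = gene_counts, variants = variants,
         n_group2 = as.integer(n_group2),
         pinned_carriers = pinned_carriers,
         tg_carrier_shift = tg_carrier_shift),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

default_clinical_moments <- function() {
  readr::read_tsv(
    system.file("extdata", "clinical_moments.tsv", package = "varprio",
                mustWork = TRUE),
    na = "na", show_col_types = FALSE, progress = FALSE
  )
}

default_gene_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "gene_carrier_counts.tsv", package = "varprio",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}

default_pinned_carriers <- function() {
  tibble::tibble(
    patient_id = c("A10", "A10", "A46", "A46", "A15"),
    variant_id = c("APOA5:c.104G>A", "APOA5:c.553G>T",
                   "APOA5:c.667C>T", "APOA5:c.553G>T",
                   "APOA5:c.500A>T"),
    zygosity = "het"
  )
}

validate_cohort_config <- function(cfg) {
  flags <- cfg$moments[cfg$moments$type == "flag", ]
  if (any(flags$hlap_n > cfg$n_hlap, na.rm = TRUE) ||
      any(flags$bap_n > cfg$n_bap, na.rm = TRUE)) {
    stop("infeasible config: a flag count exceeds its arm size",
         call. = FALSE)
  }
  gc <- cfg$gene_counts
  if (any(gc$n_any_hlap > cfg$n_hlap) || any(gc$n_any_bap > cfg$n_bap) ||
      any(gc$n_path_hlap > cfg$n_hlap) || any(gc$n_path_bap > cfg$n_bap)) {
    stop("infeasible config: a gene carrier count exceeds its arm size",
         call. = FALSE)
  }
  if (any(gc$n_path_hlap > gc$n_any_hlap) ||
      any(gc$n_path_bap > gc$n_any_bap)) {
    stop("infeasible config: pathogenic carriers exceed all-variant carriers",
         call. = FALSE)
  }
  v <- cfg$variants
  if (sum(v$n_het_hlap + v$n_hom_hlap) +
      gc$n_path_hlap[gc$gene == "APOA5"] > 2L * cfg$n_hlap) {
    stop("infeasible config: APOA5 carrier events exceed arm capacity",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n",
      " arms: ", x$n_hlap, " HLAP / ", x$n_bap, " BAP\n",
      " genes: ", nrow(x$gene_counts), " (",
      sum(x$gene_counts$group2), " group-II genes)\n",
      " APOA5 variants: ", nrow(x$variants), "\n",
      " TG carrier shift: ", x$tg_carrier_shift, " mmol/L\n", sep = "")
  invisible(x)
}

#' Read a cohort-generator configuration from a YAML file
#'
#' Flat keys override the defaults of [cohort_config()]: `n_hlap`,
#' `n_bap`, `n_group2`, `tg_carrier_shift`, and optional file paths
#' `moments`, `gene_counts`, `variants` pointing at TSVs in the packaged
#' formats.
#'
#' @param path YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_hlap", "n_bap", "n_group2", "tg_carrier_shift")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$moments)) {
    args$moments <- readr::read_tsv(y$moments, na = "na",
                                    show_col_types = FALSE, progress = FALSE)
  }
  if (!is.null(y$gene_counts)) {
    args$gene_counts <- readr::read_tsv(y$gene_counts,
                                        show_col_types = FALSE,
                                        progress = FALSE)
  }
  if (!is.null(y$variants)) args$variants <- read_variant_table(y$variants)
  do.call(cohort_config, args)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic two-arm clinical cohort with genotypes
#'
#' Draws a cohort satisfying the configured structure exactly: arm
#' sizes, per-variant APOA5 carrier counts by zygosity, per-gene
#' distinct-carrier totals (both all-variant and pathogenic), flag
#' counts, and the pinned double carriers. Continuous covariates are
#' sampled per arm: right-skewed laboratory values (TG, TC, CRP) from a
#' moment-matched log-normal, the remainder from a normal truncated at
#' zero. Runs are reproducible given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A `synthetic_cohort` list: `patients` (one row per patient),
#'   `genotypes` (long: `patient_id`, `gene`, `variant_id`, `zygosity`),
#'   `variants` (annotation table covering every `variant_id`), and the
#'   `config`/`seed` used.
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' cohort$patients
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  with_local_seed(seed, {
    hlap_ids <- paste0("A", seq_len(config$n_hlap))
    bap_ids <- paste0("B", seq_len(config$n_bap))

    geno <- list()
    apoa5 <- classify_variants(config$variants)

    res_h <- assign_arm_apoa5(config, apoa5, hlap_ids, arm = "hlap")
    res_b <- assign_arm_apoa5(config, apoa5, bap_ids, arm = "bap")
    geno <- c(geno, res_h$geno, res_b$geno)

    other <- assign_other_genes(config, hlap_ids, bap_ids,
                                apoa5_path_carriers = res_h$path_carriers)
    geno <- c(geno, other$geno)

    genotypes <- dplyr::bind_rows(geno)
    genotypes$gene <- sub(":.*$", "", genotypes$variant_id)
    genotypes <- genotypes[, c("patient_id", "gene", "variant_id", "zygosity")]

    patients <- dplyr::bind_rows(
      draw_patients(config, hlap_ids, arm = "HLAP"),
      draw_patients(config, bap_ids, arm = "BAP")
    )
    if (config$tg_carrier_shift != 0) {
      carriers <- c(res_h$path_carriers, res_b$path_carriers)
      idx <- patients$patient_id %in% carriers
      patients$tg[idx] <- patients$tg[idx] + config$tg_carrier_shift
    }

    variants <- dplyr::bind_rows(config$variants, other$variants)

    structure(
      list(patients = patients, genotypes = genotypes, variants = variants,
           config = config, seed = seed),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", sum(x$patients$arm == "HLAP"), "HLAP /",
      sum(x$patients$arm == "BAP"), "BAP patients;",
      nrow(x$genotypes), "genotype records over",
      nrow(x$variants), "variants (seed", x$seed, ")\n")
  invisible(x)
}

# Assign APOA5 genotypes for one arm so that per-variant counts by
# zygosity and the arm's distinct any/pathogenic carrier totals all hold
# exactly. Pathogenic carriers beyond the pins are drawn from patients
# not yet carrying any pathogenic APOA5 variant; benign carriers fill a
# designated any-carrier set, uncovered patients first.
assign_arm_apoa5 <- function(config, calls, ids, arm) {
  v <- tibble::as_tibble(calls)
  n_het <- v[[paste0("n_het_", arm)]]
  n_hom <- v[[paste0("n_hom_", arm)]]
  gcrow <- config$gene_counts[config$gene_counts$gene == "APOA5", ]
  n_any <- gcrow[[paste0("n_any_", arm)]]
  n_path <- gcrow[[paste0("n_path_", arm)]]

  pins <- config$pinned_carriers[config$pinned_carriers$patient_id %in% ids, ]
  geno <- list()
  carrier_of <- list()  # variant_id -> patient ids
  path_carriers <- character()

  path_idx <- which(v$verdict == "pathogenic")
  for (i in path_idx) {
    vid <- v$variant_id[i]
    if (n_het[i] + n_hom[i] == 0L) next
    p_pin <- pins$patient_id[pins$variant_id == vid]
    need <- n_het[i] + n_hom[i] - length(p_pin)
    if (need < 0L) stop("more pinned carriers than configured for ", vid,
                        call. = FALSE)
    pool <- setdiff(ids, c(path_carriers, p_pin))
    if (need > length(pool)) {
      stop("infeasible config: cannot place ", need, " carriers of ", vid,
           call. = FALSE)
    }
    drawn <- if (need > 0L) sample(pool, need) else character()
    all_c <- c(p_pin, drawn)
    homs <- if (n_hom[i] > 0L) sample(drawn, n_hom[i]) else character()
    geno[[vid]] <- tibble::tibble(
      patient_id = all_c, variant_id = vid,
      zygosity = ifelse(all_c %in% homs, "hom", "het")
    )
    carrier_of[[vid]] <- all_c
    path_carriers <- union(path_carriers, all_c)
  }
  if (length(path_carriers) != n_path) {
    stop("APOA5 pathogenic carrier structure inconsistent: got ",
         length(path_carriers), " distinct carriers, configured ", n_path,
         call. = FALSE)
  }

  extra_any <- n_any - n_path
  others <- setdiff(ids, path_carriers)
  if (extra_any > length(others)) {
    stop("infeasible config: any-variant carriers exceed arm size",
         call. = FALSE)
  }
  any_set <- c(path_carriers,
               if (extra_any > 0L) sample(others, extra_any) else character())
  covered <- path_carriers

  benign_idx <- which(v$verdict == "benign")
  benign_idx <- benign_idx[order(-(n_het[benign_idx] + n_hom[benign_idx]))]
  for (i in benign_idx) {
    vid <- v$variant_id[i]
    k <- n_het[i] + n_hom[i]
    if (k == 0L) next
    uncovered <- setdiff(any_set, covered)
    take_new <- utils::head(sample_keep(uncovered), min(k, length(uncovered)))
    rest_pool <- setdiff(setdiff(any_set, take_new), carrier_of[[vid]])
    take_old <- if (k - length(take_new) > 0L) {
      sample(rest_pool, k - length(take_new))
    } else {
      character()
    }
    all_c <- c(take_new, take_old)
    if (length(all_c) != k) {
      stop("infeasible config: cannot place benign carriers of ", vid,
           call. = FALSE)
    }
    homs <- if (n_hom[i] > 0L) sample(all_c, n_hom[i]) else character()
    geno[[vid]] <- tibble::tibble(
      patient_id = all_c, variant_id = vid,
      zygosity = ifelse(all_c %in% homs, "hom", "het")
    )
    carrier_of[[vid]] <- all_c
    covered <- union(covered, all_c)
  }
  if (!setequal(covered, any_set)) {
    stop("APOA5 any-carrier structure inconsistent: ", length(covered),
         " covered vs ", length(any_set), " designated", call. = FALSE)
  }
  list(geno = geno, path_carriers = path_carriers, any_carriers = any_set)
}

# sample() with length-1 protection
sample_keep <- function(x) if (length(x) <= 1L) x else sample(x)

# Generic one-pathogenic/one-benign variant per non-APOA5 gene; group-II
# gene events are confined to APOA5 carriers plus a designated group-II
# patient set whose every member receives at least one event.
assign_other_genes <- function(config, hlap_ids, bap_ids,
                               apoa5_path_carriers) {
  gc <- config$gene_counts[config$gene_counts$gene != "APOA5", ]
  geno <- list()

  g2_genes <- gc$gene[gc$group2]
  g2_events <- rep(g2_genes, times = gc$n_path_hlap[gc$group2])
  if (config$n_group2 > length(g2_events)) {
    stop("infeasible config: fewer group-II carrier events (",
         length(g2_events), ") than group-II patients (", config$n_group2,
         ")", call. = FALSE)
  }
  non_g1 <- setdiff(hlap_ids, apoa5_path_carriers)
  if (config$n_group2 > length(non_g1)) {
    stop("infeasible config: group-II size exceeds available patients",
         call. = FALSE)
  }
  g2_set <- sample(non_g1, config$n_group2)
  eligible <- c(apoa5_path_carriers, g2_set)

  g2_events <- sample_keep(g2_events)
  assign_to <- stats::setNames(vector("list", length(g2_genes)), g2_genes)
  # coverage pass: one event to each group-II patient
  for (j in seq_len(config$n_group2)) {
    g <- g2_events[j]
    assign_to[[g]] <- c(assign_to[[g]], g2_set[j])
  }
  # remaining events anywhere in group I or II, no same-gene duplicates
  if (length(g2_events) > config$n_group2) {
    for (g in g2_events[-seq_len(config$n_group2)]) {
      pool <- setdiff(eligible, assign_to[[g]])
      if (!length(pool)) {
        stop("infeasible config: cannot place pathogenic carrier of ", g,
             call. = FALSE)
      }
      assign_to[[g]] <- c(assign_to[[g]], sample(pool, 1L))
    }
  }

  for (i in seq_len(nrow(gc))) {
    g <- gc$gene[i]
    path_h <- if (gc$group2[i]) {
      assign_to[[g]] %||% character()
    } else if (gc$n_path_hlap[i] > 0L) {
      sample(hlap_ids, gc$n_path_hlap[i])
    } else {
      character()
    }
    path_b <- if (gc$n_path_bap[i] > 0L) {
      sample(bap_ids, gc$n_path_bap[i])
    } else {
      character()
    }
    ben_h <- sample(setdiff(hlap_ids, path_h),
                    gc$n_any_hlap[i] - gc$n_path_hlap[i])
    ben_b <- sample(setdiff(bap_ids, path_b),
                    gc$n_any_bap[i] - gc$n_path_bap[i])
    rows <- list()
    if (length(path_h) + length(path_b)) {
      rows$p <- tibble::tibble(patient_id = c(path_h, path_b),
                               variant_id = paste0(g, ":c.100G>A"),
                               zygosity = "het")
    }
    if (length(ben_h) + length(ben_b)) {
      rows$b <- tibble::tibble(patient_id = c(ben_h, ben_b),
                               variant_id = paste0(g, ":c.200T>C"),
                               zygosity = "het")
    }
    geno[[g]] <- dplyr::bind_rows(rows)
  }

  variants <- generic_gene_variants(gc)
  list(geno = geno, variants = variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Annotation rows for the generic per-gene variants: a clearly damaging
# profile for the pathogenic surrogate and a clearly tolerated one for
# the benign surrogate.
generic_gene_variants <- function(gc) {
  path <- tibble::tibble(
    variant_id = paste0(gc$gene, ":c.100G>A"), gene = gc$gene,
    exon = 1L, cdna = "c.100G>A", protein = "p.G34R", kind = "missense",
    rsid = NA_character_, status = "novel",
    sift = "D", polyphen_hdiv = "D", lrt = "D", mutation_taster = "D",
    mutation_assessor = "H", cadd = 25,
    af_all = NA_real_, af_eas = NA_real_, af_amr = NA_real_,
    phylo_hmm = NA_real_,
    n_het_hlap = gc$n_path_hlap, n_hom_hlap = 0L,
    n_het_bap = gc$n_path_bap, n_hom_bap = 0L
  )
  benign <- tibble::tibble(
    variant_id = paste0(gc$gene, ":c.200T>C"), gene = gc$gene,
    exon = 1L, cdna = "c.200T>C", protein = "p.L67M", kind = "missense",
    rsid = NA_character_, status = "novel",
    sift = "T", polyphen_hdiv = "B", lrt = "N", mutation_taster = "N",
    mutation_assessor = "N", cadd = 1,
    af_all = NA_real_, af_eas = NA_real_, af_amr = NA_real_,
    phylo_hmm = NA_real_,
    n_het_hlap = gc$n_any_hlap - gc$n_path_hlap, n_hom_hlap = 0L,
    n_het_bap = gc$n_any_bap - gc$n_path_bap, n_hom_bap = 0L
  )
  dplyr::bind_rows(path, benign)
}

draw_patients <- function(config, ids, arm) {
  n <- length(ids)
  key <- tolower(arm)
  mom <- config$moments
  out <- tibble::tibble(patient_id = ids, arm = arm)

  flag_n <- function(var) {
    r <- mom[mom$variable == var & mom$type == "flag", ]
    as.integer(r[[paste0(key, "_n")]])
  }
  pick <- function(k, from = ids) sample(from, min(k, length(from)))

  males <- pick(flag_n("male"))
  out$sex <- ifelse(ids %in% males, "male", "female")

  for (v in c("diabetes", "hypertension", "fatty_liver", "ards",
              "ctsi_gt4")) {
    out[[v]] <- ids %in% pick(flag_n(v))
  }
  rec <- pick(flag_n("recurrence"))
  out$recurrence <- ids %in% rec
  out$repeated_recurrence <- ids %in% pick(flag_n("repeated_recurrence"),
                                           from = rec)

  n_sap <- flag_n("sap")
  n_msap <- flag_n("msap_sap") - n_sap
  if (n_msap < 0L) {
    stop("infeasible config: sap count exceeds msap_sap count",
         call. = FALSE)
  }
  sap <- pick(n_sap)
  msap <- pick(n_msap, from = setdiff(ids, sap))
  out$severity <- factor(
    ifelse(ids %in% sap, "SAP", ifelse(ids %in% msap, "MSAP", "MAP")),
    levels = c("MAP", "MSAP", "SAP")
  )

  cont <- mom[mom$type %in% c("truncnorm", "lognormal"), ]
  for (i in seq_len(nrow(cont))) {
    m <- cont[[paste0(key, "_mean")]][i]
    s <- cont[[paste0(key, "_sd")]][i]
    out[[cont$variable[i]]] <-
      if (cont$type[i] == "lognormal") rlnorm_moments(n, m, s)
      else rtruncnorm0(n, m, s)
  }
  out
}

# Log-normal with given arithmetic mean and SD (moment matching).
rlnorm_moments <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Normal truncated at zero by rejection.
rtruncnorm0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Write / read the cohort and genotype tables
#'
#' `write_cohort()` serializes a `synthetic_cohort` (or equivalent
#' tibbles) as `cohort.tsv` (one row per patient), `genotypes.tsv`
#' (long format) and `variants.tsv` under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$patients, file.path(dir, "cohort.tsv"))
  readr::write_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(cohort$variants, file.path(dir, "variants.tsv"),
                   na = "na")
  invisible(dir)
}
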