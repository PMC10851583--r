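test_that("cohort generation is deterministic given a seed", {
  a <- generate_cohort(cohort_config(), seed = 11)
  b <- generate_cohort(cohort_config(), seed = 11)
  expect_equal(a$patients, b$patients)
  expect_equal(a$genotypes, b$genotypes)
  c2 <- generate_cohort(cohort_config(), seed = 12)
  expect_false(identical(a$patients$tg, c2$patients$tg))
})

test_that("configured counts are assigned exactly, not sampled", {
  co <- fixture_cohort
  p <- co$patients
  expect_equal(sum(p$arm == "HLAP"), 163L)
  expect_equal(sum(p$arm == "BAP"), 30L)

  hl <- p[p$arm == "HLAP", ]
  expect_equal(sum(hl$sex == "male"), 128L)
  expect_equal(sum(hl$diabetes), 87L)
  expect_equal(sum(hl$fatty_liver), 138L)
  expect_equal(sum(hl$severity == "SAP"), 10L)
  expect_equal(sum(hl$severity %in% c("MSAP", "SAP")), 83L)
  expect_equal(sum(hl$recurrence), 91L)
  expect_equal(sum(hl$repeated_recurrence), 61L)

  bp <- p[p$arm == "BAP", ]
  expect_equal(sum(bp$sex == "male"), 11L)
  expect_equal(sum(bp$severity %in% c("MSAP", "SAP")), 5L)

  # per-variant zygosity counts from the annotation table
  g <- co$genotypes
  g553 <- g[g$variant_id == "APOA5:c.553G>T", ]
  hl_ids <- hl$patient_id
  expect_equal(sum(g553$patient_id %in% hl_ids & g553$zygosity == "het"), 42L)
  expect_equal(sum(g553$patient_id %in% hl_ids & g553$zygosity == "hom"), 7L)
  expect_equal(sum(!g553$patient_id %in% hl_ids), 1L)
})

test_that("patient invariants hold on generated cohorts", {
  p <- fixture_cohort$patients
  labs <- c("age", "bmi", "wbc", "crp", "bun", "creatinine", "calcium",
            "glucose", "tg", "tc", "hospital_stay")
  for (v in labs) expect_true(all(p[[v]] >= 0), label = v)
  expect_true(all(p$recurrence[p$repeated_recurrence]))
  # pinned double carriers present with their named mutations
  g <- fixture_cohort$genotypes
  expect_setequal(g$variant_id[g$patient_id == "A10" & g$gene == "APOA5"],
                  c("APOA5:c.104G>A", "APOA5:c.553G>T"))
  expect_setequal(g$variant_id[g$patient_id == "A46" & g$gene == "APOA5"],
                  c("APOA5:c.667C>T", "APOA5:c.553G>T"))
  expect_equal(g$variant_id[g$patient_id == "A15" & g$gene == "APOA5"],
               "APOA5:c.500A>T")
})

test_that("infeasible configurations are rejected up front", {
  gc <- default_gene_counts()
  gc$n_path_hlap[gc$gene == "APOA5"] <- 200L
  expect_error(cohort_config(gene_counts = gc), "infeasible")

  mom <- varprio:::default_clinical_moments()
  mom$hlap_n[mom$variable == "diabetes"] <- 400
  expect_error(cohort_config(moments = mom), "infeasible")
})

test_that("synthetic CDS obeys constraints and determinism", {
  cds <- fixture_cds
  expect_equal(nchar(cds), 1101L)  # 366 codons + stop
  prot <- translate_cds(cds)
  expect_equal(substr(prot, 185, 185), "G")
  expect_equal(substr(prot, 35, 35), "S")
  expect_equal(substr(prot, 223, 223), "R")
  expect_equal(substr(prot, 1, 1), "M")

  expect_equal(apoa5_synthetic_cds(seed = 9), apoa5_synthetic_cds(seed = 9))

  pinned <- build_synthetic_cds(length = 10,
                                residue_constraints = c("4" = "W"), seed = 2)
  expect_equal(substr(translate_cds(pinned), 4, 4), "W")
  expect_true(startsWith(build_synthetic_cds(5, seed = 3), "ATG"))

  expect_error(build_synthetic_cds(10, residue_constraints = c("4" = "Z")),
               "impossible")
  expect_error(build_synthetic_cds(10, residue_constraints = c("1" = "W")),
               "Met")
  expect_error(build_synthetic_cds(5, residue_constraints = c("9" = "A")),
               "range")
})

test_that("TG generator moments match the configured mean/SD at scale", {
  big <- cohort_config(n_hlap = 10000L, n_bap = 30L)
  co <- generate_cohort(big, seed = 21)
  tg <- co$patients$tg[co$patients$arm == "HLAP"]
  expect_equal(mean(tg), 18.00, tolerance = 0.02)
  expect_equal(sd(tg), 19.30, tolerance = 0.05)
})

test_that("cohort tables serialize to TSV", {
  dir <- withr::local_tempdir()
  write_cohort(fixture_cohort, dir)
  expect_true(all(file.exists(file.path(
    dir, c("cohort.tsv", "genotypes.tsv", "variants.tsv")
  ))))
  back <- readr::read_tsv(file.path(dir, "cohort.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), 193L)
})
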