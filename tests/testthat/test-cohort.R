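burden <- gene_burden_table(fixture_cohort$patients, fixture_cohort$genotypes,
                            fixture_cohort_calls)
hlap <- fixture_cohort$patients[fixture_cohort$patients$arm == "HLAP", ]
groups <- assign_groups(hlap, fixture_cohort$genotypes, fixture_cohort_calls)
cmat <- carrier_matrix(fixture_cohort$patients, fixture_cohort$genotypes,
                       fixture_cohort_calls)

test_that("the burden table reproduces the configured per-gene carrier structure", {
  apoa5 <- burden[burden$gene == "APOA5", ]
  expect_equal(apoa5$n_path_hlap, 52L)
  expect_equal(apoa5$pct_path_hlap, 32)
  expect_equal(apoa5$n_path_bap, 1L)
  expect_equal(apoa5$pct_path_bap, 3)
  expect_equal(apoa5$n_any_hlap, 97L)
  expect_equal(apoa5$pct_any_hlap, 60)
  expect_equal(apoa5$n_any_bap, 13L)

  # whole configured table recovered, gene by gene
  gc <- varprio:::default_gene_counts()
  joined <- dplyr::left_join(gc, burden, by = "gene")
  expect_equal(joined$n_any_hlap.y, joined$n_any_hlap.x)
  expect_equal(joined$n_any_bap.y, joined$n_any_bap.x)
  expect_equal(joined$n_path_hlap.y, joined$n_path_hlap.x)
  expect_equal(joined$n_path_bap.y, joined$n_path_bap.x)

  # percentages recompute from their own numerators and denominators
  expect_equal(burden$pct_path_hlap, pct(burden$n_path_hlap, 163))
  expect_true(all(burden$n_path_hlap <= burden$n_any_hlap))
})

test_that("multi-mutation carriers count once per gene", {
  # A10 carries two APOA5 pathogenic mutations yet the count is 52 distinct
  g <- fixture_cohort$genotypes
  path_ids <- fixture_cohort_calls$variant_id[
    fixture_cohort_calls$verdict == "pathogenic"
  ]
  a10 <- g[g$patient_id == "A10" & g$gene == "APOA5" &
             g$variant_id %in% path_ids, ]
  expect_equal(nrow(a10), 2L)
  expect_equal(burden$n_path_hlap[burden$gene == "APOA5"], 52L)
})

test_that("genotypes referencing unknown variants or patients error", {
  bad <- fixture_cohort$genotypes[1, ]
  bad$variant_id <- "NOPE:c.1A>T"
  expect_error(
    gene_burden_table(fixture_cohort$patients, bad, fixture_cohort_calls),
    "unclassified variant"
  )
  bad2 <- fixture_cohort$genotypes[1, ]
  bad2$patient_id <- "Z999"
  expect_error(
    gene_burden_table(fixture_cohort$patients, bad2, fixture_cohort_calls),
    "unknown patient"
  )
})

test_that("an empty genotype set yields all-zero rows for every gene", {
  empty <- fixture_cohort$genotypes[0, ]
  b0 <- gene_burden_table(fixture_cohort$patients, empty,
                          fixture_cohort_calls)
  expect_equal(nrow(b0), 53L)
  expect_true(all(b0$n_any_hlap == 0L & b0$n_path_bap == 0L))
})

test_that("the HLAP partition is exhaustive, disjoint and sized as configured", {
  expect_equal(nrow(groups), 163L)
  expect_equal(sum(table(groups$group)), 163L)
  expect_equal(as.vector(table(groups$group)), c(52L, 50L, 61L))

  # group I takes precedence even with other pathogenic burden
  g <- fixture_cohort$genotypes
  path_ids <- fixture_cohort_calls$variant_id[
    fixture_cohort_calls$verdict == "pathogenic"
  ]
  apoa5_carriers <- unique(
    g$patient_id[g$gene == "APOA5" & g$variant_id %in% path_ids]
  )
  apoa5_carriers <- intersect(apoa5_carriers, hlap$patient_id)
  expect_setequal(groups$patient_id[groups$group == "I"], apoa5_carriers)

  expect_error(
    assign_groups(fixture_cohort$patients, fixture_cohort$genotypes,
                  fixture_cohort_calls),
    "HLAP patients only"
  )
})

test_that("carrier-matrix column indicators match burden pathogenic counts", {
  expect_equal(cmat$APOA5[cmat$patient_id == "A10"], 2L)
  expect_equal(cmat$APOA5[cmat$patient_id == "A46"], 2L)

  hl <- cmat[cmat$arm == "HLAP", ]
  genes <- setdiff(names(cmat), c("patient_id", "arm"))
  indicator_sums <- vapply(genes, function(g) sum(hl[[g]] > 0L), integer(1))
  for (g in burden$gene) {
    expect_equal(indicator_sums[[g]], burden$n_path_hlap[burden$gene == g],
                 label = g)
  }
  # non-carriers have all-zero rows
  iii <- groups$patient_id[groups$group == "III"]
  g2 <- default_group2_genes()
  expect_true(all(cmat[cmat$patient_id %in% iii,
                       c("APOA5", g2)] == 0L))
  expect_s3_class(autoplot(cmat), "ggplot")
})

test_that("group comparisons pick the documented tests and render Table-1 style output", {
  p <- fixture_cohort$patients
  p$msap_sap <- p$severity %in% c("MSAP", "SAP")
  cmp <- compare_groups(p, "arm", c("age", "bmi", "tg", "msap_sap",
                                    "diabetes"))
  s <- cmp$summary
  # configured severity percentages, one-decimal style
  expect_equal(s$pct_event[s$variable == "msap_sap" & s$group == "HLAP"],
               50.9)
  expect_equal(s$pct_event[s$variable == "msap_sap" & s$group == "BAP"],
               16.7)

  t <- tidy(cmp)
  expect_equal(nrow(t), 5L)
  # TG is strongly right-skewed so the rank test is selected; age is not
  expect_equal(t$test[t$variable == "tg"], "mann_whitney_u")
  expect_equal(t$test[t$variable == "age"], "welch_t")
  expect_true(all(t$p.value >= 0 & t$p.value <= 1))
  # arms differ strongly in TG by construction
  expect_lt(t$p.value[t$variable == "tg"], 0.001)

  gl <- glance(cmp)
  expect_equal(gl$n_tests, 5L)
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("identical groups give p = 1 and empty groups error", {
  d <- tibble::tibble(
    grp = rep(c("a", "b"), each = 20),
    flag = rep(c(TRUE, FALSE), 20)
  )
  cmp <- compare_groups(d, "grp", "flag")
  expect_equal(tidy(cmp)$p.value, 1)
  expect_error(compare_groups(d[d$grp == "a", ], "grp", "flag"),
               "at least two")
})

test_that("three-group comparisons test all pairs", {
  p <- dplyr::left_join(hlap, groups, by = "patient_id")
  cmp <- compare_groups(p, "group", c("tg", "recurrence"))
  t <- tidy(cmp)
  expect_equal(nrow(t), 6L)  # 2 variables x 3 pairs
  expect_setequal(paste(t$group1, t$group2),
                  rep(c("I II", "I III", "II III"), 2))
})

test_that("percentage helpers round half away from zero", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(31.90), 32)
  expect_equal(pct(52, 163), 32)
  expect_equal(pct(83, 163, 1), 50.9)
  expect_equal(pct(1, 30), 3)
  expect_equal(pct(5, 30, 1), 16.7)
})
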