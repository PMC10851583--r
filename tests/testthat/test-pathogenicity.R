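test_that("per-program damaging conventions are encoded exactly", {
  expect_true(predictor_damaging("mutation_assessor", "M"))
  expect_true(predictor_damaging("mutation_assessor", "H"))
  expect_false(predictor_damaging("mutation_assessor", "L"))
  expect_true(predictor_damaging("polyphen_hdiv", "P"))
  expect_true(predictor_damaging("polyphen_hdiv", "D"))
  expect_false(predictor_damaging("polyphen_hdiv", "B"))
  expect_false(predictor_damaging("lrt", "U"))
  expect_true(predictor_damaging("mutation_taster", "A"))
  expect_false(predictor_damaging("mutation_taster", "P"))
  expect_false(predictor_damaging("cadd", 3.66))
  expect_false(predictor_damaging("cadd", 15))    # strictly greater than 15
  expect_true(predictor_damaging("cadd", 15.01))
  expect_false(predictor_damaging("sift", NA_character_))
  expect_false(predictor_damaging("cadd", NA_real_))
  expect_error(predictor_damaging("sift", "Z"), "not a valid")
  expect_error(predictor_damaging("cadd", -1), "non-negative")
})

test_that("the consensus rule reproduces the printed pathogenic/benign partition", {
  calls <- fixture_calls
  path <- calls$protein[calls$verdict == "pathogenic"]
  expect_setequal(path, c("p.S35N", "p.D167V", "p.G185C", "p.K188I",
                          "p.R223C", "p.H182fs"))
  expect_equal(sum(calls$verdict == "benign"), 4L)

  expect_equal(calls$damaging_votes[calls$protein == "p.R223C"], 6L)
  expect_equal(calls$damaging_votes[calls$protein == "p.S35N"], 4L)

  # SIFT anchor: 4 damaging votes without SIFT stay benign
  g26v <- calls[calls$protein == "p.G26V", ]
  expect_equal(g26v$damaging_votes, 4L)
  expect_false(g26v$sift_damaging)
  expect_equal(g26v$verdict, "benign")

  v153m <- calls[calls$protein == "p.V153M", ]
  expect_equal(v153m$damaging_votes, 0L)

  fs <- calls[calls$kind == "frameshift", ]
  expect_equal(fs$verdict, "pathogenic")
  expect_equal(fs$auto_rule, "frameshift")
  expect_equal(fs$damaging_votes, 0L)
})

test_that("stopgain and stoploss trigger the auto rule even with benign profiles", {
  v <- fixture_variants[fixture_variants$protein == "p.V153M", ]
  for (k in c("stopgain", "stoploss")) {
    v$kind <- k
    call <- classify_variants(v)
    expect_equal(call$verdict, "pathogenic")
    expect_equal(call$auto_rule, k)
  }
})

test_that("flipping any non-damaging program to damaging never demotes a verdict", {
  damaging_value <- list(sift = "D", polyphen_hdiv = "D", lrt = "D",
                         mutation_taster = "D", mutation_assessor = "H",
                         cadd = 30)
  base <- classify_variants(fixture_variants)
  for (prog in names(damaging_value)) {
    v <- fixture_variants
    v[[prog]] <- rep(damaging_value[[prog]], nrow(v))
    flipped <- classify_variants(v)
    demoted <- base$verdict == "pathogenic" & flipped$verdict == "benign"
    expect_false(any(demoted), label = paste("flip", prog))
    expect_true(all(flipped$damaging_votes >= base$damaging_votes))
  }
})

test_that("verdicts ignore allele frequencies, conservation and rsid", {
  v <- fixture_variants
  v$af_all <- 0.5
  v$af_eas <- 0.01
  v$phylo_hmm <- -5
  v$rsid <- NA_character_
  v$status <- "novel"
  expect_equal(classify_variants(v)$verdict, fixture_calls$verdict)
  expect_equal(classify_variants(v)$damaging_votes,
               fixture_calls$damaging_votes)
})

test_that("duplicate annotations are rejected and tidy/glance summarize calls", {
  dup <- dplyr::bind_rows(fixture_variants, fixture_variants[3, ])
  expect_error(classify_variants(dup), "duplicate")

  td <- tidy(fixture_calls)
  expect_equal(nrow(td), 10L)
  expect_true(all(c("verdict", "damaging_votes", "rationale") %in% names(td)))

  gl <- glance(fixture_calls)
  expect_equal(gl$n_pathogenic, 6L)
  expect_equal(gl$n_benign, 4L)
  expect_equal(gl$n_auto_rule, 1L)

  # the top-1% CADD remark surfaces in the rationale, not the verdict
  expect_match(fixture_calls$rationale[fixture_calls$protein == "p.R223C"],
               "top 1%")
})

test_that("calls serialize to JSON one record per variant", {
  tf <- withr::local_tempfile(fileext = ".json")
  write_calls_json(fixture_calls, tf)
  back <- jsonlite::read_json(tf)
  expect_length(back, 10L)
  expect_equal(back[[1]]$verdict[[1]], "pathogenic")
})
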