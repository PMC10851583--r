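test_that("codon arithmetic maps coding positions to residues", {
  expect_equal(codon_index(553), 185L)
  expect_equal(codon_index(104), 35L)
  expect_equal(codon_index(667), 223L)
  expect_equal(codon_index(c(1, 3, 4)), c(1L, 1L, 2L))
  expect_error(codon_index(0), "positive")
  expect_error(codon_index(-5), "positive")
})

test_that("translation follows the standard code and CDS validation bites", {
  expect_equal(translate_cds("ATGGGCTAA"), "MG")
  expect_equal(translate_cds("ATGTGCTGA"), "MC")
  expect_equal(nchar(translate_cds(fixture_cds)), 366L)
  expect_error(translate_cds("ATGTAATGCTGA"), "internal stop codon at codon 2")
  expect_error(validate_cds("ATGGGC"), "stop")
  expect_error(validate_cds("GTGGGCTAA"), "ATG")
  expect_error(validate_cds("ATGGGTAA"), "multiple of 3")
})

test_that("substitutions resolve to the printed missense consequences", {
  expect_equal(call_consequence(fixture_cds, "c.553G>T")$hgvs_p, "p.G185C")
  expect_equal(call_consequence(fixture_cds, "c.104G>A")$hgvs_p, "p.S35N")
  expect_equal(call_consequence(fixture_cds, "c.667C>T")$hgvs_p, "p.R223C")
  expect_equal(call_consequence(fixture_cds, "c.500A>T")$hgvs_p, "p.D167V")
  expect_equal(call_consequence(fixture_cds, "c.563A>T")$hgvs_p, "p.K188I")

  # wobble position of the GGC codon at 185 stays glycine
  syn <- call_consequence(fixture_cds, "c.555C>T")
  expect_equal(syn$kind, "synonymous")
  expect_equal(syn$position, 185L)
})

test_that("the 5-nt insertion is a frameshift anchored at residue 182", {
  fs <- call_consequence(fixture_cds, "c.544_545insGGTGC")
  expect_equal(fs$kind, "frameshift")
  expect_equal(fs$position, 182L)
  expect_equal(fs$hgvs_p, "p.H182fs")
})

test_that("reference mismatches, stop gains/losses and in-frame indels are detected", {
  expect_error(call_consequence(fixture_cds, "c.553C>A"),
               "expects C but the CDS holds G")

  cds <- "ATGTGGAAATAA"  # M W K stop
  sg <- call_consequence(cds, "c.4T>A")  # TGG -> AGG? no: TGG->AGG is R
  expect_equal(sg$kind, "missense")
  sg2 <- call_consequence(cds, "c.5G>A")  # TGG -> TAG stop
  expect_equal(sg2$kind, "stopgain")
  expect_equal(sg2$hgvs_p, "p.W2*")
  sl <- call_consequence(cds, "c.10T>C")  # TAA -> CAA (Gln)
  expect_equal(sl$kind, "stoploss")
  expect_equal(sl$alt_aa, "Q")
  still_stop <- call_consequence(cds, "c.12A>G")  # TAA -> TAG
  expect_equal(still_stop$kind, "synonymous")

  inframe <- call_consequence(cds, "c.3_4insAAAGGG")
  expect_equal(inframe$kind, "inframe")
  fs_del <- call_consequence(cds, "c.4_5del")
  expect_equal(fs_del$kind, "frameshift")
  expect_equal(fs_del$position, 2L)
})

test_that("codon-local calls agree with the brute-force mutate-translate-diff oracle", {
  set.seed(42)
  n_cases <- 1200
  cds_pool <- lapply(1:20, function(i) random_cds(30, seed = i))
  for (i in seq_len(n_cases)) {
    cds <- cds_pool[[sample.int(20, 1)]]
    n <- nchar(cds)
    if (i %% 4 == 0) {
      # random small indel
      if (stats::runif(1) < 0.5) {
        pos <- sample.int(n - 1, 1)
        len <- sample.int(5, 1)
        change <- parse_cdna_hgvs(sprintf(
          "c.%d_%dins%s", pos, pos + 1,
          paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
        ))
      } else {
        start <- sample.int(n - 6, 1)
        len <- sample.int(min(5, n - start), 1)
        change <- parse_cdna_hgvs(
          if (len == 1) sprintf("c.%ddel", start)
          else sprintf("c.%d_%ddel", start, start + len - 1)
        )
      }
    } else {
      pos <- sample.int(n, 1)
      ref <- substr(cds, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      change <- parse_cdna_hgvs(sprintf("c.%d%s>%s", pos, ref, alt))
    }
    got <- try(call_consequence(cds, change), silent = TRUE)
    if (inherits(got, "try-error")) next  # e.g. indel destroying the start
    want <- oracle_consequence(cds, change)
    expect_equal(got$kind, want$kind,
                 info = sprintf("%s on CDS %d", change$hgvs, nchar(cds)))
    if (!is.null(want$position) && want$kind != "inframe") {
      expect_equal(got$position, want$position, info = change$hgvs)
    }
    if (want$kind == "missense") {
      expect_equal(got$ref_aa, want$ref_aa, info = change$hgvs)
      expect_equal(got$alt_aa, want$alt_aa, info = change$hgvs)
    }
  }
})

test_that("substitution positions always land on codon_index of the site", {
  set.seed(7)
  cds <- random_cds(40, seed = 99)
  for (pos in sample.int(nchar(cds) - 3, 100)) {
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- call_consequence(cds, sprintf("c.%d%s>%s", pos, ref, alt))
    expect_equal(got$position, codon_index(pos))
  }
})

test_that("CDS FASTA round-trips through Biostrings IO", {
  tf <- withr::local_tempfile(fileext = ".fa")
  write_cds_fasta(fixture_cds, tf, name = "synthetic_apoa5")
  expect_equal(read_cds_fasta(tf), fixture_cds)
})
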