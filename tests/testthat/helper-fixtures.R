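# Shared fixtures, built once per test run. The default cohort is the
# study configuration (163 HLAP / 30 BAP); generating it takes ~1 s.

fixture_variants <- apoa5_variants()
fixture_calls <- classify_variants(fixture_variants)
fixture_cohort <- generate_cohort(cohort_config(), seed = 101)
fixture_cohort_calls <- classify_variants(fixture_cohort$variants)
fixture_cds <- apoa5_synthetic_cds(seed = 1)

# Brute-force consequence oracle: apply the change, translate both
# sequences fully, and diff residue by residue. Independent of the
# codon-local path in call_consequence().
oracle_consequence <- function(cds, change) {
  mutate_nt <- function(cds, change) {
    pos <- change$position
    switch(change$kind,
      substitution = paste0(substr(cds, 1, pos - 1), change$alt_base,
                            substr(cds, pos + 1, nchar(cds))),
      insertion = paste0(substr(cds, 1, pos), change$inserted_seq,
                         substr(cds, pos + 1, nchar(cds))),
      deletion = paste0(substr(cds, 1, pos - 1),
                        substr(cds, change$end + 1, nchar(cds)))
    )
  }
  translate_all <- function(nt) {
    n <- nchar(nt) - nchar(nt) %% 3
    if (n == 0) return(character(0))
    codons <- substring(nt, seq(1, n, 3), seq(3, n, 3))
    code <- as.character(Biostrings::GENETIC_CODE)
    names(code) <- gsub("U", "T", names(Biostrings::GENETIC_CODE))
    unname(code[codons])
  }
  wt <- translate_all(cds)
  mt <- translate_all(mutate_nt(cds, change))
  prot_len <- length(wt) - 1  # excluding stop

  if (change$kind == "substitution") {
    diff <- which(utils::head(wt, length(mt)) !=
                    utils::head(mt, length(wt)))
    if (!length(diff)) {
      return(list(kind = "synonymous", position = codon_index(change$position)))
    }
    i <- diff[1]
    if (i > prot_len) {
      return(list(kind = if (mt[i] == "*") "synonymous" else "stoploss",
                  position = i))
    }
    if (mt[i] == "*") return(list(kind = "stopgain", position = i))
    list(kind = "missense", position = i, ref_aa = wt[i], alt_aa = mt[i])
  } else {
    len <- if (change$kind == "insertion") nchar(change$inserted_seq)
           else change$deleted_len
    if (len %% 3 == 0) return(list(kind = "inframe"))
    first_shifted <- if (change$kind == "insertion") change$position + 1
                     else change$position
    list(kind = "frameshift", position = codon_index(first_shifted))
  }
}

random_cds <- function(n_codons, seed = NULL) {
  build_synthetic_cds(length = n_codons, seed = seed)
}
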