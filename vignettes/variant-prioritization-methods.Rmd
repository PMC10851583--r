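---
title: "Methods: consensus variant prioritization and cohort reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus variant prioritization and cohort reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varprio)
```

## The classification model

`varprio` prioritizes coding variants with a deliberately simple,
deterministic consensus rule rather than a calibrated meta-predictor.
Six in-silico programs vote; a variant is *pathogenic* when

1. it truncates or extends the protein (frameshift, stopgain,
   stoploss) — no votes required; or
2. at least **2 of 6** programs call it damaging **and SIFT is one of
   them**.

The per-program damaging conventions are fixed constants:

| program | damaging | not damaging |
|---|---|---|
| SIFT | D | T |
| PolyPhen2-HDIV | D, P | B |
| LRT | D | N, U |
| MutationTaster | D, A | N, P |
| MutationAssessor | H, M | L, N |
| CADD | score > 15 | score ≤ 15 |

Three modelling decisions deserve comment. First, the SIFT anchor means
SIFT damaging plus any one other damaging vote suffices, and no number
of votes can compensate for a tolerated SIFT call — p.G26V in the
packaged table collects 4 damaging votes yet stays benign. Second, the
CADD cut-off is strictly greater than 15; a CADD ≥ 20 ("top 1%") remark
is carried in the rationale string but never alters the vote. Third,
missing annotation is never damaging, which makes the rule monotone: a
missing value can only be promoted to a damaging one, and promoting any
vote can only move a verdict towards pathogenic (a property the test
suite checks by exhaustive flipping). MutationTaster's automatic
category `A` is accepted and counted damaging even though it does not
occur in the packaged table; this is the conservative superset of the
documented categories. Allele frequencies, conservation scores and
database membership are annotation for the report narrative only — the
verdict depends on the six programs and the consequence class alone.

## Consequence calling

HGVS parsing covers the subset of the grammar that clinical
resequencing tables actually use: substitutions, simple insertions and
simple deletions in `c.` space; one-letter missense, `fs` frameshifts
and `*`-stopgains in `p.` space. Intronic offsets, delins and genomic
coordinates are out of scope by design.

Substitutions are resolved *codon-locally*: the affected codon is
`ceiling(position / 3)` and only that codon is retranslated. The test
suite holds this path against an independent brute-force oracle that
mutates the full sequence, translates both versions entirely and diffs
them residue by residue (over a thousand random cases on random small
coding sequences).

Frameshift anchoring follows the first-shifted-nucleotide convention:
an indel whose length is not a multiple of three is anchored at the
codon containing the first shifted nucleotide — for an insertion
between positions *i* and *i + 1*, the codon of *i + 1*. No 3'-rule
normalization is attempted, because the variant names being reproduced
were not normalized either. In-frame indels are reported as `inframe`
and are *not* auto-pathogenic; only frameshift, stopgain and stoploss
trigger the automatic rule. A substitution inside the terminal stop
codon that produces a sense codon is a stoploss; one that produces
another stop codon is reported synonymous.

Because the study transcript was never deposited, consequence names are
validated against a **synthetic** coding sequence
(`apoa5_synthetic_cds()`): 366 codons plus stop, random but
seed-deterministic, with exact codons pinned at every tabulated variant
position so that each printed nucleotide change yields its printed
residue change (e.g. GGC at codon 185 so c.553G>T gives Gly185Cys, and
AAA — not AAG — at codon 188 so c.563A>T gives Lys188Ile). The pinned
codons are the only ones compatible with the published
nucleotide/residue pairings.

## Protein annotation

Domain intervals are 1-based, inclusive on both ends, in full-length
numbering (Met1 = 1, signal peptide included). Where published boundary
statements conflict (Val169 vs Ala169 for the first lipid-binding
region; Gly268 vs Glu268 for the second), the consolidated figure-legend
values are used. The property table binarizes hydropathy from the
Kyte–Doolittle scale at threshold 0, counts His as positively charged,
and classes Cys as nonpolar — all plain constants in
`aa_property_table()`, so an alternative convention is a one-line
change. Property deltas describe substitutions; they never enter the
pathogenicity verdict.

Conservation is the fraction of non-reference alignment rows matching
the reference residue at a column, with *strict* meaning fraction 1.
Reference residue indices are mapped through reference gaps (k-th
non-gap column), and the mapping round-trips by construction.

## The synthetic cohort generator

The generator's defaults are the study conditions: two arms of 163
(HLAP) and 30 (BAP) patients; the published per-variant APOA5 carrier
counts by zygosity; per-gene distinct-carrier totals for all 53
candidate genes (both "any variant" and "pathogenic only" columns); and
the published comorbidity, severity and recurrence counts.

**Counts are assigned, not sampled.** Every count in the configuration
is reproduced exactly by assignment without replacement; only the
continuous covariates are stochastic. This separates the deterministic
acceptance surface (burden tables, partitions, percentages) from the
statistical one (means, SDs, test sizes). Consequences of this design:

- The 54 APOA5 pathogenic carrier-events sit in 52 distinct HLAP
  carriers. The only configuration consistent with the published counts
  pins two double carriers — A10 (p.G185C + p.S35N) and A46
  (p.G185C + p.R223C) — and these, plus the named p.D167V carrier A15,
  are placed deterministically; remaining carriers are sampled.
- "Any-variant" carrier totals exceed pathogenic totals, so benign
  carriers fill a designated any-carrier set, uncovered patients first;
  for APOA5 this forces exactly 8 of the 52 benign p.V153M carriers to
  coincide with pathogenic carriers (105 carrier-events, 97 distinct
  carriers).
- The 93 pathogenic carrier-events in the 25 "group II" genes are
  confined to APOA5 carriers plus a designated 50-patient set, each of
  whom receives at least one event — so the HLAP arm partitions
  52 / 50 / 61 by construction, matching the published three-group
  comparison. Genes outside this set (e.g. APOB, LPL) are assigned
  freely; they do not define groups.

Continuous covariates are drawn per arm from the published mean ± SD:
TG, TC and CRP from a moment-matched log-normal (for TG the published
SD exceeds the mean, which is impossible for a normal on positive
support and marks strong right skew), everything else from a normal
truncated at zero by rejection. Covariate correlations are not
modelled, and genotype–phenotype coupling is off by default
(`tg_carrier_shift` adds a fixed TG increment to pathogenic-APOA5
carriers when wanted). Consequently the generator emulates the marginal
structure of the study tables, not patient-level dependence: passing
tests show the pipeline recovers configured structure, not that the
biology has been re-derived.

One published inconsistency is resolved in the defaults: the male count
(128 and 11) is taken over the incompatible printed percentage for the
control arm, and one gene's control-arm "all variants" count is raised
from 1 to 2 because its pathogenic count is 2 and pathogenic carriers
are a subset of all-variant carriers.

## Statistics

Group comparisons follow a deterministic test menu. Continuous
variables: Welch's *t*-test, replaced by the Mann-Whitney U test when
either group's sample skewness exceeds 2 in magnitude (type-2 estimator;
threshold documented here because the choice is otherwise arbitrary).
Categorical variables: Pearson's χ² without continuity correction,
replaced by Fisher's exact test when any expected cell is below 5. All
tests are two-tailed at α = 0.05. No multiple-testing correction is
applied — mirroring the original analysis — but the number of tests
performed is always reported via `glance()`. Under null simulations
(equal-mean log-normal groups of 52 and 61, 1000 replicates) the
selected test's rejection rate stays within [0.03, 0.07]; this is part
of the acceptance suite.

Percentages round half away from zero; burden tables use the integer
style (52/163 → 32%) and severity summaries the one-decimal style
(83/163 → 50.9%), reproducing the published mixture. Both renderings
are available through `pct(n, total, digits)`.

## Numerical and scale choices

Problem sizes were chosen so the full suite runs in well under a
minute of compute for the deterministic parts: the consequence oracle
uses 20 random 30-codon sequences × ~1200 random changes; the null
calibration uses 1000 replicates; parameter recovery of the TG
generator uses a 10,000-patient arm (standard error ≈ 1% of the mean,
checked within 2%). All randomness flows through explicit seeds;
generators restore the caller's RNG state.

## Known limitations

- The consensus rule is reproduced, not endorsed: it is not an
  ACMG-2015 classification and the predictor thresholds are not
  recalibrated here.
- The synthetic coding sequence and cross-species alignment are
  stand-ins constrained to the published residue facts, not the real
  APOA5 transcript or UniProt orthologs; conservation results on them
  validate the machinery, not the biology.
- Duplicate annotations for one variant are rejected as input errors;
  the source material contains none and defines no merge rule.
- Table-3-style p-values on raw study covariates are not reproducible
  (patient-level data were never released); the statistics module is
  validated on its own simulations instead.
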