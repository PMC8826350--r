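# capa

Feature-driven substructure pattern analysis for multitarget modulator
landscapes of ABC transporter inhibitors.

## What this package is for

Compounds that weakly but genuinely inhibit all three major
multidrug-resistance ABC transporters — ABCB1 (P-gp), ABCC1 (MRP1) and
ABCG2 (BCRP) — occupy the *outer multitarget modulator landscape*
(IC50 = 10–200 µM on every target), as opposed to the *inner* landscape of
potent pan-inhibitors (< 10 µM). `capa` is for cheminformaticians who want
to map that landscape from a curated triple-target IC50 dataset and then
use it to triage screening libraries:

1. **Classify** every compound from its ABCB1/ABCC1/ABCG2 profile into a
   potency class (Superior/Medium/Semi Class 7, Weak/Very Weak Pan,
   unclassified pan, Semi/Real Class 0, other), honouring censored values
   such as `">200"` and `"n.i."`.
2. **Tabulate** a binary compound × substructure distribution scheme and
   per-class percentages, `pct(s, g) = 100 · n_hits(s, g) / |g|`, with
   inter-group ratios.
3. **Grade** each substructure with a two-axis point score
   (`+++`/`++`/`+`/`0` for the potent and the weak regime) and assign it a
   landscape group — Superior/Inferior Inner, Superior/Inferior Outer, or
   Intermediate, the latter refined into tolerated-negative,
   untolerated-negative, inconclusive and plain sub-populations.
4. **Screen** a library through a six-stage cascade: stereo-deduplication,
   removal of untolerated negatives, removal of compounds with more than
   one tolerated negative, removal of inner-landscape chemistry, the
   requirement of at least one outer-landscape substructure, and ranking
   of survivors by distinct outer-substructure count with
   single/concentrated/distributed/mixed composition labels.

Substructure matching is coloured-graph monomorphism (element,
aromaticity, bond type) over Open Babel-perceived molecular graphs, solved
with igraph and validated against a brute-force oracle. A deterministic
synthetic-data generator (`generate()`, `generate_screening()`) plants
substructures and class-conditional IC50 profiles with a complete
ground-truth ledger, so the whole pipeline is testable offline.

## Worked example

```r
library(capa)
d <- data.frame(
  id = c("cpd3", "cpd5", "cpd1"),
  name = c("hit 3", "hit 5", "hit 1"),
  smiles = c("CCN1CCN(Cc2ccsc2)CC1", "CCC(C1COCCN1)c1nnn[nH]1", "CCOC(=O)CC"),
  ic50_abcb1 = c("33.1", "25.6", "22.7"),
  ic50_abcc1 = c("38.6", "60.9", "n.i."),
  ic50_abcg2 = c("15.9", "12.4", "7.89"))
x <- as_compounds(d)
classify(x)
#>          cpd3          cpd5          cpd1
#> VERY_WEAK_PAN VERY_WEAK_PAN         OTHER
```

The first two profiles are textbook outer-landscape inhibitors: two
targets at 20–200 µM and the third in the weak window, hence
`VERY_WEAK_PAN`. The third compound is potent on one target but shows no
ABCC1 inhibition at all, so it is neither a pan inhibitor nor Class 0 —
`OTHER`.

A ten-compound synthetic library (two stereo duplicates, one planted hit
for every cascade stage) runs through the full cascade:

```r
sc <- generate_screening(screen_spec(
  seed = 42, n_unique = 8, n_stereo_dups = 2,
  removals = c(untolerated = 1, tolerated = 1, inner = 2, no_outer = 1),
  outer_histogram = c(1, 1, 1)))
run_cascade(sc$library, sc$sets)
#> <capa_screening_report>
#>   unique_compounds                     in    10  removed     2
#>   untolerated_negative_substructures   in     8  removed     1
#>   tolerated_negative_substructures     in     7  removed     1
#>   inner_landscape_substructures        in     6  removed     2
#>   outer_landscape_substructure         in     4  removed     1
#>   scoring                              in     3  removed     0
#>   survivors: 3
#>   outer-count histogram:  1:1 2:1 3:1
```

Each stage reports incoming and removed compounds
(`n_in(k+1) = n_in(k) − removed(k)` always holds); the three survivors are
ranked by how many distinct outer-landscape substructures they carry.

A command-line front end over the same functions ships at
`inst/cli/capa.R` (`validate`, `classify`, `matrix`, `distribution`,
`landscape`, `screen`, `simulate`).

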