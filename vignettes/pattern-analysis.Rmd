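---
title: "Substructure pattern analysis for multitarget modulator landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substructure pattern analysis for multitarget modulator landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Polypharmacology screens need datasets that say not only *whether* a
compound hits several targets, but *how hard*. For the three ABC
transporters ABCB1 (P-gp), ABCC1 (MRP1) and ABCG2 (BCRP), a curated
multitarget dataset of compounds with IC50 values against all three
targets makes it possible to map which molecular substructures travel with
potent triple-target inhibition (the *inner* multitarget modulator
landscape, IC50 < 10 µM on every target), which travel with weak but real
triple-target inhibition (the *outer* landscape, 10–200 µM), and which
impede it. The outer landscape is the interesting frontier: substructure
filters derived from it can triage a virtual library toward compounds with
a deliberately weak, broad activity profile.

`capa` implements that workflow end to end: activity classification,
binary substructure distribution statistics, two-axis point scoring into
landscape groups, and a six-stage substructure-filter screening cascade —
plus a synthetic-data generator that makes the whole pipeline testable
with known ground truth.

## Activity classes

Each compound carries up to three IC50 values in µM; a censored value
`">B"` (including the literature shorthand "n.i.", encoded as censored at
200) is known only to be at least `B`. Classification applies the first
matching rule:

| # | class | rule |
|---|-------|------|
| 1 | Superior Class 7 | all three < 5 |
| 2 | Medium Class 7 | all three < 10, at least one in [5, 10) |
| 3 | Semi Class 7 | all three ≤ 15, at least one in [10, 15] |
| 4 | Weak Pan | exactly two in [20, 200), the third < 10 |
| 5 | Very Weak Pan | exactly two in [20, 200), the third in [10, 200) |
| 6 | unclassified pan | all three < 200 |
| 7 | Semi Class 0 | none < 10, one or two in [10, 200] |
| 8 | Real Class 0 | all three inactive (censored at ≥ 200 or measured > 200) |
| 9 | other | everything else |

Boundary conventions are deliberate: "< 5", "< 10" and "< 200" are
strict, "≤ 15", "≥ 20" and the closed intervals are inclusive. A censored
value satisfies lower bounds at its censoring bound and never satisfies an
upper bound, so a compound censored at 200 on any target falls out of the
pan set, and a compound potent on one target but inactive on another is
*other* — neither pan inhibitor nor Class 0. Rules 4–5 sit before rule 6
so that the named weak tiers take precedence over the residual pan pool.
Classification is total and deterministic; property tests check the
partition on a censored-value grid and a monotonicity spot check (making
a Class 7 compound uniformly more potent can never demote it to a weak
tier).

## Distribution statistics

The binary distribution scheme is a compounds × substructures boolean
matrix: `TRUE` iff at least one embedding of the query exists in the
molecule. Multiplicity is ignored here on purpose — it only enters the
composition labels of screening candidates. Percentages are

    pct(s, g) = 100 · |{compounds of group g containing s}| / |group g|

over the five classified pan classes, Semi/Real Class 0, and the
unclassified pan compounds (the latter because the tolerated-negative
refinement needs them). Reports round half-up to one decimal; every rule
comparison uses unrounded values. Empty groups yield 0 with a warning
rather than an error so that subsets and synthetic fixtures stay usable.
Inter-group ratios divide percentages by default (`ratio_basis = "pct"`);
dividing raw counts is available as a config switch since the two differ
only by a group-size factor.

## Substructure matching

No R-native general SMARTS engine is available, so `capa` implements
substructure search as coloured-graph monomorphism: molecules and queries
are parsed by Open Babel (via ChemmineOB), rendered to TRIPOS MOL2 —
which carries perceived aromaticity explicitly — and turned into igraph
objects whose vertices carry element and aromaticity and whose edges carry
the bond type (single/double/triple/amide/aromatic). Matching uses
igraph's LAD solver with per-atom candidate domains, then filters the
returned monomorphisms for bond-type compatibility. This gives standard
substructure-search semantics: a C–C–C chain query matches cyclopropane,
an aromatic query atom only matches an aromatic target atom, and queries
written as SMILES behave as substructure patterns after aromaticity
perception. Formal charges are not compared (no catalogue query here is
charged); that is the main simplification relative to a full SMARTS
engine and is a known limitation. Stereo-free structure keys — canonical
SMILES of the largest fragment after removing stereo descriptors — drive
stereoisomer deduplication; salt counter-ions are dropped before matching.

The matcher is validated against a brute-force oracle that enumerates
every injective atom assignment on a panel of >200 (molecule, query)
pairs of ≤ 12 heavy atoms.

## Point scores and landscape groups

Each substructure is graded on two axes with scores 0 < + < ++ < +++:
the inner axis contrasts its best percentage among Superior/Medium
Class 7 against the Class 0 groups, the outer axis its best percentage
among Semi Class 7, Weak and Very Weak Pan against the same Class 0
groups. The original analysis's numeric rule scheme is not published in
the main text, so the engine is fully configuration-driven
(`rule_config()`); the shipped defaults are the package's own
calibration, chosen to be monotone and documented here:

* `+++` needs ≥ 50% in the best positive group, ≤ 10% in the worst
  Class 0 group, and a positive-to-Class-0 contrast ratio ≥ 2;
* `++` needs ≥ 20% with the same contrast ratio;
* `+` needs ≥ 5% presence;
* `0` otherwise.

Every analysis records which rule fired per substructure. Group
assignment is deterministic with inner precedence: inner `+++` → Superior
Inner, inner `++` → Inferior Inner (this is where a substructure graded
`++/++` on both axes lands), then outer `+++`/`++` → Superior/Inferior
Outer, everything else Intermediate. Intermediate substructures are
refined from the raw presence pattern: present only in Real Class 0 →
*untolerated negative*; present nowhere, or present in every populated
group with a max–min percentage spread within `inconclusive_spread`
(default 5 points — a package choice, the original judged "equal
distribution" without a printed tolerance) → *inconclusive*; present in
Semi Class 0 but absent from the unclassified pan compounds → *tolerated
negative*; otherwise plain. Only the two negative sub-populations take
part in screening; plain and inconclusive intermediates are omitted to
widen the gap between the inner and outer landscapes.

## The screening cascade

`run_cascade()` applies six stages in fixed order: stereo-redundancy
removal (first occurrence kept), removal of any untolerated-negative hit,
removal of compounds with more than one (default `max_tolerated = 1`)
distinct tolerated-negative substructure, removal of any inner-landscape
hit, removal of compounds with no outer-landscape substructure, and
scoring. All counting is by distinct substructure identity. Scoring ranks
survivors by descending outer-substructure count, ties broken
lexicographically by compound id for reproducibility, and labels the
composition of each survivor's matched outer substructures from their
embedding atom sets: *single* (one substructure), *concentrated* (every
pair overlaps), *distributed* (all pairs disjoint), *mixed*. Each matched
substructure contributes the union of its embeddings to that comparison.
The final manual hit selection of a real campaign (availability, scaffold
diversity, price) is out of computational scope; the ranked table with
composition labels is the hand-off point. The cascade is monotone
(survivor sets nested), order-insensitive up to the choice of duplicate
representative, and idempotent past the dedup stage — all property-tested.

## The synthetic generator

`generate()` and `generate_screening()` build libraries whose every
downstream number is known by construction. Molecules are assembled, not
sampled: an aliphatic backbone carries planted catalogue fragments as
branches plus a unique linear C/O/N serial tail encoding the compound
index, which guarantees pairwise distinct constitutions (asserted at run
time). The planted fragments are single rings and hetero-functional
groups chosen to be mutually non-matching, so binary-matrix column sums
equal the planted counts exactly; generation verifies every planted
fragment with the matcher (`verify = "planted"`) or the complete matrix
(`verify = "full"`). IC50 triples are drawn uniformly from intervals
shrunk strictly inside each class's defining region (e.g. Medium Class 7
forces one value into [5.05, 9.9]), so floating-point comparison can
never flip a class and `classify()` recovers the intended class with
probability 1. Stereo duplicates append a flipped tetrahedral descriptor
on an otherwise identical molecule.

The default activity-dataset quotas emulate the curated multitarget
dataset this analysis style was developed on: 1160 compounds — 138 pan
inhibitors (22/34/22/8/6 classified plus 46 unclassified; where the
source partition is stated inconsistently, the summed partition is used)
and 304 Class 0 compounds (186 Semi, 118 Real). The default screening
spec emulates the published screening dimensions: 1229 unique compounds
plus 281 stereo-redundant entries, stage removals 129/10/776/31, and
survivors carrying 1–6 outer substructures with multiplicities
30/76/102/53/19/3. These sizes are the package's fixed study conditions;
`scripts/acceptance.R` regenerates them from a seed and recomputes every
reported quantity by running the pipeline.

What passing tests on this synthetic chemistry does **not** show: the
generator's molecules are matching and classification fixtures, not
drug-like chemistry. Real catalogues contain overlapping and nested
queries (their column sums are not independent), real libraries contain
tautomers and charged species the matcher treats conservatively, and real
IC50 tables contain values on class boundaries where the stated
conventions, not the generator's shrunken intervals, decide. The
boundary fixtures in `make_fixture_suite()` cover the latter.

## Numerical and degenerate-input choices

* Rounding: reports round half-up at one decimal; comparisons never use
  rounded values.
* Division by zero in ratios is flagged (`undefined_high` / `absent`),
  never computed.
* Empty groups, empty libraries and empty catalogues are legal inputs:
  percentages fall back to 0 with a warning, the cascade runs six stages
  over zero compounds.
* Unparseable SMILES rows are skipped, counted and reported — only an
  unreadable file is fatal.
* Censored values below the 200 µM convention (e.g. `">100"`) satisfy no
  upper-bound rule and typically classify *other*; this is the
  conservative reading of an incomplete measurement.

## Problem sizes

The test suite runs entirely on small synthetic instances (tens of
compounds, ten-pattern catalogues, a 48-compound screening library), with
the full-size emulation (1160-compound dataset, 1510-compound library)
reserved for the acceptance script. These sizes are the package's chosen
defaults for a laptop-scale reproduction of the workflow.
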