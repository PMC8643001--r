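---
title: "Methods: cleanroom bioburden analysis with cleanburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleanroom bioburden analysis with cleanburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleanburden)
```

## The problem

Spacecraft-assembly cleanrooms are monitored for planetary-protection
purposes with the NASA standard assay (NSA), a culture assay that counts
heat-shock-resistant spores. Spore counts are converted to an estimate of
the total viable bioburden with the Space Studies Board (SSB) factor of
50,000 viable cells per NSA spore. Amplicon (16S rRNA) surveys of the same
surfaces see far more of the community — including non-NSA spore-formers
and the non-sporulating majority — but raw sOTU tables from such
low-biomass environments are dominated by sequencing-depth artifacts and
reagent contamination, and the spore-forming status of most sOTUs is not
observed and must be predicted from a reference phylogeny.

`cleanburden` implements that full chain as composable, seeded, tested
stages: depth QC, control-based contaminant removal, rarefaction,
phylogenetic hidden-state prediction of sporulation with leave-one-out
evaluation, spore-category read accounting, compositional log-ratio
statistics against the distance from the cleanroom entrance, richness
comparisons, and the plate-count/SSB arithmetic. A synthetic-study
generator supplies ground truth for every stage.

## Sample QC and decontamination

`qc_filter()` keeps samples with at least `min_depth` reads (default
5000, the conventional gate for low-biomass amplicon work; the boundary
passes). `flag_contaminants()` applies a two-clause rule: a feature is a
putative reagent/processing contaminant when it occurs in **every**
control sample and its aggregated abundance over no-template controls
exceeds its aggregated abundance over floor samples.

Two deliberate choices live here:

* *Which controls enter each clause.* The 100%-prevalence clause uses all
  control types (field, negative, extraction) while the abundance clause
  uses only the no-template controls (negative + extraction). Field
  controls are exposed to room air, so treating them as no-template
  material would misattribute genuine signal; requiring prevalence across
  all of them, however, makes the first clause strictly harder to
  satisfy. Both sets are arguments.
* *Aggregator.* "Higher abundance" is the arithmetic mean of raw counts
  by default; `median` and `max` are available. Raw counts (not relative
  abundances) are compared, since reagent contamination is approximately
  constant in absolute copy number while biomass varies.

`control_prevalence_stats()` reports the classic low-biomass diagnostic:
how many features appear in any control, and how many of those occur in
fewer than 10% (default) of the floor samples. Decontamination runs
before rarefaction, and "present" means a raw count above zero — the
order in which these operations are conventionally chained.

`rarefy()` subsamples each surviving sample to an even depth without
replacement, as a *single* multivariate-hypergeometric draw (sequential
conditional `rhyper`, exact and linear in the number of features) under a
logged seed. Averaging over draws would shrink variance below what a
single sequencing run delivers and is intentionally not offered.

## Sporulation hidden-state prediction

The reference object is a rooted phylogeny whose tips carry a partial
binary label (spore-former / non-spore-former / unknown), built by
`build_reference_traits()`: a culture-collection trait record labels a
tip only when its 16S sequence is *identical* (after uppercasing and gap
stripping) to the tip's sequence; conflicting records resolve by
majority, exact ties to unknown.

The estimator (`hsp_empirical()`) is the empirical-frequency variant of
hidden-state prediction: for every node, the fraction of known
spore-former tips among known tips below it (`node_state_frequencies()`);
an unknown tip takes the frequency of its **nearest informative
ancestor** — the first node on the path from its parent to the root with
at least one labeled descendant, the focal tip always excluded from the
counts. Exclusion matters: it is what makes the same routine leakage-free
when a labeled tip is masked during cross-validation. The estimator uses
topology only; predictions are invariant to branch-length rescaling (a
documented consequence, covered by a test).

Classification uses a threshold `tau = 0.5` with ties assigned to the
spore-former class — the conservative direction for planetary
protection, where a false negative (missing a spore-former) is the costly
error. `tau` is an argument.

`loocv_average_precision()` masks each labeled tip in turn, re-predicts
it, and sweeps the (state, probability) pairs into a precision-recall
curve with step interpolation, AP = sum over score groups of
(R_k − R_{k−1})·P_k, positive class = spore-former; tied scores are
processed as one group, so an all-tied score vector collapses to a single
PR point at (1, prevalence). No linear interpolation is applied — step
interpolation is reproducible and matches the hand-computable examples in
the test suite.

Query sOTUs reach the tree through `place_queries()`, a deliberately
simple placement: each query becomes a new tip, sibling to its best-hit
reference tip under normalized p-distance (equal-length sequences are
treated as pre-aligned; unequal lengths are globally aligned pairwise
first), pendant length equal to that distance, ties broken toward the
lexicographically smallest tip label. The graft inserts the new node at
the reference tip's end, so distances among pre-existing tips are
preserved exactly. This replaces evolutionary-placement tools on purpose:
the downstream estimator is topology-local (nearest informative
ancestor), so best-hit attachment is adequate, and it keeps the package
free of external aligners.

## Category accounting and compositional statistics

`classify_taxa()` bins features into NSA spore-formers (spore-forming
*and* genus on the NSA-culturable list), non-NSA spore-formers, and
non-spore-formers; features whose total reads do not **exceed** the
threshold (default 100, strict inequality) are excluded. The default NSA
genus list is the twelve spore-forming genera recovered by NSA culture in
the cleanroom survey this package models (`nsa_genus_default()`),
user-overridable. `category_fractions()` normalizes read sums per group
(overall, per session, or per location); fractions sum to 1 within 1e-12
by construction.

Log-ratios (`group_log_ratio()`) are natural-log ratios of summed counts
of two disjoint taxon groups — scale-invariant, hence insensitive to
sequencing depth. Samples with a zero sum in either group are dropped and
listed rather than pseudocounted (a `pseudocount` argument exists for
users who prefer +1). Groups can be named feature sets or `rank:name`
taxonomy selectors (lowest-common-ancestor style aggregation).

`compare_log_ratio()` uses the Welch (unequal-variance) two-sided t test
— the safer default when only "a t test" is specified — with Bonferroni
adjustment over an explicitly stated family size.
`gradient_correlation()` averages the log-ratio per location and reports
the Pearson correlation of those means with location radius (two-sided p
from the t transform on n−2 df). The location means pool PMA-treated
floor samples by default — the viable community is the one expected to
carry the spatial signal — with `pma_naive` and `all` as alternatives.
Because the orientation of a log-ratio is a convention, swapping
numerator and denominator flips only the sign of r; interfaces require
the orientation explicitly.

`richness_tests()` counts features with nonzero counts per sample (on a
rarefied table, so depths are comparable), runs Kruskal-Wallis across
sample-type × PMA groups and pairwise Wilcoxon rank-sum post hocs with
Benjamini-Hochberg adjustment. When every sample has identical richness
the KW statistic is reported as 0 (the no-variation limit) rather than
the NaN a rank test produces on fully tied data.

## Bioburden arithmetic

`cfu_per_area()` pools replicate pour plates — total colonies over total
volume plated — scales the titre to the whole concentrate and divides by
the sampled area. Pooling equals per-plate averaging for equal volumes
and remains well-defined for unequal ones. The heat-shocked aliquot is
assumed to carry the concentrate's titre; no correction is made for the
sliver of aliquot not plated. `ssb_viable_estimate()`,
`observed_ratio()` and `cultivable_from_fraction()` are the SSB
conversions; a zero spore density yields a flagged undefined ratio, never
an infinity.

## The synthetic-study generator

`simulate_cleanroom_study()` emulates the survey design the statistics
assume: 13 floor locations with radii spaced uniformly on [50, 1000]
(arbitrary "pixel" units — every statistic treats radius as opaque), 11
sessions, 98 sampling events each yielding a PMA-naive/PMA-treated pair,
plus 12 field, 12 negative and 8 extraction controls. Key mechanisms:

* *Composition.* Per-taxon log-normal baseline (sdlog 1) times
  `exp(beta * radius)` for spore-formers; `beta = -0.002` per pixel by
  default, a ~7-fold decline in spore-former intensity across the room —
  strong enough that the planted sign is recoverable from a single study.
* *Trait.* A two-state Markov chain on a random binary tree
  (`simulate_tree()`, exponential(1) branch lengths), parameterized by
  the stationary spore probability (default 0.3) and a switching rate
  (default 0.05 per unit branch length). The infinite-rate limit gives
  independent Bernoulli tips; rate 0 copies the root state everywhere.
  A configurable fraction of taxa (default 0.6) expose their true trait
  as training labels; the rest are prediction targets.
* *Viability.* Each taxon has a Beta-distributed live fraction (mean 1/3,
  concentration 4 — the low mean reflects that most DNA on a cleanroom
  floor is from dead material); the dead complement contributes only to
  PMA-naive samples, so naive richness stochastically dominates treated
  richness in matched pairs.
* *Contaminants.* Seven taxa (default) dominate control composition (80%
  of expected control reads) and appear in floors only at trace
  intensity. Each control reserves one read per contaminant before the
  multinomial draw, so contaminants are present in 100% of controls *by
  construction* while column totals still equal the drawn depths exactly.
* *Depth.* Negative-binomial totals (mean 50,000, size 5) truncated at
  the QC gate, with a configured fraction (default 0.2) forced below it
  to exercise the QC filter.

What the generator does **not** emulate: sequence-level error (chimeras,
PCR bias), taxon-taxon correlation beyond the phylogenetic trait,
session-level batch effects, and the very long tail of rare sOTUs real
deblurred tables carry. Passing tests on synthetic data therefore
demonstrate the estimators recover *planted* structure of the stated
form, not that real cleanroom tables satisfy these generative
assumptions.

## Numerical and degenerate-input choices

* Counts are integers at every boundary; a real-valued count is a format
  error naming the offending cell, never rounded (rarefaction and plate
  arithmetic both rely on integrality).
* Missing Newick branch lengths become 0 with a warning, keeping
  path-length operations total; negative lengths are rejected.
* Placement ties (equal p-distance) go to the lexicographically smallest
  tip label; classification ties at `tau` go to the positive class; AP
  score ties form one sweep group.
* Contaminant flagging with zero control samples is an explicit error
  (skip the stage deliberately instead), and LOOCV with a single
  represented state is an explicit error (AP undefined).
* Every stochastic stage derives its seed from the master seed and the
  stage name (`stage_seed()`), kept below 2^31; identical configurations
  reproduce reports byte for byte.

## Problem sizes used in validation

The packaged tests run the generator at its default design (300 features,
228 samples) for study-level checks, 500-tip trees for the
trait-recovery evaluation (20 replicates), 200 random instances for each
brute-force oracle equivalence (≤30-tip trees; ≤10×12 tables), and
10,000 seeds for the rarefaction expectation check on a two-feature toy
— sizes chosen so each property is measured with comfortable Monte-Carlo
margin on a single CPU.

## Known limitations

* The empirical hidden-state estimator ignores branch lengths by design;
  where branch lengths carry real signal a likelihood method (e.g. an
  Mk model) would use more information.
* Under leave-one-out evaluation, a positive tip with no labeled positive
  neighbor ("singleton" positives, which arise whenever the trait flips
  on a pendant edge) necessarily receives probability 0, so attainable AP
  is bounded by the non-singleton fraction of positives; fast-evolving or
  sparsely labeled traits depress AP for this structural reason.
* Best-hit placement is not an evolutionary placement: a query whose true
  attachment is deep inside the tree will still be attached next to a
  tip. This is harmless for nearest-informative-ancestor prediction but
  the extended trees should not be reused for distance-based analyses.
* The contaminant rule is the survey's own two-clause rule, not a
  statistical decontamination model; it has no notion of batch or
  cross-contamination frequency.
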