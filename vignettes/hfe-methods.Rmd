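---
title: "Hierarchical feature engineering for microbiome classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical feature engineering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxhfe)
```

## The problem and the model

Marker-gene (16S rRNA) case-control studies represent each sample
compositionally: the relative abundances of `m` OTUs, summing to 1 per
sample, with `m` typically in the thousands while samples number in the
tens to hundreds. Two structural facts make plain feature selection
wasteful here. First, features are not exchangeable — they hang on a
taxonomy, and biological traits are often shared by whole clades
(mono- or oligophyletic), so an *ancestral taxon's* aggregate abundance
can be a far better predictor than any one of its OTUs. Second, lineage
annotation is incomplete: many OTUs are confidently classified only to
family or genus level, so the hierarchy has leaves at interior depths.

`taxhfe` addresses both by *engineering* the feature space rather than
merely filtering it. With the eight-level hierarchy (kingdom, phylum,
class, order, family, genus, species, plus an OTU level at the bottom;
a virtual super-root joins multiple kingdoms and is never a feature),
the four phases of `runHFE()` are:

1. **Aggregation** (`aggregateTaxa`): each internal taxon gets the
   per-sample sum of its children's relative abundances, computed
   bottom-up so each parent sums already-aggregated children once; this
   telescopes to the sum over its OTU descendants. `m` OTU features
   become `m + m'` features.
2. **Correlation pruning** (`correlationFilter`): for each parent-child
   edge the Pearson correlation over training samples is computed; a
   child with `rho > theta` is discarded as redundant. Correlation is a
   redundancy heuristic, not an interaction-network estimate.
3. **IG path filtering** (`igPathFilter`): every retained feature is
   discretized with the Fayyad-Irani MDL criterion and scored by
   information gain against the class labels; along each OTU's
   root-to-leaf path, nodes below the path's mean IG (or with zero IG)
   are discarded. Leaves of incomplete paths are exempt.
4. **IG leaf filtering** (`igLeafFilter`): incomplete-path leaves
   survive only with IG at or above the global mean IG of the phase-3
   survivors, and strictly positive.

The discard counts `s1, s2, s3` satisfy the identity
`|selected| = m + m' - s1 - s2 - s3` on every input, which the test
suite asserts on hundreds of randomized runs. With taxonomy depth
constant, the work per phase is linear in the number of features at
fixed `n`; empirically, doubling `m` at `n = 200` multiplies `runHFE()`
runtime by about 2.3-2.5.

## Tunable parameters

* `theta` (phase 2), dimensionless in (0, 1), default **0.7**. The
  discard rule is *strict* (`rho > theta` discards; equality keeps);
  classification results are insensitive over 0.6-0.8, so 0.7 is the
  conventional "strong correlation" default.
* `phase3Average`, `"per-path"` (default) or `"global"`. The mean-IG
  threshold of phase 3 is ambiguous between a per-path and a
  feature-set-wide reading. We default to per-path averaging with a
  node kept when it passes on *any* path through it, because phase 4
  explicitly invokes a *global* average — the contrast in wording
  suggests phase 3's is local. Both readings are runnable; the switch
  isolates the decision.
* Classifier adapters (`hfeClassifier`): `"dt"`, `"rf"`, `"nb"` use
  their host packages' default settings (rpart, randomForest, e1071);
  results with other implementations of the same algorithms will differ
  numerically. Multi-class AUC is macro-averaged one-vs-rest;
  precision/recall/F are support-weighted — the averaging rule is our
  documented convention.

## Numerical choices

* **MDL discretization.** Candidate cuts are midpoints between adjacent
  distinct sorted values; the best cut maximizes information gain, ties
  resolving to the smallest cut value; a cut is accepted when
  `gain > (log2(N-1) + delta)/N` with
  `delta = log2(3^k - 2) - [k*Ent(S) - k1*Ent(S1) - k2*Ent(S2)]`, and
  recursion continues on both sides. A constant feature yields no cuts,
  one bin, and IG exactly 0. Bin membership counts cut points strictly
  below the value. The implementation (cumulative class counts,
  vectorized over candidates) is checked against an exhaustive
  brute-force oracle on >20000 enumerated small inputs.
* **Undefined correlations.** A zero-variance column makes Pearson
  correlation undefined; it is treated as 0, so the child is kept —
  conservative, since a constant-vs-variable pair carries no evidence
  of redundancy.
* **Ties at IG thresholds** are kept (`>=`), in phases 3 and 4 alike;
  "below the mean" means strictly below. Mean comparisons carry a
  1e-12 absolute tolerance so that a set of identical IG values ties
  its own mean despite floating-point summation.
* **Path means include exempt leaves.** The mean IG of a path is taken
  over all retained nodes on it, including an incomplete-path leaf; the
  exemption applies only to the discard decision, not to the averaging.
* **Phase order is strict.** A leaf discarded by phase 2 does not
  re-enter phase 4.
* **Normalization** rejects all-zero samples by name; tables whose rows
  already sum to 1 (within 1e-6) are auto-detected as relative
  abundances, overridable at the I/O boundary. On-disk orientation is
  OTUs x samples (classic QIIME); in memory it is samples x features,
  with one transposition at I/O.

## What the synthetic generator emulates

`randomTaxonomy()` + `generateDataset()` define the study conditions
for all self-contained experiments:

* **Hierarchical baseline means.** Every taxon draws a log-normal size
  factor; an OTU's mean is the product along its path. The default
  per-rank sdlog profile (phylum 1.2, class/order 1.0, family 0.8,
  genus/species 0.3, OTU 0.8) concentrates size heterogeneity at the
  upper ranks — phyla differ by orders of magnitude — while sibling
  genera stay comparable in scale, as in surveyed gut communities. The
  marginal OTU-mean distribution remains long-tailed (overall sdlog
  about 2).
* **Clade-coherent fluctuations.** Within each sample every genus draws
  a shared log-normal factor (sdlog 0.5) inherited by its OTUs; this is
  the oligophyletic premise made concrete — relatives respond together —
  and it is what gives phase 2 real redundancy to prune. An OTU
  truncated above genus level belongs to an unobserved genus of its own
  and gets a private factor, which is why such leaves do *not* correlate
  with their remote attachment ancestors and fall to phase 4 rather than
  phase 2. On top, independent per-OTU gamma noise with CV `noise`
  (default 0.5).
* **Planted effects.** Case samples multiply the planted clade's OTUs by
  `effectSize` *before* renormalization, so all other features shift
  compositionally — the realistic hard case. `effectSize = 1` gives an
  exchangeable null. Several clades can be planted (`nEffects`),
  emulating polymicrobial conditions.
* **Planted-node choice.** By default the planted genus is drawn among
  genera with at least 2 OTUs, at least one sibling genus, and at most
  15% of the family's baseline abundance. This is a well-posedness
  condition, not a convenience: a clade that constitutes the bulk of
  its parent is numerically indistinguishable from it (their feature
  columns share the effect-induced variance in full), so "which rank
  carries the trait" has no answer, for this or any method. Recovery is
  therefore judged to within one rank of the planted node.
* **Branching defaults** put ~3 genera per family and ~3 OTUs per genus
  at `m = 200`, the density of closed-reference tables, so aggregates
  are genuine sums rather than copies of single children.

What the generator does **not** emulate: sequencing-depth variation and
rarefaction, zero-inflation beyond what gamma sampling produces, OTU
mis-assignment, batch effects, and correlated effects across unrelated
clades. Passing the self-contained experiments therefore shows the
algorithm implements its contract and recovers identifiable planted
structure — not that any particular real dataset will reach a given
AUC; published AUCs on real cohorts additionally depend on the
classifier implementation used.

## Experiment sizes

The packaged checks use, as the package's own choices: 200 randomized
runs for the count identity; 20 seeds at `n = 100, m = 200`,
genus effect 3, `theta = 0.7` for planted recovery (pass mark: the
planted genus or a neighbor within one rank selected in >= 90% of
seeds, >= 80% of its OTUs pruned); 50 null seeds for false selection
(<= 10%) plus 6 null cross-validations (mean AUC in 0.5 +/- 0.1); 10
seeds at `m = 400, n = 100` with three planted genera for the
random-forest HFE-vs-baseline direction; and `m` in {1000, 2000, 4000}
at `n = 200` for runtime-scaling ratios (2x +/- 50%). Under the
single-clade recovery conditions the baseline forest is already
near-optimal — with low per-OTU dispersion each planted OTU is
individually separable — so the directional comparison is run where
aggregation has work to do: more features than samples and
polymicrobial, dispersed signal.

## Known limitations

* The phase-3 averaging rule is a documented interpretation (see
  above); both variants are implemented.
* Feature selection with very few surviving features is high-variance:
  on single-clade synthetic data the selection can collapse to 1-3
  features, so per-fold AUC varies more than with the ~30-100-feature
  selections seen on rich real datasets.
* Pearson correlation on compositional data can be inflated for
  dominant clades; with thousands of OTUs the compositional artifact is
  mild, and the filter is only a redundancy heuristic, but on very
  low-diversity communities phase 2 may over-prune.
* BIOM v2 (HDF5) is out of scope; convert to BIOM v1 JSON or classic
  TSV upstream.
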