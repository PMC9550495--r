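---
title: "Identifying conserved binding-site waters: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying conserved binding-site waters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conswat)
```

## The problem

Crystallographic waters in a protein's ligand binding site are of two
kinds. *Conserved* water molecules (CWMs) recur at essentially the same
position across homologous structures: they are typically buried, tightly
hydrogen-bonded, and often functionally important, so a ligand designer
wants to know about them in advance. *Free* water molecules (FWMs) are
displaced or variable between homologs. Telling the two apart from a single
structure is hard; conswat implements a two-part answer:

1. **Labeling by homolog superposition.** When a homologous structure is
   available, superpose it onto the reference and measure, for each
   binding-site water, the nearest Euclidean distance (NED) to any water
   oxygen of the superposed homolog. Small NED means the water recurs.
2. **Prediction from the microenvironment.** Where no homolog is available,
   predict the label from six features of the water's surroundings with a
   classifier trained on labeled waters.

## The labeling procedure

For a reference structure with a bound ligand and a homolog:

1. Superpose the homolog onto the reference by an optimal least-squares
   rigid fit (Kabsch, via SVD of the cross-covariance; reflections are
   excluded) over matched C-alpha atoms. The default matching pairs
   residues by a global sequence alignment of the chains; an explicit
   pairing can be supplied instead.
2. Keep the pair only if the superposition RMSD is at most **2.0 Å**
   (inclusive). A rejected pair is an explicit error, never silently empty
   output.
3. Define the binding pocket as every protein atom and water oxygen within
   **7.0 Å** (inclusive) of *any* ligand atom. A ligand-centroid variant is
   available (`pocketMode = "center"`), but the any-atom rule is the
   default: it is the standard pocket definition and does not depend on the
   ligand's shape.
4. For each pocket water of the reference, compute the NED to the waters of
   the superposed homolog — *all* of its waters, not only those in its own
   pocket, since conservation is about recurrence anywhere in the aligned
   frame. Label the water **CWM if NED ≤ 1.2 Å** (inclusive), FWM
   otherwise; a homolog with no waters gives an infinite NED and hence FWM.
   Waters outside the pocket stay unlabeled.

Waters are represented by their oxygen atom throughout; all distances are
oxygen–oxygen. Both thresholds are inclusive, and the suite checks the
boundary semantics explicitly (a water at exactly 1.2 Å is conserved).
Labels are invariant under any common rigid transform of both structures,
and raising the NED threshold can only promote FWMs to CWMs, never the
reverse; both properties are tested.

Whether the RMSD filter should use all-atom or C-alpha RMSD is not
determined by the procedure's description; conswat reports C-alpha RMSD
over the matched pairs, which is what the alignment optimizes.

## The six microenvironment features

Letters follow the package's combination codes:

| Letter | Feature | Definition | Units |
|---|---|---|---|
| A | atom density | protein atoms within 3.6 Å of the water oxygen | count |
| B | mobility | `(BF/mean BF) / (occ/mean occ)` over the structure's waters | – |
| C | temperature B-factor | the PDB B-factor column, verbatim | Å² |
| D | atomic hydrophilicity | `Σ h_i · exp(−r_i/d0)`, neighbors within 4 Å | – |
| E | atomic hydrophobicity | `Σ l_i · exp(−r_i/d0)`, neighbors within 4 Å | – |
| F | SASA | accessible area of the water-oxygen sphere | Å² |

All cutoffs are inclusive, consistent with the labeling thresholds.

**Exponent sign.** The hydrophilicity sum is sometimes printed with a
positive exponent `exp(+r/d0)`. A positive exponent makes the "interaction"
weight grow without bound with distance and is inconsistent with the
hydrophobicity sum's `exp(−r/d0)`; conswat uses the negative exponent in
both features by default and offers `positiveExponent = TRUE` to reproduce
the positive-sign variant. The hydrophobicity sum always uses the negative
exponent.

**The distance scale `d0`** is a free parameter with no established value;
the default is 1.0 Å, it is explicit in `featureConfig()`, and every
result depends on it only through the relative weighting of near versus far
neighbors.

**Propensity tables.** The hydration propensity `h` (how often an atom type
is hydrated when surface-exposed) and the carbon propensity `l` are
empirical, per-atom-type quantities. The package ships a compact heuristic
table (`inst/extdata/propensities.tsv`): charged and polar side-chain
oxygens/nitrogens carry the largest `h`, carbons carry `l` up to 1, with
element-class fallbacks for atom types not listed. These are package
defaults, not canonical literature values, and are fully user-replaceable
via `readPropensityTable()`; lookups fall back exact key → wildcard residue
→ element class → configurable default (0, with a warning).

**SASA** is computed by deterministic sphere-point sampling in the
Shrake–Rupley manner: the water oxygen sphere (vdW 1.52 Å + 1.4 Å probe)
is sampled with a Fibonacci point set (default 960 points), and a point is
accessible when outside every probe-expanded protein atom sphere. Default
vdW radii are O 1.52, N 1.55, C 1.70, S 1.80, H 1.20, P 1.80 Å. Other
waters and the ligand do not occlude by default (`sasaContext`), matching
the feature's reading as accessibility to bulk solvent. At 960 points the
bare-sphere and two-sphere closed forms are reproduced within 2%, and
doubling the point count moves values by well under 1% of the sphere area;
both are asserted in the suite. Because the point grid is fixed in the
laboratory frame, sampled SASA is rotation-invariant only up to the grid's
angular resolution (about 1 Å² in practice); the other five features are
rigid-motion invariant to machine precision.

**Mobility** normalizes a water's B-factor by the mean over the
structure's waters, divided by the equally normalized occupancy. The
baseline is all water oxygens of the structure (`mobilityScope =
"structure"`); a pocket-only baseline is available but makes the feature
depend on the pocket definition. Zero mean B-factor or zero occupancy is a
hard error, not a silent 0. The relation `B = 8π²·⟨u²⟩` is exposed as
`msdToBfactor()` for the synthetic generator; parsed structures report the
B-factor column verbatim.

## Classifiers, cross-validation and combination search

Seven families are evaluated: SVM (RBF, cost 1, gamma 1/p), KNN (k = 5),
decision tree (CART/Gini), logistic regression, linear discriminant
analysis, Gaussian naive Bayes, and ensemble learning (EL) realized as 100
bagged decision trees — a random forest with `mtry` equal to the number of
features, so every tree sees all features and the ensemble is pure
bagging. These hyperparameters are defaults in the tradition of
point-and-click classifier toolboxes; all are overridable in
`modelSpec()`. Features are z-scored for the scale-sensitive families
(SVM, KNN, LR, DA), with the scaler fitted on the training fold only;
trees and naive Bayes see raw features.

Evaluation is stratified five-fold cross-validation with the out-of-fold
predictions *pooled* before one metric set is computed. Pooling keeps
every ratio well-defined even when single folds are small; per-fold
averaging is the alternative but can involve undefined fold-level ratios.
Fold assignment is seeded after putting rows in a canonical content order
within each class, so pooled metrics do not depend on input row order.

Metrics use the conserved class as positive: accuracy, sensitivity,
positive predictive value, F-score `2TP/(2TP+FP+FN)`, and AUC as the
rank-statistic probability that a random positive outranks a random
negative with ties counted one half. Ratios with zero denominators are
reported as `NA` and excluded from averages with a recorded count — never
coerced to 0.

The combination search evaluates all 63 non-empty subsets of the six
features (ordered by decreasing size, then lexicographically), averages
each criterion over the models, and ranks combinations with a ±0.001 tie
tolerance: every combination within 0.001 of the maximum is "best" for
that criterion, and the overall winner is the combination best under the
most criteria, ties broken toward larger combinations. On the bundled
reference table of published averaged metrics
(`referenceCombinationMetrics()`), the full six-feature combination wins
four of the five criteria and is selected; the companion per-model table
(`referenceModelMetrics()`) is internally consistent (its F-scores are
harmonic means of the printed SN and PPV, its average-performance column
the mean of the five criteria) and ranks the EL family first. Both checks
are recomputed, not hard-coded, in the acceptance script.

## The synthetic generators

Two generators make every stage testable without downloading structures.

`generateHomologPair()` builds a toy crystal pair with planted truth: a
spherical protein cage (residues with N/CA/C/O atoms at radii 3–10 Å), a
small ligand at the origin, pocket waters placed within 6.8 Å of the
ligand with at least 2.5 Å mutual separation, and far waters outside. The
homolog jitters conserved waters by `jitterSd` (norm capped at 0.9 Å),
displaces the rest by at least `displacementMin` (default 2.0 Å) *and* at
least 1.5 Å away from every reference water, then moves everything by a
random rigid transform. With protein jitter of 0.03 Å the recovered
superposition is essentially exact, so conserved waters sit < 1.0 Å and
displaced ones > 1.4 Å from any partner after alignment — labels are
unambiguous by construction, with margin on both sides of the 1.2 Å
threshold. The generator emulates geometry and the labeling contract; it
does **not** emulate crystallographic noise, alternate conformations,
resolution effects, or realistic protein packing, so exact label recovery
here validates the pipeline's bookkeeping and geometry, not performance on
real crystals.

`generateFeatureTable()` draws labeled six-feature rows from per-class
truncated normals. The class locations and truncation bounds default to
published class-wise means and min/max ranges for conserved and free
binding-site waters; the scale is set so that roughly 99% of the
untruncated mass lies inside the bounds (`sd = nearest-bound distance /
2.576`), and the location parameter is solved (by root finding on the
truncated-normal mean) so the *truncated* mean equals the target — without
that correction the sample mean would sit a systematic ~1 standard error
off the target. The class ratio defaults to 1.25 conserved per free water,
so 4500 rows give 2500/2000. Features are drawn independently within a
class; real feature correlations (buried waters are simultaneously dense,
low-B and low-SASA) are not emulated, which makes the classification task
easier than on real data. The EL accuracy of ~0.99 the suite observes on
these tables is therefore a recovery check of the machinery, not a claim
about crystallographic performance.

A `separation` multiplier scales the distance between class locations; the
suite checks that the ensemble's CV accuracy is monotone over separations
0.5, 1, 2 at a fixed seed.

**Shuffle control.** On label-shuffled tables a classifier's predictions
are independent of the truth, so its expected accuracy is
`p·q + (1−p)(1−q)` where `p` is the majority rate (≈0.556) and `q` its
predicted-positive rate — a quantity bounded *above* by `p`. Models whose
fit on noise collapses to majority prediction (logistic regression does)
sit at `p` itself; flexible models such as deep bagged trees sit lower,
near 0.51. The suite therefore asserts the strict two-sided band around
the majority rate for logistic regression, and the chance band
`[1−p − 3σ, p + 3σ]` for the ensemble.

## Reproducibility and sizes

Every stochastic step (fold splits, stochastic fits, generators) is driven
by explicit integer seeds; reruns of the pipeline with one config and seed
produce byte-identical TSVs (floats are written at fixed precision,
default 3 decimals, and the run manifest carries a config hash computed
over a key-sorted JSON serialization, so it is stable under key
reordering). Config files are YAML, the config format with first-class R
parser support. The test suite and acceptance script use 20 synthetic
pairs of 50 pocket waters for label recovery and 4500-row feature tables
for the ensemble checks — sizes at which every result above is stable
across seeds while the whole suite runs in well under a minute. In the
ensemble checks, "single-feature models" means the EL model restricted to
one feature at a time, the EL model being the object under test.

## Known limitations

* The propensity table is heuristic; users with a calibrated per-atom
  hydration/carbon propensity set should supply it.
* `d0 = 1.0 Å` is a convention, not a fitted value.
* Sampled SASA carries O(point-count⁻¹) noise and is only approximately
  rotation-invariant.
* The synthetic generators validate contracts, not real-data performance;
  no claim about accuracy on deposited crystal structures is made or
  tested here.
* mmCIF, symmetry mates, multi-model ensembles beyond MODEL 1, and
  hydrogen placement are out of scope.
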