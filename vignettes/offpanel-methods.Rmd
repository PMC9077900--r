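---
title: "Modelling off-target safety panels with offpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling off-target safety panels with offpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Safety pharmacology panels screen candidate molecules against dozens of
anti-targets. Two properties of the resulting data shape everything in this
package. First, the compound × target interaction matrix is *sparse*:
compounds are screened against suspected off-targets, not the full panel, so
multi-task modelling over a dense matrix is not an option and one
single-task classifier is fitted per target. Second, the data are heavily
*imbalanced*: per-target hit rates (the percentage of screened compounds
with ≥ 50 % inhibition at 10 µM) span below 1 % up to ~36 %. Imbalance
corrupts naive modelling twice — during training, where an unweighted loss
happily predicts "inactive" everywhere, and during assessment, where plain
accuracy and even AUC reward exactly that behaviour. The package therefore
monitors, selects and reports on balanced accuracy, MCC, F1 and AUCPR
throughout.

## Curation model

Input rows are (compound, SMILES, target, measurement). A measurement is
either a percent inhibition at 10 µM — binarized at the fixed cutoff,
active ⟺ PCT ≥ 50, with the boundary counted active — or an already binary
label (A/N exports are mapped to 1/0). Structures are standardized with
RDKit: cleanup, largest fragment (salt/solvent strip), charge
neutralization, canonical SMILES. Duplicate handling follows the panel
logic: within one target the same canonical structure may not occur twice
(first row kept when labels agree; *all* copies dropped when labels
conflict, because picking one arbitrarily would inject label noise we
cannot measure), while the same structure measured on several targets is
retained — that cross-target duplication is the panel structure itself.
Inhibition values outside [−50, 150] are kept but flagged, as they usually
are assay artefacts. Targets with a hit percent below 1 % or fewer than 10
actives get a warning, not an exclusion: the workflow must attempt any
dataset, and the decision to discard a hopeless target belongs to the
analyst.

## Features and applicability domain

Models consume binary 1024-bit extended-connectivity fingerprints of
diameter 4. The name "ECFP4" refers to the *diameter*; the neighborhood
radius is 2, and that is what the package computes (the radius is exposed
as an argument for anyone wanting ECFP6). Bits are folded by the toolkit's
standard hashing; counts are deliberately not used — the feature contract
is "structural binary bits".

Eight descriptors — molecular weight, logP, H-bond donors and acceptors,
rotatable bonds, molar refractivity, polarizability, Lipinski failures —
serve a bounding-box applicability domain: the min–max range of each
descriptor over a target's training compounds, with closed intervals so the
training set is always inside its own box. Polarizability is estimated from
the Crippen molar refractivity through the Lorentz–Lorenz relation
(α [Å³] = 0.3964 · MR [cm³/mol]); toolkits differ in their polarizability
estimators and this choice is documented rather than hidden. The domain
flag is advisory: predictions outside the box are emitted and marked as
extrapolations, never suppressed.

## Split protocol

Each target is partitioned 80:20 into a training pool and a held-out test
set by *stratified* random splitting — with 2 % hit rates an unstratified
split can easily leave a test set with no actives at all. The pool is then
split again, stratified, into 75:25, giving 60 % training, 20 % validation,
20 % test overall. Per-class holdout counts use largest-remainder rounding,
so the total equals `round(n · fraction)` and no class deviates by more
than one sample. A deliberate design choice: the validation carve-out is
stratified too. A tail-slice validation split (a common framework default)
is only random if the rows are, and on sorted activity tables it is
catastrophically non-random; stratifying can only stabilize the monitored
metric. Splits are frozen to JSON with an FNV-1a checksum, and both the
persisted model manifests and the evaluator verify it — a model cannot be
scored against a partition it was not trained under.

One master seed fans out per-target seeds (and per-run seeds below), so any
slice of the workflow is independently reproducible.

## The network and its training

The architecture is fixed: input → dense(h, ReLU) → dense(h, ReLU) →
dense(1, sigmoid), dropout on the input and after each hidden activation,
L2 = 0.001 on every dense kernel, Adam on binary cross-entropy, classification
threshold fixed at 0.5 (deliberately untuned). The tunables and their grids:

| parameter      | grid                        |
|----------------|-----------------------------|
| hidden units   | 256, 512, 1024, 2048        |
| input dropout  | 0, 0.1, 0.2                 |
| hidden dropout | 0.2, 0.3, 0.4               |
| learning rate  | 0.01, 0.001, 0.0001         |
| batch size     | 64, 128, 256                |

The full Cartesian product has 324 combinations; a 50 % uniform subsample
(162 distinct combinations, seeded) is trained per target, up to 250
epochs. Three callbacks monitor validation balanced accuracy: checkpointing
(the best epoch's weights are the run's model), learning-rate reduction on
plateau (patience 10), and early stopping (patience 20). Two conventional
constants the protocol leaves open are fixed here and recorded in every
manifest: LR reduction factor 0.5 with floor 1e-6, and minimum improvement
1e-4 for both callbacks. Per-batch balanced accuracy with an absent class
degrades to the present class's recall; epoch-level monitoring uses the full
validation set, where stratified splits guarantee both classes. After the
grid, three checkpoints are retained per target — best validation loss,
best validation balanced accuracy, best validation binary accuracy — with
ties resolved to the earliest run in canonical grid order. All three are
evaluated; the best-balanced-accuracy model is the headline by default,
since balanced accuracy is the protocol's primary metric. The trainer is
implemented in base R matrix code inside the package, which keeps runs
bit-reproducible from (seed, hyperparameters, split) and free of any
framework dependency; backpropagation is verified against numerical
gradients in the test suite.

The Random Forest baseline fixes 100 trees and tunes `mtry` by stratified
10-fold cross-validation on the 80 % pool, maximizing balanced accuracy;
candidates default to {32, 64, 128, 256} around √1024, the classification
convention. Class weighting is off by default — the baseline is reported
with its minority-class weakness intact, as a baseline should be.

## Evaluation

All threshold metrics derive from the confusion matrix; MCC uses the
standard four-factor denominator √((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
Degenerate denominators return documented conventions (MCC → 0, precision
→ 0, F1 → 0) instead of NaN. AUC is the trapezoid area under the ROC sweep
of unique scores. AUCPR is computed as *average precision* — the step-wise
integral Σ(R_k − R_{k−1})·P_k — because trapezoidal interpolation is
optimistic in PR space; for uninformative scores it converges to the
prevalence, which is the correct null. The cross-method ranking counts, per
metric, the targets on which each method is best; exact ties credit every
tied method, which keeps the tally order-independent.

## The synthetic panel generator

The generator exists so that every stage — curation hazards included — can
be exercised end to end without proprietary screening data, and so that
"did the model learn" has a ground truth. Structures are assembled from a
fragment grammar (six ring cores × nine linkers × sixteen terminal
decorations × twelve secondary decorations), drawn as distinct
combinations; a few symmetry-equivalent structures and three deliberately
duplicated-SMILES pairs survive as natural curation fixtures. Activity is a
*planted substructure rule*: a compound is active on a target when it
carries the target's terminal motif (CF₃, sulfonamide, pyridyl, nitrile,
carboxylic acid, bromide by default). Because ECFP4 bits encode exactly
such neighborhoods, a fingerprint learner can genuinely recover the rule —
recovery tests measure learning, not memorization of noise.

Label noise deserves a precise definition. At noise rate ν the generator
flips `round(ν · n_active)` actives to inactive *and the same number* of
inactives to active. This class-count-preserving scheme was chosen over
independent symmetric flips for a concrete reason: the generator's contract
is that the realized hit rate equals the requested one (`round(h·n)/n`
exactly), and symmetric flipping either breaks that contract or — if the
rule-positive fraction is recalibrated to compensate — caps the achievable
balanced accuracy of *any* classifier at ≈ 0.77 for h = 0.2, ν = 0.1,
making recovery thresholds meaningless. Under the preserving scheme the
Bayes-optimal rule classifier attains TPR = 1 − ν and
TNR = 1 − ν·h/(1 − h), i.e. ≈ 0.94 balanced accuracy at h = 0.2, ν = 0.1,
so a ≥ 0.8 recovery bar is demanding but attainable. The monotone
degradation of recoverable signal with ν is itself under test.

What the generator does *not* emulate: real assay noise structure
(plate/day effects, threshold-adjacent symmetric errors), chemical-series
correlation beyond shared fragments, and activity cliffs. Passing recovery
tests therefore demonstrates that the pipeline learns planted structural
signal under label noise and imbalance — not that any particular real
target is predictable.

## Problem sizes and numerical choices

The package's own demonstration and verification runs use desk-scale
problems chosen to exercise every code path: a 600-compound target at a
20 % hit rate with 10 % noise for recovery runs (reduced single-combination
grid, full 250-epoch budget with live callbacks), a 240-compound noise-free
target for quick learnability checks, and a six-archetype demonstration
panel (150–1200 compounds, 3–36 % hit rates) mirroring the shapes of real
panels. The full 324-point grid over dozens of targets is the large-scale
protocol; it uses the same code path and is configuration, not code.

Numerical details worth knowing: BCE probabilities are clipped at 1e-7;
Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-7; weights initialize
Glorot-uniform from the run seed; reported validation loss includes the L2
penalty (so it matches the optimized objective); forests inherit
reproducibility from the seeded R RNG. PCA standardizes descriptors after
dropping zero-variance columns (unscaled PCA on mixed units is a molecular
weight axis with decoration); the overlap fraction tests convex-hull
membership in the first two components, with boundary and coincident
points counted inside, and falls back to a bounding box above two
dimensions or under three reference points.

## Known limitations

* The applicability-domain box is axis-aligned and ignores descriptor
  correlation; a point can be inside every marginal range yet far from the
  training distribution.
* Conflicting duplicate measurements are discarded, not averaged; with
  noisy assays near the 50 % cutoff this can drop genuinely borderline
  compounds.
* The probability outputs are raw sigmoid / vote fractions; no calibration
  is attempted, and the 0.5 threshold is a convention, not an optimum, on
  imbalanced targets.
* Chemical-space overlap in two principal components can overstate overlap
  that vanishes in higher components; the fraction is a screening
  diagnostic, not a similarity proof.
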