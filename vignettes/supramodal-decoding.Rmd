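---
title: "Decoding action representations across sensory modalities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding action representations across sensory modalities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When sighted people watch a hand action and blind people hear the same kind
of action, do their brains encode "this is an action" in a common,
modality-independent (supramodal) code? One way to ask this question with
fMRI is pattern decoding: estimate a response amplitude (a β weight) per
stimulus per voxel, train a linear classifier to separate action from
non-action stimuli within one sensory condition, and then probe whether the
discriminative information transfers across conditions — a classifier
trained on visual stimuli tested on auditory ones, a classifier trained in
sighted subjects tested in blind subjects, and classifiers tested on the
neural patterns evoked by actually executed motor pantomimes.

`supraMVPA` implements this analysis chain as a reusable, fully tested
pipeline: balanced β-pattern assembly, soft-margin linear support vector
machines (SVMs), recursive feature elimination (RFE) with 3D cluster
correction inside a 4-fold nested cross-validation (NCV), a combined
"supramodal" classifier with a knock-out mask procedure, and a
nonparametric inference layer. Because raw data of this kind are rarely
public, the package ships a synthetic-data generator that emulates the
study design and plants known informative voxel clusters, so every claim
the pipeline makes can be checked against ground truth.

## The generative model of the synthetic module

A `VoxelGrid` (default 12×12×12, isometric 2 mm voxels) carries four
pairwise disjoint informative voxel sets, each a union of face-connected
clusters grown by randomized breadth-first accretion (placement retried up
to 100 times, with a one-voxel moat so that every component keeps exactly
its requested size):

* a **shared set S** (default 40 voxels) carrying the action/non-action
  contrast in every modality — the supramodal code;
* **auditory-only A** and **visual-only V** sets (30 voxels each) carrying
  the contrast only in their modality;
* a **motor set M** (30 voxels) active during pantomime execution.

The β pattern of one example is

```
β = class effect at (S ∪ modality set) + subject offset + N(0, noiseSd²)
```

with the action effect applied at S ∪ M for pantomime examples. The design
follows the emulated study exactly: 14 sighted and 8 blind subjects, 20
action and 10 non-action sounds heard by everyone, 23 action and 11
non-action videos seen by the sighted only, and 10 motor pantomimes per
subject per session type. Pantomime counts follow the printed totals (280
sighted = 140 per session type, 80 blind) rather than a per-run
reconstruction, which is ambiguous in the source design. The subject
offset is a single scalar added to all voxels of a subject's examples —
the simplest exchangeable subject effect (default sd 0.3); noise defaults
to sd 0.5.

Three named scenarios fix the effect sizes:

| scenario   | S    | A = V | M    | emulates |
|------------|------|-------|------|----------|
| `recovery` | 1.0  | 1.0   | 1.0  | strong compact signal for feature-recovery experiments |
| `modality` | 0    | 1.0   | 1.0  | modality-specific coding only: within-condition decoding succeeds, nothing transfers across modalities |
| `shared`   | 0.15 | 0.08  | 0.15 | a weak common code over weaker modality-specific signal — the regime in which the knock-out procedure is informative |

The `shared` effect sizes were chosen by a power computation, not by
tuning: with k informative voxels of per-voxel effect e over noise σ, the
population discriminability of the optimal linear readout is d' = e√k/σ.
At e = 0.15, σ = 0.5, the within-condition signal (S ∪ A, ~70 voxels)
gives d' ≈ 2.1 (≈ 85% accuracy), dropping to d' ≈ 0.9 (≈ 67%) after
removing S, while S alone gives d' ≈ 1.9 — accuracies in the 65–85% band
of real decoding studies, off ceiling, with a detectable exclusion drop.
At e = 1.0 the same algebra gives d' ≈ 12 and every accuracy saturates at
100%, which is why the `recovery` scenario is useful for asking *where*
the information is but not *how much* of it there is.

What the generator deliberately does **not** emulate: haemodynamic
variability, motion and physiological noise, spatial autocorrelation of
real BOLD noise, anatomical variability, or group-specific idiosyncrasies
in where information lives (the informative sets are identical for sighted
and blind subjects). Passing tests on synthetic data therefore demonstrate
the correctness and calibration of the *procedure*, not the effect sizes
to be expected on scanner data. One concrete consequence: because A is
shared by both groups, auditory classifiers transfer between sighted and
blind synthetic subjects whenever A carries signal — the empirical
observation that such transfer can fail in real groups would require
group-specific informative sets, which this generator does not model.

A small sparse-sampling path (`simulateSparseRun()`, `deconvolveBetas()`)
documents where β weights come from: each trial's volumes are an amplitude
times a fixed gamma-variate kernel `h(v) = (v/3)³ exp(3(1−v/3))` sampled
at the five acquisition volumes (peak at volume 3), and per-stimulus β
weights are recovered by an ordinary-least-squares finite-impulse-response
fit and summarized as the mean of the β of volumes 2–4 (1-based). The
kernel's parameters are a documented package choice; its only load-bearing
property is that the peak lies inside volumes 2–4 so that the averaging
rule captures the response.

## Assembly: balancing, scaling, folds

**Balancing.** Class counts are equalized at 20 examples per class per
subject: non-action sounds (10) are doubled, non-action videos (11) are
duplicated at random without replacement up to 20 (doubling is the special
case of a class at exactly half the target), action videos (23) are
randomly downsampled. The choices are made once at the stimulus level and
applied identically to every subject, so the balanced matrices are 560
examples for each sighted condition and 320 for the blind condition, and
chance level is exactly 50% by construction. Duplicates carry a
`duplicateOf` pointer and always inherit their original's fold, so a
stimulus never sits on both sides of a split.

**Scaling.** Every voxel is standardized across examples and passed
through a hyperbolic tangent, bounding values in (−1, 1), preserving
per-voxel example ranks and damping outliers. Whether the tanh was meant
to apply to raw or standardized β is not specified in the emulated
procedure; standardize-then-squash is this package's choice, since a tanh
of raw β in arbitrary BOLD units would have an arbitrary operating point.
By default the scaling is fitted on each condition's full balanced matrix
before fold splitting — mirroring the classical preprocessing order, which
leaks test-example means and variances into scaling; this is kept for
fidelity, and `scalingMode = "fold"` refits the scaler on each fold's
training examples for a leakage-free variant. Pantomime examples are
test-only and are scaled at evaluation time with the statistics of the
classifier's own training condition (for the pooled supramodal classifier:
the condition matching the pantomime's session type).

**Folds.** Stimuli are split into 4 subsets stratified by class (per-class
fold sizes differ by at most one). The fold unit is the stimulus, not the
example: a sound heard by all 22 subjects is wholly in train or wholly in
test. The auditory stimulus set receives one fold assignment shared by the
sighted and blind auditory conditions, so cross-group evaluation never
tests on a sound that was a training stimulus for the other group.

## The classifier and its contract

The SVM minimizes `½‖w‖² + C Σ max(0, 1 − yᵢ(w·xᵢ + b))` with an
unpenalized bias. `C` is data-driven: the reciprocal mean squared example
norm, recomputed at every RFE iteration from the surviving-feature
training submatrix — the "small, fixed, data-driven" soft-margin
convention. The optimization contract is the objective, not a particular
solver: the implementation is sequential minimal optimization with
second-order working-set selection on a precomputed Gram matrix, and the
test suite pins it (to 1e−5 on the objective) against an independent
projected-gradient QP oracle that certifies itself through its
primal–dual gap, and cross-checks weights against a second, independently
developed SVM library. Prediction is the sign of the decision value, with
an exact zero resolved to the positive ("action") class — a documented,
tested tie rule. The Gram-matrix formulation is what makes the pipeline
fast: eliminating features downdates `K` by a rank-r update instead of
recomputing the kernel, so a full elimination run costs little more than
one kernel evaluation.

## RFE, cluster correction, nested CV

Each RFE iteration trains on the surviving voxels, records accuracy on the
fold's test subset (before that iteration's elimination), discards the 2%
of features with the smallest |w| (at least one, so the loop terminates;
ties break toward the lower voxel index for reproducibility), and applies
a cluster correction that deletes connected components smaller than a
minimum size. "Nearest neighbour" connectivity is read as face adjacency
(6-connectivity), with 18- and 26-neighbourhoods available. The whole-brain
minimum of 150 voxels (1,200 µL at 2 mm isometric) is the convention for
real group-space data; on a 12³ synthetic grid the pipeline default is a
grid-proportional 5 voxels. Elimination proceeds until the set is empty.

Nested CV wraps this: for each of the 4 folds and each condition, one RFE
run; the best iteration per classifier is the accuracy argmax, with ties
resolved toward the most pruned feature set (the parsimony convention —
feature-set sizes decrease strictly, so the last tied iteration is the
smallest such set). The best fold is the one with the highest mean best
accuracy across the three classifiers; per-condition means ± SD across
folds are reported alongside. Whether the emulated procedure selected the
RFE iteration jointly across the three classifiers or per classifier is
ambiguous; per-classifier argmax is the default and `jointIteration =
TRUE` selects one shared iteration by the across-classifier mean.

### Limits of accuracy-guided selection

A property worth knowing before trusting any RFE map: when the signal is
strong enough that fold-test accuracy saturates at 1.0 (d' ≳ 3, i.e. a
handful of voxels at effect 1.0 over noise 0.5), the accuracy trace is
flat over a long stretch of the elimination path and "highest accuracy"
cannot identify the informative set — any tie-break is arbitrary, and the
selected set may be much smaller or larger than the planted one.
Moreover, with many mutually redundant informative voxels the SVM
concentrates weight on a minimal predictive subset, so redundant true
voxels can be eliminated while tail noise voxels persist. On the
`recovery` scenario the Jaccard overlap between the selected set and the
planted set therefore stays low regardless of how the tie inside the
plateau is resolved (the acceptance script reports the measured value).
The recovery unit test instead demonstrates ground-truth recovery in the
identifiable regime (effect ~0.3, accuracy off ceiling, median Jaccard ≥
0.5), and the saturated regime is reported as a documented limitation of
accuracy-guided RFE rather than hidden by a tuned threshold.

## Supramodal classifier and the knock-out procedure

The combined supramodal classifier runs the same RFE on the best fold's
training data pooled across the three conditions (balanced classes pool to
balanced classes; no re-balancing), evaluated on the pooled test set. Its
selected voxels form the **knock-out mask**. Two re-analyses probe what
that mask carries:

* **Exclusion** — each condition's best map minus the mask, classifier
  retrained on the survivors ("removal" is re-fitting on the reduced
  feature set, the natural reading of rebuilding a classifier on a
  reduced volume of interest, and the stated procedure for the restricted
  case). An exclusion that empties a map yields a defined chance accuracy
  of 0.5 with a warning flag.
* **Restriction** — classifiers rebuilt on the mask voxels only, filling
  the full 3×3 within/across table: each model applied to every
  condition's best-fold test examples.

If the shared code lives in the mask, exclusion should lower
within-condition accuracy (tested per condition with a Wilcoxon
signed-rank over per-subject test accuracies, aggregated with Fisher's
method) while restriction should make the across-condition cells
significant. Pantomime examples, never used in training, are classified
by all variants; the fraction labelled "action" is tested against 0.5 by
a label-permutation test and by an exact binomial test (the conservative
check for an unbalanced, single-class test set). The pairing unit of the
Wilcoxon comparison is the subject (14/14/8 per condition); per-fold
pairing would confound the comparison with fold selection, and
per-example accuracies are Bernoulli, for which a signed-rank test is
inappropriate.

## Inference layer

Accuracy significance uses label permutations that shuffle **training**
labels only and retrain on the already-selected feature set (n = 500 at
study scale, 99 in the scaled-down test suites), with the add-one
estimator `p = (1 + #{null ≥ observed})/(n + 1)` — never zero, invariant
under monotone transforms of the score, and centred at 0.5 under the
balanced design. Permuting only the training side keeps the test labels
(and hence the evaluation geometry) fixed, which is the appropriate null
for "did training extract label information". The Wilcoxon implementation
drops zero differences, uses the exact signed-rank distribution up to 25
untied differences and a tie-corrected normal approximation beyond;
Fisher combination refers `−2Σlog p` to χ² with 2k degrees of freedom
(zero p-values are refused — add-one permutation p-values cannot be
zero). Binomial tails are exact. Every stochastic step takes an explicit
seed; a run is fully reproducible from (configuration, seed), and the
test suite asserts byte-identical reports for repeated runs.

## Numerical choices

* SMO tolerance 1e−6 on the KKT gap by default (1e−8 for the standalone
  trainer), tightened to 1e−10 where tests compare objectives; training is
  then permutation-invariant to example order within 1e−6 on w.
* Gram downdating accumulates floating error across ~200 rank-r updates;
  at the matrix magnitudes involved (‖x‖² ≈ 10²–10³) the drift is orders
  of magnitude below the solver tolerance.
* A surviving feature set whose training submatrix is numerically
  all-zero (possible after tanh scaling maps constant voxels to 0) stops
  the elimination loop rather than dividing by a zero mean norm.
* Accuracy ties in best-fold selection resolve to the first fold; |w|
  ties in elimination resolve to the lower voxel index; a decision value
  of exactly 0 predicts "action". All three rules exist to make the
  pipeline a pure function of (data, configuration, seed).

## Desk-scale problem sizes

The shipped defaults run the full study on a 12³ grid (1,728 voxels,
1,496 examples) in well under a minute for the fit stage and a few
minutes including all permutation tests on one CPU; the acceptance script
and test suite use these sizes, with 10-seed replication where the check
is about recovery rather than calibration. These sizes are the package's
chosen demonstration scale: they keep every experiment reproducible
interactively while leaving the algorithmic path identical to a
whole-brain analysis (where `minClusterVoxels = 150` and `nPerm = 500`
apply).

## Known limitations

* The generator's Gaussian, spatially white noise makes decoding easier
  per unit effect than real BOLD noise would; reported synthetic
  accuracies are not forecasts for scanner data.
* Accuracy-guided RFE selection is unidentifiable at saturation (above).
* Condition-level tanh scaling reproduces a preprocessing leak of the
  emulated procedure; use `scalingMode = "fold"` for clean estimates.
* Cross-group transfer in the generator is governed entirely by the
  shared sets; group-idiosyncratic representations are not modelled.
* No spatial smoothing, anatomical warping, atlas labelling or surface
  rendering: the pipeline starts at β patterns on a common grid and ends
  at accuracy tables, p-values and NIfTI maps.
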