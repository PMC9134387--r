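---
title: "Snapshot-image feature fusion for QSAR regression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot-image feature fusion for QSAR regression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

`snapqsar` implements a combination QSAR workflow for continuous
endpoints such as pharmacokinetic clearance (CL, L/h/kg), regressed on the
base-10 logarithm of the endpoint. Two feature channels are fused:

1. **Molecular descriptors.** A table of numeric 2D/3D descriptors is
   computed per compound and filtered (non-numeric columns, columns with
   zero variance on the training rows, and named leakage-risk columns are
   removed).
2. **An image-derived probability.** Each compound's single 3D conformer
   is rendered as a set of ball-and-stick snapshot PNGs taken at fixed
   rotation increments about the x, y and z axes. A binary classifier —
   trained on these images against a thresholded version of the endpoint
   (e.g. CL above 1 L/h/kg) — scores every snapshot, and the compound's
   *prediction probability* is the median of its per-image scores. That
   scalar is appended to the descriptor table as one extra column,
   `deepsnap_probability`.

The *combination model* is the regression fit on descriptors plus the
probability; the *descriptor-only model* is its control. Both are fit by
an algorithm competition (elastic net, random forest, gradient boosting,
support-vector regression, shallow neural network) in which the entrant
with the lowest stratified five-fold cross-validated RMSE wins; ties go
to the earlier registry position. Feature relevance is measured by
permutation importance, normalized within each model so the top feature
scores exactly 1, and averaged over the five split patterns ("average
effect").

## The nested split topology

The library is divided by stratified random sampling into five folds of
near-equal size. Each of five *patterns* holds out one fold as the
external test set (20%) and trains on the remaining four (80%). Within a
pattern's training set:

* the image classifier uses a stratified 3:1 train/validation split
  (stratified on the class label);
* the regression reserves a stratified 20% hold-out, and the remainder
  carries a stratified five-fold CV assignment used by the competition.

With 1545 compounds this gives folds of 309, per-pattern training/test
sets of 1236/309, classifier splits of 927/309, and hold-outs of
247 = round(0.2 × 1236) — cardinalities the test suite pins exactly.
Every compound appears in exactly one external test fold, so the five
patterns jointly cover the library.

Two deterministic choices close gaps the topology alone does not fix:
fractional part sizes are resolved by controlled rounding — overall part
sizes follow the largest-remainder rule exactly, and each stratum's
allocation to every part stays within one compound of its proportional
share (a remainder-greedy pass plus, where the greedy dead-ends, a unit
feasibility flow; such a rounding always exists because the constraint
matrix is totally unimodular) — and the regression stratification
variable is the quintile
bin of the log endpoint — the class label would be too coarse to balance
a continuous target. One master seed expands into per-stage sub-seeds by
fixed offsets, so the entire plan is a pure function of one integer.

## Rendering

The renderer is a deterministic software rasterizer: orthographic
projection, painter's-algorithm depth ordering on primitive centers,
atoms as radially shaded disks at 23% of the element van der Waals
radius in a CPK-like palette (unknown elements magenta), bonds as
flat-shaded half-cylinders colored by the nearer atom, black background.
Rotation is applied about x, then y, then z (right-handed, degrees,
reduced mod 360 so a full turn is the exact identity). At 100% zoom the
molecule's bounding sphere fills 90% of the image edge; zoom scales
linearly. Coordinates are centered on the geometric centroid and then
quantized to 10^-6 Å, which makes the output byte-stable under
translation of the input coordinates. Per axis, snapshot angles are
0, θ, 2θ, … strictly below 360° (360° duplicates 0° and is excluded —
the conventional 145° increment gives exactly 3³ = 27 views only under
exclusion); the angle grid is their Cartesian product in lexicographic
order.

A note on the bond radius: the snapshot protocol this follows lists a
bond radius of 15 mÅ, which taken literally (0.015 Å) is nearly
invisible at 256 px. The default here is 0.15 Å; the parameter is
exposed in `render_params()`. The perception thresholds
`min_bond_distance` (0.4) and `bond_tolerance` (0.8) are honored only
when a record carries no connectivity table, in which case bonds are
perceived from interatomic distances against covalent-radius sums.

## Conformers

One conformer per compound: connectivity (with explicit hydrogens) is
embedded in 3D by seeded ETKDG distance geometry followed by MMFF94
force-field minimization (UFF fallback for exotic atoms), via a bundled
RDKit helper — a single low-energy geometry is all the snapshot
procedure consumes. The embedding is a pure function of (connectivity,
seed): per-molecule seeding makes batch and single-molecule calls
bitwise-identical, and retries perturb the seed by a fixed offset.
Multi-fragment inputs (salts) are stripped to the largest
covalent fragment, logged. Conformer ensembles and protonation-state
enumeration are out of scope.

## The classifier

The image model is deliberately compact: RGB snapshots are
block-averaged to a small square edge (default 16 px) and fed to a
one-hidden-layer perceptron (32 ReLU units, sigmoid output) trained with
Adam on per-image binary cross-entropy, each snapshot inheriting its
compound's label. The aggressive downscale acts as a pooling stage — it
trades ring-level detail for robustness to the pose changes the angle
grid induces, and empirically improves the per-compound median. The
method's contract is architecture-agnostic: per-image probability in,
median per compound out, with the checkpoint of the epoch with the
lowest validation loss retained (earliest epoch on ties). The default
learning rate (3e-3) suits this small network; it is far larger than
values used with deep pre-trained architectures, and both it and the
epoch budget are exposed in `classifier_config()`. Probabilities are raw
sigmoid outputs; no calibration is applied.

## The synthetic benchmark

`generate_library()` assembles molecules from a fixed grammar of 12
scaffolds (1–3 rings, including N/S/O heterocycles) crossed with 20
substituents at two sites (halogens, alkyl chains, H-bond donors and
acceptors, a basic amine, a carboxylic acid), and attaches

endpoint = exp(β₁·z(lipo) + β₂·z(polar) + γ·z(rings) + ε),  ε ~ N(0, noise_sd)

with β = (0.7, −0.5), γ = `image_signal_weight` (default 1), noise_sd
0.3, all on the natural-log scale, z() the within-library z-score. The
class label thresholds the endpoint at 1 (strict exceedance; a value
exactly at the threshold is negative). Scaffold and substituents are
drawn independently, so the ring-count term is (by construction)
independent structural signal.

The ring count was chosen as the image-visible term because it is
salient in ball-and-stick renders and can be withheld from the
descriptor table. Withholding it takes more than dropping `ring_count`:
kekulized double-bond counts, aromatic atom/bond counts, atom totals,
molecular weight, whole-molecule logP and the 3D size descriptors are
all strong ring surrogates, so `synthetic_withheld_descriptors()`
excludes that entire family (via the same leakage mechanism used for
endpoint-derived descriptors). What remains visible to the descriptor
arm — TPSA, donor/acceptor and heteroatom counts, halogen counts,
rotatable bonds, ionizable-group counts — covers the substituent-driven
β-terms but not the scaffold ring count. With γ > 0 the classifier
probability therefore carries information the descriptor arm cannot
reach, and the combination arm should win on external-test R² in at
least 4 of 5 patterns; with γ = 0 the probability is redundant with the
descriptors and the two arms should agree to within a small gap. Both
properties are asserted by the acceptance tests at the benchmark scale
(300 compounds, 64-px renders, 10 epochs) — sizes chosen so a full
two-arm, five-pattern run is comfortable on a single CPU.

What the generator does *not* emulate: the chemical-space distribution
of any real library, activity cliffs, measurement error structure,
tautomers/charge states, or mechanism-driven endpoint structure
(transporters, metabolism classes). Passing benchmarks therefore
demonstrate that the machinery — rendering, training, aggregation,
splitting, competition, importance — behaves as specified, not that the
combination approach will improve any particular real dataset.

## Metrics and numerical choices

* RMSE is sqrt(mean squared residual); it is the competition's selection
  metric.
* R² defaults to the squared Pearson correlation (the convention when a
  "correlation coefficient" R² is reported); the
  coefficient-of-determination variant is selectable, and both are
  returned in verbose mode. For degenerate constant predictions the
  Pearson variant is defined as 0.
* AUC is the rank-based Mann–Whitney statistic; ties contribute ½.
* The PCA chemical-space check standardizes the 11 representative
  descriptors (size, lipophilicity, polarity, H-bonding, aromaticity,
  flexibility, ionization proxies) and eigendecomposes the correlation
  matrix — the descriptors carry incommensurate units, so the covariance
  matrix would be dominated by molecular weight and TPSA.
* Permutation importance clamps negative raw importances to zero before
  normalizing; an all-zero importance vector (a model that ignores its
  inputs) is reported as an error rather than silently normalized.
* Missing descriptor cells are median-imputed and all features z-scored
  inside each competition entrant, with statistics frozen on the
  training rows; the descriptor table itself is never altered by
  filtering, which keeps the filter idempotent and auditable.
* The synthetic benchmark appends one seeded pure-noise column
  (`noise_control`) to both arms as a permutation-importance negative
  control.

## Known limitations

* The rasterizer is structure-faithful but not pixel-compatible with any
  external viewer; no anti-aliasing or perspective.
* The compact classifier is a contract implementation, not a
  state-of-the-art image model; with real libraries a stronger backbone
  can be substituted behind the same train/predict surface.
* Descriptor coverage (~35 columns) is an open, reproducible set; it
  does not attempt to reproduce any commercial descriptor by name.
* Ensembling supports the average method only; stacked generalized
  linear ensembles are out of scope.
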