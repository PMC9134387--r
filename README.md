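# snapqsar

Combination QSAR regression from two feature channels: molecular
descriptors plus a probability distilled from **multi-angle 3D snapshot
images** of each compound.

Some continuous ADMET endpoints — pharmacokinetic clearance (CL, in
L/h/kg, modelled as log₁₀ CL) is the motivating case — are hard to
regress from descriptor tables alone. `snapqsar` implements a workflow
that adds an image-derived feature: each compound's single 3D conformer
is rendered as a grid of ball-and-stick PNG snapshots taken at fixed
rotation increments (θx, θy, θz) about the three axes (145° per axis
gives 3³ = 27 views), a binary image classifier is trained against the
thresholded endpoint (CL > 1 L/h/kg), and the compound's *prediction
probability* — the **median** of its per-image classifier scores, taken
from the training checkpoint with the lowest validation loss — is
appended to the descriptor table as one extra column,
`deepsnap_probability`. The *combination model* is the regression on
descriptors + probability; the *descriptor-only model* is its control.

Evaluation uses a nested stratified split: five folds, five train/test
patterns (each fold is the external 20% test set exactly once), a 3:1
classifier train/validation split, a 20% regression hold-out and
stratified five-fold CV inside each pattern. Regressions are fit by an
algorithm competition (elastic net, random forest, gradient boosting,
SVR, shallow neural net) won by the lowest CV RMSE. Feature relevance is
permutation importance, normalized per pattern (top feature = 1) and
averaged over the five patterns (*average effect*). Metrics: RMSE
`√(Σ(yᵢ−ŷᵢ)²/n)`, R² (squared Pearson by default), rank-based AUC, and a
PCA chemical-space check on 11 representative descriptors.

A bundled synthetic compound generator (fragment grammar: 12 scaffolds
of 1–3 rings × 20 substituents, endpoint
`exp(β₁·z(lipo) + β₂·z(polar) + γ·z(rings) + ε)`) makes the whole
pipeline testable offline: with γ > 0 the ring-count term is visible in
images but withheld (with its structural surrogates) from the descriptor
table, so the probability feature carries information the descriptor arm
cannot reach.

## Worked example

A full five-pattern benchmark on 300 synthetic compounds (64-px renders,
27 angles, 10 training epochs), both arms:

```r
library(snapqsar)

cfg <- run_config(
  synth  = synth_config(n_compounds = 300, seed = 1, image_signal_weight = 1),
  seed   = 1,
  out_dir = "run300")
report <- run_pipeline(cfg)

report_summary(report, "test")
#>        method   mean_r2 mean_rmse
#> 1 combination 0.7375807 0.3963910
#> 2  descriptor 0.5064566 0.5332892

head(report$importance$combination$averaged, 4)
#>                 feature average_effect
#> 1  deepsnap_probability     1.00000000
#> 15                 tpsa     0.16533217
#> 10           n_nitrogen     0.10491712
#> 2                   hba     0.07714706
```

Reading this: averaged over the five external test folds, the
combination model explains R² ≈ 0.74 of log-endpoint variance at
RMSE ≈ 0.40 log units, against R² ≈ 0.51 / RMSE ≈ 0.53 for descriptors
alone — the gap is the ring-count signal that only the image channel
carries. The snapshot probability is the top-ranked feature in every
pattern (average effect exactly 1); the strongest descriptor (TPSA)
averages ≈ 0.17. Re-running the same `run_config` reuses every cached
stage and reproduces the report.

Per-pattern metrics, chosen algorithms, classifier checkpoints,
importance tables, the PCA variance fractions and the split plan are
written as CSV/TSV under `run300/report/`.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/snapqsar.R run-all --n-compounds 300 --seed 1 --out-dir run300
```

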