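---
title: "Estimating shoulder rotation angles from 2D pose landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating shoulder rotation angles from 2D pose landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Shoulder internal/external rotation — the humerus spinning about its long
axis with the arm at the side and the elbow flexed 90° — is the hardest
shoulder motion to measure from in front of the patient. The rotation axis
points at the observer, so the classic goniometer view is from above or
behind, which rules out casual video capture. Markerless pose estimators
(33-landmark full-body models) report only 2D image coordinates of joints,
and a rotation about an axis pointing at the camera barely moves most of
them.

What does move is the **wrist**. With the elbow held at 90°, the forearm
acts as a pointer rigidly attached to the humerus: at neutral rotation it
points at the camera and projects to almost nothing; as the shoulder
rotates by θ, the wrist swings laterally by `forearm_length · sin θ`. The
projected upper-arm/forearm parallelogram area therefore tracks `sin θ`,
and its *sign* (orientation of the cross product) distinguishes internal
(negative, by convention) from external rotation. `rotometry` builds this
insight into a feature set, regresses the rotation angle on it, and ships a
forward-kinematic simulator so the whole pipeline can be exercised and
tested without volunteer video.

## The seven features

All geometry lives in normalized image coordinates (x over image width, y
over image height, both in [0, 1], y down). With

- **a** = right shoulder → right elbow,
- **b** = right elbow → right wrist,
- **c** = right shoulder → right hip (the trunk),
- **d** = left shoulder → right shoulder,

the features are

| feature | definition | units |
|---|---|---|
| `norm_elbow_size` | `(a × b) / \|c\|²` | signed, dimensionless |
| `norm_shoulder_size` | `(a × d) / \|c\|²` | signed, dimensionless |
| `norm_forearm_distance` | `\|b\| / \|c\|` | dimensionless |
| `norm_uparm_distance` | `\|a\| / \|c\|` | dimensionless |
| `elbow_angle` | ∠(shoulder–elbow–wrist) | degrees, [0, 180] |
| `shoulder_angle` | ∠(elbow–shoulder–wrist) | degrees, [0, 180] |
| `trunk_angle` | ∠(left shoulder–right shoulder–hip) | degrees, [0, 180] |

where `×` is the signed 2D cross product `u_x v_y − u_y v_x`. Dividing by
the squared trunk length makes the area features invariant to uniform
image scale — and therefore largely insensitive to camera distance — since
the trunk does not move during rotation. All seven features are invariant
to translation and uniform scaling of the landmarks; the two signed ones
flip sign under horizontal mirroring, so a consistent (non-mirrored)
camera convention matters. The cross products are deliberately kept
*signed*: an unsigned area could not tell internal from external rotation,
which have opposite-signed correlations with the angle.

Features are computed in raw normalized coordinates without aspect-ratio
correction, matching the convention of the pose-estimator dialect the
package ingests. `compute_features()` works on one frame;
`extract_feature_table()` vectorizes over a whole table and skips (or
rejects, per configuration) geometrically degenerate frames. Exact neutral
rotation under a perfectly frontal orthographic view is one such
degeneracy: the forearm projects to a single point and the elbow angle is
undefined there.

## The synthetic study

The simulator stands in for the recorded cohort the method was designed
around, and its defaults are that study's design:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 10 | simulated volunteers |
| `angles_deg` | −50…50 by 10 | 11 target angles; internal rotation negative |
| `frames_per_clip` | 96 | ≈3 s at 30 fps; 10 × 11 × 96 = 10,560 frames |
| `landmark_noise_sd` | 0.002 | iid Gaussian jitter per coordinate, normalized units |
| `anthropometric_cv` | 0.05 | between-subject segment-length variation |
| `angle_hold_sd_deg` | 1.0 | within-clip wobble around the target angle |
| camera | pinhole, 2 m away, 1.5 m high, 65° horizontal FOV, portrait 1080×1920 | the tablet-on-tripod recording geometry |

Segment lengths derive from standard anthropometric proportions of a
1.683 m stature (the cohort mean height): trunk 0.288, biacromial width
0.245, upper arm 0.186, forearm 0.146 and shoulder height 0.818 of
stature. No segment lengths were reported for the cohort, so published
proportion tables are the least-arbitrary stand-in. `frames_per_clip = 96`
makes the default dataset (10,560 frames) approximate the reported 10,608;
per-clip frame counts were not published, and 10 × 11 × 2 s × 30 fps would
give only ≈6,600, so clips were evidently longer than the nominal 2 s.

Per subject, segment lengths are drawn once (Gaussian, CV 5%). Per frame,
the realized angle is target + wobble and is recorded as the ground truth;
the pose is projected; iid Gaussian jitter is added to every coordinate
and the result clamped to [0, 1]. The jitter emulates pose-estimator
noise. What the simulator deliberately does **not** model: temporal
correlation of estimator noise (no published data to calibrate it),
scapulothoracic rhythm, trunk sway, soft-tissue artifact, landmark
dropouts or left/right swaps. Passing tests on synthetic data therefore
demonstrate the pipeline's internal correctness and the geometric
mechanism — not clinical accuracy on human video.

Two projection models are provided. The **pinhole** camera (default)
emulates the recording geometry, including perspective parallax. The
**orthographic** camera exists for analytic property tests: under it the
signed area is exactly proportional to sin θ, the projected elbow angle is
exactly 90° for θ ≠ 0, and depth translations change nothing. One
consequence worth knowing: under perspective, the forearm points *toward*
the camera, so its parallax makes `norm_elbow_size` weakly
distance-dependent — a few percent of the feature's design range between
1.5 and 3 m, versus roughly half the range for the un-normalized area.
Trunk normalization absorbs the scale effect; it cannot absorb parallax.

## Models and evaluation

`split_features()` partitions the feature table 80/20. The default unit is
the frame, matching the per-image accounting of the emulated study; clip-
and subject-level splits are offered because frame-level splitting places
near-duplicate frames of the same clip on both sides of the split, which
flatters test metrics. Both the unit and seed are recorded.

Five regressors are wrapped behind one interface (`model_spec()`,
`fit_model()`, `predict()`), with the study's tuned hyperparameters as
defaults: ordinary least squares; elastic net (penalty 1e−5, L1 ratio
0.889 — numerically near-unpenalized); RBF-kernel support vector
regression (C 10, γ 0.0046, ε 0.1); random forest (squared error, depth
≤ 6, 10 trees); gradient-boosted trees (MAE objective, learning rate
0.076, depth ≤ 8). Values the study did not print use the conventional
defaults of the implementations here — 100 boosting rounds, all 7
candidate features per forest split — and every resolved value lands in
the run manifest. The "linear regression" hyperparameters circulating with
the study (L2 penalty, C = 1.0, lbfgs) describe a regularized *classifier*
configuration; this package implements plain least squares. SVR uses the
backend's standard feature standardization; the printed γ of 0.0046
matches a variance-scaled kernel width for these features (≈ 1/(7·Var)),
and with raw unstandardized features the radial kernel degrades markedly.

Evaluation (`eval_report()`) reports Pearson correlation and MAE between
predicted and true per-frame angles, residuals defined as actual −
predicted, a per-nominal-angle mean/SD/count table ordered by angle, and
the 8×8 feature/angle correlation matrix. The per-angle grouping key is
the clip's nominal target, the index used in per-angle residual tables;
the regression target, however, is the per-frame realized angle (target +
wobble), which is what the reference instrument measured frame by frame.
"Correlation coefficient" is implemented as Pearson product-moment, the
standard agreement index for regression; SDs are sample (n−1) SDs;
singleton groups report SD 0 with a flag.

### Attribution

Tree feature importance follows the per-tree normalization: within each
tree, a feature's summed split gain is divided by the tree's total gain;
the overall importance is the mean share over all trees (zero-split trees
contribute nothing and the result is renormalized to sum to 1). For
boosted models this is computed exactly from the per-tree gain tables; the
random-forest backend does not expose per-tree gains, so forests fall back
to ensemble-total impurity shares normalized to sum 1.

Shapley attributions for boosted models are computed by this package's
own double-precision implementation of the exact tree-path algorithm
(cover-weighted path traversal), operating on the tree structure extracted
from the booster. This is deliberate: the booster's native attribution
path runs in single precision, where the additivity identity
`base + Σ contributions = prediction` holds only to ≈1e−5 on predictions
of magnitude 50°. The package also *evaluates* boosted-tree predictions by
walking the same extracted trees in double precision, so predictions and
attributions are mutually consistent to ≈1e−12 (and agree with the
booster's own float32 predictions to ≈3e−5). The test suite cross-checks
the attribution matrix against the booster's native implementation. For
random forests an interventional permutation-sampling estimator is
provided (default 2,000 permutations against a background sample); its
telescoping construction satisfies additivity exactly at any permutation
count, while the attribution values themselves converge as permutations
grow.

## Numerical and design notes

- **Angle at a vertex** clamps the normalized dot product to [−1, 1]
  before `acos` to avoid NaN at numerically (anti)parallel arms; zero
  length arms raise a degenerate-geometry error naming the frame.
- **Serialization**: landmark coordinates are written with 9 decimal
  digits; write→read→write is byte-stable.
- **Reproducibility**: every stochastic stage (simulation, split,
  stochastic learners) takes an explicit seed, runs on a temporarily
  seeded RNG stream, and restores the caller's RNG state. Identical
  configurations produce byte-identical reports; the run manifest records
  config, seeds, resolved hyperparameters, row counts and file digests,
  and a re-run over an existing output directory reuses cached simulation
  and feature stages when those digests match.
- **Problem sizes**: the reference experiment (10,560 frames, five
  models, full report) runs in well under a minute on one CPU; the test
  suite's full-size runs are shared across test files through a memoized
  helper.

## Known limitations

- Synthetic validation only: the study's volunteer videos are not
  distributable, so all quantitative results here are measured on the
  simulator that emulates its design. The printed accuracies of the
  original study serve as benchmarks, not as quantities this package
  claims to reproduce on human data.
- Under the default jitter (sd 0.002 normalized units) the per-frame
  angle information carried by the features is noise-limited at roughly
  1.5–2° near neutral; no regressor can beat that floor on per-frame
  truth, whatever its capacity.
- The camera is assumed frontal. The sign and slope of the area–angle
  relationship change when subject and camera are not facing each other,
  and the landmark dialect carries no mirroring flag — consumers must
  ensure a consistent handedness convention.
- Only the five landmarks used by the features are validated; visibility
  scores are carried through but never used.
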