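# orientHAR

Activity recognition from body-worn inertial sensor units that is robust to
the **orientation** at which each unit is attached to the body.

Wearable units containing a tri-axial accelerometer, gyroscope and
magnetometer are routinely worn slightly (or completely) differently from
one session to the next — a watch rotated on the wrist, a phone flipped in a
pocket. A recognition pipeline trained on nominally oriented sensors
collapses when the units are re-oriented. `orientHAR` implements a
pre-processing transform that removes the dependence on the worn
orientation, together with the five standard alternatives it is compared
against and the full recognition pipeline needed to measure the effect.

## Method

For each sensor unit the per-sample orientation `R_n` (sensor frame →
North-East-Down Earth frame) is estimated by a complementary quaternion
filter: short-term gyroscope integration fused by a normalised weighted
average (weight `mu = 0.98`) with a long-term Gauss–Newton solution that
aligns the measured acceleration with Earth-down and the horizontal magnetic
field with North. A 1-s steady-state prefix (zero angular rate, first
sample's acceleration and magnetic field held) is prepended so the filter
starts converged.

Two orientation-invariant representations are then built:

* **Earth-frame sequences** — every sample of every tri-axial stream is
  re-expressed in the Earth frame, `v_E[n] = R_n v_S[n]` (9 channels per
  unit).
* **Differential quaternions** — the rotation between consecutive samples,
  expressed in the Earth frame by the similarity transformation
  `D_n = R_{n+1} R_n^T`, encoded as a unit quaternion `q_n` (4 channels per
  unit). If the unit is re-oriented by any constant rotation `P`, the
  estimated orientations become `R_n P`, and
  `D̃_n = (R_{n+1} P)(R_n P)^T = D_n` exactly — the representation cannot
  see the worn orientation.

The combined representation (9 + 4 = 13 channels per unit, 65 channels for
five units) feeds the standard pipeline: non-overlapping 5-s windows, 26
statistical features per channel (min, max, mean, variance, skewness,
kurtosis, autocorrelation at lags 5–50, five largest DFT peaks with their
frequencies), per-subject min–max normalisation to [0, 1], PCA down to
F = 30, one of seven classifiers (SVM, three-layer neural network, Gaussian
and linear discriminants, k-NN, random forest, sparse-representation/OMP),
and leave-one-subject-out cross-validation.

Comparison transforms: none (reference), random re-orientation, per-sample
Euclidean norms, projection along/perpendicular to the estimated gravity
direction, and SVD-derived principal axes.

A synthetic IMU generator produces multi-subject, multi-activity datasets
with *known* ground-truth orientation trajectories (gyroscope = exact
body-frame angular velocity, accelerometer = `R^T (g_E + a_E)`,
magnetometer = `R^T m_E`), so every claim is testable without any data
download.

## Worked example

```r
library(orientHAR)

ds <- simulate_har_data(n_subjects = 4, n_classes = 6, minutes = 0.5,
                        units = 3, seed = 11)
ds
#> Synthetic activity dataset: 4 subjects x 6 activities, 3 units, 750 samples at 25 Hz per recording

# every 5-s window of every unit gets an independent random orientation;
# the proposed transform is applied before feature extraction
har_evaluate(ds, technique = "proposed", spec = classifier_spec("svm"),
             seed = 11, rotate = "segment", stationary_classes = 1:3)
#> Leave-one-subject-out evaluation
#>   technique: proposed   classifier: svm   (randomly re-oriented units)
#>   accuracy: 68.8% +/- 4.1% over 4 folds (overall 68.8%)
#>   stationary: 40.3%   non-stationary: 97.2%

# the fixed-orientation baseline on the same data
har_evaluate(ds, technique = "reference", spec = classifier_spec("svm"),
             seed = 11)
#> Leave-one-subject-out evaluation
#>   technique: reference   classifier: svm
#>   accuracy: 100.0% +/- 0.0% over 4 folds (overall 100.0%)
#>   stationary: 100.0%   non-stationary: 100.0%
```

The numbers tell the method's story in miniature: with nominally oriented
units everything is separable; once units are worn at arbitrary
orientations, motion activities are still recognised almost perfectly from
the orientation-invariant representation (97.2%), while static postures —
whose identity *is* their orientation — lose most of their information
(40.3%), and the overall accuracy settles in between.

`har_benchmark()` runs the full seven-technique comparison on the paper-shaped
synthetic dataset (8 subjects × 19 activities, 5 units), and
`inst/cli/har.R` exposes `simulate | transform | extract | evaluate |
replicate` subcommands for shell use. `replicate` accepts a user-supplied
directory containing a real recorded dataset in the `aXX/pY/sZZ.txt` layout
and reruns the whole technique × classifier grid on it; nothing is ever
downloaded.

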