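---
title: "Methods: the markerless gait pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the markerless gait pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posegait)
```

This vignette documents the model behind `posegait`, its assumptions, every
tunable parameter, the synthetic generators used for validation, and the
numerical conventions that make results reproducible.

## 1. Problem and model

A pose estimator applied to monocular video yields, per frame, 3D coordinates
and a visibility score in [0, 1] for each body landmark. `posegait` consumes
eight of these (left/right shoulders, hips, knees, ankles) and estimates:

* four sagittal-plane angle time series (knee and hip, each body side),
* discrete gait parameters: joint flexions (range of motion) and striding
  speed (stride frequency),
* optionally, a Hotelling T² atypicality score against a reference cohort.

The central difficulty of the markerless setting is that the side of the body
facing away from the camera (the *far* side) is frequently self-occluded:
its keypoints are noisy or absent, and naive angle computation produces
artefacts. The pipeline addresses this with visibility-gated Kalman filtering
followed by harmonic-domain denoising.

### 1.1 Angle definitions

* **Knee angle**: the included angle at the knee between the knee→hip and
  knee→ankle vectors; 180° is a straight leg.
* **Hip angle**: the angle between the thigh (hip→knee) and a **virtual
  forward vector** — the left→right shoulder vector rotated 90° about the
  vertical axis (right-hand rule), projected to the horizontal plane and
  normalised. A shoulder–hip–knee angle would saturate at 180° and fold back
  whenever the thigh crosses the trunk line, destroying the signal's
  periodicity; referencing the horizontal forward ray keeps the angle
  monotone through that crossing. The rotation's handedness is disambiguated
  globally: if the mean forward vector opposes the net hip-centre
  displacement over the clip, it is flipped.

All angles use `acos` of a clamped cosine, so collinear inputs yield exactly
0° or 180° rather than `NaN`. Angles are invariant to rigid translation and
to rotation about the vertical axis (tested).

A signal's per-frame visibility is the **minimum** over its constituent
joints (knee: hip, knee, ankle; hip: both shoulders, hip, knee): the least
reliable landmark governs downstream gating. The *near* side is the one with
greater mean lower-limb visibility; ties fall back to a caller-supplied depth
axis, then to "left".

### 1.2 Kalman filter with missing-measurement substitution

Each signal passes through a discrete constant-acceleration Kalman filter
with state $S = (\theta, \dot\theta, \ddot\theta)$:

$$A = \begin{pmatrix} 1 & \Delta t & \Delta t^2/2 \\ 0 & 1 & \Delta t \\ 0 & 0 & 1 \end{pmatrix},
\quad H = (1, 0, 0), \quad Q = \alpha I_3, \quad R = \beta,$$

with $\Delta t = 1/\text{fps}$ and initial covariance $P_0 = 100 I_3$. The
filter seeds at the first frame whose visibility reaches the threshold; any
prefix before it is back-filled with the seed value.

When a frame's visibility falls below the threshold (default **0.40**) the
measurement is replaced:

* **KF1** substitutes the *prior* estimate $H \hat S_t^-$ (the prediction);
* **KF2** (default) substitutes the *previous posterior* estimate
  $H \hat S_{t-1}$.

KF1's substitution feeds the filter its own extrapolation, so during long
occlusions the constant-acceleration prior runs away; KF2 anchors to the last
committed estimate and degrades more gracefully. On synthetic occluded
signals (100 seeded dropout placements, 15-frame occlusions) KF2's mean RMSE
inside the occlusion windows is ~19 % lower than KF1's — this ordering is an
acceptance test. With no sub-threshold frames the two are identical.

Each body side has its own noise pair, reflecting the far side's higher
measurement noise. Defaults: far $\alpha = 10^{-2}, \beta = 10^{-3}$
(trust measurements little, smooth hard), near $\alpha = 10, \beta = 1$
(track measurements closely). `noise_grid_search()` re-runs the pairwise
(α, β) tuning against gold-standard signals, scoring each cell by summed
normalised DTW and percentage error.

The filter logs the fed measurement sequence (`z`) and a `measured` flag per
frame, so the substitution rule is directly assertable from the output.
Output angles are clamped to [0, 180].

### 1.3 Frequency-domain filter (FDF)

After the Kalman stage, the first `floor(cut · length)` frames (default
`cut = 0.10`) are dropped: they contain the filter's convergence transient.
The remainder is denoised by **least-RMSE DFT component selection**: keep the
`N` (default **5**) frequency components whose removal would cost the most
reconstruction RMSE — by Parseval, exactly the `N` largest combined-magnitude
components (a component is a conjugate bin pair; DC and Nyquist count once).
Ties break to the lower frequency index. Reconstruction inverts the sparse
spectrum; by construction the result is real.

Walking signals are quasi-periodic with energy concentrated in the stride
fundamental and its first few harmonics, so five components suffice; the
selection is provably optimal among all N-subsets (tested against exhaustive
subset search up to length 32).

### 1.4 Discrete gait parameters

* **Flexion** = max − min of a filtered signal (degrees of range of motion).
* **Striding speed** = the dominant non-DC frequency of the near-hip
  selection, $k \cdot \text{fps} / m$ strides per second. The near hip is the
  most reliable periodic signal; a selection with no non-DC energy raises a
  `posegait_noperiod_error` rather than inventing a frequency.

### 1.5 Feature model and T²

The 8-feature vector (age, mass, height, four flexions, striding speed) mixes
years, kilograms, metres, degrees and hertz, so features are z-scored before
PCA. Components are retained in decreasing eigenvalue order until cumulative
explained variance reaches `variance_threshold` (default **0.90**; at least
one). Models are fit per gender stratum. The score

$$T^2 = \sum_{i=1}^{d_2} \frac{t_i^2}{\lambda_i}$$

is the squared Mahalanobis distance in the retained subspace: 0 at the cohort
mean, the squared z-score in the univariate case, and the full Mahalanobis
distance under complete retention (all three are acceptance tests).
Loading signs are fixed deterministically (largest-magnitude coordinate made
positive) so serialised models are stable. `loo_t2()` performs leave-one-out
cross-validation; an optional per-component normalisation
(`t2_normalisation = "per_pc"`) divides by the retained dimension for
comparisons across thresholds.

### 1.6 Agreement metrics

* **Percentage error**: per (sample, joint), frame-wise RMSE divided by the
  gold signal's range; averaged over joints within a sample, then over
  samples, × 100. Scale-covariant; a constant offset `c` against a gold range
  `R` gives exactly `100 c / R` %.
* **DTW**: classic dynamic programming with cost $|G_i - P_j|$, first
  row/column by cumulative sum, each cell extending the cheapest of left,
  diagonal, lower neighbours; normalised by `len(g) + len(p)`.
* **Missing values** are filled before scoring: by the signal mean for PE
  (gaps should not inflate squared error) and by last-observation-carried-
  forward for DTW (preserving local shape).
* **Bland–Altman**: mean difference, SD, limits of agreement
  $\bar d \pm 1.96 s_d$, t-based CI for the mean, LoA CIs with
  $SE = \sqrt{3 s_d^2 / n}$, and a Kolmogorov–Smirnov normality p-value for
  the differences. Differences are pred − gold; relative mode divides by
  gold.
* **`pc_cosine_similarity()`**: absolute cosine between corresponding PC
  loading vectors of two models (absolute value absorbs PCA's sign
  ambiguity).

## 2. Configuration reference

| Parameter | Default | Units | Role |
|---|---|---|---|
| `fps` | 30 | frames/s | frame rate; sets $\Delta t$ and DFT bin width |
| `visibility_threshold` | 0.40 | — | below it, a frame's measurement is substituted |
| `cut` | 0.10 | fraction | leading frames dropped before the FDF |
| `n_components` | 5 | count | DFT components kept by the FDF |
| `alpha_far`, `beta_far` | 1e-2, 1e-3 | deg² | far-side process / measurement noise |
| `alpha_near`, `beta_near` | 10, 1 | deg² | near-side process / measurement noise |
| `kf_mode` | "KF2" | — | missing-measurement substitution strategy |
| `p0_scale` | 100 | — | initial covariance $P_0 = 100 I$ |
| `variance_threshold` | 0.90 | fraction | PCA retention criterion |
| `t2_normalisation` | "none" | — | optional per-component T² normalisation |
| `vertical_axis` | "+y" | — | up direction for the forward-vector rotation |
| `pose_estimator_passthrough` | empty | — | free-form record of upstream estimator settings (not interpreted) |

## 3. Synthetic generators

The test and acceptance surface is built entirely on three generators.

* **`generate_gait_signal()`**: a cosine composition
  $\theta(t) = \text{offset} + \sum_j a_j \cos(2\pi m_j f t / \text{fps} + \phi_j)$
  plus seeded Gaussian noise, with the noiseless `truth` kept alongside and
  visibility dropout windows emulating occlusion. This captures the
  quasi-periodicity and noise of real angle signals; it does **not** emulate
  estimator-specific artefacts (depth jitter correlated across joints,
  identity swaps, soft-tissue artefacts).
* **`generate_walker()`**: forward kinematics. Hips advance along +x at
  constant speed; +y is up, +z is camera depth. Prescribed hip/knee angle
  profiles place knees and ankles by exactly the angle definitions of the
  kinematics stage, so extraction inverts the construction to machine
  precision at zero noise — making end-to-end recovery a sharp test. The
  left side runs in antiphase (fundamental phase shifted by π) with distinct
  noise seeds; the far side is offset in depth and given lower visibility.
  Profiles must stay inside (0°, 180°): the arccos-based recovery cannot
  distinguish a fold across those boundaries, so out-of-range profiles are
  rejected rather than silently folded.
* **`generate_cohort()`**: seeded truncated-Gaussian feature vectors per
  gender stratum (young-adult defaults: stride ≈ 0.9 strides/s, knee ROM
  ≈ 60°, hip ≈ 30°). Features are drawn independently; real gait features
  are correlated, so cohort PCA structure here is near-isotropic — adequate
  for testing the algebra, not for clinical reference ranges.

### 3.1 Stride-aligned windows

Several exactness tests use 111-frame sequences at 30 fps: after the 10 %
cut (11 frames) the 100 analysed frames hold exactly three 0.9 Hz strides.
The fundamental then falls on a DFT bin, the FDF reconstruction of a
band-limited profile closes to ~1e-13, and the stride frequency is read
exactly. On non-aligned windows spectral leakage spreads the fundamental
across bins, and range-of-motion error grows to the order of a degree — a
window-length artefact of the DFT, not an implementation error. Tolerances
on aligned windows are therefore tight (0.5° ROM, one bin of frequency);
real recordings should use the longest practical window to shrink both
leakage and the bin width `fps / frames`.

## 4. Numerical conventions

* DFT component energy counts conjugate pairs doubly; DC and (for even
  lengths) Nyquist singly. Selection ties break to the lower index;
  dominant-frequency ties break to the lower frequency.
* `floor()` in the cut; at least 2 frames must survive.
* Kalman covariance is re-symmetrised after each update
  (`P ← (P + Pᵀ)/2`); positive semidefiniteness over 10⁴ steps is tested.
* LoA confidence intervals use the classical $\sqrt{3 s^2/n}$ standard
  error; the 1.96 multiplier is literal (not a t quantile), per the standard
  Bland–Altman formulation.
* JSON serialisation uses full precision (`digits = NA`).

## 5. Problem sizes and limitations

Typical clip: 100–300 frames × 8 joints — milliseconds through the filters.
DTW is O(nm) with dense matrices: fine for signal lengths in the hundreds,
not intended for hour-long recordings. LOO T² refits one PCA per sample:
O(n · d³), trivial for cohorts of tens to hundreds.

Out of scope: the pose estimator itself (consumed through the keypoint file
contract; estimator settings ride along in `pose_estimator_passthrough`),
video decoding, coronal-plane analysis, and clinical normative data — the
shipped benchmark table and synthetic cohorts exercise the machinery, they
are not reference values for diagnosis.
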