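---
title: "Dual-stage suppression of bSSFP banding and flow artifacts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stage suppression of bSSFP banding and flow artifacts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, assumptions, numerical choices and
limitations behind `cinebands`. It states no empirical result beyond what
the package's tests and `scripts/acceptance.R` themselves compute.

## 1. The physics being emulated

### 1.1 Spectral profile

The steady-state bSSFP magnitude is the classical Freeman–Hill closed
form. With `E1 = exp(-TR/T1)`, `E2 = exp(-TR/T2)`, flip angle α and
per-repetition precession `β = 2π·Δf·TR`, the RF-phase-alternated signal
sampled at `TE = TR/2` is

```
S(β) = sinα (1−E1) √(1 + 2 E2 cosβ + E2²)
       ───────────────────────────────────────────────  · e^(−TE/T2)
       (1−E1 cosα)(1+E2 cosβ) − (E1−cosα)(E2+cosβ) E2
```

so the pass-band sits on resonance and the dark band at `β = π`, i.e. at
off-resonance `±1/(2TR)`. The implementation (`bssfp_profile`) is
cross-checked in the test suite against an independent oracle — direct
fixed-point iteration of the Bloch rotation/relaxation recursion with
alternating RF phase — and agrees to ~1e-8 relative error; the band
location is additionally verified by brute-force grid minimization.

The default TR is `1000/330 ≈ 3.0303` ms, chosen so that the 12-offset
sweep grid has exactly 27.5 Hz spacing and reaches the printed offsets
(±137.5, ±110, ±82.5, ±55, ±27.5, 0, 165 Hz); TE = TR/2 and flip 60° are
the standard balanced choice.

### 1.2 Phantom

`make_phantom` builds a short-axis scene on an H×W grid over `n_phases`
cardiac phases (default 48×48×25): a myocardial annulus whose inner
radius contracts by `motion_amp` (default 30 %) at mid-cycle with a
smooth, periodic `sin²` time course (phase 1 = end-diastole; end-systole
is the phase of minimal blood-pool area), a blood pool, a
descending-aorta analog (both marked as through-plane flow), a
subcutaneous fat rim and a liver-like abdomen. Tissue parameters are 3T
textbook values (myocardium T1/T2 1400/45 ms, blood 1900/250, fat
370/130, abdomen 800/40) with relative proton densities.

The static field map is an in-plane linear ramp (±55 Hz across the image,
seeded direction) plus a Gaussian susceptibility blob of 140 Hz amplitude
placed near the anterior body wall, away from the heart. The blob
amplitude matters: it is what decides whether any tissue ever bands
*inside* the SPC coverage. Air–tissue interfaces at 3T easily produce
1 ppm ≈ 130 Hz excursions, so with 140 Hz the phantom genuinely contains
regions where short-range cycling retains residual banding while the
heart — as in real mid-ventricular slices — stays band-free at the
central offsets. A per-subject jitter (default 8 %) randomizes radii,
centres, ramp and blob under the subject seed.

### 1.3 Artifacts

Rendering (`render_cine`) evaluates the spectral profile at
`field_map + offset` per voxel and adds Rician noise (magnitude of
complex Gaussian, default σ = 2 % of the on-resonance blood signal).

Flow ghosts (`add_flow_artifact`) are modeled phenomenologically, not by
Bloch simulation of moving spins: the ghost source at a flow voxel is its
*band weight* `1 − S(local offres)/S_max` (1 at a band centre, 0 away
from bands) times the **on-resonance** blood signal — flowing spins enter
the slice unsaturated, which is exactly why their ghosts are bright while
the banded voxel beneath them is dark. The source is replicated at
`ghost_count` equispaced circular shifts along the phase-encoding axis
with amplitude `ghost_gain` (defaults 3 and 0.6). Two consequences are
asserted as invariants: ghosts vanish when flow and bands are disjoint,
and ghost energy appears only along the PE axis.

What the generator does **not** emulate: k-space acquisition, coil
sensitivities, respiratory motion, partial-volume edges, in-plane flow,
hypointense flow artifacts, and realistic anatomy. Passing tests
demonstrate that the method behaves as designed under this artifact
model; they are not evidence about any particular scanner or cohort.

## 2. Label synthesis

`spc_combine` averages the movies with `|offset| ≤ 55 Hz` — selection is
by frequency band rather than index so it generalizes to other grids; on
the default 12-offset grid this is exactly {0, ±27.5, ±55} Hz, five
movies, covering almost half the spectral period. `fpc_combine` averages
all twelve. Both are plain magnitude means (complex-valued combination is
out of scope).

The VI label is the elementwise logistic

```
VI = sigmoid( SPC / max(original, ε) − 1 ),   ε = 1e-3 · P99(original)
```

with the logit argument clamped at 30 so that deep-band ratios cannot
round to exactly 1.0 in double precision. With non-negative magnitudes
the label lives in `(sigmoid(−1), 1) ≈ (0.269, 1)`: bands map near 1,
bright ghosts toward 0.269, artifact-free voxels to exactly 0.5 where
SPC equals the original. The asymmetry (flow can never reach 0) is a
property of the formula itself, worth keeping in mind when thresholding
VI maps; a plain unscaled logistic is used deliberately.

`preprocess` normalizes each movie by its own 99th percentile (robust to
ghost hot-spots) and records the factor; AS labels are scaled by the same
factor as their movie so input and target share one intensity scale,
while VI labels are computed from raw intensities (the ratio cancels any
common scale).

## 3. The dual-stage network

Both sub-networks share a 3D U-Net backbone: `depth` resolution levels
(default 3), two 3×3×3 convolutions + leaky-ReLU (slope 0.1) per level,
2×2 in-plane average pooling, nearest-neighbour upsampling, skip
concatenation, and a 1×1×1 output convolution. Channels start at
`base_channels` (default 16) and double per level. Convolutions span
(cardiac phase, row, column) with **circular padding along the phase
axis** — a retrospectively gated cine loop is periodic, and the test
suite asserts the resulting equivariance to loop rotation — and zero
padding in-plane.

Design choices where the design was open:

* **No normalization layers, nearest-neighbour upsampling.** At this
  scale the network trains stably without instance norm, and the leaner
  backward pass is verified *exactly* against central finite differences
  (relative error ~1e-7) — a guarantee that would be costlier to maintain
  with more layer types.
* **Heads.** VI ends in a sigmoid, so the (0,1) range of the VI map is
  architectural. AS ends in a *non-negative linear* head: a linear 1×1×1
  convolution whose output is clamped at 0 at the module boundary
  (`as_forward`). Saturating non-negative activations (softplus, hard
  ReLU at the loss) were rejected empirically: under L1 loss, Adam's
  sign-driven coordinated updates overshoot the pre-activation into the
  zero-gradient region during the first epoch and training freezes at
  the trivial constant; the linear head cannot die and the clamp still
  guarantees a valid magnitude image.
* **AS predicts the image directly**, not a residual; the channel
  contract (movie + VI map, exactly 2 channels) is enforced at build and
  call time, so silently dropping the conditioning is impossible.
* Implementation: convolutions are evaluated tap-by-tap as 27 shifted
  GEMMs (RcppArmadillo/OpenBLAS) with contiguous tile copies; He-normal
  initialization is driven by a single seed, making builds bit-
  reproducible.

## 4. Two-stage training

Stage 1 fits the VI network to the soft VI labels with MSE — the natural
loss for regression onto (0,1) soft targets. Stage 2 freezes the VI
parameters (asserted bit-identical before/after) and fits the AS network
to the SPC labels with L1, the standard restoration loss; the frozen VI
map is precomputed once per sample. Optimization is Adam (lr 1e-3,
β 0.9/0.999) with cosine decay over the stage, whole movies as batch
elements (default batch 4).

Validation splits are **by subject, never by movie**: the twelve offsets
of one anatomy are near-duplicates, and splitting by movie would leak
them across the split. All randomness (init, subject split, shuffling)
derives from the config seed; two runs with the same seed produce
identical loss histories and parameters, which the tests assert.

## 5. Evaluation

* `roi_mean_vs_offset`: mean ROI signal per offset at a chosen cardiac
  phase, summarized by its standard deviation and range across offsets.
  In simulation the heart ROI comes from the phantom's ground-truth
  labels (myocardium + blood) rather than manual contours.
* `interpretability_correlation`: OLS of the observed modification
  `sigmoid(AS/max(original, ε) − 1)` on the VI map over in-slice voxels
  (background excluded by a 5 %-of-P99 intensity floor) at end-diastole
  (phase 1) and end-systole (minimal blood-pool area). The identity
  configuration — SPC label as output, VI label as map — yields R² = 1,
  slope 1, intercept 0 by construction and is used as an exactness check.
* `compare_spc_fpc`: mean squared residual against the artifact-free
  reference (same phantom, zeroed field map, noiseless) inside
  ground-truth band and ghost regions. Residuals are measured after a
  robust per-tissue gain fit (median ratio to the reference): magnitude
  averaging over the spectral period changes tissue contrast — long-T2
  tissue loses more signal than short-T2 tissue — and without the gain
  fit that contrast shift, not artifact structure, dominates the number.
* Ground-truth masks: band = band weight > 0.5 at any offset of the
  grid; ghost = voxels receiving shifted flow-source energy at any
  offset, excluding band and flow regions.
* Statistics: `paired_score_stats` wraps `stats::wilcox.test`
  (signed-rank checked in the tests against exact enumeration of all
  sign assignments at n = 7); `bland_altman` is direct arithmetic;
  `icc_agreement` implements Shrout–Fleiss ICC(2,1)/ICC(2,k) from
  two-way ANOVA mean squares.

## 6. Problem sizes

The package's demo/experiment scale, used by the end-to-end acceptance
test, is: phantoms of 8 cardiac phases at 24×24, 12 offsets per sweep,
8 training subjects × 1 slice (96 movies; two subjects of the eight act
as validation), 5 held-out subjects, depth-3/16-channel networks, 10
epochs per stage, seed 42. Smoke tests use 16×16×4-phase phantoms with
depth-2/4-channel networks. The full study layout (18 subjects × 3
slices × 12 offsets = 648 movies at 25 phases) is exercised for its
manifest structure; nothing prevents training at that scale, it is
simply not needed to demonstrate the properties under test.

## 7. Known limitations

* The phantom's artifact model is phenomenological; conclusions transfer
  to real cine only insofar as bands are dark, ghosts are bright and
  PE-directed, and central offsets spare the heart.
* The VI label (and hence the VI network) cannot represent hypointense
  flow artifacts — they would be scored as bands.
* The sigmoid lower bound 0.269 compresses the flow side of the VI
  scale; "near 0" should be read as "near the lower bound".
* Magnitude-only combination: no complex phase-cycling estimators.
* The scaled-down network is far smaller than a production U-Net;
  residual blur and limited capacity are expected, and no claim is made
  about clinical image quality or reader scores.
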