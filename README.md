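# cinebands

Joint suppression of **banding artifacts** and **flow artifacts** in
balanced steady-state free precession (bSSFP) cardiac cine MRI, studied
end-to-end on a physics-based numerical phantom.

bSSFP delivers the high blood/myocardium contrast that makes it the
workhorse of cine imaging, but its signal is periodic in off-resonance
frequency with period 1/TR: wherever the accumulated off-resonance phase
per repetition reaches `β = 2π·Δf·TR ≡ π (mod 2π)` the signal is nulled and
a dark *band* crosses the image. Spins flowing through such a band are not
in the imaged steady state and splash back as bright *ghosts* along the
phase-encoding direction. Classical full-range phase cycling (**FPC**) —
averaging magnitude acquisitions whose centre frequencies tile the whole
period — removes the bands but averages the flow ghosts *into* the result.

`cinebands` implements a dual-stage, partially interpretable neural
approach to remove both artifact classes at once, together with everything
needed to study it without scanner data:

* **Synthetic phantom** (`make_phantom`, `render_cine`, `render_sweep`,
  `generate_dataset`): a contracting short-axis cardiac scene with
  myocardium, blood pool, fat, abdomen, a through-plane-flow aorta analog,
  and a smooth field map (ramp + susceptibility blob). Movies are rendered
  with the classical Freeman–Hill steady-state bSSFP magnitude, Rician
  noise, and band-conditioned phase-encoding ghosts.
* **Label synthesis** (`spc_combine`, `fpc_combine`, `vi_label`):
  short-range phase cycling (**SPC**) averages only the five central
  offsets (0, ±27.5, ±55 Hz on the 12-offset grid), which rarely band in
  the heart — suppressing banding while avoiding the ghost build-up of
  FPC. The voxel-identity (**VI**) soft label is
  `sigmoid(SPC / original − 1)`: ≈ 1 in dark bands, below 0.5 toward its
  lower bound `sigmoid(−1) ≈ 0.269` in bright flow ghosts, exactly 0.5
  where the image is artifact-free.
* **Dual-stage 3D U-Net** (`build_vi_net`, `build_as_net`, `vi_forward`,
  `as_forward`): a VI sub-network maps a cine movie to a VI map (sigmoid
  head); an artifact-suppression (AS) sub-network maps the movie *plus*
  the VI map to a restored movie (non-negative linear head). Convolutions
  are 3×3×3 over (cardiac phase, row, column) with circular padding along
  the cine loop; forward and backward passes are hand-written on
  Rcpp/RcppArmadillo GEMM kernels and verified against finite differences.
* **Two-stage training** (`train_vi`, `train_as`, `two_stage_train`):
  the VI network is trained first (MSE on the soft labels), then frozen —
  bit-identical, asserted — while the AS network trains against SPC labels
  (L1), conditioned on the frozen VI map.
* **Evaluation** (`roi_mean_vs_offset`, `interpretability_correlation`,
  `compare_spc_fpc`, `paired_score_stats`, `bland_altman`,
  `icc_agreement`): ROI signal flatness across the frequency sweep,
  voxelwise regression of the observed modification
  `sigmoid(AS / original − 1)` on the VI map, SPC-vs-FPC residual energy
  in ground-truth band/ghost regions, and Wilcoxon/Bland–Altman/ICC
  report helpers.

## Worked example

```r
library(cinebands)
geo   <- phantom_geometry(n_row = 32, n_col = 32, n_phases = 6)
scene <- make_phantom(geo, seed = 1)
sweep <- render_sweep(scene, n_offsets = 12, seed = 1)

spc <- spc_combine(sweep)
spc$source_offsets_hz
#> [1] -55.0 -27.5   0.0  27.5  55.0

roi_mean_vs_offset(sweep, heart_roi(scene))
#> <eval_curve> 12 offsets, phase 1: sd = 0.01967, range = 0.05305
#>    offset_hz mean_intensity
#> 1     -137.5     0.05535481
#> ...
#> 6        0.0     0.09518567
#> ...
#> 12     165.0     0.04213743
```

The heart-ROI curve dips to 44 % of its on-resonance value where bands
cross the heart; a flat curve is the signature of successful suppression.
Comparing the two phase-cycling combiners against the artifact-free
reference (mean squared residual inside ground-truth band / ghost
regions):

```r
masks <- ground_truth_masks(scene, sweep$offsets_hz)
compare_spc_fpc(sweep, masks, clean_reference(scene), scene)
#>     method band_residual ghost_residual
#> 1 original  0.0033165262   1.956849e-03
#> 2      SPC  0.0001545642   8.016617e-05
#> 3      FPC  0.0003631794   1.088888e-03
```

Both combiners suppress banding by an order of magnitude, but FPC carries
~14× more ghost energy than SPC — the trade-off that motivates training on
SPC labels. The VI label separates the two artifact classes as designed:

```r
v <- vi_label(spc, sweep$movies[[12]])
round(c(band = mean(v$data[masks$band]), ghost = mean(v$data[masks$ghost])), 3)
#>  band ghost
#> 0.710 0.293
```

Training the full dual-stage network on a synthetic cohort and applying
it to a held-out movie:

```r
coll <- generate_dataset(dataset_config(
  n_subjects = 8, n_slices = 1, n_offsets = 12,
  geometry = phantom_geometry(n_row = 24, n_col = 24, n_phases = 8)), seed = 42)
fit  <- two_stage_train(build_training_set(coll),
                        train_config(epochs = 10, seed = 42))
res  <- suppress_artifacts(movie, fit)   # list(vi_map, suppressed)
```

A command-line pipeline (`simulate | make-labels | train | apply |
evaluate`) is installed at `inst/cli/cinebands.R`.

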