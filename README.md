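# megre

Simulation and precision analysis for mesoscopic (sub-millimetre)
multi-echo gradient-echo (ME-GRE) brain MRI at ultra-high field.

Quantitative T2\*-weighted imaging at 0.5 mm resolution hinges on three
things working together: parallel-imaging reconstruction with well-behaved
noise amplification, correction of the rigid-body motion and B0 drift that
accrue over a 10–20 minute scan, and enough intrinsic SNR that R2\* and
magnetic susceptibility (χ) can be estimated precisely. `megre` implements
that entire chain on synthetic data, so the quantitative comparisons that
motivate imaging at 10.5 T versus 7 T — intrinsic-SNR gains, Cramér–Rao
precision of R2\*/frequency/χ, matched-TR scan-time reductions, and
g-factor improvements of high-density receive arrays — can be exercised,
tested and extended without scanner data. It is aimed at MR physicists and
methods developers who want a reproducible, fully seeded sandbox for
ME-GRE acquisition and reconstruction studies.

At its core are:

* a **unified encoding model** `y = M F C e^{i2πδf·TE} T x + n`, with
  per-shot rigid transform `T`, linear B0 change `δf`, coil sensitivities
  `C`, unitary FFT `F` and CAIPI sampling `M`; reconstruction solves its
  normal equations by preconditioned conjugate gradients in three modes
  (NoCo / MoCo / MoCo+B0Co), or directly per aliased voxel set for static
  lattice SENSE, with the analytic noise map
  `σ(ρ) = sqrt([(S^H Ψ⁻¹ S)⁻¹]_ρρ)`;
* the **intrinsic-SNR chain** SNR per echo → mono-exponential
  extrapolation to TE = 0 → division by the spoiled-GRE steady state and
  normalization per µl and √s;
* **Fisher-information bounds** for the idealized whole-TR acquisition:
  CRB of R2\* and of the magnitude²-weighted phase-regression frequency,
  with `CRB_χ = 3 CRB_f / f0`, normalized per unit voxel volume and unit
  total scan time.

## A worked example

Simulate a motion-corrupted, 2-fold accelerated whole-head acquisition at
10.5 T, estimate the motion and field drift from embedded navigators,
reconstruct with joint correction, and map R2\*:

```r
library(megre)

phantom <- make_phantom(c(32, 32, 32), voxel_size = c(1.5, 1.5, 1.5),
                        field_strength = 10.5, seed = 1)
coils <- simulate_coils(c(32, 32, 32), c(1.5, 1.5, 1.5), n_channels = 8,
                        correlation = 0.1, seed = 2)
protocol <- acq_protocol(10.5, tr = 0.035, te_list = 0.0102 + 0.0049 * (0:3),
                         flip_angle_nominal = 12, matrix = c(32, 32, 32),
                         fov = c(48, 48, 48), rp = 2, rs = 1, caipi_shift = 0,
                         nav_matrix = c(32, 32, 32), nav_interval_trs = 128)

traj <- make_trajectory(4, max_translation = 1, max_rotation = 0.75,
                        max_b0_offset = 6, seed = 3)
kspace <- forward_encode(phantom, coils, protocol, traj,
                         noise_scale = 0.001, seed = 4)
navs <- simulate_navigators(phantom, coils, protocol, traj, seed = 5)

motion <- estimate_motion(navs)
field <- estimate_b0_change(navs, motion)
recon <- joint_moco_recon(kspace, coils$sensitivities, coils$noise_cov,
                          motion, field, mode = "MoCo+B0Co", max_iter = 30)

maps <- fit_r2star(Mod(recon$images), protocol$te_list)
masks <- layer_masks(phantom)
layers <- sample_layers(maps$r2star, masks)
round(c(gm = mean(layers$gm), wm = mean(layers$wm)), 1)
#>   gm   wm
#> 44.7 51.3
```

The phantom's ground-truth layer values are GM 47 / WM 52.8 s⁻¹: the
corrected reconstruction preserves the GM–WM R2\* contrast. Skipping the
correction destroys it — the same data reconstructed with `mode = "NoCo"`
give

```r
#>   gm   wm
#> 47.6 47.0
```

i.e. the motion artifacts flatten the ~6 s⁻¹ cortical contrast to nothing.
Parallel-imaging performance of the array and the cross-field precision
argument come from the same objects:

```r
gfactor_map(coils$sensitivities, coils$noise_cov, kspace$pattern)
#> <gfactor_result> R = 2x1 shift 0: median 1/g = 0.7574 [0.67, 0.8117]

matched_tr(list(snr_te0 = 1.415, r2star = 44.5),          # 10.5 T, GM
           list(snr_te0 = 1, r2star = 31, tr = 0.045),    # 7 T, GM
           tr_range = c(0.01, 0.045))
#> $tr_a      0.033
#> $reduction 0.264
```

The last call says: with the measured GM iSNR gain (×1.415) and the
field-specific R2\* values, a 10.5 T acquisition at TR ≈ 33 ms reaches the
same time-normalized R2\* precision as a 7 T acquisition at TR = 45 ms —
about a one-third scan-time reduction.

`run_experiment()` / `report_experiment()` orchestrate the full pipeline
(simulation → reconstruction in each correction mode → quantitative maps →
layer iSNR and gains → g-factor tables → CRB-vs-TR sweeps) from a single
seeded `experiment_config()`, writing NIfTI maps, CSV tables and a JSON
metrics bundle.

See the vignette (`vignettes/megre-methods.Rmd`) for the model details,
parameter conventions, numerical choices and known limitations.

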