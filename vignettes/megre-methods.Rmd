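---
title: "Simulating and evaluating mesoscopic multi-echo GRE brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating mesoscopic multi-echo GRE brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megre)
```

# Scope

`megre` is a simulation and evaluation framework for very-high-resolution
multi-echo gradient-echo (ME-GRE) brain MRI at ultra-high field. It covers
the full chain that a quantitative T2\*-weighted study runs through:

1. a seeded digital brain phantom with field-strength-specific tissue
   parameters and a susceptibility-induced off-resonance map,
2. multi-channel receive arrays with correlated noise,
3. CAIPI-undersampled multi-echo k-space synthesis under rigid-body motion
   and B0 drift, plus low-resolution navigator volumes,
4. navigator-based motion and field-change estimation and SENSE
   reconstruction in three correction modes (no correction, motion-only,
   motion plus linear B0 correction), with analytic noise maps,
5. R2\* and local-frequency mapping, intrinsic-SNR (iSNR) estimation and
   parallel-imaging g-factor evaluation,
6. Fisher-information (Cramér–Rao) precision bounds for R2\*, frequency and
   susceptibility under an idealized continuous-acquisition model, used for
   cross-field (7 T vs 10.5 T) comparisons.

Everything is exercised end-to-end on synthetic data; no scanner data are
required.

# The signal model

For echo time $TE_e$, voxel magnetization $M_0$, longitudinal relaxation
time $T_1$, effective transverse rate $R_2^*$ and off-resonance $\Delta
f_0$, the spoiled steady-state ME-GRE image is

$$ s_e(\mathbf r) = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha}
   \, e^{-TE_e R_2^*}\, e^{i 2\pi \Delta f_0 TE_e}, \qquad
   E_1 = e^{-TR/T_1}. $$

The off-resonance map is generated from the tissue susceptibility $\chi$
(ppm) by the forward dipole model, applied in k-space with the kernel
$D(\mathbf k) = 1/3 - k_z^2/|\mathbf k|^2$, $D(0) = 0$, and the main field
along the third array axis. Acquisition k-space for channel $c$, echo $e$
and shot (phase/slice line) $s$ is

$$ y_{c,e,s} = \mathcal M_s \,\mathcal F\, C_c \, e^{i2\pi \delta f_s(\mathbf r) TE_e}\, T_s\, s_e + n, $$

with $T_s$ the rigid-body transform of the shot's motion interval,
$\delta f_s$ its (constant plus spatially linear) B0 change, $C_c$ the coil
sensitivity, $\mathcal F$ a unitary FFT and $\mathcal M_s$ the CAIPI
sampling of that shot. Channel noise $n$ is complex Gaussian with Hermitian
covariance $\Psi$ scaled by `noise_scale` (so `E[n n^H] = noise_scale^2
Psi`). Reconstruction solves the normal equations of exactly this operator
by preconditioned conjugate gradients; the `mode` argument removes the
$T_s$ and/or $\delta f_s$ terms to reproduce the NoCo / MoCo / MoCo+B0Co
comparison. For lattice sampling without motion the problem is solved
directly per aliased voxel set (classic SENSE), and the analytic noise map

$$ \sigma(\rho) = \sqrt{[(S^H \Psi^{-1} S)^{-1}]_{\rho\rho}} $$

(scaled to the data noise level, reported as per-quadrature standard
deviation) underlies both the per-echo SNR maps and the g-factor
$g = [\sigma_R/\sigma_1]/\sqrt R$.

# The phantom and what it does (not) emulate

The phantom is a concentric-ellipsoid "head": CSF rim, cortical gray-matter
ribbon, white-matter core, a deep nucleus with elevated $R_2^*$ and $\chi$,
and two ventricle-like CSF spaces. Distinct semi-axes and the off-axis
internal structures keep all three rotation angles observable to the
navigator registration. Tissue memberships are fuzzy (about one voxel of
sigmoidal partial-volume transition); hard step edges would make trilinear
motion interpolation non-physical and bias motion estimates.

Literature values parameterize $T_1$ (GM 2.1 s / WM 1.4 s at 10.5 T, 1.8 /
1.2 s at 7 T) and the in-vivo layer measurements parameterize $R_2^*$ (two
subject presets per field, e.g. GM 47 / WM 53 s$^{-1}$ at 10.5 T). No
published values exist for this phantom's $M_0$, $\chi$, CSF or nucleus
parameters; the defaults ($\chi$: GM 0.02, WM −0.03, CSF 0, nucleus 0.1
ppm; $M_0$: CSF 1.0, GM 0.8, WM 0.7, nucleus 0.75; CSF $T_1$ 4.3 s, CSF
$R_2^*$ 5 s$^{-1}$) are plausible relative contrasts, flagged `synthetic`
in `tissue_table()`, and are conventions rather than claims. A ±5 %
smooth, seeded spatial variation (zero-mean within each pure tissue class)
provides texture. The phantom is not an anatomical atlas: there is no
cortical folding, no hippocampal substructure, and a single water
compartment per voxel — mono-exponential decay is exactly true here, so
tests of the fitting bias use explicitly constructed two-compartment
signals instead.

Cortical "layers" are extracted geometrically: the GM layer at the radial
mid-depth of the ribbon and the paired WM layer 40 % of the local ribbon
thickness below the GM–WM boundary, pairing voxels one-to-one along the
shared radial direction. They stand in for surface-based layer extraction
on real anatomy.

# Navigators, motion and B0 estimation

One low-resolution complex navigator volume is synthesized per motion
interval at the navigator TE (4.3 ms), by k-space truncation with a
radially symmetric Hann window. The radial window matters: a separable
(cube-shaped) band limit does not commute with rotation and biases
registration. For the same reason the navigator's rigid transform is
applied on a 2× band-limited supersampled grid, and registration operates
on 2× Fourier-upsampled magnitudes: both choices suppress trilinear
interpolation artifacts that are not features of a real acquisition.

Motion is estimated by three-level multiresolution Gauss–Newton
least-squares registration to the reference navigator; B0 changes by a
magnitude²-weighted least-squares fit of constant plus three linear terms
to the phase difference divided by $2\pi\,TE_{nav}$, after counter-rotating
each volume by its motion estimate. A single navigator TE makes offsets
beyond $\pm 1/(2\,TE_{nav})$ (≈116 Hz at 4.3 ms) ambiguous; the constant
term is therefore unwrapped temporally against the previous interval, and a
flag records every branch correction. A drift that jumps by more than the
ambiguity between consecutive navigators is genuinely unrecoverable.

At desk scale the phantom spans only 20–50 voxels, far fewer resolution
elements than a head at the published navigator resolution, so rotational
precision is resolution-limited: noiseless recovery reaches 0.2 mm / 0.1°
with full-matrix navigators at 32³, while noisy (SNR ≈ 20) navigators are
held to 0.5 mm / 1°. This is a property of the scaled-down study
conditions, not of the estimation algorithm.

# SNR and iSNR

Per-echo SNR is $|s_e|/\sigma$ with the analytic noise map; SNR at TE = 0
comes from the same mono-exponential fitter applied to the SNR-vs-TE
series. iSNR divides SNR$_{TE0}$ by the spoiled-GRE steady-state amplitude
(removing flip-angle — from AFI if available —, $T_1$ and TR effects), the
nominal voxel volume (µl) and the square root of the per-echo acquisition
time, yielding units of 1/(µl·√s). Cross-field gains are computed as the
mean of location-wise ratios along the paired layers, never as ratios of
means. Absolute iSNR values depend on an arbitrary signal scale and are
validated by round-trip recovery (within 5 % in the GM layer at
SNR$_{TE0} \gtrsim 40$, independent of the flip angle used), not against
absolute published numbers.

# Precision bounds

The idealized acquisition assumes instantaneous excitation and data
acquired during the entire TR; the complex model $y(t) = A e^{-R_2^* t}
e^{i2\pi f t}$ is discretized at $J$ midpoints of $(0, TR)$. The Fisher
matrix uses analytic derivatives, $F_{mn} = \sigma^{-2}\,\mathrm{Re}\sum_j
\partial_m y_j^H \partial_n y_j$, and bounds are reported as standard
deviations $\sqrt{[F^{-1}]_{kk}}$, rescaled to unit voxel volume and unit
total acquisition time (multiplying by $\sqrt{TR/T_{total}}$).

The per-sample noise is $\sigma_J = \sqrt{J/TR}\,/\,\mathrm{SNR}_{TE0}$.
This makes the bounds independent of the discretization $J$ (below 0.5 %
change from $J = 64$ to 512) while the information collected per excitation
grows linearly with the readout duration, as it physically must for
acquisition at fixed noise spectral density. Under this convention the
time-normalized $CRB_{R_2^*}$ has an interior minimum in TR at a small
multiple of $1/R_2^*$, and parameterizing the two fields by the measured
iSNR gain (1.415 for GM) and the layer $R_2^*$ values reproduces the
published matched-TR observation: the 10.5 T bound at TR ≈ 33 ms equals
the 7 T bound at TR = 45 ms (scan-time reduction ≈ 0.27, "about one
third"), and likewise TR ≈ 21.5 ms matches a 7 T TR of 30 ms. The ΔR2\*
normalization is available (`normalized_crb_r2star`, and optionally inside
`matched_tr`) but is not part of the cross-field match: dividing by the
field-specific ΔR2\* (7.5 vs 5.5 s$^{-1}$) makes the 10.5 T curve strictly
better everywhere, so no equal-precision TR exists in that metric.

The frequency bound uses the magnitude²-weighted phase-regression model
(with intercept); it coincides exactly with the full complex-signal Fisher
bound once amplitude, decay and initial phase are co-estimated — both
routes are implemented and tested against each other. The susceptibility
bound is $CRB_\chi = 3\,CRB_f/f_0$, the sphere geometry factor, with
$f_0 = 42.577\ \mathrm{MHz/T} \times B_0$ (the gyromagnetic ratio is fixed
by convention since no nominal frequency is published). Attainability of
the bounds is verified by Monte-Carlo maximum-likelihood fitting (empirical
standard deviation within 0.95–1.15× the bound at SNR$_{TE0}$ = 200).

# Numerical conventions and degenerate inputs

* **FFT**: unitary, DC at array index 1 (wrap-around order). Sampling
  patterns are defined on 0-based (ky, kz) indices in that order. The SENSE
  aliasing kernel is extracted numerically from the mask with the same FFT
  code, so the unfolding is correct for any phase convention by
  construction; non-periodic pattern/matrix combinations are rejected (a
  CAIPI shift Δ requires $(n_y/R_p)\,\Delta \equiv 0 \bmod R_s$).
* **Coordinates**: 0-based voxel indices, coordinates at voxel centres,
  right-handed axes, volume centre at index $N\!\div\!2$ — grids derived
  from one another by Fourier resampling then share one physical frame.
  Rotations are extrinsic x→y→z in degrees about that centre.
* **Motion operator**: sparse trilinear interpolation; its adjoint is the
  interpolation transpose (not the inverse transform), verified by the
  adjointness property in every mode. CG uses a block-SENSE preconditioner
  (the exact inverse of the static normal operator per aliased voxel set),
  tolerance $10^{-6}$, no regularization; non-convergence is reported,
  never silently accepted. Under motion at R = 4 with few channels the
  normal operator is genuinely ill-conditioned and residual image error
  remains after convergence slows — the correction-mode ordering is robust
  to this, exact recovery is not claimed.
* **Degenerate voxels**: aliased sets with vanishing sensitivity are masked
  with a warning; R2\* fits with fewer than two finite echoes are flagged;
  AFI arccos arguments outside [−1, 1] are flagged invalid; magnitude noise
  is treated as Gaussian (valid above SNR ≈ 5, no Rician correction — the
  R2\* bias guard test runs at SNR 50 where the bias is below 2 %).
* **Seeding**: every stochastic function takes an explicit seed and
  restores the caller's RNG state; identical inputs give bit-identical
  outputs. `run_experiment` derives stage seeds deterministically from one
  master seed.

# Problem sizes

The shipped tests run the full pipeline at 16³–48³ matrices with 4–16
channels (96 channels for the coil-density comparison), two to four echoes
and four motion intervals: correction-mode ordering at 48³, noise-map
Monte-Carlo at 32³ with 16 channels and 200 replicates, bound-attainability
at 2000 replicates. These sizes are chosen so the entire suite represents
every published behavior while remaining desk-scale; none of the
qualitative conclusions change with grid size, but absolute conditioning
(and hence CG iteration counts and rotational information) improves on
larger grids.

# Known limitations

* Single-compartment relaxation only; multi-compartment white-matter decay
  appears solely as constructed test signals for the bias demonstration.
* No transmit (B1+) modeling: the nominal flip angle is spatially uniform,
  and AFI maps are simulated through the signal equations rather than a
  transmit-field model.
* Linear-only B0 correction, B0 phase applied per echo at TE (no
  intra-readout evolution; the readout is short against drift scales).
* Navigators are synthesized in image space (no EPI readout, no fat
  signal); the k-space container is an RDS file with a JSON protocol
  sidecar rather than a scanner raw format.
* Total-scan-time prediction from matrix/TR arithmetic is exposed via
  `protocol_timing` but absolute protocol durations include vendor
  overheads that are not modeled.
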