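---
title: "Methods: field mapping and mask-restricted shimming of the lung"
author: "lungshim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field mapping and mask-restricted shimming of the lung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungshim)
```

## Why the lung needs its own shim

Balanced SSFP signal is periodic in the local off-resonance ν with period
1/TR and collapses near the stop bands at ±n/(2·TR), odd n — for the
ultra-fast protocol modeled here (TR = 1.38 ms) the first bands sit at
±362.3 Hz, and signal already degrades beyond roughly ±1/(3·TR) ≈ ±242 Hz.
Susceptibility gradients at the diaphragm and lung apex spread the in-lung
off-resonance distribution over several hundred Hz, so without a
subject-specific shim a fraction of the parenchyma sits in or near a band.
Conventional field mapping fails in the lung because parenchymal T2\* at 3T
is a few hundred microseconds; by the first millisecond there is almost no
signal left to carry phase. The acquisition modeled here side-steps this by
acquiring one gradient echo per TR and stepping the echo time across
repetitions of the phase-encode loop: TEⱼ = (j−1)·ΔT + TE₁ with TE₁ =
570 μs and ΔT = 100 μs, so all four echoes fall inside the usable decay
window.

## Field-map model

For each voxel the complex echo signals are normalized to the first echo,
ŝⱼ₁ = ŝⱼ/ŝ₁, and the incremental phase φ̂ⱼ₁ = arg ŝⱼ₁ is fit by linear
least squares to the model

φⱼ₁ = 2πν·(j−1)·ΔT + φ₀,

minimizing χ²(ν, φ₀) = Σⱼ (φ̂ⱼ₁ − φⱼ₁)². The slope estimates the local
off-resonance ν̂ (Hz), the intercept the phase offset φ̂₀. Because the fit is
linear, the estimator is exact on noiseless data (the test suite asserts
agreement with ground truth to 10⁻⁶ Hz) and equals a brute-force grid
minimization of the same χ² on noisy voxels (asserted against a
hierarchical dense grid search at 0.1 Hz × 10⁻³ rad resolution).

Numerical choices:

* **Intercept.** The normalization forces φ̂₁₁ = 0, yet the intercept is
  retained (it absorbs first-echo noise); with only two echoes the
  intercept is underdetermined and is forced to 0, flagged in the output.
* **Phase wraps.** Each per-step increment 2πν·ΔT stays inside (−π, π] for
  |ν| < 1/(2ΔT) = 5 kHz, far beyond physiological offsets. The *cumulative*
  principal phase, however, would wrap beyond 1/(2(n−1)ΔT) ≈ 1.7 kHz, so
  the fit re-accumulates the principal-valued per-step increments
  (`unwrap_incremental_phases()`), which reconstructs the sequence exactly
  whenever each step is unambiguous. No spatial unwrapping exists anywhere
  in the package. A guard flags voxels whose per-step increment exceeds
  0.9·π.
* **Weighting.** The cost is written unweighted and is fit unweighted by
  default; a magnitude-weighting flag exists (`weighted = TRUE`) for noisy
  late echoes but is off because the cost above carries no weights.
* **Background.** Voxels whose first-echo magnitude falls below 5 % of the
  in-image 99th percentile are marked invalid rather than raising errors;
  air regions carry no phase information.
* **Precision.** The per-voxel frequency standard error is derived from the
  fit residuals and the design matrix; Monte-Carlo tests confirm it scales
  as 1/SNR.

T2\* is estimated from the same series as the negative inverse slope of
log-magnitude against echo time, with the fit R² reported; non-decaying
voxels return `Inf` with a flag instead of a negative relaxation time.

## Registration and averaging

Free-breathing acquisition displaces the diaphragm between repetitions, so
magnitude images are aligned by a multi-resolution (3-level) diffusion-
regularized demons registration before any averaging. Defaults
(`register_settings()`): 100/60/30 iterations coarse-to-fine, update
smoothing σ = 1 px, field smoothing σ = 2.5 px, per-iteration step cap
1 px. The strong field regularization reflects the physics: respiratory
deformation fields are smooth at the scale of centimeters, and the lung
interior is nearly featureless, so the in-lung displacement must be
interpolated from diaphragm and boundary structure — heavier smoothing
markedly reduces endpoint error on simulated motion (≈0.7 px mean at 5 px
peak displacement, SNR 20). The solver never returns a field that worsens
the mean squared intensity difference relative to the identity.

Two deliberate deviations from a literal reading of the workflow:

* **Which images are registered.** By default the *first-echo* magnitude of
  each repetition is registered to the reference and that deformation is
  applied to all echoes of the repetition. In a TR-shifted acquisition all
  echoes of one repetition interleave over the same ~1.2 s and share the
  breathing state, whereas echo-to-echo T2\* contrast (lung magnitude drops
  ×0.63 over the echo train while soft tissue barely decays) would bias an
  intensity-based force. `per_echo = TRUE` registers every
  (repetition, echo) image independently for users who want the literal
  behavior.
* **What is interpolated.** Deformations are applied to the real and
  imaginary channels separately, never to wrapped phase values; the output
  phase is the phase of the warped complex image. Likewise repetitions are
  averaged as complex numbers (vector averaging), which implicitly
  down-weights unreliable low-magnitude voxels; circular quantities are
  never averaged arithmetically.

## Segmentation

The clinical reference uses a learned segmenter trained on in-house data
that cannot be reproduced here; a deterministic classical pipeline with the
same contract substitutes: Otsu body mask with hole filling, low-intensity
candidates inside the body (threshold relative to the median body
intensity, hence invariant to global scaling), morphological opening and
closing, then component filtering by area, border contact and a centrality
heuristic that rejects trachea/airway candidates whose centroid falls in
the central column (±8 % of image width by default). The two largest
surviving components are kept — all their voxels, including vessels, since
the reference does not state that intra-lung structures were excluded. Any
external 0/1 mask can bypass the stage (`as_lung_mask()`, CLI `--mask`).

## Shim model

The field is modeled as ν = a·c over the nine 0th–2nd order spherical-
harmonic shapes a = [1, z, x, y, z² − (x²+y²)/2, zx, zy, x² − y², xy] in mm
from isocenter. A single coronal slice makes the anterior–posterior
coordinate an arbitrary offset, so y = 0 is substituted; columns 3, 6, 8
vanish identically and are excluded from the optimization with their
coefficients pinned to exactly 0. The remaining six coefficients solve the
mask-restricted least-squares problem over L = lung mask ∩ valid voxels.

Numerics: the design is column-scaled (max-abs) before a QR solve and the
coefficients rescaled on output, so the mixed mm⁰/mm¹/mm² units do not
degrade conditioning; rank deficiency (e.g. a mask collapsed onto a line)
raises an error naming the deficient basis directions. Coefficients are
stored in field units — c₀ in Hz reported separately as a center-frequency
offset, linear terms in Hz/mm, quadratic in Hz/mm² — because the conversion
to hardware shim currents is a scanner calibration outside scope. The
plain-text configuration file (fixed keys, 6-decimal floats) is the entire
interface between shim calculation and application; write→read round trips
are exact at the printed precision.

Least-squares structure guarantees two testable properties: the in-mask
residual is orthogonal to every retained basis column, and the residual sum
of squares never exceeds that of the unshimmed field (zero currents are
feasible). On noiseless phantoms a second calibration pass returns
coefficients below 5 % of the first pass, reproducing the observation that
a single pass suffices.

## What the phantom states, and what it does not

`phantom_params()` defaults encode the conditions the method targets:

| parameter | default | why |
|---|---|---|
| matrix / FOV | 128 × 128 / 450 mm | protocol geometry |
| TE₁ / ΔT / echoes / repetitions | 570 μs / 100 μs / 4 / 3 | protocol timing |
| lung T2\* | 640 μs | parenchymal value measured at 3T |
| soft-tissue T2\* | 20 ms | ≥ 10 ms, effectively non-decaying over 870 μs |
| lung / tissue proton density | 0.25 / 1 | low lung aeration-scaled signal |
| in-lung mean ν / range | 85 Hz / 434 Hz | representative measured slice |
| field shape | harmonic background − diaphragm blob + apex blob | negative offsets above the diaphragm, positive near the apex |
| motion amplitude | 5 px (≈ 18 mm) | free-breathing diaphragm excursion |
| SNR | free parameter (default 20) | acquisition SNR is not stated anywhere; the ~25 Hz field precision quoted for the in-vivo data ties to an unknown SNR, so precision is reported per dataset instead of asserted |

The off-resonance map is built from a low-order harmonic background plus
two Gaussian perturbations and then *affinely rescaled* so the in-lung mean
and max−min range hit the requested targets exactly; if every amplitude is
zero the field is identically zero and rescaling is skipped (a constant
non-zero field with a positive requested range is rejected as infeasible).
Respiratory motion is a sinusoidal-in-repetition head–foot displacement
weighted toward the lower thorax plus a small smooth random residual
(10 %); repetition 1 is the reference. Noise is single-coil complex
Gaussian in the image domain with σ = (mean in-lung first-echo
magnitude)/SNR — coil combination and parallel-imaging reconstruction are
out of scope, so image-domain noise is the right abstraction.

A green test on this phantom establishes that the *estimation chain* is
correct: exact forward-model inversion, oracle-equivalent least squares,
LSQ-optimal shim algebra, and robustness to the stated motion and noise.
It does not establish in-vivo performance: the phantom has no fat chemical
shift, no multi-compartment decay (a mono-exponential model is justified by
the near-perfect linear log-magnitude decay observed in vivo), no
through-plane motion, no coil shading, and its anatomy is two clipped
ellipses, not a thorax atlas. Printed in-vivo improvements (e.g. 54 → 11 Hz
mean offset) depend on patient data this package cannot access and are not
asserted anywhere; the tests assert the properties that must hold for any
input instead.

## bSSFP evaluation

The banding demonstration uses the standard steady-state magnitude with
E₁ = exp(−TR/T₁), E₂ = exp(−TR/T₂) and per-TR precession angle
θ = 2πν·TR + Δφ (Δφ = 180° cycling by default), which places the pass-band
on resonance and the nulls at ±1/(2·TR). Lung relaxation defaults for
rendering are T₁ = 1300 ms, T₂ = 40 ms — representative 3T values chosen
once for a qualitative demonstration (the source protocol states none);
transient and eddy-current effects are ignored. The rendered image is
m₀ × |M(ν)| per voxel; after shimming the in-lung intensity histogram
shifts up and narrows, and the count of voxels beyond ±1/(3·TR) drops —
both asserted numerically in the test suite.

## Degenerate inputs and error behavior

Constant images cannot be registered or segmented (explicit degenerate-
input errors); a segmentation that finds no candidate region raises an
empty-mask error with a diagnostic rather than returning an empty mask;
all-invalid field maps and empty or rank-deficient shim masks are errors;
background voxels and non-positive magnitudes are flagged invalid per voxel
rather than failing the image. Pipeline stage failures propagate with the
stage name attached, and every stochastic operation takes an explicit seed
(identical seed ⇒ bit-identical output, asserted end-to-end).

## Known limitations

Single-slice 2D only (no volumetric shim); no GRAPPA/k-space simulation;
no DICOM ingestion; no hardware current limits or third-order terms in the
solver; the classical segmenter, while contract-equivalent, is not the
learned segmenter and its Dice ≥ 0.9 guarantee holds on phantom anatomy,
not on patients. The built-in NIfTI reader handles only the subset the
package writes (uncompressed single-file volumes, no scaling slopes or
orientation matrices).
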