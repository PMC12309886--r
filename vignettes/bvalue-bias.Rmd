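---
title: "Imaging-gradient b-value bias and its propagation into IVIM estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging-gradient b-value bias and its propagation into IVIM estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimbias)
```

## The problem

Diffusion-weighted MRI attributes a *nominal* b-value to each image, computed
from the diffusion-encoding gradients alone. The imaging gradients of the
pulse sequence — slice selection, crushers, pre- and rewinders — also dephase
spins, and where their dephasing overlaps in time with that of the diffusion
gradients they produce *cross-terms* that can raise or lower the true
diffusion weighting. For ADC or DTI work at b of several hundred s/mm² the
error is often tolerable. Intravoxel incoherent motion (IVIM) analysis is
different: the perfusion parameters f and D\* live in the signal at
b ≲ 200 s/mm², exactly where the relative b-value error is largest, and an
image "without diffusion weighting" can in truth carry b of order
1–15 s/mm² depending on resolution.

`ivimbias` quantifies this chain end to end: it builds pulsed gradient
spin-echo (PGSE) waveforms at the gradient-raster level, decomposes their
b-tensor, and measures how analysing signals against nominal instead of
actual b-values distorts IVIM parameter estimates.

## The model

For an effective gradient $\mathbf g(t) = \mathbf g_{img}(t) + \mathbf
g_{diff}(t)$ (sign-inverted after the refocusing pulse centre), the spin
dephasing vector is $\mathbf q(t) = \gamma \int_0^t \mathbf g(u)\,du$ and the
b-tensor over $[0, TE]$ is

$$\mathbf B = \int_0^{TE} \mathbf q \otimes \mathbf q \; dt
  = \mathbf B_{img} + \mathbf B_{diff} + \mathbf B_{ct},$$

where the three terms collect the imaging-only, diffusion-only and mixed
outer products. The b-value is the trace. Three bookkeeping scenarios are
exposed by `scenario_bvalue()`:

* `"nominal"` — $tr\,\mathbf B_{diff}$, what scanner metadata reports;
* `"img"` — $tr(\mathbf B_{diff} + \mathbf B_{img})$, a direction-independent
  correction;
* `"img_ct"` — the full trace, the actual b-value of the sequence.

$\mathbf B_{ct}$ is odd under diffusion-direction negation, which is why
averaging antipodal acquisitions ("experimental cross-term correction")
cancels it to first order.

## The two sequence designs

Both designs share the same events: a rectangular excitation slice-select
plateau (6 ms), a rectangular refocusing slice-select plateau (7 ms) split
about the refocusing centre, triangular crushers bracketing the refocusing
block, a triangular excitation rewinder, a readout prewinder ending at TE,
and a rectangular diffusion lobe pair (δ = 20 ms, Δ = 40 ms by default)
placed symmetrically about the refocusing centre.

* **`large_ct`** merges the excitation rewinder into the pre-refocusing
  crusher lobe (one triangular lobe whose area is the sum of the two), and
  applies crushers regardless of the diffusion amplitude. The slice-axis
  imaging dephasing therefore stays elevated from excitation to the
  refocusing block — precisely the window in which the diffusion dephasing is
  active — producing large cross-terms.
* **`minimal_ct`** rewinds immediately after excitation, keeping the imaging
  dephasing at zero for as long as possible, and omits the crushers whenever
  the diffusion lobes alone dephase spurious echoes by at least the crusher
  target across every crushed voxel dimension. With the defaults this
  switches crushers off for nominal b above 10 s/mm².

Slice-select amplitudes follow $G_z = 2\pi\Delta f/(\gamma\Delta z)$
(600 Hz transmit bandwidth by default); crusher and pre-/rewinder lobes are
sized from a target dephasing $\Delta\phi = \gamma\,\Delta r \int G\,dt$ with
$\Delta\phi = 6\pi$ for crushing (across the voxel dimension of the lobe's
axis) and $\pi$ across the in-plane voxel for the readout prewinder (the
half k-space sweep).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `raster_dt_us` | 12 | µs | waveform sample spacing |
| `g_max`, `slew_max` | 80, 200 | mT/m, T/m/s | typical clinical limits; configurable because figure-level results depend on them |
| `bandwidth_hz` | 600 | Hz | transmit bandwidth of both RF pulses |
| `excitation_ms`, `refocus_ms` | 6, 7 | ms | slice-select plateau durations |
| `crusher_dephasing` | 6π | rad | crusher target |
| `crusher_axes` | x, y, z | — | clinical sequences sometimes crush the slice axis only; the synthetic prostate protocol uses `"z"` |
| `delta_ms`, `Delta_ms` | 20, 40 | ms | diffusion lobe duration / separation |
| IVIM bounds | f ∈ [0, 0.7], D\* ∈ [1, 300], D ∈ [0.05, 4] | —, µm²/ms | generous physiological envelopes that never bind at prostate-like truths |
| segmentation threshold | 200 (inclusive) | s/mm² | the b = 200 shell belongs to the high-b segment |

## Numerical choices

* **Time origin and excitation.** t = 0 at the excitation RF centre; only
  gradient area after t = 0 dephases the transverse magnetization, so the
  excitation slice gradient contributes its post-isocentre half plus its
  rewinder.
* **Rectangles are ideal.** Slice-select plateaus and diffusion lobes are
  rasterized as ideal steps, as in the modelled designs. A true rectangle
  cannot satisfy a finite slew limit, so slew assertions apply to the
  triangular/trapezoidal lobes. This keeps the isolated diffusion pair in
  exact correspondence with the Stejskal–Tanner closed form
  $b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)$, which the test suite uses
  as an independent oracle (agreement within 0.1% at the 12 µs raster).
* **Area-exact sampling.** Each lobe is sampled by cell-averaging its
  analytic cumulative area, so rasterized lobe areas are exact regardless of
  where block edges fall on the raster; q(t) and the B integrals then use
  trapezoidal quadrature on the raster.
* **Nominal b exact on the raster.** The diffusion amplitude for a nominal
  b is solved against the rasterized $tr\,\mathbf B_{diff}$ of the isolated
  pair; since that trace is exactly proportional to $G^2$, a single
  unit-amplitude evaluation gives the closed-form solution.
* **Minimal-TE packing.** Blocks are packed with zero inter-block gaps;
  TE = 2 × (excitation centre → refocusing centre). Timing that cannot
  accommodate the refocusing block between the diffusion lobes raises an
  error rather than silently overlapping blocks.
* **Segmented fit details.** Step 1 is a log-linear fit for b ≥ threshold;
  step 2 clips negative residuals to $10^{-6}\,\max S$ before fitting the
  perfusion component (amplitude and D\*) on the low-b points; step 3 refits
  (S0, f, D\*) with D fixed. All nonlinear steps use bounded
  Levenberg–Marquardt (tolerance $10^{-10}$, at most 1000 iterations);
  non-convergence is flagged on the result, not raised.
* **Direction sets.** `well_distributed()` minimizes the Coulomb energy of n
  unit charges on the sphere (seeded initialization, BFGS with an analytic
  tangent-projected gradient), which for n = 6 converges to the octahedron;
  the scheme behind the published 200-direction set is not reproducible, so
  any well-distributed set is acceptable and worst-case/extreme statistics
  over directions are the quantities compared.

## Design choices where the design was open

* **Hardware limits** are never stated for the simulated sequences; 80 mT/m
  and 200 T/m/s were chosen as typical clinical values and every
  waveform-level result is understood to carry that uncertainty.
* **Crusher axes.** Crushers are placed on all three axes, with Eq.-style
  areas using each axis's voxel dimension. This is what makes the in-plane
  resolution sweeps meaningful and reproduces the b = 0 floor values at both
  1 mm and 3 mm isotropic; slice-only crushing (available via
  `crusher_axes`) reproduces the clinical prostate protocol, whose recorded
  b0 is ~0.5 s/mm².
* **Parameter-sweep geometry.** The parameter sweeps (f 1–30%, D\* 5–50,
  D 0.5–3 µm²/ms, 50 steps each) are run at 1 mm isotropic. That choice is
  pinned by the study design itself: the reported collapse of f estimates to
  −100% for the minimal-cross-term design requires the ~11 s/mm² b = 0
  imaging floor of the 1 mm geometry, and the published signal simulations
  use 1 mm isotropic.
* **Reference fits.** In the bias sweeps the full-calculation reference fit
  pools the per-direction (actual b, signal) points, so its error is zero by
  construction; the nominal and imaging-corrected fits use geometrically
  direction-averaged signals, the common analysis practice whose bias is
  under study.
* **Synthetic prostate fixtures.** Ground-truth maps draw
  f ~ N(0.10, 0.03) truncated to [0.01, 0.3], D\* ~ N(20, 5) µm²/ms,
  D ~ N(1.0, 0.15) µm²/ms — centred on prostate-representative values; the
  spreads are fixture choices. Rician noise is the magnitude of a complex
  Gaussian with per-channel σ = S0/SNR. The generator emulates voxelwise
  parameter heterogeneity and magnitude noise only: no partial volume, no
  motion, no T2/TR weighting, no spatial correlation, no EPI artefacts —
  passing tests therefore validate the estimation pipeline, not robustness
  to those real-data effects.
* **Recorded clinical b-values.** For the end-to-end nominal-versus-actual
  experiment the package ships the waveform-derived actual b-values of a
  clinical 3 T prostate protocol (`clinical_actual_bvalues()`). The
  fully simulated protocol (`protocol_b_table()`) is also available; its
  cross-term offsets fall off as $1/\sqrt b$ in relative terms, whereas the
  recorded clinical offsets are close to a constant ~6% per shell — a
  reminder that real implementations contain gradient events beyond the two
  stylized designs.

## Known limitations

* The exact TE, inter-block gaps and hardware limits of the sequences the
  study emulated are unknown. With minimal-TE packing and the default limits
  the package's cross-term magnitudes come out ~25–30% below the published
  figure-level values (the acceptance script computes ~18% worst-case
  directional spread at 4 mm/b = 50 against a reported ±25%), and the
  crushers-off worst case at 1 mm isotropic computes to ~17% rather than
  below 10% — under the stated slice-select parameters the refocusing
  plateau cross-term alone exceeds that bound at b = 15, so the published
  bound must rest on an implementation detail (for example a broader, weaker
  refocusing slice gradient) that the stated parameters do not determine.
  These comparisons are left failing rather than tuned.
* Antipodal averaging cancels cross-terms exactly for b-values and for
  mono-exponential signals, but only to second order for the bi-exponential
  model; the residual parameter error is measured at ~0.5–0.7% at
  2 × 2 × 4 mm (sub-percent, but not below the 10⁻³ sometimes quoted for
  "eliminated" bias).
* EPI readout trains, RF/slice-profile effects, eddy currents, concomitant
  fields and background-gradient interactions are out of scope.

## Problem sizes

The shipped experiments are desk-scale: 200-direction spreads evaluate 400
waveforms (~20 s), the three 50-step parameter sweeps fit 150 noise-free
curves (~5 s), and the synthetic prostate experiment fits 4000 voxels twice
(~15 s).
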