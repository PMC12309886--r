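# ivimbias

Imaging gradients bias the b-value of diffusion-weighted MRI. Every pulsed
gradient spin-echo (PGSE) sequence carries slice-select, crusher and
pre-/rewinder gradients that dephase spins alongside the diffusion-encoding
lobes; the b-tensor of the full sequence is

    B = B_img + B_diff + B_ct,        b = tr(B),

where **B**\_img comes from the imaging gradients, **B**\_diff from the
diffusion gradients (the only part reported as the "nominal" b-value in
image metadata), and **B**\_ct from cross-terms between the two, which are
odd in the diffusion-gradient polarity and can push the true b-value either
way. Intravoxel incoherent motion (IVIM) analysis,

    S(b) = S0 [ f exp(-b D*) + (1 - f) exp(-b D) ],

extracts the perfusion fraction f and pseudo-diffusion coefficient D\* from
the low-b signal (≲ 200 s/mm²), exactly where the relative b-value error is
largest — an "unweighted" b = 0 image can really carry 1–15 s/mm² depending
on resolution.

`ivimbias` is for MR physicists and quantitative-imaging researchers who
want to quantify that bias for a given sequence design: it builds PGSE
gradient waveforms on a 12 µs raster for two archetypal designs (one with
large cross-terms, one designed to minimize them), integrates the dephasing
vector q(t) = γ∫g dt, decomposes the b-tensor, imports externally recorded
g(t) waveforms, and propagates the b-value errors into IVIM estimates with
both a single-step bounded nonlinear least-squares fit and the three-step
segmented algorithm (log-linear D above a 200 s/mm² threshold, perfusion
component from the low-b residual, final refit with D fixed). A seeded
synthetic DWI generator with Rician noise supports end-to-end experiments.

## Worked example

The actual diffusion weighting of a "b = 50" acquisition at 1 mm isotropic
resolution, minimal-cross-term design, diffusion gradient on z:

```r
library(ivimbias)
dec <- pgse_btensor(sequence_config("minimal_ct", slice_thickness_mm = 1,
                                    in_plane_mm = 1, nominal_b = 50,
                                    direction = c(0, 0, 1)))
dec
#> b-tensor decomposition (s/mm^2), traces:
#>   img 0.5808 | diff 49.99 | ct 3.567 | total 54.14
```

The sequence the scanner would report as b = 50 actually weights at
54.1 s/mm² (+8%): 0.58 from the imaging gradients alone plus 3.57 from
their cross-terms with the diffusion lobes. The b = 0 floor versus
resolution:

```r
min_bvalue_curve("minimal_ct", c(1, 2, 3, 4))
#>   resolution_mm         b0
#> 1             1 10.8054102
#> 2             2  2.6146899
#> 3             3  1.1474791
#> 4             4  0.6404316
```

A 1 mm isotropic "unweighted" image carries ~10.8 s/mm². Propagating the
bias into IVIM: generate noise-free signals with the actual b-values of the
large-cross-term design at 1 mm isotropic (prostate-like truth f = 10%,
D\* = 20 µm²/ms, D = 1 µm²/ms), geometrically average over [x, y, z], and
fit against the *nominal* b-grid:

```r
ab <- actual_bvalues("large_ct", slice_mm = 1, in_plane_mm = c(1, 1),
                     cardinal_sets()$xyz)
S <- matrix(ivim_signal(ab$b_actual, 1, 0.10, 20, 1), 34)
ivim(ab$nominal, directional_average(S, "geometric"),
     init = list(S0 = 1, f = 0.10, Dstar = 20, D = 1))
#> IVIM bi-exponential fit (nlls)
#>   S0 = 0.9558, f = 8.81%, D* = 27.28 um^2/ms, D = 1.074 um^2/ms
#>   RSS 0.000112 over 34 points
```

Nominal-b analysis underestimates f (8.8% vs 10%) and overestimates D\*
(27.3 vs 20) and D (1.07 vs 1) — the characteristic bias signature of a
sequence with large cross-terms. Fitting the same signals against
`ab$b_actual` recovers the truth exactly, and `ivim_bias_sweep()` tabulates
these errors over parameter, slice-thickness and in-plane-resolution
sweeps. An `ivim` fit is a standard model object with `print`, `summary`,
`coef`, `predict`, `fitted`, `residuals`, `plot` and `simulate` methods.

A thin command-line front end is installed at `exec/ivimbias`
(`ivimbias min-b-curve`, `deviation-table`, `simulate-sequence`, `btensor`,
`ivim-sweep`, `synth-dwi`, `fit`, `directions`).

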