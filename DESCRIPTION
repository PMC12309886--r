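Package: ivimbias
Title: Imaging-Gradient b-Value Bias in IVIM Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates pulsed gradient spin-echo (PGSE) diffusion-weighting
    sequences at the gradient-waveform level and quantifies how slice-select,
    crusher and pre-/rewinder imaging gradients -- and their cross-terms with
    the diffusion gradients -- bias the b-value relative to its nominal
    (metadata) value. The b-tensor is decomposed into imaging, diffusion and
    cross-term contributions from the spin dephasing vector, and the resulting
    b-value errors are propagated into intravoxel incoherent motion (IVIM)
    parameter estimates (perfusion fraction f, pseudo-diffusion coefficient
    D*, diffusion coefficient D) via bi-exponential model fits. Includes full
    nonlinear and segmented (threshold-based) IVIM estimators, diffusion
    direction-set generation, waveform import/export, resolution and parameter
    sweep experiments, and a seeded synthetic DWI generator with Rician noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    RNifti,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
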