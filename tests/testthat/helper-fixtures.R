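# shared fixtures for the suite: small, fast sequence configs and truths

default_limits <- hardware_limits()

prostate_truth <- list(S0 = 1, f = 0.10, Dstar = 20, D = 1)

quick_cfg <- function(design = "minimal_ct", res = 3, b = 100,
                      direction = c(0, 0, 1), ...) {
  sequence_config(design, slice_thickness_mm = res[length(res)],
                  in_plane_mm = if (length(res) == 3) res[1:2] else res,
                  nominal_b = b, direction = direction, ...)
}

# relative difference helper
rel <- function(x, ref) abs(x - ref) / abs(ref)

# a hand-built two-lobe rectangular waveform on the diffusion channel
toy_pair_waveform <- function(G = 20, delta = 10, Delta = 25, TE = 50,
                              axis = 3, dt = 0.01) {
  t <- seq(0, TE, by = dt)
  dif <- matrix(0, length(t), 3, dimnames = list(NULL, c("x", "y", "z")))
  lob <- function(t0) as.numeric(t >= t0 & t < t0 + delta) * G
  dif[, axis] <- lob(5) + lob(5 + Delta)
  structure(list(t_ms = t, img = dif * 0, diff = dif, raster_dt_us = dt * 1e3,
                 refocus_ms = 5 + (Delta + delta) / 2, TE_ms = TE,
                 effective = FALSE, gamma = ivimbias:::GAMMA_1H),
            class = "gradient_waveform")
}
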