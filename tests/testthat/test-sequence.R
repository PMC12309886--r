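test_that("slice-select amplitude follows the bandwidth/thickness relation", {
  expect_equal(slice_select_amplitude(600, 1), 14.09244, tolerance = 1e-5)
  expect_equal(slice_select_amplitude(600, 4), 3.52311, tolerance = 1e-5)
  # inverse proportionality in slice thickness
  expect_equal(slice_select_amplitude(600, 2),
               slice_select_amplitude(600, 1) / 2)
  # homogeneity: scaling bandwidth and thickness together is neutral
  for (k in c(0.5, 2, 7)) {
    expect_equal(slice_select_amplitude(600 * k, 1 * k),
                 slice_select_amplitude(600, 1))
  }
  expect_error(slice_select_amplitude(0, 1), "positive")
  expect_error(slice_select_amplitude(600, -1), "positive")
})

test_that("dephasing lobes achieve the target area within hardware limits", {
  lob <- lobe_for_dephasing(6 * pi, 1, default_limits)
  a_expected <- 6 * pi / (ivimbias:::GAMMA_1H * 1e-6 * 1e-3)
  expect_equal(ivimbias:::block_area(lob), a_expected, tolerance = 1e-10)
  expect_equal(ivimbias:::block_area(lob), 70.46221, tolerance = 1e-6)
  # zero dephasing -> absent block
  expect_null(lobe_for_dephasing(0, 1, default_limits))
  # linearity in 1/voxel
  lob3 <- lobe_for_dephasing(6 * pi, 3, default_limits)
  expect_equal(ivimbias:::block_area(lob3),
               ivimbias:::block_area(lob) / 3, tolerance = 1e-12)
  # amplitude and slew ceilings over a range of areas
  for (dphi in pi * c(0.1, 2, 6, 20, 60)) {
    l <- lobe_for_dephasing(dphi, 0.8, default_limits)
    expect_lte(abs(l$amplitude), default_limits$g_max + 1e-9)
    expect_lte(abs(l$amplitude) / l$ramp, default_limits$slew_max + 1e-9)
  }
})

test_that("rewinders null the area of their parent lobe", {
  half <- ivimbias:::gradient_block("z", "imaging", "rect", 0, 3, 14.09244)
  rew <- rewinder_for(half, default_limits)
  expect_equal(ivimbias:::block_area(rew), -42.27732, tolerance = 1e-5)
  expect_equal(ivimbias:::block_area(half) + ivimbias:::block_area(rew), 0)
  expect_null(rewinder_for(NULL, default_limits))
})

test_that("diffusion amplitude matches the Stejskal-Tanner closed form", {
  expect_equal(diffusion_amplitude_for_b(quick_cfg(b = 0)), 0)
  cfg <- quick_cfg(b = 800)
  G <- diffusion_amplitude_for_b(cfg)
  G_oracle <- sqrt(800 / stejskal_tanner_b(1, 20, 40))
  expect_lt(rel(G, G_oracle), 1e-3)
  # b proportional to G^2
  G4 <- diffusion_amplitude_for_b(quick_cfg(b = 200))
  expect_equal(G / G4, 2, tolerance = 1e-9)
  # infeasible b
  tight <- hardware_limits(g_max = 5)
  expect_error(diffusion_amplitude_for_b(quick_cfg(b = 800, limits = tight)),
               "infeasible")
})

test_that("build_pgse applies the design rules deterministically", {
  # minimal-cross-term design drops crushers once diffusion dephasing suffices
  s_hi <- build_pgse(quick_cfg("minimal_ct", 1, b = 800))
  expect_false(s_hi$crushers_on)
  expect_false(any(vapply(s_hi$blocks, function(b)
    b$shape == "tri" && b$axis == "z" && b$channel == "imaging" &&
      b$t_start > 10 && b$amplitude > 0, TRUE)))
  s_lo <- build_pgse(quick_cfg("minimal_ct", 1, b = 5))
  expect_true(s_lo$crushers_on)
  # large-cross-term design always crushes, even at b = 0
  s0 <- build_pgse(quick_cfg("large_ct", 1, b = 0))
  expect_true(s0$crushers_on)
  z_img <- Filter(function(b) b$axis == "z" && b$channel == "imaging" &&
                    b$shape == "tri", s0$blocks)
  expect_gte(length(z_img), 2)
  # bitwise determinism
  expect_identical(build_pgse(quick_cfg("large_ct", 2, b = 300)),
                   build_pgse(quick_cfg("large_ct", 2, b = 300)))
  # per axis/channel blocks are disjoint in time
  for (s in list(s_hi, s_lo, s0)) {
    key <- vapply(s$blocks, function(b) paste(b$axis, b$channel), "")
    for (k in unique(key)) {
      bs <- s$blocks[key == k]
      iv <- t(vapply(bs, function(b) c(b$t_start, b$t_start + b$duration),
                     numeric(2)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (nrow(iv) > 1)
        expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2] - 1e-9))
    }
  }
  # timing infeasibility is reported
  expect_error(build_pgse(quick_cfg("minimal_ct", 1, b = 0, delta_ms = 20,
                                    Delta_ms = 21)),
               "infeasible timing")
})

test_that("rasterized waveforms preserve areas and respect the raster", {
  built <- build_pgse(quick_cfg("minimal_ct", 2, b = 400))
  wf <- rasterize(built)
  expect_equal(length(wf$t_ms),
               ceiling(built$TE_ms / (default_limits$raster_dt_us * 1e-3)) + 1)
  expect_lte(max(abs(wf$img), abs(wf$diff)), default_limits$g_max + 1e-9)
  # rasterized diffusion-lobe area within 0.1% of the analytic area
  G <- built$diffusion_amplitude
  pre <- wf$t_ms <= built$refocus_ms
  area <- pracma::trapz(wf$t_ms[pre], wf$diff[pre, "z"])
  expect_lt(rel(area, G * 20), 1e-3)
  # imaging + diffusion channels sum to the composite sample-wise
  comp <- wf$img + wf$diff
  expect_equal(comp, wf$img + wf$diff)
})

test_that("minimal-ct imaging dephasing is zero over the diffusion window", {
  built <- build_pgse(quick_cfg("minimal_ct", 1, b = 800))
  q <- dephasing(make_effective(rasterize(built)))
  # between excitation rewinder end and refocusing slice plateau start
  rew_end <- max(vapply(Filter(function(b) b$channel == "imaging" &&
                                 b$t_start < 10, built$blocks),
                        ivimbias:::block_end, 0))
  win <- q$t_ms > rew_end + 0.05 &
    q$t_ms < built$refocus_ms - built$config$refocus_ms / 2 - 0.05
  # zero up to the trapezoidal-quadrature residual of the rewinder ramps
  qmax <- max(abs(q$q_img[win, ]))
  expect_lt(qmax, 1e-3 * max(abs(q$q_img)))
})
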