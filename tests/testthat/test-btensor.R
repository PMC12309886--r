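test_that("effective-gradient conversion flips post-refocusing samples once", {
  wf <- toy_pair_waveform()
  eff <- make_effective(wf)
  post <- eff$t_ms > eff$refocus_ms
  expect_equal(eff$diff[post, 3], -wf$diff[post, 3])
  expect_equal(eff$diff[!post, 3], wf$diff[!post, 3])
  expect_error(make_effective(eff), "already")
  # zero waveform is unchanged
  z <- toy_pair_waveform(G = 0)
  expect_equal(make_effective(z)$diff, z$diff)
  # spin-echo balance: equal physical lobes rephase at TE
  q <- dephasing(eff)
  expect_lt(abs(q$q_diff[nrow(q$q_diff), 3]), 1e-6 * max(abs(q$q_diff)))
})

test_that("dephasing is the cumulative integral of the effective gradient", {
  # constant gradient: q linear with slope gamma * g
  dt <- 0.012
  t <- seq(0, 10, by = dt)
  g <- matrix(0, length(t), 3)
  g[, 1] <- 10
  wf <- structure(list(t_ms = t, img = g, diff = g * 0, raster_dt_us = 12,
                       refocus_ms = 9.9, TE_ms = 10, effective = TRUE,
                       gamma = ivimbias:::GAMMA_1H),
                  class = "gradient_waveform")
  q <- dephasing(wf)
  expect_equal(q$q_img[, 1], ivimbias:::qfac() * 10 * t, tolerance = 1e-12)
  # plateau between a rectangular pair: |q| = gamma G delta
  built <- build_pgse(quick_cfg("minimal_ct", 2, b = 400))
  G <- built$diffusion_amplitude
  qq <- dephasing(make_effective(rasterize(built)))
  mid <- which.min(abs(qq$t_ms - built$refocus_ms))
  expect_equal(unname(abs(qq$q_diff[mid, 3])), ivimbias:::qfac() * G * 20,
               tolerance = 1e-3)
  expect_error(dephasing(rasterize(built)), "effective")
})

test_that("isolated rectangular pairs match the Stejskal-Tanner closed form", {
  for (b in c(50, 200, 800)) {
    dec <- pgse_btensor(quick_cfg("minimal_ct", 3, b = b))
    seqb <- attr(dec, "sequence")
    st <- stejskal_tanner_b(seqb$diffusion_amplitude, 20, 40)
    expect_lt(rel(bvalue(dec$B_diff), st), 1e-3)
    expect_lt(rel(bvalue(dec$B_diff), b), 1e-3)  # nominal exact on the raster
  }
})

test_that("b-tensor decomposition is additive, symmetric and channel-aware", {
  dirs <- rbind(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3),
                c(0.36, -0.48, 0.8))
  for (i in seq_len(nrow(dirs))) {
    dec <- pgse_btensor(quick_cfg("large_ct", c(2, 2, 4), b = 100,
                                  direction = dirs[i, ]))
    # distributivity to machine precision
    expect_lt(max(abs(dec$B_total - (dec$B_img + dec$B_diff + dec$B_ct))),
              1e-10 * bvalue(dec$B_total))
    for (M in dec) expect_equal(M, t(M))
    expect_gte(min(eigen(dec$B_img)$values), -1e-9 * bvalue(dec$B_img))
    expect_gte(min(eigen(dec$B_diff)$values), -1e-9 * bvalue(dec$B_diff))
  }
  # no diffusion gradients: B_diff and B_ct vanish
  d0 <- pgse_btensor(quick_cfg("large_ct", 2, b = 0))
  expect_equal(bvalue(d0$B_diff), 0)
  expect_equal(max(abs(d0$B_ct)), 0)
  expect_equal(d0$B_total, d0$B_img)
})

test_that("cross-terms vanish without temporal overlap and are odd in direction", {
  # toy: imaging activity only before, diffusion only after -> B_ct = 0
  dt <- 0.01
  t <- seq(0, 40, by = dt)
  img <- matrix(0, length(t), 3); dif <- img
  img[t >= 1 & t < 6, 3] <- 10
  img[t >= 6 & t < 11, 3] <- -10        # rewound: q_img returns to zero
  dif[t >= 12 & t < 20, 3] <- 15
  dif[t >= 22 & t < 30, 3] <- 15
  wf <- structure(list(t_ms = t, img = img, diff = dif, raster_dt_us = 10,
                       refocus_ms = 21, TE_ms = 40, effective = FALSE,
                       gamma = ivimbias:::GAMMA_1H),
                  class = "gradient_waveform")
  dec <- btensor(dephasing(make_effective(wf)))
  expect_lt(max(abs(dec$B_ct)), 1e-9 * bvalue(dec$B_total))

  # antipodal antisymmetry on full sequences, elementwise
  for (dir in list(c(0, 0, 1), c(1, 2, 2) / 3)) {
    dp <- pgse_btensor(quick_cfg("large_ct", c(2, 2, 4), b = 50,
                                 direction = dir))
    dm <- pgse_btensor(quick_cfg("large_ct", c(2, 2, 4), b = 50,
                                 direction = -dir))
    expect_equal(dp$B_ct, -dm$B_ct, tolerance = 1e-9)
    expect_equal(dp$B_img, dm$B_img, tolerance = 1e-12)
  }
})

test_that("diffusion amplitude scaling laws hold", {
  # scale the diffusion channel by k: tr(B_diff) by k^2, B_ct elementwise by k
  built <- build_pgse(quick_cfg("large_ct", c(2, 2, 4), b = 100,
                                direction = c(1, 1, 1) / sqrt(3)))
  wf <- make_effective(rasterize(built))
  d1 <- btensor(dephasing(wf))
  k <- 3
  wf2 <- wf; wf2$diff <- wf$diff * k
  d2 <- btensor(dephasing(wf2))
  expect_equal(bvalue(d2$B_diff), k^2 * bvalue(d1$B_diff), tolerance = 1e-10)
  expect_equal(d2$B_ct, k * d1$B_ct, tolerance = 1e-10)
  expect_equal(d2$B_img, d1$B_img)
})

test_that("scenario b-values follow the three bookkeeping conventions", {
  expect_equal(bvalue(diag(c(1, 2, 3))), 6)
  expect_equal(bvalue(matrix(0, 3, 3)), 0)
  grid <- c(0, 5, 50, 400)
  trBimg <- list()
  for (dir in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    for (b in grid) {
      dec <- pgse_btensor(quick_cfg("large_ct", c(2, 2, 4), b = b,
                                    direction = dir))
      b_nom <- scenario_bvalue(dec, "nominal")
      b_img <- scenario_bvalue(dec, "img")
      b_full <- scenario_bvalue(dec, "img_ct")
      expect_gte(b_nom, 0)
      expect_gte(b_img, b_nom)
      expect_true(is.finite(b_full))
      expect_equal(b_full, bvalue(dec$B_total), tolerance = 1e-12)
      # IMG - NOMINAL = tr(B_img), independent of diffusion direction
      trb <- b_img - b_nom
      key <- as.character(b)
      if (is.null(trBimg[[key]])) trBimg[[key]] <- trb
      expect_equal(trb, trBimg[[key]], tolerance = 1e-9)
    }
  }
  # zero diffusion: nominal scenario gives exactly 0
  d0 <- pgse_btensor(quick_cfg("minimal_ct", 2, b = 0))
  expect_equal(scenario_bvalue(d0, "nominal"), 0)
  # antipodal averaging cancels the cross-term contribution
  dp <- pgse_btensor(quick_cfg("large_ct", 1, b = 50, direction = c(0, 0, 1)))
  dm <- pgse_btensor(quick_cfg("large_ct", 1, b = 50, direction = c(0, 0, -1)))
  avg <- (scenario_bvalue(dp, "img_ct") + scenario_bvalue(dm, "img_ct")) / 2
  expect_equal(avg, scenario_bvalue(dp, "img"), tolerance = 1e-9)
})

test_that("waveform export/import round-trips the b-value", {
  built <- build_pgse(quick_cfg("large_ct", c(2, 2, 4), b = 150,
                                direction = c(0.6, 0, 0.8)))
  wf <- rasterize(built)
  path <- withr::local_tempfile(fileext = ".txt")
  export_waveform(wf, path, channel = "composite")
  imp <- import_waveform(path)
  expect_equal(imp$TE_ms, wf$TE_ms)
  b_ref <- scenario_bvalue(btensor(dephasing(make_effective(wf))), "img_ct")
  expect_lt(rel(waveform_bvalue(imp), b_ref), 1e-6)

  # all-zero gradients give b = 0
  wf0 <- wf; wf0$img[] <- 0; wf0$diff[] <- 0
  p0 <- withr::local_tempfile(fileext = ".txt")
  export_waveform(wf0, p0)
  expect_equal(waveform_bvalue(import_waveform(p0)), 0)

  # malformed rows are reported with their line number
  lines <- readLines(path)
  lines[10] <- "1.0 2.0"
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, bad)
  expect_error(import_waveform(bad), "line 10")

  # non-uniform time column is rejected
  tab <- read.table(path)
  tab[5, 1] <- tab[5, 1] + 0.004
  bad2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(sprintf("# TE_ms=%g", wf$TE_ms),
               sprintf("# refocus_ms=%g", wf$refocus_ms)), bad2)
  write.table(tab, bad2, append = TRUE, row.names = FALSE, col.names = FALSE)
  expect_error(import_waveform(bad2), "raster|increasing")
})
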