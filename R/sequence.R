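#' Gradient hardware limits
#'
#' Amplitude and slew-rate ceilings plus the waveform raster. The raster
#' default of 12 us matches the temporal resolution used throughout the
#' package's simulations; the amplitude and slew defaults are typical
#' whole-body clinical values and are configurable.
#'
#' @param g_max gradient amplitude ceiling, mT/m.
#' @param slew_max slew-rate ceiling, T/m/s (numerically equal to mT/m/ms).
#' @param raster_dt_us waveform sample spacing, microseconds.
#' @return an object of class `hardware_limits`.
#' @export
hardware_limits <- function(g_max = 80, slew_max = 200, raster_dt_us = 12) {
  stopifnot(g_max > 0, slew_max > 0, raster_dt_us > 0)
  structure(list(g_max = g_max, slew_max = slew_max,
                 raster_dt_us = raster_dt_us),
            class = "hardware_limits")
}

#' Slice-select gradient amplitude
#'
#' Amplitude of a rectangular slice-select gradient,
#' \eqn{G_z = 2\pi \Delta f / (\gamma \Delta z)}, where \eqn{\Delta f} is the
#' transmit bandwidth and \eqn{\Delta z} the slice thickness.
#'
#' @param bandwidth_hz transmit bandwidth, Hz.
#' @param slice_thickness_mm slice thickness, mm.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return amplitude in mT/m.
#' @examples
#' slice_select_amplitude(600, 1)  # about 14.09 mT/m
#' @export
slice_select_amplitude <- function(bandwidth_hz, slice_thickness_mm,
                                   gamma = GAMMA_1H) {
  if (bandwidth_hz <= 0 || slice_thickness_mm <= 0)
    stop("bandwidth and slice thickness must be positive")
  2 * pi * bandwidth_hz / (gamma * slice_thickness_mm * 1e-3) * 1e3
}

# --- gradient blocks ---------------------------------------------------------

# A gradient block is one lobe on one axis/channel. shape "rect" is an ideal
# step (slice-select plateaus, diffusion lobes, as in the modelled sequences);
# shape "tri" is a slew-limited triangle, widening into a trapezoid when the
# amplitude ceiling binds (crushers, pre-/rewinders).
gradient_block <- function(axis, channel, shape, t_start, duration, amplitude,
                           ramp = 0) {
  structure(list(axis = axis, channel = channel, shape = shape,
                 t_start = t_start, duration = duration,
                 amplitude = amplitude, ramp = ramp),
            class = "gradient_block")
}

block_area <- function(block) {
  if (is.null(block) || block$duration <= 0) return(0)
  if (block$shape == "rect") block$amplitude * block$duration
  else block$amplitude * (block$duration - block$ramp)
}

block_end <- function(block) block$t_start + block$duration

# Exact cumulative area of one block, integral of g from -Inf to t, in
# (mT/m)*ms. Piecewise quadratic for linear lobe segments.
block_cumarea <- function(block, t) {
  if (is.null(block) || block$duration <= 0) return(numeric(length(t)))
  t0 <- block$t_start
  if (block$shape == "rect") {
    return(block$amplitude * (clamp(t, t0, t0 + block$duration) - t0))
  }
  r <- block$ramp
  knots <- t0 + c(0, r, block$duration - r, block$duration)
  gk <- c(0, block$amplitude, block$amplitude, 0)
  Ak <- c(0, cumsum(diff(knots) * (gk[-1] + gk[-4]) / 2))
  tc <- clamp(t, knots[1], knots[4])
  i <- findInterval(tc, knots, rightmost.closed = TRUE)
  i <- pmin(i, 3)
  dtk <- tc - knots[i]
  slope <- (gk[i + 1] - gk[i]) / (knots[i + 1] - knots[i])
  Ak[i] + gk[i] * dtk + 0.5 * slope * dtk^2
}

# Sample one block on a time grid (ms): cell-averaged amplitude so that the
# rasterized area of every lobe is exact (no half-open step truncation).
sample_block <- function(block, t) {
  if (is.null(block) || block$duration <= 0) return(numeric(length(t)))
  dt <- if (length(t) > 1) min(diff(t)) else 1e-3
  (block_cumarea(block, t + dt / 2) - block_cumarea(block, t - dt / 2)) / dt
}

#' Shortest slew-limited lobe achieving a target dephasing
#'
#' Builds the shortest triangular (or, when the amplitude ceiling binds,
#' trapezoidal) gradient lobe whose time integral A satisfies
#' \eqn{\gamma \Delta r A = \Delta\phi}, the crusher/rewinder area condition.
#'
#' @param dephasing_rad target dephasing \eqn{\Delta\phi} across the voxel,
#'   radians. Zero yields an empty (NULL) block.
#' @param voxel_mm voxel size \eqn{\Delta r} along the gradient axis, mm.
#' @param limits a [hardware_limits()] object.
#' @param axis,channel,t_start block placement metadata.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return a `gradient_block`, or NULL for zero dephasing.
#' @examples
#' b <- lobe_for_dephasing(6 * pi, 1, hardware_limits())
#' ivimbias:::block_area(b)  # about 70.5 (mT/m) ms
#' @export
lobe_for_dephasing <- function(dephasing_rad, voxel_mm, limits,
                               axis = "z", channel = "imaging", t_start = 0,
                               gamma = GAMMA_1H) {
  if (dephasing_rad < 0) stop("dephasing target must be non-negative")
  if (voxel_mm <= 0) stop("voxel size must be positive")
  if (dephasing_rad == 0) return(NULL)
  area <- dephasing_rad / (qfac(gamma) * voxel_mm * 1e-3)
  shortest_lobe(area, limits, axis = axis, channel = channel,
                t_start = t_start)
}

# Shortest tri/trapezoid lobe of given signed area under hardware limits.
shortest_lobe <- function(area, limits, axis, channel, t_start = 0) {
  if (area == 0) return(NULL)
  a <- abs(area)
  s <- limits$slew_max            # mT/m/ms
  h <- sqrt(a * s)
  if (h <= limits$g_max) {
    ramp <- h / s
    dur <- 2 * ramp
    amp <- h
  } else {
    amp <- limits$g_max
    ramp <- amp / s
    dur <- 2 * ramp + (a / amp - ramp)
  }
  gradient_block(axis, channel, "tri", t_start, dur, sign(area) * amp,
                 ramp = ramp)
}

#' Rewinder for a gradient block
#'
#' Returns the shortest lobe with equal-magnitude, opposite-sign area,
#' nulling the net dephasing of `block` (the condition
#' \eqn{\Delta\phi_{img} + \Delta\phi_{re} = 0}).
#'
#' @param block a `gradient_block` (or NULL).
#' @param limits a [hardware_limits()] object.
#' @param t_start placement time, ms; defaults to immediately after `block`.
#' @return a `gradient_block`, or NULL if `block` has zero area.
#' @export
rewinder_for <- function(block, limits, t_start = NULL) {
  a <- block_area(block)
  if (a == 0) return(NULL)
  if (is.null(t_start)) t_start <- block_end(block)
  shortest_lobe(-a, limits, axis = block$axis, channel = block$channel,
                t_start = t_start)
}

#' Sequence configuration
#'
#' Everything needed to deterministically build one PGSE waveform: the design
#' variant, imaging geometry, RF/slice parameters, crusher and readout
#' prewinder dephasing targets, diffusion timing and direction, and hardware
#' limits.
#'
#' Two designs are modelled. `"large_ct"` merges the excitation slice
#' rewinder into the crusher prewinder (a single lobe just before the
#' refocusing pulse) and applies crushers regardless of the diffusion
#' gradients, so the imaging dephasing stays non-zero throughout the
#' diffusion encoding and large cross-terms arise. `"minimal_ct"` rewinds
#' immediately after excitation and drops the crushers whenever the diffusion
#' gradients alone dephase spurious echoes sufficiently, keeping the imaging
#' dephasing at zero for as long as possible.
#'
#' @param design `"large_ct"` or `"minimal_ct"`.
#' @param slice_thickness_mm slice thickness, mm.
#' @param in_plane_mm in-plane voxel size, mm; length-2 (x, y) or scalar.
#' @param nominal_b nominal b-value, s/mm^2.
#' @param direction diffusion gradient direction, unit 3-vector.
#' @param delta_ms diffusion lobe duration, ms.
#' @param Delta_ms diffusion lobe separation (leading edge to leading edge), ms.
#' @param bandwidth_hz RF transmit bandwidth, Hz.
#' @param excitation_ms,refocus_ms slice-select pulse (plateau) durations, ms.
#' @param crusher_dephasing crusher target dephasing, radians (default 6 pi).
#' @param crusher_axes axes carrying crusher lobes when crushers are on
#'   (default all three; clinical implementations sometimes crush the slice
#'   axis only).
#' @param readout_dephasing readout prewinder dephasing across the in-plane
#'   voxel, radians (default pi, the half k-space sweep).
#' @param limits a [hardware_limits()] object.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1.
#' @return an object of class `sequence_config`.
#' @examples
#' cfg <- sequence_config("minimal_ct", slice_thickness_mm = 1,
#'                        in_plane_mm = 1, nominal_b = 800)
#' @export
sequence_config <- function(design = c("minimal_ct", "large_ct"),
                            slice_thickness_mm = 4,
                            in_plane_mm = c(2, 2),
                            nominal_b = 0,
                            direction = c(0, 0, 1),
                            delta_ms = 20, Delta_ms = 40,
                            bandwidth_hz = 600,
                            excitation_ms = 6, refocus_ms = 7,
                            crusher_dephasing = 6 * pi,
                            crusher_axes = c("x", "y", "z"),
                            readout_dephasing = pi,
                            limits = hardware_limits(),
                            gamma = GAMMA_1H) {
  design <- match.arg(design)
  if (length(in_plane_mm) == 1) in_plane_mm <- rep(in_plane_mm, 2)
  stopifnot(slice_thickness_mm > 0, all(in_plane_mm > 0),
            delta_ms > 0, Delta_ms >= delta_ms, nominal_b >= 0,
            bandwidth_hz > 0, excitation_ms > 0, refocus_ms > 0,
            crusher_dephasing >= 0, all(crusher_axes %in% c("x", "y", "z")))
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) {
    if (nrm == 0) stop("direction must be a non-zero vector")
    direction <- direction / nrm
  }
  structure(list(design = design,
                 slice_thickness_mm = slice_thickness_mm,
                 in_plane_mm = in_plane_mm,
                 nominal_b = nominal_b,
                 direction = direction,
                 delta_ms = delta_ms, Delta_ms = Delta_ms,
                 bandwidth_hz = bandwidth_hz,
                 excitation_ms = excitation_ms, refocus_ms = refocus_ms,
                 crusher_dephasing = crusher_dephasing,
                 crusher_axes = crusher_axes,
                 readout_dephasing = readout_dephasing,
                 limits = limits, gamma = gamma),
            class = "sequence_config")
}

# Voxel dimension along each axis (x, y in-plane; z slice), mm.
voxel_dims <- function(config) {
  c(x = config$in_plane_mm[1], y = config$in_plane_mm[2],
    z = config$slice_thickness_mm)
}

#' Diffusion gradient amplitude for a nominal b-value
#'
#' Solves for the rectangular-lobe amplitude G such that the isolated
#' diffusion pair, rasterized at the configured raster, has
#' `tr(B_diff)` equal to the nominal b-value. Because the rasterized trace is
#' exactly proportional to G^2, one unit-amplitude evaluation gives the
#' solution in closed form; the Stejskal-Tanner expression
#' [stejskal_tanner_b()] serves as the analytic cross-check.
#'
#' @param config a [sequence_config()] (fields `nominal_b`, `delta_ms`,
#'   `Delta_ms`, `limits`, `gamma` are used).
#' @return amplitude in mT/m (0 for nominal b = 0).
#' @export
diffusion_amplitude_for_b <- function(config) {
  b <- config$nominal_b
  if (b == 0) return(0)
  b_unit <- isolated_pair_trace(1, config)
  G <- sqrt(b / b_unit)
  if (G > config$limits$g_max)
    stop(sprintf("nominal b = %g s/mm^2 infeasible: requires %.1f mT/m > g_max",
                 b, G))
  G
}

# tr(B_diff) of an isolated rasterized rectangular pair at amplitude G.
isolated_pair_trace <- function(G, config) {
  d <- config$delta_ms; D <- config$Delta_ms
  dt <- config$limits$raster_dt_us * 1e-3
  TE <- D + d + 2          # small tail either side
  t <- seq(0, TE, by = dt)
  # effective polarity: second lobe negated after the refocusing pulse
  g <- sample_block(gradient_block("z", "diffusion", "rect", 1, d, G), t) -
    sample_block(gradient_block("z", "diffusion", "rect", 1 + D, d, G), t)
  q <- qfac(config$gamma) * pracma::cumtrapz(t, g)
  sum_trapz(t, q^2) * B_UNIT
}

# trapezoid integral of sampled values y over t
sum_trapz <- function(t, y) pracma::trapz(t, y)

#' Build a PGSE gradient-block timeline
#'
#' Assembles the full block list for the configured design with minimal-TE
#' packing: time origin at the excitation RF centre (so the excitation
#' slice-select gradient contributes its post-isocentre half plus rewinder),
#' diffusion lobes symmetric about the refocusing pulse centre, crushers
#' bracketing the refocusing slice plateau on all three axes, and the readout
#' prewinder ending at TE.
#'
#' For `"minimal_ct"`, the excitation rewinder follows the excitation plateau
#' immediately and crushers are omitted once the diffusion dephasing across
#' every voxel dimension meets the crusher target. For `"large_ct"`, the
#' excitation rewinder is merged with the slice-axis crusher prewinder into a
#' single lobe placed just before the refocusing plateau, and crushers are
#' always present.
#'
#' @param config a [sequence_config()].
#' @return a list of class `pgse_sequence` with elements `blocks`,
#'   `refocus_ms`, `TE_ms`, `crushers_on`, `diffusion_amplitude`, `config`.
#' @export
build_pgse <- function(config) {
  lim <- config$limits
  gss_ex <- slice_select_amplitude(config$bandwidth_hz,
                                   config$slice_thickness_mm, config$gamma)
  gss_ref <- gss_ex
  if (max(gss_ex, gss_ref) > lim$g_max)
    stop("slice-select amplitude exceeds g_max")
  vox <- voxel_dims(config)
  Gd <- diffusion_amplitude_for_b(config)
  q_d <- qfac(config$gamma) * Gd * config$delta_ms   # rad/m at refocusing

  crushers_on <- if (config$design == "large_ct") TRUE else
    !all(q_d * vox[config$crusher_axes] * 1e-3 >= config$crusher_dephasing)

  blocks <- list()
  add <- function(b) if (!is.null(b)) blocks[[length(blocks) + 1]] <<- b

  # excitation slice select: post-isocentre half of the plateau
  exc <- gradient_block("z", "imaging", "rect", 0, config$excitation_ms / 2,
                        gss_ex)
  add(exc)
  rew <- rewinder_for(exc, lim)

  exc_end <- block_end(exc)
  if (config$design == "minimal_ct") {
    add(rew)
    exc_end <- block_end(rew)
  }

  t_ref <- exc_end + (config$Delta_ms + config$delta_ms) / 2
  TE <- 2 * t_ref
  half_gap <- (config$Delta_ms - config$delta_ms) / 2

  # refocusing slice plateau, split symmetrically about the pulse centre
  ref_block <- gradient_block("z", "imaging", "rect",
                              t_ref - config$refocus_ms / 2,
                              config$refocus_ms, gss_ref)
  add(ref_block)

  crusher_area <- config$crusher_dephasing / (qfac(config$gamma) * vox * 1e-3)
  pre_end <- t_ref - config$refocus_ms / 2
  post_start <- t_ref + config$refocus_ms / 2

  used_pre <- 0
  if (crushers_on) {
    for (ax in config$crusher_axes) {
      a <- crusher_area[[ax]]
      if (config$design == "large_ct" && ax == "z") {
        # merged lobe: excitation rewinder + crusher prewinder areas
        a <- a + block_area(rew)   # rewinder area is negative
      }
      pre <- shortest_lobe(a, lim, ax, "imaging")
      pre$t_start <- pre_end - pre$duration
      post <- shortest_lobe(crusher_area[[ax]], lim, ax, "imaging",
                            t_start = post_start)
      used_pre <- max(used_pre, pre$duration)
      add(pre); add(post)
    }
  }
  if (config$refocus_ms / 2 + used_pre > half_gap)
    stop("infeasible timing: refocusing block does not fit between diffusion lobes")

  # readout prewinder, in-plane axis, ending at TE
  ro <- shortest_lobe(-config$readout_dephasing /
                        (qfac(config$gamma) * vox[["x"]] * 1e-3),
                      lim, "x", "imaging")
  ro$t_start <- TE - ro$duration
  if (ro$t_start < t_ref + (config$Delta_ms + config$delta_ms) / 2)
    stop("infeasible timing: readout prewinder overlaps diffusion lobe")
  add(ro)

  # diffusion lobes, same physical polarity, symmetric about t_ref
  if (Gd > 0) {
    t1 <- t_ref - (config$Delta_ms + config$delta_ms) / 2
    t2 <- t1 + config$Delta_ms
    for (i in 1:3) {
      ax <- c("x", "y", "z")[i]
      gi <- Gd * config$direction[i]
      if (gi != 0) {
        add(gradient_block(ax, "diffusion", "rect", t1, config$delta_ms, gi))
        add(gradient_block(ax, "diffusion", "rect", t2, config$delta_ms, gi))
      }
    }
  }

  check_blocks(blocks, lim)
  structure(list(blocks = blocks, refocus_ms = t_ref, TE_ms = TE,
                 crushers_on = crushers_on, diffusion_amplitude = Gd,
                 config = config),
            class = "pgse_sequence")
}

# invariants: amplitude/slew ceilings, per axis-channel disjointness
check_blocks <- function(blocks, lim) {
  for (b in blocks) {
    if (abs(b$amplitude) > lim$g_max + 1e-9)
      stop("block amplitude exceeds g_max")
    if (b$shape == "tri" && abs(b$amplitude) / b$ramp > lim$slew_max + 1e-9)
      stop("block slew exceeds slew_max")
  }
  key <- vapply(blocks, function(b) paste(b$axis, b$channel), "")
  for (k in unique(key)) {
    bs <- blocks[key == k]
    if (length(bs) < 2) next
    iv <- t(vapply(bs, function(b) c(b$t_start, block_end(b)), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-9))
      stop("overlapping blocks on axis/channel ", k)
  }
  invisible(TRUE)
}

#' @export
print.pgse_sequence <- function(x, ...) {
  cat(sprintf("PGSE sequence (%s design)\n", x$config$design))
  cat(sprintf("  TE = %.3f ms, refocusing at %.3f ms\n", x$TE_ms, x$refocus_ms))
  cat(sprintf("  nominal b = %g s/mm^2, G_diff = %.3f mT/m, crushers %s\n",
              x$config$nominal_b, x$diffusion_amplitude,
              if (x$crushers_on) "on" else "off"))
  cat(sprintf("  %d gradient blocks\n", length(x$blocks)))
  invisible(x)
}

#' Rasterize a PGSE block timeline
#'
#' Samples the imaging and diffusion channels separately on the common raster
#' over \[0, TE\]. Lobes are sampled from their analytic piecewise form, so
#' per-lobe area errors are bounded by one raster sample.
#'
#' @param seq_built a `pgse_sequence` from [build_pgse()].
#' @return an object of class `gradient_waveform` with fields `t_ms`,
#'   `img` and `diff` (N x 3 matrices, mT/m), `raster_dt_us`, `refocus_ms`,
#'   `TE_ms`, `effective` (FALSE: physical polarity).
#' @export
rasterize <- function(seq_built) {
  lim <- seq_built$config$limits
  dt <- lim$raster_dt_us * 1e-3
  t <- seq(0, seq_built$TE_ms, by = dt)
  if (t[length(t)] < seq_built$TE_ms) t <- c(t, seq_built$TE_ms)
  img <- matrix(0, length(t), 3, dimnames = list(NULL, c("x", "y", "z")))
  dif <- img
  for (b in seq_built$blocks) {
    col <- match(b$axis, c("x", "y", "z"))
    g <- sample_block(b, t)
    if (b$channel == "imaging") img[, col] <- img[, col] + g
    else dif[, col] <- dif[, col] + g
  }
  structure(list(t_ms = t, img = img, diff = dif,
                 raster_dt_us = lim$raster_dt_us,
                 refocus_ms = seq_built$refocus_ms, TE_ms = seq_built$TE_ms,
                 effective = FALSE, gamma = seq_built$config$gamma),
            class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("gradient waveform: %d samples at %g us, TE %.3f ms, %s polarity\n",
              length(x$t_ms), x$raster_dt_us, x$TE_ms,
              if (x$effective) "effective" else "physical"))
  invisible(x)
}
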