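#' Apply the effective-gradient sign convention
#'
#' Negates all samples after the refocusing pulse centre on both channels, so
#' that spin-echo rephasing appears as net dephasing cancellation. Errors if
#' the waveform is already in effective form (guarding against double
#' inversion).
#'
#' @param waveform a `gradient_waveform`.
#' @return the waveform with `effective = TRUE`.
#' @export
make_effective <- function(waveform) {
  stopifnot(inherits(waveform, "gradient_waveform"))
  if (isTRUE(waveform$effective))
    stop("waveform is already in effective form")
  post <- waveform$t_ms > waveform$refocus_ms
  waveform$img[post, ] <- -waveform$img[post, ]
  waveform$diff[post, ] <- -waveform$diff[post, ]
  waveform$effective <- TRUE
  waveform
}

#' Spin dephasing trajectories
#'
#' Cumulative trapezoidal integral \eqn{q(t) = \gamma \int_0^t g(u)\,du} of
#' the effective gradient, per axis and channel, in rad/m.
#'
#' @param waveform an effective `gradient_waveform` (see [make_effective()]).
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1; defaults to the waveform's.
#' @return an object of class `dephasing_trajectory` with `t_ms`, `q_img`,
#'   `q_diff` (N x 3, rad/m).
#' @export
dephasing <- function(waveform, gamma = NULL) {
  stopifnot(inherits(waveform, "gradient_waveform"))
  if (!isTRUE(waveform$effective))
    stop("dephasing requires an effective waveform; call make_effective() first")
  if (is.null(gamma)) gamma <- waveform$gamma %||% GAMMA_1H
  f <- qfac(gamma)
  structure(list(t_ms = waveform$t_ms,
                 q_img = f * pracma::cumtrapz(waveform$t_ms, waveform$img),
                 q_diff = f * pracma::cumtrapz(waveform$t_ms, waveform$diff)),
            class = "dephasing_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' b-tensor decomposition from dephasing trajectories
#'
#' Trapezoidal integrals over \[0, TE\] of the outer products of the imaging
#' and diffusion dephasing vectors:
#' \eqn{B_{img} = \int q_{img} \otimes q_{img}\,dt},
#' \eqn{B_{diff} = \int q_{diff} \otimes q_{diff}\,dt},
#' \eqn{B_{ct} = \int (q_{img} \otimes q_{diff} + q_{diff} \otimes q_{img})\,dt},
#' with \eqn{B = B_{img} + B_{diff} + B_{ct}}. Tensors are numerically
#' symmetrized and reported in s/mm^2.
#'
#' @param q a `dephasing_trajectory` from [dephasing()].
#' @return an object of class `btensor_decomposition` with 3 x 3 matrices
#'   `B_img`, `B_diff`, `B_ct`, `B_total`.
#' @export
btensor <- function(q) {
  stopifnot(inherits(q, "dephasing_trajectory"))
  t <- q$t_ms
  n <- length(t)
  # trapezoid weights for non-uniform grids
  w <- numeric(n)
  dt <- diff(t)
  w[1] <- dt[1] / 2
  w[n] <- dt[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dt[-1] + dt[-(n - 1)]) / 2
  symm <- function(M) (M + t(M)) / 2
  xprod <- function(A, B) crossprod(A * w, B) * B_UNIT
  B_img <- symm(xprod(q$q_img, q$q_img))
  B_diff <- symm(xprod(q$q_diff, q$q_diff))
  cr <- xprod(q$q_img, q$q_diff)
  B_ct <- symm(cr + t(cr))
  structure(list(B_img = B_img, B_diff = B_diff, B_ct = B_ct,
                 B_total = B_img + B_diff + B_ct),
            class = "btensor_decomposition")
}

#' @export
print.btensor_decomposition <- function(x, digits = 4, ...) {
  cat("b-tensor decomposition (s/mm^2), traces:\n")
  cat(sprintf("  img %.*g | diff %.*g | ct %.*g | total %.*g\n",
              digits, bvalue(x$B_img), digits, bvalue(x$B_diff),
              digits, bvalue(x$B_ct), digits, bvalue(x$B_total)))
  invisible(x)
}

#' b-value of a b-tensor
#'
#' The b-value is the trace of the b-tensor.
#'
#' @param B a symmetric 3 x 3 matrix, s/mm^2.
#' @return trace, s/mm^2.
#' @export
bvalue <- function(B) sum(diag(B))

#' Scenario b-values
#'
#' Evaluates the b-value under one of three bookkeeping scenarios:
#' `"nominal"` counts only the diffusion gradients (`tr B_diff`), `"img"`
#' adds the imaging gradients (`tr(B_diff + B_img)`), and `"img_ct"` is the
#' full calculation including cross-terms -- the actual b-value of the pulse
#' sequence.
#'
#' @param decomp a `btensor_decomposition`.
#' @param scenario one of `"nominal"`, `"img"`, `"img_ct"`.
#' @return b-value in s/mm^2.
#' @export
scenario_bvalue <- function(decomp,
                            scenario = c("nominal", "img", "img_ct")) {
  stopifnot(inherits(decomp, "btensor_decomposition"))
  scenario <- match.arg(scenario)
  switch(scenario,
         nominal = bvalue(decomp$B_diff),
         img = bvalue(decomp$B_diff) + bvalue(decomp$B_img),
         img_ct = bvalue(decomp$B_total))
}

#' Build, rasterize and decompose a PGSE sequence in one call
#'
#' Convenience pipeline: [build_pgse()], [rasterize()], [make_effective()],
#' [dephasing()], [btensor()].
#'
#' @param config a [sequence_config()].
#' @return a `btensor_decomposition`; the built sequence is attached as
#'   attribute `"sequence"`.
#' @examples
#' d <- pgse_btensor(sequence_config("minimal_ct", 3, 3, nominal_b = 100))
#' scenario_bvalue(d, "img_ct")
#' @export
pgse_btensor <- function(config) {
  built <- build_pgse(config)
  wf <- make_effective(rasterize(built))
  out <- btensor(dephasing(wf))
  attr(out, "sequence") <- built
  out
}

# --- waveform text I/O -------------------------------------------------------

#' Export a gradient waveform as delimited text
#'
#' Writes header lines `# TE_ms=`, `# refocus_ms=`, `# raster_us=` followed by
#' whitespace-delimited columns `t_ms gx_mT_per_m gy gz`. One file per
#' channel (`"imaging"`, `"diffusion"`) or the sample-wise sum
#' (`"composite"`).
#'
#' @param waveform a `gradient_waveform`.
#' @param path output file path.
#' @param channel `"composite"`, `"imaging"` or `"diffusion"`.
#' @return `path`, invisibly.
#' @export
export_waveform <- function(waveform, path,
                            channel = c("composite", "imaging", "diffusion")) {
  channel <- match.arg(channel)
  g <- switch(channel,
              composite = waveform$img + waveform$diff,
              imaging = waveform$img,
              diffusion = waveform$diff)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# TE_ms=%.9g", waveform$TE_ms),
               sprintf("# refocus_ms=%.9g", waveform$refocus_ms),
               sprintf("# raster_us=%.9g", waveform$raster_dt_us),
               "# t_ms gx_mT_per_m gy gz"), con)
  write.table(data.frame(t = waveform$t_ms, g),
              con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import a recorded gradient waveform
#'
#' Reads the delimited-text dialect written by [export_waveform()] (or any
#' file with columns time, gx, gy, gz and the same headers). Imported samples
#' are assigned to a single composite channel, so only the total b-tensor and
#' b-value are defined downstream -- channel decomposition requires
#' builder-produced waveforms. Header metadata may be overridden by the
#' `refocus_ms` / `TE_ms` arguments (required if absent from the file).
#'
#' @param path input file.
#' @param refocus_ms,TE_ms refocusing-centre time and echo time, ms.
#' @param effective whether the recorded samples already follow the
#'   effective-gradient sign convention (default FALSE).
#' @return a `gradient_waveform` whose composite samples are stored on the
#'   imaging channel with an attribute `composite = TRUE`.
#' @export
import_waveform <- function(path, refocus_ms = NULL, TE_ms = NULL,
                            effective = FALSE) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^#\\s*(\\w+)=([0-9.eE+-]+)", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop(sprintf("malformed waveform row at line %d: expected 4 columns, got %d",
                 setdiff(seq_along(lines), hdr)[bad], nf[bad]))
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                  ncol = 4, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1, anyNA))[1]
    stop(sprintf("malformed waveform row at line %d: non-numeric field",
                 setdiff(seq_along(lines), hdr)[bad]))
  }
  t <- vals[, 1]
  if (is.unsorted(t, strictly = TRUE))
    stop("time column must be strictly increasing")
  dts <- diff(t)
  if (max(dts) - min(dts) > 1e-3 * stats::median(dts))
    stop("non-uniform raster beyond tolerance")
  refocus_ms <- refocus_ms %||% meta$refocus_ms
  TE_ms <- TE_ms %||% meta$TE_ms
  if (is.null(refocus_ms) || is.null(TE_ms))
    stop("refocus_ms and TE_ms must be given in the header or as arguments")
  g <- vals[, 2:4, drop = FALSE]
  colnames(g) <- c("x", "y", "z")
  wf <- structure(list(t_ms = t, img = g, diff = 0 * g,
                       raster_dt_us = stats::median(dts) * 1e3,
                       refocus_ms = refocus_ms, TE_ms = TE_ms,
                       effective = isTRUE(effective), gamma = GAMMA_1H),
                  class = "gradient_waveform")
  attr(wf, "composite") <- TRUE
  wf
}

#' Total b-value of a composite (imported) waveform
#'
#' Applies the effective-gradient convention if needed, integrates the
#' dephasing vector and returns `tr(B)` of the full waveform. This is the
#' actual-b-value computation for recorded g(t) arrays, where imaging and
#' diffusion channels cannot be separated.
#'
#' @param waveform a `gradient_waveform` (typically from [import_waveform()]).
#' @return b-value in s/mm^2.
#' @export
waveform_bvalue <- function(waveform) {
  if (!isTRUE(waveform$effective)) waveform <- make_effective(waveform)
  bvalue(btensor(dephasing(waveform))$B_total)
}
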