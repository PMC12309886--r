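#' Bi-exponential IVIM signal model
#'
#' \eqn{S(b) = S_0 [ f e^{-b D^*} + (1 - f) e^{-b D} ]}, with the perfusion
#' fraction `f` stored as a fraction and the diffusion coefficients given in
#' um^2/ms (converted to mm^2/s internally, factor 1e-3, before multiplying
#' by b in s/mm^2).
#'
#' @param b b-values, s/mm^2.
#' @param S0 signal at b = 0 (arbitrary units).
#' @param f perfusion fraction in \[0, 1\].
#' @param Dstar pseudo-diffusion coefficient, um^2/ms.
#' @param D diffusion coefficient, um^2/ms.
#' @return signal values, same length as `b`.
#' @examples
#' ivim_signal(800, S0 = 1, f = 0.1, Dstar = 20, D = 1)
#' @export
ivim_signal <- function(b, S0 = 1, f, Dstar, D) {
  stopifnot(all(b >= 0))
  S0 * (f * exp(-b * Dstar * 1e-3) + (1 - f) * exp(-b * D * 1e-3))
}

#' Default IVIM parameter bounds
#'
#' Generous physiological envelopes used by the bounded least-squares fits:
#' f in \[0, 0.7\], D* in \[1, 300\] um^2/ms, D in \[0.05, 4\] um^2/ms, S0
#' positive.
#'
#' @return list with `lower` and `upper` named vectors.
#' @export
ivim_bounds <- function() {
  list(lower = c(S0 = 1e-12, f = 0, Dstar = 1, D = 0.05),
       upper = c(S0 = Inf, f = 0.7, Dstar = 300, D = 4))
}

#' Fit the IVIM model
#'
#' Estimates (S0, f, D*, D) from diffusion-weighted signals by either a
#' single-step bounded nonlinear least-squares fit (`method = "nlls"`,
#' Levenberg-Marquardt) or the three-step segmented algorithm
#' (`method = "segmented"`):
#' \enumerate{
#'   \item D and an extrapolated intercept from a linear fit to the log
#'     signal at b-values at or above `threshold`;
#'   \item the extrapolated mono-exponential is subtracted from the total
#'     signal and a nonlinear fit of the low-b residual yields initial
#'     estimates of f and D*;
#'   \item a final nonlinear least-squares fit of (S0, f, D*) on the
#'     original signal with D fixed, initialized at the step-2 values.
#' }
#'
#' The default `threshold` of 200 s/mm^2 is inclusive (a b = 200 shell
#' belongs to the high-b segment). Negative step-2 residuals are clipped to
#' `1e-6 * max(signal)` before the log/nonlinear step. Non-convergence is
#' flagged on the returned object, not raised.
#'
#' @param x b-values (s/mm^2) for the default method, or a formula
#'   `signal ~ b` for the formula method.
#' @param signal signal values (default method).
#' @param data a data frame holding the formula variables.
#' @param method `"nlls"` or `"segmented"`.
#' @param init optional named list/vector with starting values `S0`, `f`,
#'   `Dstar`, `D` (e.g. ground truth in simulation studies). Heuristic
#'   starting values are derived from the data when omitted.
#' @param threshold segmentation threshold, s/mm^2.
#' @param bounds parameter bounds as from [ivim_bounds()].
#' @param control passed to [minpack.lm::nls.lm.control()]; defaults to
#'   `ftol = ptol = 1e-10`, `maxiter = 1000`.
#' @param ... passed between methods.
#' @return an object of class `"ivim"`: a list with components
#'   `coefficients` (S0, f, Dstar, D), `fitted.values`, `residuals`, `rss`,
#'   `converged`, `method`, `data`, `threshold`, `call`.
#' @examples
#' b <- nominal_b_grid()
#' s <- ivim_signal(b, S0 = 100, f = 0.1, Dstar = 20, D = 1)
#' fit <- ivim(b, s)
#' coef(fit)
#' @export
ivim <- function(x, ...) UseMethod("ivim")

#' @rdname ivim
#' @export
ivim.formula <- function(x, data = parent.frame(), ...) {
  mf <- stats::model.frame(x, data)
  out <- ivim.default(mf[[2L]], mf[[1L]], ...)
  out$call <- match.call()
  out
}

#' @rdname ivim
#' @export
ivim.default <- function(x, signal, method = c("nlls", "segmented"),
                         init = NULL, threshold = 200,
                         bounds = ivim_bounds(),
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 1000),
                         ...) {
  b <- as.numeric(x)
  signal <- as.numeric(signal)
  method <- match.arg(method)
  stopifnot(length(b) == length(signal))
  if (any(!is.finite(b)) || any(!is.finite(signal)))
    stop("b and signal must be finite")
  if (any(signal <= 0)) stop("signals must be positive")
  if (length(unique(b)) < 4) stop("need at least 4 distinct b-values")

  fit <- if (method == "nlls")
    fit_ivim_nlls(b, signal, init, bounds, control)
  else
    fit_ivim_segmented(b, signal, init, threshold, bounds, control)

  est <- fit$par
  fitted <- ivim_signal(b, est["S0"], est["f"], est["Dstar"], est["D"])
  res <- signal - fitted
  structure(list(coefficients = est,
                 fitted.values = fitted,
                 residuals = res,
                 rss = sum(res^2),
                 converged = fit$converged,
                 niter = fit$niter,
                 method = method,
                 threshold = if (method == "segmented") threshold else NA_real_,
                 data = list(b = b, signal = signal),
                 bounds = bounds,
                 call = match.call()),
            class = "ivim")
}

heuristic_init <- function(b, signal, threshold, bounds) {
  hi <- b >= threshold & b > 0
  if (sum(hi) >= 2) {
    cf <- stats::lm.fit(cbind(1, b[hi]), log(signal[hi]))$coefficients
    D0 <- clamp(-cf[2] * 1e3, bounds$lower["D"], bounds$upper["D"])
    Sint <- exp(cf[1])
  } else {
    D0 <- 1
    Sint <- max(signal)
  }
  S00 <- max(signal)
  f0 <- clamp(1 - Sint / S00, 0.01, bounds$upper["f"])
  c(S0 = unname(S00), f = unname(f0),
    Dstar = unname(clamp(10 * D0, bounds$lower["Dstar"], bounds$upper["Dstar"])),
    D = unname(D0))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

as_init <- function(init, b, signal, threshold, bounds) {
  if (is.null(init)) return(heuristic_init(b, signal, threshold, bounds))
  init <- unlist(init)
  stopifnot(all(c("S0", "f", "Dstar", "D") %in% names(init)))
  init[c("S0", "f", "Dstar", "D")]
}

fit_ivim_nlls <- function(b, signal, init, bounds, control) {
  p0 <- as_init(init, b, signal, 200, bounds)
  p0 <- clamp(p0, bounds$lower, bounds$upper)
  p0["S0"] <- min(p0["S0"], 10 * max(signal))
  resid_fn <- function(p) signal - ivim_signal(b, p[1], p[2], p[3], p[4])
  fit <- minpack.lm::nls.lm(par = p0, lower = bounds$lower,
                            upper = bounds$upper, fn = resid_fn,
                            control = control)
  list(par = setNames(fit$par, names(p0)),
       converged = fit$info %in% 1:4, niter = fit$niter)
}

fit_ivim_segmented <- function(b, signal, init, threshold, bounds, control) {
  hi <- b >= threshold
  lo <- !hi
  if (sum(hi) < 2 || sum(lo) < 2)
    stop("segmented fit needs at least 2 b-values on each side of the threshold")

  # step 1: log-linear fit above the threshold -> D, extrapolated intercept
  cf <- stats::lm.fit(cbind(1, b[hi]), log(signal[hi]))$coefficients
  D <- clamp(-cf[2] * 1e3, bounds$lower["D"], bounds$upper["D"])
  S_int <- exp(cf[1])

  # step 2: subtract the extrapolated mono-exponential, fit the residual
  floor_val <- 1e-6 * max(signal)
  r <- pmax(signal - S_int * exp(-b * D * 1e-3), floor_val)
  amp0 <- max(r[lo])
  pos <- lo & r > floor_val
  Dstar0 <- 20
  if (sum(pos) >= 2) {
    cf2 <- stats::lm.fit(cbind(1, b[pos]), log(r[pos]))$coefficients
    Dstar0 <- clamp(-cf2[2] * 1e3, bounds$lower["Dstar"], bounds$upper["Dstar"])
  }
  p2 <- c(amp = unname(amp0), Dstar = unname(Dstar0))
  fit2 <- minpack.lm::nls.lm(
    par = p2,
    lower = c(amp = 0, Dstar = unname(bounds$lower["Dstar"])),
    upper = c(amp = Inf, Dstar = unname(bounds$upper["Dstar"])),
    fn = function(p) r[lo] - p[1] * exp(-b[lo] * p[2] * 1e-3),
    control = control)
  amp <- fit2$par[1]
  Dstar <- fit2$par[2]

  # step 3: final fit of (S0, f, D*) with D fixed
  S0_0 <- S_int + amp
  f0 <- clamp(amp / S0_0, bounds$lower["f"], bounds$upper["f"])
  p3 <- c(S0 = unname(S0_0), f = unname(f0), Dstar = unname(Dstar))
  fit3 <- minpack.lm::nls.lm(
    par = p3,
    lower = c(S0 = unname(bounds$lower["S0"]), f = unname(bounds$lower["f"]),
              Dstar = unname(bounds$lower["Dstar"])),
    upper = c(S0 = unname(bounds$upper["S0"]), f = unname(bounds$upper["f"]),
              Dstar = unname(bounds$upper["Dstar"])),
    fn = function(p) signal - ivim_signal(b, p[1], p[2], p[3], D),
    control = control)

  list(par = c(setNames(fit3$par, c("S0", "f", "Dstar")), D = unname(D)),
       converged = fit2$info %in% 1:4 && fit3$info %in% 1:4,
       niter = fit3$niter)
}
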