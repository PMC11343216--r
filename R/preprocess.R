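## Notch filtering, photobleach detrending (dF/F), generic zero-phase band
## filtering, and the two channel-decrosstalking procedures.

#' Zero-phase band-stop (notch) filter
#'
#' Forward-backward application of an 8th-order recursive band-stop design
#' (order refers to the single-pass filter). Used to remove narrow-band
#' instrumentation lines, e.g. 300 +- 1 Hz and 600 +- 1 Hz diffuser artifacts
#' or 60 Hz mains contamination.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param center notch center frequency, Hz.
#' @param halfwidth half width of the stop band, Hz (band is center +- halfwidth).
#' @param order single-pass filter order (default 8).
#' @export
notch_filter <- function(x, fs, center, halfwidth = 1, order = 8) {
  lo <- center - halfwidth
  hi <- center + halfwidth
  if (lo <= 0 || hi >= fs / 2) stop("notch band outside (0, Nyquist)")
  sosfiltfilt(butter_sos(order, c(lo, hi), fs, "stop"), x)
}

#' Band-pass filter (optionally zero-phase)
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param lo,hi band edges, Hz.
#' @param order single-pass Butterworth order (default 3).
#' @param zero_phase apply forward-backward (default `TRUE`).
#' @export
bandpass <- function(x, fs, lo, hi, order = 3, zero_phase = TRUE) {
  if (!(0 < lo && lo < hi && hi < fs / 2)) stop("invalid band")
  sos <- butter_sos(order, c(lo, hi), fs, "pass")
  if (zero_phase) sosfiltfilt(sos, x) else sosfilt(sos, x)
}

#' Estimate the time-varying baseline fluorescence F0(t)
#'
#' Either a zero-phase low-pass of the trace (4th-order recursive design,
#' default 0.5 Hz cutoff) or a nonlinear least-squares multi-exponential fit
#' `F0(t) = sum_i a_i exp(-t / tau_i) + c` with all time-constants positive.
#' Exponential fits use multi-start (log-spaced tau initializations) to avoid
#' local minima; `half_life` is the time for the fitted decay to fall to half
#' of its initial value, solved numerically.
#'
#' @param x numeric vector, raw fluorescence (strictly positive for
#'   exponential methods).
#' @param fs sampling rate, Hz.
#' @param method one of `"lowpass"`, `"exp1"`, `"exp2"`, `"exp3"`.
#' @param cutoff low-pass cutoff, Hz (lowpass method).
#' @param order low-pass filter order.
#' @return object of class `baseline_fit` with fields `method`, `baseline`,
#'   `params`, `half_life`.
#' @export
estimate_baseline <- function(x, fs, method = c("lowpass", "exp1", "exp2",
                                                "exp3"),
                              cutoff = 0.5, order = 4) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (stats::sd(x) == 0) {
    return(structure(list(method = method, baseline = x, params = NULL,
                          half_life = Inf), class = "baseline_fit"))
  }
  if (method == "lowpass") {
    if (n < 10 * fs / cutoff) {
      stop("trace too short for the requested low-pass baseline")
    }
    f0 <- sosfiltfilt(butter_sos(order, cutoff, fs, "low"), x)
    return(structure(list(method = method, baseline = f0, params = NULL,
                          half_life = NA_real_), class = "baseline_fit"))
  }
  if (any(x <= 0)) stop("exponential baseline fits require a positive trace")
  n_exp <- as.integer(substr(method, 4, 4))
  fit <- fit_multiexp(x, fs, n_exp)
  structure(list(method = method, baseline = fit$baseline, params = fit$params,
                 half_life = fit$half_life), class = "baseline_fit")
}

## Multi-start separable (variable-projection) nonlinear least squares for a
## sum of n_exp exponentials plus an offset: amplitudes and offset are linear
## given the time-constants, so only the log time-constants are optimized.
fit_multiexp <- function(x, fs, n_exp, n_starts = 8) {
  t <- seq(0, by = 1 / fs, length.out = length(x))
  dur <- max(t)
  dt <- 1 / fs
  design <- function(tau) {
    m <- vapply(tau, function(ti) exp(-t / ti), numeric(length(t)))
    cbind(m, 1)
  }
  lin_solve <- function(tau) {
    A <- design(tau)
    co <- try(qr.coef(qr(A), x), silent = TRUE)
    if (inherits(co, "try-error") || any(!is.finite(co))) return(NULL)
    r <- x - A %*% co
    list(coef = co, rss = sum(r * r))
  }
  obj <- function(logtau) {
    s <- lin_solve(exp(logtau))
    if (is.null(s)) return(1e300)
    s$rss
  }
  best <- NULL
  lo <- log(2 * dt)
  hi <- log(50 * dur)
  for (s in seq_len(n_starts)) {
    span <- seq(lo + (s - 1) / n_starts * (hi - lo) / 2,
                hi - (n_starts - s) / n_starts * (hi - lo) / 2,
                length.out = n_exp)
    res <- try(stats::optim(span, obj, method = "BFGS",
                            control = list(maxit = 3000, reltol = 1e-15)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("exponential baseline fit failed to converge")
  }
  tau <- exp(best$par)
  sol <- lin_solve(tau)
  a <- sol$coef[seq_len(n_exp)]
  cc <- sol$coef[n_exp + 1]
  ord <- order(tau)
  a <- a[ord]; tau <- tau[ord]
  f0 <- as.numeric(design(tau) %*% c(a, cc))
  ## half life: time for the full fitted curve to fall to half its initial
  ## value; infinite when the offset keeps it above F(0)/2 forever
  f_start <- sum(a) + cc
  gfun <- function(tt) sum(a * exp(-tt / tau)) + cc - f_start / 2
  up <- max(tau) * 100
  half_life <- if (gfun(up) > 0) Inf else
    stats::uniroot(gfun, c(0, up), tol = 1e-9)$root
  list(baseline = f0,
       params = list(amplitudes = a, tau = tau, offset = cc,
                     residual = best$value),
       half_life = half_life)
}

#' Detrend a trace to dF/F by its fitted baseline
#'
#' Divides by `F0(t)`; optionally applies a zero-phase linear-phase FIR
#' high-pass afterwards (0.5 Hz is the anesthetized-preparation default,
#' 1.5 Hz the awake default).
#'
#' @param x numeric vector, the same trace used to fit `baseline`.
#' @param baseline a `baseline_fit` from [estimate_baseline()].
#' @param fs sampling rate, Hz (needed if `highpass` is set).
#' @param highpass optional FIR high-pass cutoff, Hz.
#' @export
detrend <- function(x, baseline, fs = NULL, highpass = NULL) {
  f0 <- baseline$baseline
  if (any(f0 <= 0)) stop("baseline is not strictly positive")
  out <- as.numeric(x) / f0
  if (!is.null(highpass)) {
    if (is.null(fs)) stop("fs required for the high-pass stage")
    out <- fir_highpass(out - mean(out), fs, highpass) + 1
  }
  out
}

#' Decrosstalk a fiber-photometry reference trace from a donor GEVI trace
#'
#' Regresses the band-passed reference against the band-passed donor
#' (3rd-order zero-phase band-pass; default bands 3-7 Hz cortex, 5-9 Hz
#' hippocampus), then subtracts `coefficient * donor` from the unfiltered
#' reference.
#'
#' @param reference,donor numeric vectors, same length and rate.
#' @param fs sampling rate, Hz.
#' @param band length-2 regression band, Hz.
#' @return list with `corrected` trace and `coefficient`.
#' @export
decrosstalk_fiber <- function(reference, donor, fs, band = c(3, 7)) {
  if (length(reference) != length(donor)) stop("length mismatch")
  rb <- bandpass(reference, fs, band[1], band[2], order = 3)
  db <- bandpass(donor, fs, band[1], band[2], order = 3)
  v <- sum(db * db)
  if (v < 1e-12 * length(db)) stop("band-passed donor variance is ~0")
  coefficient <- sum(rb * db) / v
  list(corrected = reference - coefficient * donor,
       coefficient = coefficient)
}

#' Decrosstalk a movie channel by a known bleed-through coefficient
#'
#' Subtracts `coefficient * green` from the red channel frame-wise. Typical
#' bleed-through fractions are ~0.07 for ASAP3 and ~0.095 for Ace-mNeon1
#' (selectable by indicator name).
#'
#' @param red,green numeric arrays of identical shape.
#' @param coefficient bleed-through fraction in `[0, 1)`, or an indicator
#'   name (`"asap3"`, `"ace-mneon1"`).
#' @export
decrosstalk_movie <- function(red, green, coefficient = 0.07) {
  if (is.character(coefficient)) {
    coefficient <- switch(tolower(coefficient),
                          "asap3" = 0.07, "ace-mneon1" = 0.095,
                          stop("unknown indicator name"))
  }
  if (coefficient < 0 || coefficient >= 1) stop("coefficient must be in [0,1)")
  if (!identical(dim(red), dim(green)) ||
      (is.null(dim(red)) && length(red) != length(green))) {
    stop("shape mismatch between channels")
  }
  red - coefficient * green
}
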