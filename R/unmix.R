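## Frequency-dependent convolutional (Wiener) unmixing of reference-channel
## artifacts from the voltage channel. The GEVI trace G(t) is modeled as
## voltage V(t) plus an artifact H(t) = (F * R)(t): a stationary linear
## transform of the reference trace. The transfer f(w) is the segment-averaged
## cross-spectrum over auto-spectrum ratio, its amplitude clipped relative to
## the heartbeat-frequency coefficient, and applied as a two-sided time-domain
## kernel.

#' Parameters for Wiener-filter estimation
#'
#' @param tau segment duration, seconds (typical 0.5-2).
#' @param overlap fractional segment overlap in `[0, 1)`.
#' @param window taper name (`"hann"` or `"rect"`).
#' @param alpha relative spectral amplitude limit: coefficients exceeding
#'   `alpha * |f(w0)|` in magnitude are clipped to that magnitude with phase
#'   preserved (typical 1.0-1.3).
#' @param heartbeat_band length-2 band, Hz, searched for the heartbeat
#'   fundamental w0.
#' @export
wiener_params <- function(tau = 1.0, overlap = 0.75, window = "hann",
                          alpha = 1.1, heartbeat_band = c(8, 14)) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(tau = tau, overlap = overlap, window = window, alpha = alpha,
                 heartbeat_band = heartbeat_band), class = "wiener_params")
}

#' Locate the heartbeat fundamental frequency
#'
#' Frequency of the maximum Welch PSD of the reference trace within the search
#' band. Errors if no clear spectral peak exists (peak power must exceed
#' `prominence_ratio` times the median in-band power), suggesting a manual w0.
#'
#' @param r reference-channel trace.
#' @param fs sampling rate, Hz.
#' @param band length-2 search band, Hz (default 8-14, heart rate ~10-12 Hz in
#'   mice).
#' @param prominence_ratio required peak-to-median power ratio.
#' @return the heartbeat fundamental, Hz.
#' @export
estimate_heartbeat <- function(r, fs, band = c(8, 14), prominence_ratio = 4) {
  if (band[2] >= fs / 2) stop("band outside Nyquist")
  p <- welch_psd(r, fs, window_len = min(4, length(r) / fs / 4))
  inb <- p$freqs >= band[1] & p$freqs <= band[2]
  if (!any(inb)) stop("no PSD bins inside the heartbeat band")
  pk <- max(p$psd[inb])
  if (pk < prominence_ratio * stats::median(p$psd[inb])) {
    stop("no clear heartbeat peak in band; supply omega0 manually")
  }
  p$freqs[inb][which.max(p$psd[inb])]
}

#' Estimate the Wiener unmixing filter between a GEVI and a reference trace
#'
#' Cuts both traces into tapered segments of duration `tau` with the given
#' overlap, computes per-frequency cross- and auto-spectra averaged over
#' segments, forms `f(w) = <g r*> / <r r*>`, clips amplitudes exceeding
#' `alpha * |f(w0)|` (phase preserved), and returns the two-sided zero-lag
#' centered time-domain kernel.
#'
#' @param g,r numeric vectors (GEVI and reference), equal length.
#' @param fs sampling rate, Hz.
#' @param params a [wiener_params()].
#' @param omega0 heartbeat fundamental, Hz; estimated from `r` when `NULL`.
#' @return object of class `wiener_filter` with fields `freqs`, `f_raw`,
#'   `f` (clipped), `omega0`, `kernel`, `kernel_center`, `params`,
#'   `n_segments`, `diagnostics`.
#' @export
estimate_wiener_filter <- function(g, r, fs, params = wiener_params(),
                                   omega0 = NULL) {
  if (length(g) != length(r)) stop("length mismatch")
  nseg <- as.integer(round(params$tau * fs))
  if (nseg < 8) stop("tau * fs must be at least 8 samples")
  if (length(g) < 2 * nseg) stop("need at least 2 * tau * fs samples")
  hop <- max(1L, as.integer(round((1 - params$overlap) * nseg)))
  n_segments <- length(seq(1, length(g) - nseg + 1, by = hop))
  if (n_segments < 4) stop("fewer than 4 segments; reduce tau or overlap")
  w <- if (identical(params$window, "rect")) rep(1, nseg) else hann_window(nseg)
  gk <- segment_ffts(g, nseg, hop, w)
  rk <- segment_ffts(r, nseg, hop, w)
  cross <- rowMeans(gk * Conj(rk))
  auto <- rowMeans(Mod(rk)^2)
  zero_bins <- auto <= .Machine$double.eps * max(auto, 1)
  f_raw <- ifelse(zero_bins, 0 + 0i, cross / ifelse(zero_bins, 1, auto))
  freqs <- (seq_len(nseg) - 1) * fs / nseg
  if (is.null(omega0)) {
    omega0 <- estimate_heartbeat(r, fs, params$heartbeat_band)
  }
  i0 <- which.min(abs(freqs[seq_len(nseg %/% 2 + 1)] - omega0))
  limit <- params$alpha * Mod(f_raw[i0])
  f <- f_raw
  over <- Mod(f) > limit
  f[over] <- limit * exp(1i * Arg(f[over]))
  kernel <- Re(stats::fft(f, inverse = TRUE)) / nseg
  center <- nseg %/% 2 + 1L
  kernel <- c(kernel[(center):nseg], kernel[seq_len(center - 1)])
  structure(list(freqs = freqs, f_raw = f_raw, f = f, omega0 = omega0,
                 kernel = kernel, kernel_center = center, params = params,
                 n_segments = n_segments,
                 diagnostics = list(n_zero_power_bins = sum(zero_bins),
                                    n_clipped_bins = sum(over))),
            class = "wiener_filter")
}

#' @export
print.wiener_filter <- function(x, ...) {
  cat(sprintf(
    "<wiener_filter> %d bins, w0 = %.2f Hz, |f(w0)| = %.3g, %d/%d clipped\n",
    length(x$f), x$omega0, Mod(x$f[which.min(abs(x$freqs - x$omega0))]),
    x$diagnostics$n_clipped_bins, length(x$f)))
  invisible(x)
}

## Correlate (no kernel flip) x with the two-sided kernel, reflection padding,
## output of the same length as x.
apply_kernel <- function(x, kernel, center) {
  n <- length(x)
  pad <- min(length(kernel), n - 1)
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  ext <- c(pre, x, post)
  ## true convolution of ext with the kernel; tap j of the kernel holds lag
  ## (j - center), so H_t = z[t + pad + center - 1]
  z <- stats::convolve(ext, rev(kernel), type = "open")
  z[(pad + center):(pad + center + n - 1)]
}

#' Unmix a GEVI trace with a Wiener filter
#'
#' Estimates (or reuses) the transfer filter, computes the artifact estimate
#' `H = F * R` by linear convolution with the two-sided kernel, and returns
#' the voltage trace `V = G - H`. Samples within half a kernel length of the
#' recording edges are flagged in the diagnostics.
#'
#' @inheritParams estimate_wiener_filter
#' @param filter optional pre-estimated `wiener_filter` (skips estimation).
#' @return object of class `unmix_result` with fields `voltage`, `artifact`,
#'   `filter`, `diagnostics`.
#' @export
unmix_trace <- function(g, r, fs, params = wiener_params(), omega0 = NULL,
                        filter = NULL) {
  if (is.null(filter)) {
    filter <- estimate_wiener_filter(g, r, fs, params, omega0)
  }
  h <- apply_kernel(as.numeric(r), filter$kernel, filter$kernel_center)
  v <- as.numeric(g) - h
  edge <- filter$kernel_center
  structure(list(voltage = v, artifact = h, filter = filter,
                 diagnostics = list(
                   residual_variance = stats::var(v),
                   edge_samples = c(head = edge, tail = edge))),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat(sprintf("<unmix_result> %d samples, residual variance %.4g\n",
              length(x$voltage), x$diagnostics$residual_variance))
  invisible(x)
}

#' Frequency-independent (scalar regression) unmixing baseline
#'
#' Ordinary least-squares slope of G on R; `V = G - beta R`. The comparison
#' baseline that the convolutional filter outperforms when artifacts carry
#' inter-channel phase lags.
#'
#' @param g,r numeric vectors of equal length.
#' @export
scalar_regression_unmix <- function(g, r) {
  if (length(g) != length(r)) stop("length mismatch")
  rc <- r - mean(r)
  v <- sum(rc * rc)
  if (v == 0) stop("reference variance is zero")
  beta <- sum((g - mean(g)) * rc) / v
  h <- beta * (r - mean(r))
  structure(list(voltage = g - h, artifact = h, beta = beta,
                 diagnostics = list(residual_variance = stats::var(g - h))),
            class = "unmix_result")
}

#' Select tau and alpha by train/test split
#'
#' For each grid cell the filter is estimated on the first half of the
#' recording and applied to the second half; the objective is the variance of
#' the unmixed test trace ("minimizing the remaining signal"). Ties break
#' toward smaller tau, then smaller alpha.
#'
#' @param g,r traces.
#' @param fs sampling rate, Hz.
#' @param tau_grid,alpha_grid candidate values.
#' @param params base [wiener_params()] supplying overlap/window/band.
#' @param omega0 optional fixed heartbeat frequency.
#' @return list with `tau`, `alpha`, and the full `objective` table.
#' @export
select_params <- function(g, r, fs, tau_grid = c(0.5, 1, 1.5, 2),
                          alpha_grid = c(1.0, 1.1, 1.2, 1.3),
                          params = wiener_params(), omega0 = NULL) {
  if (!length(tau_grid) || !length(alpha_grid)) stop("empty grid")
  n <- length(g)
  if (n < 4 * max(tau_grid) * fs) stop("recording too short for the grid")
  half <- n %/% 2
  idx_train <- seq_len(half)
  idx_test <- (half + 1):n
  grid <- expand.grid(alpha = sort(alpha_grid), tau = sort(tau_grid))
  grid <- grid[order(grid$tau, grid$alpha), c("tau", "alpha")]
  grid$objective <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$tau <- grid$tau[i]
    p$alpha <- grid$alpha[i]
    obj <- try({
      flt <- estimate_wiener_filter(g[idx_train], r[idx_train], fs, p, omega0)
      res <- unmix_trace(g[idx_test], r[idx_test], fs, filter = flt)
      stats::var(res$voltage)
    }, silent = TRUE)
    if (!inherits(obj, "try-error")) grid$objective[i] <- obj
  }
  if (all(is.na(grid$objective))) stop("all grid cells failed")
  best <- which.min(grid$objective)   # first minimum: smaller tau, then alpha
  list(tau = grid$tau[best], alpha = grid$alpha[best], objective = grid)
}
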