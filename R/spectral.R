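## Wavelet spectrograms (analytic Morlet), band envelopes, analytic signals,
## event-triggered averages and event-related spectrograms.

#' Analytic signal via the Hilbert transform
#' @param x numeric vector.
#' @return complex vector, the analytic signal.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Analytic Morlet wavelet spectrogram
#'
#' Continuous wavelet transform on a log-spaced frequency grid. The wavelet is
#' an analytic Morlet with center frequency `omega0` (rad), normalized so the
#' ridge magnitude of a unit-amplitude sinusoid at an on-grid frequency equals
#' 1 away from the edges. A cone-of-influence mask marks samples within one
#' e-folding time of the record edges.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param freq_range length-2 frequency range, Hz.
#' @param voices_per_octave frequency-grid density (default 10).
#' @param omega0 Morlet center frequency, rad (default 6).
#' @return object of class `spectrogram` with `times`, `freqs`, `values`
#'   (magnitude, n_freqs x n_times), `coi` (logical validity mask) and
#'   `kind = "wavelet"`.
#' @export
wavelet_spectrogram <- function(x, fs, freq_range = c(1, 120),
                                voices_per_octave = 10, omega0 = 6) {
  if (freq_range[1] <= 0 || freq_range[2] >= fs / 2) {
    stop("freq_range must lie within (0, fs/2)")
  }
  n <- length(x)
  n_oct <- log2(freq_range[2] / freq_range[1])
  freqs <- freq_range[1] * 2^(seq(0, n_oct, by = 1 / voices_per_octave))
  X <- stats::fft(x)
  w <- 2 * pi * fs * (seq_len(n) - 1) / n      # rad/s on the DFT grid
  pos <- w <= pi * fs                           # analytic: positive freqs only
  vals <- matrix(0, length(freqs), n)
  coi <- matrix(TRUE, length(freqs), n)
  t <- (seq_len(n) - 1) / fs
  for (i in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[i])           # scale in seconds
    psi <- numeric(n)
    psi[pos] <- 2 * exp(-0.5 * (s * w[pos] - omega0)^2)
    vals[i, ] <- Mod(stats::fft(X * psi, inverse = TRUE) / n)
    efold <- sqrt(2) * s
    coi[i, ] <- t >= efold & t <= (n - 1) / fs - efold
  }
  structure(list(times = t, freqs = freqs, values = vals, coi = coi,
                 kind = "wavelet"),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram:%s> %d freqs (%.3g-%.3g Hz) x %d times\n",
              x$kind, length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times)))
  invisible(x)
}

#' Short-time Fourier (Welch-style) spectrogram
#'
#' @inheritParams wavelet_spectrogram
#' @param window_len segment length, s.
#' @param overlap overlap, s.
#' @export
stft_spectrogram <- function(x, fs, window_len = 1, overlap = 0.8) {
  nseg <- as.integer(round(window_len * fs))
  hop <- max(1L, nseg - as.integer(round(overlap * fs)))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  w <- hann_window(nseg)
  half <- seq_len(nseg %/% 2 + 1)
  vals <- vapply(starts, function(s) {
    seg <- x[s:(s + nseg - 1)]
    (Mod(stats::fft((seg - mean(seg)) * w))^2 / (fs * sum(w^2)))[half]
  }, numeric(length(half)))
  structure(list(times = (starts - 1 + nseg / 2) / fs,
                 freqs = (half - 1) * fs / nseg,
                 values = vals, coi = NULL, kind = "stft"),
            class = "spectrogram")
}

#' Band-limited amplitude envelope
#'
#' `"wavelet"`: mean wavelet-spectrogram magnitude across the rows inside the
#' band. `"hilbert"`: magnitude of the analytic signal of the zero-phase
#' band-passed trace.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param band length-2 band, Hz.
#' @param method `"wavelet"` or `"hilbert"`.
#' @param voices_per_octave wavelet grid density.
#' @export
band_envelope <- function(x, fs, band, method = c("wavelet", "hilbert"),
                          voices_per_octave = 12) {
  method <- match.arg(method)
  if (method == "hilbert") {
    return(Mod(analytic_signal(bandpass(x, fs, band[1], band[2], order = 3))))
  }
  sp <- wavelet_spectrogram(x, fs, band, voices_per_octave)
  colMeans(sp$values)
}

#' Event-triggered average with a confidence band
#'
#' Stacks fixed windows around event times and averages; events whose window
#' is clipped by the recording edge are dropped and counted. The 95%
#' confidence band uses a percentile bootstrap over events (default) or a
#' normal approximation.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param event_times event times, s (relative to the first sample).
#' @param window length-2 window around each event, s (e.g. `c(-0.5, 1)`).
#' @param ci `"bootstrap"` or `"normal"`.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @export
event_triggered_average <- function(x, fs, event_times, window = c(-0.5, 0.5),
                                    ci = c("bootstrap", "normal"),
                                    n_boot = 1000, seed = 1) {
  ci <- match.arg(ci)
  i0 <- as.integer(round(window[1] * fs))
  i1 <- as.integer(round(window[2] * fs))
  rel <- (i0:i1) / fs
  centers <- as.integer(round(event_times * fs)) + 1L
  ok <- centers + i0 >= 1 & centers + i1 <= length(x)
  n_dropped <- sum(!ok)
  centers <- centers[ok]
  if (length(centers) < 1) stop("no usable events inside the recording")
  stack <- t(vapply(centers, function(c0) x[(c0 + i0):(c0 + i1)],
                    numeric(length(rel))))
  m <- colMeans(stack)
  ne <- nrow(stack)
  if (ne == 1) {
    lo <- hi <- m
  } else if (ci == "normal") {
    se <- apply(stack, 2, stats::sd) / sqrt(ne)
    lo <- m - 1.96 * se
    hi <- m + 1.96 * se
  } else {
    set.seed(seed)
    bm <- t(vapply(seq_len(n_boot), function(b) {
      colMeans(stack[sample.int(ne, ne, replace = TRUE), , drop = FALSE])
    }, numeric(length(rel))))
    lo <- apply(bm, 2, stats::quantile, 0.025)
    hi <- apply(bm, 2, stats::quantile, 0.975)
  }
  list(times = rel, mean = m, lower = lo, upper = hi,
       n_events = ne, n_dropped = n_dropped)
}

#' Event-related (event-mean) wavelet spectrogram
#'
#' Computes the wavelet spectrogram of the whole trace, then averages
#' fixed windows around each event along the time axis.
#'
#' @inheritParams event_triggered_average
#' @param freq_range length-2 frequency range, Hz.
#' @param voices_per_octave wavelet grid density.
#' @export
event_related_spectrogram <- function(x, fs, event_times,
                                      window = c(-0.5, 1),
                                      freq_range = c(1, 120),
                                      voices_per_octave = 10) {
  sp <- wavelet_spectrogram(x, fs, freq_range, voices_per_octave)
  i0 <- as.integer(round(window[1] * fs))
  i1 <- as.integer(round(window[2] * fs))
  centers <- as.integer(round(event_times * fs)) + 1L
  ok <- centers + i0 >= 1 & centers + i1 <= ncol(sp$values)
  if (!any(ok)) stop("no usable events inside the recording")
  centers <- centers[ok]
  acc <- matrix(0, length(sp$freqs), i1 - i0 + 1)
  for (c0 in centers) acc <- acc + sp$values[, (c0 + i0):(c0 + i1)]
  structure(list(times = (i0:i1) / fs, freqs = sp$freqs,
                 values = acc / length(centers), coi = NULL,
                 kind = "wavelet", n_events = length(centers),
                 n_dropped = sum(!ok)),
            class = "spectrogram")
}
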