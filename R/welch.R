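## Welch-style segmented spectral estimation shared by the PSD, coherence and
## Wiener-filter code: cut into tapered, mean-subtracted segments, FFT, and
## average cross/auto spectra per frequency bin.

segment_ffts <- function(x, nseg, hop, window = hann_window(nseg)) {
  n <- length(x)
  starts <- seq(1, n - nseg + 1, by = hop)
  m <- matrix(0 + 0i, nrow = nseg, ncol = length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + nseg - 1)]
    m[, k] <- stats::fft((seg - mean(seg)) * window)
  }
  m
}

#' Welch power spectral density
#'
#' One-sided PSD with Hann-tapered, mean-subtracted segments; scaled so that
#' it integrates to the signal variance (Parseval).
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param window_len segment length, seconds.
#' @param overlap segment overlap, seconds.
#' @return list with `freqs` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, window_len = 1, overlap = window_len / 2) {
  nseg <- max(8L, as.integer(round(window_len * fs)))
  hop <- max(1L, nseg - as.integer(round(overlap * fs)))
  if (length(x) < nseg) stop("signal shorter than one segment")
  w <- hann_window(nseg)
  g <- segment_ffts(x, nseg, hop, w)
  p <- rowMeans(Mod(g)^2) / (fs * sum(w^2))
  half <- seq_len(nseg %/% 2 + 1)
  psd <- p[half]
  scale2 <- rep(2, length(half)); scale2[1] <- 1
  if (nseg %% 2 == 0) scale2[length(half)] <- 1
  list(freqs = (half - 1) * fs / nseg, psd = psd * scale2,
       n_segments = ncol(g))
}

#' Welch magnitude-squared coherence and cross-spectral phase
#'
#' Segmented coherence between two equal-length traces (default 1-s segments
#' overlapping by 0.8 s). `magnitude` is the magnitude-squared coherence
#' `|Sxy|^2 / (Sxx Syy)` in `[0, 1]`; `phase` is the cross-spectral phase with
#' the convention that `y` delayed by `d` seconds gives a slope of `-2 pi f d`.
#'
#' @param x,y numeric vectors of identical length.
#' @param fs sampling rate, Hz.
#' @param window_len segment length, s.
#' @param overlap segment overlap, s.
#' @return object of class `coherence_result`.
#' @export
coherence <- function(x, y, fs, window_len = 1, overlap = 0.8) {
  if (length(x) != length(y)) stop("length mismatch")
  nseg <- as.integer(round(window_len * fs))
  hop <- max(1L, nseg - as.integer(round(overlap * fs)))
  n_segments <- length(seq(1, length(x) - nseg + 1, by = hop))
  if (n_segments < 5) stop("need at least 5 segments for coherence")
  w <- hann_window(nseg)
  gx <- segment_ffts(x, nseg, hop, w)
  gy <- segment_ffts(y, nseg, hop, w)
  sxy <- rowMeans(Conj(gx) * gy)
  sxx <- rowMeans(Mod(gx)^2)
  syy <- rowMeans(Mod(gy)^2)
  half <- seq_len(nseg %/% 2 + 1)
  denom <- sxx[half] * syy[half]
  msc <- ifelse(denom > 0, Mod(sxy[half])^2 / denom, 0)
  structure(list(freqs = (half - 1) * fs / nseg,
                 magnitude = pmin(1, msc),
                 phase = Arg(sxy[half]),
                 n_segments = n_segments,
                 window_len = window_len, overlap = overlap),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d bins, %d segments of %g s\n",
              length(x$freqs), x$n_segments, x$window_len))
  invisible(x)
}
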