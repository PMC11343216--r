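## Phase-amplitude cross-frequency coupling. Phase convention throughout:
## 0 degrees is the trough of the carrier oscillation (greatest
## hyperpolarization in a depolarization-positive trace), so the carrier peak
## sits at 180 degrees.

#' Instantaneous carrier phase, trough-referenced, in degrees
#'
#' Phase of the analytic signal of the zero-phase band-passed trace, shifted
#' so the waveform trough maps to 0 degrees and the peak to 180 degrees.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param band length-2 carrier band, Hz.
#' @param order band-pass order.
#' @return phase in degrees in `[0, 360)`.
#' @export
carrier_phase <- function(x, fs, band, order = 3) {
  xb <- bandpass(x, fs, band[1], band[2], order = order)
  if (stats::var(xb) < 1e-12 * max(stats::var(x), .Machine$double.eps)) {
    stop("carrier band power below floor")
  }
  ## analytic phase is 0 at the peak; add 180 so the trough maps to 0
  (Arg(analytic_signal(xb)) * 180 / pi + 180) %% 360
}

#' Phase-conditioned amplitude profile (phase-amplitude coupling)
#'
#' Extracts the carrier phase (optionally from a separate phase-source trace,
#' e.g. an LFP), computes the high-band amplitude envelope, aligns cycles at
#' phase resets (the wrap crossing of the trough-referenced phase), averages
#' the envelope per phase bin over all complete cycles, and tiles the
#' single-cycle profile to two cycles (720 degrees) for display.
#'
#' @param x numeric vector carrying the high-frequency amplitude.
#' @param fs sampling rate, Hz.
#' @param carrier_band,amp_band length-2 bands, Hz.
#' @param n_bins phase bins per cycle (default 36, i.e. 10 degrees).
#' @param method envelope route, `"wavelet"` (default) or `"hilbert"`.
#' @param phase_source optional separate trace whose carrier phase is used.
#' @param amplitude optional precomputed amplitude time series overriding the
#'   envelope computation.
#' @param min_cycles minimum number of complete carrier cycles required.
#' @return object of class `cfc_profile` with `phase_bins` (degrees over
#'   `[0, 720)`), `amplitude`, `preferred_phase`, `n_cycles`.
#' @export
cfc_profile <- function(x, fs, carrier_band, amp_band, n_bins = 36,
                        method = "wavelet", phase_source = NULL,
                        amplitude = NULL, min_cycles = 20) {
  ph <- carrier_phase(if (is.null(phase_source)) x else phase_source,
                      fs, carrier_band)
  env <- if (is.null(amplitude)) band_envelope(x, fs, amp_band, method)
  else as.numeric(amplitude)
  ## phase resets: wrap crossings (phase drops by more than 180 degrees)
  resets <- which(diff(ph) < -180) + 1L
  n_cycles <- length(resets) - 1L
  if (n_cycles < min_cycles) {
    stop(sprintf("only %d complete carrier cycles (need >= %d)", n_cycles,
                 min_cycles))
  }
  keep <- seq(resets[1], resets[length(resets)] - 1L)
  bins <- pmin(n_bins, floor(ph[keep] / (360 / n_bins)) + 1L)
  sums <- tapply(env[keep], bins, sum)
  counts <- tapply(rep(1, length(keep)), bins, sum)
  prof <- rep(NA_real_, n_bins)
  prof[as.integer(names(sums))] <- sums / counts
  centers <- (seq_len(n_bins) - 0.5) * 360 / n_bins
  structure(list(phase_bins = c(centers, centers + 360),
                 amplitude = rep(prof, 2),
                 carrier_band = carrier_band, amp_band = amp_band,
                 n_cycles = n_cycles,
                 preferred_phase = centers[which.max(prof)],
                 phase_convention = "0 deg = carrier trough"),
            class = "cfc_profile")
}

#' @export
print.cfc_profile <- function(x, ...) {
  cat(sprintf(
    "<cfc_profile> %d cycles, preferred phase %.1f deg (trough = 0)\n",
    x$n_cycles, x$preferred_phase))
  invisible(x)
}

#' Timing offsets between envelope peaks and carrier depolarization peaks
#'
#' For each event window, finds the time of the high-band envelope maximum
#' and the time of the carrier-band maximum (the depolarization peak), and
#' reports their per-event difference (negative = envelope apex precedes the
#' carrier peak) with mean, s.e.m. and a two-sided Wilcoxon signed-rank test
#' against zero (omitted for a single event).
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param carrier_band,amp_band length-2 bands, Hz.
#' @param events event times, s.
#' @param window length-2 window around each event, s.
#' @param method envelope route.
#' @export
amplitude_peak_offsets <- function(x, fs, carrier_band, amp_band, events,
                                   window = c(-0.5, 0.5),
                                   method = "hilbert") {
  carrier <- bandpass(x, fs, carrier_band[1], carrier_band[2], order = 3)
  env <- band_envelope(x, fs, amp_band, method)
  i0 <- as.integer(round(window[1] * fs))
  i1 <- as.integer(round(window[2] * fs))
  offsets <- numeric(0)
  n_dropped <- 0L
  for (et in events) {
    c0 <- as.integer(round(et * fs)) + 1L
    if (c0 + i0 < 1 || c0 + i1 > length(x)) {
      n_dropped <- n_dropped + 1L
      next
    }
    idx <- (c0 + i0):(c0 + i1)
    ic <- which.max(carrier[idx])
    if (ic == 1 || ic == length(idx)) {        # no interior carrier peak
      n_dropped <- n_dropped + 1L
      next
    }
    ie <- which.max(env[idx])
    offsets <- c(offsets, (ie - ic) / fs)
  }
  if (!length(offsets)) stop("no usable events")
  p <- if (length(offsets) >= 2 && stats::sd(offsets) > 0) {
    stats::wilcox.test(offsets, mu = 0, exact = FALSE)$p.value
  } else NA_real_
  list(offsets = offsets, mean = mean(offsets),
       sem = if (length(offsets) > 1) stats::sd(offsets) /
         sqrt(length(offsets)) else NA_real_,
       p_value = p, n_events = length(offsets), n_dropped = n_dropped)
}
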