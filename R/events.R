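## Discrete-event detection: sharp-wave ripples via the normalized squared
## signal (NSS), ictal spikes, theta-power locomotor-state segmentation, and
## movie-level wave-event windows.

#' Detect hippocampal ripples via the normalized squared signal
#'
#' Band-passes the LFP at the ripple band (3rd-order zero-phase), squares it,
#' applies a 20-ms moving maximum, smooths with a 20-ms centered moving
#' average, min-max rescales to `[0, 1]` over the recording (making detection
#' invariant to overall gain), and finds peaks with the standard criteria
#' (prominence 0.1, distance 10 ms, width 10-200 ms). Each event gets a
#' 300-ms window centered on its peak; windows clipped by the recording edge
#' are flagged.
#'
#' @param x LFP trace.
#' @param fs sampling rate, Hz (>= 500 required).
#' @param band ripple band, Hz (default 120-200).
#' @param criteria a [peak_criteria()]; defaults to the standard ripple
#'   values.
#' @param window_s event window length, s.
#' @param smooth_s moving max/average window, s.
#' @return list with `events` (data.frame: peak_time, prominence, width,
#'   window_start, window_end, clipped) and `nss` (the detection trace).
#' @export
detect_ripples <- function(x, fs, band = c(120, 200),
                           criteria = peak_criteria(0.1, 0.010, 0.010, 0.200),
                           window_s = 0.3, smooth_s = 0.020) {
  if (fs < 500) stop("ripple detection requires fs >= 500 Hz")
  if (length(x) < fs) stop("recording shorter than 1 s")
  xb <- bandpass(x, fs, band[1], band[2], order = 3)
  w <- max(1L, as.integer(round(smooth_s * fs)))
  nss <- moving_avg_cpp(moving_max_cpp(xb^2, w), w)
  rng <- range(nss)
  nss <- if (diff(rng) > 0) (nss - rng[1]) / diff(rng) else nss * 0
  pk <- find_peaks(nss, fs, criteria)
  half <- window_s / 2
  ws <- pk$time - half
  we <- pk$time + half
  events <- data.frame(peak_time = pk$time, prominence = pk$prominence,
                       width = pk$width,
                       window_start = pmax(0, ws), window_end =
                         pmin((length(x) - 1) / fs, we),
                       clipped = ws < 0 | we > (length(x) - 1) / fs)
  list(events = events, nss = nss)
}

#' Detect ictal (epileptiform) spikes
#'
#' Zero-phase 6th-order high-pass at 25 Hz, then peak detection with width
#' 2-20 ms and prominence 1000 uV. Units must be declared so the amplitude
#' threshold is meaningful.
#'
#' @param x LFP trace.
#' @param fs sampling rate, Hz.
#' @param units `"uV"` or `"V"` (no default: undeclared units are an error).
#' @param highpass high-pass cutoff, Hz.
#' @param min_prominence_uv prominence threshold, uV.
#' @return data.frame of detected spikes (time, prominence, width).
#' @export
detect_ictal_spikes <- function(x, fs, units, highpass = 25,
                                min_prominence_uv = 1000) {
  if (missing(units) || !units %in% c("uV", "V")) {
    stop("declare units as \"uV\" or \"V\"")
  }
  thr <- if (units == "uV") min_prominence_uv else min_prominence_uv * 1e-6
  xh <- sosfiltfilt(butter_sos(6, highpass, fs, "high"), x)
  find_peaks(xh, fs, peak_criteria(thr, 0, 0.002, 0.020))
}

#' Segment run/rest locomotor state from LFP theta power
#'
#' Theta-band envelope (Hilbert), smoothed over 1 s; the mask is
#' envelope > threshold, where the threshold is either absolute or a quantile
#' of the envelope. Bouts shorter than `min_bout` seconds are merged into
#' their surroundings.
#'
#' @param x LFP trace (>= 30 s).
#' @param fs sampling rate, Hz.
#' @param theta_band Hz pair, default 5-9.
#' @param threshold absolute envelope threshold; if `NULL`, the `q` quantile
#'   is used.
#' @param q quantile for the threshold (default 0.5).
#' @param min_bout minimum bout duration, s.
#' @return logical vector, `TRUE` = run (high theta).
#' @export
segment_locomotor_state <- function(x, fs, theta_band = c(5, 9),
                                    threshold = NULL, q = 0.5,
                                    min_bout = 0.5) {
  if (length(x) < 30 * fs) stop("recording must be at least 30 s")
  env <- Mod(analytic_signal(
    bandpass(x, fs, theta_band[1], theta_band[2], order = 3)))
  env <- moving_avg_cpp(env, as.integer(fs))
  thr <- if (is.null(threshold)) stats::quantile(env, q) else threshold
  mask <- env > thr
  min_len <- as.integer(round(min_bout * fs))
  if (min_len > 1) {
    r <- rle(mask)
    short <- which(r$lengths < min_len)
    for (s in short) r$values[s] <- !r$values[s]
    r2 <- rle(inverse.rle(r))           # merge newly adjacent runs
    mask <- inverse.rle(r2)
  }
  mask
}

#' Detect global depolarization (wave) events in a voltage movie
#'
#' Thresholds the field-of-view-mean fluorescence trace at
#' `mean + k_sd * sd` (whole-trace statistics) and returns contiguous
#' supra-threshold intervals, padded by `margin` seconds.
#'
#' @param movie T x H x W numeric array (unmixed, optionally denoised).
#' @param fs frame rate, Hz.
#' @param k_sd threshold in standard deviations (default 3).
#' @param margin padding added to each side of an event, s.
#' @return data.frame with `start_time`, `end_time`, `peak_time` (s).
#' @export
detect_wave_events <- function(movie, fs, k_sd = 3, margin = 0) {
  net <- apply(movie, 1, mean)
  thr <- mean(net) + k_sd * stats::sd(net)
  above <- net > thr
  if (!any(above)) {
    return(data.frame(start_time = numeric(0), end_time = numeric(0),
                      peak_time = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  pad <- as.integer(round(margin * fs))
  out <- data.frame(
    start_time = (pmax(1L, starts[keep] - pad) - 1L) / fs,
    end_time = (pmin(length(net), ends[keep] + pad) - 1L) / fs)
  out$peak_time <- vapply(seq_len(nrow(out)), function(i) {
    idx <- (round(out$start_time[i] * fs):round(out$end_time[i] * fs)) + 1L
    (idx[which.max(net[idx])] - 1L) / fs
  }, 0)
  ## merge overlapping padded intervals
  if (nrow(out) > 1) {
    merged <- out[1, ]
    for (i in 2:nrow(out)) {
      if (out$start_time[i] <= merged$end_time[nrow(merged)]) {
        merged$end_time[nrow(merged)] <-
          max(merged$end_time[nrow(merged)], out$end_time[i])
      } else {
        merged <- rbind(merged, out[i, ])
      }
    }
    out <- merged
  }
  out
}
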