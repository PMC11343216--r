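## Temporal alignment of optical and electrical streams via a shared
## randomized square-wave sync signal, plus spatial binning of movies.

#' Align optical and electrical streams on a common time base
#'
#' Both streams must carry the same randomized square-wave synchronization
#' waveform. The electrical stream is resampled to the optical rate (cubic
#' spline for the continuous signal, nearest neighbor for the binary sync),
#' the lag between the two sync waveforms is estimated by normalized
#' cross-correlation, and the electrical stream is shifted so the waveforms
#' coincide. Time origin is the first optical sample.
#'
#' @param optical a [dual_channel_trace()] with `meta$sync`.
#' @param electrical an [electrical_trace()] with `sync`.
#' @param max_lag maximum lag searched, seconds.
#' @param min_peak minimum normalized cross-correlation peak required
#'   (alignment-failure error below this).
#' @return list with elements `optical` (unchanged except time origin at 0),
#'   `electrical` (resampled + shifted to the optical grid), `shift` (seconds
#'   the electrical stream was advanced) and `peak` (sync correlation).
#' @export
align_streams <- function(optical, electrical, max_lag = 5, min_peak = 0.9) {
  if (is.null(optical$meta$sync)) stop("optical stream carries no sync")
  if (is.null(electrical$sync)) stop("electrical stream carries no sync")
  fs <- optical$fs
  n_opt <- length(optical$gevi)
  t_opt <- seq(0, by = 1 / fs, length.out = n_opt)
  t_ele <- seq(0, by = 1 / electrical$fs, length.out = length(electrical$signal))
  ## resample electrical sync to the optical rate (nearest neighbor)
  sync_e <- interp_nearest(t_ele, electrical$sync, t_opt)
  sync_o <- as.numeric(optical$meta$sync)
  so <- sync_o - mean(sync_o)
  se <- sync_e - mean(sync_e)
  if (stats::sd(so) == 0 || stats::sd(se) == 0) {
    stop("alignment failure: degenerate (constant) sync waveform")
  }
  ml <- min(n_opt - 1L, as.integer(round(max_lag * fs)))
  cc <- xcorr_norm_cpp(so, se, ml)
  peak <- max(cc)
  if (peak < min_peak) {
    stop(sprintf(
      "alignment failure: sync correlation peak %.3f below %.2f", peak,
      min_peak))
  }
  ## positive lag means the electrical sync lags the optical one
  lag <- (which.max(cc) - ml - 1L) / fs
  t_shifted <- t_ele - lag
  sig_fun <- stats::splinefun(t_shifted, electrical$signal, method = "natural")
  inside <- t_opt >= min(t_shifted) & t_opt <= max(t_shifted)
  signal_rs <- rep(NA_real_, n_opt)
  signal_rs[inside] <- sig_fun(t_opt[inside])
  sync_rs <- interp_nearest(t_shifted, electrical$sync, t_opt)
  out_opt <- optical
  out_opt$time <- t_opt
  out_ele <- electrical_trace(
    ifelse(is.na(signal_rs), 0, signal_rs), fs = fs,
    sync = sync_rs, meta = c(electrical$meta, list(shift = -lag, peak = peak)))
  list(optical = out_opt, electrical = out_ele, shift = -lag, peak = peak)
}

interp_nearest <- function(x, y, xout) {
  idx <- findInterval(xout, x, all.inside = TRUE)
  take_next <- (xout - x[idx]) > (x[pmin(idx + 1, length(x))] - xout)
  y[ifelse(take_next, pmin(idx + 1, length(x)), idx)]
}

#' Generate a randomized square-wave synchronization waveform
#'
#' Square wave with 1-s ON states (50% duty within each pulse pair) separated
#' by OFF intervals of random duration, so the cross-correlation of two copies
#' has an unambiguous peak.
#'
#' @param duration recording length, s.
#' @param fs sampling rate, Hz.
#' @param gap_range range of random OFF-interval durations, s.
#' @export
make_sync_wave <- function(duration, fs, gap_range = c(0.2, 1.5)) {
  n <- round(duration * fs)
  sync <- numeric(n)
  t <- 1
  while (t < n) {
    on <- round(1 * fs)
    sync[t:min(n, t + on - 1)] <- 1
    gap <- round(stats::runif(1, gap_range[1], gap_range[2]) * fs)
    t <- t + on + gap
  }
  sync
}

#' Spatially bin a dual-channel movie
#'
#' Averages non-overlapping `factor x factor` pixel blocks in each frame of
#' both channels; trailing rows/columns that do not fill a block are dropped
#' and the pixel pitch is multiplied by `factor`.
#'
#' @param movie a [dual_channel_movie()].
#' @param factor integer binning factor (8 gives the standard 8 x 8 binning).
#' @export
spatial_bin <- function(movie, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  d <- dim(movie$gevi)
  if (factor > d[2] || factor > d[3]) {
    stop("factor exceeds a spatial dimension")
  }
  if (factor == 1) return(movie)
  dual_channel_movie(bin_stack(movie$gevi, factor),
                     bin_stack(movie$reference, factor),
                     fs = movie$fs,
                     pixel_pitch = movie$pixel_pitch * factor,
                     meta = movie$meta)
}

bin_stack <- function(a, f) {
  d <- dim(a)
  h <- (d[2] %/% f) * f
  w <- (d[3] %/% f) * f
  a <- a[, seq_len(h), seq_len(w), drop = FALSE]
  ## average over f x f blocks: fold each spatial axis in turn
  dim(a) <- c(d[1], f, h %/% f, w)
  a <- colMeans(aperm(a, c(2, 1, 3, 4)))
  dim(a) <- c(d[1], h %/% f, f, w %/% f)
  a <- colMeans(aperm(a, c(3, 1, 2, 4)))
  a
}
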