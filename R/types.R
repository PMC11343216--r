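#' Dual-channel optical trace
#'
#' Container for a paired recording of a voltage-indicator (GEVI) channel and
#' a voltage-insensitive reference channel on a shared uniform time grid.
#'
#' @param gevi numeric vector, GEVI-channel fluorescence (a.u. or dF/F).
#' @param reference numeric vector, reference-channel fluorescence.
#' @param fs sampling rate, Hz.
#' @param time optional time vector in seconds; defaults to a uniform grid
#'   starting at 0 with spacing `1/fs`.
#' @param labels character length-2, channel names.
#' @param meta free-form named list (e.g. a `sync` waveform for alignment).
#' @return object of class `dual_channel_trace`.
#' @export
dual_channel_trace <- function(gevi, reference, fs, time = NULL,
                               labels = c("gevi", "reference"), meta = list()) {
  gevi <- as.numeric(gevi)
  reference <- as.numeric(reference)
  if (length(gevi) != length(reference)) {
    stop("gevi and reference must have identical length")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  if (is.null(time)) {
    time <- seq(0, by = 1 / fs, length.out = length(gevi))
  } else {
    time <- as.numeric(time)
    if (length(time) != length(gevi)) stop("time length mismatch")
    dt <- stats::median(diff(time))
    if (abs(dt - 1 / fs) > 1e-6 / fs) {
      stop("fs does not match the median time step within 1e-6 relative")
    }
  }
  structure(list(time = time, gevi = gevi, reference = reference, fs = fs,
                 labels = labels, meta = meta),
            class = "dual_channel_trace")
}

#' @export
print.dual_channel_trace <- function(x, ...) {
  cat(sprintf("<dual_channel_trace> %d samples @ %g Hz (%.1f s) [%s | %s]\n",
              length(x$gevi), x$fs, length(x$gevi) / x$fs,
              x$labels[1], x$labels[2]))
  invisible(x)
}

#' Dual-channel movie
#'
#' Paired T x H x W image stacks for the GEVI and reference channels.
#'
#' @param gevi,reference numeric arrays of identical dimension `c(T, H, W)`.
#' @param fs frame rate, Hz.
#' @param pixel_pitch pixel size at the specimen, mm/pixel.
#' @param meta free-form named list.
#' @export
dual_channel_movie <- function(gevi, reference, fs, pixel_pitch,
                               meta = list()) {
  if (length(dim(gevi)) != 3 || !identical(dim(gevi), dim(reference))) {
    stop("gevi and reference must be T x H x W arrays of identical dimension")
  }
  if (fs <= 0) stop("fs must be > 0")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  structure(list(gevi = gevi, reference = reference, fs = fs,
                 pixel_pitch = pixel_pitch, meta = meta),
            class = "dual_channel_movie")
}

#' @export
print.dual_channel_movie <- function(x, ...) {
  d <- dim(x$gevi)
  cat(sprintf(
    "<dual_channel_movie> %d frames x %d x %d px @ %g Hz, %.4g mm/px\n",
    d[1], d[2], d[3], x$fs, x$pixel_pitch))
  invisible(x)
}

#' Electrical (electrode) trace
#'
#' @param signal numeric vector, volts (or microvolts, declared downstream).
#' @param fs sampling rate, Hz.
#' @param sync optional binary synchronization waveform sampled at `fs`.
#' @param meta free-form named list.
#' @export
electrical_trace <- function(signal, fs, sync = NULL, meta = list()) {
  signal <- as.numeric(signal)
  if (fs <= 0) stop("fs must be > 0")
  if (!is.null(sync)) {
    sync <- as.numeric(sync)
    if (length(sync) != length(signal)) stop("sync length mismatch")
    if (length(unique(sync)) > 2) stop("sync must take exactly two values")
  }
  structure(list(signal = signal, fs = fs, sync = sync, meta = meta),
            class = "electrical_trace")
}

#' @export
print.electrical_trace <- function(x, ...) {
  cat(sprintf("<electrical_trace> %d samples @ %g Hz%s\n", length(x$signal),
              x$fs, if (is.null(x$sync)) "" else " (+sync)"))
  invisible(x)
}
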