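## File readers/writers. Traces travel as CSV (columns time,gevi,reference)
## or HDF5; movies as HDF5 (one dataset per channel, fs and pixel_pitch
## attributes) or the package's flat-binary container. Numeric payloads
## round-trip bit-identically.

#' Write / read a dual-channel trace as CSV
#' @param trace a [dual_channel_trace()].
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time = trace$time, gevi = trace$gevi,
               reference = trace$reference),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param fs sampling rate; if `NULL`, inferred from the time column.
#' @export
read_trace_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time", "gevi", "reference") %in% names(d))) {
    stop("CSV must have columns time, gevi, reference")
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$time))
  dual_channel_trace(d$gevi, d$reference, fs = fs, time = d$time)
}

#' Write / read a dual-channel trace as HDF5
#' @inheritParams write_trace_csv
#' @export
write_trace_h5 <- function(trace, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(trace$time, path, "time")
  rhdf5::h5write(trace$gevi, path, "gevi")
  rhdf5::h5write(trace$reference, path, "reference")
  rhdf5::h5write(trace$fs, path, "fs")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_trace_h5
#' @export
read_trace_h5 <- function(path) {
  fs <- as.numeric(rhdf5::h5read(path, "fs"))
  tr <- dual_channel_trace(
    as.numeric(rhdf5::h5read(path, "gevi")),
    as.numeric(rhdf5::h5read(path, "reference")),
    fs = fs, time = as.numeric(rhdf5::h5read(path, "time")))
  rhdf5::h5closeAll()
  tr
}

#' Write / read a dual-channel movie as HDF5
#' @param movie a [dual_channel_movie()].
#' @param path file path.
#' @export
write_movie_h5 <- function(movie, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(movie$gevi, path, "gevi")
  rhdf5::h5write(movie$reference, path, "reference")
  rhdf5::h5write(movie$fs, path, "fs")
  rhdf5::h5write(movie$pixel_pitch, path, "pixel_pitch")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_movie_h5
#' @export
read_movie_h5 <- function(path) {
  mv <- dual_channel_movie(
    rhdf5::h5read(path, "gevi"),
    rhdf5::h5read(path, "reference"),
    fs = as.numeric(rhdf5::h5read(path, "fs")),
    pixel_pitch = as.numeric(rhdf5::h5read(path, "pixel_pitch")))
  rhdf5::h5closeAll()
  mv
}

#' Write / read an electrical trace as CSV
#' @param elec an [electrical_trace()].
#' @param path file path.
#' @param fs sampling rate in Hz (reader only; required, CSV carries samples).
#' @export
write_electrical_csv <- function(elec, path) {
  d <- data.frame(signal = elec$signal)
  if (!is.null(elec$sync)) d$sync <- elec$sync
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrical_csv
#' @export
read_electrical_csv <- function(path, fs) {
  d <- utils::read.csv(path)
  electrical_trace(d$signal, fs = fs,
                   sync = if ("sync" %in% names(d)) d$sync else NULL)
}
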