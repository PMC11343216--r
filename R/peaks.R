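## Local-maximum detection with prominence, width and minimum-distance
## filtering, reimplementing the findpeaks semantics the event detectors rely
## on. Definitions: prominence is the peak height above the higher of the two
## flanking minima (searched out to the nearest higher sample or the signal
## edge); width is measured at half prominence with linear interpolation;
## minimum distance keeps the larger of two close peaks (greedy by height).

#' Peak-filtering criteria
#' @param min_prominence minimum prominence (signal units).
#' @param min_distance minimum peak separation, s.
#' @param min_width,max_width width bounds at half prominence, s.
#' @export
peak_criteria <- function(min_prominence = 0, min_distance = 0,
                          min_width = 0, max_width = Inf) {
  if (min_width >= max_width) stop("min_width must be < max_width")
  list(min_prominence = min_prominence, min_distance = min_distance,
       min_width = min_width, max_width = max_width)
}

local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && x[j + 1] < x[i]) {
        out <- c(out, (i + j) %/% 2L)   # middle of a plateau
        i <- j
      }
    }
    i <- i + 1L
  }
  out
}

peak_prominence <- function(x, p) {
  n <- length(x)
  ## left base: minimum between the peak and the nearest higher sample (or
  ## the signal start)
  i <- p
  left_min <- x[p]
  while (i > 1) {
    i <- i - 1L
    if (x[i] > x[p]) break
    if (x[i] < left_min) left_min <- x[i]
  }
  i <- p
  right_min <- x[p]
  while (i < n) {
    i <- i + 1L
    if (x[i] > x[p]) break
    if (x[i] < right_min) right_min <- x[i]
  }
  x[p] - max(left_min, right_min)
}

peak_width <- function(x, p, prominence) {
  h <- x[p] - prominence / 2
  n <- length(x)
  i <- p
  left <- 1
  while (i > 1) {
    i <- i - 1L
    if (x[i] <= h) {
      left <- i + (h - x[i]) / (x[i + 1] - x[i])
      break
    }
    if (x[i] > x[p]) { left <- i; break }
  }
  i <- p
  right <- n
  while (i < n) {
    i <- i + 1L
    if (x[i] <= h) {
      right <- i - (h - x[i]) / (x[i - 1] - x[i])
      break
    }
    if (x[i] > x[p]) { right <- i; break }
  }
  right - left
}

#' Find peaks with prominence, width and distance filtering
#'
#' @param x numeric vector (finite values).
#' @param fs sampling rate, Hz (1 treats indices as time).
#' @param criteria a [peak_criteria()].
#' @return data.frame with columns `index`, `time`, `height`, `prominence`,
#'   `width` (s); zero rows when nothing qualifies.
#' @export
find_peaks <- function(x, fs = 1, criteria = peak_criteria()) {
  if (any(!is.finite(x))) stop("signal must be finite")
  idx <- local_maxima(x)
  empty <- data.frame(index = integer(0), time = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      width = numeric(0))
  if (!length(idx)) return(empty)
  prom <- vapply(idx, function(p) peak_prominence(x, p), 0)
  keep <- prom >= criteria$min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(empty)
  wid <- vapply(seq_along(idx),
                function(i) peak_width(x, idx[i], prom[i]), 0) / fs
  keep <- wid >= criteria$min_width & wid <= criteria$max_width
  idx <- idx[keep]; prom <- prom[keep]; wid <- wid[keep]
  if (!length(idx)) return(empty)
  ## greedy distance filter, larger peaks first
  ord <- order(x[idx], decreasing = TRUE)
  min_sep <- criteria$min_distance * fs
  kept <- integer(0)
  for (o in ord) {
    if (!length(kept) || all(abs(idx[o] - idx[kept]) > min_sep)) {
      kept <- c(kept, o)
    }
  }
  kept <- sort(kept)
  data.frame(index = idx[kept], time = (idx[kept] - 1) / fs,
             height = x[idx[kept]], prominence = prom[kept],
             width = wid[kept])
}
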