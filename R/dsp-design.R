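## IIR filter design: analog Butterworth prototype -> band transform ->
## bilinear transform -> second-order sections. No external DSP package is
## available, so the design chain is implemented here and exercised by
## tone-response tests (attenuation / passband-gain post-conditions).

butter_prototype <- function(order) {
  m <- seq(-order + 1, order - 1, by = 2)
  p <- -exp(1i * pi * m / (2 * order))
  list(z = complex(0), p = p, k = 1)
}

lp2lp_zpk <- function(zpk, wo) {
  degree <- length(zpk$p) - length(zpk$z)
  list(z = zpk$z * wo, p = zpk$p * wo, k = zpk$k * wo^degree)
}

lp2hp_zpk <- function(zpk, wo) {
  degree <- length(zpk$p) - length(zpk$z)
  z <- if (length(zpk$z)) wo / zpk$z else complex(0)
  p <- wo / zpk$p
  k <- zpk$k * Re(prod(-zpk$z) / prod(-zpk$p))
  list(z = c(z, rep(0 + 0i, degree)), p = p, k = k)
}

lp2bp_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  zl <- zpk$z * bw / 2
  pl <- zpk$p * bw / 2
  z <- c(zl + sqrt(zl^2 - wo^2), zl - sqrt(zl^2 - wo^2))
  p <- c(pl + sqrt(pl^2 - wo^2), pl - sqrt(pl^2 - wo^2))
  list(z = c(z, rep(0 + 0i, degree)), p = p, k = zpk$k * bw^degree)
}

lp2bs_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  zh <- if (length(zpk$z)) (bw / 2) / zpk$z else complex(0)
  ph <- (bw / 2) / zpk$p
  z <- c(zh + sqrt(zh^2 - wo^2), zh - sqrt(zh^2 - wo^2))
  p <- c(ph + sqrt(ph^2 - wo^2), ph - sqrt(ph^2 - wo^2))
  z <- c(z, rep(1i * wo, degree), rep(-1i * wo, degree))
  k <- zpk$k * Re(prod(-zpk$z) / prod(-zpk$p))
  list(z = z, p = p, k = k)
}

bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  degree <- length(zpk$p) - length(zpk$z)
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  kd <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  list(z = c(zd, rep(-1 + 0i, degree)), p = pd, k = kd)
}

## Split a conjugate-closed root multiset into units: conjugate pairs (length-2)
## and reals (length-1), each unit keeping real coefficients when expanded.
root_units <- function(r, tol = 1e-8) {
  units <- list()
  used <- rep(FALSE, length(r))
  for (i in seq_along(r)) {
    if (used[i]) next
    if (abs(Im(r[i])) > tol * max(1, abs(r[i]))) {
      j <- which(!used & abs(r - Conj(r[i])) < 1e-6 * max(1, abs(r[i])))
      j <- setdiff(j, i)[1]
      if (is.na(j)) stop("non-conjugate complex root in filter design")
      units[[length(units) + 1]] <- c(r[i], r[j])
      used[c(i, j)] <- TRUE
    } else {
      units[[length(units) + 1]] <- r[i]
      used[i] <- TRUE
    }
  }
  units
}

poly_from_roots <- function(r) {
  cf <- 1
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  Re(cf)
}

## Pair pole units with nearest zero units into second-order sections.
## After the bilinear transform the zero and pole counts are equal.
zpk2sos <- function(zpk) {
  p_units <- root_units(zpk$p)
  z_units <- root_units(zpk$z)
  ## merge real pole singles into pairs (sorted by magnitude)
  pair_up <- function(units) {
    singles <- units[vapply(units, length, 1L) == 1]
    pairs <- units[vapply(units, length, 1L) == 2]
    if (length(singles)) {
      ord <- order(vapply(singles, function(u) Mod(u), 0))
      singles <- singles[ord]
      while (length(singles) >= 2) {
        pairs[[length(pairs) + 1]] <- c(singles[[1]], singles[[2]])
        singles <- singles[-(1:2)]
      }
    }
    list(pairs = pairs, single = if (length(singles)) singles[[1]] else NULL)
  }
  pp <- pair_up(p_units)
  ## process pole pairs closest to the unit circle first so they get the
  ## nearest zeros (numerical conditioning)
  ord <- order(vapply(pp$pairs, function(u) abs(1 - Mod(u[1])), 0))
  pp$pairs <- pp$pairs[ord]
  sections <- list()
  take_zeros <- function(n_needed, near) {
    taken <- complex(0)
    while (length(taken) < n_needed && length(z_units) > 0) {
      d <- vapply(z_units, function(u) min(Mod(u - near)), 0)
      sizes <- vapply(z_units, length, 1L)
      cand <- which(sizes <= n_needed - length(taken))
      if (!length(cand)) cand <- seq_along(z_units)
      i <- cand[which.min(d[cand])]
      taken <- c(taken, z_units[[i]])
      z_units[[i]] <<- NULL
    }
    taken
  }
  for (u in pp$pairs) {
    zz <- take_zeros(2, u[1])
    sections[[length(sections) + 1]] <- list(z = zz, p = u)
  }
  if (!is.null(pp$single)) {
    zz <- take_zeros(1, pp$single)
    sections[[length(sections) + 1]] <- list(z = zz, p = pp$single)
  }
  sos <- matrix(0, nrow = length(sections), ncol = 6)
  for (i in seq_along(sections)) {
    b <- poly_from_roots(sections[[i]]$z)
    a <- poly_from_roots(sections[[i]]$p)
    b <- c(b, rep(0, 3 - length(b)))
    a <- c(a, rep(0, 3 - length(a)))
    sos[i, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * zpk$k
  sos
}

#' Design a digital Butterworth filter as second-order sections
#'
#' @param order single-pass filter order of the analog prototype.
#' @param w cutoff frequency in Hz (scalar for `low`/`high`, length-2 vector
#'   for `pass`/`stop`).
#' @param fs sampling rate in Hz.
#' @param type one of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @return numeric matrix with one row per biquad section, columns
#'   `b0,b1,b2,a0,a1,a2`.
#' @export
butter_sos <- function(order, w, fs, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= fs / 2)) {
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  proto <- butter_prototype(order)
  warped <- 2 * fs * tan(pi * w / fs)
  zpk <- switch(type,
    low  = lp2lp_zpk(proto, warped),
    high = lp2hp_zpk(proto, warped),
    pass = lp2bp_zpk(proto, sqrt(prod(warped)), diff(warped)),
    stop = lp2bs_zpk(proto, sqrt(prod(warped)), diff(warped))
  )
  zpk2sos(bilinear_zpk(zpk, fs))
}

## Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_freqz <- function(sos, f, fs) {
  z <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    num <- sos[i, 1] + sos[i, 2] * z + sos[i, 3] * z^2
    den <- sos[i, 4] + sos[i, 5] * z + sos[i, 6] * z^2
    h <- h * num / den
  }
  h
}

## Effective impulse-response length (samples) from the slowest pole.
sos_ir_length <- function(sos, tol = 1e-9) {
  rmax <- 0
  for (i in seq_len(nrow(sos))) {
    r <- Mod(polyroot(rev(sos[i, 4:6])))
    rmax <- max(rmax, r[is.finite(r)])
  }
  if (rmax >= 1 - 1e-12) return(Inf)
  ceiling(log(tol) / log(rmax))
}

#' Apply an SOS filter (single pass)
#' @param sos second-order-section matrix from [butter_sos()].
#' @param x numeric vector.
#' @export
sosfilt <- function(sos, x) sosfilt_cpp(sos, as.numeric(x))

#' Zero-phase (forward-backward) SOS filtering
#'
#' Applies the filter forward and backward with odd-reflection padding of
#' roughly three effective impulse-response lengths, so symmetric pulses keep
#' their peak location and no group delay is introduced.
#' @inheritParams sosfilt
#' @export
sosfiltfilt <- function(sos, x) {
  x <- as.numeric(x)
  n <- length(x)
  nir <- sos_ir_length(sos)
  padlen <- if (!is.finite(nir)) n - 1L else min(n - 1L, as.integer(3 * nir))
  padlen <- max(padlen, min(n - 1L, 3L * (2L * nrow(sos) + 1L)))
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  y <- sosfilt_cpp(sos, ext, dc_init = TRUE)
  y <- rev(sosfilt_cpp(sos, rev(y), dc_init = TRUE))
  y[(padlen + 1):(padlen + n)]
}

#' Linear-phase FIR high-pass filter applied with zero net delay
#'
#' Windowed-sinc (Hamming) design by spectral inversion of the complementary
#' low-pass; applied by centered convolution, so the output has no group delay.
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param cutoff high-pass cutoff, Hz.
#' @param n_taps odd number of taps; default scales with `fs / cutoff`.
#' @export
fir_highpass <- function(x, fs, cutoff, n_taps = NULL) {
  if (is.null(n_taps)) n_taps <- min(length(x) - 1, round(6 * fs / cutoff))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  m <- (n_taps - 1) / 2
  k <- seq(-m, m)
  fc <- cutoff / fs
  h <- 2 * fc * sinc(2 * fc * k) * hamming_window(n_taps)
  h <- h / sum(h)
  h <- -h
  h[m + 1] <- h[m + 1] + 1
  pad <- c(2 * x[1] - x[seq(min(m, length(x) - 1) + 1, 2)], x,
           2 * x[length(x)] - x[seq(length(x) - 1, length(x) - min(m, length(x) - 1))])
  y <- stats::filter(pad, h, method = "convolution", sides = 2)
  mm <- min(m, length(x) - 1)
  as.numeric(y[(mm + 1):(mm + length(x))])
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
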