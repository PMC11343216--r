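# Shared fixtures and independent oracles, built in code at test time.

# Exhaustive brute-force peak scan: every local maximum (plateau middle),
# naive full-signal searches for prominence bases and half-prominence
# crossings, then the same filtering definitions as the package routine.
oracle_find_peaks <- function(x, fs = 1, min_prominence = 0, min_distance = 0,
                              min_width = 0, max_width = Inf) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    ls <- i; while (ls > 1 && x[ls - 1] == x[i]) ls <- ls - 1
    rs <- i; while (rs < n && x[rs + 1] == x[i]) rs <- rs + 1
    if (ls > 1 && rs < n && x[ls - 1] < x[i] && x[rs + 1] < x[i] &&
        i == (ls + rs) %/% 2) {
      cand <- c(cand, i)
    }
  }
  prom <- sapply(cand, function(p) {
    left <- 1
    for (i in seq(p - 1, 1)) if (x[i] > x[p]) { left <- i + 1; break }
    right <- n
    for (i in seq(p + 1, n)) if (x[i] > x[p]) { right <- i - 1; break }
    x[p] - max(min(x[left:p]), min(x[p:right]))
  })
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(integer(0))
  wid <- sapply(seq_along(cand), function(k) {
    p <- cand[k]
    h <- x[p] - prom[k] / 2
    left <- 1
    for (i in seq(p - 1, 1)) {
      if (x[i] > x[p]) { left <- i; break }
      if (x[i] <= h) { left <- i + (h - x[i]) / (x[i + 1] - x[i]); break }
    }
    right <- n
    for (i in seq(p + 1, n)) {
      if (x[i] > x[p]) { right <- i; break }
      if (x[i] <= h) { right <- i - (h - x[i]) / (x[i - 1] - x[i]); break }
    }
    (right - left) / fs
  })
  keep <- wid >= min_width & wid <= max_width
  cand <- cand[keep]
  if (!length(cand)) return(integer(0))
  ord <- order(x[cand], decreasing = TRUE)
  kept <- integer(0)
  for (o in ord) {
    if (!length(kept) || all(abs(cand[o] - cand[kept]) > min_distance * fs)) {
      kept <- c(kept, o)
    }
  }
  sort(cand[kept])
}

# Band power from a Welch PSD, integrated over [lo, hi] Hz.
band_power <- function(x, fs, lo, hi, window_len = 2) {
  p <- welch_psd(x, fs, window_len = window_len, overlap = window_len / 2)
  sel <- p$freqs >= lo & p$freqs <= hi
  sum(p$psd[sel]) * (p$freqs[2] - p$freqs[1])
}

# Plane-wave movie with optional noise; thin wrapper over the generator.
make_wave_movie <- function(speed, direction_deg, snr = Inf, freq = 2,
                            n_frames = 300, hw = 64, fs = 300,
                            pixel_pitch = 0.05, t_off = 0.5, seed = 1) {
  th <- direction_deg * pi / 180
  gen_movie_pair(movie_synth_spec(
    n_frames = n_frames, height = hw, width = hw, fs = fs,
    pixel_pitch = pixel_pitch,
    waves = list(list(slowness = c(cos(th), sin(th)) / speed, freq = freq,
                      amplitude = 1, t_on = 0, t_off = t_off)),
    noise = if (is.finite(snr)) 1 / snr else 0, seed = seed))
}
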