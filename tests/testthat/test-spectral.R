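test_that("welch PSD integrates to the variance of white noise", {
  set.seed(30)
  fs <- 250
  x <- rnorm(120 * fs)
  p <- welch_psd(x, fs, window_len = 1)
  expect_equal(sum(p$psd) * (p$freqs[2] - p$freqs[1]), var(x),
               tolerance = 0.05)
})

test_that("coherence calibration: identity, gain-invariance, bias, delay", {
  set.seed(31)
  fs <- 200
  x <- rnorm(60 * fs)
  ch <- coherence(x, x, fs)
  expect_true(all(ch$magnitude > 0.999))
  expect_lt(max(abs(ch$phase[-1])), 1e-6)
  # invariant to a constant gain
  ch_g <- coherence(x, 17 * x, fs)
  expect_true(all(ch_g$magnitude > 0.999))
  # independent noises, non-overlapping segments: E[msc] = 1/K
  y <- rnorm(60 * fs)
  ch0 <- coherence(x, y, fs, window_len = 1, overlap = 0)
  k <- ch0$n_segments
  bins <- ch0$magnitude[-c(1, length(ch0$magnitude))]
  se <- sd(bins) / sqrt(length(bins))
  expect_lt(abs(mean(bins) - 1 / k), 2 * se + 0.005)
  # delay phase slope -2 pi f d (delay small enough to avoid phase wrap)
  d <- 2
  yd <- c(rep(0, d), x[1:(length(x) - d)])
  chd <- coherence(x, yd, fs)
  sel <- ch$freqs > 5 & ch$freqs < 50
  slope <- coef(lm(chd$phase[sel] ~ chd$freqs[sel]))[2]
  expect_equal(unname(slope), -2 * pi * d / fs, tolerance = 0.02)
  expect_error(coherence(x[1:300], y[1:300], fs), "5 segments")
})

test_that("wavelet spectrogram calibrates on tones without cross-terms", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  sp <- wavelet_spectrogram(sin(2 * pi * 40 * t), fs, c(5, 80))
  i40 <- which.min(abs(sp$freqs - 40))
  ridge <- sp$values[i40, sp$coi[i40, ]]
  expect_equal(mean(ridge), 1, tolerance = 0.05)
  expect_lt(sd(ridge) / mean(ridge), 0.05)
  # zero signal -> all zeros
  expect_equal(max(wavelet_spectrogram(0 * t, fs, c(5, 80))$values), 0)
  # two tones: two ridges, no cross-terms above 10%
  x2 <- sin(2 * pi * 7 * t) + sin(2 * pi * 60 * t)
  sp2 <- wavelet_spectrogram(x2, fs, c(3, 100))
  i7 <- which.min(abs(sp2$freqs - 7))
  i60 <- which.min(abs(sp2$freqs - 60))
  imid <- which.min(abs(sp2$freqs - 25))
  mid_ok <- sp2$coi[imid, ]
  expect_gt(mean(sp2$values[i7, sp2$coi[i7, ]]), 0.9)
  expect_gt(mean(sp2$values[i60, sp2$coi[i60, ]]), 0.9)
  expect_lt(max(sp2$values[imid, mid_ok]), 0.1 *
              mean(sp2$values[i7, sp2$coi[i7, ]]))
})

test_that("band envelope tracks amplitude modulation", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  a <- 1 + 0.5 * sin(2 * pi * 0.7 * t)
  x <- a * cos(2 * pi * 40 * t)
  env <- band_envelope(x, fs, c(30, 50), method = "hilbert")
  mid <- 500:(length(t) - 500)
  expect_lt(max(abs(env[mid] - a[mid]) / a[mid]), 0.1)
  # constant tone -> constant envelope
  env_c <- band_envelope(cos(2 * pi * 40 * t), fs, c(30, 50), "hilbert")
  expect_lt(sd(env_c[mid]), 0.02)
  # out-of-band tone -> ~0
  env_o <- band_envelope(cos(2 * pi * 5 * t), fs, c(30, 50), "hilbert")
  expect_lt(max(env_o[mid]), 0.02)
})

test_that("event-triggered averaging recovers transients, drops edge events", {
  fs <- 100
  n <- 60 * fs
  x <- numeric(n)
  tmpl <- exp(-0.5 * ((-50:50) / 10)^2)
  ev <- seq(2, 55, by = 1.5)
  for (e in ev) {
    i <- round(e * fs) + 1
    x[(i - 50):(i + 50)] <- x[(i - 50):(i + 50)] + tmpl
  }
  eta <- event_triggered_average(x, fs, ev, window = c(-0.5, 0.5))
  expect_equal(eta$mean, tmpl, tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(eta$upper - eta$lower), 1e-10)
  # edge event dropped and reported
  eta2 <- event_triggered_average(x, fs, c(0.1, ev), window = c(-0.5, 0.5))
  expect_equal(eta2$n_dropped, 1)
  # CI shrinks ~1/sqrt(n) with independent noise
  set.seed(32)
  noisy <- function(nev) {
    xx <- rep(tmpl, nev) + rnorm(101 * nev)
    event_triggered_average(xx, fs, (seq_len(nev) - 0.5) * 101 / fs,
                            window = c(-0.5, 0.5), ci = "normal")
  }
  w16 <- mean(noisy(16)$upper - noisy(16)$lower)
  w64 <- mean(noisy(64)$upper - noisy(64)$lower)
  expect_equal(w16 / w64, 2, tolerance = 0.2)
})

test_that("event-related spectrogram localizes injected gamma bursts", {
  set.seed(33)
  fs <- 250
  n <- 120 * fs
  t <- (1:n) / fs
  x <- 0.2 * rnorm(n)
  ev <- seq(5, 110, by = 5)
  for (e in ev) {
    burst_t <- t - (e + 0.2)
    x <- x + exp(-0.5 * (burst_t / 0.05)^2) * sin(2 * pi * 50 * t)
  }
  es <- event_related_spectrogram(x, fs, ev, window = c(-1, 1), c(20, 80))
  i50 <- which.min(abs(es$freqs - 50))
  row <- es$values[i50, ]
  at_burst <- row[which.min(abs(es$times - 0.2))]
  baseline <- mean(row[es$times < -0.3])
  expect_gt(at_burst / baseline, 3)
  # stationary signal -> flat event mean
  es0 <- event_related_spectrogram(0.2 * rnorm(n) + sin(2 * pi * 30 * t),
                                   fs, ev, window = c(-1, 1), c(20, 80))
  i30 <- which.min(abs(es0$freqs - 30))
  r30 <- es0$values[i30, ]
  expect_lt((max(r30) - min(r30)) / mean(r30), 0.2)
})
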