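test_that("notch filter kills the target tone and spares everything else", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  tone300 <- sin(2 * pi * 300 * t)
  out <- notch_filter(tone300, fs, 300, halfwidth = 1)
  expect_lt(sqrt(mean(out^2)) / sqrt(mean(tone300^2)), 0.01)
  # DC-offset constant passes unchanged
  const <- rep(2.5, 2000)
  expect_equal(notch_filter(const, fs, 300, 1), const, tolerance = 1e-9)
  # far-away tone amplitude preserved within 1%
  tone40 <- sin(2 * pi * 40 * t)
  out40 <- notch_filter(tone40, fs, 300, 1)
  expect_equal(sqrt(mean(out40^2)) / sqrt(mean(tone40^2)), 1,
               tolerance = 0.01)
  expect_error(notch_filter(tone40, fs, 499.5, 1), "Nyquist")
  # >= 40 dB attenuation at center by design
  h <- Mod(tempotools:::sos_freqz(butter_sos(8, c(299, 301), fs, "stop"),
                                  300, fs))
  expect_lt(20 * log10(h), -40)
})

test_that("bandpass has ~unit in-band gain and steep stopband rolloff", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  inband <- sin(2 * pi * 150 * t)
  out <- bandpass(inband, fs, 120, 200, order = 3)
  expect_equal(sd(out) / sd(inband), 1, tolerance = 0.02)
  # single-pass -3 dB points near the band edges
  sos <- butter_sos(3, c(120, 200), fs, "pass")
  expect_equal(Mod(tempotools:::sos_freqz(sos, c(120, 200), fs)),
               rep(1 / sqrt(2), 2), tolerance = 0.02)
  # tone at 4x hi: cumulative attenuation >= order * 6 dB per octave
  hi4 <- Mod(tempotools:::sos_freqz(sos, 400, fs))
  expect_lt(20 * log10(hi4), -3 * 6)
  expect_equal(bandpass(rep(0, 1000), fs, 10, 50), rep(0, 1000))
  expect_error(bandpass(inband, fs, 50, 10), "invalid band")
})

test_that("zero-phase filters preserve symmetric pulse peak location", {
  fs <- 500
  x <- exp(-0.5 * ((seq_len(2000) - 1000) / 30)^2)
  for (sos in list(butter_sos(3, c(5, 40), fs, "pass"),
                   butter_sos(4, 10, fs, "low"))) {
    y <- sosfiltfilt(sos, x)
    expect_equal(which.max(y), 1000)
  }
})

test_that("baseline estimation recovers exponential decay constants", {
  fs <- 2
  t <- seq(0, 600, by = 1 / fs)
  x1 <- 3 * exp(-t / 100) + 1
  b1 <- estimate_baseline(x1, fs, "exp1")
  expect_equal(b1$params$tau, 100, tolerance = 0.01)
  # constant trace: F0 constant, half-life infinite
  bc <- estimate_baseline(rep(5, 1000), fs, "exp1")
  expect_equal(bc$baseline, rep(5, 1000))
  expect_equal(bc$half_life, Inf)
  # half-life: single exponential to zero offset halves at tau*log(2)
  x2 <- 2 * exp(-t / 50)
  b2 <- estimate_baseline(x2, fs, "exp1")
  expect_equal(b2$half_life, 50 * log(2), tolerance = 0.01)
  expect_error(estimate_baseline(x1 - 2, fs, "exp1"), "positive")
})

test_that("detrend is exact on algebraic identities and scale-invariant", {
  fs <- 100
  t <- seq(0, 120, by = 1 / fs)
  f0 <- 2 + 0 * t
  x <- f0 * (1 + 0.01 * sin(2 * pi * 5 * t))
  bl <- structure(list(method = "lowpass", baseline = f0, params = NULL,
                       half_life = NA), class = "baseline_fit")
  expect_equal(detrend(x, bl), 1 + 0.01 * sin(2 * pi * 5 * t),
               tolerance = 1e-6)
  expect_equal(detrend(f0, bl), rep(1, length(t)))
  # scale invariance with a lowpass-estimated baseline
  raw <- (3 + exp(-t / 60)) * (1 + 0.005 * sin(2 * pi * 8 * t))
  d1 <- detrend(raw, estimate_baseline(raw, fs, "lowpass"))
  d2 <- detrend(7.3 * raw, estimate_baseline(7.3 * raw, fs, "lowpass"))
  expect_equal(d1, d2, tolerance = 1e-10)
  bl_bad <- bl; bl_bad$baseline[5] <- 0
  expect_error(detrend(x, bl_bad), "positive")
})

test_that("fiber decrosstalking recovers an injected mixing coefficient", {
  set.seed(7)
  fs <- 500
  t <- seq(0, 60, by = 1 / fs)
  donor <- sin(2 * pi * 5 * t) + 0.3 * rnorm(length(t))
  clean <- sin(2 * pi * 5.7 * t + 1) + 0.3 * rnorm(length(t))
  ref <- clean + 0.1 * donor
  dc <- decrosstalk_fiber(ref, donor, fs, band = c(3, 7))
  expect_equal(dc$coefficient, 0.1, tolerance = 0.05)
  expect_lt(mean((dc$corrected - clean)^2), 0.05 * mean(clean^2))
  # exact proportionality zeroes out
  dc2 <- decrosstalk_fiber(0.25 * donor, donor, fs)
  expect_equal(dc2$coefficient, 0.25, tolerance = 1e-6)
  expect_lt(sd(dc2$corrected), 1e-6 * sd(donor))
  expect_error(decrosstalk_fiber(ref, rep(1, length(t)), fs), "variance")
})

test_that("movie decrosstalking is exact frame-wise algebra", {
  set.seed(8)
  pure <- array(rnorm(20 * 8 * 8), c(20, 8, 8))
  green <- array(rnorm(20 * 8 * 8), c(20, 8, 8))
  red <- pure + 0.07 * green
  expect_equal(decrosstalk_movie(red, green, 0.07), pure)
  expect_equal(decrosstalk_movie(red, green, 0), red)
  expect_equal(decrosstalk_movie(red, green, "asap3"), pure)
  mixed <- pure + 0.095 * green
  corr <- decrosstalk_movie(mixed, green, 0.095)
  expect_lt(abs(cor(as.numeric(corr), as.numeric(green))), 0.1)
  expect_error(decrosstalk_movie(red, green[1:10, , ], 0.07), "mismatch")
  expect_error(decrosstalk_movie(red, green, 1.5), "coefficient")
})
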