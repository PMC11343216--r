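test_that("heartbeat frequency is located by Welch peak, errors on noise", {
  set.seed(10)
  fs <- 500
  t <- seq(0, 30, by = 1 / fs)
  r <- cos(2 * pi * 10.5 * t) + 0.3 * cos(2 * pi * 21 * t) +
    0.05 * rnorm(length(t))
  expect_equal(estimate_heartbeat(r, fs), 10.5, tolerance = 0.05)
  expect_error(estimate_heartbeat(rnorm(length(t)), fs), "heartbeat")
  # two peaks, the stronger wins
  r2 <- 0.5 * cos(2 * pi * 9 * t) + cos(2 * pi * 11 * t)
  expect_equal(estimate_heartbeat(r2, fs), 11, tolerance = 0.05)
})

test_that("frequency-independent mixing gives a flat real transfer", {
  set.seed(11)
  fs <- 250
  r <- rnorm(60 * fs)
  g <- 0.5 * r
  flt <- estimate_wiener_filter(g, r, fs,
                                wiener_params(tau = 1, alpha = 1e6),
                                omega0 = 10)
  sel <- flt$freqs > 1 & flt$freqs < fs / 2 - 1
  expect_lt(max(Mod(flt$f[sel] - 0.5)), 0.02)
})

test_that("a pure delay shows up as a linear phase ramp in f(w)", {
  set.seed(12)
  fs <- 250
  n <- 60 * fs
  d <- 5
  r <- as.numeric(sosfiltfilt(butter_sos(4, 40, fs, "low"), rnorm(n + d)))
  g <- r[1:n] + 0.1 * sin(2 * pi * 60 * (1:n) / fs)
  rr <- r[(d + 1):(n + d)]      # g leads rr: g(t) = rr(t - d) + signal
  flt <- estimate_wiener_filter(g, rr, fs, wiener_params(tau = 1, alpha = 1e6),
                                omega0 = 10)
  sel <- flt$freqs > 2 & flt$freqs < 30
  expected <- -2 * pi * flt$freqs[sel] * d / fs
  ph <- Arg(flt$f[sel] * exp(-1i * expected))
  expect_lt(max(abs(ph)), 0.1)
})

test_that("amplitude clipping preserves phase and caps at alpha*|f(w0)|", {
  # constructed arithmetic: raw |f| = 5 at some bin, |f(w0)| = 2, alpha = 1.1
  f_raw <- c(2 + 0i, 5i, 1 + 1i)
  limit <- 1.1 * Mod(f_raw[1])
  over <- Mod(f_raw) > limit
  f <- f_raw
  f[over] <- limit * exp(1i * Arg(f[over]))
  expect_equal(Mod(f[2]), 2.2)
  expect_equal(Arg(f[2]), pi / 2)
  expect_equal(f[3], f_raw[3])
})

test_that("single-tiled-segment estimate equals the direct FFT ratio", {
  set.seed(13)
  fs <- 128
  nseg <- 2 * fs
  r1 <- as.numeric(sosfiltfilt(butter_sos(2, c(2, 50), fs, "pass"),
                               rnorm(nseg)))
  g1 <- as.numeric(stats::filter(r1, c(0.4, 0.3, 0.2), sides = 1))
  g1[is.na(g1)] <- 0
  r <- rep(r1, 4)
  g <- rep(g1, 4)
  flt <- estimate_wiener_filter(g, r, fs,
                                wiener_params(tau = 2, overlap = 0,
                                              window = "rect", alpha = 1e9),
                                omega0 = 10)
  fr <- fft(g1 - mean(g1)) / fft(r1 - mean(r1))
  pow <- Mod(fft(r1 - mean(r1)))^2
  sel <- pow > 0.05 * max(pow)
  sel[1] <- FALSE
  expect_lt(max(Mod(flt$f[sel] - fr[sel])), 1e-6)
})

test_that("unmixing removes a phase-lagged artifact, scalar regression cannot", {
  tp <- gen_trace_pair(trace_synth_spec(seed = 42))
  fs <- 500
  g <- tp$trace$gevi - mean(tp$trace$gevi)
  r <- tp$trace$reference - mean(tp$trace$reference)
  res <- unmix_trace(g, r, fs)
  # artifact band: heartbeat fundamental +- 1 Hz
  f0 <- 10.5
  att <- band_power(g, fs, f0 - 1, f0 + 1) /
    band_power(res$voltage, fs, f0 - 1, f0 + 1)
  expect_gt(10 * log10(att), 20)
  # 40 Hz signal preserved within 1 dB
  p_v <- band_power(res$voltage, fs, 39, 41)
  p_s <- band_power(tp$truth$voltage, fs, 39, 41)
  expect_lt(abs(10 * log10(p_v / p_s)), 1)
  # frequency-independent regression leaves strictly more artifact power
  sc <- scalar_regression_unmix(g, r)
  expect_gt(band_power(sc$voltage, fs, f0 - 1, f0 + 1),
            band_power(res$voltage, fs, f0 - 1, f0 + 1))
})

test_that("unmix_trace identities: zero reference, additivity, V + H = G", {
  set.seed(14)
  fs <- 200
  g <- rnorm(20 * fs)
  res0 <- unmix_trace(g, rep(0, length(g)), fs, omega0 = 10)
  expect_equal(res0$voltage, g)
  expect_equal(res0$artifact, rep(0, length(g)))
  # V + H = G exactly for any estimated filter
  r <- rnorm(20 * fs)
  res <- unmix_trace(g, r, fs, omega0 = 10)
  expect_equal(res$voltage + res$artifact, g, tolerance = 1e-12)
  # linearity at fixed filter (affine weights: H depends on R alone)
  g2 <- rnorm(20 * fs)
  ra <- unmix_trace(g, r, fs, filter = res$filter)
  rb <- unmix_trace(g2, r, fs, filter = res$filter)
  rc <- unmix_trace(2 * g - g2, r, fs, filter = res$filter)
  expect_equal(rc$voltage, 2 * ra$voltage - rb$voltage, tolerance = 1e-9)
})

test_that("wiener filter invariants: hermitian f, kernel round-trip, clipping",
{
  set.seed(15)
  fs <- 250
  tp <- gen_trace_pair(trace_synth_spec(duration = 20, fs = fs, seed = 15))
  flt <- estimate_wiener_filter(tp$trace$gevi - 1, tp$trace$reference - 1, fs)
  n <- length(flt$f)
  # hermitian symmetry (real kernel)
  expect_lt(max(Mod(flt$f[2:(n %/% 2)] - Conj(flt$f[n:(n %/% 2 + 2)]))),
            1e-12)
  # kernel inverse-transforms f (round trip)
  center <- flt$kernel_center
  raw <- c(flt$kernel[center:n], flt$kernel[1:(center - 1)])
  expect_lt(max(Mod(fft(raw) - flt$f)), 1e-9 * max(Mod(flt$f)))
  # clipping bound
  i0 <- which.min(abs(flt$freqs - flt$omega0))
  expect_lte(max(Mod(flt$f)), 1.1 * Mod(flt$f[i0]) * (1 + 1e-12))
})

test_that("estimated transfer matches the generator's declared h(w)", {
  tp <- gen_trace_pair(trace_synth_spec(
    duration = 120, fs = 500,
    noise = list(gevi = 1e-4, reference = 1e-4), seed = 16))
  flt <- estimate_wiener_filter(tp$trace$gevi - 1, tp$trace$reference - 1,
                                500, wiener_params(tau = 2))
  for (k in seq_len(nrow(tp$truth$transfer))) {
    fk <- tp$truth$transfer$freq[k]
    hk <- tp$truth$transfer$h[k]
    i <- which.min(abs(flt$freqs[1:(length(flt$f) %/% 2)] - fk))
    expect_lt(abs(Mod(flt$f[i]) / Mod(hk) - 1), 0.05)
    expect_lt(abs(Arg(flt$f[i] / hk)) * 180 / pi, 5)
  }
})

test_that("noise is not transferred from a 10x-noisier reference", {
  set.seed(17)
  fs <- 500
  n <- 60 * fs
  t <- (1:n) / fs
  g <- 0.005 * sin(2 * pi * 40 * t) + 5e-4 * rnorm(n)
  r <- 5e-3 * rnorm(n)
  res <- unmix_trace(g, r, fs, omega0 = 10)
  expect_lt(var(res$voltage) / var(g), 1.05)
})

test_that("select_params picks a sensible cell and honors tie-breaks", {
  tp <- gen_trace_pair(trace_synth_spec(
    duration = 60, fs = 250,
    oscillations = list(),              # pure artifact data
    noise = list(gevi = 2e-4, reference = 2e-4), seed = 18))
  g <- tp$trace$gevi - 1
  r <- tp$trace$reference - 1
  sel <- select_params(g, r, 250, tau_grid = c(0.5, 1),
                       alpha_grid = c(0, 1.1), omega0 = 10.5)
  tab <- sel$objective
  # alpha = 0 means no filtering (V = G): worse than a well-matched cell
  expect_gt(min(tab$objective[tab$alpha == 0]),
            min(tab$objective[tab$alpha > 0]))
  # single-cell grid returns that cell
  one <- select_params(g, r, 250, 1, 1.1, omega0 = 10.5)
  expect_equal(c(one$tau, one$alpha), c(1, 1.1))
  # artifact-free data: objective ~flat in alpha, smallest tau by tie-break
  set.seed(19)
  g2 <- rnorm(60 * 250) * 1e-3
  r2 <- rnorm(60 * 250) * 1e-3
  sel2 <- select_params(g2, r2, 250, tau_grid = c(0.5, 1),
                        alpha_grid = c(1, 1.2), omega0 = 10)
  expect_equal(sel2$tau, 0.5)
})

test_that("movie unmixing: uniform artifact removed by pass 1; zero ref is identity", {
  set.seed(20)
  fs <- 100
  nf <- 30 * fs
  t <- (1:nf) / fs
  art_r <- 0.01 * cos(2 * pi * 10 * t)
  art_g <- 0.01 * cos(2 * pi * 10 * t + pi / 4)
  sig <- 0.003 * sin(2 * pi * 3 * t)
  h <- 6; w <- 6
  g <- array(0, c(nf, h, w)); r <- array(0, c(nf, h, w))
  for (i in 1:h) for (j in 1:w) {
    g[, i, j] <- sig + art_g + 2e-4 * rnorm(nf)
    r[, i, j] <- art_r + 2e-4 * rnorm(nf)
  }
  mv <- dual_channel_movie(g, r, fs, pixel_pitch = 0.2)
  # pass 1 only (field smaller than the averaging scale -> global average)
  res1 <- unmix_movie(mv, wiener_params(tau = 2), prefilter_scale = 5,
                      per_pixel = FALSE)
  art_pow_in <- band_power(g[, 1, 1], fs, 9, 11)
  art_pow_out <- band_power(res1$voltage[, 1, 1], fs, 9, 11)
  expect_lt(art_pow_out / art_pow_in, 0.05)
  # pass 2 changes little when the artifact is spatially uniform
  res2 <- unmix_movie(mv, wiener_params(tau = 2), prefilter_scale = 5,
                      per_pixel = TRUE)
  expect_lt(mean((res2$voltage - res1$voltage)^2) /
              mean((res1$voltage - mean(res1$voltage))^2), 0.05)
  # all-zero reference: V = G untouched
  mv0 <- dual_channel_movie(g, array(0, dim(g)), fs, 0.2)
  expect_equal(unmix_movie(mv0)$voltage, g)
})

test_that("per-pixel pass wins when artifact phase differs across regions", {
  set.seed(21)
  fs <- 100
  nf <- 30 * fs
  t <- (1:nf) / fs
  art <- cos(2 * pi * 10 * t)
  art_shift <- cos(2 * pi * 10 * t + pi / 2)   # second vessel region
  h <- 4; w <- 8
  g <- array(0, c(nf, h, w)); r <- array(0, c(nf, h, w))
  for (i in 1:h) for (j in 1:w) {
    a <- if (j <= w / 2) art else art_shift
    g[, i, j] <- 0.01 * a + 2e-4 * rnorm(nf)
    r[, i, j] <- 0.01 * cos(2 * pi * 10 * t - pi / 6) *
      (if (j <= w / 2) 1 else 1) + 2e-4 * rnorm(nf)
  }
  ## reference has one phase; gevi artifact has two regional phases, so the
  ## global pass-1 filter cannot match both regions
  mv <- dual_channel_movie(g, r, fs, 0.2)
  res1 <- unmix_movie(mv, wiener_params(tau = 2), prefilter_scale = 10,
                      per_pixel = FALSE)
  res2 <- unmix_movie(mv, wiener_params(tau = 2), prefilter_scale = 10,
                      per_pixel = TRUE)
  for (j in c(1, w)) {
    p1 <- band_power(res1$voltage[, 2, j], fs, 9, 11)
    p2 <- band_power(res2$voltage[, 2, j], fs, 9, 11)
    expect_lt(p2, p1)
  }
})
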