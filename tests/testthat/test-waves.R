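test_that("delay maps are exact on noiseless plane waves", {
  mv <- make_wave_movie(50, 0, snr = Inf, freq = 2, hw = 32, t_off = Inf)
  dm <- delay_map(mv$voltage, fs = 300, seed = c(16, 16), x_min = 0.75,
                  max_lag = 0.2)
  # seed pixel correlates perfectly with itself at zero lag
  expect_equal(dm$peak_corr[16, 16], 1, tolerance = 1e-9)
  expect_equal(dm$delay[16, 16], 0, tolerance = 1e-9)
  # delay is linear in position along the propagation axis
  d_row <- dm$delay[16, ]
  x_mm <- (seq_len(32) - 16) * 0.05
  fit <- lm(d_row ~ x_mm)
  expect_equal(unname(coef(fit)[2]), 1 / 50, tolerance = 0.02)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_error(delay_map(array(0, c(50, 8, 8)), 300, c(4, 4)),
               "zero-variance")
})

test_that("plane fits report both velocity conventions correctly", {
  # tau = 0.02 x: gradient convention v = (50, 0)
  delay <- outer(rep(1, 20), 0.02 * (0:19) * 1)  # pitch 1 mm
  dm <- structure(list(peak_corr = matrix(1, 20, 20), delay = delay,
                       seed = c(10, 10), x_min = 0.75), class = "delay_map")
  pf <- plane_fit_velocity(dm, pixel_pitch = 1)
  expect_equal(pf$velocity_gradient, c(50, 0), tolerance = 1e-6)
  expect_equal(pf$speed_gradient, 50, tolerance = 1e-6)
  expect_equal(pf$direction, 0, tolerance = 1e-6)
  # tau = 0.01 x + 0.01 y: reciprocal (100, 100), speed 141.4;
  # gradient (50, 50), speed 70.7
  delay2 <- outer(0.01 * (0:19), 0.01 * (0:19), "+")
  dm2 <- structure(list(peak_corr = matrix(1, 20, 20), delay = delay2,
                        seed = c(10, 10), x_min = 0.75), class = "delay_map")
  pf2 <- plane_fit_velocity(dm2, pixel_pitch = 1)
  expect_equal(pf2$velocity_reciprocal, c(100, 100), tolerance = 1e-6)
  expect_equal(pf2$speed_reciprocal, sqrt(2) * 100, tolerance = 1e-6)
  expect_equal(pf2$velocity_gradient, c(50, 50), tolerance = 1e-6)
  expect_equal(pf2$speed_gradient, sqrt(2) * 50, tolerance = 1e-4)
})

test_that("noisy plane-wave delay maps still track the true linear field", {
  mv <- make_wave_movie(30, 30, snr = 3, freq = 2, hw = 32, t_off = Inf,
                        n_frames = 1200, seed = 3)
  dm <- delay_map(mv$movie$gevi, fs = 300, seed = c(16, 16), x_min = 0.6,
                  max_lag = 0.2)
  th <- 30 * pi / 180
  x_mm <- outer(rep(1, 32), (seq_len(32) - 16) * 0.05)
  y_mm <- outer((seq_len(32) - 16) * 0.05, rep(1, 32))
  truth <- (cos(th) * x_mm + sin(th) * y_mm) / 30
  mask <- !is.na(dm$delay)
  expect_gt(sum(mask), 100)
  expect_gt(cor(dm$delay[mask], truth[mask]), 0.95)
})

test_that("spacetime projections behave on separable and plane-wave movies", {
  # separable movie f(x) g(t): projections reproduce g(t) up to scale
  nf <- 100
  g_t <- sin(2 * pi * (1:nf) / 30)
  f_x <- seq(1, 2, length.out = 16)
  mv <- array(0, c(nf, 16, 16))
  for (k in 1:nf) mv[k, , ] <- outer(rep(1, 16), f_x) * g_t[k]
  pr <- spacetime_project(mv, pixel_pitch = 0.1)
  expect_equal(cor(pr$col_axis[, 5], g_t), 1, tolerance = 1e-9)
  # x-propagating wave: tilted crest along x, simultaneous along y
  wv <- make_wave_movie(50, 0, snr = Inf, freq = 2, hw = 32)
  pw <- spacetime_project(wv$voltage, pixel_pitch = 0.05)
  tp_x <- apply(pw$col_axis, 2, which.max)
  tp_y <- apply(pw$row_axis, 2, which.max)
  expect_gt(diff(range(tp_x)), 5)      # crest sweeps across x
  expect_lt(diff(range(tp_y)), 3)      # near-simultaneous along y
})

test_that("slowness fits recover speed and direction in closed form", {
  # slowness (0.02, 0): speed 50, direction 0
  mv <- make_wave_movie(50, 0, snr = Inf, freq = 2, hw = 32)
  fit <- fit_slowness(spacetime_project(mv$voltage, 0.05, c(1, 150)), 300)
  expect_equal(fit$speed, 50, tolerance = 0.02)
  expect_lt(abs(fit$direction - 0), 2)
  expect_true(fit$accepted)
  # slowness (0.02, 0.02): speed 35.36, direction 45
  th <- 45 * pi / 180
  sp <- 1 / sqrt(2 * 0.02^2)
  mv2 <- make_wave_movie(sp, 45, snr = Inf, freq = 2, hw = 32)
  fit2 <- fit_slowness(spacetime_project(mv2$voltage, 0.05, c(1, 150)), 300)
  expect_equal(fit2$speed, 35.36, tolerance = 0.02)
  expect_equal(fit2$direction, 45, tolerance = 0.05)
  # degenerate: synchronous flash -> alpha = 0, p = 1, rejected
  flash <- array(rep(exp(-0.5 * ((1:100 - 50) / 5)^2), 64), c(100, 8, 8))
  fit0 <- fit_slowness(spacetime_project(flash, 0.05), 300)
  expect_equal(c(fit0$alpha_x, fit0$alpha_y), c(0, 0))
  expect_equal(c(fit0$p_x, fit0$p_y), c(1, 1))
  expect_false(fit0$accepted)
})

test_that("flow maps agree in direction on uniform waves, reject static movies", {
  mv <- make_wave_movie(50, 90, snr = Inf, freq = 2, hw = 32, t_off = Inf)
  fm <- flow_map(mv$voltage, fs = 300, pixel_pitch = 0.05, tile_size = 16,
                 x_min = 0.6, max_lag = 0.2)
  expect_gte(nrow(fm$tiles), 3)
  dd <- abs(((fm$tiles$direction - 90) + 180) %% 360 - 180)
  expect_lt(max(dd), 5)
  # static movie yields no accepted tiles
  fm0 <- flow_map(array(1, c(50, 16, 16)), 300, 0.05, tile_size = 8)
  expect_equal(nrow(fm0$tiles), 0)
})

test_that("velocity distributions summarize modes and degenerate cases", {
  # all events identical: single-bin degenerate histograms
  ev1 <- data.frame(speed = rep(50, 8), direction = rep(30, 8))
  vd1 <- velocity_distributions(ev1)
  expect_equal(sum(vd1$speed_hist$counts > 0), 1)
  expect_equal(sum(vd1$direction_hist$counts > 0), 1)
  # two planted direction modes 90 deg apart
  set.seed(60)
  ev2 <- data.frame(speed = c(rnorm(40, 50, 2), rnorm(40, 52, 2)),
                    direction = c(rnorm(40, 45, 5), rnorm(40, 135, 5)))
  vd2 <- velocity_distributions(ev2, direction_bin_deg = 30)
  top2 <- sort(vd2$direction_modes[1:2])
  expect_lt(abs(top2[1] - 45), 30)
  expect_lt(abs(top2[2] - 135), 30)
  # equal-median planted speeds: rank-sum rarely significant
  set.seed(61)
  p_vals <- replicate(60, {
    ev <- data.frame(speed = c(rnorm(25, 60, 5), rnorm(25, 60, 5)),
                     direction = rep(c(0, 90), each = 25))
    velocity_distributions(ev, groups = rep(c("a", "b"), each = 25))$ranksum_p
  })
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("method cross-validation and rotation equivariance hold", {
  mv <- make_wave_movie(80, 30, snr = Inf, freq = 2, hw = 32, t_off = Inf,
                        n_frames = 900, seed = 7)
  # route A: full-field delay map + plane fit (gradient convention)
  dm <- delay_map(mv$voltage, 300, c(16, 16), x_min = 0.6, max_lag = 0.2)
  pf <- plane_fit_velocity(dm, pixel_pitch = 0.05)
  # route B: space-time regression over one temporal period
  fit <- fit_slowness(spacetime_project(mv$voltage, 0.05, c(1, 150)), 300)
  expect_equal(pf$speed_gradient / fit$speed, 1, tolerance = 0.02)
  dd <- abs(((pf$direction - fit$direction) + 180) %% 360 - 180)
  expect_lt(dd, 2)
  # rotating the movie by 90 deg rotates direction by 90, speed unchanged
  rot <- aperm(mv$voltage, c(1, 3, 2))[, , dim(mv$voltage)[2]:1]
  fit_r <- fit_slowness(spacetime_project(rot, 0.05, c(1, 150)), 300)
  expect_equal(fit_r$speed / fit$speed, 1, tolerance = 0.02)
  drot <- abs(((fit_r$direction - fit$direction - 90) + 180) %% 360 - 180)
  expect_lt(drot, 2)
})

test_that("co-propagating harmonics share the carrier's velocity", {
  # 4 Hz carrier with a locked 8 Hz harmonic traveling identically
  sl <- c(1, 0) / 60
  spec <- movie_synth_spec(
    n_frames = 900, height = 32, width = 32, fs = 300, pixel_pitch = 0.05,
    waves = list(list(slowness = sl, freq = 4, amplitude = 1, t_on = 0,
                      t_off = Inf),
                 list(slowness = sl, freq = 8, amplitude = 0.4, t_on = 0,
                      t_off = Inf)),
    seed = 8)
  mv <- gen_movie_pair(spec)
  band_movie <- function(v, lo, hi) {
    out <- array(0, dim(v))
    for (i in seq_len(dim(v)[2])) for (j in seq_len(dim(v)[3])) {
      out[, i, j] <- bandpass(v[, i, j], 300, lo, hi, order = 3)
    }
    out
  }
  carr <- band_movie(mv$voltage, 2, 6)
  harm <- band_movie(mv$voltage, 6, 10)
  ## mid-movie windows shifted by whole periods, each shorter than one period
  ## and positioned so every position holds exactly one crest (no wrap)
  fit_c <- fit_slowness(spacetime_project(carr, 0.05, c(316, 389)), 300)
  fit_h <- fit_slowness(spacetime_project(harm, 0.05, c(307, 343)), 300)
  expect_equal(fit_h$speed / fit_c$speed, 1, tolerance = 0.1)
  dd <- abs(((fit_h$direction - fit_c$direction) + 180) %% 360 - 180)
  expect_lt(dd, 10)
  # an independently propagating high band does not co-propagate
  spec2 <- spec
  spec2$waves[[2]]$slowness <- c(0, 1) / 60
  mv2 <- gen_movie_pair(spec2)
  harm2 <- band_movie(mv2$voltage, 6, 10)
  fit_h2 <- fit_slowness(spacetime_project(harm2, 0.05, c(307, 343)), 300)
  dd2 <- abs(((fit_h2$direction - fit_c$direction) + 180) %% 360 - 180)
  expect_gt(dd2, 45)
})
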