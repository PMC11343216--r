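## Synthetic dual-channel data with known ground truth. Artifacts (heartbeat
## plus slow hemodynamics) enter both channels through per-harmonic complex
## gains, so the implied GEVI<->reference transfer h(w) = g_gevi(w)/g_ref(w)
## is known exactly; voltage-band oscillations, phase-amplitude coupling,
## ripple bursts, photobleaching and noise are layered on top. Signals are
## built multiplicatively on the bleaching baseline (the small-signal,
## <= 1% dF/F regime) so detrending linearizes them additively.

#' Specification for a synthetic dual-channel trace pair
#'
#' Defaults describe a 60-s, 500-Hz recording with a 10.5-Hz heartbeat
#' (3 harmonics) whose reference-to-GEVI transfer has a 60-degree phase lag
#' at the fundamental, a 40-Hz voltage oscillation of 0.5% dF/F, mild
#' bi-exponential photobleaching and Gaussian shot-like noise.
#'
#' @param duration s.
#' @param fs Hz.
#' @param oscillations list of `list(freq, amplitude, phase = 0)` voltage
#'   components (dF/F units).
#' @param cfc `NULL` or `list(carrier_freq, carrier_amp, amp_freq, amp_amp,
#'   m, phi0_deg)`: gamma amplitude modulated by carrier phase
#'   (trough-referenced preferred phase `phi0_deg`).
#' @param ripples `NULL` or `list(times, duration, freq, amplitude)` burst
#'   injections.
#' @param heartbeat `NULL` or `list(f0, n_harmonics, gain_gevi, gain_ref)`
#'   with complex per-harmonic gains (recycled).
#' @param hemodynamics `NULL` or `list(freq, gain_gevi, gain_ref)` slow
#'   oscillatory drift with complex gains.
#' @param bleach `NULL` or `list(amplitudes, tau, offset)` exponential decay
#'   multiplying both channels.
#' @param noise `list(gevi, reference)` Gaussian noise s.d. (dF/F units).
#' @param seed RNG seed; generation is a pure function of spec + seed.
#' @export
trace_synth_spec <- function(duration = 60, fs = 500,
                             oscillations = list(list(freq = 40,
                                                      amplitude = 0.005)),
                             cfc = NULL, ripples = NULL,
                             heartbeat = list(
                               f0 = 10.5, n_harmonics = 3,
                               gain_gevi = 0.01 * exp(1i * pi / 3),
                               gain_ref = 0.01),
                             hemodynamics = NULL,
                             bleach = NULL,
                             noise = list(gevi = 5e-4, reference = 5e-4),
                             seed = 1) {
  if (!is.null(heartbeat) && (heartbeat$f0 <= 0 || heartbeat$f0 >= fs / 2)) {
    stop("heartbeat fundamental outside (0, fs/2)")
  }
  structure(list(duration = duration, fs = fs, oscillations = oscillations,
                 cfc = cfc, ripples = ripples, heartbeat = heartbeat,
                 hemodynamics = hemodynamics, bleach = bleach, noise = noise,
                 seed = seed),
            class = "trace_synth_spec")
}

#' Generate a synthetic dual-channel trace pair with ground truth
#'
#' @param spec a [trace_synth_spec()].
#' @return list with `trace` (a [dual_channel_trace()]) and `truth`
#'   (`voltage`, `artifact_gevi`, `artifact_ref`, `transfer` table of
#'   frequency and complex h(w), `event_times`).
#' @export
gen_trace_pair <- function(spec) {
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  t <- seq(0, by = 1 / spec$fs, length.out = n)
  voltage <- numeric(n)
  for (o in spec$oscillations) {
    ph <- if (is.null(o$phase)) 0 else o$phase
    if (o$amplitude < 0) stop("oscillation amplitude must be >= 0")
    voltage <- voltage + o$amplitude * sin(2 * pi * o$freq * t + ph)
  }
  if (!is.null(spec$cfc)) {
    cf <- spec$cfc
    theta <- 2 * pi * cf$carrier_freq * t
    ## carrier = -cos(theta): trough at theta = 0, so trough-referenced phase
    ## equals theta (deg)
    voltage <- voltage - cf$carrier_amp * cos(theta)
    mod <- 1 + cf$m * cos(theta - cf$phi0_deg * pi / 180)
    voltage <- voltage + cf$amp_amp * mod * sin(2 * pi * cf$amp_freq * t)
  }
  event_times <- numeric(0)
  if (!is.null(spec$ripples)) {
    rp <- spec$ripples
    event_times <- rp$times
    for (tc in rp$times) {
      env <- exp(-0.5 * ((t - tc) / (rp$duration / 4))^2)
      voltage <- voltage + rp$amplitude * env * sin(2 * pi * rp$freq * (t - tc))
    }
  }
  art_g <- numeric(n)
  art_r <- numeric(n)
  transfer <- data.frame(freq = numeric(0), h = complex(0))
  add_gain_component <- function(freq, g_g, g_r, phase0) {
    wt <- 2 * pi * freq * t + phase0
    list(g = Mod(g_g) * cos(wt + Arg(g_g)), r = Mod(g_r) * cos(wt + Arg(g_r)))
  }
  if (!is.null(spec$heartbeat)) {
    hb <- spec$heartbeat
    gg <- rep_len(hb$gain_gevi, hb$n_harmonics)
    gr <- rep_len(hb$gain_ref, hb$n_harmonics)
    for (k in seq_len(hb$n_harmonics)) {
      fk <- hb$f0 * k
      amp_scale <- 0.5^(k - 1)        # harmonics fall off
      ph0 <- stats::runif(1, 0, 2 * pi)
      cmp <- add_gain_component(fk, gg[k] * amp_scale, gr[k] * amp_scale, ph0)
      art_g <- art_g + cmp$g
      art_r <- art_r + cmp$r
      transfer <- rbind(transfer, data.frame(freq = fk, h = gg[k] / gr[k]))
    }
  }
  if (!is.null(spec$hemodynamics)) {
    hd <- spec$hemodynamics
    ph0 <- stats::runif(1, 0, 2 * pi)
    cmp <- add_gain_component(hd$freq, hd$gain_gevi, hd$gain_ref, ph0)
    art_g <- art_g + cmp$g
    art_r <- art_r + cmp$r
    transfer <- rbind(transfer,
                      data.frame(freq = hd$freq, h = hd$gain_gevi / hd$gain_ref))
  }
  baseline <- if (is.null(spec$bleach)) rep(1, n) else {
    b <- rep(spec$bleach$offset, n)
    for (i in seq_along(spec$bleach$amplitudes)) {
      b <- b + spec$bleach$amplitudes[i] * exp(-t / spec$bleach$tau[i])
    }
    b
  }
  gevi <- baseline * (1 + voltage + art_g) +
    stats::rnorm(n, 0, spec$noise$gevi)
  reference <- baseline * (1 + art_r) +
    stats::rnorm(n, 0, spec$noise$reference)
  list(trace = dual_channel_trace(gevi, reference, spec$fs),
       truth = list(voltage = voltage, artifact_gevi = art_g,
                    artifact_ref = art_r, baseline = baseline,
                    transfer = transfer, event_times = event_times))
}

#' Specification for a synthetic dual-channel movie
#'
#' @param n_frames,height,width movie geometry.
#' @param fs frame rate, Hz.
#' @param pixel_pitch mm/pixel.
#' @param waves list of `list(slowness = c(ax, ay) s/mm, freq Hz, amplitude,
#'   t_on, t_off)` plane waves; each is active inside its time window with a
#'   smooth ramp.
#' @param hemo `NULL` or `list(f0, gain_map_gevi, gain_map_ref)`: complex
#'   H x W gain maps applied to a common heartbeat waveform (scalars are
#'   recycled into uniform maps).
#' @param background_rank rank of smooth random background components.
#' @param background_amp amplitude of background components.
#' @param noise Gaussian pixel noise s.d.
#' @param seed RNG seed.
#' @export
movie_synth_spec <- function(n_frames = 300, height = 64, width = 64,
                             fs = 300, pixel_pitch = 0.05,
                             waves = list(list(slowness = c(0.02, 0),
                                               freq = 4, amplitude = 1,
                                               t_on = 0, t_off = Inf)),
                             hemo = NULL, background_rank = 0,
                             background_amp = 0, noise = 0, seed = 1) {
  for (w in waves) {
    if (w$freq >= fs / 2) stop("wave temporal frequency must be < fs/2")
  }
  structure(list(n_frames = n_frames, height = height, width = width,
                 fs = fs, pixel_pitch = pixel_pitch, waves = waves,
                 hemo = hemo, background_rank = background_rank,
                 background_amp = background_amp, noise = noise, seed = seed),
            class = "movie_synth_spec")
}

#' Generate a synthetic dual-channel movie with ground truth
#'
#' The voltage channel holds plane waves with phase
#' `2 pi (f t - ax x - ay y)` (slowness `(ax, ay)` in s/mm), giving true
#' speed `1/|alpha|` mm/s toward `atan2(ay, ax)`; the reference channel holds
#' spatially patterned heartbeat artifacts. Pure function of spec + seed.
#'
#' @param spec a [movie_synth_spec()].
#' @return list with `movie` (a [dual_channel_movie()]), `voltage` (clean
#'   T x H x W array) and `truth` (per-wave slowness, speed, direction).
#' @export
gen_movie_pair <- function(spec) {
  set.seed(spec$seed)
  t <- seq(0, by = 1 / spec$fs, length.out = spec$n_frames)
  x_mm <- (seq_len(spec$width) - 1) * spec$pixel_pitch
  y_mm <- (seq_len(spec$height) - 1) * spec$pixel_pitch
  v <- array(0, c(spec$n_frames, spec$height, spec$width))
  truth <- data.frame(ax = numeric(0), ay = numeric(0), speed = numeric(0),
                      direction = numeric(0), t_on = numeric(0),
                      t_off = numeric(0))
  for (w in spec$waves) {
    ax <- w$slowness[1]; ay <- w$slowness[2]
    env_t <- as.numeric(t >= w$t_on & t <= min(w$t_off, max(t)))
    ## spatial delay map, shifted so the earliest pixel has zero delay (a
    ## constant delay offset only moves the wave's time origin)
    phase_xy <- outer(ay * y_mm, ax * x_mm, "+")   # H x W, s
    phase_xy <- phase_xy - min(phase_xy)
    for (k in seq_len(spec$n_frames)) {
      if (env_t[k] == 0) next
      v[k, , ] <- v[k, , ] +
        w$amplitude * sin(2 * pi * w$freq * (t[k] - phase_xy))
    }
    a2 <- ax^2 + ay^2
    truth <- rbind(truth, data.frame(
      ax = ax, ay = ay, speed = if (a2 > 0) 1 / sqrt(a2) else Inf,
      direction = atan2(ay, ax) * 180 / pi,
      t_on = w$t_on, t_off = min(w$t_off, max(t))))
  }
  g <- v
  r <- array(0, dim(v))
  if (spec$background_rank > 0) {
    for (k in seq_len(spec$background_rank)) {
      sp <- matrix(stats::rnorm(spec$height * spec$width), spec$height)
      sp <- median_filter_3x3(median_filter_3x3(sp))
      tc <- sosfiltfilt(butter_sos(2, min(2, spec$fs / 4), spec$fs, "low"),
                        stats::rnorm(spec$n_frames))
      g <- g + spec$background_amp * outer(tc, sp)
    }
  }
  if (!is.null(spec$hemo)) {
    hb <- spec$hemo
    gmap_g <- matrix(hb$gain_map_gevi, spec$height, spec$width)
    gmap_r <- matrix(hb$gain_map_ref, spec$height, spec$width)
    ph0 <- stats::runif(1, 0, 2 * pi)
    wt <- 2 * pi * hb$f0 * t + ph0
    for (k in seq_len(spec$n_frames)) {
      g[k, , ] <- g[k, , ] + Mod(gmap_g) * cos(wt[k] + Arg(gmap_g))
      r[k, , ] <- r[k, , ] + Mod(gmap_r) * cos(wt[k] + Arg(gmap_r))
    }
  }
  if (spec$noise > 0) {
    g <- g + array(stats::rnorm(length(g), 0, spec$noise), dim(g))
    r <- r + array(stats::rnorm(length(r), 0, spec$noise), dim(r))
  }
  list(movie = dual_channel_movie(g, r, spec$fs, spec$pixel_pitch),
       voltage = v, truth = truth)
}

#' Generate the 7-experiment indicator-delay design with ground truth
#'
#' Six ordered indicator-pair assignments of three indicators to two cell
#' classes plus one repeated assignment, with per-experiment mean delays
#' `d + delta(i1, class1) - delta(i2, class2)` perturbed by sampling noise of
#' the mean (`sd / sqrt(n_events)`).
#'
#' @param d_phys physiological delay, ms.
#' @param delta named vector of 6 indicator delays, names
#'   `<indicator>.class<1|2>`; per-class minima should be ~0 for the
#'   min-norm representative to match the truth.
#' @param sd per-experiment event-level s.d., ms.
#' @param n_events events per experiment.
#' @param seed RNG seed.
#' @export
gen_delay_experiments <- function(d_phys = 2.3,
                                  delta = c(indA.class1 = 0.02,
                                            indB.class1 = 3.1,
                                            indC.class1 = 5.4,
                                            indA.class2 = 1.2,
                                            indB.class2 = 0,
                                            indC.class2 = 4.0),
                                  sd = 0.2, n_events = 100, seed = 1) {
  set.seed(seed)
  inds <- c("indA", "indB", "indC")
  pairs <- expand.grid(i1 = inds, i2 = inds, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$i1 != pairs$i2, ]
  pairs <- rbind(pairs, pairs[1, ])      # 6 assignments + 1 repeat
  mu <- d_phys + delta[paste0(pairs$i1, ".class1")] -
    delta[paste0(pairs$i2, ".class2")]
  obs <- delay_observations(
    experiment_id = seq_len(nrow(pairs)),
    indicator_on_class1 = pairs$i1, indicator_on_class2 = pairs$i2,
    mean_delay = mu + stats::rnorm(nrow(pairs), 0, sd / sqrt(n_events)),
    sd_delay = rep(sd, nrow(pairs)), n_events = rep(n_events, nrow(pairs)))
  list(obs = obs, truth = list(d_phys = d_phys, delta = delta))
}

#' Shot-noise-limited SNR bound for wave imaging
#'
#' Upper bound on the SNR for detecting a traveling wave of fluorescence
#' amplitude `dFF`, averaging photoelectrons over half a spatial wavelength:
#' `SNR <= dFF * (M * lambda_gamma / (2 * l_px)) * sqrt(n_f * W_C)`, together
#' with the maximum usable photoelectron count
#' `n_max = (M * lambda_gamma / (2 * l_px))^2 * n_f * W_C`.
#'
#' @param dFF wave fluorescence amplitude, dF/F.
#' @param M optical magnification.
#' @param lambda_gamma spatial wavelength of the wave, mm.
#' @param n_f frames averaged.
#' @param W_C pixel well capacity, electrons.
#' @param l_px pixel pitch, mm.
#' @return list with `snr` and `n_max`.
#' @export
snr_bound <- function(dFF, M, lambda_gamma, n_f, W_C, l_px) {
  if (any(c(M, lambda_gamma, n_f, W_C, l_px) <= 0) || dFF < 0) {
    stop("all design parameters must be positive (dFF >= 0)")
  }
  npix <- M * lambda_gamma / (2 * l_px)
  list(snr = dFF * npix * sqrt(n_f * W_C), n_max = npix^2 * n_f * W_C)
}
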