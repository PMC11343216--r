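## Traveling-wave velocimetry by two routes: (A) seed-pixel normalized
## cross-correlation delay maps with plane fits of the delay field, and
## (B) space-time projections with robust regression of per-position peak
## times on position, yielding a slowness (wavenumber) vector in s/mm with
## speed = 1/|alpha| and direction = atan2(alpha_y, alpha_x).
##
## Coordinate convention: x runs along image columns, y along rows, both in
## mm from the first pixel.

parabolic_refine <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(0)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom == 0) return(0)
  d <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  max(-0.5, min(0.5, d))
}

#' Seed-pixel delay map
#'
#' Normalized cross-correlation of the seed-pixel trace with every pixel's
#' trace, over lags within `+-max_lag`; stores the peak correlation and the
#' sub-sample-refined lag of the peak (positive = pixel lags the seed). Delays
#' are defined only where the peak correlation reaches `x_min`.
#'
#' @param movie T x H x W numeric array (unmixed voltage movie).
#' @param fs frame rate, Hz.
#' @param seed length-2 integer `(row, col)` of the seed pixel.
#' @param window optional frame-index range `c(first, last)` restricting the
#'   analysis window.
#' @param x_min correlation threshold in `[0, 1]` (default 0.75; 0.6-0.9
#'   balances spatial range against waveform SNR).
#' @param max_lag maximum lag, s.
#' @return object of class `delay_map` with `peak_corr`, `delay` (s, `NA`
#'   below threshold), `seed`, `x_min`.
#' @export
delay_map <- function(movie, fs, seed, window = NULL, x_min = 0.75,
                      max_lag = 0.25) {
  d <- dim(movie)
  if (seed[1] < 1 || seed[1] > d[2] || seed[2] < 1 || seed[2] > d[3]) {
    stop("seed outside the field of view")
  }
  frames <- if (is.null(window)) seq_len(d[1]) else window[1]:window[2]
  s <- movie[frames, seed[1], seed[2]]
  s <- s - mean(s)
  if (stats::sd(s) == 0) stop("zero-variance seed trace")
  ml <- max(1L, min(length(frames) - 1L, as.integer(round(max_lag * fs))))
  peak_corr <- matrix(NA_real_, d[2], d[3])
  delay <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      p <- movie[frames, i, j]
      p <- p - mean(p)
      if (stats::sd(p) == 0) { peak_corr[i, j] <- 0; next }
      cc <- xcorr_norm_cpp(s, p, ml)
      im <- which.max(cc)
      peak_corr[i, j] <- cc[im]
      delay[i, j] <- (im - ml - 1 + parabolic_refine(cc, im)) / fs
    }
  }
  delay[peak_corr < x_min] <- NA_real_
  structure(list(peak_corr = peak_corr, delay = delay, seed = seed,
                 x_min = x_min, fs = fs),
            class = "delay_map")
}

#' Plane fit of a delay map and the implied wavefront velocity
#'
#' Least-squares fit of the masked delays to `tau(x, y) = A x + B y + C`
#' (x, y in mm). Two velocity conventions are reported: `reciprocal`
#' `v = (1/A, 1/B)` (the component-wise formula common in optical-mapping
#' reports) and `gradient` `v = (A, B) / (A^2 + B^2)` (plane-wave
#' kinematics; the default elsewhere in the package). The two disagree for
#' off-axis propagation.
#'
#' @param dmap a [delay_map()].
#' @param pixel_pitch mm per pixel.
#' @param region optional logical matrix restricting the fit.
#' @return object of class `plane_fit` with `A`, `B`, `C` (s/mm, s/mm, s),
#'   `r_squared`, `velocity_gradient`, `velocity_reciprocal` (mm/s vectors),
#'   `speed_gradient`, `speed_reciprocal`, `direction` (degrees),
#'   `n_pixels`.
#' @export
plane_fit_velocity <- function(dmap, pixel_pitch, region = NULL) {
  mask <- !is.na(dmap$delay)
  if (!is.null(region)) mask <- mask & region
  if (sum(mask) < 10) stop("fewer than 10 masked pixels for the plane fit")
  ij <- which(mask, arr.ind = TRUE)
  x <- (ij[, 2] - 1) * pixel_pitch
  y <- (ij[, 1] - 1) * pixel_pitch
  tau <- dmap$delay[mask]
  fit <- stats::lm(tau ~ x + y)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient plane-fit design")
  co <- stats::coef(fit)
  a <- unname(co["x"]); b <- unname(co["y"]); cc <- unname(co["(Intercept)"])
  g2 <- a^2 + b^2
  vg <- if (g2 > 0) c(a, b) / g2 else c(NA_real_, NA_real_)
  vp <- c(if (a != 0) 1 / a else NA_real_, if (b != 0) 1 / b else NA_real_)
  r2 <- if (stats::var(tau) > 0) {
    1 - sum(stats::resid(fit)^2) / sum((tau - mean(tau))^2)
  } else 0
  structure(list(A = a, B = b, C = cc, r_squared = r2,
                 velocity_gradient = vg, velocity_reciprocal = vp,
                 speed_gradient = sqrt(sum(vg^2)),
                 speed_reciprocal = sqrt(sum(vp^2, na.rm = TRUE)),
                 direction = atan2(b, a) * 180 / pi,
                 n_pixels = sum(mask)),
            class = "plane_fit")
}

#' Tiled flow map of local wavefront velocities
#'
#' Partitions the field into square tiles, computes a local delay map per
#' tile (seed at the tile center) and a plane fit, and returns the per-tile
#' velocity field (unit-normalized vectors for display) plus raw speed and
#' direction samples. Tiles whose fit fails or is poor are dropped and
#' counted.
#'
#' @param movie T x H x W array.
#' @param fs frame rate, Hz.
#' @param pixel_pitch mm/pixel.
#' @param event_window optional frame-index range.
#' @param tile_size tile side, pixels.
#' @param x_min correlation threshold.
#' @param max_lag maximum lag, s.
#' @param min_r2 minimum plane-fit r-squared for acceptance.
#' @export
flow_map <- function(movie, fs, pixel_pitch, event_window = NULL,
                     tile_size = 8, x_min = 0.75, max_lag = 0.25,
                     min_r2 = 0.5) {
  d <- dim(movie)
  rows <- tile_index(d[2], tile_size)
  cols <- tile_index(d[3], tile_size)
  out <- list()
  n_dropped <- 0L
  for (rt in rows) {
    for (ct in cols) {
      sub <- movie[, rt, ct, drop = FALSE]
      dim(sub) <- c(d[1], length(rt), length(ct))
      res <- try({
        dm <- delay_map(sub, fs,
                        seed = c(ceiling(length(rt) / 2),
                                 ceiling(length(ct) / 2)),
                        window = event_window, x_min = x_min,
                        max_lag = max_lag)
        pf <- plane_fit_velocity(dm, pixel_pitch)
        if (pf$r_squared < min_r2 || !is.finite(pf$speed_gradient) ||
            pf$speed_gradient == 0) stop("poor fit")
        pf
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        n_dropped <- n_dropped + 1L
        next
      }
      out[[length(out) + 1]] <- data.frame(
        row = rt[1], col = ct[1],
        y_mm = (rt[1] + length(rt) / 2 - 1.5) * pixel_pitch,
        x_mm = (ct[1] + length(ct) / 2 - 1.5) * pixel_pitch,
        speed = res$speed_gradient, direction = res$direction,
        ux = cos(res$direction * pi / 180),
        uy = sin(res$direction * pi / 180),
        r_squared = res$r_squared)
    }
  }
  tiles <- if (length(out)) do.call(rbind, out) else
    data.frame(row = integer(0), col = integer(0), y_mm = numeric(0),
               x_mm = numeric(0), speed = numeric(0), direction = numeric(0),
               ux = numeric(0), uy = numeric(0), r_squared = numeric(0))
  list(tiles = tiles, n_dropped = n_dropped,
       speeds = tiles$speed, directions = tiles$direction)
}

#' Project a movie onto its row and column axes
#'
#' Averages over the orthogonal spatial axis, yielding a pair of
#' position-by-time one-dimensional movies with physical coordinates in mm.
#'
#' @param movie T x H x W array.
#' @param pixel_pitch mm/pixel.
#' @param event_window optional frame-index range `c(first, last)`.
#' @return list with `row_axis` (`times` x `pos` matrix along y) and
#'   `col_axis` (along x), each with a `pos_mm` attribute.
#' @export
spacetime_project <- function(movie, pixel_pitch, event_window = NULL) {
  d <- dim(movie)
  frames <- if (is.null(event_window)) seq_len(d[1]) else
    event_window[1]:event_window[2]
  sub <- movie[frames, , , drop = FALSE]
  row_axis <- apply(sub, c(1, 2), mean)   # average over columns -> y profile
  col_axis <- apply(sub, c(1, 3), mean)   # average over rows -> x profile
  attr(row_axis, "pos_mm") <- (seq_len(d[2]) - 1) * pixel_pitch
  attr(col_axis, "pos_mm") <- (seq_len(d[3]) - 1) * pixel_pitch
  list(row_axis = row_axis, col_axis = col_axis, frames = frames)
}

robust_slope <- function(pos, tpeak) {
  if (length(unique(tpeak)) == 1 || stats::var(tpeak) == 0) {
    return(list(slope = 0, se = NA_real_, p = 1))
  }
  fit <- try(suppressWarnings(
    MASS::rlm(tpeak ~ pos, psi = MASS::psi.bisquare, maxit = 100)),
    silent = TRUE)
  if (inherits(fit, "try-error")) fit <- stats::lm(tpeak ~ pos)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)["pos"])
  se <- tryCatch(sm$coefficients["pos", "Std. Error"],
                 error = function(e) NA_real_)
  df <- length(pos) - 2
  p <- if (is.finite(se) && se > 0) 2 * stats::pt(-abs(slope / se), df) else
    if (abs(slope) > 0) 0 else 1
  list(slope = slope, se = se, p = p)
}

#' Fit a slowness vector from space-time projections
#'
#' For each axis, takes the time at which each position attains its maximum
#' (first maximum on plateaus) and robust-regresses peak time on position
#' (iteratively reweighted least squares with bisquare weights), giving the
#' slowness components `alpha_x`, `alpha_y` in s/mm. Speed is
#' `1 / |alpha|` (mm/s) and direction `atan2(alpha_y, alpha_x)` in degrees.
#' Acceptance requires the slowness magnitude to be significantly nonzero:
#' by default a joint chi-square test on both components (`p < 0.01`); the
#' strict mode instead requires each component individually `p < 0.01`,
#' which rejects axis-aligned waves. `smooth_s` applies a centered
#' (zero-phase) moving average to each projection trace before crest
#' picking; ~1/4 of the wave period markedly improves peak-time precision on
#' noisy movies without biasing the crest location.
#'
#' @param projections output of [spacetime_project()].
#' @param fs frame rate, Hz.
#' @param strict require both components individually significant.
#' @param p_threshold significance level for acceptance.
#' @return object of class `slowness_fit`.
#' @export
fit_slowness <- function(projections, fs, strict = FALSE, p_threshold = 0.01,
                         smooth_s = 0, refine_s = 0) {
  w <- max(1L, as.integer(round(smooth_s * fs)))
  hw <- as.integer(round(refine_s * fs))
  axis_fit <- function(mat) {
    pos <- attr(mat, "pos_mm")
    if (length(pos) < 8) stop("each projection needs >= 8 positions")
    tpeak <- vapply(seq_along(pos), function(p) {
      tr <- if (w > 1) moving_avg_cpp(mat[, p], w) else mat[, p]
      im <- which.max(tr)                # first maximum on plateaus
      if (hw > 1) {
        ## least-squares quadratic vertex over the crest neighborhood
        lo <- max(1L, im - hw); hi <- min(length(tr), im + hw)
        idx <- lo:hi
        cf <- stats::coef(stats::lm(tr[idx] ~ idx + I(idx^2)))
        v <- if (any(is.na(cf)) || cf[3] >= 0) im else -cf[2] / (2 * cf[3])
        (max(lo, min(hi, v)) - 1) / fs
      } else {
        (im - 1 + parabolic_refine(tr, im)) / fs
      }
    }, 0)
    robust_slope(pos, tpeak)
  }
  fx <- axis_fit(projections$col_axis)   # along x (columns)
  fy <- axis_fit(projections$row_axis)   # along y (rows)
  alpha <- c(fx$slope, fy$slope)
  a2 <- sum(alpha^2)
  speed <- if (a2 > 0) 1 / sqrt(a2) else Inf
  direction <- atan2(alpha[2], alpha[1]) * 180 / pi
  p_joint <- if (all(is.finite(c(fx$se, fy$se))) && fx$se > 0 && fy$se > 0) {
    stats::pchisq((fx$slope / fx$se)^2 + (fy$slope / fy$se)^2, df = 2,
                  lower.tail = FALSE)
  } else if (a2 > 0) 0 else 1
  accepted <- if (strict) {
    fx$p < p_threshold && fy$p < p_threshold
  } else {
    p_joint < p_threshold
  }
  structure(list(alpha_x = fx$slope, alpha_y = fy$slope,
                 se_x = fx$se, se_y = fy$se, p_x = fx$p, p_y = fy$p,
                 p_joint = p_joint, speed = speed, direction = direction,
                 accepted = accepted && is.finite(speed),
                 n_pixels = length(attr(projections$col_axis, "pos_mm")) +
                   length(attr(projections$row_axis, "pos_mm"))),
            class = "slowness_fit")
}

#' @export
print.slowness_fit <- function(x, ...) {
  cat(sprintf(
    "<slowness_fit> alpha = (%.4g, %.4g) s/mm, speed %.3g mm/s, dir %.1f deg%s\n",
    x$alpha_x, x$alpha_y, x$speed, x$direction,
    if (x$accepted) "" else " (rejected)"))
  invisible(x)
}

#' Speed and direction distributions over accepted wave events
#'
#' @param events data.frame with `speed` and `direction` columns (or a list
#'   of `slowness_fit`/`plane_fit` objects).
#' @param speed_breaks,direction_bin_deg histogram binning.
#' @param n_boot bootstrap resamples for the s.e.m. of the medians.
#' @param seed bootstrap seed.
#' @param groups optional factor splitting events into two direction modes
#'   for a rank-sum speed comparison.
#' @export
velocity_distributions <- function(events, speed_breaks = 20,
                                   direction_bin_deg = 30, n_boot = 200,
                                   seed = 1, groups = NULL) {
  if (is.list(events) && !is.data.frame(events)) {
    events <- data.frame(
      speed = vapply(events, function(e) e$speed, 0),
      direction = vapply(events, function(e) e$direction, 0))
  }
  if (!nrow(events)) stop("no accepted events")
  sp <- events$speed[is.finite(events$speed)]
  dr <- events$direction %% 360
  set.seed(seed)
  boot_med <- function(v) {
    if (length(v) < 2 || stats::var(v) == 0) return(0)
    stats::sd(vapply(seq_len(n_boot), function(b) {
      stats::median(sample(v, replace = TRUE))
    }, 0))
  }
  dir_breaks <- seq(0, 360, by = direction_bin_deg)
  dir_hist <- graphics::hist(dr, breaks = dir_breaks, plot = FALSE)
  ## circular mode detection on the tiled histogram
  cnt <- dir_hist$counts
  tiled <- c(cnt, cnt, cnt)
  pk <- find_peaks(c(0, tiled, 0))
  centers_tiled <- c(dir_hist$mids - 360, dir_hist$mids, dir_hist$mids + 360)
  in_mid <- pk$index - 1 > length(cnt) & pk$index - 1 <= 2 * length(cnt)
  modes <- centers_tiled[pk$index[in_mid] - 1]
  modes <- (modes[order(-pk$height[in_mid])]) %% 360
  ranksum <- NULL
  if (!is.null(groups) && nlevels(factor(groups)) == 2) {
    g <- factor(groups)
    ranksum <- stats::wilcox.test(events$speed[g == levels(g)[1]],
                                  events$speed[g == levels(g)[2]],
                                  exact = FALSE)$p.value
  }
  list(speed_hist = graphics::hist(sp, breaks = speed_breaks, plot = FALSE),
       direction_hist = dir_hist,
       median_speed = stats::median(sp), sem_speed = boot_med(sp),
       median_direction = stats::median(dr), direction_modes = modes,
       ranksum_p = ranksum, n_events = nrow(events))
}
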