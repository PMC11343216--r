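## Decomposition of apparent inter-channel oscillation delays into
## indicator-kinetics delays (one nonnegative delay per (indicator, class)
## pair) plus a single physiological delay, by penalized weighted least
## squares, with a resampling distribution.
##
## Model: for an experiment pairing indicator i1 on cell class 1 (green
## channel) with indicator i2 on class 2, the apparent delay is
##   d_apparent = d_phys + delta(i1, class1) - delta(i2, class2).
## The physiological delay is identified because the penalty (plus the
## nonnegativity constraint) pins the per-class delta sets at their minimal
## representatives.

#' Per-event apparent delay between two band-limited traces
#'
#' Band-passes both traces (default 3-7 Hz), cross-correlates them per event
#' window, and returns the sub-sample-refined lag of the correlation maximum
#' in ms. Positive delay means `y` lags `x`. Events with a flat correlation
#' are dropped; events whose correlation has a near-tied secondary peak
#' (half-period aliasing of narrow-band signals) are flagged `ambiguous`.
#'
#' @param x,y numeric traces of equal length.
#' @param fs sampling rate, Hz.
#' @param band regression band, Hz.
#' @param events optional data.frame/list of `start`,`end` times (s); the
#'   whole trace is one event when `NULL`.
#' @param max_lag maximum lag searched, s.
#' @return data.frame with `delay_ms`, `peak_corr`, `ambiguous`.
#' @export
apparent_delay <- function(x, y, fs, band = c(3, 7), events = NULL,
                           max_lag = 0.1) {
  xb <- bandpass(x, fs, band[1], band[2], order = 3)
  yb <- bandpass(y, fs, band[1], band[2], order = 3)
  if (is.null(events)) events <- data.frame(start = 0,
                                            end = (length(x) - 1) / fs)
  ml <- as.integer(round(max_lag * fs))
  out <- list()
  for (e in seq_len(nrow(events))) {
    idx <- (round(events$start[e] * fs):round(events$end[e] * fs)) + 1L
    idx <- idx[idx >= 1 & idx <= length(x)]
    xs <- xb[idx]; ys <- yb[idx]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    cc <- xcorr_norm_cpp(xs - mean(xs), ys - mean(ys), min(ml, length(idx) - 1))
    im <- which.max(cc)
    if (max(cc) - min(cc) < 1e-12) next
    lag <- (im - (length(cc) + 1) / 2 + parabolic_refine(cc, im)) / fs
    ## ambiguity: another local maximum within 1% of the global one
    lm <- local_maxima(cc)
    amb <- any(abs(cc[lm] - cc[im]) < 0.01 * abs(cc[im]) & lm != im)
    out[[length(out) + 1]] <- data.frame(delay_ms = lag * 1000,
                                         peak_corr = cc[im], ambiguous = amb)
  }
  if (!length(out)) return(data.frame(delay_ms = numeric(0),
                                      peak_corr = numeric(0),
                                      ambiguous = logical(0)))
  do.call(rbind, out)
}

#' Build a table of delay observations
#'
#' @param experiment_id identifiers.
#' @param indicator_on_class1,indicator_on_class2 indicator labels (class 1 is
#'   the green-channel cell class by convention).
#' @param mean_delay,sd_delay per-experiment delay mean and s.d., ms
#'   (`sd_delay > 0`).
#' @param n_events events per experiment.
#' @export
delay_observations <- function(experiment_id, indicator_on_class1,
                               indicator_on_class2, mean_delay, sd_delay,
                               n_events) {
  if (any(sd_delay <= 0)) stop("sd_delay must be > 0")
  if (any(n_events < 1)) stop("n_events must be >= 1")
  data.frame(experiment_id = experiment_id,
             indicator_on_class1 = indicator_on_class1,
             indicator_on_class2 = indicator_on_class2,
             mean_delay = mean_delay, sd_delay = sd_delay,
             n_events = n_events)
}

delay_design <- function(obs) {
  ## one column per (indicator, class) pair that actually occurs
  pnames <- sort(unique(c(paste0(obs$indicator_on_class1, ".class1"),
                          paste0(obs$indicator_on_class2, ".class2"))))
  X <- matrix(0, nrow(obs), length(pnames), dimnames = list(NULL, pnames))
  for (e in seq_len(nrow(obs))) {
    X[e, paste0(obs$indicator_on_class1[e], ".class1")] <- 1
    X[e, paste0(obs$indicator_on_class2[e], ".class2")] <- -1
  }
  X
}

#' Fit the indicator-delay decomposition model
#'
#' Minimizes the weighted sum of squared residuals between measured and
#' predicted mean delays, `sum_e w_e (dbar_e - (d + delta_i1c1 -
#' delta_i2c2))^2 + lambda P(delta)`, with weights `w_e = 1 / sd_e^2`,
#' `delta >= 0` (hard constraint), and `P` either the Euclidean norm of the
#' delta vector (default, as described for the original fit) or its L1 norm.
#'
#' @param obs a [delay_observations()] table.
#' @param lambda penalty weight (default 0.01).
#' @param penalty `"euclidean"` or `"l1"`.
#' @param fixed_delta optional named numeric, deltas fixed at given values.
#' @return object of class `delay_model` with `physiological_delay` (ms),
#'   `indicator_delays` (named, ms), `lambda`, `penalty`, `objective`.
#' @export
fit_delay_model <- function(obs, lambda = 0.01,
                            penalty = c("euclidean", "l1"),
                            fixed_delta = NULL) {
  penalty <- match.arg(penalty)
  X <- delay_design(obs)
  free <- setdiff(colnames(X), names(fixed_delta))
  wts <- 1 / obs$sd_delay^2
  offset <- if (is.null(fixed_delta)) rep(0, nrow(obs)) else
    as.numeric(X[, names(fixed_delta), drop = FALSE] %*% fixed_delta)
  if (lambda == 0) {
    A <- cbind(d = 1, X[, free, drop = FALSE])
    Asq <- rbind(sqrt(wts) * A,
                 matrix(0, max(0, ncol(A) - nrow(A)), ncol(A)))
    sv <- svd(Asq)
    if (min(sv$d) < 1e-10 * max(sv$d)) {
      null_dir <- sv$v[, which.min(sv$d)]
      stop(sprintf(
        "design unidentifiable with lambda = 0; null-space direction: %s",
        paste(sprintf("%s=%.2f", c("d", free), null_dir), collapse = ", ")))
    }
  }
  nfree <- length(free)
  pen_fun <- switch(penalty,
                    euclidean = function(d) sqrt(sum(d^2) + 1e-30),
                    l1 = function(d) sum(d))
  obj <- function(par) {
    d <- par[1]
    delta <- par[-1]
    pred <- d + offset
    if (nfree > 0) pred <- pred + as.numeric(X[, free, drop = FALSE] %*% delta)
    sum(wts * (obs$mean_delay - pred)^2) + lambda * pen_fun(delta)
  }
  best <- NULL
  for (start in list(c(0, rep(0.1, nfree)),
                     c(mean(obs$mean_delay), rep(1, nfree)),
                     c(stats::median(obs$mean_delay), rep(0.01, nfree)))) {
    res <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = c(-Inf, rep(0, nfree)),
                        control = list(maxit = 2000, factr = 10))
    if (is.null(best) || res$value < best$value) best <- res
  }
  delta <- best$par[-1]
  names(delta) <- free
  if (!is.null(fixed_delta)) delta <- c(delta, fixed_delta)
  structure(list(physiological_delay = best$par[1],
                 indicator_delays = delta[order(names(delta))],
                 lambda = lambda, penalty = penalty,
                 objective = best$value, obs = obs),
            class = "delay_model")
}

#' @export
print.delay_model <- function(x, ...) {
  cat(sprintf("<delay_model> physiological delay %.3f ms (lambda = %g, %s)\n",
              x$physiological_delay, x$lambda, x$penalty))
  print(round(x$indicator_delays, 3))
  invisible(x)
}

#' Resampling distribution of the delay-model parameters
#'
#' Each resample draws every experiment's mean delay from
#' `Normal(mean, sd / sqrt(n_events))` (the sampling distribution of the
#' mean), refits, and aggregates per-parameter mean and s.d. Deterministic
#' under a fixed seed.
#'
#' @inheritParams fit_delay_model
#' @param n_resamples number of resamples (default 100).
#' @param seed RNG seed.
#' @param sd_of_mean if `FALSE`, draw with the printed sd instead of the
#'   s.e.m.
#' @export
resample_delay_model <- function(obs, n_resamples = 100, seed = 1,
                                 lambda = 0.01,
                                 penalty = c("euclidean", "l1"),
                                 fixed_delta = NULL, sd_of_mean = TRUE) {
  penalty <- match.arg(penalty)
  set.seed(seed)
  draws <- matrix(NA_real_, n_resamples, 0)
  fits <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    ob <- obs
    s <- if (sd_of_mean) obs$sd_delay / sqrt(obs$n_events) else obs$sd_delay
    ob$mean_delay <- stats::rnorm(nrow(obs), obs$mean_delay, s)
    fits[[b]] <- fit_delay_model(ob, lambda, penalty, fixed_delta)
  }
  d <- vapply(fits, function(f) f$physiological_delay, 0)
  deltas <- t(vapply(fits, function(f) f$indicator_delays,
                     fits[[1]]$indicator_delays))
  list(physiological_delay = c(mean = mean(d), sd = stats::sd(d)),
       indicator_delays = data.frame(mean = colMeans(deltas),
                                     sd = apply(deltas, 2, stats::sd)),
       draws = d)
}
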