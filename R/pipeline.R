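## Pipeline orchestration: an ordered list of stages with parameter blocks,
## executed on a shared state bundle, with a provenance manifest (config
## hash, package version, seed). Configs are YAML (or plain R lists).

default_params <- function() {
  list(tau = 1.0, overlap = 0.75, alpha = 1.1, heartbeat_band = c(8, 14),
       ripple_band = c(120, 200),
       ripple_criteria = list(min_prominence = 0.1, min_distance = 0.010,
                              min_width = 0.010, max_width = 0.200),
       x_min = 0.75, lambda = 0.01, svd_rank = 5, svd_segment = 2500,
       detrend_cutoff = 0.5)
}

#' Build / validate a pipeline configuration
#'
#' @param stages list of `list(name = <stage>, params = <list>)`; supported
#'   stages: `synth_trace`, `synth_movie`, `notch`, `detrend`, `unmix`,
#'   `unmix_movie`, `denoise`, `ripples`, `coherence`, `waves`.
#' @param seed global seed.
#' @param log_level `"info"` or `"quiet"`.
#' @export
pipeline_config <- function(stages = list(), seed = 1, log_level = "info") {
  known <- c("synth_trace", "synth_movie", "notch", "detrend", "unmix",
             "unmix_movie", "denoise", "ripples", "coherence", "waves")
  names_seen <- character(0)
  for (s in stages) {
    if (is.null(s$name) || !s$name %in% known) {
      stop("unknown stage: ", if (is.null(s$name)) "<missing>" else s$name)
    }
    if (s$name == "unmix" && !"detrend" %in% names_seen &&
        !"synth_trace" %in% names_seen) {
      stop("unmix requires detrended (or synthetic) input earlier in the chain")
    }
    if (s$name == "denoise" && !any(c("unmix", "unmix_movie", "synth_movie")
                                    %in% names_seen)) {
      stop("denoise requires an unmixed movie earlier in the chain")
    }
    names_seen <- c(names_seen, s$name)
  }
  structure(list(stages = stages, seed = seed, log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with keys `seed` and `stages`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(stages = y$stages,
                  seed = if (is.null(y$seed)) 1 else y$seed,
                  log_level = if (is.null(y$log_level)) "info" else
                    y$log_level)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a processing pipeline
#'
#' Executes the configured stages in order on a shared state bundle; no stage
#' mutates its inputs. Returns the final state plus a provenance manifest
#' (config hash, package version, seed, per-stage log). Rerunning an
#' identical config reproduces the manifest hash and all deterministic
#' outputs.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  state <- list()
  log <- character(0)
  say <- function(msg) {
    if (identical(config$log_level, "info")) message("[tempo] ", msg)
    log <<- c(log, msg)
  }
  dp <- default_params()
  for (s in config$stages) {
    p <- utils::modifyList(dp, if (is.null(s$params)) list() else s$params)
    say(sprintf("stage %s", s$name))
    state <- switch(s$name,
      synth_trace = {
        sp <- trace_synth_spec(seed = config$seed)
        if (!is.null(s$params)) sp[names(s$params)] <- s$params
        out <- gen_trace_pair(sp)
        c(state, list(trace = out$trace, truth = out$truth))
      },
      synth_movie = {
        sp <- movie_synth_spec(seed = config$seed)
        if (!is.null(s$params)) sp[names(s$params)] <- s$params
        out <- gen_movie_pair(sp)
        c(state, list(movie = out$movie, voltage_movie = out$voltage,
                      movie_truth = out$truth))
      },
      notch = {
        tr <- state$trace
        for (ctr in p$centers) {
          tr$gevi <- notch_filter(tr$gevi, tr$fs, ctr)
          tr$reference <- notch_filter(tr$reference, tr$fs, ctr)
        }
        state$trace <- tr
        state
      },
      detrend = {
        tr <- state$trace
        bg <- estimate_baseline(tr$gevi, tr$fs, "lowpass",
                                cutoff = p$detrend_cutoff)
        br <- estimate_baseline(tr$reference, tr$fs, "lowpass",
                                cutoff = p$detrend_cutoff)
        tr$gevi <- detrend(tr$gevi, bg)
        tr$reference <- detrend(tr$reference, br)
        state$trace <- tr
        state
      },
      unmix = {
        tr <- state$trace
        wp <- wiener_params(tau = p$tau, overlap = p$overlap,
                            alpha = p$alpha,
                            heartbeat_band = p$heartbeat_band)
        state$unmix <- unmix_trace(tr$gevi - mean(tr$gevi),
                                   tr$reference - mean(tr$reference),
                                   tr$fs, wp)
        state
      },
      unmix_movie = {
        wp <- wiener_params(tau = p$tau, overlap = p$overlap,
                            alpha = p$alpha,
                            heartbeat_band = p$heartbeat_band)
        state$unmixed_movie <- unmix_movie(state$movie, wp)$voltage
        state
      },
      denoise = {
        mv <- if (!is.null(state$unmixed_movie)) state$unmixed_movie else
          state$voltage_movie
        state$denoised_movie <- denoise_movie(mv, k = p$svd_rank,
                                              segment_len = p$svd_segment)
        state
      },
      ripples = {
        v <- if (!is.null(state$unmix)) state$unmix$voltage else
          state$trace$gevi
        state$ripples <- detect_ripples(v, state$trace$fs,
                                        band = p$ripple_band)
        state
      },
      coherence = {
        v <- if (!is.null(state$unmix)) state$unmix$voltage else
          state$trace$gevi
        state$coherence <- coherence(v, state$trace$reference,
                                     state$trace$fs)
        state
      },
      waves = {
        mv <- if (!is.null(state$denoised_movie)) state$denoised_movie else
          if (!is.null(state$unmixed_movie)) state$unmixed_movie else
            state$voltage_movie
        pr <- spacetime_project(mv, state$movie$pixel_pitch)
        state$slowness <- fit_slowness(pr, state$movie$fs)
        state
      })
  }
  manifest <- list(config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("tempotools")),
                   seed = config$seed,
                   stages = vapply(config$stages, function(s) s$name, ""),
                   log = log)
  list(state = state, manifest = manifest)
}
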