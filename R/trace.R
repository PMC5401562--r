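#' Render a current trace from an occupancy path
#'
#' Converts a simulated [simulate_state_path()] occupancy path into a sampled
#' current trace under given acquisition settings and ionic conditions. The
#' per-sample current at occupancy level m is
#' `I_m = level_conductances[m] * (V - E_rev) / 1000` (pA from pS and mV),
#' with the reversal potential E_rev taken from [ghk_reversal()]. The
#' piecewise-constant level current is smoothed by a Gaussian low-pass filter
#' with -3 dB point at `filter_cutoff` (disabled when `NA`), then Gaussian
#' baseline noise of standard deviation `noise_sd` is added, so `noise_sd`
#' is the baseline noise of the recorded trace as seen in an all-points
#' histogram.
#'
#' @param path a `"state_path"` whose total duration is at least
#'   `config$duration`.
#' @param config a [recording_config()].
#' @param conditions an [ion_conditions()] object.
#' @param model the [gating_model()] that generated the path (source of the
#'   level conductances).
#' @return An object of class `"channel_trace"`: list with `current` (pA),
#'   `dt` (s), and acquisition metadata.
#' @export
render_trace <- function(path, config, conditions, model) {
  stopifnot(inherits(path, "state_path"),
            inherits(config, "recording_config"),
            inherits(conditions, "ion_conditions"),
            inherits(model, "gating_model"))
  if (path$total_duration < config$duration - 1e-12)
    stop("path total_duration is shorter than the requested recording duration")
  n <- round(config$duration * config$sampling_rate)
  dt <- 1 / config$sampling_rate
  tt <- (seq_len(n) - 1L) * dt
  breaks <- c(0, cumsum(path$dwells))
  seg <- findInterval(tt, breaks)
  seg[seg > length(path$levels)] <- length(path$levels)
  e_rev <- ghk_reversal(conditions)
  v <- config$holding_potential
  level_current <- model$level_conductances * (v - e_rev) / 1000
  x <- level_current[path$levels[seg] + 1L]
  if (!is.na(config$filter_cutoff))
    x <- gaussian_lowpass(x, config$sampling_rate, config$filter_cutoff)
  if (config$noise_sd > 0) {
    if (!is.null(config$seed)) set.seed(as.integer(config$seed))
    x <- x + stats::rnorm(n, 0, config$noise_sd)
  }
  new_channel_trace(x, dt = dt, sampling_rate = config$sampling_rate,
                    filter_cutoff = config$filter_cutoff,
                    holding_potential = v, noise_sd = config$noise_sd,
                    seed = config$seed, conditions = conditions)
}

new_channel_trace <- function(current, dt, sampling_rate,
                              filter_cutoff = NA, holding_potential = NA,
                              noise_sd = NA, seed = NULL,
                              conditions = NULL) {
  if (!all(is.finite(current))) stop("trace samples must be finite")
  structure(list(current = as.numeric(current), dt = dt,
                 sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff,
                 holding_potential = holding_potential,
                 noise_sd = noise_sd, seed = seed,
                 conditions = conditions),
            class = "channel_trace")
}

#' Construct a current trace from raw samples
#'
#' @param current numeric vector of current samples, pA.
#' @param sampling_rate Hz.
#' @param holding_potential mV.
#' @param filter_cutoff Hz (`NA` if unknown/unfiltered).
#' @return A `"channel_trace"`.
#' @export
channel_trace <- function(current, sampling_rate,
                          holding_potential = NA, filter_cutoff = NA) {
  new_channel_trace(current, dt = 1 / sampling_rate,
                    sampling_rate = sampling_rate,
                    filter_cutoff = filter_cutoff,
                    holding_potential = holding_potential)
}

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf(
    "Current trace: %d samples at %g kHz (%.4g s), V = %s mV, filter = %s Hz\n",
    length(x$current), x$sampling_rate / 1000,
    length(x$current) * x$dt,
    format(x$holding_potential), format(x$filter_cutoff)))
  invisible(x)
}

# Gaussian low-pass filter with -3 dB (half-power) point at fc.
# sigma_t = 0.1325 / fc is the standard relation for a Gaussian kernel.
# Edges are handled by replicate padding so the output has the input length.
gaussian_lowpass <- function(x, sampling_rate, fc) {
  sigma <- 0.1325 / fc * sampling_rate # in samples
  if (sigma < 0.2) return(x)           # cutoff ~ Nyquist: nothing to do
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, kern, sides = 2)
  as.numeric(y[(half + 1):(half + length(x))])
}

#' Simulate a complete single-channel recording
#'
#' Convenience wrapper running [simulate_state_path()] and [render_trace()]
#' from a single seed (one RNG stream drives both the jump chain and the
#' noise).
#'
#' @inheritParams render_trace
#' @param seed optional integer seed.
#' @return List with elements `path` (the `"state_path"`) and `trace`
#'   (the `"channel_trace"`).
#' @export
simulate_recording <- function(model, config, conditions, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- config
  cfg$seed <- NULL # keep the single stream
  path <- simulate_state_path(model, duration = config$duration, seed = NULL)
  trace <- render_trace(path, cfg, conditions, model)
  list(path = path, trace = trace)
}

#' Write / read a trace as tab-separated text
#'
#' Two columns (`time_s`, `current_pA`) preceded by `#`-prefixed metadata
#' lines (`sampling_rate_hz`, `filter_cutoff_hz`, `holding_potential_mV`,
#' `seed`).
#'
#' @param trace a `"channel_trace"`.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `"channel_trace"`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "channel_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sampling_rate_hz = trace$sampling_rate,
            filter_cutoff_hz = trace$filter_cutoff,
            holding_potential_mV = trace$holding_potential,
            seed = if (is.null(trace$seed)) NA else trace$seed)
  writeLines(sprintf("# %s: %s", names(meta), format(meta, trim = TRUE)),
             con)
  writeLines("time_s\tcurrent_pA", con)
  tt <- (seq_along(trace$current) - 1L) * trace$dt
  utils::write.table(data.frame(tt, trace$current), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- suppressWarnings(as.numeric(kv[2]))
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  sr <- meta[["sampling_rate_hz"]]
  if (is.null(sr) || is.na(sr)) {
    dtm <- diff(dat[[1]][1:2])
    sr <- 1 / dtm
  }
  new_channel_trace(dat[[2]], dt = 1 / sr, sampling_rate = sr,
                    filter_cutoff = meta[["filter_cutoff_hz"]] %||% NA,
                    holding_potential = meta[["holding_potential_mV"]] %||% NA,
                    seed = meta[["seed"]] %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
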