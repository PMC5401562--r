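#' Gating model for an N-mer of independent monomeric pores
#'
#' A homo-N-meric channel in which each monomer gates independently between a
#' closed and an open state (opening rate `k_open`, closing rate `k_close`,
#' both per second). The number of open monomers m then follows an aggregated
#' birth-death chain on 0..N with transition rates
#' `up(m) = (N - m) * k_open` and `down(m) = m * k_close`. Total conductance
#' at each occupancy level is a free parameter: measured multimeric levels are
#' typically sub-additive (e.g. 42.2, 100.6, 163.7 pS for one, two and three
#' open pores of a trimer), so levels are not forced to multiples of the
#' single-pore conductance.
#'
#' @param n_monomers number of monomeric pores (default 3, a trimer).
#' @param k_open per-monomer opening rate, 1/s.
#' @param k_close per-monomer closing rate, 1/s.
#' @param level_conductances numeric vector of length `n_monomers + 1`;
#'   entry m+1 is the total conductance (pS) with m monomers open. Must start
#'   at 0 and be non-decreasing.
#' @return An object of class `"gating_model"`.
#' @export
#' @examples
#' gating_model(k_open = 10, k_close = 10,
#'              level_conductances = c(0, 42.2, 100.6, 163.7))
gating_model <- function(n_monomers = 3L, k_open, k_close,
                         level_conductances) {
  n_monomers <- as.integer(n_monomers)
  if (n_monomers < 1L) stop("'n_monomers' must be >= 1")
  if (!is.numeric(k_open) || !is.numeric(k_close) ||
      k_open < 0 || k_close < 0)
    stop("rates 'k_open' and 'k_close' must be >= 0")
  if (k_open == 0 && k_close == 0)
    stop("at least one of 'k_open', 'k_close' must be > 0")
  if (length(level_conductances) != n_monomers + 1L)
    stop("'level_conductances' must have length n_monomers + 1")
  if (level_conductances[1] != 0)
    stop("level_conductances[1] (fully closed) must be 0")
  if (is.unsorted(level_conductances))
    stop("'level_conductances' must be non-decreasing")
  structure(list(n_monomers = n_monomers, k_open = k_open,
                 k_close = k_close,
                 level_conductances = as.numeric(level_conductances)),
            class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat(sprintf("Gating model: %d independent monomers, k_open = %g /s, k_close = %g /s\n",
              x$n_monomers, x$k_open, x$k_close))
  cat("Level conductances (pS):",
      paste(format(x$level_conductances), collapse = ", "), "\n")
  invisible(x)
}

#' Recording / acquisition configuration
#'
#' Acquisition settings emulating a patch-clamp amplifier: sampling rate,
#' low-pass filter cutoff, baseline noise and holding potential. Defaults
#' follow common single-channel practice (50 kHz sampling, 0.5 kHz filter).
#'
#' @param sampling_rate Hz; must exceed twice the filter cutoff.
#' @param filter_cutoff -3 dB cutoff of the Gaussian low-pass filter, Hz;
#'   `NA` disables filtering.
#' @param noise_sd baseline (post-filter) Gaussian noise standard deviation,
#'   pA.
#' @param duration recording length, s.
#' @param holding_potential mV (bath minus pipette).
#' @param seed optional integer seed for the noise generator.
#' @return An object of class `"recording_config"`.
#' @export
recording_config <- function(sampling_rate = 50000, filter_cutoff = 500,
                             noise_sd = 0.35, duration = 1,
                             holding_potential = 60, seed = NULL) {
  if (duration <= 0) stop("'duration' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.na(filter_cutoff) && sampling_rate <= 2 * filter_cutoff)
    stop("'sampling_rate' must exceed 2 * filter_cutoff")
  structure(list(sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff, noise_sd = noise_sd,
                 duration = duration,
                 holding_potential = holding_potential, seed = seed),
            class = "recording_config")
}

#' Simulate the occupancy path of an N-mer channel
#'
#' Exact stochastic (Gillespie) simulation of the aggregated birth-death
#' chain of a [gating_model()]: from level m the chain waits an exponential
#' time with rate `(N-m)*k_open + m*k_close`, then steps to m+1 with
#' probability `(N-m)*k_open / rate`, else to m-1. Waiting times are drawn by
#' inverse-CDF so a fixed seed reproduces the path exactly.
#'
#' @param model a [gating_model()].
#' @param duration total simulated time, s.
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @param start_level initial number of open monomers (default 0, all
#'   closed).
#' @return An object of class `"state_path"`: list with `levels` (integer
#'   occupancy per dwell), `dwells` (durations, s), `total_duration` and
#'   `n_monomers`. Consecutive levels differ by exactly 1 and dwells sum to
#'   `total_duration`.
#' @export
simulate_state_path <- function(model, duration, seed = NULL,
                                start_level = 0L) {
  stopifnot(inherits(model, "gating_model"))
  if (!is.numeric(duration) || duration <= 0)
    stop("'duration' must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- model$n_monomers
  ko <- model$k_open
  kc <- model$k_close
  start_level <- as.integer(start_level)
  if (start_level < 0L || start_level > n)
    stop("'start_level' must lie in [0, n_monomers]")

  cap <- 1024L
  lev <- integer(cap)
  dw <- numeric(cap)
  m <- start_level
  t <- 0
  i <- 0L
  block <- 8192L
  done <- FALSE
  while (!done) {
    u1 <- stats::runif(block)
    u2 <- stats::runif(block)
    for (j in seq_len(block)) {
      up <- (n - m) * ko
      down <- m * kc
      rate <- up + down
      tau <- if (rate > 0) -log(u1[j]) / rate else Inf # absorbing level
      i <- i + 1L
      if (i > cap) {
        cap <- cap * 2L
        length(lev) <- cap
        length(dw) <- cap
      }
      lev[i] <- m
      if (t + tau >= duration) { # truncate final dwell to the horizon
        dw[i] <- duration - t
        done <- TRUE
        break
      }
      dw[i] <- tau
      t <- t + tau
      m <- if (u2[j] < up / rate) m + 1L else m - 1L
    }
  }
  structure(list(levels = lev[seq_len(i)], dwells = dw[seq_len(i)],
                 total_duration = duration, n_monomers = n),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("State path: %d dwells over %.4g s (N = %d monomers)\n",
              length(x$levels), x$total_duration, x$n_monomers))
  tf <- state_path_occupancy(x)
  cat("Level time fractions:", paste(sprintf("%.4f", tf), collapse = " "),
      "\n")
  invisible(x)
}

#' Time fraction spent at each occupancy level of a state path
#'
#' @param path a `"state_path"`.
#' @return Numeric vector of length `n_monomers + 1` summing to 1.
#' @export
state_path_occupancy <- function(path) {
  stopifnot(inherits(path, "state_path"))
  tf <- vapply(0:path$n_monomers, function(m) {
    sum(path$dwells[path$levels == m])
  }, numeric(1))
  tf / sum(tf)
}

#' Convert a state path to an idealized record
#'
#' A simulated occupancy path is structurally identical to an idealized
#' (level-labelled dwell) record with zero dead time; this converter lets the
#' dwell, NPo and occupancy statistics run directly on simulator output.
#'
#' @param path a `"state_path"`.
#' @return An `"idealized_record"` (see [idealize()]).
#' @export
as_idealized_record <- function(path) {
  stopifnot(inherits(path, "state_path"))
  starts <- cumsum(c(0, path$dwells[-length(path$dwells)]))
  new_idealized_record(
    data.frame(level = path$levels, start = starts,
               duration = path$dwells),
    n_levels = path$n_monomers + 1L, dead_time = 0,
    total_time = path$total_duration
  )
}
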