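#' Open probability NPo of an idealized record
#'
#' `NPo = t_o / T`: the total time the channel spends at any level above the
#' fully closed level, divided by the total recording time. This is the
#' unweighted definition (time at O1 counts the same as time at O3); see
#' [npo_weighted()] for the variant weighted by the number of open pores.
#'
#' @param record an `"idealized_record"` (level 0 = closed).
#' @return Dimensionless value in \[0, 1\].
#' @export
npo <- function(record) {
  stopifnot(inherits(record, "idealized_record"))
  if (nrow(record$events) == 0 || record$total_time <= 0)
    stop("empty record")
  ev <- record$events
  sum(ev$duration[ev$level > 0]) / sum(ev$duration)
}

#' Level-weighted open probability
#'
#' `sum_m m * f_m`, the time-average number of open monomeric pores (`f_m`
#' is the time fraction at level m). Provided under a distinct name so it is
#' never confused with the unweighted [npo()].
#'
#' @inheritParams npo
#' @return Time-average number of open pores (0 .. n_levels - 1).
#' @export
npo_weighted <- function(record) {
  stopifnot(inherits(record, "idealized_record"))
  if (nrow(record$events) == 0 || record$total_time <= 0)
    stop("empty record")
  f <- level_time_fractions(record)
  sum((seq_along(f) - 1) * f)
}

#' Time fraction at each level of an idealized record
#'
#' @inheritParams npo
#' @return Numeric vector of length `n_levels` summing to 1.
#' @export
level_time_fractions <- function(record) {
  stopifnot(inherits(record, "idealized_record"))
  ev <- record$events
  tf <- vapply(0:(record$n_levels - 1L), function(m) {
    sum(ev$duration[ev$level == m])
  }, numeric(1))
  tf / sum(tf)
}

#' Summary statistics of a dwell-time sample
#'
#' Sample mean and standard deviation plus the maximum-likelihood
#' single-exponential rate (`1/mean`). Boundary-truncated (censored) dwells
#' flagged by [extract_dwells()] are dropped by default: the first and last
#' sojourns of a record are interrupted by the recording window, not by a
#' gating transition.
#'
#' @param dwells numeric vector of durations (s), e.g. from
#'   [extract_dwells()].
#' @param drop_censored drop dwells flagged censored by the `"censored"`
#'   attribute, when present.
#' @return List with `mean`, `sd`, `rate` (1/s), `n`.
#' @export
dwell_summary <- function(dwells, drop_censored = TRUE) {
  d <- as.numeric(dwells)
  cens <- attr(dwells, "censored")
  if (drop_censored && !is.null(cens) && length(d)) {
    if (isTRUE(cens[["last"]])) d <- d[-length(d)]
    if (isTRUE(cens[["first"]]) && length(d)) d <- d[-1]
  }
  if (!length(d)) stop("no (uncensored) dwells to summarise")
  m <- mean(d)
  list(mean = m, sd = stats::sd(d), rate = 1 / m, n = length(d))
}

#' Two-sample t test between groups of measurements
#'
#' Thin wrapper around [stats::t.test()] used to compare per-patch statistics
#' (NPo, mean dwell times) between constructs. Defaults to the Welch
#' unequal-variance test; `var_equal = TRUE` gives the pooled-variance
#' Student test. Two identical zero-variance groups return `t = 0, p = 1`;
#' different constant groups return `p = 0`.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param var_equal assume equal variances (pooled test).
#' @return List with `t`, `df`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, df = length(values_a) + length(values_b) - 2,
                  p_value = 1))
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf,
                df = length(values_a) + length(values_b) - 2, p_value = 0))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Binomial occupancy diagnostic for independent monomers
#'
#' If the N monomeric pores of a channel gate independently with a common
#' open probability p, the time fractions at occupancy levels 0..N follow
#' Binomial(N, p). This diagnostic estimates `p_hat` as the mean per-monomer
#' open fraction (`sum_m m * f_m / N`) and computes a chi-square statistic of
#' the observed level fractions against Binomial(N, p_hat), using an
#' effective sample size of `total_time / spacing` approximately independent
#' time points (`spacing` defaults to 10 mean event durations, a conservative
#' choice relative to the chain's correlation time). A large chi-square is
#' the signature of cooperative (non-independent) gating.
#'
#' @param record an `"idealized_record"` with `n_levels = n_monomers + 1`.
#' @param n_monomers number of monomeric pores.
#' @param spacing effective independence spacing, s (default: 10 x mean
#'   event duration).
#' @return List with `p_hat`, `chi_square`, `df` (`n_monomers - 1`, one
#'   degree lost to the estimated p), `p_value`, `n_effective`.
#' @export
binomial_occupancy_check <- function(record, n_monomers = 3,
                                     spacing = NULL) {
  stopifnot(inherits(record, "idealized_record"))
  n_monomers <- as.integer(n_monomers)
  if (record$n_levels != n_monomers + 1L)
    stop("record n_levels must equal n_monomers + 1")
  f <- level_time_fractions(record)
  p_hat <- sum((seq_along(f) - 1) * f) / n_monomers
  if (is.null(spacing))
    spacing <- 10 * mean(record$events$duration)
  n_eff <- max(1, record$total_time / spacing)
  expected <- stats::dbinom(0:n_monomers, n_monomers, p_hat)
  ok <- expected > 0
  chi2 <- n_eff * sum((f[ok] - expected[ok])^2 / expected[ok])
  if (any(!ok) && any(f[!ok] > 0)) chi2 <- Inf
  df <- n_monomers - 1L
  list(p_hat = p_hat, chi_square = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       n_effective = n_eff)
}

#' Gating statistics summary of an idealized record
#'
#' Bundles the open probability, level time fractions and open/closed dwell
#' summaries. "Open" and "closed" here are the binary collapse of the level
#' sequence (closed = level 0, open = any level > 0), so an open event is a
#' maximal sojourn above the baseline.
#'
#' @inheritParams npo
#' @return An object of class `"gating_stats"`: list with `npo`,
#'   `level_time_fractions`, `mean_open_dwell`, `mean_closed_dwell`,
#'   `n_open_events`, `n_closed_events`.
#' @export
gating_stats <- function(record) {
  stopifnot(inherits(record, "idealized_record"))
  ev <- record$events
  if (nrow(ev) == 0) stop("empty record")
  open <- ev$level > 0
  r <- rle(open)
  grp <- rep(seq_along(r$lengths), r$lengths)
  dur <- vapply(split(ev$duration, grp), sum, numeric(1))
  is_open <- r$values
  structure(list(
    npo = npo(record),
    level_time_fractions = level_time_fractions(record),
    mean_open_dwell = if (any(is_open)) mean(dur[is_open]) else NA_real_,
    mean_closed_dwell = if (any(!is_open)) mean(dur[!is_open]) else NA_real_,
    n_open_events = sum(is_open),
    n_closed_events = sum(!is_open)
  ), class = "gating_stats")
}

#' @export
print.gating_stats <- function(x, ...) {
  cat(sprintf("NPo = %.4f; open events: %d (mean %.4g s); closed events: %d (mean %.4g s)\n",
              x$npo, x$n_open_events, x$mean_open_dwell,
              x$n_closed_events, x$mean_closed_dwell))
  cat("Level time fractions:",
      paste(sprintf("%.4f", x$level_time_fractions), collapse = " "), "\n")
  invisible(x)
}
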