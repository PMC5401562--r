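#' Current-voltage dataset
#'
#' Mean single-channel currents at a set of holding potentials, with the
#' between-measurement SEM and the number of measurements per point.
#'
#' @param voltage holding potentials, mV (at least 2 distinct values).
#' @param current mean currents, pA.
#' @param sem standard errors of the means, pA (>= 0).
#' @param n number of measurements per point (>= 1).
#' @return A data frame of class `"iv_dataset"` with columns `voltage_mV`,
#'   `current_pA`, `sem_pA`, `n`.
#' @export
iv_dataset <- function(voltage, current, sem = 0, n = 1L) {
  if (length(unique(voltage)) < 2)
    stop("need at least 2 distinct voltages")
  if (length(current) != length(voltage))
    stop("'voltage' and 'current' lengths differ")
  sem <- rep_len(sem, length(voltage))
  n <- rep_len(as.integer(n), length(voltage))
  if (any(sem < 0)) stop("'sem' must be >= 0")
  if (any(n < 1)) stop("'n' must be >= 1")
  structure(data.frame(voltage_mV = voltage, current_pA = current,
                       sem_pA = sem, n = n),
            class = c("iv_dataset", "data.frame"))
}

#' Linear fit of a current-voltage relation
#'
#' Ordinary least-squares line `I = a V + b`. The slope conductance is
#' `1000 a` (pS from pA/mV) and the reversal potential is the zero crossing
#' `-b/a`. Standard errors come from the usual linear-regression formulas;
#' the reversal-potential standard error is propagated to first order
#' including the slope-intercept covariance. With exactly two points the fit
#' is exact and the standard errors are `NA`.
#'
#' @param data an [iv_dataset()] or a data frame whose first two columns are
#'   voltage (mV) and current (pA).
#' @param v_max restrict the fit to points with `|V| <= v_max` (mV). The
#'   GHK current is only locally linear, so reversal-potential estimation
#'   conventionally uses a +/-40 mV window; the default `Inf` uses all
#'   points (appropriate for conductance fits).
#' @return An object of class `"iv_fit"`: list with `slope_conductance`
#'   (pS), `e_rev` (mV), `slope_stderr` (pS), `e_rev_stderr` (mV),
#'   `intercept` (pA), `n_points`.
#' @export
fit_iv <- function(data, v_max = Inf) {
  v <- data[[1]]
  i <- data[[2]]
  keep <- abs(v) <= v_max
  v <- v[keep]
  i <- i[keep]
  if (length(unique(v)) < 2)
    stop("need at least 2 distinct voltages within the fit window")
  fit <- stats::lm(i ~ v)
  b <- unname(stats::coef(fit)[1])
  a <- unname(stats::coef(fit)[2])
  vc <- suppressWarnings(stats::vcov(fit))
  se_b <- sqrt(vc[1, 1])
  se_a <- sqrt(vc[2, 2])
  cov_ab <- vc[1, 2]
  if (a == 0 || (is.finite(se_a) && abs(a) < 2 * se_a))
    stop("slope indistinguishable from 0: reversal potential undefined")
  e_rev <- -b / a
  e_rev_se <- if (is.finite(se_a) && is.finite(se_b))
    sqrt(se_b^2 / a^2 + b^2 * se_a^2 / a^4 - 2 * b * cov_ab / a^3)
  else NA_real_
  structure(list(slope_conductance = 1000 * a, e_rev = e_rev,
                 slope_stderr = 1000 * se_a, e_rev_stderr = e_rev_se,
                 intercept = b, n_points = length(v)),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf(
    "I/V fit (%d points): slope conductance %.4g +/- %.2g pS, E_rev %.4g +/- %.2g mV\n",
    x$n_points, x$slope_conductance, x$slope_stderr, x$e_rev,
    x$e_rev_stderr))
  invisible(x)
}

#' Simulate a noisy I/V dataset from the GHK model
#'
#' Generates mean currents at the requested voltages from [ghk_current()],
#' scaled so the slope conductance at the reversal potential equals
#' `conductance` (pS), then emulates the experimental protocol: each
#' voltage's mean current is the average of `n_per_point` measurements, each
#' carrying independent Gaussian noise of sd `noise_sd` (pA).
#'
#' @param conditions an [ion_conditions()] object.
#' @param voltages mV.
#' @param conductance slope conductance at the reversal potential, pS.
#' @param noise_sd per-measurement noise, pA.
#' @param n_per_point measurements averaged per voltage.
#' @param seed optional integer seed.
#' @return An [iv_dataset()].
#' @export
simulate_iv_dataset <- function(conditions, voltages = seq(-40, 40, by = 20),
                                conductance = 163.7, noise_sd = 0.5,
                                n_per_point = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  scale <- ghk_conductance_scale(conditions, conductance)
  truth <- ghk_current(voltages, conditions, scale = scale)
  reps <- vapply(truth, function(mu) {
    x <- mu + stats::rnorm(n_per_point, 0, noise_sd)
    c(mean(x), stats::sd(x) / sqrt(n_per_point))
  }, numeric(2))
  iv_dataset(voltages, reps[1, ],
             sem = if (n_per_point > 1) reps[2, ] else 0,
             n = n_per_point)
}

#' Read / write an I/V table as TSV
#'
#' Columns `voltage_mV`, `current_pA`, `sem_pA`, `n`.
#'
#' @param data an `"iv_dataset"`.
#' @param path file path.
#' @export
write_iv_table <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_iv_table
#' @export
read_iv_table <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t")
  iv_dataset(dat$voltage_mV, dat$current_pA,
             sem = dat$sem_pA %||% 0, n = dat$n %||% 1L)
}
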