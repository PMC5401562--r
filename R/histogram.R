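#' All-points amplitude histogram
#'
#' Histogram of every current sample in a recording, the standard display in
#' which channel conductance levels appear as Gaussian peaks. Bins are
#' uniform, right-open (`[left, right)`) and anchored so that one bin edge
#' falls exactly at 0 pA.
#'
#' @param trace a `"channel_trace"` or a plain numeric vector of currents
#'   (pA).
#' @param bin_width bin width in pA (default 0.03).
#' @return An object of class `"amplitude_histogram"`: list with
#'   `breaks` (bin edges, pA), `counts`, `mids` and `n_samples`.
#' @export
build_histogram <- function(trace, bin_width = 0.03) {
  x <- if (inherits(trace, "channel_trace")) trace$current else
    as.numeric(trace)
  if (length(x) == 0) stop("empty trace")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("'bin_width' must be > 0")
  lo <- floor(min(x) / bin_width)
  hi <- floor(max(x) / bin_width) + 1L
  idx <- pmin(floor(x / bin_width) - lo + 1L, hi - lo) # right-open bins
  counts <- tabulate(idx, nbins = hi - lo)
  breaks <- (lo:hi) * bin_width
  structure(list(breaks = breaks, counts = counts,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 bin_width = bin_width, n_samples = length(x)),
            class = "amplitude_histogram")
}

#' @export
print.amplitude_histogram <- function(x, ...) {
  cat(sprintf(
    "All-points amplitude histogram: %d samples, %d bins of %g pA over [%g, %g] pA\n",
    x$n_samples, length(x$counts), x$bin_width, min(x$breaks),
    max(x$breaks)))
  invisible(x)
}

#' Decompose an amplitude histogram into a sum of Gaussians
#'
#' Nonlinear least-squares fit of `k` Gaussian components to the bin counts
#' versus bin centres, the standard way of resolving closed and multimeric
#' open levels in an all-points histogram (e.g. four components for one
#' trimer: C, O1, O2, O3; seven for two trimers). Counts are fitted
#' unweighted by default; `weights = "poisson"` divides residuals by
#' `sqrt(count)`.
#'
#' Initial means default to the `k` highest local maxima of the counts after
#' a 5-bin moving-average smoothing (which stabilises maxima detection
#' without displacing peaks at 0.03-pA bins); initial widths come from the
#' half-width at half maximum around each peak. The fit is deterministic for
#' fixed inputs. Components are returned sorted by mean, ties broken by
#' ascending sd. A component whose fitted area falls below
#' `degenerate_area_frac` of the total area is flagged degenerate (the
#' signature of requesting more components than resolvable peaks).
#'
#' @param hist an [build_histogram()] result.
#' @param k number of Gaussian components (1..8).
#' @param init_means optional numeric vector of length `k` of starting means
#'   (pA).
#' @param weights `"none"` (default) or `"poisson"`.
#' @param shared_sd logical; constrain all components to one common sd. The
#'   constraint is echoed in the fit object (`sd_constraint`).
#' @param degenerate_area_frac area fraction below which a component is
#'   flagged degenerate.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return An object of class `"mixture_fit"`: list with `components`
#'   (data frame: `mean`, `sd`, `area`, `amplitude`, `degenerate`), `k`,
#'   `rss`, `converged`, `sd_constraint`, `weighting`.
#' @export
fit_mixture <- function(hist, k, init_means = NULL,
                        weights = c("none", "poisson"), shared_sd = FALSE,
                        degenerate_area_frac = 1e-3, max_iter = 200) {
  stopifnot(inherits(hist, "amplitude_histogram"))
  weights <- match.arg(weights)
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop("'k' must lie in 1..8")
  x <- hist$mids
  y <- as.numeric(hist$counts)
  w <- hist$bin_width

  init <- .init_mixture(x, y, k, init_means, w)
  wt <- if (weights == "poisson") sqrt(pmax(y, 1)) else rep(1, length(y))

  if (shared_sd) {
    par0 <- c(init$amp, init$mean, mean(init$sd))
    unpack <- function(p) list(a = p[1:k], m = p[k + 1:k],
                               s = rep(p[2 * k + 1], k))
    lower <- c(rep(0, k), rep(min(x) - w, k), w / 4)
    upper <- c(rep(Inf, k), rep(max(x) + w, k), diff(range(x)) + w)
  } else {
    par0 <- c(init$amp, init$mean, init$sd)
    unpack <- function(p) list(a = p[1:k], m = p[k + 1:k],
                               s = p[2 * k + 1:k])
    lower <- c(rep(0, k), rep(min(x) - w, k), rep(w / 4, k))
    upper <- c(rep(Inf, k), rep(max(x) + w, k),
               rep(diff(range(x)) + w, k))
  }
  model_at <- function(p) {
    q <- unpack(p)
    yy <- numeric(length(x))
    for (j in seq_len(k))
      yy <- yy + q$a[j] * exp(-(x - q$m[j])^2 / (2 * q$s[j]^2))
    yy
  }
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) (y - model_at(p)) / wt,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = max_iter)
  )
  q <- unpack(fit$par)
  comp <- data.frame(mean = q$m, sd = q$s, amplitude = q$a,
                     area = q$a * q$s * sqrt(2 * pi))
  ord <- order(comp$mean, comp$sd)
  comp <- comp[ord, c("mean", "sd", "area", "amplitude")]
  rownames(comp) <- NULL
  total_area <- sum(comp$area)
  comp$degenerate <- if (total_area > 0)
    comp$area < degenerate_area_frac * total_area else rep(TRUE, k)
  resid <- y - model_at(fit$par)
  structure(list(components = comp, k = k, rss = sum(resid^2),
                 converged = fit$info %in% 1:3,
                 sd_constraint = if (shared_sd) "shared" else "free",
                 weighting = weights, n_samples = hist$n_samples,
                 bin_width = w),
            class = "mixture_fit")
}

# Peak-seeded initial values: local maxima of 5-bin smoothed counts,
# greedily thinned to a minimum separation, topped up with evenly spaced
# positions if fewer than k maxima exist.
.init_mixture <- function(x, y, k, init_means, w) {
  ys <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  if (is.null(init_means)) {
    n <- length(ys)
    cand <- which(ys > c(-Inf, ys[-n]) & ys >= c(ys[-1], -Inf) & ys > 0)
    cand <- cand[order(ys[cand], decreasing = TRUE)]
    keep <- integer(0)
    min_sep <- max(3L, floor(length(x) / (8 * k)))
    for (i in cand) {
      if (!length(keep) || all(abs(i - keep) >= min_sep)) keep <- c(keep, i)
      if (length(keep) == k) break
    }
    means <- x[sort(keep)]
    if (length(means) < k) {
      extra <- seq(min(x), max(x), length.out = k + 2)[2:(k + 1)]
      means <- sort(c(means,
                      extra[seq_len(k - length(means))]))
    }
  } else {
    if (length(init_means) != k) stop("'init_means' must have length k")
    means <- sort(as.numeric(init_means))
  }
  idx0 <- vapply(means, function(m) which.min(abs(x - m)), integer(1))
  sds <- vapply(idx0, function(i0) {
    half <- ys[i0] / 2
    r <- i0
    while (r < length(ys) && ys[r] > half) r <- r + 1L
    l <- i0
    while (l > 1L && ys[l] > half) l <- l - 1L
    hwhm <- max(1, (r - l) / 2) * w
    max(w, hwhm / 1.1774)
  }, numeric(1))
  amps <- pmax(ys[idx0], 1)
  list(mean = means, sd = sds, amp = amps)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian mixture fit: k = %d (%s sds, %s weighting), converged = %s, RSS = %.4g\n",
    x$k, x$sd_constraint, x$weighting, x$converged, x$rss))
  print(x$components, digits = 4)
  invisible(x)
}

#' Convert fitted histogram peaks to per-level conductances
#'
#' Given a mixture fit of an all-points histogram recorded at holding
#' potential `v`, computes the chord conductance of each open level:
#' `gamma_m = 1000 * (mu_m - mu_0) / (v - e_rev)` (pS from pA and mV), where
#' `mu_0` is the closed-level mean, identified as the component whose mean is
#' smallest in absolute value.
#'
#' @param fit a [fit_mixture()] result with at least two components.
#' @param v holding potential, mV.
#' @param e_rev reversal potential, mV; must differ from `v`.
#' @return Numeric vector of conductances (pS), one per non-closed component
#'   in ascending order of component mean.
#' @export
#' @examples
#' # means 0 and 2.532 pA at +60 mV, E_rev = 0 -> 42.2 pS
levels_to_conductances <- function(fit, v, e_rev = 0) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (nrow(fit$components) < 2)
    stop("need at least 2 fitted components")
  if (abs(v - e_rev) < 1e-9)
    stop("zero driving force: v equals e_rev, conductance undefined")
  mu <- fit$components$mean
  closed <- which.min(abs(mu))
  1000 * (mu[-closed] - mu[closed]) / (v - e_rev)
}

#' Write / read an amplitude histogram as TSV
#'
#' Columns `bin_left_pA`, `bin_right_pA`, `count`.
#'
#' @param hist an `"amplitude_histogram"`.
#' @param path file path.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "amplitude_histogram"))
  dat <- data.frame(bin_left_pA = hist$breaks[-length(hist$breaks)],
                    bin_right_pA = hist$breaks[-1],
                    count = hist$counts)
  utils::write.table(dat, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t")
  w <- dat$bin_right_pA[1] - dat$bin_left_pA[1]
  breaks <- c(dat$bin_left_pA, dat$bin_right_pA[nrow(dat)])
  structure(list(breaks = breaks, counts = dat$count,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 bin_width = w, n_samples = sum(dat$count)),
            class = "amplitude_histogram")
}

#' Mixture fit report as a JSON-ready list
#'
#' @param fit a `"mixture_fit"`.
#' @param path optional path; when given, the report is written as JSON.
#' @return The report list, invisibly when written to file.
#' @export
mixture_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  rep <- list(k = fit$k, components = fit$components, rss = fit$rss,
              converged = fit$converged, sd_constraint = fit$sd_constraint,
              weighting = fit$weighting, bin_width_pA = fit$bin_width)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(rep))
  }
  rep
}
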