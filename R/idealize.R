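new_idealized_record <- function(events, n_levels, dead_time, total_time,
                                 level_means = NULL) {
  stopifnot(is.data.frame(events),
            all(c("level", "start", "duration") %in% names(events)))
  structure(list(events = events, n_levels = as.integer(n_levels),
                 dead_time = dead_time, total_time = total_time,
                 level_means = level_means),
            class = "idealized_record")
}

#' Idealize a current trace into a level-labelled dwell sequence
#'
#' Multi-level half-amplitude idealization: each sample is assigned to the
#' conductance level whose mean current is nearest (equivalently, thresholds
#' sit at the midpoints between adjacent level means; a sample exactly at a
#' midpoint is assigned to the lower level). Runs shorter than `dead_time`
#' are merged into the temporally preceding event (a leading short run merges
#' into the following one), reflecting that events shorter than the filter
#' response cannot reach half amplitude and are not resolvable.
#'
#' @param trace a `"channel_trace"`.
#' @param level_means sorted increasing vector of level mean currents, pA;
#'   at least 2 levels.
#' @param dead_time shortest resolvable event, s. The default
#'   `0.3 / filter_cutoff` (about 0.6 ms at 500 Hz) is twice the nominal
#'   Gaussian-filter rise time; it falls back to 0 for unfiltered traces.
#' @return An object of class `"idealized_record"`: list with `events`
#'   (data frame `level` 0-based, `start` s, `duration` s; contiguous and
#'   non-overlapping), `n_levels`, `dead_time`, `total_time`,
#'   `level_means`.
#' @export
idealize <- function(trace, level_means, dead_time = NULL) {
  stopifnot(inherits(trace, "channel_trace"))
  if (length(level_means) < 2)
    stop("need at least 2 level means to idealize")
  if (is.unsorted(level_means, strictly = TRUE))
    stop("'level_means' must be strictly increasing")
  if (is.null(dead_time))
    dead_time <- if (!is.na(trace$filter_cutoff))
      0.3 / trace$filter_cutoff else 0
  if (dead_time < 0) stop("'dead_time' must be >= 0")
  x <- trace$current
  dt <- trace$dt
  thr <- (level_means[-1] + level_means[-length(level_means)]) / 2
  lev <- findInterval(x, thr, left.open = TRUE) # 0-based; midpoint -> lower
  r <- rle(lev)
  merged <- .merge_dead_time(r$values, r$lengths * dt, dead_time)
  starts <- cumsum(c(0, merged$dur[-length(merged$dur)]))
  new_idealized_record(
    data.frame(level = merged$lev, start = starts, duration = merged$dur),
    n_levels = length(level_means), dead_time = dead_time,
    total_time = length(x) * dt, level_means = level_means
  )
}

# Dead-time merging: sub-dead-time runs are absorbed into the preceding
# event; leading short runs accumulate and are absorbed into the first
# retained event. Adjacent same-level events are collapsed.
.merge_dead_time <- function(levels, durs, dead_time) {
  n <- length(levels)
  out_lev <- integer(n)
  out_dur <- numeric(n)
  top <- 0L
  pending <- 0
  eps <- 1e-12
  for (j in seq_len(n)) {
    d <- durs[j] + pending
    pending <- 0
    if (d < dead_time - eps) {
      if (top > 0L) out_dur[top] <- out_dur[top] + d else pending <- d
    } else if (top > 0L && out_lev[top] == levels[j]) {
      out_dur[top] <- out_dur[top] + d
    } else {
      top <- top + 1L
      out_lev[top] <- levels[j]
      out_dur[top] <- d
    }
  }
  if (top == 0L) { # every run was shorter than the dead time
    top <- 1L
    out_lev[1] <- levels[which.max(durs)]
    out_dur[1] <- pending
  }
  list(lev = out_lev[seq_len(top)], dur = out_dur[seq_len(top)])
}

#' @export
print.idealized_record <- function(x, ...) {
  cat(sprintf(
    "Idealized record: %d events over %.4g s (%d levels, dead time %g s)\n",
    nrow(x$events), x$total_time, x$n_levels, x$dead_time))
  invisible(x)
}

#' Dwell durations at one conductance level
#'
#' Durations of all maximal runs at `level`, in temporal order. The result
#' carries a `"censored"` attribute flagging whether the first and/or last
#' returned dwell is boundary-truncated (the record starts or ends inside
#' it); [dwell_summary()] uses this to exclude censored dwells.
#'
#' @param record an `"idealized_record"`.
#' @param level 0-based level index.
#' @return Numeric vector of durations (s), possibly empty.
#' @export
extract_dwells <- function(record, level) {
  stopifnot(inherits(record, "idealized_record"))
  level <- as.integer(level)
  if (level < 0L || level >= record$n_levels)
    stop("'level' out of range [0, n_levels - 1]")
  ev <- record$events
  d <- ev$duration[ev$level == level]
  n <- nrow(ev)
  attr(d, "censored") <- c(first = n > 0 && ev$level[1] == level,
                           last = n > 0 && ev$level[n] == level)
  d
}

#' Write / read an idealized event list as TSV
#'
#' Columns `level`, `start_s`, `duration_s`, preceded by `#` metadata lines
#' (`n_levels`, `dead_time_s`, `total_time_s`).
#'
#' @param record an `"idealized_record"`.
#' @param path file path.
#' @export
write_events <- function(record, path) {
  stopifnot(inherits(record, "idealized_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_levels: %d", record$n_levels),
               sprintf("# dead_time_s: %.10g", record$dead_time),
               sprintf("# total_time_s: %.10g", record$total_time),
               "level\tstart_s\tduration_s"), con)
  utils::write.table(record$events, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           header = TRUE, sep = "\t")
  names(dat) <- c("level", "start", "duration")
  new_idealized_record(dat,
                       n_levels = meta[["n_levels"]] %||%
                         (max(dat$level) + 1),
                       dead_time = meta[["dead_time_s"]] %||% 0,
                       total_time = meta[["total_time_s"]] %||%
                         sum(dat$duration))
}
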