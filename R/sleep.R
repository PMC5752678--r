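#' Immobility-defined sleep scoring
#'
#' Scores sleep from a per-second immobility trace: a sleep episode is a
#' maximal run of seconds in which at least `area_threshold` of the
#' animal's area is immobile, lasting strictly longer than
#' `min_duration_s`. The defaults (95% area, > 40 s) are the video-scoring
#' convention validated against EEG/EMG-defined sleep.
#'
#' @param trace An [immobility_trace()].
#' @param area_threshold Immobile-area fraction defining immobility.
#'   Default 0.95.
#' @param min_duration_s Minimum episode duration in seconds (strict
#'   inequality). Default 40.
#' @return A data frame of class `sleep_episodes`: `start_s`, `end_s`
#'   (half-open seconds from trace start) and `duration_s`.
#' @export
score_sleep <- function(trace, area_threshold = 0.95, min_duration_s = 40) {
  stopifnot(inherits(trace, "immobility_trace"))
  immobile <- trace$immobile_fraction >= area_threshold
  r <- rle(immobile)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_duration_s
  df <- data.frame(
    start_s = starts[keep] - 1L,   # seconds from trace start, 0-based
    end_s = ends[keep],
    duration_s = r$lengths[keep]
  )
  class(df) <- c("sleep_episodes", "data.frame")
  attr(df, "start_zt") <- trace$start_zt
  df
}

#' Collapse sleep episodes to one-minute bins
#'
#' A minute is marked asleep when at least `min_overlap_s` of its 60
#' seconds fall inside a scored episode (default 30 s, the majority rule;
#' `min_overlap_s = 1` gives the any-overlap rule).
#'
#' @param episodes A `sleep_episodes` table from [score_sleep()].
#' @param trace The [immobility_trace()] the episodes were scored from.
#' @param min_overlap_s Seconds of overlap required. Default 30.
#' @return Integer vector (0/1), one element per minute of the trace.
#' @export
bin_sleep_minutes <- function(episodes, trace, min_overlap_s = 30) {
  n_min <- length(trace$immobile_fraction) %/% 60L
  asleep_s <- logical(n_min * 60L)
  for (i in seq_len(nrow(episodes)))
    asleep_s[(episodes$start_s[i] + 1L):episodes$end_s[i]] <- TRUE
  per_min <- colSums(matrix(asleep_s, nrow = 60L))
  as.integer(per_min >= min_overlap_s)
}

# ZT hour of each minute bin's left edge and its analysis-day index.
minute_zt_day <- function(n_min, start_zt) {
  abs_min <- start_zt * 60 + (seq_len(n_min) - 1)
  list(zt = (abs_min %% 1440) / 60, day = floor(abs_min / 1440))
}

#' Total sleep time per phase window, averaged over selected cycles
#'
#' Sums asleep minutes in each window for each sleep-wake cycle (analysis
#' day) and averages over `cycles`. The conventional analysis averages the
#' 3rd and 4th cycles of a recording of at least five cycles.
#'
#' @param minutes Per-minute 0/1 vector from [bin_sleep_minutes()].
#' @param trace The source [immobility_trace()].
#' @param windows List of [phase_window()]s. Default rest, active, 24 h.
#' @param cycles 1-based cycle indices to average (default `3:4`); `NULL`
#'   uses all complete cycles.
#' @return Data frame: one row per window with `total_sleep_min` (mean over
#'   cycles) plus per-cycle columns.
#' @export
sleep_totals <- function(minutes, trace,
                         windows = list(rest_phase(), active_phase(), full_day()),
                         cycles = 3:4) {
  md <- minute_zt_day(length(minutes), trace$start_zt)
  n_cycles <- trace$n_days
  if (is.null(cycles)) cycles <- seq_len(n_cycles)
  if (max(cycles) > n_cycles)
    stop_data("recording has ", n_cycles, " complete cycles; requested cycle ",
              max(cycles))
  rows <- lapply(windows, function(w) {
    per_cycle <- vapply(cycles, function(cy)
      sum(minutes[md$day == (cy - 1L) & zt_in_window(md$zt, w)]), numeric(1))
    data.frame(window = w$label, total_sleep_min = mean(per_cycle),
               t(stats::setNames(per_cycle, paste0("cycle_", cycles))))
  })
  do.call(rbind, rows)
}

#' Sleep-to-wake transition time and its cycle-to-cycle deviation
#'
#' Per cycle, the sleep offset (wake onset) is located on the minute-binned
#' sleep series. The default `"changepoint"` method takes the minutes of
#' the cycle inside `search_window_zt` and places the offset at the CUSUM
#' changepoint — the minute maximizing the cumulative sum of mean-centered
#' sleep indicators — which is the natural estimator for a drop in sleep
#' occupancy and is robust to the minute-to-minute raggedness of scored
#' sleep. The `"last_episode"` method instead reports the end of the last
#' consolidated episode (at least `consolidation_min` minutes) starting in
#' the cycle's rest phase; it is simpler but tied to the ZT 12 boundary.
#' A least-squares line is fitted to the offsets across cycles and the
#' deviation is the mean absolute residual in minutes, so a steady drift
#' in wake time does not inflate the variability.
#'
#' @param episodes `sleep_episodes` from [score_sleep()].
#' @param trace The source [immobility_trace()].
#' @param cycles Cycle indices to use; `NULL` (default) uses all.
#' @param method `"changepoint"` (default) or `"last_episode"`.
#' @param search_window_zt ZT window searched for the transition
#'   (changepoint method). Default `c(6, 18)`.
#' @param consolidation_min Minimum episode length (minutes) anchoring the
#'   offset in the last-episode method. Default 5.
#' @return A `wake_onset` object: data frame `per_cycle` (`cycle`,
#'   `offset_zt`), `wake_onset_zt` (mean offset), `deviation_min`,
#'   `n_missing`.
#' @export
wake_onset_and_deviation <- function(episodes, trace, cycles = NULL,
                                     method = c("changepoint",
                                                "last_episode"),
                                     search_window_zt = c(6, 18),
                                     consolidation_min = 5) {
  stopifnot(inherits(trace, "immobility_trace"))
  method <- match.arg(method)
  n_cycles <- trace$n_days
  if (is.null(cycles)) cycles <- seq_len(n_cycles)
  offset_abs_h <- rep(NA_real_, length(cycles))
  if (method == "changepoint") {
    minutes <- bin_sleep_minutes(episodes, trace)
    md <- minute_zt_day(length(minutes), trace$start_zt)
    for (j in seq_along(cycles)) {
      d <- cycles[j] - 1L
      sel <- which(md$day == d & md$zt >= search_window_zt[1] &
                     md$zt < search_window_zt[2])
      if (length(sel) < 60 || sum(minutes[sel]) == 0) next
      S <- cumsum(minutes[sel] - mean(minutes[sel]))
      m <- sel[which.max(S)]
      offset_abs_h[j] <- trace$start_zt + m / 60   # end of that minute
    }
  } else {
    start_abs_h <- trace$start_zt + episodes$start_s / 3600
    end_abs_h <- trace$start_zt + episodes$end_s / 3600
    start_day <- floor(start_abs_h / 24)
    start_zt_ep <- start_abs_h %% 24
    long_enough <- episodes$duration_s >= consolidation_min * 60
    for (j in seq_along(cycles)) {
      d <- cycles[j] - 1L
      sel <- long_enough & start_day == d & start_zt_ep < 12
      if (any(sel)) offset_abs_h[j] <- max(end_abs_h[sel])
    }
  }
  ok <- !is.na(offset_abs_h)
  n_missing <- sum(!ok)
  if (sum(ok) < 2)
    stop_data("fewer than two cycles with a detectable sleep offset")
  cyc <- cycles
  fit <- stats::lm(offset_abs_h[ok] ~ cyc[ok])
  deviation_min <- mean(abs(stats::residuals(fit))) * 60
  structure(
    list(per_cycle = data.frame(cycle = cycles,
                                offset_zt = offset_abs_h %% 24),
         wake_onset_zt = mean(offset_abs_h[ok] %% 24),
         deviation_min = deviation_min,
         n_missing = n_missing,
         method = method),
    class = "wake_onset"
  )
}

#' @export
print.wake_onset <- function(x, ...) {
  cat(sprintf("Wake onset: ZT %.2f h, cycle-to-cycle deviation %.1f min (%d cycles%s)\n",
              x$wake_onset_zt, x$deviation_min, nrow(x$per_cycle),
              if (x$n_missing) paste0(", ", x$n_missing, " missing") else ""))
  invisible(x)
}

#' Full sleep-architecture summary for one animal
#'
#' Runs [score_sleep()], [bin_sleep_minutes()], [sleep_totals()] and
#' [wake_onset_and_deviation()] and adds per-window bout counts and mean
#' bout durations (episodes assigned to the window containing their start).
#'
#' @inheritParams score_sleep
#' @inheritParams sleep_totals
#' @inheritParams wake_onset_and_deviation
#' @return A `sleep_summary` object.
#' @export
sleep_summary <- function(trace, area_threshold = 0.95, min_duration_s = 40,
                          cycles = 3:4, consolidation_min = 5) {
  eps <- score_sleep(trace, area_threshold, min_duration_s)
  minutes <- bin_sleep_minutes(eps, trace)
  totals <- sleep_totals(minutes, trace, cycles = cycles)
  start_zt_ep <- (trace$start_zt + eps$start_s / 3600) %% 24
  windows <- list(rest_phase(), active_phase(), full_day())
  bouts <- do.call(rbind, lapply(windows, function(w) {
    sel <- zt_in_window(start_zt_ep, w)
    data.frame(window = w$label,
               bouts_per_day = sum(sel) / trace$n_days,
               mean_bout_min = if (any(sel)) mean(eps$duration_s[sel]) / 60
                               else NA_real_)
  }))
  onset <- tryCatch(
    wake_onset_and_deviation(eps, trace,
                             consolidation_min = consolidation_min),
    error = function(e) NULL)
  structure(
    list(episodes = eps, minutes = minutes, totals = totals, bouts = bouts,
         wake_onset = onset, animal_id = trace$animal_id,
         cycles = cycles),
    class = "sleep_summary"
  )
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf("Sleep summary '%s' (cycles %s):\n", x$animal_id,
              paste(x$cycles, collapse = "-")))
  tot <- x$totals[, c("window", "total_sleep_min")]
  print(tot, row.names = FALSE)
  if (!is.null(x$wake_onset))
    cat(sprintf("wake onset ZT %.2f h, deviation %.1f min\n",
                x$wake_onset$wake_onset_zt, x$wake_onset$deviation_min))
  invisible(x)
}
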