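#' Activity bout segmentation
#'
#' A bin is "active" when its count rate meets `threshold_cpm` (counts per
#' minute, converted to a per-bin count as `threshold_cpm * bin_minutes`).
#' Consecutive active runs separated by sub-threshold gaps of at most
#' `max_gap_min` are merged into a single bout; bouts are maximal. The
#' defaults (3 counts/min, 21-min maximum gap) are the conventional cage
#' actigraphy settings.
#'
#' @param rec An [activity_recording()].
#' @param threshold_cpm Activity threshold in counts/min. Default 3.
#' @param max_gap_min Maximum within-bout quiet gap in minutes. Default 21.
#' @return A data frame of class `bout_table`: `start` and `end` (bin
#'   indices, half-open), `start_zt`, `duration_min`, `total_counts`.
#' @export
detect_bouts <- function(rec, threshold_cpm = 3, max_gap_min = 21) {
  stopifnot(inherits(rec, "activity_recording"))
  thr <- threshold_cpm * rec$bin_minutes
  active <- rec$counts >= thr
  out <- merge_active_runs(active, max_gap_bins = max_gap_min %/% rec$bin_minutes)
  zt <- bin_zt(rec)
  df <- data.frame(
    start = out$start, end = out$end,
    start_zt = if (nrow(out)) zt[out$start] else numeric(0),
    duration_min = (out$end - out$start) * rec$bin_minutes,
    total_counts = vapply(seq_len(nrow(out)), function(i)
      sum(rec$counts[out$start[i]:(out$end[i] - 1L)]), numeric(1))
  )
  class(df) <- c("bout_table", "data.frame")
  attr(df, "bin_minutes") <- rec$bin_minutes
  df
}

# Maximal runs of TRUE in `active`, merging runs separated by at most
# `max_gap_bins` FALSE bins. Returns half-open bin index ranges.
merge_active_runs <- function(active, max_gap_bins) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values] + 1L)
  if (nrow(runs) == 0L) return(runs)
  merged_start <- runs$start[1]
  out_start <- integer(0); out_end <- integer(0)
  cur_end <- runs$end[1]
  for (i in seq_len(nrow(runs))[-1]) {
    gap <- runs$start[i] - cur_end
    if (gap <= max_gap_bins) {
      cur_end <- runs$end[i]
    } else {
      out_start <- c(out_start, merged_start); out_end <- c(out_end, cur_end)
      merged_start <- runs$start[i]; cur_end <- runs$end[i]
    }
  }
  out_start <- c(out_start, merged_start); out_end <- c(out_end, cur_end)
  data.frame(start = out_start, end = out_end)
}

#' Per-day bout counts and durations within a phase window
#'
#' A bout belongs to the window (and analysis day) containing its *start*
#' bin, so a bout straddling ZT 12 is counted once, in the phase where it
#' began. Counts are averaged over the recording's days.
#'
#' @param bouts A `bout_table` from [detect_bouts()].
#' @param rec The recording the bouts came from.
#' @param window A [phase_window()]; default the full 24-h day.
#' @return A one-row data frame: `window`, `bouts_per_day`,
#'   `mean_duration_min` (NA when no bouts fall in the window), `n_days`.
#' @export
bout_summary <- function(bouts, rec, window = full_day()) {
  stopifnot(inherits(bouts, "bout_table"), inherits(rec, "activity_recording"))
  in_win <- if (nrow(bouts)) zt_in_window(bouts$start_zt, window) else logical(0)
  sel <- bouts[in_win, , drop = FALSE]
  data.frame(
    window = window$label,
    bouts_per_day = nrow(sel) / rec$n_days,
    mean_duration_min = if (nrow(sel)) mean(sel$duration_min) else NA_real_,
    n_days = rec$n_days
  )
}
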