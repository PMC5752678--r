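#' Binned locomotor activity recording
#'
#' Container for evenly binned infrared-motion (or wheel) activity counts
#' with light-schedule metadata. Counts are arbitrary units (a.u.) per bin.
#' Rhythm metrics (periodogram, onsets) expect at least 10 complete days of
#' 3-min bins, the standard acquisition setting for cage actigraphy.
#'
#' @param counts Non-negative integer counts, one per bin, covering complete
#'   days (length must equal `n_days * 24 * 60 / bin_minutes`).
#' @param bin_minutes Bin width in minutes; must divide 60. Default 3.
#' @param start_zt ZT hour of the first bin's left edge. Default 0.
#' @param schedule A [light_schedule()].
#' @param animal_id Animal label.
#' @return An `activity_recording` object with fields `counts`,
#'   `bin_minutes`, `start_zt`, `n_days`, `schedule`, `animal_id`.
#' @export
activity_recording <- function(counts, bin_minutes = 3, start_zt = 0,
                               schedule = light_schedule(),
                               animal_id = "animal") {
  stopifnot(is.numeric(counts), is.numeric(bin_minutes),
            length(bin_minutes) == 1L)
  if (60 %% bin_minutes != 0)
    stop_data("`bin_minutes` must divide 60")
  if (anyNA(counts) || any(counts < 0))
    stop_data("activity counts must be non-negative and complete")
  bins_per_day <- 24L * 60L %/% as.integer(bin_minutes)
  if (length(counts) %% bins_per_day != 0L)
    stop_data("counts must cover complete days (length ", length(counts),
              " is not a multiple of ", bins_per_day, " bins/day)")
  structure(
    list(counts = as.numeric(counts),
         bin_minutes = as.integer(bin_minutes),
         start_zt = start_zt %% 24,
         n_days = length(counts) %/% bins_per_day,
         schedule = schedule,
         animal_id = animal_id),
    class = "activity_recording"
  )
}

#' @export
print.activity_recording <- function(x, ...) {
  cat(sprintf("Activity recording '%s': %d d of %d-min bins (%d bins), %.1f a.u./h\n",
              x$animal_id, x$n_days, x$bin_minutes, length(x$counts),
              mean_activity_per_hour(x)))
  invisible(x)
}

# ZT hour of each bin's left edge.
bin_zt <- function(rec) {
  (rec$start_zt + (seq_along(rec$counts) - 1) * rec$bin_minutes / 60) %% 24
}

# Analysis-day index (days delimited at ZT 0) of each bin.
bin_day <- function(rec) {
  abs_h <- rec$start_zt + (seq_along(rec$counts) - 1) * rec$bin_minutes / 60
  floor(abs_h / 24)
}

#' Per-second immobility trace from video tracking
#'
#' The immobile fraction is the share of the animal's tracked area that
#' stayed immobile over the preceding second; sleep is scored from it with
#' [score_sleep()].
#'
#' @param immobile_fraction Values in `[0, 1]`, sampled at 1 Hz, covering
#'   complete days.
#' @param start_zt ZT hour of the first sample.
#' @param schedule A [light_schedule()].
#' @param animal_id Animal label.
#' @return An `immobility_trace` object.
#' @export
immobility_trace <- function(immobile_fraction, start_zt = 0,
                             schedule = light_schedule(),
                             animal_id = "animal") {
  stopifnot(is.numeric(immobile_fraction))
  if (anyNA(immobile_fraction) ||
      any(immobile_fraction < 0 | immobile_fraction > 1))
    stop_data("immobile fractions must lie in [0, 1] with no missing values")
  if (length(immobile_fraction) %% 86400L != 0L)
    stop_data("trace must cover complete days at 1 Hz")
  structure(
    list(immobile_fraction = as.numeric(immobile_fraction),
         start_zt = start_zt %% 24,
         n_days = length(immobile_fraction) %/% 86400L,
         schedule = schedule,
         animal_id = animal_id),
    class = "immobility_trace"
  )
}

#' @export
print.immobility_trace <- function(x, ...) {
  cat(sprintf("Immobility trace '%s': %d d at 1 Hz\n", x$animal_id, x$n_days))
  invisible(x)
}

#' Beat-to-beat (RR) interval series from telemetry
#'
#' @param rr_ms Positive RR intervals in milliseconds, in temporal order.
#' @param start_zt ZT hour of the first beat.
#' @param schedule A [light_schedule()].
#' @param animal_id Animal label.
#' @return An `rr_series` with `rr_ms` and cumulative timestamps `t_s`
#'   (seconds from recording start, strictly increasing).
#' @export
rr_series <- function(rr_ms, start_zt = 0, schedule = light_schedule(),
                      animal_id = "animal") {
  stopifnot(is.numeric(rr_ms))
  if (length(rr_ms) == 0L) stop_data("empty RR series")
  if (anyNA(rr_ms) || any(rr_ms <= 0))
    stop_data("RR intervals must be positive")
  structure(
    list(rr_ms = as.numeric(rr_ms),
         t_s = cumsum(as.numeric(rr_ms)) / 1000,
         start_zt = start_zt %% 24,
         schedule = schedule,
         animal_id = animal_id),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series '%s': %d beats spanning %.1f h, mean RR %.1f ms\n",
              x$animal_id, length(x$rr_ms), max(x$t_s) / 3600, mean(x$rr_ms)))
  invisible(x)
}

#' Per-animal motor performance scores
#'
#' Trial-averaged scores from the accelerating rotarod (latency to fall) and
#' the challenging beam test (foot-slip errors, overall and per beam width).
#'
#' @param animal_id Animal label.
#' @param latency_to_fall_s Mean latency to fall across trials, seconds.
#' @param beam_errors Mean number of crossing errors across trials.
#' @param per_beam_errors Optional numeric vector of length 4 (widest to
#'   narrowest beam segment).
#' @return A `motor_scores` object.
#' @export
motor_scores <- function(animal_id, latency_to_fall_s, beam_errors,
                         per_beam_errors = NULL) {
  stopifnot(latency_to_fall_s >= 0, beam_errors >= 0)
  if (!is.null(per_beam_errors)) {
    stopifnot(length(per_beam_errors) == 4L, all(per_beam_errors >= 0))
  }
  structure(
    list(animal_id = animal_id,
         latency_to_fall_s = latency_to_fall_s,
         beam_errors = beam_errors,
         per_beam_errors = per_beam_errors),
    class = "motor_scores"
  )
}
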