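#' Light schedule and zeitgeber-time conventions
#'
#' A light schedule fixes the mapping between clock time and zeitgeber time
#' (ZT): ZT 0 is lights-on, and under a 12/12 h light/dark cycle ZT 12 is
#' lights-off. All analyses in this package are expressed in ZT hours with
#' half-open bins `[start, start + bin)`, and analysis days are delimited at
#' ZT 0 so that the active phase (ZT 12-24) of nocturnal rodents lies within
#' a single analysis day.
#'
#' @param lights_on_clock Clock time of lights-on in decimal hours of day
#'   (e.g. `6` for 06:00).
#' @param photoperiod_h Hours of light per day; must lie strictly between 0
#'   and 24 (12 for a 12/12 LD cycle).
#' @return An object of class `light_schedule`.
#' @examples
#' sched <- light_schedule(lights_on_clock = 6)
#' to_zt(18, sched)  # lights-off under 12/12 -> ZT 12
#' @export
light_schedule <- function(lights_on_clock = 6, photoperiod_h = 12) {
  stopifnot(is.numeric(lights_on_clock), length(lights_on_clock) == 1L,
            is.finite(lights_on_clock),
            is.numeric(photoperiod_h), length(photoperiod_h) == 1L)
  if (photoperiod_h <= 0 || photoperiod_h >= 24)
    stop_data("`photoperiod_h` must lie strictly between 0 and 24 h")
  structure(
    list(lights_on_clock = lights_on_clock %% 24,
         photoperiod_h = photoperiod_h),
    class = "light_schedule"
  )
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("Light schedule: lights-on %05.2f h clock, %g/%g h LD\n",
              x$lights_on_clock, x$photoperiod_h, 24 - x$photoperiod_h))
  invisible(x)
}

#' Convert clock time to zeitgeber time
#'
#' ZT 0 maps to lights-on; the conversion is periodic with period 24 h.
#'
#' @param clock_time Clock time(s) in decimal hours (may exceed 24 or be
#'   negative; reduced modulo 24).
#' @param schedule A [light_schedule()].
#' @return ZT hours in `[0, 24)`.
#' @export
to_zt <- function(clock_time, schedule) {
  if (!inherits(schedule, "light_schedule"))
    stop_data("`schedule` must be a light_schedule object")
  (clock_time - schedule$lights_on_clock) %% 24
}

#' Phase windows of the circadian day
#'
#' Half-open ZT windows `[start_zt, end_zt)`. The conventional rest phase of
#' a nocturnal rodent is ZT 0-12 (lights on) and the active phase ZT 12-24;
#' together they partition the day.
#'
#' @param start_zt,end_zt Window bounds in ZT hours; `end_zt` may exceed 24
#'   for windows crossing midnight-ZT (e.g. ZT 23-26 means ZT 23-24 plus
#'   ZT 0-2), but the window length must not exceed 24 h.
#' @param label Optional window name.
#' @return A `phase_window` object.
#' @export
phase_window <- function(start_zt, end_zt, label = NULL) {
  stopifnot(is.numeric(start_zt), is.numeric(end_zt))
  if (start_zt < 0 || start_zt >= 24)
    stop_data("`start_zt` must lie in [0, 24)")
  if (end_zt <= start_zt || end_zt - start_zt > 24)
    stop_data("window must have positive length of at most 24 h")
  structure(list(start_zt = start_zt, end_zt = end_zt,
                 label = label %||%
                   sprintf("ZT%g-%g", start_zt, end_zt)),
            class = "phase_window")
}

#' @rdname phase_window
#' @export
rest_phase <- function() phase_window(0, 12, "rest")

#' @rdname phase_window
#' @export
active_phase <- function() phase_window(12, 24, "active")

#' @rdname phase_window
#' @export
full_day <- function() phase_window(0, 24, "24h")

# TRUE for ZT values falling inside the (possibly wrapping) window.
zt_in_window <- function(zt, window) {
  zt <- zt %% 24
  if (window$end_zt <= 24) {
    zt >= window$start_zt & zt < window$end_zt
  } else {
    zt >= window$start_zt | zt < (window$end_zt - 24)
  }
}
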