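#' Filter an RR series to normal-to-normal (NN) intervals
#'
#' Two-stage artifact rejection: intervals outside the physiological band
#' `band_ms` are dropped, then intervals deviating more than `local_k`
#' robust SDs (MAD of the deviations) from a centered rolling median of
#' `roll_beats` beats are dropped. The retained fraction is reported; a
#' retained fraction below 0.5 indicates an unusable recording and is an
#' error.
#'
#' @param rr An [rr_series()].
#' @param band_ms Physiological RR band in ms (default `c(50, 250)`,
#'   covering heart rates of 240-1200 bpm, appropriate for mice).
#' @param local_k Rejection threshold in robust SD units. Default 4.
#' @param roll_beats Rolling-median window (odd). Default 31.
#' @return An `nn_series`: `nn_ms`, `t_s` (timestamps of retained beats),
#'   `retained_fraction`, plus the source metadata.
#' @export
filter_rr <- function(rr, band_ms = c(50, 250), local_k = 4,
                      roll_beats = 31) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr_ms
  in_band <- x >= band_ms[1] & x <= band_ms[2]
  xb <- x[in_band]
  tb <- rr$t_s[in_band]
  keep <- rep(TRUE, length(xb))
  if (length(xb) > roll_beats) {
    med <- stats::runmed(xb, k = roll_beats, endrule = "median")
    dev <- xb - med
    s <- stats::mad(dev)
    if (s > 0) keep <- abs(dev) <= local_k * s
  }
  nn <- xb[keep]
  retained <- length(nn) / length(x)
  if (retained < 0.5)
    stop_data("fewer than half the beats survived filtering (",
              round(100 * retained, 1), "% retained)")
  structure(
    list(nn_ms = nn, t_s = tb[keep], retained_fraction = retained,
         start_zt = rr$start_zt, schedule = rr$schedule,
         animal_id = rr$animal_id),
    class = "nn_series"
  )
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("NN series '%s': %d beats (%.1f%% retained), mean NN %.1f ms\n",
              x$animal_id, length(x$nn_ms), 100 * x$retained_fraction,
              mean(x$nn_ms)))
  invisible(x)
}

#' Hourly heart rate and time-domain HRV summary
#'
#' NN intervals are grouped into `segment_s`-second segments; each
#' segment's instantaneous HR is `60000 / mean(NN)` bpm. Segment HRs are
#' averaged into ZT-hour bins (folded across days). SDNN per hour is the
#' SD of *all* NN intervals falling in that ZT hour (population SD by the
#' time-domain convention; set `sd_mode = "sample"` for the n-1
#' denominator), not the SD of segment means. The 24-h means average over
#' the hours present; empty hours are flagged and excluded with a warning.
#'
#' @param nn An `nn_series` from [filter_rr()], spanning at least 24 h.
#' @param segment_s Segment length in seconds. Default 20.
#' @param sd_mode `"population"` (default) or `"sample"`.
#' @return An `hrv_summary`: data frame `hourly` (`zt`, `hr_bpm`,
#'   `sdnn_ms`, `n_beats`), `mean_24h_hr_bpm`, `mean_24h_sdnn_ms`,
#'   `missing_hours`, `retained_fraction`.
#' @export
segment_stats <- function(nn, segment_s = 20,
                          sd_mode = c("population", "sample")) {
  stopifnot(inherits(nn, "nn_series"))
  sd_mode <- match.arg(sd_mode)
  if (max(nn$t_s) - min(nn$t_s) < 86400 - 60)   # allow a partial last beat
    stop_data("HRV summary requires at least 24 h of data")
  seg_id <- floor(nn$t_s / segment_s)
  seg_mean_nn <- tapply(nn$nn_ms, seg_id, mean)
  seg_t <- tapply(nn$t_s, seg_id, function(t) t[1])
  seg_hr <- 60000 / seg_mean_nn
  seg_zt_h <- floor((nn$start_zt + seg_t / 3600) %% 24)
  beat_zt_h <- floor((nn$start_zt + nn$t_s / 3600) %% 24)
  sd_fun <- if (sd_mode == "population") sd_pop else stats::sd
  hr_by_h <- tapply(seg_hr, seg_zt_h, mean)
  sdnn_by_h <- tapply(nn$nn_ms, beat_zt_h, sd_fun)
  n_by_h <- tapply(nn$nn_ms, beat_zt_h, length)
  hourly <- data.frame(zt = 0:23, hr_bpm = NA_real_, sdnn_ms = NA_real_,
                       n_beats = 0L)
  hourly$hr_bpm[as.integer(names(hr_by_h)) + 1L] <- hr_by_h
  hourly$sdnn_ms[as.integer(names(sdnn_by_h)) + 1L] <- sdnn_by_h
  hourly$n_beats[as.integer(names(n_by_h)) + 1L] <- n_by_h
  missing_hours <- hourly$zt[is.na(hourly$hr_bpm)]
  if (length(missing_hours))
    warning("no data in ZT hour(s) ",
            paste(missing_hours, collapse = ", "),
            "; excluded from 24-h means", call. = FALSE)
  structure(
    list(hourly = hourly,
         mean_24h_hr_bpm = mean(hourly$hr_bpm, na.rm = TRUE),
         mean_24h_sdnn_ms = mean(hourly$sdnn_ms, na.rm = TRUE),
         missing_hours = missing_hours,
         retained_fraction = nn$retained_fraction,
         animal_id = nn$animal_id),
    class = "hrv_summary"
  )
}

#' @export
print.hrv_summary <- function(x, ...) {
  cat(sprintf(
    "HRV summary '%s': 24-h HR %.1f bpm, SDNN %.1f ms, amplitude ratio %s\n",
    x$animal_id, x$mean_24h_hr_bpm, x$mean_24h_sdnn_ms,
    if (length(x$missing_hours)) "unavailable (missing hours)"
    else sprintf("%.3f", hr_amplitude(x))))
  invisible(x)
}

#' Heart-rate rhythm amplitude as the daily max/min ratio
#'
#' The ratio of the maximum to the minimum of the 24 hourly HR means. The
#' ratio is only computed on complete days: any missing hour is an error
#' (exclude-and-warn is deliberate upstream; imputation would manufacture
#' spurious extremes here).
#'
#' @param summary An `hrv_summary` from [segment_stats()].
#' @return The max/min ratio (at least 1).
#' @export
hr_amplitude <- function(summary) {
  stopifnot(inherits(summary, "hrv_summary"))
  if (length(summary$missing_hours))
    stop_data("hourly HR incomplete (missing ZT hour(s) ",
              paste(summary$missing_hours, collapse = ", "),
              "); amplitude ratio requires all 24 hours — record longer or ",
              "relax the artifact filter rather than imputing")
  max(summary$hourly$hr_bpm) / min(summary$hourly$hr_bpm)
}

#' Hourly core body temperature waveform
#'
#' Uniformly sampled temperature is folded into ZT-hour bins: each hour's
#' mean over all samples, SEM across days, and the 24-h mean over hourly
#' means (equal to the overall mean for complete data).
#'
#' @param temp_c Temperature samples (deg C), uniform sampling.
#' @param sample_s Sampling interval in seconds.
#' @param start_zt ZT hour of the first sample.
#' @return A `cbt_waveform`: data frame `hourly` (`zt`, `mean`, `sem`) and
#'   `mean_24h`.
#' @export
cbt_waveform <- function(temp_c, sample_s, start_zt = 0) {
  stopifnot(is.numeric(temp_c), length(temp_c) > 0, sample_s > 0)
  t_h <- start_zt + (seq_along(temp_c) - 1) * sample_s / 3600
  zt_h <- floor(t_h %% 24)
  day <- floor(t_h / 24)
  hourly_mean <- tapply(temp_c, zt_h, mean)
  day_means <- tapply(temp_c, list(zt_h, day), mean)
  sem_h <- apply(day_means, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sem(v) else 0
  })
  hourly <- data.frame(zt = as.integer(names(hourly_mean)),
                       mean = as.numeric(hourly_mean),
                       sem = as.numeric(sem_h))
  structure(list(hourly = hourly, mean_24h = mean(hourly$mean)),
            class = "cbt_waveform")
}
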