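#' Hourly activity waveform
#'
#' Per animal, each ZT hour's value is the mean over days of the total
#' counts in that hour (a.u./h), so the 24 hourly values sum to the mean
#' daily total. For a group of animals the waveform is the across-animal
#' mean with SEM computed across animals (not days).
#'
#' @param recs An [activity_recording()] or a list of them (one per animal).
#' @return An `activity_waveform`: data frame `hourly` (`zt`, `mean`, `sem`),
#'   `n_days`, `n_animals`, and the per-animal matrix `per_animal`
#'   (24 x n_animals).
#' @export
average_waveform <- function(recs) {
  if (inherits(recs, "activity_recording")) recs <- list(recs)
  stopifnot(length(recs) >= 1,
            all(vapply(recs, inherits, logical(1), "activity_recording")))
  per_animal <- vapply(recs, hourly_profile, numeric(24))
  grand <- rowMeans(per_animal)
  sem_h <- if (ncol(per_animal) > 1) apply(per_animal, 1, sem) else rep(0, 24)
  structure(
    list(hourly = data.frame(zt = 0:23, mean = grand, sem = sem_h),
         n_days = recs[[1]]$n_days,
         n_animals = length(recs),
         per_animal = per_animal),
    class = "activity_waveform"
  )
}

# 24 hourly mean totals (a.u./h) for one animal, hours in ZT.
hourly_profile <- function(rec) {
  zt_h <- floor(bin_zt(rec))
  totals <- tapply(rec$counts, zt_h, sum)
  out <- numeric(24)
  out[as.integer(names(totals)) + 1L] <- totals / rec$n_days
  out
}

#' @export
print.activity_waveform <- function(x, ...) {
  cat(sprintf("Activity waveform: %d animal(s), %d d; peak %.1f a.u./h at ZT %d\n",
              x$n_animals, x$n_days, max(x$hourly$mean),
              x$hourly$zt[which.max(x$hourly$mean)]))
  invisible(x)
}

#' Mean activity level in arbitrary units per hour
#'
#' Total counts divided by total recorded hours; with the optional `window`,
#' only bins whose ZT falls in the window contribute (counts and hours).
#'
#' @param rec An [activity_recording()].
#' @param window Optional [phase_window()].
#' @return Activity in a.u./h.
#' @export
mean_activity_per_hour <- function(rec, window = NULL) {
  stopifnot(inherits(rec, "activity_recording"))
  if (is.null(window)) {
    sum(rec$counts) / (length(rec$counts) * rec$bin_minutes / 60)
  } else {
    keep <- zt_in_window(bin_zt(rec), window)
    if (!any(keep)) return(NA_real_)
    sum(rec$counts[keep]) / (sum(keep) * rec$bin_minutes / 60)
  }
}
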