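test_that("periodogram statistic matches the naive fold-and-variance oracle", {
  set.seed(11)
  x <- rpois(2 * 480, lambda = 3 + 2 * sin(2 * pi * seq_len(960) / 480))
  rec <- activity_recording(x, bin_minutes = 3)
  # toy comparison over a reduced scan so each trial period is checked
  pg <- chi_square_periodogram(rec, period_range_h = c(22.8, 24),
                               multiplicity = "none", min_days = 2)
  for (i in seq_along(pg$periods_h)) {
    P <- round(pg$periods_h[i] * 20)
    expect_equal(pg$qp[i], oracle_qp(x, P), tolerance = 1e-9)
  }
})

test_that("a noiseless 24-h periodic signal peaks at exactly 24 h", {
  day <- c(rep(0, 240), rep(50, 240))
  rec <- activity_recording(rep(day, 10), bin_minutes = 3)
  pg <- chi_square_periodogram(rec)
  expect_identical(pg$peak_period_h, 24)
  expect_true(pg$significant)
  expect_gt(pg$power_pct_v, 0)
})

test_that("rhythm power is invariant to count scaling and modes behave", {
  rec <- simulate_activity(activity_sim_params(seed = 21))
  pg1 <- chi_square_periodogram(rec)
  rec2 <- rec
  rec2$counts <- rec$counts * 7
  pg2 <- chi_square_periodogram(rec2)
  expect_equal(pg1$power_pct_v, pg2$power_pct_v, tolerance = 1e-12)
  expect_equal(pg1$qp, pg2$qp, tolerance = 1e-12)
  # raw mode reports 100 * Qp / N and exceeds the excess mode
  praw <- chi_square_periodogram(rec, power_mode = "raw")
  expect_gt(praw$power_pct_v, pg1$power_pct_v)
  # significance line grows with the trial period's bin count
  expect_true(all(diff(pg1$sig_line) > 0))
  expect_error(
    chi_square_periodogram(
      activity_recording(rep(1, 480 * 6), bin_minutes = 3)),
    "7 complete days")
})

test_that("bout detection matches the brute-force merger across gap lengths", {
  rec0 <- activity_recording(rep(0, 480), bin_minutes = 3)
  expect_equal(nrow(detect_bouts(rec0)), 0)

  day <- rep(0, 480)
  day[101:110] <- 20               # one 30-min suprathreshold block
  rec1 <- activity_recording(day, bin_minutes = 3)
  b1 <- detect_bouts(rec1)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$duration_min, 30)

  # two blocks separated by every gap length 3..45 min
  for (gap_bins in 1:15) {
    day <- rep(0, 480)
    day[51:60] <- 20
    day[(61 + gap_bins):(70 + gap_bins)] <- 20
    rec <- activity_recording(day, bin_minutes = 3)
    got <- detect_bouts(rec)
    want <- oracle_bouts(day >= 9, max_gap_bins = 7)
    expect_equal(got$start, want$start, info = paste("gap", gap_bins * 3))
    expect_equal(got$end, want$end, info = paste("gap", gap_bins * 3))
    expect_equal(nrow(got), if (gap_bins * 3 <= 21) 1 else 2)
  }

  # random instances against the oracle
  set.seed(7)
  for (i in 1:50) {
    counts <- rpois(200, 4)
    rec <- activity_recording(rep(counts, length.out = 480),
                              bin_minutes = 3)
    got <- detect_bouts(rec)
    want <- oracle_bouts(rec$counts >= 9, max_gap_bins = 7)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("bout detection is idempotent under zero padding", {
  set.seed(8)
  day <- rpois(480, 3)
  rec <- activity_recording(day, bin_minutes = 3)
  padded <- activity_recording(c(rep(0, 480), day, rep(0, 480)),
                               bin_minutes = 3)
  b <- detect_bouts(rec)
  bp <- detect_bouts(padded)
  expect_equal(bp$start - 480L, b$start)
  expect_equal(bp$duration_min, b$duration_min)
})

test_that("bouts are assigned to phase windows by their start bin", {
  # bout starting ZT 11.9, ending ZT 12.5 -> rest phase only
  day <- rep(0, 480)
  day[239:250] <- 20                # bins cover ZT 11.9 .. 12.5
  rec <- activity_recording(rep(day, 10), bin_minutes = 3)
  b <- detect_bouts(rec)
  expect_equal(bout_summary(b, rec, rest_phase())$bouts_per_day, 1)
  expect_equal(bout_summary(b, rec, active_phase())$bouts_per_day, 0)
  expect_equal(bout_summary(b, rec)$bouts_per_day, 1)

  # one bout per night for 10 nights
  night <- rep(0, 480); night[261:400] <- 20
  recn <- activity_recording(rep(night, 10), bin_minutes = 3)
  bn <- detect_bouts(recn)
  expect_equal(bout_summary(bn, recn, active_phase())$bouts_per_day, 1)
  expect_equal(bout_summary(bn, recn, rest_phase())$bouts_per_day, 0)
})

test_that("hourly waveforms conserve totals and group SEM is across animals", {
  rec <- activity_recording(rep(5, 4800), bin_minutes = 3)
  wf <- average_waveform(rec)
  expect_equal(wf$hourly$mean, rep(100, 24))    # 5 counts x 20 bins/h
  expect_equal(sum(wf$hourly$mean), sum(rec$counts) / rec$n_days)

  set.seed(9)
  recr <- activity_recording(rpois(4800, 6), bin_minutes = 3)
  wfr <- average_waveform(recr)
  expect_equal(sum(wfr$hourly$mean), sum(recr$counts) / recr$n_days)

  group <- average_waveform(rep(list(recr), 8))
  expect_equal(group$hourly$sem, rep(0, 24))
  expect_equal(group$n_animals, 8)
})

test_that("mean activity per hour matches hand-computed totals", {
  rec <- activity_recording(rep(5, 4800), bin_minutes = 3)
  expect_equal(mean_activity_per_hour(rec), 100)
  expect_equal(mean_activity_per_hour(
    activity_recording(rep(0, 480), bin_minutes = 3)), 0)
  # windowed variant on a day-active series
  day <- c(rep(2, 240), rep(10, 240))
  recw <- activity_recording(rep(day, 2), bin_minutes = 3)
  expect_equal(mean_activity_per_hour(recw, rest_phase()),
               sum(rep(2, 240)) / 12)
  expect_equal(mean_activity_per_hour(recw, active_phase()),
               sum(rep(10, 240)) / 12)
})

test_that("onset variability is zero for clean fixed onsets and exact for
           constructed shifts", {
  rec <- step_recording(rep(12, 8))
  for (m in c("threshold", "template")) {
    o <- estimate_onsets(rec, method = m)
    expect_equal(o$variability_min, 0, info = m)
  }
  # +/-12-min alternation balanced against a linear trend: flat fit at
  # ZT 12, deviation exactly 12 min
  shifts <- c(1, -1, -1, 1, 1, -1, -1, 1) * 0.2
  rec2 <- step_recording(12 + shifts)
  for (m in c("threshold", "template")) {
    o2 <- estimate_onsets(rec2, method = m)
    expect_equal(o2$variability_min, 12, tolerance = 1e-8, info = m)
    expect_equal(o2$slope_h_per_day, 0, tolerance = 1e-8, info = m)
  }
})

test_that("onset variability absorbs linear drift and constant shifts", {
  # steady 6-min/day drift (free-run-like): variability stays 0
  rec <- step_recording(12 + 0.1 * (0:7))
  o <- estimate_onsets(rec)
  expect_equal(o$variability_min, 0, tolerance = 1e-8)
  expect_equal(o$slope_h_per_day, 0.1, tolerance = 1e-8)
  # constant phase shift leaves variability unchanged
  shifts <- c(1, -1, -1, 1, 1, -1, -1, 1) * 0.2
  v1 <- estimate_onsets(step_recording(12 + shifts))$variability_min
  v2 <- estimate_onsets(step_recording(13 + shifts))$variability_min
  expect_equal(v1, v2, tolerance = 1e-8)
})
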