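test_that("generators are deterministic under a fixed seed", {
  a1 <- simulate_activity(activity_sim_params(seed = 61))
  a2 <- simulate_activity(activity_sim_params(seed = 61))
  expect_identical(a1$counts, a2$counts)
  s1 <- simulate_immobility(sleep_sim_params(seed = 61), n_days = 2)
  s2 <- simulate_immobility(sleep_sim_params(seed = 61), n_days = 2)
  expect_identical(s1$immobile_fraction, s2$immobile_fraction)
  r1 <- simulate_rr(rr_sim_params(seed = 61))
  r2 <- simulate_rr(rr_sim_params(seed = 61))
  expect_identical(r1$rr_ms, r2$rr_ms)
  e1 <- simulate_expression(expression_sim_params(seed = 61))
  e2 <- simulate_expression(expression_sim_params(seed = 61))
  expect_identical(e1$counts, e2$counts)
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_activity(activity_sim_params(seed = 61)))
  expect_identical(rnorm(1), before)
})

test_that("zero-amplitude unfragmented activity is statistically flat", {
  p <- activity_sim_params(rel_amplitude = 0, fragmentation_p = 0,
                           day_leak = 1, onset_jitter_sd_min = 0, seed = 62)
  rec <- simulate_activity(p, n_days = 20)
  wf <- average_waveform(rec)
  expect_lt(max(wf$hourly$mean) / min(wf$hourly$mean), 1.25)
  pg <- chi_square_periodogram(rec)
  expect_false(pg$significant)
  expect_equal(pg$power_pct_v, 0)
})

test_that("a planted 24-h rhythm is recovered within 0.2 h", {
  p <- activity_sim_params(rel_amplitude = 0.9, onset_jitter_sd_min = 5,
                           seed = 63)
  rec <- simulate_activity(p, n_days = 10)
  pg <- chi_square_periodogram(rec)
  expect_lt(abs(pg$peak_period_h - 24), 0.2)
  expect_true(pg$significant)
  # cross-check the peak against the naive fold-and-variance oracle
  grid <- seq(23, 25, by = 0.05)
  qps <- sapply(round(grid * 20), function(P) oracle_qp(rec$counts, P))
  expect_equal(grid[which.max(qps)], pg$peak_period_h, tolerance = 1e-9)
})

test_that("rhythm power rises monotonically with relative amplitude", {
  amps <- seq(0.05, 0.95, length.out = 10)
  pow <- sapply(seq_along(amps), function(i) {
    rec <- simulate_activity(
      activity_sim_params(rel_amplitude = amps[i], seed = 640 + i))
    chi_square_periodogram(rec)$power_pct_v
  })
  expect_gt(cor(amps, pow, method = "spearman"), 0.9)
})

test_that("bout counts rise with the fragmentation parameter", {
  # monotone operating range: above ~0.06/bin, suppression gaps shrink
  # below the 21-min merging threshold and bouts re-consolidate
  frag <- seq(0.005, 0.06, length.out = 10)
  bouts <- sapply(seq_along(frag), function(i) {
    mean(sapply(1:3, function(j) {
      rec <- simulate_activity(
        activity_sim_params(fragmentation_p = frag[i],
                            seed = 650 + 10 * i + j))
      bout_summary(detect_bouts(rec), rec)$bouts_per_day
    }))
  })
  expect_gt(cor(frag, bouts, method = "spearman"), 0.8)
})

test_that("immobility generator respects degenerate occupancies", {
  p0 <- sleep_sim_params(p_sleep_rest = 0, p_sleep_active = 0, seed = 66)
  tr0 <- simulate_immobility(p0, n_days = 1)
  expect_equal(nrow(score_sleep(tr0)), 0)
  p1 <- sleep_sim_params(p_sleep_rest = 1, p_sleep_active = 1, seed = 66)
  tr1 <- simulate_immobility(p1, n_days = 1)
  m1 <- bin_sleep_minutes(score_sleep(tr1), tr1)
  # occupancy ~0.996, minus the ~1.5% of sleep time in runs <= 40 s that
  # the strict duration rule discards
  expect_gt(mean(m1), 0.97)
})

test_that("RR generator reduces to closed forms without noise", {
  p <- rr_sim_params(hr_mesor_bpm = 400, hr_amplitude_bpm = 0,
                     rr_noise_sd_ms = 0, artifact_rate = 0, seed = 67)
  rr <- simulate_rr(p, n_days = 1)
  expect_lt(max(abs(rr$rr_ms - 150)), 1e-6)
})

test_that("null expression simulations give uniform p-values", {
  # pool per-gene Welch p over null replicates; KS against uniform
  ps <- unlist(lapply(1:11, function(i) {
    m <- simulate_expression(expression_sim_params(seed = 680 + i))
    norm <- normalize_housekeeping(normalize_positive(m))
    de <- differential_expression(norm)
    10^(-de$neg_log10_p)
  }))
  expect_gt(length(ps), 1000)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("cohorts have the configured structure and are reproducible", {
  cfg <- cohort_config(n_per_group = 3, n_telemetry = 2,
                       n_days_activity = 7, n_days_sleep = 4,
                       n_days_rr = 2, seed = 69)
  co <- simulate_cohort(cfg)
  expect_equal(length(co$activity), 6)
  expect_equal(length(co$immobility), 6)
  expect_equal(length(co$rr), 4)
  expect_equal(nrow(co$motor), 6)
  expect_equal(ncol(co$expression$counts), 6)
  co2 <- simulate_cohort(cfg)
  expect_identical(co$activity[[1]]$counts, co2$activity[[1]]$counts)
  expect_identical(co$motor, co2$motor)
  # generator/analyzer closure: outputs satisfy the input invariants
  for (rec in co$activity) expect_s3_class(rec, "activity_recording")
  for (tr in co$immobility)
    expect_true(all(tr$immobile_fraction >= 0 & tr$immobile_fraction <= 1))
})

test_that("motor-score coupling drives the power-errors correlation sign", {
  rs <- sapply(1:6, function(i) {
    cfg <- cohort_config(n_per_group = 8, n_telemetry = 0,
                         n_days_activity = 7, n_days_sleep = 4,
                         beam_coupling = -0.3, seed = 700 + i)
    cfg$beam_sd <- 0.4
    cfg$beam_intercept <- 16   # keep errors off the floor at this coupling
    co <- simulate_cohort(cfg)
    m <- co$motor[co$motor$group == "TRF", ]
    pearson(m$power_pct_v, m$beam_errors)$r
  })
  expect_lt(mean(rs), -0.4)
})
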