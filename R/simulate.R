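#' Parameter sets for the synthetic cohort generator
#'
#' Constructors with validation for the per-modality simulation parameters.
#' Defaults describe a mid-stage HD-model mouse under ad libitum feeding;
#' [cohort_config()] holds the group-level settings emulating a
#' time-restricted-feeding study design.
#'
#' @param mesor_rate Mean activity counts per 3-min bin (midline of the
#'   daily oscillation).
#' @param rel_amplitude Relative circadian amplitude in `[0, 1]`.
#' @param period_h Circadian period in hours. Default 24.
#' @param onset_jitter_sd_min SD of the day-to-day activity-onset jitter,
#'   minutes.
#' @param fragmentation_p Per-bin probability of toggling an
#'   activity-suppression state during the active phase (higher = more,
#'   shorter bouts).
#' @param day_leak Multiplier on the rest-phase activity rate in `[0, 1]`
#'   (inappropriate daytime activity).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A parameter object of the corresponding class.
#' @export
activity_sim_params <- function(mesor_rate = 5, rel_amplitude = 0.55,
                                period_h = 24, onset_jitter_sd_min = 34,
                                fragmentation_p = 0.10, day_leak = 0.5,
                                seed = NULL) {
  stopifnot(mesor_rate >= 0, rel_amplitude >= 0, rel_amplitude <= 1,
            period_h > 0, onset_jitter_sd_min >= 0,
            fragmentation_p >= 0, fragmentation_p <= 1,
            day_leak >= 0, day_leak <= 1)
  structure(as.list(environment()), class = "activity_sim_params")
}

#' @rdname activity_sim_params
#' @param p_sleep_rest,p_sleep_active Stationary sleep-state occupancy in
#'   the rest and active phase.
#' @param mean_episode_min Mean sleep-episode duration in minutes (must
#'   exceed 40/60 so episodes can pass the 40-s scoring rule).
#' @param wake_onset_zt Phase (ZT h) at which occupancy switches from the
#'   rest to the active level.
#' @param wake_onset_jitter_min SD of the cycle-to-cycle wake-onset jitter,
#'   minutes.
#' @export
sleep_sim_params <- function(p_sleep_rest = 0.75, p_sleep_active = 0.35,
                             mean_episode_min = 4, wake_onset_zt = 12.6,
                             wake_onset_jitter_min = 48, seed = NULL) {
  stopifnot(p_sleep_rest >= 0, p_sleep_rest <= 1,
            p_sleep_active >= 0, p_sleep_active <= 1,
            mean_episode_min > 40 / 60,
            wake_onset_zt > 0, wake_onset_zt < 24,
            wake_onset_jitter_min >= 0)
  structure(as.list(environment()), class = "sleep_sim_params")
}

#' @rdname activity_sim_params
#' @param hr_mesor_bpm,hr_amplitude_bpm Midline and half-range of the
#'   circadian heart-rate oscillation, bpm; the trough
#'   `hr_mesor_bpm - hr_amplitude_bpm` must stay positive.
#' @param acrophase_zt ZT hour of the HR peak.
#' @param rr_noise_sd_ms SD of beat-to-beat RR noise in ms (the target
#'   SDNN).
#' @param artifact_rate Fraction of beats replaced by 3-10x outliers
#'   (must be below 0.1).
#' @export
rr_sim_params <- function(hr_mesor_bpm = 406, hr_amplitude_bpm = 81,
                          acrophase_zt = 18, rr_noise_sd_ms = 13.7,
                          artifact_rate = 0.02, seed = NULL) {
  stopifnot(hr_mesor_bpm - hr_amplitude_bpm > 0, rr_noise_sd_ms >= 0,
            artifact_rate >= 0, artifact_rate < 0.1)
  structure(as.list(environment()), class = "rr_sim_params")
}

#' @rdname activity_sim_params
#' @param n_genes Number of endogenous + housekeeping genes (~100-gene
#'   panel).
#' @param housekeeping_ids Labels of the stable housekeeping genes
#'   (default: the eight-gene reference set of the striatal HD panel).
#' @param base_means Per-gene expected counts at scale factor 1; `NULL`
#'   for a deterministic log-spaced default.
#' @param dispersion Negative-binomial dispersion of endogenous and
#'   housekeeping genes.
#' @param sample_scale_sd SD of the per-sample log-normal assay-input
#'   factor.
#' @param group_log2fc Named or unnamed per-gene log2 fold change
#'   (treated vs control); housekeeping genes must have 0.
#' @param n_per_group Samples per group.
#' @export
expression_sim_params <- function(n_genes = 100,
                                  housekeeping_ids = c("Gins1", "Myh15",
                                    "Pank2", "Poc1b", "Pum2", "Slc25a15",
                                    "Ssrp1", "Utp3"),
                                  base_means = NULL, dispersion = 0.02,
                                  sample_scale_sd = 0.15,
                                  group_log2fc = NULL, n_per_group = 8,
                                  seed = NULL) {
  stopifnot(n_genes > length(housekeeping_ids), dispersion >= 0,
            sample_scale_sd >= 0, n_per_group >= 2)
  n_endo <- n_genes - length(housekeeping_ids)
  gene_ids <- c(sprintf("Gene%03d", seq_len(n_endo)), housekeeping_ids)
  if (is.null(base_means)) {
    # deterministic log-spaced means, 100-5000 counts
    base_means <- rep(exp(seq(log(100), log(5000), length.out = 10)),
                      length.out = n_genes)
  }
  stopifnot(length(base_means) == n_genes, all(base_means > 0))
  if (is.null(group_log2fc)) group_log2fc <- numeric(n_genes)
  stopifnot(length(group_log2fc) == n_genes)
  hk_idx <- match(housekeeping_ids, gene_ids)
  if (any(group_log2fc[hk_idx] != 0))
    stop_data("housekeeping genes must have group_log2fc = 0")
  structure(list(n_genes = n_genes, gene_ids = gene_ids,
                 housekeeping_ids = housekeeping_ids,
                 base_means = base_means, dispersion = dispersion,
                 sample_scale_sd = sample_scale_sd,
                 group_log2fc = group_log2fc, n_per_group = n_per_group,
                 seed = seed),
            class = "expression_sim_params")
}

# Smooth active-phase indicator in [0, 1] at absolute hours `t_h`, with
# logistic edges (`edge_h` ~ 30-min transition), onsets jittered per cycle.
smooth_active <- function(t_h, n_cycles, period_h, onset_jitter_h,
                          edge_h = 0.125) {
  a <- numeric(length(t_h))
  for (d in seq_len(n_cycles + 1L) - 1L) {
    on_d <- d * period_h + period_h / 2 +
      if (d < n_cycles) onset_jitter_h[d + 1L] else 0
    off_d <- (d + 1) * period_h
    a <- a + stats::plogis((t_h - on_d) / edge_h) -
      stats::plogis((t_h - off_d) / edge_h)
  }
  pmin(pmax(a, 0), 1)
}

#' Simulate a binned locomotor activity recording
#'
#' Counts are Poisson per 3-min bin with rate `mesor_rate * (1 +
#' rel_amplitude * s(t)) * leak(t) * supp(t)`, where `s` is a smoothed
#' square wave (logistic edges, ~30-min transition, in `[-1, 1]`) whose
#' nightly onset is jittered by `N(0, onset_jitter_sd_min^2)`; `leak`
#' ramps the rest-phase rate down by `day_leak`; and `supp` is a two-state
#' suppression process toggling with probability `fragmentation_p` per
#' active-phase bin (suppressed bins run at 10% rate), which fragments the
#' night into discrete bouts. The plateau shape (rather than a sinusoid)
#' matches nocturnal rodent cage activity and gives the onset estimator a
#' well-defined rising edge.
#'
#' @param params An [activity_sim_params()].
#' @param n_days Number of days. Default 10.
#' @param bin_minutes Bin width. Default 3.
#' @param schedule,animal_id Passed to [activity_recording()].
#' @return An [activity_recording()].
#' @export
simulate_activity <- function(params, n_days = 10, bin_minutes = 3,
                              schedule = light_schedule(),
                              animal_id = "sim") {
  stopifnot(inherits(params, "activity_sim_params"))
  with_seed(params$seed, {
    bins_per_day <- 24 * 60 / bin_minutes
    n_bins <- n_days * bins_per_day
    t_h <- (seq_len(n_bins) - 0.5) * bin_minutes / 60
    n_cycles <- ceiling(n_days * 24 / params$period_h)
    jit_h <- stats::rnorm(n_cycles, 0, params$onset_jitter_sd_min / 60)
    A <- smooth_active(t_h, n_cycles, params$period_h, jit_h)
    s <- 2 * A - 1
    leak <- params$day_leak + (1 - params$day_leak) * A
    # suppression chain, evaluated in active bins, reset at each onset;
    # exits suppression at twice the entry rate, so nights keep a ~2/3
    # active duty cycle while fragmentation_p sets how often bouts break
    supp <- numeric(n_bins) + 1
    state <- 1
    u <- stats::runif(n_bins)
    prev_active <- FALSE
    for (i in seq_len(n_bins)) {
      act <- A[i] > 0.5
      if (act && !prev_active) state <- 1          # new night starts unsuppressed
      if (act) {
        p_sw <- if (state == 1) params$fragmentation_p
                else min(1, 2 * params$fragmentation_p)
        if (u[i] < p_sw) state <- 1 - state
      }
      supp[i] <- if (act && state == 0) 0.1 else 1
      prev_active <- act
    }
    rate <- params$mesor_rate * (1 + params$rel_amplitude * s) * leak * supp
    counts <- stats::rpois(n_bins, pmax(rate, 0))
    activity_recording(counts, bin_minutes = bin_minutes,
                       schedule = schedule, animal_id = animal_id)
  })
}

#' Simulate a per-second immobility trace
#'
#' A two-state (sleep/wake) chain with geometric dwell times: the sleep
#' exit rate is `1 / (mean_episode_min * 60)` per second and the entry
#' rate is set so the stationary sleep occupancy equals `p_sleep_rest`
#' before the (jittered) wake-onset phase and `p_sleep_active` after it,
#' within each cycle. Dwell times are truncated and redrawn at phase
#' boundaries, which by memorylessness is exactly the per-second chain.
#' Sleep seconds emit immobile fractions in `[0.955, 1]`, wake seconds in
#' `[0.2, 0.9]`, so the 95%-area scoring threshold is genuinely exercised.
#'
#' @param params A [sleep_sim_params()].
#' @param n_days Number of days. Default 5.
#' @param schedule,animal_id Passed to [immobility_trace()].
#' @return An [immobility_trace()].
#' @export
simulate_immobility <- function(params, n_days = 5,
                                schedule = light_schedule(),
                                animal_id = "sim") {
  stopifnot(inherits(params, "sleep_sim_params"))
  with_seed(params$seed, {
    total_s <- n_days * 86400L
    q_exit <- 1 / (params$mean_episode_min * 60)
    wake_jit <- stats::rnorm(n_days, 0, params$wake_onset_jitter_min / 60)
    wake_s <- pmin(pmax((params$wake_onset_zt + wake_jit) * 3600, 1),
                   86399) + (seq_len(n_days) - 1) * 86400
    boundaries <- sort(unique(c((seq_len(n_days) - 1) * 86400, wake_s,
                                total_s)))
    occupancy_at <- function(t) {
      d <- floor(t / 86400) + 1
      if (t >= wake_s[min(d, n_days)]) params$p_sleep_active
      else params$p_sleep_rest
    }
    asleep <- logical(total_s)
    t <- 0; state <- 0   # start awake at ZT 0
    while (t < total_s) {
      p_occ <- occupancy_at(t)
      rate <- if (state == 1) q_exit else {
        if (p_occ >= 1) 1 else if (p_occ <= 0) 0 else
          q_exit * p_occ / (1 - p_occ)
      }
      dur <- if (rate <= 0) Inf else if (rate >= 1) 1 else
        stats::rgeom(1, rate) + 1
      next_b <- boundaries[boundaries > t][1]
      t_end <- min(t + dur, next_b, total_s)
      if (state == 1 && t_end > t) asleep[(t + 1):t_end] <- TRUE
      if (t + dur <= next_b) state <- 1 - state   # real transition
      t <- t_end
    }
    frac <- numeric(total_s)
    frac[asleep] <- stats::runif(sum(asleep), 0.955, 1)
    frac[!asleep] <- stats::runif(sum(!asleep), 0.2, 0.9)
    immobility_trace(frac, schedule = schedule, animal_id = animal_id)
  })
}

#' Simulate a telemetry RR-interval series
#'
#' Instantaneous HR follows `mesor + amplitude * cos(2 * pi * (ZT -
#' acrophase) / 24)` bpm. Noise-free beat times are obtained by inverting
#' the cumulative beat count (the integral of HR), giving intervals of
#' `60000 / HR` ms; zero-mean Gaussian noise of SD `rr_noise_sd_ms` is
#' added, and a fraction `artifact_rate` of beats is replaced by 3-10x
#' outliers (attribute `artifact` marks them, so filter performance can be
#' measured against ground truth).
#'
#' @param params An [rr_sim_params()].
#' @param n_days Number of days. Default 1.
#' @param schedule,animal_id Passed to [rr_series()].
#' @return An [rr_series()] with logical attribute `artifact`.
#' @export
simulate_rr <- function(params, n_days = 1, schedule = light_schedule(),
                        animal_id = "sim") {
  stopifnot(inherits(params, "rr_sim_params"))
  with_seed(params$seed, {
    total_s <- n_days * 86400
    grid <- seq(0, total_s, by = 1)
    hr <- params$hr_mesor_bpm + params$hr_amplitude_bpm *
      cos(2 * pi * (grid / 3600 - params$acrophase_zt) / 24)
    beats_cum <- c(0, cumsum((hr[-1] + hr[-length(hr)]) / 2 / 60))
    m <- floor(beats_cum[length(beats_cum)])
    t_beat <- stats::approx(beats_cum, grid, xout = seq_len(m))$y
    rr <- diff(c(0, t_beat)) * 1000
    rr <- rr + stats::rnorm(length(rr), 0, params$rr_noise_sd_ms)
    artifact <- stats::runif(length(rr)) < params$artifact_rate
    rr[artifact] <- rr[artifact] * stats::runif(sum(artifact), 3, 10)
    rr <- pmax(rr, 1)
    out <- rr_series(rr, schedule = schedule, animal_id = animal_id)
    attr(out, "artifact") <- artifact
    out
  })
}

#' Simulate a two-group expression count matrix
#'
#' Endogenous and housekeeping genes are negative-binomial with mean
#' `base_mean * scale_s * 2^(log2fc)` in the treated group (`log2fc = 0`
#' for housekeeping genes), where `scale_s` is a per-sample log-normal
#' assay-input factor. Six positive-control probes follow a fixed
#' titration (Poisson, technical noise only) scaled by the same factor,
#' so positive-control normalization can recover `scale_s`.
#'
#' @param params An [expression_sim_params()].
#' @param group_labels Labels for control and treated group.
#' @return An [expression_matrix()] with attribute `scale_factors`.
#' @export
simulate_expression <- function(params,
                                group_labels = c("ad_lib", "TRF")) {
  stopifnot(inherits(params, "expression_sim_params"))
  with_seed(params$seed, {
    n <- params$n_per_group
    groups <- rep(group_labels, each = n)
    n_samples <- 2 * n
    sf <- exp(stats::rnorm(n_samples, 0, params$sample_scale_sd))
    pos_means <- c(POS_A = 30000, POS_B = 12000, POS_C = 5000,
                   POS_D = 2000, POS_E = 800, POS_F = 300)
    treated <- groups == group_labels[2]
    mu <- outer(params$base_means, sf) *
      2^(params$group_log2fc %o% as.numeric(treated))
    size <- if (params$dispersion > 0) 1 / params$dispersion else Inf
    counts <- matrix(
      if (params$dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = size)
      else stats::rpois(length(mu), mu),
      nrow = nrow(mu))
    pos_counts <- matrix(
      stats::rpois(length(pos_means) * n_samples, outer(pos_means, sf)),
      nrow = length(pos_means))
    all_counts <- rbind(counts, pos_counts)
    rownames(all_counts) <- c(params$gene_ids, names(pos_means))
    colnames(all_counts) <- sprintf("%s_%02d", groups,
                                    c(seq_len(n), seq_len(n)))
    out <- expression_matrix(all_counts, groups,
                             housekeeping = params$housekeeping_ids,
                             positive = names(pos_means))
    attr(out, "scale_factors") <- sf
    out
  })
}

#' Default study design for the synthetic cohort
#'
#' Two groups of 8 animals (7 with telemetry), 10 d of activity, 5
#' sleep-wake cycles, 2 d of telemetry, one expression matrix, and motor
#' scores linearly coupled to each animal's *realized* rhythm power. The
#' treated-group parameters encode the intervention phenotype: higher,
#' better-consolidated nocturnal activity (higher amplitude, less
#' fragmentation and daytime leak, tighter onsets), earlier and more
#' precise wake onset, larger HR amplitude and higher SDNN.
#'
#' @param n_per_group Animals per group. Default 8.
#' @param n_telemetry Animals per group with telemetry. Default 7.
#' @param n_days_activity,n_days_sleep,n_days_rr Recording lengths.
#' @param beam_coupling Errors per %V of realized rhythm power (negative:
#'   stronger rhythms, fewer errors). Default -0.12.
#' @param latency_coupling Seconds on the rotarod per %V. Default 6.
#' @param seed Cohort-level seed; per-animal substreams derive from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 8, n_telemetry = 7,
                          n_days_activity = 10, n_days_sleep = 5,
                          n_days_rr = 2, beam_coupling = -0.12,
                          latency_coupling = 6, seed = 1L) {
  list(
    n_per_group = n_per_group, n_telemetry = n_telemetry,
    n_days_activity = n_days_activity, n_days_sleep = n_days_sleep,
    n_days_rr = n_days_rr,
    beam_coupling = beam_coupling, latency_coupling = latency_coupling,
    beam_intercept = 10, beam_sd = 0.8,
    latency_intercept = 120, latency_sd = 45,
    groups = list(
      ad_lib = list(
        activity = activity_sim_params(),
        sleep = sleep_sim_params(),
        rr = rr_sim_params()
      ),
      TRF = list(
        activity = activity_sim_params(mesor_rate = 9, rel_amplitude = 0.85,
                                       onset_jitter_sd_min = 20,
                                       fragmentation_p = 0.04,
                                       day_leak = 0.35),
        sleep = sleep_sim_params(p_sleep_rest = 0.70, p_sleep_active = 0.25,
                                 wake_onset_zt = 11.9,
                                 wake_onset_jitter_min = 24),
        rr = rr_sim_params(hr_mesor_bpm = 424, hr_amplitude_bpm = 98,
                           rr_noise_sd_ms = 17)
      )
    ),
    expression = expression_sim_params(
      group_log2fc = c(rep(0.9, 5), rep(-0.6, 5), numeric(90))),
    seed = seed
  )
}

#' Simulate a full study cohort
#'
#' Generates, per animal: an activity recording, an immobility trace, an
#' RR series (telemetry subset only) and motor scores, plus one
#' expression matrix for the cohort. Motor scores are linear in the
#' animal's realized (periodogram-measured) rhythm power plus Gaussian
#' noise, which exercises the downstream power-vs-performance correlation
#' analysis without asserting any biology. All randomness derives from
#' `config$seed` through per-animal substream seeds, so the cohort is
#' reproducible and any single animal can be regenerated.
#'
#' @param config A [cohort_config()].
#' @return A `cohort`: per-group lists of `activity`, `immobility`, `rr`,
#'   data frame `motor`, and `expression`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  groups <- names(config$groups)
  counter <- 0L
  cohort <- list(groups = groups, activity = list(), immobility = list(),
                 rr = list(), motor = NULL, config = config)
  motor_rows <- list()
  for (g in groups) {
    gp <- config$groups[[g]]
    for (i in seq_len(config$n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      ap <- gp$activity; ap$seed <- substream_seed(config$seed, counter)
      sp <- gp$sleep; sp$seed <- substream_seed(config$seed, counter + 1L)
      counter <- counter + 3L
      cohort$activity[[id]] <-
        simulate_activity(ap, n_days = config$n_days_activity,
                          animal_id = id)
      cohort$immobility[[id]] <-
        simulate_immobility(sp, n_days = config$n_days_sleep,
                            animal_id = id)
      if (i <= config$n_telemetry) {
        rp <- gp$rr; rp$seed <- substream_seed(config$seed, counter - 1L)
        cohort$rr[[id]] <- simulate_rr(rp, n_days = config$n_days_rr,
                                       animal_id = id)
      }
      power <- chi_square_periodogram(cohort$activity[[id]])$power_pct_v
      ms <- with_seed(substream_seed(config$seed, 100000L + counter), {
        c(beam = max(0, config$beam_intercept +
                       config$beam_coupling * power +
                       stats::rnorm(1, 0, config$beam_sd)),
          latency = max(0, config$latency_intercept +
                          config$latency_coupling * power +
                          stats::rnorm(1, 0, config$latency_sd)))
      })
      motor_rows[[id]] <- data.frame(
        animal_id = id, group = g, power_pct_v = power,
        beam_errors = unname(ms["beam"]),
        latency_to_fall_s = unname(ms["latency"]))
    }
  }
  cohort$motor <- do.call(rbind, c(motor_rows, make.row.names = FALSE))
  expr_params <- config$expression
  expr_params$seed <- substream_seed(config$seed, 900000L)
  expr_params$n_per_group <- config$n_per_group
  cohort$expression <- simulate_expression(expr_params,
                                           group_labels = groups)
  class(cohort) <- "cohort"
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %s; %d activity recordings, %d immobility traces, %d RR series\n",
    paste(x$groups, collapse = " vs "), length(x$activity),
    length(x$immobility), length(x$rr)))
  invisible(x)
}
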