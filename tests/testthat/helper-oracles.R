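# Independent brute-force oracles, deliberately naive implementations that
# share no code with the package internals.

# Fold-and-variance periodogram statistic at a single trial period P (bins),
# using the K complete cycles available.
oracle_qp <- function(x, P) {
  K <- length(x) %/% P
  xs <- x[seq_len(K * P)]
  m <- mean(xs)
  col_means <- sapply(seq_len(P), function(h) mean(xs[seq(h, K * P, by = P)]))
  K * sum((col_means - m)^2) / (sum((xs - m)^2) / (K * P))
}

# Exhaustive bout merger: active runs, then repeatedly merge the pair of
# neighbouring runs with the smallest gap while it is <= max_gap bins.
oracle_bouts <- function(active, max_gap_bins) {
  runs <- list()
  i <- 1
  n <- length(active)
  while (i <= n) {
    if (active[i]) {
      j <- i
      while (j < n && active[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j + 1)  # half-open
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) return(data.frame(start = integer(0), end = integer(0)))
  repeat {
    merged <- FALSE
    if (length(runs) >= 2) {
      for (k in seq_len(length(runs) - 1)) {
        gap <- runs[[k + 1]][1] - runs[[k]][2]
        if (gap <= max_gap_bins) {
          runs[[k]] <- c(runs[[k]][1], runs[[k + 1]][2])
          runs[[k + 1]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  data.frame(start = sapply(runs, `[`, 1), end = sapply(runs, `[`, 2))
}

# Brute-force sleep run scan over every (start, length) pair.
oracle_sleep_runs <- function(frac, thr = 0.95, min_s = 40) {
  immobile <- frac >= thr
  n <- length(immobile)
  out <- data.frame(start_s = integer(0), end_s = integer(0),
                    duration_s = integer(0))
  i <- 1
  while (i <= n) {
    if (immobile[i]) {
      j <- i
      while (j < n && immobile[j + 1]) j <- j + 1
      if ((j - i + 1) > min_s)
        out <- rbind(out, data.frame(start_s = i - 1, end_s = j,
                                     duration_s = j - i + 1))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Build a recording with activity 100 counts/bin from `onset_zt` to ZT 24
# on each day, 0 elsewhere (3-min bins).
step_recording <- function(onsets_zt, high = 100) {
  counts <- unlist(lapply(onsets_zt, function(o) {
    day <- numeric(480)
    day[seq.int(round(o * 20) + 1L, 480)] <- high
    day
  }))
  activity_recording(counts, bin_minutes = 3)
}

# Build an immobility trace asleep (fraction 1) from ZT 0 until `offset_zt`
# each day, awake (fraction 0) otherwise.
step_trace <- function(offsets_zt) {
  frac <- unlist(lapply(offsets_zt, function(o) {
    day <- numeric(86400)
    day[seq_len(round(o * 3600))] <- 1
    day
  }))
  immobility_trace(frac)
}
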