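---
title: "Methods: rhythm, sleep, HRV and expression-panel analysis in chronofeed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm, sleep, HRV and expression-panel analysis in chronofeed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronofeed)
```

`chronofeed` analyses the five data modalities of a time-restricted-feeding
(TRF) circadian intervention study — cage actigraphy, immobility-defined
sleep, telemetric heart-rate/temperature, a targeted expression panel and
motor scores — and provides a synthetic cohort generator so that every
stage can be validated end to end. This vignette documents the models,
their assumptions, the parameters that matter, and the design decisions
taken where the underlying methods literature (or the commercial tools the
field uses) leaves the procedure unspecified.

## Time conventions

All analyses run in zeitgeber time (ZT): ZT 0 is lights-on and, under the
12/12 h light/dark cycle assumed by default, ZT 12 is lights-off. Bins are
half-open `[start, start + bin)` so no sample is counted twice at the
ZT 0/24 boundary, and analysis days are delimited at ZT 0, which keeps a
nocturnal animal's active phase (ZT 12–24) inside a single analysis day.
Readers reject records that violate the container invariants (negative
counts, incomplete days, non-uniform bins) rather than coercing them; a
missing activity bin is an error naming the missing timestamp, with an
opt-in zero-fill that warns.

## χ² periodogram and rhythm power

For a trial period of $P$ bins, the recording's first $KP$ bins (its $K$
complete cycles; the trailing remainder is discarded per trial period) are
folded into $P$ columns, and

$$Q_P = \frac{K \sum_h (\bar x_h - \bar x)^2}{\hat\sigma^2}, \qquad
\hat\sigma^2 = \frac{1}{KP}\sum_i (x_i - \bar x)^2 .$$

Under the null of no periodicity $Q_P \sim \chi^2_{P-1}$ approximately,
which gives the significance line at level $\alpha = 0.001$. The trial
grid covers every whole-bin period with 20 h ≤ P ≤ 28 h (0.05-h steps at
3-min bins, 161 periods).

**Multiplicity.** A per-period $\chi^2_{0.999}$ line controls the error of
a *single* trial period, but the scan reports its *peak*. Simulating
non-rhythmic recordings (i.i.d. Poisson counts, 10 d of 3-min bins) shows
the peak crossing a per-period line in roughly 6–7% of null series —
sixty-fold above the nominal α. The default line is therefore
Bonferroni-adjusted across the trial-period grid
(`multiplicity = "bonferroni"`), which the test suite verifies empirically
to hold the peak-level false-positive rate below 1% over 1000 null
series. `multiplicity = "none"` reproduces the conventional per-period
line drawn by classic actigraphy software; on strongly rhythmic data the
two differ by well under one percentage point of %V.

**Rhythm power.** Commercial periodogram tools print "power (%V)" without
a formula. We define it as
$100\,(Q_{peak} - \text{sig line}_{peak})/N$, clamped at 0 when the peak
fails the line — this makes power scale-free (multiplying all counts by a
constant changes nothing, which the suite asserts), zero for arrhythmic
records, and on the 30–60 %V scale reported for mice. The alternative raw
reading $100\,Q_{peak}/N$ is available via `power_mode = "raw"`.

## Bouts and onsets

A bin is active when its rate meets 3 counts/min (converted to counts/bin,
so the threshold is a rate, not a per-bin constant); active runs separated
by sub-threshold gaps of at most 21 min merge into one maximal bout. The
merger is verified against an exhaustive brute-force implementation over
every gap length from 3 to 45 min and on random series. Bouts are
assigned to phase windows by their start bin — unambiguous, and consistent
with per-day counting when a bout straddles lights-off.

**Onset detection.** The tools used in practice do not document their
onset algorithm. We ship two detectors. The default threshold detector
smooths counts with a 15-min running mean, places a threshold 30% of the
way from the rest-phase level (median smoothed activity, ZT 2–10) to the
active-phase level (ZT 13–23), and takes the earliest time in ZT 8–16
whose smoothed activity reaches the threshold, sustains it for 30 min of
raw counts, and follows 60 min below it. This locks onto the first
sustained bout of the night, which matters because realistic records
contain within-night lulls: a step-template correlator (also provided,
`method = "template"`) develops a plateau across such lulls and drifts
toward later bouts. Onset variability is the mean absolute deviation of
daily onsets from their least-squares line over days — the line absorbs
steady drift (a free-running period), and the absolute deviation is used
because signed least-squares residuals average to zero by construction.
On generated cohorts the threshold detector recovers a planted 15-min
onset jitter at the half-normal expectation (≈12 min) within the
tolerances the test suite asserts, with an intrinsic noise floor of
roughly 8–10 min from bout-timing randomness.

## Immobility-defined sleep

Sleep episodes are maximal runs of seconds with at least 95% of the
animal's area immobile, lasting strictly more than 40 s (`> 40`, not
`≥`; the boundary is tested). Scoring is verified identical to a
brute-force run scan on 1000 random traces and is monotone in both
thresholds. Minute binning marks a minute asleep when at least 30 of its
60 s fall inside episodes (majority rule; the exported 1-min format never
states its rule, and majority minimises discretisation bias — an
any-overlap mode exists). Phase totals are computed per sleep–wake cycle
and averaged over the 3rd and 4th cycles of a ≥5-cycle recording, the
convention for letting animals acclimate; rest + active totals equal the
24-h total exactly.

**Wake onset.** The sleep-to-wake transition is located per cycle by a
CUSUM changepoint on the minute-binned sleep series within ZT 6–18: the
minute maximising the cumulative sum of mean-centred sleep indicators,
i.e. the maximum-contrast split of high sleep occupancy before versus low
after. We chose this over "end of the last consolidated rest-phase
episode" (also available, `method = "last_episode"`) because the episode
rule is hard-coupled to the ZT 12 boundary: when the true transition
drifts past lights-off it reports the boundary, not the transition, and
its cycle-to-cycle deviation stops responding to the actual wake-time
variability the metric is supposed to measure. The changepoint estimator
recovers planted 20- and 48-min wake jitter near the half-normal
expectation (verified in the test suite), with a floor of ~13 min set by the
raggedness of scored sleep near the transition.

## Heart-rate variability

RR intervals pass a two-stage filter: a physiological band of 50–250 ms
(heart rates 240–1200 bpm; mice at a 400-bpm mesor with an 80-bpm
circadian amplitude reach ~185 ms at the trough, so a tighter ceiling
would clip genuine beats), then rejection of beats deviating more than 4
robust SDs (MAD) from a 31-beat rolling median. Retained fraction is
reported; below 50% is an error. NN intervals are summarised in 20-s
segments (instantaneous HR = 60000/mean NN), averaged into ZT-hour bins
folded across days. SDNN per hour is the **population** SD of all NN
intervals in that hour — "SD of all NN intervals", not the SD of segment
means; a sample-SD mode exists. The HR rhythm amplitude is the max/min
ratio of the 24 hourly means; it refuses to compute when any hour is
missing (imputing would manufacture spurious extremes), and hourly
binning attenuates a cosine's true ratio by under 2%, which the tests
account for. With a planted 15-ms beat noise SD the pipeline recovers
24-h SDNN within 1 ms; the residual ~0.4 ms excess comes from the
within-hour drift of the circadian RR baseline, which is part of any
hourly SDNN.

## Expression panel

Counts are scaled per sample by the positive-control sum ratio (to the
cohort geometric mean), then by the housekeeping geometric mean (to the
cohort mean of per-sample geometric means). After normalization the
housekeeping geometric mean is *identical* across samples to machine
precision — the suite asserts this fixed point — and relative profiles
and fold changes are exactly invariant to rescaling any single sample.
(Exact restoration of the absolute counts is impossible with any
data-dependent cohort target, since scaling one sample moves the common
target; only the shared reporting scale shifts, never a between-sample
ratio.) Differential expression is the log₂ ratio of normalized group
means with a per-gene Welch t, reported as −log₁₀ p with no
multiple-testing correction by default, matching how targeted-panel
reports print raw p (a Benjamini–Hochberg column is optional). Ranking
is by p, ties by |log₂FC| then gene id, deterministically.

## Group statistics

The summary-based t, $t = (m_1 - m_2)/\sqrt{sem_1^2 + sem_2^2}$ with
$df = n_1 + n_2 - 2$, equals the pooled two-sample t at equal group sizes
(asserted to 1e−12 against the raw-data route) and reproduces published
t values from printed means ± SEM to ~1% — the limit set by input
rounding. The repeated-measures ANOVA is the standard mixed design
(between = treatment, within = time) via an `Error(animal)` stratum on a
balanced table; missing cells are an error, and sphericity-uncorrected F
is the default with Greenhouse–Geisser correction behind a flag, since
published df follow the uncorrected convention. Holm–Šidák is the
step-down rule $1-(1-p_{(i)})^{m-i+1}$ with cumulative-max monotonicity
and the sequential stopping rule. The two-sample t's type-I error is
verified within [0.045, 0.055] over 10,000 null replicates. A
noncentral-t observed-power helper is included but is deliberately not
claimed equivalent to any commercial tool's undocumented "observed power"
column.

## The synthetic cohort generator

The generator is a first-order circadian model of each modality, built to
exercise the analyses' assumptions, not to be physiologically complete:

- **Activity**: Poisson counts per 3-min bin with rate
  $\text{mesor} \times (1 + a\,s(t)) \times \text{leak}(t) \times \text{supp}(t)$.
  $s$ is a smoothed square wave (logistic edges, ~30-min transition) —
  plateau-like like real nocturnal cage activity, and with a defined
  rising edge for the onset estimator — whose nightly onset is jittered
  $N(0, \sigma^2_{onset})$. `day_leak` raises rest-phase activity
  (daytime restlessness); a two-state suppression process
  (entry probability `fragmentation_p` per active bin, exit at twice
  that rate, suppressed bins at 10% rate) breaks the night into bouts at
  a ~2/3 active duty cycle. The asymmetric exit rate is deliberate: a
  symmetric toggle pins every night at 50% suppression, which makes
  onset timing nearly unrecoverable by *any* estimator — unlike real
  records of comparable bout counts, on which the field's standard tools
  measure 16–27 min onset variability. Bout counts increase with
  `fragmentation_p` through its monotone operating range (≤ ~0.06/bin);
  beyond it the suppression gaps fall under the 21-min merge threshold
  and bouts re-consolidate, which is documented rather than hidden.
- **Sleep**: a two-state sleep/wake chain at 1 Hz with geometric dwell
  times; the sleep-entry rate is set from the target occupancy (0.75
  rest / 0.35 active by default, jittered wake-onset phase at ZT 12.6),
  and dwell times are truncated and redrawn at phase boundaries, which by
  memorylessness is exactly the per-second chain. Sleep seconds emit
  immobile fractions in [0.955, 1], wake in [0.2, 0.9], so the 95%-area
  threshold is genuinely exercised rather than handed a binary.
- **RR**: instantaneous HR is a cosine (406-bpm mesor, 81-bpm amplitude,
  acrophase ZT 18 by default); noise-free beat times invert the
  integrated HR, beat noise is Gaussian (SD = target SDNN), and a small
  fraction of beats becomes 3–10× outliers, flagged so filter performance
  is measurable against ground truth.
- **Expression**: negative-binomial counts (dispersion 0.02) under
  per-sample log-normal input factors, eight housekeeping genes fixed at
  log₂FC 0, six Poisson positive-control probes on a fixed titration.
- **Cohort**: two groups (8 animals, 7 with telemetry, mirroring the
  study design), per-animal substream seeds derived from one cohort seed
  by a counter scheme (reproducible and individually regenerable), and
  motor scores linear in each animal's *realized* periodogram power plus
  noise — exercising the power-versus-performance correlation analysis
  without asserting any biology.

Default group parameter sets (`cohort_config()`) encode the intervention
phenotype — treated animals get higher amplitude, less fragmentation and
daytime leak, tighter onsets, an earlier and more precise wake onset,
larger HR amplitude and higher SDNN — with magnitudes chosen once to sit
in the ranges published for mid-stage HD-model mice and their treated
counterparts.

What the generator does **not** contain: ultradian harmonics, torpor,
food-anticipatory activity, non-stationary episode structure, frequency
structure in HRV (the noise is white), or probe-level background in the
panel. Passing tests therefore demonstrate correctness of the estimators
under first-order circadian structure, not robustness to every feature of
real recordings.

## Numerical choices and degenerate inputs

Ties in onset search break to the earliest time; the periodogram peak is
the first maximum on the grid. Constant responses short-circuit the RM
ANOVA to F = 0 rather than 0/0. Zero SEMs with equal means give t = 0 by
convention, with unequal means an error. Zero-variance correlation input
is an error, not NA. The CUSUM wake estimator requires at least two
detectable cycles. All generators restore the caller's RNG state and are
bit-identical under a fixed seed.

Problem sizes used by the test and acceptance suites — 10-d recordings at
3-min bins, 5-cycle sleep traces, 1-d RR series (~580k beats), 1000-series
null calibrations, 10,000-replicate type-I checks, 100-cohort recovery
runs — were chosen so the full suite completes in about two minutes on a
single CPU while keeping Monte-Carlo error well inside every asserted
tolerance.

## Known limitations

The onset and wake estimators have intrinsic noise floors (~8–10 and
~13 min respectively under the default generator), so planted jitters
well below those floors are reported at the floor, not at zero. The
periodogram's χ² null is approximate for very short records (< 7 d is
refused by default). The RM ANOVA handles only complete balanced designs
by design — no imputation. The expression module does not model probe
background subtraction, and its p-values assume per-gene normality of
normalized intensities, adequate at panel count depths but not for
near-zero counts.
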