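#' Group summary (mean, SEM, n)
#'
#' @param label Group label.
#' @param mean Group mean.
#' @param sem Standard error of the mean (must be non-negative).
#' @param n Group size (at least 2).
#' @return A `group_summary` object.
#' @export
group_summary <- function(label, mean, sem, n) {
  stopifnot(sem >= 0, n >= 2)
  structure(list(label = label, mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample t test from printed summary statistics
#'
#' Recomputes the two-sample t statistic from group means, SEMs and sizes,
#' as published results report them: `t = (m1 - m2) / sqrt(sem1^2 +
#' sem2^2)` with `df = n1 + n2 - 2` (the pooled convention; at equal group
#' sizes this is numerically identical to the pooled-variance t on the raw
#' data). Agreement with published t values is limited to about 1% by the
#' rounding of the printed means and SEMs.
#'
#' @param g1,g2 [group_summary()] objects.
#' @return A `test_result`: `statistic`, `df`, `p_value`, `test_name`.
#' @export
t_from_summary <- function(g1, g2) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  se <- sqrt(g1$sem^2 + g2$sem^2)
  if (se == 0) {
    if (g1$mean == g2$mean) {
      tval <- 0
    } else {
      stop_data("zero SEM in both groups with unequal means: t undefined")
    }
  } else {
    tval <- (g1$mean - g2$mean) / se
  }
  df <- g1$n + g2$n - 2L
  test_result(tval, df, 2 * stats::pt(-abs(tval), df),
              sprintf("summary t (%s vs %s)", g1$label, g2$label))
}

#' Two-sample test on raw values
#'
#' Classical two-sample t test (pooled or Welch) or the Mann-Whitney
#' rank-sum alternative used when distributional screens fail.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param mode `"pooled"` (default), `"welch"` or `"rank"`.
#' @return A `test_result`.
#' @export
t_two_sample <- function(x, y, mode = c("pooled", "welch", "rank")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (mode == "rank") {
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    return(test_result(unname(ht$statistic), NA_real_, ht$p.value,
                       "Mann-Whitney rank sum"))
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(test_result(0, length(x) + length(y) - 2L, 1, "two-sample t"))
    stop_data("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = (mode == "pooled"))
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              if (mode == "pooled") "two-sample t (pooled)"
              else "two-sample t (Welch)")
}

test_result <- function(statistic, df, p_value, test_name) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 test_name = test_name),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df_txt <- if (all(is.na(x$df))) "" else
    paste0("(", paste(round(x$df, 1), collapse = ","), ")")
  cat(sprintf("%s: statistic%s = %.3f, p = %.4g\n",
              x$test_name, df_txt, x$statistic, x$p_value))
  invisible(x)
}

#' Two-way repeated-measures ANOVA (treatment x time)
#'
#' Mixed-design ANOVA with a between-subject factor (`treatment`) and a
#' within-subject repeated factor (`time`), as used for hourly activity,
#' sleep, CBT, HR and HRV waveforms. Fitted with `stats::aov` using an
#' `Error(animal)` stratum on a balanced design (every animal at every
#' time point; missing cells are an error, no imputation). F values carry
#' the conventional (df effect, df error) pairs; the default F is
#' sphericity-uncorrected, with a Greenhouse-Geisser-corrected p available.
#'
#' @param data Long-format data frame.
#' @param response,animal,treatment,time Column names.
#' @param gg_correction Also report Greenhouse-Geisser adjusted p-values
#'   for the within-subject effects. Default FALSE.
#' @return An `rm_anova` object: list of `test_result`s `treatment`,
#'   `time`, `interaction`.
#' @export
two_way_rm_anova <- function(data, response = "value", animal = "animal",
                             treatment = "treatment", time = "time",
                             gg_correction = FALSE) {
  d <- data.frame(
    y = data[[response]],
    animal = factor(data[[animal]]),
    treatment = factor(data[[treatment]]),
    time = factor(data[[time]])
  )
  tab <- table(d$animal, d$time)
  if (any(tab != 1))
    stop_data("design not balanced: every animal must be measured exactly ",
              "once at every time point (no imputation is performed)")
  if (stats::var(d$y) == 0) {
    zero <- function(df) test_result(0, df, 1, "RM ANOVA (constant response)")
    n_an <- nlevels(d$animal); n_t <- nlevels(d$time)
    out <- list(
      treatment = zero(c(1, n_an - 2)),
      time = zero(c(n_t - 1, (n_t - 1) * (n_an - 2))),
      interaction = zero(c(n_t - 1, (n_t - 1) * (n_an - 2))))
    class(out) <- "rm_anova"
    return(out)
  }
  fit <- stats::aov(y ~ treatment * time + Error(animal), data = d)
  s <- summary(fit)
  between <- s[["Error: animal"]][[1]]
  within <- s[["Error: Within"]][[1]]
  row_of <- function(tbl, name) {
    i <- which(trimws(rownames(tbl)) == name)
    if (length(i) != 1) stop_data("ANOVA term `", name, "` not found")
    tbl[i, , drop = FALSE]
  }
  mk <- function(tbl, name, err_row) {
    r <- row_of(tbl, name)
    fval <- r[1, "F value"]
    pval <- r[1, "Pr(>F)"]
    if (is.na(fval) && r[1, "Sum Sq"] == 0) {     # 0/0 on constant response
      fval <- 0
      pval <- 1
    }
    test_result(fval, c(r[1, "Df"], err_row[1, "Df"]), pval,
                paste0("RM ANOVA ", name))
  }
  res_tr <- mk(between, "treatment", row_of(between, "Residuals"))
  err_w <- row_of(within, "Residuals")
  res_ti <- mk(within, "time", err_w)
  res_int <- mk(within, "treatment:time", err_w)
  out <- list(treatment = res_tr, time = res_ti, interaction = res_int)
  if (gg_correction) {
    eps <- gg_epsilon(d)
    for (nm in c("time", "interaction")) {
      r <- out[[nm]]
      out[[paste0(nm, "_gg_p")]] <-
        stats::pf(r$statistic, eps * r$df[1], eps * r$df[2],
                  lower.tail = FALSE)
    }
    out$gg_epsilon <- eps
  }
  class(out) <- "rm_anova"
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# animal x time response matrix.
gg_epsilon <- function(d) {
  wide <- stats::xtabs(y ~ animal + time, data = d)
  grp <- tapply(as.character(d$treatment), d$animal, `[`, 1)
  centered <- do.call(rbind, lapply(split(seq_len(nrow(wide)), grp[rownames(wide)]),
    function(idx) scale(wide[idx, , drop = FALSE], scale = FALSE)))
  S <- stats::cov(centered)
  k <- ncol(S)
  num <- (k * (mean(diag(S)) - mean(S)))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2)
  min(1, max(1 / (k - 1), num / den))
}

#' @export
print.rm_anova <- function(x, ...) {
  for (nm in c("treatment", "time", "interaction")) {
    r <- x[[nm]]
    cat(sprintf("%-12s F(%g, %g) = %.3f, p = %.4g\n", nm,
                r$df[1], r$df[2], r$statistic, r$p_value))
  }
  invisible(x)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Orders the m raw p-values ascending and adjusts the i-th smallest as
#' `1 - (1 - p_(i))^(m - i + 1)`, enforcing monotonicity by a cumulative
#' maximum (step-down). Significance decisions at `alpha` follow the
#' sequential rule: testing stops at the first non-rejection.
#'
#' @param pvalues Raw p-values.
#' @param alpha Family-wise level. Default 0.05.
#' @return Data frame with `p_raw`, `p_adj`, `significant`, in the input
#'   order.
#' @export
holm_sidak <- function(pvalues, alpha = 0.05) {
  stopifnot(all(is.finite(pvalues)), all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  adj <- 1 - (1 - p_sorted)^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  sig_sorted <- adj <= alpha
  if (any(!sig_sorted)) {
    first_fail <- which(!sig_sorted)[1]
    sig_sorted[first_fail:m] <- FALSE
  }
  out <- data.frame(p_raw = pvalues, p_adj = NA_real_, significant = NA)
  out$p_adj[ord] <- adj
  out$significant[ord] <- sig_sorted
  out
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length, n >= 3, finite, each with
#'   positive variance.
#' @return A `correlation_result`: `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_data("Pearson correlation undefined for zero-variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ht$estimate), p_value = ht$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), p = %.4g\n", x$r, x$n, x$p_value))
  invisible(x)
}

#' Normality and equal-variance screens
#'
#' Shapiro-Wilk normality per group and the Brown-Forsythe test
#' (median-centered Levene) for equality of variances across groups, with
#' flags at `alpha`.
#'
#' @param values Numeric vector.
#' @param group Group labels, same length; n >= 3 per group.
#' @param alpha Flagging level. Default 0.05.
#' @return List: `shapiro` (data frame per group), `brown_forsythe`
#'   (statistic, df, p), `normal_ok`, `equal_var_ok`.
#' @export
distribution_screens <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (any(table(group) < 3))
    stop_data("each group needs at least 3 values")
  sw <- do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    p <- if (stats::sd(v) == 0) 1 else stats::shapiro.test(v)$p.value
    data.frame(group = g, p_value = p)
  }))
  if (nlevels(group) < 2) {
    bf <- data.frame(statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p_value = NA_real_)
  } else if (stats::sd(values) == 0 ||
             all(tapply(values, group, stats::sd) == 0)) {
    bf <- data.frame(statistic = 0, df1 = nlevels(group) - 1,
                     df2 = length(values) - nlevels(group), p_value = 1)
  } else {
    lt <- car::leveneTest(values, group, center = stats::median)
    bf <- data.frame(statistic = lt[1, "F value"], df1 = lt[1, "Df"],
                     df2 = lt[2, "Df"], p_value = lt[1, "Pr(>F)"])
  }
  list(shapiro = sw, brown_forsythe = bf,
       normal_ok = all(sw$p_value > alpha),
       equal_var_ok = bf$p_value > alpha)
}

#' Observed power for a two-sample t test
#'
#' Standard noncentral-t post hoc power at the observed effect size. Note
#' that commercial statistics packages compute "observed power" with
#' undocumented variants; this helper follows the textbook noncentral-t
#' definition and is not numerically equivalent to any particular tool.
#'
#' @param t_observed Observed t statistic.
#' @param n1,n2 Group sizes.
#' @param alpha Test level. Default 0.05.
#' @return Estimated power in `[0, 1]`.
#' @export
observed_power_t <- function(t_observed, n1, n2, alpha = 0.05) {
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- abs(t_observed)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}
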