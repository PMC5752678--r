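test_that("summary t reproduces published worked examples", {
  # onset variability: 27.3 +/- 4.6 vs 15.8 +/- 2.4 min, n = 8 -> t(14) ~ 2.2
  r1 <- t_from_summary(group_summary("ctrl", 27.3, 4.6, 8),
                       group_summary("trt", 15.8, 2.4, 8))
  expect_equal(r1$df, 14)
  expect_equal(r1$statistic, 2.2, tolerance = 0.01)
  # rotarod latency: 256 +/- 30.4 vs 420.1 +/- 32.2 s -> t(14) ~ -3.7
  r2 <- t_from_summary(group_summary("ctrl", 256, 30.4, 8),
                       group_summary("trt", 420.1, 32.2, 8))
  expect_equal(r2$statistic, -3.7, tolerance = 0.01)
  # identical summaries
  r3 <- t_from_summary(group_summary("a", 5, 1, 8),
                       group_summary("b", 5, 1, 8))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_equal(t_from_summary(group_summary("a", 5, 0, 8),
                              group_summary("b", 5, 0, 8))$statistic, 0)
  expect_error(t_from_summary(group_summary("a", 5, 0, 8),
                              group_summary("b", 6, 0, 8)), "undefined")
})

test_that("raw two-sample t agrees with the summary route to 1e-12", {
  set.seed(41)
  for (i in 1:25) {
    x <- rnorm(8, 10, 3)
    y <- rnorm(8, 11, 3)
    raw <- t_two_sample(x, y, mode = "pooled")
    summ <- t_from_summary(
      group_summary("x", mean(x), sd(x) / sqrt(8), 8),
      group_summary("y", mean(y), sd(y) / sqrt(8), 8))
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-12)
    expect_equal(raw$df, summ$df)
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
  }
  expect_equal(t_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  r <- t_two_sample(c(1, 2, 3, 4), c(10, 20, 30, 40), mode = "rank")
  expect_match(r$test_name, "rank")
  expect_error(t_two_sample(c(2, 2), c(3, 3)), "undefined")
})

test_that("repeated-measures ANOVA partitions a mixed design correctly", {
  # constant response -> all F = 0
  d0 <- expand.grid(animal = paste0("m", 1:6), time = 0:3)
  d0$treatment <- ifelse(as.integer(factor(d0$animal)) <= 3, "a", "b")
  d0$value <- 5
  a0 <- two_way_rm_anova(d0)
  expect_equal(a0$treatment$statistic, 0)
  expect_equal(a0$time$statistic, 0)
  expect_equal(a0$interaction$statistic, 0)

  # df layout: 8 + 8 animals x 24 times -> time F(23, 322), treatment F(1, 14)
  set.seed(42)
  d <- expand.grid(animal = sprintf("m%02d", 1:16), time = 0:23)
  d$treatment <- ifelse(as.integer(factor(d$animal)) <= 8, "a", "b")
  d$value <- rnorm(nrow(d)) + as.numeric(d$time) * 0.1
  a <- two_way_rm_anova(d)
  expect_equal(a$treatment$df, c(1, 14))
  expect_equal(a$time$df, c(23, 322))
  expect_equal(a$interaction$df, c(23, 322))

  # missing cell -> error
  expect_error(two_way_rm_anova(d[-1, ]), "balanced")

  # treatment F equals the squared two-sample t on animal means
  am <- aggregate(value ~ animal + treatment, data = d, FUN = mean)
  tt <- t_two_sample(am$value[am$treatment == "a"],
                     am$value[am$treatment == "b"])
  expect_equal(a$treatment$statistic, tt$statistic^2, tolerance = 1e-8)

  # a large injected treatment offset is detected
  d$value <- d$value + ifelse(d$treatment == "b", 5, 0)
  ab <- two_way_rm_anova(d)
  expect_lt(ab$treatment$p_value, 1e-6)

  # Greenhouse-Geisser correction: epsilon in its admissible range and the
  # adjusted p never smaller than the uncorrected one
  ag <- two_way_rm_anova(d, gg_correction = TRUE)
  expect_gte(ag$gg_epsilon, 1 / 23)
  expect_lte(ag$gg_epsilon, 1)
  expect_gte(ag$time_gg_p, ag$time$p_value - 1e-12)
})

test_that("Holm-Sidak step-down matches hand-computed adjustments", {
  # single p is its own adjustment
  one <- holm_sidak(0.04)
  expect_equal(one$p_adj, 0.04)
  expect_true(one$significant)
  # hand-computed three-test case: sorted p .01, .03, .04 adjusted with
  # exponents 3, 2, 1 then cumulative max
  hs <- holm_sidak(c(0.01, 0.04, 0.03))
  exp_sorted <- cummax(c(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2,
                         1 - (1 - 0.04)^1))
  expect_equal(hs$p_adj, exp_sorted[c(1, 3, 2)])
  # sequential rule: 0.03 adjusts to 0.059 > 0.05, so testing stops after
  # the smallest p
  expect_equal(hs$significant, c(TRUE, FALSE, FALSE))
  # none significant at p = 1
  expect_false(any(holm_sidak(rep(1, 5))$significant))
  # never more rejections than unadjusted testing; monotone in raw order
  set.seed(43)
  for (i in 1:20) {
    p <- runif(8)^2
    h <- holm_sidak(p)
    expect_lte(sum(h$significant), sum(p <= 0.05))
    expect_true(all(h$p_adj >= p - 1e-12))
    ord <- order(p)
    expect_true(all(diff(h$p_adj[ord]) >= -1e-12))
  }
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(3, 5)), "zero-variance")
  r <- pearson(x, c(2, 1, 4, 3, 6))
  ref <- cor.test(x, c(2, 1, 4, 3, 6))
  expect_equal(r$r, unname(ref$estimate))
  expect_equal(r$p_value, ref$p.value)
})

test_that("distribution screens flag heavy tails but pass normal data", {
  set.seed(44)
  vals <- c(rnorm(20), rnorm(20))
  grp <- rep(c("a", "b"), each = 20)
  sc <- distribution_screens(vals, grp)
  expect_equal(nrow(sc$shapiro), 2)
  expect_true(sc$brown_forsythe$p_value > 0 &&
                sc$brown_forsythe$p_value <= 1)
  # identical groups: Brown-Forsythe defaults to no evidence
  sc0 <- distribution_screens(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(sc0$brown_forsythe$statistic, 0, tolerance = 1e-12)
  # heavy-tailed samples reject more often than normal ones
  rej <- function(gen) {
    mean(sapply(1:60, function(i) {
      distribution_screens(gen(), rep("g", 30))$shapiro$p_value < 0.05
    }))
  }
  expect_gt(rej(function() rcauchy(30)), rej(function() rnorm(30)) + 0.3)
})

test_that("observed power behaves like noncentral-t power", {
  expect_lt(observed_power_t(0, 8, 8), 0.06)
  expect_gt(observed_power_t(5, 8, 8), 0.95)
  expect_gt(observed_power_t(3, 8, 8), observed_power_t(2, 8, 8))
})
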