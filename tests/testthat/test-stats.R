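test_that("screen_metric estimates ratios with Welch intervals", {
  set.seed(21)
  # identical groups: ratio 1, not flagged
  x <- stats::rlnorm(200, 1, 0.3)
  r <- screen_metric(x, x)
  expect_equal(r$estimate, 1)
  expect_false(r$flagged)

  # a known 0.8 ratio at large n is recovered and flagged
  ctrl <- stats::rlnorm(500, 0, 0.1)
  case <- stats::rlnorm(500, 0, 0.1) * 0.8
  r2 <- screen_metric(case, ctrl)
  expect_gt(r2$estimate, 0.78)
  expect_lt(r2$estimate, 0.82)
  expect_true(r2$flagged)
  expect_true(r2$ci_low <= r2$estimate && r2$estimate <= r2$ci_high)

  # CI excluding 1 is not enough without the 5% magnitude rule
  big1 <- stats::rlnorm(5000, 0, 0.05)
  big2 <- stats::rlnorm(5000, 0, 0.05) * 1.03
  r3 <- screen_metric(big2, big1)
  expect_true(r3$ci_low > 1 || r3$ci_high < 1)
  expect_false(r3$flagged)

  # too few values: not screenable
  expect_null(screen_metric(1, c(1, 2)))
})

test_that("screen_metric is antisymmetric under group swap", {
  set.seed(22)
  a <- stats::rlnorm(80, 0.5, 0.4)
  b <- stats::rlnorm(120, 0.3, 0.5)
  fwd <- screen_metric(a, b)
  rev <- screen_metric(b, a)
  expect_equal(fwd$estimate, 1 / rev$estimate)
  expect_equal(fwd$ci_low, 1 / rev$ci_high)
  expect_equal(fwd$ci_high, 1 / rev$ci_low)
  expect_equal(fwd$flagged, rev$flagged)
})

test_that("zeros are offset by half the smallest positive value", {
  x <- c(0, 1, 2, 4)
  y <- c(1, 2, 3, 4)
  r <- screen_metric(x, y)
  off <- 0.5  # half of min positive (1)
  expect_equal(r$estimate,
               exp(mean(log(x + off)) - mean(log(y + off))))
})

test_that("linear-scale screening tests a difference for clock metrics", {
  set.seed(23)
  a <- stats::rnorm(100, 8, 0.5)
  b <- stats::rnorm(100, 7, 0.5)
  r <- screen_metric(a, b, scale = "linear")
  expect_lt(abs(r$estimate - 1), 1.5)
  expect_true(r$flagged)
  same <- screen_metric(a, a, scale = "linear")
  expect_false(same$flagged)
})

test_that("one-way ANOVA matches the pooled t-test identity", {
  set.seed(24)
  y <- stats::rlnorm(60, 1, 0.4)
  g <- rep(c("RA", "control"), each = 30)
  a <- anova_oneway(y, g)
  tt <- stats::t.test(log(y) ~ g, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2)
  expect_equal(a$p, tt$p.value)

  # identical groups: F near 0, p near 1
  y2 <- rep(c(1, 2, 3), 4)
  a2 <- anova_oneway(y2, rep(c("x", "y"), each = 6))
  expect_lt(a2$F, 1e-20)

  expect_error(anova_oneway(1:6, rep("a", 6)), "two")
  expect_error(anova_oneway(1:3, c("a", "b", "b")), "at least two values")
})

test_that("ANCOVA adjusts the group effect for a covariate", {
  set.seed(25)
  n <- 2000
  # covariate independent of group: adjusted p close to unadjusted
  g <- rep(c("RA", "control"), each = n / 2)
  cov_ind <- stats::rnorm(n)
  y <- exp(0.2 * (g == "RA") + stats::rnorm(n, 0, 0.5))
  p_unadj <- anova_oneway(y, g)$p
  p_adj <- ancova(y, g, cov_ind)$p
  expect_lt(abs(log10(p_adj + 1e-300) - log10(p_unadj + 1e-300)), 1)

  # group effect fully mediated by the covariate shrinks to ~0
  z <- stats::rnorm(n) + (g == "RA")
  y2 <- exp(z + stats::rnorm(n, 0, 0.1))
  a2 <- ancova(y2, g, z)
  expect_lt(abs(a2$group_effect), 0.05)

  expect_error(ancova(y, g, rep(1, n)), "constant")
})

test_that("activity profiles are probability curves and recover effects", {
  # single participant always sedentary
  l <- label_series(rep("sedentary", 2 * 2880), start = MIDNIGHT)
  g <- MIDNIGHT + 7 * 3600
  data <- list(
    A = list(labels = l, getups = g),
    B = list(labels = l, getups = g)
  )
  groups <- c(A = "RA", B = "control")
  pr <- activity_profiles(data, groups, horizon_hours = 4)
  expect_true(all(pr$case["sedentary", ] == 1))
  expect_true(all(pr$case[c("sleep", "light", "MVPA"), ] == 0))
  expect_true(all(pr$difference == 0))
  cs <- colSums(pr$case)
  expect_true(all(abs(cs - 1) < 1e-9))

  expect_error(activity_profiles(data, c(A = "RA", B = "RA")), "both groups")
})

test_that("morning delay lowers early-day MVPA probability for cases", {
  p <- quiet_params()
  eff <- ra_effect(mvpa_time_ratio = 1, mvpa_run_ratio = 1,
                   morning_delay_minutes = 90,
                   sleep_interrupt_rate_ratio = 1)
  data <- list()
  groups <- c()
  for (i in 1:8) {
    ra_l <- simulate_labels(default_profile(), p, eff, seed = 500 + i)
    ct_l <- simulate_labels(default_profile("control"), p, NULL,
                            seed = 600 + i)
    data[[paste0("R", i)]] <- list(labels = ra_l,
                                   getups = getup_times(consolidate_nights(ra_l)))
    data[[paste0("C", i)]] <- list(labels = ct_l,
                                   getups = getup_times(consolidate_nights(ct_l)))
    groups[paste0("R", i)] <- "RA"
    groups[paste0("C", i)] <- "control"
  }
  pr <- activity_profiles(data, groups)
  early <- pr$time_hours < 1.5
  diff_mvpa <- mean(pr$difference["MVPA", early], na.rm = TRUE)
  expect_lt(diff_mvpa, 0)
})

test_that("PCA standardizes, tracks variance, and records exclusions", {
  set.seed(26)
  # two perfectly correlated metrics: first fraction 1
  x <- stats::rnorm(50)
  m <- cbind(a = x, b = 2 * x + 3)
  p <- pca_metrics(m)
  expect_equal(p$variance_fraction[1], 1)

  # uncorrelated standardized noise spreads variance evenly
  m2 <- matrix(stats::rnorm(4000 * 5), ncol = 5,
               dimnames = list(NULL, paste0("m", 1:5)))
  p2 <- pca_metrics(m2)
  expect_true(all(abs(p2$variance_fraction - 0.2) < 0.05))
  expect_equal(sum(p2$variance_fraction), 1)
  # loadings are orthonormal
  expect_equal(crossprod(p2$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)

  # metrics with missing values are dropped and recorded
  m3 <- cbind(m2, bad = c(NA, stats::rnorm(3999)))
  p3 <- pca_metrics(m3)
  expect_equal(p3$excluded_for_missingness, "bad")
  expect_false("bad" %in% p3$included_metrics)

  expect_error(pca_metrics(m2[, 1, drop = FALSE]), "two")
  expect_error(pca_metrics(m2[1:2, ]), "three")
})

test_that("null screens are calibrated near the nominal 5% level", {
  ns <- simulate_null_screens(n_screens = 400, seed = 9)
  rate <- mean(ns$ci_excludes_1)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  expect_lte(mean(ns$flagged), rate)
})
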