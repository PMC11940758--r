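test_that("the registry has 147 registrations over 145 unique metrics", {
  reg <- build_registry()
  expect_equal(nrow(reg), 147L)
  expect_equal(length(unique(reg$metric_id)), 145L)
  counts <- table(reg$domain)
  expect_equal(as.integer(counts[c("total_volume", "morning", "night",
                                   "fragmentation")]),
               c(77L, 30L, 15L, 25L))
  dup <- names(which(table(reg$metric_id) == 2))
  expect_setequal(dup, c("m10_level", "mvpa_pct_wear"))
  # the dual metrics bridge the documented domain pairs
  expect_setequal(reg$domain[reg$metric_id == "m10_level"],
                  c("total_volume", "night"))
  expect_setequal(reg$domain[reg$metric_id == "mvpa_pct_wear"],
                  c("total_volume", "fragmentation"))
  # clock-time metrics are tagged for linear-scale screening
  sc <- registry_scales(reg)
  expect_setequal(names(sc)[sc == "linear"],
                  c("sleep_midpoint_mean", "l5_midpoint", "m10_midpoint"))
})

test_that("intensity bins capture constant signals exactly", {
  n <- 7 * 2880
  s60 <- make_series(rep(60, n))
  l <- label_series(rep("sedentary", n), start = MIDNIGHT)
  empty <- detect_bouts(s60, bout_config("MVPA"))
  act <- detect_bouts(s60, bout_config("active"))
  tv <- compute_total_volume(s60, l, act, empty,
                             sedentary_complement(s60, act),
                             ambulatory_bouts(l))
  expect_equal(tv[["bin_40_80_pct_wear"]], 100)
  other <- grep("^bin_.*_pct_wear$", names(tv), value = TRUE)
  expect_equal(sum(tv[other]), 100)

  s150 <- make_series(rep(150, n))
  act2 <- detect_bouts(s150, bout_config("active"))
  tv2 <- compute_total_volume(s150, l, act2,
                              detect_bouts(s150, bout_config("MVPA")),
                              sedentary_complement(s150, act2),
                              ambulatory_bouts(l))
  expect_equal(tv2[["weekly_mvpa_min"]], 10080)
  expect_equal(tv2[["time_ge100_daily_min"]], 1440)
  expect_equal(tv2[["mvpa_pct_wear"]], 100)
})

test_that("bin percentages sum to at most 100, exactly when nothing >= 400", {
  set.seed(12)
  for (hi in c(300, 600)) {
    v <- stats::runif(7 * 2880, 0, hi)
    s <- make_series(v)
    l <- label_series(rep("sedentary", length(v)), start = MIDNIGHT)
    act <- detect_bouts(s, bout_config("active"))
    tv <- compute_total_volume(s, l, act,
                               detect_bouts(s, bout_config("MVPA")),
                               sedentary_complement(s, act),
                               ambulatory_bouts(l))
    pct <- sum(tv[grep("^bin_.*_pct_wear$", names(tv))])
    if (hi <= 400 && !any(v >= 400)) expect_equal(pct, 100)
    expect_lte(pct, 100 + 1e-9)
  }
})

test_that("morning windows summarize magnitude after getting up", {
  n <- 2 * 2880
  s <- make_series(rep(50, n))
  getup <- MIDNIGHT + 7 * 3600
  m <- compute_morning(s, getup)
  expect_equal(m[["morning_w120_mean_mg"]], 50)
  expect_equal(m[["morning_w120_auc"]], 6000)
  expect_equal(m[["morning_w120_pct_ge40"]], 100)
  expect_equal(m[["morning_w120_mvpa_min"]], 0)

  # linear ramp 0 -> 100 mg over the 2 h after get-up averages to ~50
  v <- rep(5, n)
  ridx <- (7 * 120 + 1):(9 * 120)
  v[ridx] <- seq(0, 100, length.out = length(ridx))
  m2 <- compute_morning(make_series(v), getup)
  expect_lt(abs(m2[["morning_w120_mean_mg"]] - 50), 1)

  # no get-up detected: all morning metrics missing
  m3 <- compute_morning(s, as.POSIXct(character(), tz = "UTC"))
  expect_true(all(is.na(m3)))

  # window extending past the recording end excludes that day
  late <- MIDNIGHT + (48 * 3600 - 30 * 60)
  m4 <- compute_morning(s, c(getup, late))
  expect_equal(m4[["morning_w15_mean_mg"]], 50)  # both getups fit 15 min
  expect_equal(m4[["morning_w240_mean_mg"]], 50) # only the first fits 4 h
})

test_that("night metrics follow their definitions", {
  # synthetic windows: 480 min, 432 min sleep, 6 movement episodes
  win <- data.frame(
    night_index = 1L, start_epoch = 2761L, end_epoch = 3720L,
    start = MIDNIGHT + 23 * 3600, end = MIDNIGHT + 31 * 3600,
    sleep_epochs = 864L, movement_episodes = 6L
  )
  l <- label_series(rep("sedentary", 2 * 2880), start = MIDNIGHT)
  s <- make_series(rep(10, 2 * 2880))
  nt <- compute_night(l, win, s)
  expect_equal(nt[["sleep_efficiency_mean"]], 90)
  expect_equal(nt[["rest_fragmentation_mean"]], 10 / 6)
  expect_equal(nt[["movement_episodes_mean"]], 6)
  # window 23:00-07:00: midpoint 03:00
  expect_equal(nt[["sleep_midpoint_mean"]], 3)

  # zero movement episodes give rest fragmentation 0
  win0 <- win
  win0$movement_episodes <- 0L
  win0$sleep_epochs <- 960L
  nt0 <- compute_night(l, win0, s)
  expect_equal(nt0[["rest_fragmentation_mean"]], 0)
  expect_equal(nt0[["sleep_efficiency_mean"]], 100)
})

test_that("L5/M10 locate the extremes of a sinusoidal profile", {
  n <- 7 * 2880
  h <- (epoch_of_day(make_series(rep(1, n)))) * 30 / 3600
  v <- 100 + 80 * cos(2 * pi * (h - 14) / 24)
  s <- make_series(v)
  l <- label_series(rep("sedentary", n), start = MIDNIGHT)
  nt <- compute_night(l, consolidate_nights(l), s)
  expect_lt(abs(nt[["m10_midpoint"]] - 14), 0.1)
  expect_lt(abs(nt[["l5_midpoint"]] - 2), 0.1)
  # closed-form rolling means: mean of cos over +-w/2 = sinc attenuation
  att10 <- sin(pi * 10 / 24) / (pi * 10 / 24)
  expect_lt(abs(nt[["m10_level"]] - (100 + 80 * att10)), 0.5)
  att5 <- sin(pi * 5 / 24) / (pi * 5 / 24)
  expect_lt(abs(nt[["l5_level"]] - (100 - 80 * att5)), 0.5)
})

test_that("fragmentation identities hold on hand-counted sequences", {
  # S S A A S S A at 30-s epochs (S < 40 mg, A >= 40)
  s <- make_series(c(10, 10, 50, 50, 10, 10, 50))
  f <- compute_fragmentation(s)
  expect_equal(f[["transprob_sed_to_act"]], 0.5)   # 2 exits / 4 epochs
  expect_equal(f[["hazard_sed_to_act"]], 0.5)      # 1 / mean(c(2, 2))
  expect_equal(f[["transprob_act_to_sed"]], 1 / 3) # 1 exit / 3 epochs
  expect_equal(f[["hazard_act_to_sed"]], 0.5)      # 1 / mean(c(2))

  # MVPA runs of length 2, 2, 2 epochs, all completed
  v <- c(rep(150, 2), rep(10, 3), rep(150, 2), rep(10, 3), rep(150, 2),
         rep(10, 2))
  f2 <- compute_fragmentation(make_series(v))
  expect_equal(f2[["hazard_mvpa_to_nonmvpa"]], 0.5)

  # constant MVPA: no completed run, hazard missing; run stats present
  f3 <- compute_fragmentation(make_series(rep(150, 100)))
  expect_true(is.na(f3[["hazard_mvpa_to_nonmvpa"]]))
  expect_true(is.na(f3[["transprob_mvpa_to_nonmvpa"]]))
  expect_equal(f3[["run_mvpa_mean_min"]], 50)
  expect_true(is.na(f3[["run_nonmvpa_mean_min"]]))
})

test_that("hazard approximates transition probability for geometric runs", {
  set.seed(77)
  p_exit_a <- 0.2
  p_exit_b <- 0.4
  n <- 1e5
  x <- logical(n)
  x[1] <- TRUE
  flips <- stats::runif(n)
  for (i in 2:n) {
    x[i] <- if (x[i - 1]) flips[i] >= p_exit_a else flips[i] < p_exit_b
  }
  s <- make_series(ifelse(x, 10, 50))  # TRUE = sedentary
  f <- compute_fragmentation(s)
  expect_lt(abs(f[["hazard_sed_to_act"]] - f[["transprob_sed_to_act"]]), 0.01)
  expect_lt(abs(f[["hazard_sed_to_act"]] - p_exit_a), 0.01)
  expect_lt(abs(f[["hazard_act_to_sed"]] - p_exit_b), 0.015)
})

test_that("every registry metric is computable on a fully worn week", {
  d <- simulate_participant(default_profile(), quiet_params(), seed = 41)
  m <- compute_metrics(d$series, d$labels)
  expect_equal(length(m), 145L)
  expect_identical(names(m), registry_metric_ids())
  expect_false(anyNA(m))
  # percentages live in [0, 100]
  pct_ids <- build_registry()$metric_id[build_registry()$units == "percent"]
  expect_true(all(m[unique(pct_ids)] >= 0 & m[unique(pct_ids)] <= 100))
  # clock times in [0, 24)
  expect_true(all(m[c("sleep_midpoint_mean", "l5_midpoint",
                      "m10_midpoint")] >= 0))
  expect_true(all(m[c("sleep_midpoint_mean", "l5_midpoint",
                      "m10_midpoint")] < 24))
  # MVPA bout time never exceeds total MVPA time
  expect_lte(m[["mvpa_bout_daily_min"]], m[["time_ge100_daily_min"]])
})

test_that("metrics are invariant to shifting the recording by whole weeks", {
  d <- simulate_participant(default_profile(), quiet_params(), seed = 43)
  m1 <- compute_metrics(d$series, d$labels)
  shift <- 7 * 86400
  s2 <- d$series
  s2$start <- s2$start + shift
  l2 <- d$labels
  l2$start <- l2$start + shift
  m2 <- compute_metrics(s2, l2)
  expect_equal(m1, m2)
})

test_that("fast MVPA family metrics match the full registry computation", {
  for (seed in c(3, 19)) {
    d <- simulate_participant(default_profile(), quiet_params(), seed = seed)
    fam <- mvpa_time_metrics(d$series)
    full <- compute_metrics(d$series, d$labels)
    expect_equal(fam, full[names(fam)])
  }
})
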