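test_that("generate_cohort is seeded, conserves counts, and validates", {
  a <- generate_cohort(10, 100, seed = 1)
  b <- generate_cohort(10, 100, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a), 110L)
  expect_equal(sum(a$group == "RA"), 10L)
  expect_error(generate_cohort(0, 10), "positive")
  expect_error(generate_cohort(10, 15), "twice")
})

test_that("cohort demographics track the configured marginals", {
  ch <- generate_cohort(1000, 2000, seed = 3)
  ra <- ch[ch$group == "RA", ]
  expect_lt(abs(mean(ra$sex == "female") - 0.67), 0.05)
  expect_lt(abs(mean(ra$age >= 60) - 0.746), 0.05)
  # controls carry no diagnosis fields
  ctrl <- ch[ch$group == "control", ]
  expect_true(all(ctrl$diagnosis_source == "none"))
  expect_true(all(ctrl$onset == "none"))
  expect_true(all(is.na(ctrl$age_at_diagnosis)))
  # late onset iff age at diagnosis >= 60
  late <- ra$onset == "late"
  expect_true(all(ra$age_at_diagnosis[late] >= 60))
  expect_true(all(ra$age_at_diagnosis[!late] < 60))
})

test_that("simulated labels are circadian and seed-deterministic", {
  l1 <- simulate_labels(default_profile(), quiet_params(), seed = 11)
  l2 <- simulate_labels(default_profile(), quiet_params(), seed = 11)
  expect_identical(l1$labels, l2$labels)
  expect_equal(n_epochs(l1), 7L * 2880L)

  h <- (epoch_of_day(l1)) * 30 / 3600
  night_sleep <- mean(l1$labels[h < 6] == "sleep")
  day_sleep <- mean(l1$labels[h >= 12 & h < 18] == "sleep")
  expect_gt(night_sleep, day_sleep)
  expect_gt(night_sleep, 0.5)
})

test_that("invalid generator parameters are rejected", {
  expect_error(
    activity_model_params(mean_run_minutes = c(sleep = 60, sedentary = 25,
                                               light = 8, MVPA = 0,
                                               walking = 3)),
    "strictly positive"
  )
  expect_error(activity_model_params(days = 0), "days")
  expect_error(ra_effect(mvpa_time_ratio = 0), "positive")
  expect_error(ra_effect(morning_delay_minutes = -1), ">= 0")
  expect_error(
    simulate_labels(default_profile("control"), quiet_params(),
                    effect = ra_effect(), seed = 1),
    "RA"
  )
})

test_that("the nominal MVPA time ratio is recovered by simulation", {
  p <- quiet_params()
  eff <- ra_effect(mvpa_time_ratio = 0.5, mvpa_run_ratio = 1,
                   morning_delay_minutes = 0,
                   sleep_interrupt_rate_ratio = 1)
  n_rep <- 60
  m0 <- m1 <- 0
  for (i in seq_len(n_rep)) {
    l0 <- simulate_labels(default_profile(), p, NULL, seed = 7000 + i)
    l1 <- simulate_labels(default_profile(), p, eff, seed = 8000 + i)
    m0 <- m0 + sum(l0$labels %in% c("MVPA", "walking"))
    m1 <- m1 + sum(l1$labels %in% c("MVPA", "walking"))
  }
  expect_gt(m1 / m0, 0.4)
  expect_lt(m1 / m0, 0.6)
})

test_that("RA effect knobs change only their targeted components", {
  p <- quiet_params()
  run_eff <- ra_effect(mvpa_time_ratio = 1, mvpa_run_ratio = 0.5,
                       morning_delay_minutes = 0,
                       sleep_interrupt_rate_ratio = 1)
  runs0 <- c()
  runs1 <- c()
  mid0 <- mid1 <- c()
  for (i in 1:25) {
    l0 <- simulate_labels(default_profile(), p, NULL, seed = 100 + i)
    l1 <- simulate_labels(default_profile(), p, run_eff, seed = 300 + i)
    r0 <- rle(as.character(l0$labels))
    r1 <- rle(as.character(l1$labels))
    runs0 <- c(runs0, r0$lengths[r0$values == "MVPA"])
    runs1 <- c(runs1, r1$lengths[r1$values == "MVPA"])
    w0 <- consolidate_nights(l0)
    w1 <- consolidate_nights(l1)
    mid0 <- c(mid0, ((as.numeric(w0$start) + as.numeric(w0$end)) / 2) %% 86400)
    mid1 <- c(mid1, ((as.numeric(w1$start) + as.numeric(w1$end)) / 2) %% 86400)
  }
  # halved mean run length, within Monte-Carlo error
  expect_lt(mean(runs1) / mean(runs0), 0.7)
  # sleep-phase timing untouched (mid-sleep clock time within 30 min)
  expect_lt(abs(mean(mid0) - mean(mid1)) / 3600, 0.5)
})

test_that("magnitudes follow the label-conditional distributions", {
  sleep_week <- label_series(rep("sleep", 7 * 2880), start = MIDNIGHT)
  p <- activity_model_params(
    magnitude_median = c(sleep = 15, sedentary = 18, light = 55, MVPA = 165,
                         walking = 130, nonwear = 2)
  )
  s <- simulate_magnitudes(sleep_week, p, seed = 2)
  expect_gt(stats::median(s$values), 13)
  expect_lt(stats::median(s$values), 17)

  # degenerate geometric SD = 1 gives exactly the state median
  pd <- activity_model_params(
    magnitude_median = c(sleep = 15, sedentary = 18, light = 55, MVPA = 165,
                         walking = 130, nonwear = 2),
    magnitude_gsd = c(sleep = 1, sedentary = 1, light = 1, MVPA = 1,
                      walking = 1, nonwear = 1)
  )
  s2 <- simulate_magnitudes(sleep_week, pd, seed = 3)
  expect_equal(s2$values, rep(15, n_epochs(sleep_week)))

  # zero nonwear rate keeps the wear mask all-true
  l <- simulate_labels(default_profile(), quiet_params(), seed = 5)
  s3 <- simulate_magnitudes(l, quiet_params(), seed = 5)
  expect_true(all(s3$wear))

  bad <- label_series(rep("sleep", 10))
  bad$labels <- factor(rep("unknown", 10))
  expect_error(simulate_magnitudes(bad, p, seed = 1), "state set")
})

test_that("nonwear episodes are masked and labeled consistently", {
  p <- activity_model_params(nonwear_rate = 2, nonwear_mean_minutes = 120)
  l <- simulate_labels(default_profile(), p, seed = 13)
  s <- simulate_magnitudes(l, p, seed = 13)
  expect_gt(sum(l$labels == "nonwear"), 0)
  expect_identical(!s$wear, as.vector(l$labels == "nonwear"))
})
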