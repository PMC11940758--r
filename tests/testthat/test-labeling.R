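test_that("fallback labeler applies the 40/100 mg cutpoints", {
  expect_true(all(fallback_labeler(make_series(rep(150, 100)))$labels == "MVPA"))
  expect_true(all(fallback_labeler(make_series(rep(60, 100)))$labels == "light"))
  # sustained quiescence (8 h at 5 mg) becomes sleep
  expect_true(all(fallback_labeler(make_series(rep(5, 8 * 120)))$labels == "sleep"))
  # 20 min at 5 mg stays sedentary (below the 30-min rule)
  s <- make_series(c(rep(60, 40), rep(5, 40), rep(60, 40)))
  expect_true(all(fallback_labeler(s)$labels[41:80] == "sedentary"))
  expect_error(fallback_labeler(make_series(rep(1, 10)), cutpoints = c(100, 40)),
               "increasing")
})

test_that("fallback labeler agrees with direct cutpoint classification on
           wear epochs not relabeled sleep", {
  set.seed(31)
  v <- abs(stats::rnorm(2880, 70, 60))
  wear <- stats::runif(2880) > 0.05
  s <- make_series(v, wear = wear)
  lab <- as.character(fallback_labeler(s)$labels)
  direct <- ifelse(v >= 100, "MVPA", ifelse(v >= 40, "light", "sedentary"))
  keep <- wear & lab != "sleep"
  expect_identical(lab[keep], direct[keep])
  expect_true(all(lab[!wear] == "nonwear"))
})

test_that("night consolidation follows the block-expansion rule", {
  # one uninterrupted 8-h sleep run, 23:00-07:00 within night 1
  l <- make_labels(
    list(label = "sedentary", min = 23 * 60),
    list(label = "sleep", min = 8 * 60),
    list(label = "sedentary", min = 17 * 60)
  )
  w <- consolidate_night(l, 1)
  expect_equal(as.numeric(w$end - w$start, units = "hours"), 8)
  expect_equal(w$movement_episodes, 0L)
  expect_equal(w$sleep_epochs, 8L * 120L)

  # 23:00-03:00 sleep, 10-min wake, sleep to 07:00: one window, 1 episode
  l2 <- make_labels(
    list(label = "sedentary", min = 23 * 60),
    list(label = "sleep", min = 4 * 60),
    list(label = "sedentary", min = 10),
    list(label = "sleep", min = 230),
    list(label = "sedentary", min = 17 * 60)
  )
  w2 <- consolidate_night(l2, 1)
  expect_equal(as.numeric(w2$end - w2$start, units = "hours"), 8)
  expect_equal(w2$movement_episodes, 1L)
  expect_equal(w2$sleep_epochs, (8 * 60 - 10) * 2)

  # afternoon nap plus a longer night sleep: window is the night run
  l3 <- make_labels(
    list(label = "sedentary", min = 13 * 60),
    list(label = "sleep", min = 60),            # 13:00-14:00 nap
    list(label = "sedentary", min = 9 * 60),    # to 23:00
    list(label = "sleep", min = 8 * 60),        # 23:00-07:00
    list(label = "sedentary", min = 17 * 60)
  )
  w3 <- consolidate_night(l3, 1)
  expect_equal(format(w3$start, "%H:%M"), "23:00")
  expect_equal(format(w3$end, "%H:%M"), "07:00")

  # a night span without sleep has no window
  l4 <- make_labels(list(label = "sedentary", min = 48 * 60))
  expect_null(consolidate_night(l4, 1))
})

test_that("night windows do not overlap and get-up times increase", {
  l <- simulate_labels(default_profile(), quiet_params(), seed = 17)
  w <- consolidate_nights(l)
  expect_gt(nrow(w), 1)
  if (nrow(w) > 1) {
    expect_true(all(w$start_epoch[-1] > w$end_epoch[-nrow(w)]))
    g <- getup_times(w)
    expect_true(all(diff(as.numeric(g)) > 0))
  }
  expect_length(getup_times(w[0, ]), 0L)
})

test_that("ambulatory bouts bridge a single class-dependent break", {
  # 5 minutes of continuous walking: one 2-10 min bout
  l <- make_labels(list(label = "sedentary", min = 10),
                   list(label = "walking", min = 5),
                   list(label = "sedentary", min = 10))
  b <- ambulatory_bouts(l)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_class, "2-10min")
  expect_equal(b$duration_minutes, 5)

  # 4 min + 30-s gap + 4 min: one 8.5-min bout using the single break
  l2 <- make_labels(list(label = "sedentary", min = 10),
                    list(label = "walking", min = 4),
                    list(label = "sedentary", min = 0.5),
                    list(label = "walking", min = 4),
                    list(label = "sedentary", min = 10))
  b2 <- ambulatory_bouts(l2)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$duration_minutes, 8.5)
  expect_equal(b2$break_epochs_used, 1L)

  # gap of 2 min exceeds every allowance: two separate bouts
  l3 <- make_labels(list(label = "sedentary", min = 10),
                    list(label = "walking", min = 4),
                    list(label = "sedentary", min = 2),
                    list(label = "walking", min = 4),
                    list(label = "sedentary", min = 10))
  b3 <- ambulatory_bouts(l3)
  expect_equal(nrow(b3), 2L)
  expect_true(all(b3$duration_class == "2-10min"))

  # a 1-min gap is allowed only once the bout reaches 10 minutes
  l4 <- make_labels(list(label = "walking", min = 6),
                    list(label = "sedentary", min = 1),
                    list(label = "walking", min = 6))
  b4 <- ambulatory_bouts(l4)
  expect_equal(nrow(b4), 1L)
  expect_equal(b4$duration_minutes, 13)
  expect_equal(b4$duration_class, "10-30min")

  # the same gap between two short walks is not bridged
  l5 <- make_labels(list(label = "walking", min = 3),
                    list(label = "sedentary", min = 1),
                    list(label = "walking", min = 3))
  b5 <- ambulatory_bouts(l5)
  expect_equal(nrow(b5), 2L)
})

test_that("ambulatory bout walking time never exceeds labeled walking plus
           bridged gaps", {
  for (seed in 1:10) {
    l <- simulate_labels(default_profile(), quiet_params(), seed = seed)
    b <- ambulatory_bouts(l)
    total_bout <- sum(b$duration_minutes)
    walking_min <- sum(l$labels == "walking") / 2
    bridged_min <- sum(b$break_epochs_used) / 2
    expect_lte(total_bout, walking_min + bridged_min)
    if (nrow(b) > 1) {
      expect_true(all(b$start_epoch[-1] > b$end_epoch[-nrow(b)]))
    }
  }
})
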