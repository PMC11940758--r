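test_that("enmo matches the closed form and truncates at zero", {
  expect_equal(enmo(0, 0, 1000), 0)
  expect_equal(enmo(600, 800, 0), 0)  # norm exactly 1 g
  expect_equal(enmo(0, 0, 1100), 100)
  expect_equal(enmo(c(0, 0), c(0, 0), c(900, 1200)), c(0, 200))
  expect_error(enmo(NA, 0, 0), "finite")
  expect_error(enmo(Inf, 0, 0), "finite")
})

test_that("enmo is rotation invariant", {
  set.seed(42)
  for (i in 1:20) {
    v <- stats::rnorm(3, sd = 500)
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))  # random orthogonal matrix
    w <- as.vector(q %*% v)
    expect_equal(enmo(v[1], v[2], v[3]), enmo(w[1], w[2], w[3]))
  }
})

test_that("epoch_aggregate averages samples into epochs and flags gaps", {
  ts <- MIDNIGHT + 0:59
  s <- epoch_aggregate(data.frame(timestamp = ts, magnitude = 50))
  expect_equal(s$values, c(50, 50))
  expect_true(all(s$wear))

  alt <- epoch_aggregate(data.frame(timestamp = MIDNIGHT + 0:29,
                                    magnitude = rep(c(0, 100), 15)))
  expect_equal(alt$values, 50)

  gap_ts <- c(MIDNIGHT + 0:29, MIDNIGHT + 60:89)  # epoch 2 empty
  g <- epoch_aggregate(data.frame(timestamp = gap_ts, magnitude = 10))
  expect_equal(g$wear, c(TRUE, FALSE, TRUE))

  expect_error(
    epoch_aggregate(data.frame(timestamp = rev(ts), magnitude = 1)),
    "sorted"
  )
})

test_that("epoch_aggregate conserves the sample mean over covered spans", {
  set.seed(7)
  ts <- MIDNIGHT + seq(0, 599, by = 1)
  mg <- stats::runif(600, 0, 200)
  s <- epoch_aggregate(data.frame(timestamp = ts, magnitude = mg))
  expect_equal(mean(s$values), mean(mg))
})

test_that("detect_nonwear flags long low-variability windows only", {
  set.seed(1)
  noisy <- abs(stats::rnorm(240, 100, 50))
  flat90 <- rep(30, 180)
  s <- make_series(c(noisy, flat90, noisy))
  d <- detect_nonwear(s)
  expect_true(all(!d$wear[241:420]))

  # white noise with SD 50 mg: no window falls under the 13 mg threshold
  wn <- make_series(abs(stats::rnorm(2880, 150, 50)))
  expect_true(all(detect_nonwear(wn)$wear))

  # constant stretch below the 60-min window is not flagged
  s30 <- make_series(c(noisy, rep(30, 60), noisy))
  expect_true(all(detect_nonwear(s30)$wear))

  expect_error(detect_nonwear(s, window_minutes = 0.1), "window")
})

test_that("detect_nonwear is idempotent", {
  set.seed(2)
  s <- make_series(c(abs(stats::rnorm(300, 80, 40)), rep(5, 200),
                     abs(stats::rnorm(300, 80, 40))))
  once <- detect_nonwear(s)
  twice <- detect_nonwear(once)
  expect_identical(once$wear, twice$wear)
})

test_that("impute_missing fills by same-time-of-day mean and flags slots", {
  # three days; epoch at 10:00 missing on day 2, values 40/60 other days
  epd <- 2880
  v <- rep(20, 3 * epd)
  slot_10h <- 10 * 120 + 1
  v[slot_10h] <- 40
  v[2 * epd + slot_10h] <- 60
  wear <- rep(TRUE, 3 * epd)
  wear[epd + slot_10h] <- FALSE
  s <- make_series(v, wear = wear)
  imp <- impute_missing(s)
  expect_equal(imp$values[epd + slot_10h], 50)
  expect_true(imp$imputed[epd + slot_10h])
  expect_equal(sum(imp$imputed), 1L)
  # wear-epoch values never change
  expect_identical(imp$values[wear], s$values[wear])

  # fully worn series is returned unchanged
  full <- make_series(rep(10, 100))
  expect_identical(impute_missing(full), full)

  # a slot with no wear data anywhere errors, naming the slot
  w2 <- rep(TRUE, 2880)
  w2[1201] <- FALSE
  one_day <- make_series(rep(10, 2880), wear = w2)
  expect_error(impute_missing(one_day), "10:00:00")
})

test_that("wear-time validity uses the 72-hour threshold as a boundary", {
  epd <- 2880
  n <- 7 * epd
  # exactly 72.0 h wear
  wear <- rep(FALSE, n)
  wear[seq_len(72 * 120)] <- TRUE
  expect_true(check_validity(make_series(rep(10, n), wear = wear))$valid)
  # 71.99 h (one epoch short is already below)
  wear2 <- wear
  wear2[72 * 120] <- FALSE
  rep2 <- check_validity(make_series(rep(10, n), wear = wear2))
  expect_false(rep2$valid)
  # seven fully worn days
  full <- check_validity(make_series(rep(10, n)))
  expect_true(full$valid)
  expect_equal(full$total_wear_hours, 168)
  expect_equal(length(full$per_day_wear_hours), 7L)
})
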