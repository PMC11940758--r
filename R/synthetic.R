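# Synthetic cohort and actigraphy generator.
#
# Emulates the structure of large-cohort wrist-accelerometer studies:
# 7-day recordings at 30-s epochs, circadian-structured activity states
# generated by a semi-Markov process, label-conditional log-normal
# acceleration magnitudes, sporadic non-wear, and injectable disease effects
# (reduced MVPA, delayed morning activity, fragmented sleep).

SIM_STATES <- c("sleep", "sedentary", "light", "MVPA", "walking")

#' Parameters of the activity-state simulator
#'
#' Defines the semi-Markov generative model: per-state mean sojourn times,
#' 24-h circadian modulation of state entry rates and sojourns, per-state
#' log-normal magnitude distributions, sleep-interruption and non-wear
#' processes, and the recording grid.
#'
#' Sojourns are geometric on the epoch scale with mean equal to the state's
#' `mean_run_minutes` scaled by its circadian multiplier at entry time,
#' dampened by `sojourn_exponent` so entry timing, not run length, carries
#' most of the circadian signal. The circadian multiplier of state s at hour
#' h is `exp(amplitude_s * cos(2 * pi * (h - peak_s) / 24))`, strictly
#' positive. Consecutive sojourns may re-enter the same state; observed runs
#' are therefore mixtures of geometric sojourns.
#'
#' @param mean_run_minutes Named numeric vector of mean sojourn minutes per
#'   state (sleep, sedentary, light, MVPA, walking).
#' @param entry_weight Named numeric vector of baseline state entry weights.
#' @param circadian_peak Named numeric vector: hour of day at which each
#'   state's entry rate peaks.
#' @param circadian_amplitude Named numeric vector: log-scale amplitude of
#'   each state's 24-h modulation (0 = no modulation).
#' @param sojourn_exponent Exponent in (0, 1] applied to the circadian
#'   multiplier when scaling sojourn means (default 0.4).
#' @param magnitude_median Named numeric vector of per-state median
#'   acceleration magnitude (mg); includes a `nonwear` entry for the
#'   on-table signal.
#' @param magnitude_gsd Named numeric vector of per-state geometric SD of
#'   magnitude (>= 1).
#' @param sleep_interrupt_rate Expected brief nocturnal movement episodes per
#'   hour of sleep.
#' @param sleep_interrupt_mean_minutes Mean duration of a movement episode.
#' @param nonwear_rate Expected non-wear episodes per day.
#' @param nonwear_mean_minutes Mean non-wear episode duration.
#' @param days Recording length in days (default 7).
#' @param epoch_seconds Epoch length in seconds (default 30; must divide 60).
#' @param start Timestamp of the first epoch (default a Monday midnight).
#' @return An object of class `activity_model_params`.
#' @export
activity_model_params <- function(
    mean_run_minutes = c(sleep = 60, sedentary = 25, light = 8,
                         MVPA = 4, walking = 3),
    entry_weight = c(sleep = 1.2, sedentary = 10, light = 7,
                     MVPA = 2.2, walking = 3),
    circadian_peak = c(sleep = 2, sedentary = 14, light = 11,
                       MVPA = 10.5, walking = 11.5),
    circadian_amplitude = c(sleep = 2.6, sedentary = 0.3, light = 0.7,
                            MVPA = 0.9, walking = 0.8),
    sojourn_exponent = 0.4,
    magnitude_median = c(sleep = 8, sedentary = 18, light = 55,
                         MVPA = 165, walking = 130, nonwear = 2),
    magnitude_gsd = c(sleep = 1.6, sedentary = 1.7, light = 1.3,
                      MVPA = 1.35, walking = 1.25, nonwear = 1.3),
    sleep_interrupt_rate = 1.5,
    sleep_interrupt_mean_minutes = 2,
    nonwear_rate = 0.2,
    nonwear_mean_minutes = 120,
    days = 7,
    epoch_seconds = 30,
    start = as.POSIXct("2015-03-02 00:00:00", tz = "UTC")) {
  p <- list(
    states = SIM_STATES,
    mean_run_minutes = mean_run_minutes[SIM_STATES],
    entry_weight = entry_weight[SIM_STATES],
    circadian_peak = circadian_peak[SIM_STATES],
    circadian_amplitude = circadian_amplitude[SIM_STATES],
    sojourn_exponent = sojourn_exponent,
    magnitude_median = magnitude_median[c(SIM_STATES, "nonwear")],
    magnitude_gsd = magnitude_gsd[c(SIM_STATES, "nonwear")],
    sleep_interrupt_rate = sleep_interrupt_rate,
    sleep_interrupt_mean_minutes = sleep_interrupt_mean_minutes,
    nonwear_rate = nonwear_rate,
    nonwear_mean_minutes = nonwear_mean_minutes,
    days = days,
    epoch_seconds = epoch_seconds,
    start = as.POSIXct(start, tz = "UTC")
  )
  validate_activity_model_params(p)
  structure(p, class = "activity_model_params")
}

validate_activity_model_params <- function(p) {
  if (anyNA(p$mean_run_minutes) || any(p$mean_run_minutes <= 0)) {
    stop("mean_run_minutes must be strictly positive for every state")
  }
  if (anyNA(p$entry_weight) || any(p$entry_weight <= 0)) {
    stop("entry_weight must be strictly positive for every state")
  }
  if (anyNA(p$circadian_amplitude) || anyNA(p$circadian_peak)) {
    stop("circadian modulation must be specified for every state")
  }
  if (anyNA(p$magnitude_median) || any(p$magnitude_median <= 0) ||
      anyNA(p$magnitude_gsd) || any(p$magnitude_gsd < 1)) {
    stop("magnitude distribution requires positive medians and gsd >= 1")
  }
  if (p$sleep_interrupt_rate < 0 || p$sleep_interrupt_mean_minutes <= 0 ||
      p$nonwear_rate < 0 || p$nonwear_mean_minutes <= 0) {
    stop("rates must be non-negative and durations strictly positive")
  }
  if (is.null(p$sojourn_exponent) || p$sojourn_exponent <= 0 ||
      p$sojourn_exponent > 1) {
    stop("sojourn_exponent must be in (0, 1]")
  }
  if (is.null(p$days) || p$days <= 0) stop("days must be positive")
  if (p$epoch_seconds <= 0 || 60 %% p$epoch_seconds != 0) {
    stop("epoch_seconds must be positive and divide 60")
  }
  invisible(TRUE)
}

#' Injectable rheumatoid-arthritis effect on the activity generator
#'
#' Encodes, as multiplicative knobs on the generative model, the qualitative
#' activity differences reported for rheumatoid arthritis: less MVPA,
#' shorter sustained MVPA runs, delayed morning activity, and more
#' fragmented nocturnal sleep.
#'
#' @param mvpa_time_ratio Multiplicative effect on time in the MVPA range
#'   (< 1 = less MVPA). Ratios below 1 are realized by binomial thinning of
#'   MVPA/walking runs (each run replaced by sedentary time with
#'   probability `1 - ratio`), which scales expected MVPA time by exactly
#'   the nominal ratio; walking is included because its acceleration
#'   magnitude lies in the MVPA range. Ratios above 1 scale the MVPA and
#'   walking entry rates instead.
#' @param mvpa_run_ratio Multiplier on the MVPA mean run length.
#' @param morning_delay_minutes Minutes over which MVPA/walking entry rates
#'   ramp from 0 to their full value after the nocturnal phase ends.
#' @param sleep_interrupt_rate_ratio Multiplier on the nocturnal
#'   movement-episode rate.
#' @return An object of class `ra_effect`.
#' @export
ra_effect <- function(mvpa_time_ratio = 0.7,
                      mvpa_run_ratio = 0.85,
                      morning_delay_minutes = 45,
                      sleep_interrupt_rate_ratio = 1.5) {
  if (mvpa_time_ratio <= 0 || mvpa_run_ratio <= 0 ||
      sleep_interrupt_rate_ratio <= 0) {
    stop("ra_effect ratios must be strictly positive")
  }
  if (morning_delay_minutes < 0) stop("morning_delay_minutes must be >= 0")
  structure(
    list(
      mvpa_time_ratio = mvpa_time_ratio,
      mvpa_run_ratio = mvpa_run_ratio,
      morning_delay_minutes = morning_delay_minutes,
      sleep_interrupt_rate_ratio = sleep_interrupt_rate_ratio
    ),
    class = "ra_effect"
  )
}

#' Default demographic distributions for cohort generation
#'
#' Marginals are calibrated to a large UK population cohort of participants
#' with rheumatoid arthritis (about 75% aged 60 or over and 67% female) and
#' are fully configurable. Control-pool distributions include mild
#' configurable imbalances in smoking, alcohol, chronotype, season and work
#' status so that covariate adjustment is exercised downstream.
#'
#' @return A nested list of sampling settings accepted by
#'   [generate_cohort()].
#' @export
cohort_config <- function() {
  list(
    age_breaks = c(45, 50, 55, 60, 65, 70, 75, 80),
    age_probs = c(37, 90, 148, 207, 310, 251, 39) / 1082,
    p_female = c(RA = 0.67, control = 0.55),
    bmi_breaks = c(16, 18.5, 25, 30, 40, 45),
    bmi_probs = c(7, 332, 446, 267, 26) / 1078,
    adi_mean = -1.48,
    adi_sd = 2.88,
    smoking_probs = list(
      RA = c(ever = 0.469, never = 0.525, unknown = 0.006),
      control = c(ever = 0.52, never = 0.474, unknown = 0.006)
    ),
    alcohol_levels = c("daily", "3-4_per_week", "1-2_per_week",
                       "1-3_per_month", "rarely", "never"),
    alcohol_probs = list(
      RA = c(184, 212, 268, 138, 162, 118) / 1082,
      control = c(0.22, 0.22, 0.25, 0.12, 0.11, 0.08)
    ),
    chronotype_probs = list(
      RA = c(morning = 0.543, evening = 0.324, unknown = 0.133),
      control = c(morning = 0.58, evening = 0.28, unknown = 0.14)
    ),
    season_probs = list(
      RA = c(spring = 0.22, summer = 0.22, autumn = 0.34, winter = 0.22),
      control = c(spring = 0.25, summer = 0.27, autumn = 0.23, winter = 0.25)
    ),
    p_working = c(RA = 0.30, control = 0.40),
    diagnosis_source_probs = c(primary_care = 0.089, hospital = 0.283,
                               self_report = 0.628),
    p_seropositive = 0.087,
    p_late_onset = 0.26,
    comorbidity_probs = c(heart_failure = 0.032, respiratory_failure = 0.006,
                          stroke = 0.022, thyroiditis = 0.001,
                          sjogren = 0.046),
    p_diagnosed_after_recording = 0.0,
    rf_meanlog = log(8),
    rf_sdlog = 0.5,
    activity_level_sdlog = 0.2,
    mvpa_propensity_sdlog = 0.35
  )
}

#' Generate a synthetic participant table
#'
#' Draws `n_ra` rheumatoid-arthritis profiles and `n_pool` control-pool
#' profiles from configurable demographic distributions. Control profiles
#' carry no diagnosis fields; late onset is defined as first symptoms at age
#' 60 or over. Two latent activity traits (`activity_level`,
#' `mvpa_propensity`) encode between-participant heterogeneity used by the
#' label simulator.
#'
#' @param n_ra Number of RA participants (>= 1).
#' @param n_pool Number of control-pool participants (>= 2 * n_ra).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param config Distribution settings, see [cohort_config()].
#' @return A data frame with one row per participant.
#' @export
generate_cohort <- function(n_ra, n_pool, seed = 1, config = cohort_config()) {
  if (n_ra < 1 || n_pool < 1) stop("participant counts must be positive")
  if (n_pool < 2 * n_ra) {
    stop("control pool must contain at least twice as many participants as cases")
  }
  n <- n_ra + n_pool
  group <- rep(c("RA", "control"), c(n_ra, n_pool))
  cfg <- config
  with_seed(seed, {
    age_cat <- sample.int(length(cfg$age_probs), n, replace = TRUE,
                          prob = cfg$age_probs)
    age <- cfg$age_breaks[age_cat] +
      stats::runif(n) * diff(cfg$age_breaks)[age_cat]
    sex <- ifelse(stats::runif(n) < cfg$p_female[group], "female", "male")
    bmi_cat <- sample.int(length(cfg$bmi_probs), n, replace = TRUE,
                          prob = cfg$bmi_probs)
    bmi <- cfg$bmi_breaks[bmi_cat] +
      stats::runif(n) * diff(cfg$bmi_breaks)[bmi_cat]
    adi <- stats::rnorm(n, cfg$adi_mean, cfg$adi_sd)
    smoking <- vapply(group, function(g) {
      sample(names(cfg$smoking_probs[[g]]), 1, prob = cfg$smoking_probs[[g]])
    }, character(1))
    alcohol <- vapply(group, function(g) {
      sample(cfg$alcohol_levels, 1, prob = cfg$alcohol_probs[[g]])
    }, character(1))
    chronotype <- vapply(group, function(g) {
      sample(names(cfg$chronotype_probs[[g]]), 1,
             prob = cfg$chronotype_probs[[g]])
    }, character(1))
    season <- vapply(group, function(g) {
      sample(names(cfg$season_probs[[g]]), 1, prob = cfg$season_probs[[g]])
    }, character(1))
    working <- stats::runif(n) < cfg$p_working[group]

    is_ra <- group == "RA"
    diagnosis_source <- rep("none", n)
    diagnosis_type <- rep("none", n)
    onset <- rep("none", n)
    age_at_diagnosis <- rep(NA_real_, n)
    if (any(is_ra)) {
      diagnosis_source[is_ra] <- sample(
        names(cfg$diagnosis_source_probs), sum(is_ra), replace = TRUE,
        prob = cfg$diagnosis_source_probs
      )
      diagnosis_type[is_ra] <- ifelse(
        stats::runif(sum(is_ra)) < cfg$p_seropositive, "seropositive", "other"
      )
      # late onset requires age >= 60; condition the onset draw so the
      # marginal late-onset fraction matches the configured probability
      p60 <- mean(age[is_ra] >= 60)
      p_late_cond <- if (p60 > 0) min(1, cfg$p_late_onset / p60) else 0
      late <- age[is_ra] >= 60 & stats::runif(sum(is_ra)) < p_late_cond
      onset[is_ra] <- ifelse(late, "late", "early")
      aad <- numeric(sum(is_ra))
      a <- age[is_ra]
      aad[late] <- stats::runif(sum(late), 60, pmax(60.01, a[late]))
      aad[!late] <- stats::runif(sum(!late), pmax(18, a[!late] - 30),
                                 pmin(59.99, a[!late]))
      age_at_diagnosis[is_ra] <- aad
    }

    comorbidity <- rep("none", n)
    p_any <- sum(cfg$comorbidity_probs)
    hit <- stats::runif(n) < p_any
    if (any(hit)) {
      comorbidity[hit] <- sample(names(cfg$comorbidity_probs), sum(hit),
                                 replace = TRUE,
                                 prob = cfg$comorbidity_probs)
    }
    diagnosed_after_recording <- is_ra &
      stats::runif(n) < cfg$p_diagnosed_after_recording
    rf_iu <- ifelse(is_ra, NA_real_,
                    stats::rlnorm(n, cfg$rf_meanlog, cfg$rf_sdlog))

    data.frame(
      id = sprintf("P%05d", seq_len(n)),
      group = group,
      age = age,
      sex = sex,
      bmi = bmi,
      adi = adi,
      smoking = smoking,
      alcohol = alcohol,
      chronotype = chronotype,
      season = season,
      working = working,
      diagnosis_source = diagnosis_source,
      diagnosis_type = diagnosis_type,
      onset = onset,
      age_at_diagnosis = age_at_diagnosis,
      comorbidity = comorbidity,
      diagnosed_after_recording = diagnosed_after_recording,
      rf_iu = rf_iu,
      activity_level = stats::rlnorm(n, 0, cfg$activity_level_sdlog),
      mvpa_propensity = stats::rlnorm(n, 0, cfg$mvpa_propensity_sdlog),
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  })
}

# Circadian multiplier of each state at hour-of-day h (strictly positive).
circadian_multiplier <- function(params, h) {
  exp(params$circadian_amplitude *
        cos(2 * pi * (h - params$circadian_peak) / 24))
}

#' Simulate a per-epoch activity-label sequence
#'
#' Semi-Markov generator: at each state entry the next state is drawn with
#' probability proportional to baseline entry weights times the circadian
#' multiplier at the entry hour, and the sojourn is geometric on epochs with
#' mean `mean_run_minutes` scaled by the same multiplier. Brief nocturnal
#' movement episodes interrupt sleep runs at a configurable rate, and
#' non-wear episodes are superimposed. RA effects modulate MVPA entry and
#' run length, ramp morning MVPA/walking entries after the nocturnal phase,
#' and scale the sleep-interruption rate.
#'
#' @param profile One participant row from [generate_cohort()] (or a list
#'   with at least `group`; latent traits default to 1).
#' @param params An [activity_model_params()].
#' @param effect An [ra_effect()] or `NULL`; only allowed when the profile's
#'   group is `"RA"`.
#' @param seed Integer seed.
#' @return A [label_series()] of `days * 86400 / epoch_seconds` epochs.
#' @export
simulate_labels <- function(profile, params, effect = NULL, seed = 1) {
  stopifnot(inherits(params, "activity_model_params"))
  validate_activity_model_params(params)
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "ra_effect"))
    if (!identical(as.character(profile$group), "RA")) {
      stop("an RA effect can only be applied to a profile with group = \"RA\"")
    }
  }
  epd <- 86400L %/% params$epoch_seconds
  n <- as.integer(params$days * epd)
  if (n < 1L) stop("recording must contain at least one epoch")

  act_lvl <- as.double(profile$activity_level %||% 1)
  mvpa_prop <- as.double(profile$mvpa_propensity %||% 1)
  base_w <- params$entry_weight
  base_w[c("sedentary", "light", "MVPA", "walking")] <-
    base_w[c("sedentary", "light", "MVPA", "walking")] * act_lvl
  base_w[c("MVPA", "walking")] <- base_w[c("MVPA", "walking")] * mvpa_prop

  run_mult <- stats::setNames(rep(1, 5), SIM_STATES)
  interrupt_rate <- params$sleep_interrupt_rate
  delay_min <- 0
  mvpa_ratio <- 1
  if (!is.null(effect)) {
    mvpa_ratio <- effect$mvpa_time_ratio
    run_mult["MVPA"] <- effect$mvpa_run_ratio
    interrupt_rate <- interrupt_rate * effect$sleep_interrupt_rate_ratio
    delay_min <- effect$morning_delay_minutes
  }
  night_end <- (params$circadian_peak[["sleep"]] + 6) %% 24

  ep_min <- params$epoch_seconds / 60
  with_seed(seed, {
    labs <- integer(n)
    # hour-of-day lookup per epoch-of-day, and per-state circadian tables
    hours <- (seq_len(epd) - 1L) * params$epoch_seconds / 3600
    cmat <- sapply(SIM_STATES, function(s) {
      exp(params$circadian_amplitude[[s]] *
            cos(2 * pi * (hours - params$circadian_peak[[s]]) / 24))
    })
    ramp <- rep(1, epd)
    if (delay_min > 0) {
      rel <- (hours - night_end) %% 24
      inside <- rel < delay_min / 60
      ramp[inside] <- rel[inside] / (delay_min / 60)
      ramp[ramp < 0.02] <- 0.02  # entry rates stay strictly positive
    }

    # precomputed per-epoch-of-day tables: cumulative entry weights and
    # log(1 - p) of the geometric sojourn at each entry hour
    wmat <- sweep(cmat, 2, base_w, "*")
    wmat[, 4:5] <- wmat[, 4:5] * ramp
    if (mvpa_ratio > 1) {
      # more MVPA than baseline: scale entry weights (approximate)
      wmat[, 4:5] <- wmat[, 4:5] * mvpa_ratio
    }
    tot <- wmat[, 1L] + wmat[, 2L] + wmat[, 3L] + wmat[, 4L] + wmat[, 5L]
    cw1 <- wmat[, 1L] / tot
    cw2 <- cw1 + wmat[, 2L] / tot
    cw3 <- cw2 + wmat[, 3L] / tot
    cw4 <- cw3 + wmat[, 4L] / tot
    mean_ep <- sweep(cmat^params$sojourn_exponent, 2,
                     params$mean_run_minutes * run_mult / ep_min, "*")
    mean_ep[mean_ep < 1] <- 1
    lg <- log1p(-1 / mean_ep)  # log(1 - p), p = 1 / mean sojourn epochs
    lg[mean_ep == 1] <- -Inf

    # pre-drawn uniforms, topped up if the sojourn stream runs short
    cap <- as.integer(n / 4) + 100L
    u_state <- stats::runif(cap)
    u_len <- stats::runif(cap)
    k <- 0L
    t <- 1L
    eod <- 1L  # epoch-of-day (1-based) of the current entry
    repeat {
      k <- k + 1L
      if (k > cap) {
        u_state <- c(u_state, stats::runif(cap))
        u_len <- c(u_len, stats::runif(cap))
        cap <- length(u_state)
      }
      u <- u_state[k]
      cur <- 1L + (u > cw1[eod]) + (u > cw2[eod]) + (u > cw3[eod]) +
        (u > cw4[eod])
      l <- lg[eod, cur]
      len <- if (l == -Inf) 1L else 1L + floor(log(u_len[k]) / l)
      end <- min(n, t + len - 1L)
      labs[t:end] <- cur
      t <- end + 1L
      if (t > n) break
      eod <- ((t - 1L) %% epd) + 1L
    }

    if (mvpa_ratio < 1) {
      # less MVPA than baseline: binomial thinning of MVPA/walking runs --
      # each run is kept with probability mvpa_time_ratio, so expected
      # MVPA/walking time scales by exactly the nominal ratio while the
      # run-length distribution of surviving runs is unchanged
      runs <- rle_runs(labs)
      mw_runs <- which(runs$value >= 4L)
      drop <- mw_runs[stats::runif(length(mw_runs)) > mvpa_ratio]
      for (j in drop) {
        labs[runs$start[j]:runs$end[j]] <- 2L  # replaced by sedentary time
      }
    }

    # brief movement episodes fragmenting sleep runs
    if (interrupt_rate > 0) {
      runs <- rle_runs(labs)
      sleep_runs <- runs[runs$value == which(SIM_STATES == "sleep") &
                           runs$length >= 6L, , drop = FALSE]
      if (nrow(sleep_runs) > 0) {
        mean_int_ep <- max(1, params$sleep_interrupt_mean_minutes / ep_min)
        for (k in seq_len(nrow(sleep_runs))) {
          L <- sleep_runs$length[k]
          n_int <- stats::rpois(1L, interrupt_rate * L * ep_min / 60)
          if (n_int > 0) {
            pos <- sample.int(L - 2L, min(n_int, L - 2L)) + sleep_runs$start[k]
            for (p0 in pos) {
              l_int <- 1L + stats::rgeom(1L, prob = 1 / mean_int_ep)
              stop_at <- min(p0 + l_int - 1L, sleep_runs$end[k] - 1L)
              labs[p0:stop_at] <- which(SIM_STATES == "sedentary")
            }
          }
        }
      }
    }

    out <- SIM_STATES[labs]

    # non-wear episodes
    if (params$nonwear_rate > 0) {
      n_nw <- stats::rpois(1L, params$nonwear_rate * params$days)
      if (n_nw > 0) {
        starts <- sample.int(n, n_nw)
        lens <- pmax(1L, stats::rpois(n_nw, params$nonwear_mean_minutes / ep_min))
        for (k in seq_len(n_nw)) {
          out[starts[k]:min(n, starts[k] + lens[k] - 1L)] <- "nonwear"
        }
      }
    }
    label_series(out, start = params$start,
                 epoch_seconds = params$epoch_seconds)
  })
}

#' Simulate epoch magnitudes conditional on activity labels
#'
#' Draws each epoch's acceleration magnitude from the log-normal
#' distribution of its activity state; non-wear epochs receive the low
#' "device on table" signal and a `FALSE` wear mask.
#'
#' @param labels A [label_series()] from [simulate_labels()] or elsewhere.
#' @param params An [activity_model_params()] supplying the per-state
#'   magnitude distributions.
#' @param seed Integer seed.
#' @return An [epoch_series()] aligned to `labels`.
#' @export
simulate_magnitudes <- function(labels, params, seed = 1) {
  stopifnot(inherits(labels, "label_series"),
            inherits(params, "activity_model_params"))
  lab <- as.character(labels$labels)
  bad <- setdiff(unique(lab), names(params$magnitude_median))
  if (length(bad) > 0) stop("labels outside the model state set: ",
                            paste(bad, collapse = ", "))
  n <- length(lab)
  with_seed(seed, {
    meanlog <- log(params$magnitude_median[lab])
    sdlog <- log(params$magnitude_gsd[lab])
    values <- stats::rlnorm(n, meanlog, sdlog)
    epoch_series(
      values = values,
      start = labels$start,
      epoch_seconds = labels$epoch_seconds,
      wear = lab != "nonwear"
    )
  })
}

#' Simulate a full participant recording
#'
#' Convenience wrapper pairing [simulate_labels()] and
#' [simulate_magnitudes()] with derived child seeds.
#'
#' @inheritParams simulate_labels
#' @return A list with elements `labels` ([label_series()]) and `series`
#'   ([epoch_series()]).
#' @export
simulate_participant <- function(profile, params, effect = NULL, seed = 1) {
  s <- derive_seeds(seed, 2)
  labels <- simulate_labels(profile, params, effect, seed = s[1])
  series <- simulate_magnitudes(labels, params, seed = s[2])
  list(labels = labels, series = series)
}
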