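# Per-participant computation of the physical-activity metrics.
#
# Daily statistics are computed per calendar day and then averaged (or
# SD'd) across days; clock-time metrics are expressed as hours since
# midnight in [0, 24) with circular averaging; magnitude metrics operate on
# the (optionally imputed) epoch series, label metrics on wear epochs only.

ep_minutes <- function(x) x$epoch_seconds / 60

# Calendar-day factor via integer day numbers (fast path: no character
# dates); levels are days since 1970-01-01.
day_factor <- function(x) {
  d <- (as.numeric(x$start) %/% 86400) +
    ((as.numeric(x$start) %% 86400) + (seq_len(n_epochs(x)) - 1L) *
       x$epoch_seconds) %/% 86400
  factor(d, levels = sort(unique(d)))
}

is_weekend <- function(day_levels) {
  d <- as.Date(as.numeric(as.character(day_levels)), origin = "1970-01-01")
  format(d, "%u") %in% c("6", "7")
}

daily_stat <- function(values, day, fun) {
  as.numeric(tapply(values, day, fun))
}

sd0 <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)

#' Compute total-volume-of-activity metrics
#'
#' Seventy-seven metrics covering intensity-bin occupancy (40 mg bins from
#' 0 to 400 mg), overall magnitude summaries, time above 40/100 mg, bout
#' time/count/duration/magnitude, per-state magnitude, walking time,
#' ambulatory bout counts and durations, weekly totals, and daily extremes.
#'
#' @param series An [epoch_series()] (imputed or fully worn).
#' @param labels A [label_series()] aligned to `series`.
#' @param bouts_active,bouts_mvpa,bouts_sedentary Bout data frames from
#'   [detect_bouts()] / [sedentary_complement()].
#' @param amb Ambulatory bout data frame from [ambulatory_bouts()].
#' @param m10_level Optional precomputed M10 mean level (computed from the
#'   series when `NULL`).
#' @return Named numeric vector of metric values.
#' @export
compute_total_volume <- function(series, labels, bouts_active, bouts_mvpa,
                                 bouts_sedentary, amb, m10_level = NULL) {
  check_aligned(series, labels)
  out <- c()
  epm <- ep_minutes(series)
  day <- day_factor(series)
  v <- series$values
  ndays <- nlevels(day)
  if (ndays == 0L || !any(series$wear | series$imputed)) {
    ids <- registry_metric_ids()
    reg <- build_registry()
    tv <- unique(reg$metric_id[reg$domain == "total_volume"])
    return(stats::setNames(rep(NA_real_, length(tv)), tv))
  }

  edges <- bin_edges()
  day_ep <- as.numeric(table(day))
  for (i in 1:10) {
    inbin <- v >= edges[i] & v < edges[i + 1L]
    dmin <- daily_stat(inbin, day, sum) * epm
    dpct <- 100 * daily_stat(inbin, day, sum) / day_ep
    out[paste0(bin_id(i), "_daily_min")] <- mean(dmin)
    out[paste0(bin_id(i), "_pct_wear")] <- mean(dpct)
    out[paste0(bin_id(i), "_daily_min_sd")] <- sd0(dmin)
  }

  dmean <- daily_stat(v, day, mean)
  out["overall_mean_mg"] <- mean(v)
  out["daily_mean_mg_sd"] <- sd0(dmean)
  out["daily_p95_mg_mean"] <- mean(daily_stat(v, day, function(x) {
    stats::quantile(x, 0.95, names = FALSE)
  }))
  wkend <- is_weekend(levels(day))
  out["weekday_mean_mg"] <- if (any(!wkend)) mean(dmean[!wkend]) else NA_real_
  out["weekend_mean_mg"] <- if (any(wkend)) mean(dmean[wkend]) else NA_real_
  out["daily_auc_mean"] <- mean(daily_stat(v, day, sum) * epm)

  ge40 <- daily_stat(v >= 40, day, sum)
  ge100 <- daily_stat(v >= 100, day, sum)
  out["time_ge40_daily_min"] <- mean(ge40 * epm)
  out["time_ge40_pct_wear"] <- mean(100 * ge40 / day_ep)
  out["time_ge100_daily_min"] <- mean(ge100 * epm)
  out["mvpa_pct_wear"] <- mean(100 * ge100 / day_ep)

  in_bout <- function(bouts) {
    ind <- rep(FALSE, length(v))
    for (k in seq_len(nrow(bouts))) {
      ind[bouts$start_epoch[k]:bouts$end_epoch[k]] <- TRUE
    }
    ind
  }
  bsets <- list(sedentary = bouts_sedentary, active = bouts_active,
                mvpa = bouts_mvpa)
  binds <- lapply(bsets, in_bout)
  for (s in names(bsets)) {
    dmin <- daily_stat(binds[[s]], day, sum) * epm
    out[paste0(s, "_bout_daily_min")] <- mean(dmin)
    out[paste0(s, "_bout_pct_wear")] <-
      mean(100 * daily_stat(binds[[s]], day, sum) / day_ep)
  }
  count_by_day <- function(bouts) {
    if (nrow(bouts) == 0L) return(rep(0, ndays))
    bd <- day[bouts$start_epoch]
    as.numeric(table(bd))
  }
  out["active_bout_count_daily"] <- mean(count_by_day(bouts_active))
  out["mvpa_bout_count_daily"] <- mean(count_by_day(bouts_mvpa))
  for (s in names(bsets)) {
    durs <- bsets[[s]]$duration_epochs * epm
    out[paste0(s, "_bout_dur_mean")] <- if (length(durs)) mean(durs) else NA_real_
    out[paste0(s, "_bout_dur_sd")] <- sd0(durs)
  }
  for (s in c("active", "mvpa")) {
    sel <- binds[[s]]
    if (any(sel)) {
      dmg <- as.numeric(tapply(v[sel], day[sel], mean))
      dmg <- dmg[!is.na(dmg)]
      out[paste0(s, "_bout_mg_daily_mean")] <- mean(dmg)
      out[paste0(s, "_bout_mg_daily_sd")] <- sd0(dmg)
    } else {
      out[paste0(s, "_bout_mg_daily_mean")] <- NA_real_
      out[paste0(s, "_bout_mg_daily_sd")] <- NA_real_
    }
  }

  lab <- as.character(labels$labels)
  for (s in c("light", "MVPA", "walking")) {
    sel <- lab == s & series$wear
    nm <- switch(s, light = "light_state_mg_daily_mean",
                 MVPA = "mvpa_state_mg_daily_mean",
                 walking = "walking_state_mg_daily_mean")
    if (any(sel)) {
      dmg <- as.numeric(tapply(v[sel], day[sel], mean))
      out[nm] <- mean(dmg[!is.na(dmg)])
    } else {
      out[nm] <- NA_real_
    }
  }

  walkd <- daily_stat(lab == "walking" & series$wear, day, sum) * epm
  out["walking_daily_min"] <- mean(walkd)
  out["walking_pct_wear"] <- mean(100 * daily_stat(lab == "walking" &
                                                     series$wear, day, sum) /
                                    day_ep)
  out["walking_daily_min_sd"] <- sd0(walkd)

  cls <- c("2-10min" = "2_10", "10-30min" = "10_30", ">30min" = "gt30")
  for (k in seq_along(cls)) {
    sel <- amb[amb$duration_class == names(cls)[k], , drop = FALSE]
    cnt <- rep(0, ndays)
    mins <- rep(0, ndays)
    if (nrow(sel) > 0L) {
      bd <- day[sel$start_epoch]
      tb <- table(bd)
      cnt <- as.numeric(tb)
      mins <- as.numeric(tapply(sel$duration_minutes, bd, sum))
      mins[is.na(mins)] <- 0
    }
    out[paste0("amb_", cls[k], "_count_daily")] <- mean(cnt)
    out[paste0("amb_", cls[k], "_daily_min")] <- mean(mins)
  }

  out["weekly_mvpa_min"] <- mean(ge100 * epm) * 7
  out["weekly_mvpa_bout_min"] <- out[["mvpa_bout_daily_min"]] * 7
  out["weekly_active_bout_min"] <- out[["active_bout_daily_min"]] * 7
  out["weekly_walking_min"] <- out[["walking_daily_min"]] * 7
  out["most_active_day_mvpa_min"] <- max(ge100 * epm)
  wk <- mean((ge100 * epm)[!wkend])
  we <- if (any(wkend)) mean((ge100 * epm)[wkend]) else NA_real_
  out["weekday_weekend_mvpa_ratio"] <-
    if (!is.na(we) && we > 0) wk / we else NA_real_

  if (is.null(m10_level)) {
    m10_level <- circadian_rolling(series)$m10_level
  }
  out["m10_level"] <- m10_level
  out
}

# L5/M10 from the across-day average 24-h profile: rolling circular means of
# width 5 h and 10 h; midpoints as hours since midnight.
circadian_rolling <- function(series) {
  epd <- epochs_per_day(series)
  if (n_epochs(series) < epd) {
    return(list(l5_midpoint = NA_real_, l5_level = NA_real_,
                m10_midpoint = NA_real_, m10_level = NA_real_))
  }
  slot <- epoch_of_day(series)
  use <- series$wear | series$imputed
  prof <- as.numeric(tapply(series$values[use], factor(slot[use],
                                                       levels = 0:(epd - 1L)),
                            mean))
  if (anyNA(prof)) {
    # slots never observed: fall back to overall mean so the window mean
    # stays defined
    prof[is.na(prof)] <- mean(prof, na.rm = TRUE)
  }
  roll <- function(width_hours) {
    w <- as.integer(width_hours * 3600 / series$epoch_seconds)
    rm <- stats::filter(c(prof, prof), rep(1 / w, w), sides = 1)
    # window ending at position i (1-based over doubled profile)
    means <- as.numeric(rm[(epd + 1L):(2L * epd)])
    # means[i]: window covering slots (i - w, i] of the circular profile
    list(means = means, w = w)
  }
  r5 <- roll(5)
  r10 <- roll(10)
  i5 <- which.min(r5$means)
  i10 <- which.max(r10$means)
  mid_hour <- function(i, w) {
    centre <- i - (w - 1) / 2  # slot index of the window midpoint
    ((centre - 0.5) * series$epoch_seconds / 3600) %% 24
  }
  list(
    l5_midpoint = mid_hour(i5, r5$w),
    l5_level = r5$means[i5],
    m10_midpoint = mid_hour(i10, r10$w),
    m10_level = r10$means[i10]
  )
}

#' Compute morning-activity metrics
#'
#' Summary statistics of acceleration magnitude over windows of 15 and 30
#' minutes and 1, 2 and 4 hours after the estimated get-up time, averaged
#' across days. The AUC of a window is its mean magnitude times the window
#' length in minutes; days whose window extends past the recording end are
#' excluded for that window.
#'
#' @param series An [epoch_series()].
#' @param getups `POSIXct` vector of get-up times (see [getup_times()]).
#' @param windows Window lengths in minutes (default
#'   `c(15, 30, 60, 120, 240)`).
#' @return Named numeric vector of metric values.
#' @export
compute_morning <- function(series, getups,
                            windows = morning_windows()) {
  out <- c()
  secs <- as.numeric(epoch_times(series))
  end_sec <- secs[length(secs)] + series$epoch_seconds
  for (w in windows) {
    wl <- paste0("morning_w", w)
    stats_by_day <- list()
    for (g in as.numeric(getups)) {
      if (g + w * 60 > end_sec) next
      sel <- secs >= g & secs < g + w * 60
      if (!any(sel)) next
      x <- series$values[sel]
      stats_by_day[[length(stats_by_day) + 1L]] <- c(
        mean = mean(x),
        sd = sd0(x),
        p95 = stats::quantile(x, 0.95, names = FALSE),
        auc = mean(x) * w,
        pct_ge40 = 100 * mean(x >= 40),
        mvpa_min = sum(x >= 100) * ep_minutes(series)
      )
    }
    if (length(stats_by_day) == 0L) {
      vals <- rep(NA_real_, 6)
      names(vals) <- c("mean", "sd", "p95", "auc", "pct_ge40", "mvpa_min")
    } else {
      vals <- colMeans(do.call(rbind, stats_by_day), na.rm = TRUE)
    }
    out[paste0(wl, "_mean_mg")] <- vals[["mean"]]
    out[paste0(wl, "_sd_mg")] <- vals[["sd"]]
    out[paste0(wl, "_p95_mg")] <- vals[["p95"]]
    out[paste0(wl, "_auc")] <- vals[["auc"]]
    out[paste0(wl, "_pct_ge40")] <- vals[["pct_ge40"]]
    out[paste0(wl, "_mvpa_min")] <- vals[["mvpa_min"]]
  }
  out
}

#' Compute night-time-activity metrics
#'
#' Sleep efficiency and its variability, sleep midpoint (circular mean
#' clock time), L5/M10 timing and level from the average 24-h profile,
#' nocturnal and diurnal sleep-episode durations, movement episodes per
#' night, and rest fragmentation.
#'
#' @param labels A [label_series()].
#' @param windows Night windows from [consolidate_nights()].
#' @param series The aligned [epoch_series()].
#' @return Named numeric vector of metric values.
#' @export
compute_night <- function(labels, windows, series) {
  check_aligned(series, labels)
  out <- c()
  epm <- ep_minutes(labels)
  nw <- nrow(windows)

  if (nw > 0L) {
    win_ep <- windows$end_epoch - windows$start_epoch + 1L
    eff <- 100 * windows$sleep_epochs / win_ep
    out["sleep_efficiency_mean"] <- mean(eff)
    out["sleep_efficiency_sd"] <- sd0(eff)
    mids <- (as.numeric(windows$start) + as.numeric(windows$end)) / 2
    mid_h <- (mids %% 86400) / 3600
    cm <- circular_mean_hours(mid_h)
    out["sleep_midpoint_mean"] <- cm
    dev <- ((mid_h - cm + 12) %% 24) - 12
    out["sleep_midpoint_sd"] <- sd0(dev)
    out["movement_episodes_mean"] <- mean(windows$movement_episodes)
    out["movement_episodes_sd"] <- sd0(windows$movement_episodes)
    rf <- ifelse(windows$movement_episodes > 0,
                 (100 * (1 - windows$sleep_epochs / win_ep)) /
                   windows$movement_episodes,
                 0)
    out["rest_fragmentation_mean"] <- mean(rf)
  } else {
    for (id in c("sleep_efficiency_mean", "sleep_efficiency_sd",
                 "sleep_midpoint_mean", "sleep_midpoint_sd",
                 "movement_episodes_mean", "movement_episodes_sd",
                 "rest_fragmentation_mean")) {
      out[id] <- NA_real_
    }
  }

  circ <- circadian_rolling(series)
  out["l5_midpoint"] <- circ$l5_midpoint
  out["l5_level"] <- circ$l5_level
  out["m10_midpoint"] <- circ$m10_midpoint
  out["m10_level"] <- circ$m10_level

  runs <- rle_runs(as.character(labels$labels) == "sleep")
  sruns <- runs[runs$value, , drop = FALSE]
  if (nrow(sruns) > 0L && nw > 0L) {
    midp <- (sruns$start + sruns$end) / 2
    noct <- vapply(midp, function(m) {
      any(m >= windows$start_epoch & m <= windows$end_epoch)
    }, logical(1))
    ndur <- sruns$length[noct] * epm
    ddur <- sruns$length[!noct] * epm
    out["nocturnal_episode_dur_mean"] <- if (length(ndur)) mean(ndur) else NA_real_
    out["nocturnal_episode_dur_sd"] <- sd0(ndur)
    out["diurnal_episode_dur_mean"] <- if (length(ddur)) mean(ddur) else NA_real_
    out["diurnal_episode_dur_sd"] <- sd0(ddur)
  } else {
    out["nocturnal_episode_dur_mean"] <- NA_real_
    out["nocturnal_episode_dur_sd"] <- NA_real_
    out["diurnal_episode_dur_mean"] <- NA_real_
    out["diurnal_episode_dur_sd"] <- NA_real_
  }
  out
}

#' Compute activity-fragmentation metrics
#'
#' The wear-time magnitude sequence is binarized twice -- sedentary vs
#' active at 40 mg and non-MVPA vs MVPA at 100 mg -- and summarized by exit
#' hazards (reciprocal of the mean completed run length, per epoch),
#' between-state transition probabilities (transitions out of a state
#' divided by total epochs in the state), and run-duration statistics in
#' minutes. Runs truncated by the recording end or a non-wear gap are
#' censored: excluded from hazards, included in run-duration statistics.
#'
#' @param series An [epoch_series()].
#' @return Named numeric vector of metric values (including
#'   `mvpa_pct_wear`, shared with the total-volume domain).
#' @export
compute_fragmentation <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  out <- c()
  epm <- ep_minutes(series)

  frag_pair <- function(state_a, ids) {
    # state_a: logical over wear epochs, TRUE = state A; censoring at
    # non-wear gaps is handled by analysing each wear segment separately
    segs <- rle_runs(series$wear)
    segs <- segs[segs$value, , drop = FALSE]
    completed_a <- completed_b <- integer(0)
    all_a <- all_b <- integer(0)
    trans_ab <- trans_ba <- 0L
    tot_a <- tot_b <- 0L
    for (k in seq_len(nrow(segs))) {
      x <- state_a[segs$start[k]:segs$end[k]]
      r <- rle(x)
      nr <- length(r$lengths)
      if (nr == 0L) next
      a_idx <- which(r$values)
      b_idx <- which(!r$values)
      all_a <- c(all_a, r$lengths[a_idx])
      all_b <- c(all_b, r$lengths[b_idx])
      comp <- seq_len(nr - 1L)  # last run of the segment is censored
      completed_a <- c(completed_a, r$lengths[intersect(a_idx, comp)])
      completed_b <- c(completed_b, r$lengths[intersect(b_idx, comp)])
      trans_ab <- trans_ab + length(intersect(a_idx, comp))
      trans_ba <- trans_ba + length(intersect(b_idx, comp))
      tot_a <- tot_a + sum(r$lengths[a_idx])
      tot_b <- tot_b + sum(r$lengths[b_idx])
    }
    res <- c()
    res[ids$hazard_ab] <- if (length(completed_a)) 1 / mean(completed_a) else NA_real_
    res[ids$hazard_ba] <- if (length(completed_b)) 1 / mean(completed_b) else NA_real_
    # the denominator keeps censored-run epochs (per the hand-count
    # definition), but without any completed run the exit rate is
    # unidentified and reported missing
    res[ids$trans_ab] <- if (tot_a > 0 && length(completed_a)) {
      trans_ab / tot_a
    } else {
      NA_real_
    }
    res[ids$trans_ba] <- if (tot_b > 0 && length(completed_b)) {
      trans_ba / tot_b
    } else {
      NA_real_
    }
    run_stats <- function(lens, prefix) {
      if (length(lens) == 0L) {
        v <- rep(NA_real_, 4)
      } else {
        d <- lens * epm
        v <- c(mean(d), sd0(d), stats::median(d),
               stats::quantile(d, 0.95, names = FALSE))
      }
      stats::setNames(v, paste0("run_", prefix,
                                c("_mean_min", "_sd_min", "_median_min",
                                  "_p95_min")))
    }
    c(res, run_stats(all_a, ids$prefix_a), run_stats(all_b, ids$prefix_b))
  }

  # sedentary (A, < 40 mg) vs active (B, >= 40 mg)
  out <- c(out, frag_pair(
    series$values < 40,
    list(hazard_ab = "hazard_sed_to_act", hazard_ba = "hazard_act_to_sed",
         trans_ab = "transprob_sed_to_act", trans_ba = "transprob_act_to_sed",
         prefix_a = "sedentary", prefix_b = "active")
  ))
  # MVPA (A, >= 100 mg) vs non-MVPA (B)
  out <- c(out, frag_pair(
    series$values >= 100,
    list(hazard_ab = "hazard_mvpa_to_nonmvpa",
         hazard_ba = "hazard_nonmvpa_to_mvpa",
         trans_ab = "transprob_mvpa_to_nonmvpa",
         trans_ba = "transprob_nonmvpa_to_mvpa",
         prefix_a = "mvpa", prefix_b = "nonmvpa")
  ))

  day <- day_factor(series)
  ge100 <- daily_stat(series$values >= 100, day, sum)
  day_ep <- as.numeric(table(day))
  out["mvpa_pct_wear"] <- mean(100 * ge100 / day_ep)
  out
}

#' Compute every registry metric for one participant
#'
#' Runs the standard per-participant pipeline: non-wear imputation for
#' magnitude metrics, bout detection (active: 10 min, MVPA: 3 min, both
#' with one-epoch break tolerance), sedentary complement, night-window
#' consolidation, get-up times, ambulatory bouts, and the four domain
#' calculators.
#'
#' @param series An [epoch_series()].
#' @param labels A [label_series()] aligned to `series` (when `NULL`, the
#'   [fallback_labeler()] is used).
#' @return Named numeric vector over the 145 unique registry metrics, in
#'   registry order.
#' @export
compute_metrics <- function(series, labels = NULL) {
  if (is.null(labels)) labels <- fallback_labeler(series)
  check_aligned(series, labels)
  series_imp <- if (all(series$wear)) series else impute_missing(series)

  b_act <- detect_bouts(series, bout_config("active"))
  b_mvpa <- detect_bouts(series, bout_config("MVPA"))
  b_sed <- sedentary_complement(series, b_act)
  amb <- ambulatory_bouts(labels)
  nights <- consolidate_nights(labels)
  getups <- getup_times(nights)

  circ <- circadian_rolling(series_imp)
  night <- compute_night(labels, nights, series_imp)
  tv <- compute_total_volume(series_imp, labels, b_act, b_mvpa, b_sed, amb,
                             m10_level = circ$m10_level)
  morning <- compute_morning(series_imp, getups)
  frag <- compute_fragmentation(series)

  all_vals <- c(tv, morning, night, frag)
  all_vals <- all_vals[!duplicated(names(all_vals))]
  ids <- registry_metric_ids()
  missing_ids <- setdiff(ids, names(all_vals))
  if (length(missing_ids) > 0L) {
    stop("internal: metrics not computed: ",
         paste(missing_ids, collapse = ", "))
  }
  all_vals[ids]
}

#' Build a participant-by-metric matrix
#'
#' @param data Named list of per-participant lists with elements `series`
#'   and `labels` (as from [simulate_participant()]).
#' @return Numeric matrix, rows = participants, columns = the 145 unique
#'   metrics.
#' @export
metric_matrix <- function(data) {
  ids <- registry_metric_ids()
  m <- t(vapply(data, function(d) {
    compute_metrics(d$series, d$labels)
  }, numeric(length(ids))))
  colnames(m) <- ids
  m
}

#' Fast MVPA time-quantity metrics
#'
#' Computes the subset of registry metrics that quantify the amount of MVPA
#' time directly from a series (daily minutes, percent of wear, weekly and
#' most-active-day totals, and MVPA-bout time and counts), matching
#' [compute_metrics()] exactly on the same input. Used for large replicate
#' simulations where the full registry is not needed.
#'
#' @param series An [epoch_series()].
#' @return Named numeric vector over the MVPA time-metric family.
#' @export
mvpa_time_metrics <- function(series) {
  out <- c()
  epm <- ep_minutes(series)
  n <- n_epochs(series)
  # integer day index (fast path, no factors)
  di <- (as.numeric(series$start) %/% 86400) +
    ((as.numeric(series$start) %% 86400) + (seq_len(n) - 1L) *
       series$epoch_seconds) %/% 86400
  di <- di - min(di) + 1L
  ndays <- max(di)
  day_ep <- tabulate(di, ndays)
  ge100 <- tabulate(di[series$values >= 100 &
                         (series$wear | series$imputed)], ndays)
  out["time_ge100_daily_min"] <- mean(ge100 * epm)
  out["mvpa_pct_wear"] <- mean(100 * ge100 / day_ep)
  out["weekly_mvpa_min"] <- mean(ge100 * epm) * 7
  out["most_active_day_mvpa_min"] <- max(ge100 * epm)

  b <- detect_bouts(series, bout_config("MVPA"))
  bmin <- numeric(ndays)
  cnt <- numeric(ndays)
  if (nrow(b) > 0L) {
    ind <- rep(FALSE, n)
    for (k in seq_len(nrow(b))) ind[b$start_epoch[k]:b$end_epoch[k]] <- TRUE
    bmin <- tabulate(di[ind], ndays)
    cnt <- tabulate(di[b$start_epoch], ndays)
  }
  out["mvpa_bout_daily_min"] <- mean(bmin * epm)
  out["mvpa_bout_pct_wear"] <- mean(100 * bmin / day_ep)
  out["mvpa_bout_count_daily"] <- mean(cnt)
  out["weekly_mvpa_bout_min"] <- mean(bmin * epm) * 7
  out
}
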