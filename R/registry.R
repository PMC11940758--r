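# Canonical registry of the physical-activity metrics.
#
# 147 domain registrations over 145 unique metrics across four domains:
# total volume of activity (77), morning activity (30), night-time activity
# (15) and fragmentation of activity (25). Two metrics belong to two domains
# each: the M10 mean level (total volume + night) and MVPA percent of wear
# time (total volume + fragmentation). This registry is the single source of
# truth for metric identifiers, domains, units and screening scale.

bin_edges <- function() seq(0, 400, by = 40)

bin_id <- function(i) {
  e <- bin_edges()
  sprintf("bin_%d_%d", e[i], e[i + 1L])
}

morning_windows <- function() c(15, 30, 60, 120, 240)

#' Build the metric registry
#'
#' @return A data frame with one row per domain registration (147 rows over
#'   145 unique `metric_id`s) and columns `metric_id`, `domain`, `units`,
#'   `scale` (`"log"` for ratio screening, `"linear"` for clock-time
#'   metrics) and `family`.
#' @export
build_registry <- function() {
  rows <- list()
  add <- function(id, domain, units, family, scale = "log") {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric_id = id, domain = domain, units = units, scale = scale,
      family = family, stringsAsFactors = FALSE
    )
  }

  ## -- total volume of activity (77 registrations) ------------------------
  for (i in 1:10) {
    add(paste0(bin_id(i), "_daily_min"), "total_volume", "min", "intensity_bin")
    add(paste0(bin_id(i), "_pct_wear"), "total_volume", "percent", "intensity_bin")
  }
  for (i in 1:10) {
    add(paste0(bin_id(i), "_daily_min_sd"), "total_volume", "min", "intensity_bin")
  }
  add("overall_mean_mg", "total_volume", "mg", "overall_magnitude")
  add("daily_mean_mg_sd", "total_volume", "mg", "overall_magnitude")
  add("daily_p95_mg_mean", "total_volume", "mg", "overall_magnitude")
  add("weekday_mean_mg", "total_volume", "mg", "overall_magnitude")
  add("weekend_mean_mg", "total_volume", "mg", "overall_magnitude")
  add("daily_auc_mean", "total_volume", "mg.min", "overall_magnitude")
  add("time_ge40_daily_min", "total_volume", "min", "time_above")
  add("time_ge40_pct_wear", "total_volume", "percent", "time_above")
  add("time_ge100_daily_min", "total_volume", "min", "time_above")
  add("mvpa_pct_wear", "total_volume", "percent", "time_above")
  add("sedentary_bout_daily_min", "total_volume", "min", "bout_time")
  add("sedentary_bout_pct_wear", "total_volume", "percent", "bout_time")
  add("active_bout_daily_min", "total_volume", "min", "bout_time")
  add("active_bout_pct_wear", "total_volume", "percent", "bout_time")
  add("mvpa_bout_daily_min", "total_volume", "min", "bout_time")
  add("mvpa_bout_pct_wear", "total_volume", "percent", "bout_time")
  add("active_bout_count_daily", "total_volume", "count", "bout_count")
  add("mvpa_bout_count_daily", "total_volume", "count", "bout_count")
  for (s in c("sedentary", "active", "mvpa")) {
    add(paste0(s, "_bout_dur_mean"), "total_volume", "min", "bout_duration")
    add(paste0(s, "_bout_dur_sd"), "total_volume", "min", "bout_duration")
  }
  add("active_bout_mg_daily_mean", "total_volume", "mg", "in_bout_magnitude")
  add("active_bout_mg_daily_sd", "total_volume", "mg", "in_bout_magnitude")
  add("mvpa_bout_mg_daily_mean", "total_volume", "mg", "in_bout_magnitude")
  add("mvpa_bout_mg_daily_sd", "total_volume", "mg", "in_bout_magnitude")
  add("light_state_mg_daily_mean", "total_volume", "mg", "in_state_magnitude")
  add("mvpa_state_mg_daily_mean", "total_volume", "mg", "in_state_magnitude")
  add("walking_state_mg_daily_mean", "total_volume", "mg", "in_state_magnitude")
  add("walking_daily_min", "total_volume", "min", "walking")
  add("walking_pct_wear", "total_volume", "percent", "walking")
  add("walking_daily_min_sd", "total_volume", "min", "walking")
  for (cl in c("2_10", "10_30", "gt30")) {
    add(paste0("amb_", cl, "_count_daily"), "total_volume", "count", "ambulatory")
    add(paste0("amb_", cl, "_daily_min"), "total_volume", "min", "ambulatory")
  }
  add("weekly_mvpa_min", "total_volume", "min", "weekly_total")
  add("weekly_mvpa_bout_min", "total_volume", "min", "weekly_total")
  add("weekly_active_bout_min", "total_volume", "min", "weekly_total")
  add("weekly_walking_min", "total_volume", "min", "weekly_total")
  add("most_active_day_mvpa_min", "total_volume", "min", "daily_extreme")
  add("weekday_weekend_mvpa_ratio", "total_volume", "ratio", "daily_extreme")
  add("m10_level", "total_volume", "mg", "circadian")

  ## -- morning activity (30 registrations) --------------------------------
  for (w in morning_windows()) {
    wl <- paste0("morning_w", w)
    add(paste0(wl, "_mean_mg"), "morning", "mg", "morning_window")
    add(paste0(wl, "_sd_mg"), "morning", "mg", "morning_window")
    add(paste0(wl, "_p95_mg"), "morning", "mg", "morning_window")
    add(paste0(wl, "_auc"), "morning", "mg.min", "morning_window")
    add(paste0(wl, "_pct_ge40"), "morning", "percent", "morning_window")
    add(paste0(wl, "_mvpa_min"), "morning", "min", "morning_window")
  }

  ## -- night-time activity (15 registrations) -----------------------------
  add("sleep_efficiency_mean", "night", "percent", "sleep_quality")
  add("sleep_efficiency_sd", "night", "percent", "sleep_quality")
  add("sleep_midpoint_mean", "night", "hours", "sleep_timing", scale = "linear")
  add("sleep_midpoint_sd", "night", "hours", "sleep_timing")
  add("l5_midpoint", "night", "hours", "circadian", scale = "linear")
  add("l5_level", "night", "mg", "circadian")
  add("m10_midpoint", "night", "hours", "circadian", scale = "linear")
  add("m10_level", "night", "mg", "circadian")
  add("nocturnal_episode_dur_mean", "night", "min", "sleep_episodes")
  add("nocturnal_episode_dur_sd", "night", "min", "sleep_episodes")
  add("diurnal_episode_dur_mean", "night", "min", "sleep_episodes")
  add("diurnal_episode_dur_sd", "night", "min", "sleep_episodes")
  add("movement_episodes_mean", "night", "count", "sleep_quality")
  add("movement_episodes_sd", "night", "count", "sleep_quality")
  add("rest_fragmentation_mean", "night", "percent_per_episode", "sleep_quality")

  ## -- fragmentation of activity (25 registrations) -----------------------
  add("hazard_sed_to_act", "fragmentation", "per_epoch", "hazard")
  add("hazard_act_to_sed", "fragmentation", "per_epoch", "hazard")
  add("hazard_nonmvpa_to_mvpa", "fragmentation", "per_epoch", "hazard")
  add("hazard_mvpa_to_nonmvpa", "fragmentation", "per_epoch", "hazard")
  add("transprob_sed_to_act", "fragmentation", "probability", "transition")
  add("transprob_act_to_sed", "fragmentation", "probability", "transition")
  add("transprob_nonmvpa_to_mvpa", "fragmentation", "probability", "transition")
  add("transprob_mvpa_to_nonmvpa", "fragmentation", "probability", "transition")
  for (s in c("sedentary", "active", "mvpa", "nonmvpa")) {
    add(paste0("run_", s, "_mean_min"), "fragmentation", "min", "run_stats")
    add(paste0("run_", s, "_sd_min"), "fragmentation", "min", "run_stats")
    add(paste0("run_", s, "_median_min"), "fragmentation", "min", "run_stats")
    add(paste0("run_", s, "_p95_min"), "fragmentation", "min", "run_stats")
  }
  add("mvpa_pct_wear", "fragmentation", "percent", "time_above")

  reg <- do.call(rbind, rows)
  stopifnot(nrow(reg) == 147L,
            length(unique(reg$metric_id)) == 145L)
  reg
}

#' Unique metric identifiers, in canonical order
#' @param registry Optional prebuilt registry.
#' @return Character vector of 145 metric ids.
#' @export
registry_metric_ids <- function(registry = build_registry()) {
  unique(registry$metric_id)
}

#' Screening scale of each unique metric
#' @param registry Optional prebuilt registry.
#' @return Named character vector (`"log"` or `"linear"`) over unique ids.
#' @export
registry_scales <- function(registry = build_registry()) {
  u <- !duplicated(registry$metric_id)
  stats::setNames(registry$scale[u], registry$metric_id[u])
}
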