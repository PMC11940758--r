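# Eligibility filtering and 2:1 matched case-control construction on
# categorized demographics (sex, 5-year age bins, BMI class, ADI quintile).

#' Apply eligibility filters to a participant table
#'
#' Removes participants with comorbid conditions known to influence
#' physical activity (heart failure, respiratory failure, stroke,
#' thyroiditis, Sjogren syndrome), RA diagnoses recorded only after the
#' actigraphy recording, and controls with rheumatoid factor above the
#' normal range (> 20 IU/mL). Every exclusion is counted by reason.
#'
#' @param profiles Data frame from [generate_cohort()].
#' @param comorbidity_exclusions Character vector of excluding comorbidity
#'   values (set to `character(0)` to disable).
#' @param exclude_diagnosis_after_recording Drop cases whose diagnosis
#'   postdates the recording (default `TRUE`).
#' @param rf_threshold Rheumatoid-factor exclusion threshold for controls in
#'   IU/mL (default 20; `NA` disables).
#' @return A list with `profiles` (the retained rows) and `exclusions`
#'   (data frame of reason counts).
#' @export
apply_filters <- function(profiles,
                          comorbidity_exclusions = c(
                            "heart_failure", "respiratory_failure", "stroke",
                            "thyroiditis", "sjogren"
                          ),
                          exclude_diagnosis_after_recording = TRUE,
                          rf_threshold = 20) {
  drop_reason <- rep(NA_character_, nrow(profiles))

  if (length(comorbidity_exclusions) > 0 && "comorbidity" %in% names(profiles)) {
    hit <- profiles$comorbidity %in% comorbidity_exclusions
    drop_reason[is.na(drop_reason) & hit] <-
      paste0("comorbidity_", profiles$comorbidity)[is.na(drop_reason) & hit]
  }
  if (exclude_diagnosis_after_recording &&
      "diagnosed_after_recording" %in% names(profiles)) {
    hit <- profiles$diagnosed_after_recording %in% TRUE
    drop_reason[is.na(drop_reason) & hit] <- "diagnosis_after_recording"
  }
  if (!is.na(rf_threshold) && "rf_iu" %in% names(profiles)) {
    hit <- profiles$group == "control" & !is.na(profiles$rf_iu) &
      profiles$rf_iu > rf_threshold
    drop_reason[is.na(drop_reason) & hit] <- "rheumatoid_factor_above_normal"
  }

  keep <- is.na(drop_reason)
  tab <- table(drop_reason[!keep])
  list(
    profiles = profiles[keep, , drop = FALSE],
    exclusions = data.frame(
      reason = names(tab),
      n = as.integer(tab),
      stringsAsFactors = FALSE
    )
  )
}

#' Matching configuration
#'
#' @param ratio Controls per case (default 2).
#' @param age_breaks 5-year age bins over 45-80.
#' @param bmi_breaks BMI class edges: underweight < 18.5, healthy 18.5-25,
#'   overweight 25-30, obese 30-40, severely obese >= 40.
#' @param max_distance Maximum admissible category distance per matched
#'   control (default 0 = exact-category matching).
#' @param seed Seed for the case processing order.
#' @return An object of class `match_config`.
#' @export
match_config <- function(ratio = 2,
                         age_breaks = seq(45, 80, by = 5),
                         bmi_breaks = c(-Inf, 18.5, 25, 30, 40, Inf),
                         max_distance = 0,
                         seed = 1) {
  if (ratio < 1) stop("ratio must be >= 1")
  structure(
    list(ratio = as.integer(ratio), age_breaks = age_breaks,
         bmi_breaks = bmi_breaks, max_distance = max_distance, seed = seed),
    class = "match_config"
  )
}

#' ADI quintile edges from the case group
#'
#' Quintile edges are estimated from the case group's empirical ADI
#' distribution and then applied to both groups.
#'
#' @param case_adi Numeric vector of case ADI values.
#' @return Numeric vector of 4 inner quintile edges.
#' @export
adi_quintile_edges <- function(case_adi) {
  stats::quantile(case_adi, probs = c(0.2, 0.4, 0.6, 0.8), names = FALSE)
}

#' Categorize a participant for matching
#'
#' @param profile One-row data frame (or list) with `sex`, `age`, `bmi`,
#'   `adi`.
#' @param config A [match_config()].
#' @param adi_edges Quintile edges from [adi_quintile_edges()].
#' @return Named integer-ish list `(sex, age_bin, bmi_bin, adi_quintile)`.
#' @export
categorize <- function(profile, config = match_config(),
                       adi_edges) {
  age <- as.numeric(profile$age)
  if (age < min(config$age_breaks) || age > max(config$age_breaks)) {
    stop(sprintf("age %.1f outside the matchable range [%d, %d]",
                 age, min(config$age_breaks), max(config$age_breaks)))
  }
  list(
    sex = as.character(profile$sex),
    age_bin = findInterval(age, config$age_breaks,
                           rightmost.closed = TRUE),
    bmi_bin = findInterval(as.numeric(profile$bmi), config$bmi_breaks),
    adi_quintile = findInterval(as.numeric(profile$adi), adi_edges) + 1L
  )
}

categorize_all <- function(profiles, config, adi_edges) {
  data.frame(
    id = profiles$id,
    sex = as.character(profiles$sex),
    age_bin = findInterval(profiles$age, config$age_breaks,
                           rightmost.closed = TRUE),
    bmi_bin = findInterval(profiles$bmi, config$bmi_breaks),
    adi_quintile = findInterval(profiles$adi, adi_edges) + 1L,
    stringsAsFactors = FALSE
  )
}

#' Nearest-neighbour 2:1 matching without replacement
#'
#' Cases are processed in a seeded random order; each case takes its
#' `ratio` nearest available controls, where distance is infinite across
#' sexes and otherwise the sum of absolute category-index differences over
#' age bin, BMI class and ADI quintile. A case is recorded unmatched if any
#' of its nearest available controls would exceed `max_distance`
#' (all-or-nothing). Matching is deterministic given the seed.
#'
#' @param cases Data frame of case profiles.
#' @param pool Data frame of candidate control profiles (disjoint from
#'   `cases`).
#' @param config A [match_config()].
#' @return A list of class `matched_cohort` with `pairs` (case id ->
#'   control ids), `unmatched_cases`, `matched_controls`, and `balance`
#'   (per-variable category frequency tables by group).
#' @export
match_cohort <- function(cases, pool, config = match_config()) {
  if (nrow(pool) == 0L) stop("control pool is empty")
  if (any(pool$id %in% cases$id)) stop("pool must be disjoint from cases")
  edges <- adi_quintile_edges(cases$adi)
  cc <- categorize_all(cases, config, edges)
  pc <- categorize_all(pool, config, edges)

  order_idx <- with_seed(config$seed, sample.int(nrow(cases)))
  available <- rep(TRUE, nrow(pool))
  pairs <- stats::setNames(vector("list", nrow(cases)), cases$id)
  unmatched <- character(0)

  pmat <- cbind(pc$age_bin, pc$bmi_bin, pc$adi_quintile)
  for (i in order_idx) {
    d <- abs(pmat[, 1] - cc$age_bin[i]) + abs(pmat[, 2] - cc$bmi_bin[i]) +
      abs(pmat[, 3] - cc$adi_quintile[i])
    d[pc$sex != cc$sex[i]] <- Inf
    d[!available] <- Inf
    ord <- order(d)[seq_len(config$ratio)]
    if (any(!is.finite(d[ord])) || any(d[ord] > config$max_distance)) {
      unmatched <- c(unmatched, cases$id[i])
      next
    }
    pairs[[cases$id[i]]] <- pool$id[ord]
    available[ord] <- FALSE
  }

  matched_ids <- unlist(pairs, use.names = FALSE)
  matched_cases <- setdiff(cases$id, unmatched)
  balance <- match_balance(cases[cases$id %in% matched_cases, , drop = FALSE],
                           pool[pool$id %in% matched_ids, , drop = FALSE],
                           config, edges)
  structure(
    list(
      pairs = pairs[matched_cases],
      unmatched_cases = unmatched,
      matched_controls = matched_ids,
      adi_edges = edges,
      balance = balance
    ),
    class = "matched_cohort"
  )
}

match_balance <- function(cases, controls, config, edges) {
  cc <- categorize_all(cases, config, edges)
  pc <- categorize_all(controls, config, edges)
  lapply(c(sex = "sex", age_bin = "age_bin", bmi_bin = "bmi_bin",
           adi_quintile = "adi_quintile"), function(v) {
    rbind(
      case = table(factor(cc[[v]], levels = sort(unique(c(cc[[v]], pc[[v]]))))),
      control = table(factor(pc[[v]], levels = sort(unique(c(cc[[v]], pc[[v]])))))
    )
  })
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d matched cases (%d unmatched), %d controls\n",
              length(x$pairs), length(x$unmatched_cases),
              length(x$matched_controls)))
  invisible(x)
}
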