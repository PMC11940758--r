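# Activity labeling: threshold fallback labeler, consolidation of
# night-time lying-down windows, get-up times, and ambulatory bouts.

#' Threshold-based fallback activity labeler
#'
#' Stands in when no external human-activity-recognition labels are
#' available. Wear epochs are classified by magnitude cutpoints (MVPA at or
#' above the upper cutpoint, light between the cutpoints, sedentary below),
#' and sustained quiescent sedentary runs (at least `sleep_min_minutes`
#' long with mean magnitude below `sleep_max_mg`) are relabeled as sleep.
#' Non-wear epochs are labeled `nonwear`.
#'
#' @param series An [epoch_series()].
#' @param cutpoints Strictly increasing pair of magnitude cutpoints in mg
#'   (default `c(40, 100)`).
#' @param sleep_min_minutes Minimum sedentary run length for sleep
#'   relabeling (default 30).
#' @param sleep_max_mg Maximum mean magnitude of a run relabeled as sleep
#'   (default 10).
#' @return A [label_series()] aligned to `series`.
#' @export
fallback_labeler <- function(series, cutpoints = c(40, 100),
                             sleep_min_minutes = 30, sleep_max_mg = 10) {
  stopifnot(inherits(series, "epoch_series"))
  if (length(cutpoints) != 2L || diff(cutpoints) <= 0) {
    stop("cutpoints must be a strictly increasing pair")
  }
  lab <- ifelse(series$values >= cutpoints[2], "MVPA",
                ifelse(series$values >= cutpoints[1], "light", "sedentary"))
  lab[!series$wear] <- "nonwear"
  runs <- rle_runs(lab)
  min_ep <- sleep_min_minutes * 60 / series$epoch_seconds
  sed <- runs[runs$value == "sedentary" & runs$length >= min_ep, ,
              drop = FALSE]
  for (k in seq_len(nrow(sed))) {
    idx <- sed$start[k]:sed$end[k]
    if (mean(series$values[idx]) < sleep_max_mg) lab[idx] <- "sleep"
  }
  label_series(lab, start = series$start,
               epoch_seconds = series$epoch_seconds)
}

#' Consolidate one night-time lying-down window
#'
#' Within a noon-to-noon night span, the window is initialized at the
#' longest run of sleep-labeled epochs and its edges are extended outward
#' in blocks (default 30 minutes) while the adjacent block contains at
#' least `block_sleep_fraction` sleep epochs; the final window is trimmed
#' to start and end on sleep epochs. Movement episodes are the maximal
#' non-sleep runs strictly inside the window.
#'
#' @param labels A [label_series()].
#' @param night_index 1-based index of the noon-to-noon night to
#'   consolidate.
#' @param block_minutes Extension block length in minutes (default 30).
#' @param block_sleep_fraction Minimum sleep fraction of a block for the
#'   window edge to extend into it (default 0.5).
#' @return A one-row data frame (`night_index`, `start_epoch`, `end_epoch`,
#'   `start`, `end`, `sleep_epochs`, `movement_episodes`), or `NULL` when
#'   the span contains no sleep.
#' @export
consolidate_night <- function(labels, night_index, block_minutes = 30,
                              block_sleep_fraction = 0.5) {
  stopifnot(inherits(labels, "label_series"))
  span <- night_span(labels, night_index)
  if (is.null(span)) return(NULL)
  is_sleep <- labels$labels == "sleep"
  sl <- is_sleep[span$from:span$to]
  if (!any(sl)) return(NULL)

  runs <- rle_runs(sl)
  runs <- runs[runs$value, , drop = FALSE]
  best <- runs[which.max(runs$length), ]
  lo <- span$from + best$start - 1L
  hi <- span$from + best$end - 1L

  bl <- as.integer(round(block_minutes * 60 / labels$epoch_seconds))
  repeat {
    extended <- FALSE
    # extend left
    nlo <- max(span$from, lo - bl)
    if (nlo < lo &&
        mean(is_sleep[nlo:(lo - 1L)]) >= block_sleep_fraction) {
      lo <- nlo
      extended <- TRUE
    }
    # extend right
    nhi <- min(span$to, hi + bl)
    if (nhi > hi &&
        mean(is_sleep[(hi + 1L):nhi]) >= block_sleep_fraction) {
      hi <- nhi
      extended <- TRUE
    }
    if (!extended) break
  }
  # trim to sleep epochs at the edges
  while (!is_sleep[lo]) lo <- lo + 1L
  while (!is_sleep[hi]) hi <- hi - 1L

  inside <- is_sleep[lo:hi]
  moves <- rle_runs(inside)
  times <- epoch_times(labels)
  data.frame(
    night_index = night_index,
    start_epoch = lo,
    end_epoch = hi,
    start = times[lo],
    end = times[hi] + labels$epoch_seconds,
    sleep_epochs = sum(inside),
    movement_episodes = sum(!moves$value),
    stringsAsFactors = FALSE
  )
}

# Epoch range of the night_index-th complete noon-to-noon span, or NULL.
night_span <- function(labels, night_index) {
  n <- n_epochs(labels)
  secs <- as.numeric(epoch_times(labels))
  # noon boundaries present in the recording
  first_noon <- ceiling((secs[1] - 43200) / 86400) * 86400 + 43200
  from_sec <- first_noon + (night_index - 1) * 86400
  to_sec <- from_sec + 86400
  if (from_sec < secs[1] || to_sec > secs[n] + labels$epoch_seconds) {
    return(NULL)
  }
  from <- which(secs >= from_sec)[1]
  to <- max(which(secs < to_sec))
  if (is.na(from) || from >= to) return(NULL)
  list(from = from, to = to)
}

#' Consolidate all complete nights of a recording
#'
#' Applies [consolidate_night()] to every complete noon-to-noon span;
#' nights without sleep-labeled epochs are recorded as absent.
#'
#' @inheritParams consolidate_night
#' @return A data frame of night windows (possibly zero rows).
#' @export
consolidate_nights <- function(labels, block_minutes = 30,
                               block_sleep_fraction = 0.5) {
  n_nights <- max(0L, floor((n_epochs(labels) * labels$epoch_seconds -
                               first_noon_offset(labels)) / 86400))
  out <- list()
  for (k in seq_len(n_nights)) {
    w <- consolidate_night(labels, k, block_minutes, block_sleep_fraction)
    if (!is.null(w)) out[[length(out) + 1L]] <- w
  }
  if (length(out) == 0L) {
    return(data.frame(night_index = integer(), start_epoch = integer(),
                      end_epoch = integer(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()), sleep_epochs = integer(),
                      movement_episodes = integer()))
  }
  do.call(rbind, out)
}

first_noon_offset <- function(labels) {
  s <- as.numeric(labels$start)
  ceiling((s - 43200) / 86400) * 86400 + 43200 - s
}

#' Get-up times from consolidated night windows
#'
#' The time of getting up is estimated as the end of each consolidated
#' night-time lying-down window.
#'
#' @param windows Data frame from [consolidate_nights()].
#' @return `POSIXct` vector of get-up times (one per present night window).
#' @export
getup_times <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0L) {
    return(as.POSIXct(character(), tz = "UTC"))
  }
  windows$end
}

#' Extract ambulatory (sustained walking) bouts
#'
#' Maximal walking runs, optionally bridged across a single non-walking
#' break, form ambulatory bouts of at least 2 minutes, grouped by duration:
#' 2-10 minutes (break allowance up to 30 s, i.e. one epoch), 10-30 minutes
#' and over 30 minutes (allowance up to 1 minute, i.e. two epochs). Bouts
#' start and end on walking epochs and never overlap.
#'
#' @param labels A [label_series()].
#' @return Data frame with `start_epoch`, `end_epoch`, `duration_minutes`,
#'   `duration_class` (`"2-10min"`, `"10-30min"`, `">30min"`) and
#'   `break_epochs_used`.
#' @export
ambulatory_bouts <- function(labels) {
  stopifnot(inherits(labels, "label_series"))
  ep_min <- labels$epoch_seconds / 60
  runs <- rle_runs(as.character(labels$labels))
  walk <- which(runs$value == "walking")
  if (length(walk) == 0L) return(empty_amb())

  segs <- list()
  i <- 1L
  while (i <= length(walk)) {
    r <- walk[i]
    start <- runs$start[r]
    end <- runs$end[r]
    brk <- 0L
    # attempt to bridge a single break to the next walking run
    if (i < length(walk) && walk[i + 1L] == r + 2L) {
      gap <- runs$length[r + 1L]
      merged_end <- runs$end[r + 2L]
      dur_min <- (merged_end - start + 1L) * ep_min
      allow <- if (dur_min >= 10) 2L else 1L
      if (gap <= allow && dur_min >= 2) {
        end <- merged_end
        brk <- gap
        i <- i + 1L
      }
    }
    segs[[length(segs) + 1L]] <- c(start, end, brk)
    i <- i + 1L
  }
  m <- do.call(rbind, segs)
  dur <- (m[, 2] - m[, 1] + 1L) * ep_min
  keep <- dur >= 2
  if (!any(keep)) return(empty_amb())
  m <- m[keep, , drop = FALSE]
  dur <- dur[keep]
  data.frame(
    start_epoch = m[, 1],
    end_epoch = m[, 2],
    duration_minutes = dur,
    duration_class = ifelse(dur > 30, ">30min",
                            ifelse(dur >= 10, "10-30min", "2-10min")),
    break_epochs_used = m[, 3],
    stringsAsFactors = FALSE
  )
}

empty_amb <- function() {
  data.frame(start_epoch = integer(), end_epoch = integer(),
             duration_minutes = numeric(), duration_class = character(),
             break_epochs_used = integer(), stringsAsFactors = FALSE)
}
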