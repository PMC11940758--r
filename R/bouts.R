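# Sustained-activity bout detection.
#
# A bout is a maximal interval whose boundary epochs satisfy an intensity
# predicate, whose internal runs of non-compliant epochs each last at most
# `break_tolerance_epochs`, and whose total duration reaches
# `min_duration_minutes`. The production detector works on a run-length
# encoding; `oracle_bouts()` re-derives the same set by forward scanning
# from every candidate start and is used to cross-check the detector.

#' Bout detection configuration
#'
#' @param predicate Intensity class: `"sedentary"` (< 40 mg), `"active"`
#'   (40 to < 100 mg) or `"MVPA"` (>= 100 mg).
#' @param min_duration_minutes Minimum bout duration in minutes; the
#'   conventional thresholds are 10 for active bouts (aligned with
#'   physical-activity guidance) and 3 for MVPA bouts.
#' @param break_tolerance_epochs Maximum length, in epochs, of any internal
#'   non-compliant run (default 1).
#' @return An object of class `bout_config`.
#' @export
bout_config <- function(predicate = c("MVPA", "active", "sedentary"),
                        min_duration_minutes = NULL,
                        break_tolerance_epochs = 1) {
  predicate <- match.arg(predicate)
  if (is.null(min_duration_minutes)) {
    min_duration_minutes <- switch(predicate,
                                   MVPA = 3, active = 10, sedentary = 10)
  }
  if (min_duration_minutes <= 0) stop("min_duration_minutes must be positive")
  if (break_tolerance_epochs < 0) stop("break_tolerance_epochs must be >= 0")
  structure(
    list(
      predicate = predicate,
      min_duration_minutes = min_duration_minutes,
      break_tolerance_epochs = as.integer(break_tolerance_epochs)
    ),
    class = "bout_config"
  )
}

# Per-epoch compliance with a bout predicate; non-wear epochs never comply.
bout_compliance <- function(series, config) {
  v <- series$values
  ok <- switch(config$predicate,
               sedentary = v < 40,
               active = v >= 40 & v < 100,
               MVPA = v >= 100)
  ok & series$wear
}

#' Detect sustained-activity bouts
#'
#' Returns all maximal intervals whose boundary epochs are compliant, whose
#' internal non-compliant runs are each no longer than the break tolerance,
#' and whose duration reaches the minimum; bouts are disjoint and sorted.
#'
#' @param series An [epoch_series()].
#' @param config A [bout_config()].
#' @return Data frame with `start_epoch`, `end_epoch` (inclusive),
#'   `duration_minutes` and `compliant_fraction`.
#' @export
detect_bouts <- function(series, config) {
  stopifnot(inherits(series, "epoch_series"), inherits(config, "bout_config"))
  per_wear_segment(series, function(ok) {
    bouts_from_logical(ok, config$break_tolerance_epochs,
                       min_epochs(series, config))
  }, config)
}

# Non-wear epochs break bouts regardless of tolerance: apply the detector
# within each maximal wear segment and offset the indices.
per_wear_segment <- function(series, fn, config) {
  ok <- bout_compliance(series, config)
  segs <- rle_runs(series$wear)
  segs <- segs[segs$value, , drop = FALSE]
  out <- lapply(seq_len(nrow(segs)), function(k) {
    b <- fn(ok[segs$start[k]:segs$end[k]])
    b$start_epoch <- b$start_epoch + segs$start[k] - 1L
    b$end_epoch <- b$end_epoch + segs$start[k] - 1L
    b
  })
  if (length(out) == 0L) return(empty_bouts())
  do.call(rbind, out)
}

min_epochs <- function(series, config) {
  as.integer(ceiling(config$min_duration_minutes * 60 / series$epoch_seconds))
}

# Core detector on a logical compliance vector: merge compliant runs across
# gaps <= tol, trim to compliant boundaries, filter by duration.
bouts_from_logical <- function(ok, tol, min_ep) {
  n <- length(ok)
  if (n == 0L || !any(ok)) return(empty_bouts())
  runs <- rle_runs(ok)
  comp <- which(runs$value)
  # group consecutive compliant runs whose separating gaps are <= tol
  grp <- cumsum(c(
    1L,
    vapply(seq_along(comp)[-1L], function(j) {
      gap_len <- runs$start[comp[j]] - runs$end[comp[j - 1L]] - 1L
      as.integer(gap_len > tol)
    }, integer(1))
  ))
  starts <- tapply(runs$start[comp], grp, min)
  ends <- tapply(runs$end[comp], grp, max)
  dur <- ends - starts + 1L
  keep <- dur >= min_ep
  if (!any(keep)) return(empty_bouts())
  starts <- as.integer(starts[keep])
  ends <- as.integer(ends[keep])
  frac <- vapply(seq_along(starts), function(k) {
    mean(ok[starts[k]:ends[k]])
  }, numeric(1))
  data.frame(
    start_epoch = starts,
    end_epoch = ends,
    duration_epochs = ends - starts + 1L,
    compliant_fraction = frac,
    stringsAsFactors = FALSE
  )
}

empty_bouts <- function() {
  data.frame(start_epoch = integer(), end_epoch = integer(),
             duration_epochs = integer(), compliant_fraction = numeric(),
             stringsAsFactors = FALSE)
}

#' Brute-force reference bout detector
#'
#' Independently re-derives the bout set by scanning forward from every
#' compliant epoch for the furthest admissible end, then keeping maximal
#' intervals of sufficient duration. Quadratic in the worst case; intended
#' for verification on short inputs.
#'
#' @param series An [epoch_series()].
#' @param config A [bout_config()].
#' @param cap Maximum admissible series length in epochs (default 5000).
#' @return Same format as [detect_bouts()].
#' @export
oracle_bouts <- function(series, config, cap = 5000) {
  stopifnot(inherits(series, "epoch_series"), inherits(config, "bout_config"))
  if (n_epochs(series) > cap) {
    stop("oracle_bouts input exceeds the length cap (", cap, " epochs)")
  }
  per_wear_segment(series, function(ok) {
    oracle_from_logical(ok, config$break_tolerance_epochs,
                        min_epochs(series, config))
  }, config)
}

oracle_from_logical <- function(ok, tol, min_ep) {
  n <- length(ok)
  cand <- list()
  for (s in seq_len(n)) {
    if (!ok[s]) next
    gap <- 0L
    last_ok <- s
    e <- s
    while (e <= n) {
      if (ok[e]) {
        gap <- 0L
        last_ok <- e
      } else {
        gap <- gap + 1L
        if (gap > tol) break
      }
      e <- e + 1L
    }
    cand[[length(cand) + 1L]] <- c(s, last_ok)
  }
  if (length(cand) == 0L) return(empty_bouts())
  m <- unique(do.call(rbind, cand))
  # maximality: drop intervals contained in another candidate
  keep <- vapply(seq_len(nrow(m)), function(i) {
    !any(m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] &
           (m[, 1] < m[i, 1] | m[, 2] > m[i, 2]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[m[, 2] - m[, 1] + 1L >= min_ep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty_bouts())
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(
    start_epoch = m[, 1],
    end_epoch = m[, 2],
    duration_epochs = m[, 2] - m[, 1] + 1L,
    compliant_fraction = vapply(seq_len(nrow(m)), function(k) {
      mean(ok[m[k, 1]:m[k, 2]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Sedentary bouts as the complement of active time
#'
#' Sedentary bouts are the maximal wear-time intervals not covered by any
#' active bout.
#'
#' @param series An [epoch_series()].
#' @param active_bouts Data frame of disjoint, sorted bouts
#'   (from [detect_bouts()]).
#' @return Data frame in the same format as [detect_bouts()]
#'   (`compliant_fraction` is 1 by construction).
#' @export
sedentary_complement <- function(series, active_bouts) {
  stopifnot(inherits(series, "epoch_series"))
  n <- n_epochs(series)
  covered <- rep(FALSE, n)
  if (nrow(active_bouts) > 0L) {
    if (is.unsorted(active_bouts$start_epoch)) {
      stop("active bouts must be sorted")
    }
    if (any(active_bouts$start_epoch[-1L] <=
              active_bouts$end_epoch[-nrow(active_bouts)])) {
      stop("active bouts must be disjoint")
    }
    for (k in seq_len(nrow(active_bouts))) {
      covered[active_bouts$start_epoch[k]:active_bouts$end_epoch[k]] <- TRUE
    }
  }
  free <- series$wear & !covered
  if (!any(free)) return(empty_bouts())
  runs <- rle_runs(free)
  runs <- runs[runs$value, , drop = FALSE]
  data.frame(
    start_epoch = runs$start,
    end_epoch = runs$end,
    duration_epochs = runs$length,
    compliant_fraction = rep(1, nrow(runs)),
    stringsAsFactors = FALSE
  )
}
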