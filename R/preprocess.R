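# Preprocessing of accelerometer data: ENMO magnitude, epoch aggregation,
# non-wear detection, imputation, and wear-time validity.

#' Euclidean norm minus one (ENMO)
#'
#' Converts tri-axial acceleration (in milligravities) to the standard
#' wrist-actigraphy magnitude: the Euclidean norm of the three axes minus
#' 1 g (1000 mg), truncated at zero so a stationary device reads 0.
#'
#' @param x,y,z Numeric vectors of axis acceleration in mg.
#' @return Numeric vector of magnitudes in mg (>= 0).
#' @examples
#' enmo(0, 0, 1000)  # stationary: 0
#' enmo(0, 0, 1100)  # 100
#' @export
enmo <- function(x, y, z) {
  if (anyNA(x) || anyNA(y) || anyNA(z) ||
      any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))) {
    stop("enmo requires finite inputs")
  }
  pmax(0, sqrt(x^2 + y^2 + z^2) - 1000)
}

#' Aggregate timestamped magnitude samples to a uniform epoch grid
#'
#' Each epoch value is the mean of samples falling in `[t, t + epoch)`;
#' epochs containing no sample are marked non-wear.
#'
#' @param samples Data frame with columns `timestamp` (`POSIXct`, sorted
#'   ascending) and `magnitude` (mg).
#' @param epoch_seconds Epoch length in seconds (default 30).
#' @return An [epoch_series()].
#' @export
epoch_aggregate <- function(samples, epoch_seconds = 30) {
  stopifnot(is.data.frame(samples),
            all(c("timestamp", "magnitude") %in% names(samples)))
  ts <- as.numeric(as.POSIXct(samples$timestamp, tz = "UTC"))
  if (is.unsorted(ts, strictly = FALSE)) {
    stop("sample timestamps must be sorted ascending")
  }
  t0 <- floor(ts[1] / epoch_seconds) * epoch_seconds
  idx <- floor((ts - t0) / epoch_seconds) + 1L
  n <- max(idx)
  sums <- tabulate_weighted(idx, samples$magnitude, n)
  counts <- tabulate(idx, nbins = n)
  values <- ifelse(counts > 0, sums / pmax(counts, 1L), 0)
  epoch_series(
    values = values,
    start = as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"),
    epoch_seconds = epoch_seconds,
    wear = counts > 0
  )
}

tabulate_weighted <- function(bin, w, nbins) {
  as.vector(unname(vapply(
    split(w, factor(bin, levels = seq_len(nbins))),
    function(v) if (length(v)) sum(v) else 0,
    numeric(1)
  )))
}

#' Detect non-wear periods from low signal variability
#'
#' Flags as non-wear every epoch inside any sliding window of at least
#' `window_minutes` whose magnitude standard deviation falls below
#' `sd_threshold`. Defaults follow the large-cohort wrist-accelerometer
#' convention of 60-minute windows and a 13 mg threshold.
#'
#' @param series An [epoch_series()].
#' @param window_minutes Window length in minutes (default 60).
#' @param sd_threshold Standard-deviation threshold in mg (default 13).
#' @return The series with its wear mask updated (idempotent).
#' @export
detect_nonwear <- function(series, window_minutes = 60, sd_threshold = 13) {
  stopifnot(inherits(series, "epoch_series"))
  w <- as.integer(round(window_minutes * 60 / series$epoch_seconds))
  if (w < 1L) stop("window shorter than one epoch")
  x <- series$values
  n <- length(x)
  flag <- rep(FALSE, n)
  if (n >= w) {
    cs <- c(0, cumsum(x))
    cs2 <- c(0, cumsum(x^2))
    i <- seq_len(n - w + 1L)
    s <- cs[i + w] - cs[i]
    s2 <- cs2[i + w] - cs2[i]
    v <- pmax(0, (s2 - s^2 / w) / (w - 1))
    low <- which(sqrt(v) < sd_threshold)
    if (length(low)) {
      # union of all low-variability windows via a difference array
      d <- integer(n + 1L)
      d[low] <- d[low] + 1L
      d[low + w] <- d[low + w] - 1L
      flag <- cumsum(d[seq_len(n)]) > 0L
    }
  }
  series$wear <- series$wear & !flag
  series
}

#' Impute non-wear epochs by the same-time-of-day mean
#'
#' Each non-wear epoch is replaced by the mean magnitude over epochs at the
#' same time-of-day slot on days where the device was worn; the imputation
#' mask records the substitution. Wear epochs are never altered.
#'
#' @param series An [epoch_series()].
#' @return The imputed series.
#' @export
impute_missing <- function(series) {
  stopifnot(inherits(series, "epoch_series"))
  if (all(series$wear)) return(series)
  slot <- epoch_of_day(series)
  miss <- !series$wear
  need <- unique(slot[miss])
  slot_mean <- vapply(need, function(s) {
    sel <- slot == s & series$wear
    if (!any(sel)) {
      stop(sprintf(
        "no wear data anywhere at time-of-day slot %02d:%02d:%02d",
        (s * series$epoch_seconds) %/% 3600,
        ((s * series$epoch_seconds) %% 3600) %/% 60,
        (s * series$epoch_seconds) %% 60
      ))
    }
    mean(series$values[sel])
  }, numeric(1))
  names(slot_mean) <- as.character(need)
  series$values[miss] <- slot_mean[as.character(slot[miss])]
  series$imputed <- series$imputed | miss
  series
}

#' Wear-time validity report
#'
#' A recording is valid when total wear time reaches `min_hours`
#' (default 72 hours, the standard large-cohort actigraphy criterion).
#'
#' @param series An [epoch_series()].
#' @param min_hours Minimum total wear hours (default 72).
#' @return A list of class `validity_report` with `total_wear_hours`,
#'   `valid`, and `per_day_wear_hours`.
#' @export
check_validity <- function(series, min_hours = 72) {
  stopifnot(inherits(series, "epoch_series"))
  hrs_per_epoch <- series$epoch_seconds / 3600
  total <- sum(series$wear) * hrs_per_epoch
  per_day <- vapply(
    split(series$wear, epoch_dates(series)),
    function(w) sum(w) * hrs_per_epoch, numeric(1)
  )
  structure(
    list(
      total_wear_hours = total,
      valid = total >= min_hours,
      per_day_wear_hours = per_day
    ),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> %.2f wear hours; %s\n", x$total_wear_hours,
              if (x$valid) "valid" else "invalid"))
  invisible(x)
}
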