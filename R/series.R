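# Epoch-level containers: acceleration magnitude series and activity-label
# series on a shared uniform 30-second grid.

#' Activity-state vocabulary
#'
#' The per-epoch activity states used throughout the package: sleep,
#' sedentary behaviour, light activity, moderate-to-vigorous physical
#' activity (MVPA), walking, and non-wear.
#'
#' @return Character vector of state names, in canonical order.
#' @export
activity_states <- function() {
  c("sleep", "sedentary", "light", "MVPA", "walking", "nonwear")
}

#' Construct an epoch-level acceleration magnitude series
#'
#' An `epoch_series` holds per-epoch acceleration magnitude (ENMO, in
#' milligravities) on a uniform time grid, together with a wear mask and an
#' imputation mask.
#'
#' @param values Numeric vector of non-negative magnitudes (mg), one per epoch.
#' @param start Start timestamp of the first epoch (`POSIXct`); timezone-naive
#'   local time, represented in UTC.
#' @param epoch_seconds Epoch length in seconds (default 30; must divide 60).
#' @param wear Logical wear mask, same length as `values` (default all `TRUE`).
#' @param imputed Logical mask marking imputed epochs (default all `FALSE`).
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(values,
                         start = as.POSIXct("2015-03-02 00:00:00", tz = "UTC"),
                         epoch_seconds = 30,
                         wear = NULL,
                         imputed = NULL) {
  values <- as.double(values)
  if (length(values) == 0L) stop("epoch_series requires at least one epoch")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("epoch_series values must be finite")
  }
  if (any(values < 0)) stop("epoch_series values must be >= 0")
  if (epoch_seconds <= 0 || 60 %% epoch_seconds != 0) {
    stop("epoch_seconds must be positive and divide 60")
  }
  wear <- wear %||% rep(TRUE, length(values))
  imputed <- imputed %||% rep(FALSE, length(values))
  if (length(wear) != length(values) || length(imputed) != length(values)) {
    stop("wear and imputed masks must match the length of values")
  }
  structure(
    list(
      start = as.POSIXct(start, tz = "UTC"),
      epoch_seconds = as.integer(epoch_seconds),
      values = values,
      wear = as.logical(wear),
      imputed = as.logical(imputed)
    ),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> %d epochs of %ds from %s; wear %.1f h\n",
    length(x$values), x$epoch_seconds, format(x$start),
    sum(x$wear) * x$epoch_seconds / 3600
  ))
  invisible(x)
}

#' Construct a per-epoch activity label series
#'
#' A `label_series` assigns one activity state per epoch, aligned to the grid
#' of an [epoch_series()].
#'
#' @param labels Character or factor vector of states from
#'   [activity_states()].
#' @param start Start timestamp of the first epoch.
#' @param epoch_seconds Epoch length in seconds.
#' @return An object of class `label_series`.
#' @export
label_series <- function(labels,
                         start = as.POSIXct("2015-03-02 00:00:00", tz = "UTC"),
                         epoch_seconds = 30) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("label_series requires at least one epoch")
  bad <- setdiff(unique(labels), activity_states())
  if (length(bad) > 0L) {
    stop("unknown activity labels: ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      start = as.POSIXct(start, tz = "UTC"),
      epoch_seconds = as.integer(epoch_seconds),
      labels = factor(labels, levels = activity_states())
    ),
    class = "label_series"
  )
}

#' @export
print.label_series <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<label_series> %d epochs from %s\n", length(x$labels),
              format(x$start)))
  print(tab)
  invisible(x)
}

#' Number of epochs in a series
#' @param x An `epoch_series` or `label_series`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) {
  if (inherits(x, "epoch_series")) length(x$values)
  else if (inherits(x, "label_series")) length(x$labels)
  else stop("not an epoch- or label-series")
}

#' Epoch timestamps of a series
#' @param x An `epoch_series` or `label_series`.
#' @return `POSIXct` vector of epoch start times.
#' @export
epoch_times <- function(x) {
  x$start + (seq_len(n_epochs(x)) - 1L) * x$epoch_seconds
}

# Zero-based epoch-of-day index (0 .. epochs_per_day - 1).
epoch_of_day <- function(x) {
  epd <- 86400L %/% x$epoch_seconds
  off <- as.integer(as.numeric(x$start) %% 86400) %/% x$epoch_seconds
  (off + seq_len(n_epochs(x)) - 1L) %% epd
}

# Hour of day in [0, 24) for each epoch.
hour_of_day <- function(x) {
  epoch_of_day(x) * x$epoch_seconds / 3600
}

# Calendar date of each epoch.
epoch_dates <- function(x) {
  as.Date(floor(as.numeric(epoch_times(x)) / 86400), origin = "1970-01-01")
}

epochs_per_day <- function(x) 86400L %/% x$epoch_seconds

check_aligned <- function(series, labels) {
  if (n_epochs(series) != n_epochs(labels) ||
      series$epoch_seconds != labels$epoch_seconds ||
      abs(as.numeric(series$start) - as.numeric(labels$start)) > 1e-6) {
    stop("epoch series and label series are not aligned")
  }
  invisible(TRUE)
}
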