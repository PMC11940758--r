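# Shared fixtures built in code.

MIDNIGHT <- as.POSIXct("2015-03-02 00:00:00", tz = "UTC")  # a Monday

# Epoch series from a per-epoch magnitude vector starting at midnight.
make_series <- function(values, wear = NULL, start = MIDNIGHT) {
  epoch_series(values, start = start, epoch_seconds = 30, wear = wear)
}

# Magnitudes given per-minute blocks: c(minutes = mg, ...).
minutes_of <- function(...) {
  blocks <- list(...)
  unlist(lapply(blocks, function(b) rep(b[["mg"]], b[["min"]] * 2)))
}

# Label series from a run-length specification list(label =, min =).
make_labels <- function(..., start = MIDNIGHT) {
  blocks <- list(...)
  lab <- unlist(lapply(blocks, function(b) rep(b$label, b$min * 2)))
  label_series(lab, start = start, epoch_seconds = 30)
}

default_profile <- function(group = "RA") {
  list(group = group, activity_level = 1, mvpa_propensity = 1)
}

quiet_params <- function(...) activity_model_params(nonwear_rate = 0, ...)
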