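# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded operations are reproducible without perturbing the session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from a master seed; kept below 2^31 so the
# values remain representable as R integers.
derive_seeds <- function(seed, n) {
  (as.double(seed) * 48271 + 11 * seq_len(n)) %% 2147483629
}

# Circular mean of clock times expressed as hours in [0, 24).
circular_mean_hours <- function(h, na.rm = TRUE) {
  if (na.rm) h <- h[!is.na(h)]
  if (length(h) == 0L) return(NA_real_)
  ang <- h / 24 * 2 * pi
  m <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * 24
  if (m < 0) m <- m + 24
  m
}

# Run-length encoding that keeps start indices alongside lengths and values.
rle_runs <- function(x) {
  r <- rle(as.vector(x))
  ends <- cumsum(r$lengths)
  data.frame(
    value = r$values,
    start = ends - r$lengths + 1L,
    end = ends,
    length = r$lengths,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
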