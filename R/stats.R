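# Group screening and adjustment: log-ratio screening with Welch
# confidence intervals, one-way ANOVA, single-covariate ANCOVA,
# wake-aligned population activity profiles, and standardized PCA.

#' Screen one metric for a case-control difference
#'
#' Values are natural-log transformed in each group (zeros offset by half
#' the smallest positive observed value) and the geometric-mean ratio
#' (case / control) is estimated with a Welch 95% confidence interval on
#' the log-mean difference. A metric is flagged when the mean relative
#' difference exceeds 5% (|ratio - 1| > 0.05) and the interval excludes 1.
#' Clock-time metrics (`scale = "linear"`) are screened on the linear scale
#' with an arithmetic-difference interval and flagged when the interval
#' excludes 0.
#'
#' @param values_case,values_ctrl Numeric vectors of metric values.
#' @param conf_level Confidence level (default 0.95).
#' @param min_ratio_diff Magnitude rule on the ratio scale (default 0.05).
#' @param scale `"log"` (ratio screening) or `"linear"` (difference
#'   screening for clock-time metrics).
#' @param zero_offset Offset added before the log transform; default half
#'   the smallest positive observed value, used only when zeros are
#'   present.
#' @return A one-row data frame (`estimate`, `ci_low`, `ci_high`,
#'   `flagged`, `n_case`, `n_ctrl`, `scale`), or `NULL` when either group
#'   has fewer than two non-missing values.
#' @export
screen_metric <- function(values_case, values_ctrl, conf_level = 0.95,
                          min_ratio_diff = 0.05, scale = c("log", "linear"),
                          zero_offset = NULL) {
  scale <- match.arg(scale)
  x <- values_case[!is.na(values_case)]
  y <- values_ctrl[!is.na(values_ctrl)]
  if (length(x) < 2L || length(y) < 2L) return(NULL)

  if (scale == "log") {
    if (any(x < 0) || any(y < 0)) {
      stop("log-scale screening requires non-negative values")
    }
    if (any(x == 0) || any(y == 0)) {
      off <- zero_offset %||% {
        pos <- c(x[x > 0], y[y > 0])
        if (length(pos) == 0L) return(NULL)
        min(pos) / 2
      }
      x <- x + off
      y <- y + off
    }
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(NULL)
    tt <- stats::t.test(log(x), log(y), conf.level = conf_level)
    est <- exp(mean(log(x)) - mean(log(y)))
    ci <- exp(tt$conf.int)
    flagged <- abs(est - 1) > min_ratio_diff && (ci[1] > 1 || ci[2] < 1)
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(NULL)
    tt <- stats::t.test(x, y, conf.level = conf_level)
    est <- mean(x) - mean(y)
    ci <- tt$conf.int
    flagged <- ci[1] > 0 || ci[2] < 0
  }
  data.frame(
    estimate = est, ci_low = ci[1], ci_high = ci[2], flagged = flagged,
    n_case = length(x), n_ctrl = length(y), scale = scale,
    stringsAsFactors = FALSE
  )
}

#' Screen every metric of a metric matrix
#'
#' @param matrix Participant-by-metric matrix from [metric_matrix()].
#' @param groups Character vector (`"RA"` / `"control"`) aligned to rows.
#' @param registry Metric registry (for the per-metric screening scale).
#' @param ... Passed to [screen_metric()].
#' @return Data frame with one row per screenable metric, including
#'   `metric_id`.
#' @export
screen_all <- function(matrix, groups, registry = build_registry(), ...) {
  scales <- registry_scales(registry)
  is_case <- groups == "RA"
  rows <- lapply(colnames(matrix), function(id) {
    r <- screen_metric(matrix[is_case, id], matrix[!is_case, id],
                       scale = scales[[id]] %||% "log", ...)
    if (is.null(r)) return(NULL)
    cbind(data.frame(metric_id = id, stringsAsFactors = FALSE), r)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' One-way ANOVA on log-transformed metric values
#'
#' Supports the group factor as well as diagnosis source, diagnosis type
#' and disease onset as factors.
#'
#' @param values Numeric vector of metric values.
#' @param factor_ Factor (or coercible) with at least two non-empty levels.
#' @param log_transform Log-transform values first (default `TRUE`; zeros
#'   offset by half the smallest positive value).
#' @return A list with `F` and `p`.
#' @export
anova_oneway <- function(values, factor_, log_transform = TRUE) {
  keep <- !is.na(values) & !is.na(factor_)
  values <- values[keep]
  f <- droplevels(factor(factor_[keep]))
  if (nlevels(f) < 2L) stop("factor must have at least two non-empty levels")
  if (any(table(f) < 2L)) stop("every factor level needs at least two values")
  y <- transform_log(values, log_transform)
  fit <- stats::aov(y ~ f)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1])
}

transform_log <- function(values, log_transform) {
  if (!log_transform) return(values)
  if (any(values < 0)) stop("log transform requires non-negative values")
  if (any(values == 0)) {
    pos <- values[values > 0]
    values <- values + (if (length(pos)) min(pos) / 2 else 1)
  }
  log(values)
}

#' Single-covariate ANCOVA for the group effect
#'
#' Linear model of (log) metric values on the covariate plus group; the
#' group effect is tested adjusted for the covariate (sequential F with
#' the group term last).
#'
#' @param values Numeric metric values.
#' @param group Two-level group labels.
#' @param covariate Numeric covariate or categorical labels (indicator
#'   contrasts).
#' @param log_transform Log-transform values first (default `TRUE`).
#' @return A list with `group_effect` (adjusted log-scale difference,
#'   case level vs reference), `p` (adjusted group p-value) and `fit`.
#' @export
ancova <- function(values, group, covariate, log_transform = TRUE) {
  keep <- !is.na(values) & !is.na(group) & !is.na(covariate)
  values <- values[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (is.numeric(covariate)) {
    cov <- covariate[keep]
    if (stats::var(cov) == 0) stop("covariate is constant")
  } else {
    cov <- droplevels(factor(covariate[keep]))
    if (nlevels(cov) < 2L) stop("covariate is constant")
  }
  y <- transform_log(values, log_transform)
  fit <- stats::lm(y ~ cov + group)
  an <- stats::anova(fit)
  co <- stats::coef(fit)
  gcoef <- co[grep("^group", names(co))][1]
  list(
    group_effect = unname(gcoef),
    p = an[["Pr(>F)"]][rownames(an) == "group"],
    fit = fit
  )
}

#' Wake-aligned population activity profiles
#'
#' For each participant, per-epoch indicators of the four displayed
#' activity types (sleep, sedentary, light, MVPA; walking epochs count as
#' MVPA) are aligned to time since the estimated wake-up of each day,
#' averaged within participant across days, then across participants
#' within each group. The difference profile is case minus control.
#'
#' @param data Named list of per-participant lists with `labels`
#'   ([label_series()]) and `getups` (`POSIXct` vector).
#' @param groups Named character vector (`"RA"` / `"control"`) over the
#'   same participant ids.
#' @param horizon_hours Profile length in hours since wake-up (default 24).
#' @return A list of class `profile_matrix` with `time_hours`, per-group
#'   probability matrices (`labels x bins`), and `difference`.
#' @export
activity_profiles <- function(data, groups, horizon_hours = 24) {
  show_states <- c("sleep", "sedentary", "light", "MVPA")
  ids <- names(data)
  stopifnot(!is.null(ids), all(ids %in% names(groups)))
  if (!any(groups[ids] == "RA") || !any(groups[ids] == "control")) {
    stop("both groups must contain at least one participant")
  }

  participant_profile <- function(d) {
    labels <- d$labels
    eps <- labels$epoch_seconds
    nbin <- as.integer(horizon_hours * 3600 / eps)
    lab <- as.character(labels$labels)
    lab[lab == "walking"] <- "MVPA"
    secs <- as.numeric(epoch_times(labels))
    counts <- matrix(0, nrow = length(show_states), ncol = nbin,
                     dimnames = list(show_states, NULL))
    denom <- numeric(nbin)
    for (g in as.numeric(d$getups)) {
      i0 <- which(secs >= g)[1]
      if (is.na(i0)) next
      idx <- i0:min(length(lab), i0 + nbin - 1L)
      bins <- seq_along(idx)
      keep <- lab[idx] %in% show_states
      for (s in show_states) {
        sel <- bins[keep & lab[idx] == s]
        counts[s, sel] <- counts[s, sel] + 1
      }
      denom[bins[keep]] <- denom[bins[keep]] + 1
    }
    prob <- sweep(counts, 2, pmax(denom, 1), "/")
    prob[, denom == 0] <- NA_real_
    prob
  }

  profs <- lapply(data, participant_profile)
  group_mean <- function(g) {
    sel <- profs[groups[ids] == g]
    arr <- simplify2array(sel)
    apply(arr, c(1, 2), mean, na.rm = TRUE)
  }
  p_case <- group_mean("RA")
  p_ctrl <- group_mean("control")
  eps <- data[[1]]$labels$epoch_seconds
  structure(
    list(
      time_hours = (seq_len(ncol(p_case)) - 0.5) * eps / 3600,
      case = p_case,
      control = p_ctrl,
      difference = p_case - p_ctrl
    ),
    class = "profile_matrix"
  )
}

#' Standardized principal component analysis of the metric matrix
#'
#' Metrics with any missing value are excluded (and recorded), the
#' remaining columns are centred and standardized to unit SD, and the PCA
#' is computed by singular value decomposition. Constant columns cannot be
#' standardized and are likewise excluded.
#'
#' @param matrix Participant-by-metric matrix.
#' @param cumulative_variance Threshold used to suggest a component count
#'   (default 0.70).
#' @return A list of class `pca_result` with `loadings`, `scores`,
#'   `variance_fraction`, `n_components` (smallest count reaching the
#'   threshold), and `excluded_for_missingness`.
#' @export
pca_metrics <- function(matrix, cumulative_variance = 0.70) {
  has_na <- apply(matrix, 2, anyNA)
  excluded <- colnames(matrix)[has_na]
  m <- matrix[, !has_na, drop = FALSE]
  constant <- apply(m, 2, function(x) stats::var(x) == 0)
  excluded_const <- colnames(m)[constant]
  m <- m[, !constant, drop = FALSE]
  if (ncol(m) < 2L) stop("PCA requires at least two complete metrics")
  if (nrow(m) < 3L) stop("PCA requires at least three participants")
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      included_metrics = colnames(m),
      loadings = pc$rotation,
      scores = pc$x,
      variance_fraction = vf,
      n_components = which(cumsum(vf) >= cumulative_variance)[1],
      excluded_for_missingness = excluded,
      excluded_constant = excluded_const
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d metrics, %d components to reach %.0f%% variance\n",
    length(x$included_metrics), x$n_components,
    100 * sum(x$variance_fraction[seq_len(x$n_components)])
  ))
  invisible(x)
}
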