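# Shared configuration for the analysis scripts.
#
# The study is fully synthetic and deterministic given SEED: each script can
# rebuild the simulated dataset on its own, with a cache under scratch/ to
# avoid recomputation across scripts.

library(actipat)

SEED <- 20250326
N_RA <- 40
N_POOL <- 160
DAYS <- 7
RESULTS <- "results"
SCRATCH <- "scratch"

dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

study_config <- function() {
  run_config(seed = SEED, n_ra = N_RA, n_pool = N_POOL, days = DAYS,
             effect = ra_effect())  # the default RA effect bundle
}

# Simulated cohort + epoch data + getups, cached across scripts.
load_study <- function() {
  cache <- file.path(SCRATCH, "study.rds")
  if (file.exists(cache)) return(readRDS(cache))
  cfg <- study_config()
  res <- run_pipeline(structure(modifyList(unclass(cfg),
                                           list(stages = "simulate")),
                                class = "run_config"))
  saveRDS(res, cache)
  res
}

load_metrics <- function() {
  path <- file.path(SCRATCH, "metric_matrix.rds")
  if (file.exists(path)) return(readRDS(path))
  stop("run analysis/02_metrics.R first")
}
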