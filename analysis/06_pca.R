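#!/usr/bin/env Rscript
# Standardized PCA of the flagged metrics over all participants: how the
# differentiating metrics co-vary, how much variance the leading
# components carry, and which metrics load on them.

source("analysis/00_config.R")

mm <- load_metrics()
screen <- read.csv(file.path(RESULTS, "screen.csv"))

flagged <- screen$metric_id[screen$flagged]
cat(sprintf("PCA over %d flagged metrics, %d participants\n",
            length(flagged), nrow(mm)))

p <- pca_metrics(mm[, flagged, drop = FALSE])
if (length(p$excluded_for_missingness)) {
  cat("excluded for missing data:",
      paste(p$excluded_for_missingness, collapse = ", "), "\n")
}
vf <- p$variance_fraction
cat(sprintf("variance fractions: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%% (cum %.1f%%)\n",
            100 * vf[1], 100 * vf[2], 100 * vf[3], 100 * sum(vf[1:3])))
cat(sprintf("components needed for 70%% cumulative variance: %d\n",
            p$n_components))

top <- function(k) {
  ld <- sort(abs(p$loadings[, k]), decreasing = TRUE)
  paste(names(ld)[1:3], collapse = ", ")
}
for (k in 1:3) cat(sprintf("PC%d top loadings: %s\n", k, top(k)))

write.csv(data.frame(metric_id = rownames(p$loadings),
                     p$loadings[, 1:min(5, ncol(p$loadings))],
                     check.names = FALSE),
          file.path(RESULTS, "pca_loadings.csv"), row.names = FALSE)
write.csv(data.frame(component = seq_along(vf), variance_fraction = vf),
          file.path(RESULTS, "pca_variance.csv"), row.names = FALSE)
write.csv(data.frame(id = rownames(p$scores),
                     p$scores[, 1:min(3, ncol(p$scores))],
                     check.names = FALSE),
          file.path(RESULTS, "pca_scores.csv"), row.names = FALSE)
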