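#!/usr/bin/env Rscript
# Can a blind model tell whether a urine specimen came from a female donor?
# DAPC models at the four variance tiers, each evaluated by the blind
# leave-one-out build/test routine (PCA and discriminant refit without the
# held-out specimen in every fold). Writes the accuracy/sensitivity/
# specificity table to results/.

library(ramanurine)

scans <- read_scan_matrix("scratch/cohort_preprocessed.csv", "wide")
set <- assemble_set(scans, scans[[1]]$shifts)
meta <- read_metadata("results/cohort_metadata.csv")

donor_ids <- meta$specimen_id[!meta$is_control]
donors <- subset_rows(set, set$specimen_ids %in% donor_ids)
sex <- setNames(meta$sex[!meta$is_control], donor_ids)

vf <- fit_pca(donors)$variance_fraction
tiers <- c(0.90, 0.95, 0.99, 0.999)
rows <- lapply(tiers, function(t) {
  k <- select_n_pcs(vf, t)
  r <- loo_validate(donors, sex, positive_class = "F", n_pcs = k)
  m <- r$metrics
  cat(sprintf("tier %5.1f%% (%3d PCs): accuracy %s, sensitivity %s, specificity %s\n",
              100 * t, k, format_percent(m$accuracy),
              format_percent(m$sensitivity), format_percent(m$specificity)))
  data.frame(tier_pct = 100 * t, n_pcs = k, accuracy = m$accuracy,
             sensitivity = m$sensitivity, specificity = m$specificity)
})
write.csv(do.call(rbind, rows), "results/sex_loo_metrics.csv", row.names = FALSE)
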