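#!/usr/bin/env Rscript
# The 30-day daily-collection subset: per-donor TPD ranges, whether donor
# identity and menstruation explain TPD (two-way ANOVA + Tukey HSD), and
# whether a blind model can link a specimen to its donor or flag
# menstruation. Writes per-donor summaries and LOO metrics to results/.

library(ramanurine)

scans <- read_scan_matrix("scratch/thirty_day_preprocessed.csv", "wide")
set <- assemble_set(scans, scans[[1]]$shifts)
meta <- read_metadata("results/thirty_day_metadata.csv")

pca <- fit_pca(set)
dt <- distance_table(set, pca, meta)
md <- meta[match(dt$specimen_id, meta$specimen_id), ]

summ <- tpd_summary(dt, md$donor_id)
cat("per-donor TPD (mean ± 1 s.d., range):\n")
print(summ[, c("group", "n", "summary", "range")])
write.csv(summ, "results/thirty_day_tpd_summary.csv", row.names = FALSE)

tab <- two_way_anova(dt$tpd, md$donor_id, md$menstruation,
                     factor_names = c("donor", "menstruation"))
cat(sprintf("donor p = %s; menstruation p = %s\n",
            format_p(tab$p[tab$source == "donor"]),
            format_p(tab$p[tab$source == "menstruation"])))
write.csv(as.data.frame(tab), "results/thirty_day_anova.csv", row.names = FALSE)

tk <- tukey_hsd(dt$tpd, md$donor_id)
print(tk)
write.csv(tk, "results/thirty_day_tukey.csv", row.names = FALSE)

donor_ids <- meta$specimen_id[!meta$is_control]
donors <- subset_rows(set, set$specimen_ids %in% donor_ids)
lab <- setNames(meta$donor_id[!meta$is_control], donor_ids)
k <- select_n_pcs(fit_pca(donors)$variance_fraction, 0.99)
r <- loo_validate(donors, lab, n_pcs = k)
cat(sprintf("donor-identity LOO at the 99%% tier (%d PCs):\n", k))
print(r)
per <- do.call(rbind, lapply(names(r$metrics), function(cl) {
  m <- r$metrics[[cl]]
  data.frame(donor = cl, accuracy = m$accuracy, sensitivity = m$sensitivity,
             specificity = m$specificity)
}))
cat(sprintf("average donor-ID accuracy %s (sensitivity %s, specificity %s)\n",
            format_percent(mean(per$accuracy)),
            format_percent(mean(per$sensitivity)),
            format_percent(mean(per$specificity))))
write.csv(per, "results/thirty_day_donor_loo.csv", row.names = FALSE)

# menstruation flag as a binary classification (two flagged donors only)
mens <- setNames(ifelse(meta$menstruation[!meta$is_control], "yes", "no"),
                 donor_ids)
rm_ <- loo_validate(donors, mens, positive_class = "yes", n_pcs = k)
cat("menstruation-flag LOO: ")
print(rm_$metrics)
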