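#!/usr/bin/env Rscript
# Reduce every specimen to its distance from the synthetic-urine control:
# TPD (first four PC scores) and TSD (full windowed spectrum). Then ask
# whether donor sex and birth year explain TPD by the two-step two-way
# ANOVA (interaction first; dropped if non-significant). Writes the
# distance table and ANOVA tables to results/.

library(ramanurine)

scans <- read_scan_matrix("scratch/cohort_preprocessed.csv", "wide")
set <- assemble_set(scans, scans[[1]]$shifts)
meta <- read_metadata("results/cohort_metadata.csv")

pca <- fit_pca(set)
dt <- distance_table(set, pca, meta)
write.csv(dt, "results/cohort_distances.csv", row.names = FALSE)
cat(sprintf("TPD over %d specimens: mean %.3f, range %.3f - %.3f\n",
            nrow(dt), mean(dt$tpd), min(dt$tpd), max(dt$tpd)))

md <- meta[match(dt$specimen_id, meta$specimen_id), ]
out <- anova_two_step(dt$tpd, md$sex, md$birth_year,
                      factor_names = c("sex", "birth_year"))
cat(sprintf("interaction p = %s (%s)\n", format_p(out$interaction_p),
            if (out$interaction_kept) "kept" else "dropped"))
fin <- as.data.frame(out$final)
fin$p_rendered <- format_p(fin$p)
print(fin)
cat(sprintf("sex p = %s; birth-year p = %s\n",
            format_p(fin$p[fin$source == "sex"]),
            format_p(fin$p[fin$source == "birth_year"])))
write.csv(fin, "results/tpd_anova.csv", row.names = FALSE)
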