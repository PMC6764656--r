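#!/usr/bin/env Rscript
# Generate the synthetic study data: a cross-sectional healthy cohort
# (39 female + 9 male donors, 5 specimens each, 10 scans per specimen), a
# synthetic-urine control, and a 30-day daily-collection subset (3 female +
# 1 male donors). Scan matrices are large, so they land in scratch/; the
# small metadata tables go to results/.

library(ramanurine)

seed <- 20260921L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
coh <- generate_cohort(cfg)
ctl <- generate_control(cfg, n_scans = 10)

write_scan_matrix(assemble_set(c(coh$scans, ctl$scans)),
                  "scratch/cohort_scans.csv")
write.csv(rbind(coh$metadata, ctl$metadata), "results/cohort_metadata.csv",
          row.names = FALSE)

cfg30 <- cohort_config(scans_per_specimen = 2, donor_cv = 0.30,
                       day_cv = 0.05, seed = seed + 1L)
td <- generate_30day(cfg30, menstruation_days = list(F01 = 1:5, F02 = 10:14))
ctl30 <- generate_control(cfg30, n_scans = 5)
write_scan_matrix(assemble_set(c(td$scans, ctl30$scans)),
                  "scratch/thirty_day_scans.csv")
write.csv(rbind(td$metadata, ctl30$metadata),
          "results/thirty_day_metadata.csv", row.names = FALSE)

cat(sprintf("cohort: %d scans, %d specimens (%d donors)\n",
            length(coh$scans) + length(ctl$scans),
            nrow(coh$metadata), length(unique(coh$metadata$donor_id))))
cat(sprintf("30-day: %d scans, %d specimens (4 donors x 30 days)\n",
            length(td$scans) + length(ctl30$scans), nrow(td$metadata)))
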