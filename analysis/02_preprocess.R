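#!/usr/bin/env Rscript
# Preprocess the raw scan matrices written by 01_simulate.R: per-scan
# baseline correction, replicate averaging per specimen, vector
# normalization, and truncation to the 400-1800 cm^-1 analysis window.
# Writes the per-specimen normalized sets (one wide CSV each) to scratch/
# and a range-of-normal summary (mean +/- sd envelope) to results/.

library(ramanurine)

for (study in c("cohort", "thirty_day")) {
  scans <- read_scan_matrix(sprintf("scratch/%s_scans.csv", study), "wide")
  set <- preprocess_pipeline(scans)
  set <- truncate_window(set, c(400, 1800))
  write_scan_matrix(set, sprintf("scratch/%s_preprocessed.csv", study))
  env <- summarize_spectra(set)
  write.csv(env, sprintf("results/%s_spectrum_envelope.csv", study),
            row.names = FALSE)
  cat(sprintf("%s: %d specimens x %d channels; mean spectrum peak at %g cm^-1\n",
              study, nrow(set$intensities), length(set$grid),
              env$shift[which.max(env$mean)]))
}
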