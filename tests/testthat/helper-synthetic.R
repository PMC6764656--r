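# Shared fixture builders. Everything is generated in code at test time.

# A tiny spectrum on an equispaced grid with a known analytic form.
toy_spectrum <- function(n = 21, id = "S1", scan = 1L,
                         f = function(x) 2 * x) {
  x <- seq(400, 400 + 2 * (n - 1), by = 2)
  raman_spectrum(x, f(x), id, scan)
}

# A small spectrum_set from a plain matrix.
toy_set <- function(m, ids = paste0("S", seq_len(nrow(m))),
                    grid = seq(400, 400 + 2 * (ncol(m) - 1), by = 2),
                    scan = NA_integer_) {
  spectrum_set(grid, m, ids, scan)
}

# One synthetic spectrum = quadratic baseline + Lorentzian peaks + noise,
# returning the generating truth alongside the observation.
peaky_spectrum <- function(seed, n_peaks = sample(3:8, 1), noise_sd = 1,
                           grid = default_grid()) {
  set.seed(seed)
  x <- grid / 1000
  bl <- runif(1, 0, 50) + runif(1, -30, 30) * x + runif(1, -10, 10) * x^2
  centers <- runif(n_peaks, min(grid) + 50, max(grid) - 50)
  amps <- runif(n_peaks, 50, 200)
  fw <- runif(n_peaks, 8, 14)
  peak_signal <- rep(0, length(grid))
  for (j in seq_len(n_peaks)) {
    g <- fw[j] / 2
    peak_signal <- peak_signal + amps[j] * g^2 / ((grid - centers[j])^2 + g^2)
  }
  y <- bl + peak_signal + rnorm(length(grid), 0, noise_sd)
  peak_cover <- mean(peak_signal > 0.01 * max(amps))
  list(spectrum = raman_spectrum(grid, y, "syn"),
       baseline = bl, centers = centers, amps = amps, fwhm = fw,
       peak_fraction = max(peak_cover, 0.05))
}

# A sex-effect cohort config with all nuisance knobs set explicitly.
sex_cohort_config <- function(seed, n_per_sex = 30, urea_multiplier = 1,
                              donor_cv = 0.25, day_cv = 0,
                              scans = 1L, noise_sd = 1) {
  mult <- ifelse(vapply(default_peaks(), `[[`, character(1),
                        "metabolite") == "urea", urea_multiplier, 1)
  cohort_config(n_female = n_per_sex, n_male = n_per_sex,
                specimens_per_donor = 1L, scans_per_specimen = scans,
                sex_multiplier = mult, age_slope = 0,
                donor_cv = donor_cv, day_cv = day_cv,
                noise_sd = noise_sd, seed = seed)
}

# Generate, preprocess, and window a cohort in one call.
preprocessed_cohort <- function(config, window = c(400, 1800),
                                with_control = FALSE, n_control_scans = 3L) {
  coh <- generate_cohort(config)
  scans <- coh$scans
  meta <- coh$metadata
  if (with_control) {
    ctl <- generate_control(config, n_scans = n_control_scans)
    scans <- c(scans, ctl$scans)
    meta <- rbind(meta, ctl$metadata)
  }
  set <- truncate_window(preprocess_pipeline(scans), window)
  list(set = set, metadata = meta)
}
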