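test_that("the degenerate generator collapses to identical spectra", {
  cfg <- cohort_config(n_female = 2, n_male = 2, specimens_per_donor = 2,
                       scans_per_specimen = 2, sex_multiplier = 1,
                       age_slope = 0, donor_cv = 0, day_cv = 0,
                       noise_sd = 0, seed = 5)
  coh <- generate_cohort(cfg)
  ref <- coh$scans[[1]]$intensities
  for (sp in coh$scans) expect_identical(sp$intensities, ref)
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- cohort_config(n_female = 3, n_male = 2, specimens_per_donor = 2,
                       scans_per_specimen = 2, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$scans, `[[`, "intensities"),
                   lapply(b$scans, `[[`, "intensities"))
  expect_identical(a$metadata, b$metadata)
  cfg2 <- cohort_config(n_female = 3, n_male = 2, specimens_per_donor = 2,
                        scans_per_specimen = 2, seed = 124)
  c <- generate_cohort(cfg2)
  expect_false(identical(a$scans[[1]]$intensities, c$scans[[1]]$intensities))
})

test_that("substreams are split per donor: subsetting does not shift draws", {
  big <- cohort_config(n_female = 4, n_male = 0, specimens_per_donor = 1,
                       scans_per_specimen = 1, age_slope = 0, seed = 9)
  small <- cohort_config(n_female = 2, n_male = 0, specimens_per_donor = 1,
                         scans_per_specimen = 1, age_slope = 0, seed = 9)
  a <- generate_cohort(big)
  b <- generate_cohort(small)
  # donor birth years are drawn in one block, so amplitudes can differ via
  # the age term; with age_slope = 0 the first two donors' spectra coincide
  expect_identical(a$scans[[1]]$intensities, b$scans[[1]]$intensities)
  expect_identical(a$scans[[2]]$intensities, b$scans[[2]]$intensities)
})

test_that("the configured sex multiplier is recovered from apex heights", {
  mult <- ifelse(vapply(default_peaks(), `[[`, character(1),
                        "metabolite") == "urea", 2, 1)
  cfg <- cohort_config(n_female = 50, n_male = 50, specimens_per_donor = 1,
                       scans_per_specimen = 1, sex_multiplier = mult,
                       age_slope = 0, donor_cv = 0.1, day_cv = 0,
                       noise_sd = 0.5, seed = 31)
  coh <- generate_cohort(cfg)
  grid <- cfg$grid
  apex <- which.min(abs(grid - 1002))
  bgcfg <- preprocess_config(poly_order = 7, peak_fraction = 0.3)
  heights <- vapply(coh$scans, function(sp) {
    correct_baseline(sp, bgcfg)$intensities[apex]
  }, numeric(1))
  sex <- coh$metadata$sex[match(vapply(coh$scans, `[[`, character(1),
                                       "specimen_id"),
                                coh$metadata$specimen_id)]
  ratio <- mean(heights[sex == "M"]) / mean(heights[sex == "F"])
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)
})

test_that("donor-level amplitude variation converges to the configured CV", {
  cfg <- cohort_config(n_female = 500, n_male = 0, specimens_per_donor = 1,
                       scans_per_specimen = 1, sex_multiplier = 1,
                       age_slope = 0, donor_cv = 0.25, day_cv = 0,
                       noise_sd = 0, seed = 77)
  # read the urea apex straight off the noise-free clean spectra
  apex <- which.min(abs(cfg$grid - 1002))
  coh <- generate_cohort(cfg)
  h <- vapply(coh$scans, function(sp) sp$intensities[apex], numeric(1))
  # subtract the shared background at the apex channel
  cfg0 <- cohort_config(n_female = 1, n_male = 0, specimens_per_donor = 1,
                        scans_per_specimen = 1, sex_multiplier = 1,
                        age_slope = 0, donor_cv = 0, day_cv = 0, noise_sd = 0,
                        peaks = list(peak_spec(1002, 10, 0, "urea")), seed = 1)
  bg <- generate_cohort(cfg0)$scans[[1]]$intensities[apex]
  amp <- h - bg
  cv_hat <- sd(amp) / mean(amp)
  expect_lt(abs(cv_hat - 0.25) / 0.25, 0.10)
})

test_that("control scans are fixed, flagged, and reproducible", {
  cfg <- cohort_config(noise_sd = 0, seed = 10)
  ctl <- generate_control(cfg, n_scans = 10)
  expect_length(ctl$scans, 10)
  ref <- ctl$scans[[1]]$intensities
  for (sp in ctl$scans) expect_identical(sp$intensities, ref)
  expect_true(ctl$metadata$is_control)
  # with noise the scans differ but are seed-stable
  cfgn <- cohort_config(noise_sd = 1, seed = 10)
  a <- generate_control(cfgn, 3)
  b <- generate_control(cfgn, 3)
  expect_identical(a$scans[[2]]$intensities, b$scans[[2]]$intensities)
  expect_false(identical(a$scans[[1]]$intensities, a$scans[[2]]$intensities))
  # the control profile differs from the cohort's metabolite profile
  coh <- generate_cohort(cohort_config(n_female = 1, n_male = 0,
                                       specimens_per_donor = 1,
                                       scans_per_specimen = 1,
                                       sex_multiplier = 1, age_slope = 0,
                                       donor_cv = 0, day_cv = 0, noise_sd = 0,
                                       seed = 10))
  expect_false(identical(ctl$scans[[1]]$intensities,
                         coh$scans[[1]]$intensities))
})

test_that("the 30-day design produces donor-by-day specimens with flags", {
  cfg <- cohort_config(scans_per_specimen = 1, seed = 3)
  td <- generate_30day(cfg, menstruation_days = list(F01 = 1:4))
  expect_equal(nrow(td$metadata), 120)  # 4 donors x 30 days
  expect_length(td$scans, 120)
  expect_equal(sum(td$metadata$menstruation), 4)
  expect_true(all(td$metadata$menstruation[td$metadata$sex == "M"] == FALSE))
  expect_equal(sort(unique(td$metadata$donor_id)), c("F01", "F02", "F03", "M01"))
  expect_error(generate_30day(cfg, menstruation_days = list(M01 = 1:2)),
               "config error")
})

test_that("a zero menstruation effect leaves flagged spectra indistinguishable", {
  cfg <- cohort_config(scans_per_specimen = 1, menstruation_effect = 0,
                       donor_cv = 0, day_cv = 0, noise_sd = 1, seed = 8)
  td <- generate_30day(cfg, n_female = 1, n_male = 0, days = 30,
                       menstruation_days = list(F01 = 1:15))
  apex <- which.min(abs(cfg$grid - 750))
  h <- vapply(td$scans, `[[`, numeric(851), "intensities")[apex, ]
  p <- t.test(h[td$metadata$menstruation], h[!td$metadata$menstruation])$p.value
  expect_gt(p, 0.01)
  # a large effect is clearly visible at the blood-marker band
  cfg2 <- cohort_config(scans_per_specimen = 1, menstruation_effect = 50,
                        donor_cv = 0, day_cv = 0, noise_sd = 1, seed = 8)
  td2 <- generate_30day(cfg2, n_female = 1, n_male = 0, days = 30,
                        menstruation_days = list(F01 = 1:15))
  h2 <- vapply(td2$scans, `[[`, numeric(851), "intensities")[apex, ]
  expect_gt(mean(h2[td2$metadata$menstruation]) -
              mean(h2[!td2$metadata$menstruation]), 25)
})

test_that("config validation rejects out-of-grid peaks and bad counts", {
  expect_error(cohort_config(peaks = list(peak_spec(2100, 10, 5, "x"))),
               "outside working grid")
  expect_error(cohort_config(n_female = 0, n_male = 0), "n_female")
  expect_error(peak_spec(1000, -1, 5), "fwhm")
  # generated data sails through io and preprocessing validation untouched
  cfg <- cohort_config(n_female = 2, n_male = 1, specimens_per_donor = 1,
                       scans_per_specimen = 2, seed = 2)
  coh <- generate_cohort(cfg)
  expect_no_warning({
    set <- assemble_set(coh$scans)
    meta <- validate_metadata(coh$metadata)
    pp <- preprocess_pipeline(set)
  })
  expect_equal(nrow(pp$intensities), 3)
})
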