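#' Specification of one synthetic Raman band
#'
#' @param center Band center in cm^-1, inside the working grid.
#' @param fwhm Full width at half maximum in cm^-1 (> 0). Default 10: the
#'   instrument's 8 cm^-1 spectral resolution broadens natural linewidths.
#' @param base_amplitude Apex intensity in arbitrary units (>= 0).
#' @param metabolite Free-text tag for the assigned metabolite.
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(center, fwhm = 10, base_amplitude, metabolite = "") {
  stopifnot(fwhm > 0, base_amplitude >= 0)
  structure(list(center = center, fwhm = fwhm,
                 base_amplitude = base_amplitude, metabolite = metabolite),
            class = "peak_spec")
}

#' Default urine band table
#'
#' The bands attributed to metabolites in normal urine: urea at 1002 cm^-1
#' (dominant), uric acid 981, creatinine 680, collagen 870, glucose 1071 and
#' 1117 cm^-1. Amplitudes are order-of-magnitude choices: relative band
#' intensities of normal urine are only qualitatively known.
#'
#' @return List of `peak_spec`.
#' @export
default_peaks <- function() {
  list(
    peak_spec(1002, 10, 100, "urea"),
    peak_spec(981, 10, 25, "uric acid"),
    peak_spec(680, 10, 40, "creatinine"),
    peak_spec(870, 10, 15, "collagen"),
    peak_spec(1071, 10, 20, "glucose"),
    peak_spec(1117, 10, 15, "glucose")
  )
}

#' Synthetic-cohort configuration
#'
#' Defines the statistical structure of a generated urine Raman cohort. The
#' default donor counts mirror a healthy-donor study population of 39 female
#' and 9 male donors; 5 specimens per donor give ~240 specimens, and 10
#' scans per specimen is the acquisition minimum. Peak amplitudes are
#' multiplicative in all effects (concentration-proportional in the linear
#' Raman regime); scan noise is additive Gaussian.
#'
#' Donor amplitude for peak p:
#' `base_amplitude * sex_multiplier[p]^is_male * (1 + age_slope[p] * (birth_year - median_year)) * LogNormal(cv = donor_cv)`;
#' each specimen applies a scalar day factor `LogNormal(cv = day_cv)`; each
#' scan adds N(0, noise_sd) per channel. The fluorescence background is
#' `fluorescence_amp * exp(-shift / fluorescence_decay)` plus a polynomial
#' in (shift / 1000) with coefficients `baseline_coeffs`.
#'
#' @param n_female,n_male Donor counts.
#' @param specimens_per_donor Specimens contributed per donor.
#' @param scans_per_specimen Scan replicates per specimen (default 10).
#' @param birth_year_range Inclusive year range donors are drawn from.
#' @param peaks List of [peak_spec()].
#' @param sex_multiplier Per-peak multiplicative factor applied to male
#'   donors (recycled). Default: 1.2 on the urea band, 1 elsewhere — a
#'   modest sex difference in urea concentration.
#' @param age_slope Per-peak fractional amplitude change per year of birth
#'   year (recycled). Default: 0.004/yr on urea, 0 elsewhere.
#' @param donor_cv,day_cv Lognormal coefficients of variation for
#'   donor-level and day-level amplitude variation (defaults 0.25, 0.10).
#' @param menstruation_effect Additive apex amplitude on the blood-marker
#'   bands (750 and 1580 cm^-1) for specimens flagged as collected during
#'   menstruation. Default 0.
#' @param baseline_coeffs Polynomial coefficients (ascending powers of
#'   shift/1000).
#' @param fluorescence_amp,fluorescence_decay Broad-background parameters.
#' @param noise_sd Additive Gaussian per-channel scan noise.
#' @param control_amplitudes Per-peak apex amplitudes of the fixed
#'   synthetic-urine control profile (same order as `peaks`). Default: a
#'   metabolite-poor profile — reduced urea/creatinine/uric acid, no
#'   collagen or glucose bands.
#' @param grid Working Raman-shift grid.
#' @param seed Integer seed; fixed seed gives bit-reproducible output, and
#'   generator streams are split per (donor, specimen, scan) so subsetting
#'   does not shift draws.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_female = 39L, n_male = 9L,
                          specimens_per_donor = 5L, scans_per_specimen = 10L,
                          birth_year_range = c(1950, 2000),
                          peaks = default_peaks(),
                          sex_multiplier = NULL, age_slope = NULL,
                          donor_cv = 0.25, day_cv = 0.10,
                          menstruation_effect = 0,
                          baseline_coeffs = c(40, -30, 8),
                          fluorescence_amp = 300, fluorescence_decay = 700,
                          noise_sd = 1,
                          control_amplitudes = NULL,
                          grid = default_grid(), seed = 1L) {
  np <- length(peaks)
  stopifnot(np >= 1L, n_female >= 0L, n_male >= 0L, n_female + n_male >= 1L,
            specimens_per_donor >= 1L, scans_per_specimen >= 1L,
            donor_cv >= 0, day_cv >= 0, noise_sd >= 0)
  centers <- vapply(peaks, `[[`, numeric(1), "center")
  if (any(centers < min(grid) | centers > max(grid))) {
    stop("config error: peak center outside working grid", call. = FALSE)
  }
  tags <- vapply(peaks, `[[`, character(1), "metabolite")
  if (is.null(sex_multiplier)) {
    sex_multiplier <- ifelse(tags == "urea", 1.2, 1)
  }
  if (is.null(age_slope)) {
    age_slope <- ifelse(tags == "urea", 0.004, 0)
  }
  if (is.null(control_amplitudes)) {
    base <- vapply(peaks, `[[`, numeric(1), "base_amplitude")
    control_amplitudes <- base *
      c(urea = 0.7, `uric acid` = 0.4, creatinine = 0.5)[tags]
    control_amplitudes[is.na(control_amplitudes)] <- 0
    names(control_amplitudes) <- NULL
  }
  structure(
    list(n_female = as.integer(n_female), n_male = as.integer(n_male),
         specimens_per_donor = as.integer(specimens_per_donor),
         scans_per_specimen = as.integer(scans_per_specimen),
         birth_year_range = as.integer(birth_year_range), peaks = peaks,
         sex_multiplier = rep_len(sex_multiplier, np),
         age_slope = rep_len(age_slope, np),
         donor_cv = donor_cv, day_cv = day_cv,
         menstruation_effect = menstruation_effect,
         baseline_coeffs = baseline_coeffs,
         fluorescence_amp = fluorescence_amp,
         fluorescence_decay = fluorescence_decay,
         noise_sd = noise_sd, control_amplitudes = control_amplitudes,
         grid = grid, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Deterministic substream seed from (seed, indices); keeps intermediates
# below 2^53 and the result below 2^31 so set.seed() is exact.
child_seed <- function(seed, ...) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (idx in c(...)) {
    s <- (s * 69069 + as.numeric(idx) * 7919 + 1) %% 2147483647
    s <- (s * 69069 + 12345) %% 2147483647
  }
  as.integer(s)
}

lorentzian <- function(shift, center, fwhm, amplitude) {
  g <- fwhm / 2
  amplitude * g^2 / ((shift - center)^2 + g^2)
}

.background <- function(config) {
  x <- config$grid / 1000
  bl <- rep(0, length(x))
  for (j in seq_along(config$baseline_coeffs)) {
    bl <- bl + config$baseline_coeffs[j] * x^(j - 1)
  }
  bl + config$fluorescence_amp * exp(-config$grid / config$fluorescence_decay)
}

.clean_spectrum <- function(config, amplitudes) {
  y <- .background(config)
  for (j in seq_along(config$peaks)) {
    pk <- config$peaks[[j]]
    y <- y + lorentzian(config$grid, pk$center, pk$fwhm, amplitudes[j])
  }
  y
}

.lnorm_factor <- function(n, cv, seed) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  set.seed(seed)
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.donor_amplitudes <- function(config, donor_idx, is_male, birth_year) {
  base <- vapply(config$peaks, `[[`, numeric(1), "base_amplitude")
  med <- stats::median(seq(config$birth_year_range[1], config$birth_year_range[2]))
  amps <- base * config$sex_multiplier^as.integer(is_male) *
    (1 + config$age_slope * (birth_year - med))
  amps <- pmax(amps, 0)
  amps * .lnorm_factor(length(amps), config$donor_cv,
                       child_seed(config$seed, 1L, donor_idx))
}

.make_scans <- function(config, clean, specimen_id, donor_idx, spec_idx) {
  lapply(seq_len(config$scans_per_specimen), function(sc) {
    if (config$noise_sd > 0) {
      set.seed(child_seed(config$seed, 3L, donor_idx, spec_idx, sc))
      y <- clean + stats::rnorm(length(clean), 0, config$noise_sd)
    } else {
      y <- clean
    }
    raman_spectrum(config$grid, y, specimen_id, sc)
  })
}

#' Generate a synthetic urine Raman cohort
#'
#' Draws per-donor metabolite amplitudes (sex, birth-year, and lognormal
#' donor effects), per-specimen day factors, and per-scan Gaussian noise on
#' top of a shared polynomial + exponential-fluorescence background. Random
#' streams are split deterministically by (donor, specimen, scan).
#'
#' @param config A [cohort_config()].
#' @return List with `scans` (list of `raman_spectrum`) and `metadata`
#'   (validated specimen table).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n_don <- config$n_female + config$n_male
  sexes <- rep(c("F", "M"), c(config$n_female, config$n_male))
  donor_ids <- sprintf("%s%02d", sexes, c(seq_len(config$n_female),
                                          seq_len(config$n_male)))
  set.seed(child_seed(config$seed, 0L))
  birth_years <- sample(seq(config$birth_year_range[1],
                            config$birth_year_range[2]),
                        n_don, replace = TRUE)
  scans <- list()
  meta <- list()
  start_date <- as.Date("2018-01-01")
  for (d in seq_len(n_don)) {
    amps_d <- .donor_amplitudes(config, d, sexes[d] == "M", birth_years[d])
    for (s in seq_len(config$specimens_per_donor)) {
      day_f <- .lnorm_factor(1, config$day_cv, child_seed(config$seed, 2L, d, s))
      clean <- .clean_spectrum(config, amps_d * day_f)
      spec_id <- sprintf("%s-S%02d", donor_ids[d], s)
      scans <- c(scans, .make_scans(config, clean, spec_id, d, s))
      meta[[spec_id]] <- data.frame(
        specimen_id = spec_id, donor_id = donor_ids[d], sex = sexes[d],
        birth_year = birth_years[d],
        collection_date = as.character(start_date + 7L * (s - 1L)),
        menstruation = FALSE, is_control = FALSE, stringsAsFactors = FALSE)
    }
  }
  list(scans = scans,
       metadata = validate_metadata(do.call(rbind, c(meta, make.row.names = FALSE))))
}

#' Generate control scans of the synthetic-urine standard
#'
#' A fixed reference amplitude profile — no donor or day variation — with
#' the same background and scan-noise model as the cohort. Emulates scans of
#' a commercial synthetic-urine negative control used as the fixed reference
#' point for distance statistics.
#'
#' @param config A [cohort_config()].
#' @param n_scans Number of replicate control scans.
#' @param specimen_id Id given to the control specimen.
#' @return List with `scans` and `metadata` (one row, `is_control = TRUE`).
#' @export
generate_control <- function(config = cohort_config(), n_scans = 10L,
                             specimen_id = "CTRL") {
  stopifnot(inherits(config, "cohort_config"), n_scans >= 1L)
  clean <- .clean_spectrum(config, config$control_amplitudes)
  scans <- lapply(seq_len(n_scans), function(sc) {
    if (config$noise_sd > 0) {
      set.seed(child_seed(config$seed, 4L, sc))
      y <- clean + stats::rnorm(length(clean), 0, config$noise_sd)
    } else {
      y <- clean
    }
    raman_spectrum(config$grid, y, specimen_id, sc)
  })
  meta <- data.frame(specimen_id = specimen_id, donor_id = "CONTROL",
                     sex = "F", birth_year = config$birth_year_range[1],
                     collection_date = "2018-01-01", menstruation = FALSE,
                     is_control = TRUE, stringsAsFactors = FALSE)
  list(scans = scans, metadata = validate_metadata(meta))
}

#' Generate a longitudinal daily-collection cohort
#'
#' One specimen per donor per day over `days` days (default: 3 female + 1
#' male donors, 30 days — a first-morning-void daily collection).
#' Menstruation days, listed per female donor, set the metadata flag and add
#' `menstruation_effect` to the blood-marker bands (750 and 1580 cm^-1);
#' with the default effect of 0 the flag is statistically invisible.
#'
#' @param config A [cohort_config()] (its donor counts are ignored here).
#' @param n_female,n_male Donor counts (defaults 3 and 1).
#' @param days Collection days per donor.
#' @param menstruation_days Named list mapping female donor ids (e.g. "F01")
#'   to integer day vectors.
#' @return List with `scans` and `metadata`.
#' @export
generate_30day <- function(config = cohort_config(), n_female = 3L,
                           n_male = 1L, days = 30L,
                           menstruation_days = list()) {
  stopifnot(inherits(config, "cohort_config"), days >= 1L)
  n_don <- n_female + n_male
  sexes <- rep(c("F", "M"), c(n_female, n_male))
  donor_ids <- sprintf("%s%02d", sexes, c(seq_len(n_female), seq_len(n_male)))
  bad <- setdiff(names(menstruation_days), donor_ids[sexes == "F"])
  if (length(bad)) {
    stop("config error: menstruation days for non-female donor ",
         bad[1], call. = FALSE)
  }
  set.seed(child_seed(config$seed, 5L))
  birth_years <- sample(seq(config$birth_year_range[1],
                            config$birth_year_range[2]),
                        n_don, replace = TRUE)
  blood_peaks <- list(peak_spec(750, 12, 1, "heme"), peak_spec(1580, 14, 1, "heme"))
  scans <- list()
  meta <- list()
  start_date <- as.Date("2018-06-01")
  for (d in seq_len(n_don)) {
    amps_d <- .donor_amplitudes(config, 1000L + d, sexes[d] == "M", birth_years[d])
    mdays <- menstruation_days[[donor_ids[d]]]
    for (day in seq_len(days)) {
      day_f <- .lnorm_factor(1, config$day_cv,
                             child_seed(config$seed, 6L, d, day))
      clean <- .clean_spectrum(config, amps_d * day_f)
      is_mens <- !is.null(mdays) && day %in% mdays
      if (is_mens && config$menstruation_effect > 0) {
        for (bp in blood_peaks) {
          clean <- clean + lorentzian(config$grid, bp$center, bp$fwhm,
                                      config$menstruation_effect)
        }
      }
      spec_id <- sprintf("%s-D%02d", donor_ids[d], day)
      scans <- c(scans, .make_scans(config, clean, spec_id, 1000L + d, day))
      meta[[spec_id]] <- data.frame(
        specimen_id = spec_id, donor_id = donor_ids[d], sex = sexes[d],
        birth_year = birth_years[d],
        collection_date = as.character(start_date + (day - 1L)),
        menstruation = is_mens, is_control = FALSE, stringsAsFactors = FALSE)
    }
  }
  list(scans = scans,
       metadata = validate_metadata(do.call(rbind, c(meta, make.row.names = FALSE))))
}
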