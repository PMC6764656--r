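#' Preprocessing configuration
#'
#' Controls the baseline fit and the downstream normalization/window choices.
#' The baseline model is a polynomial of degree `poly_order` fitted by
#' iteratively reweighted least squares with an asymmetric cost: channels
#' below the current baseline keep full quadratic weight, channels above it
#' by more than a data-driven threshold have their influence clipped. The
#' threshold is retuned every iteration so that the fraction of channels
#' flagged as strongly positive approaches `peak_fraction`.
#'
#' @param poly_order Baseline polynomial degree (>= 1). Default 7: flexible
#'   enough for fluorescence backgrounds, stiff enough not to chase peaks on
#'   an 851-channel grid.
#' @param peak_fraction Fraction of channels assumed to carry peak signal,
#'   in (0, 1). Default 0.5: roughly half the biological window of a urine
#'   spectrum sits on or near a band.
#' @param max_iter Maximum reweighting iterations.
#' @param tol Convergence tolerance on the relative change of baseline
#'   coefficients.
#' @param window Analysis window in cm^-1 applied before chemometrics;
#'   default `c(400, 1800)`, the window the distance statistics are defined
#'   on. Acquisition keeps 250-1950.
#' @param normalize Whether the pipeline vector-normalizes averaged spectra.
#' @param method Baseline method: `"goldindec"` (asymmetric clipped IRLS, the
#'   default) or `"als"` (plain asymmetric least squares).
#' @param norm Normalization norm: `"l2"` (Euclidean, the standard meaning of
#'   vector normalization in vibrational spectroscopy) or `"l1"` (area).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(poly_order = 7L, peak_fraction = 0.5,
                              max_iter = 100L, tol = 1e-6,
                              window = c(400, 1800), normalize = TRUE,
                              method = c("goldindec", "als"),
                              norm = c("l2", "l1")) {
  method <- match.arg(method)
  norm <- match.arg(norm)
  poly_order <- as.integer(poly_order)
  max_iter <- as.integer(max_iter)
  stopifnot(poly_order >= 1L, max_iter >= 1L, tol > 0,
            peak_fraction > 0, peak_fraction < 1,
            length(window) == 2L, window[1] < window[2])
  structure(
    list(poly_order = poly_order, peak_fraction = peak_fraction,
         max_iter = max_iter, tol = tol, window = as.numeric(window),
         normalize = isTRUE(normalize), method = method, norm = norm),
    class = "preprocess_config"
  )
}

#' Fit a fluorescence baseline under the Raman peaks
#'
#' Iteratively reweighted polynomial regression with an asymmetric cost.
#' Residuals below the baseline are penalized quadratically (the baseline
#' must not cut under the signal floor); residuals above the baseline beyond
#' a scale threshold `s` — peak channels — have their cost clipped, i.e.
#' their least-squares weight decays as (s/r)^2 so arbitrarily tall peaks
#' exert bounded pull. `s` is retuned each iteration to the empirical
#' (1 - peak_fraction) residual quantile, so the fraction of strongly
#' positive channels approaches `peak_fraction`. Terminates on coefficient
#' convergence (`tol`) or after `max_iter` iterations.
#'
#' With `method = "als"` a plain asymmetric least squares is used instead:
#' constant weight 0.05 above the baseline, 1 below.
#'
#' @param spectrum A `raman_spectrum`, or a numeric intensity vector (then
#'   `shifts` must be supplied via attributes or an equispaced axis is
#'   assumed).
#' @param config A [preprocess_config()].
#' @return Numeric baseline vector on the spectrum's grid.
#' @export
fit_baseline <- function(spectrum, config = preprocess_config()) {
  if (inherits(spectrum, "raman_spectrum")) {
    x <- spectrum$shifts; y <- spectrum$intensities
  } else {
    y <- as.numeric(spectrum); x <- seq_along(y)
  }
  n <- length(y)
  if (n < config$poly_order + 1L) {
    stop("underdetermined fit: ", n, " channels for degree ",
         config$poly_order, " baseline", call. = FALSE)
  }
  # orthogonal polynomial basis on a scaled axis for conditioning
  basis <- cbind(1, stats::poly(x, degree = config$poly_order))
  w <- rep(1, n)
  beta_old <- NULL
  for (iter in seq_len(config$max_iter)) {
    fit <- stats::lm.wfit(basis, y, w)
    b <- as.numeric(basis %*% fit$coefficients)
    r <- y - b
    if (!is.null(beta_old)) {
      denom <- max(abs(beta_old), 1e-12)
      if (max(abs(fit$coefficients - beta_old)) / denom < config$tol) break
    }
    beta_old <- fit$coefficients
    if (config$method == "als") {
      w <- ifelse(r > 0, 0.05, 1)
    } else {
      s <- stats::quantile(r, probs = 1 - config$peak_fraction, names = FALSE)
      s <- max(s, 1e-3 * max(stats::sd(r), 1e-12))
      w <- rep(1, n)
      above <- r > s
      w[above] <- (s / r[above])^2
    }
  }
  as.numeric(b)
}

#' Subtract the fitted baseline from a scan
#'
#' Pointwise subtraction of [fit_baseline()]. Small negative intensities in
#' the output are retained, not clipped: clipping would bias the subsequent
#' vector normalization.
#'
#' @inheritParams fit_baseline
#' @return A baseline-corrected `raman_spectrum`.
#' @export
correct_baseline <- function(spectrum, config = preprocess_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  b <- fit_baseline(spectrum, config)
  raman_spectrum(spectrum$shifts, spectrum$intensities - b,
                 spectrum$specimen_id, spectrum$scan_index)
}

#' Average scan replicates per specimen
#'
#' Per-channel arithmetic mean over each specimen's scans. The output has one
#' row per distinct specimen, in first-appearance order, with the scan index
#' dropped.
#'
#' @param set A `spectrum_set` of scans on a common grid.
#' @return A `spectrum_set`, one row per specimen.
#' @export
average_replicates <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  ids <- unique(set$specimen_ids)
  m <- do.call(rbind, lapply(ids, function(id) {
    colMeans(set$intensities[set$specimen_ids == id, , drop = FALSE])
  }))
  spectrum_set(set$grid, m, ids, NA_integer_)
}

#' Vector-normalize each spectrum
#'
#' Divides every row by its norm so that intensity scale differences between
#' specimens cancel. Default is the Euclidean (L2) norm; `"l1"` gives area
#' normalization.
#'
#' @param set A `spectrum_set`.
#' @param norm `"l2"` or `"l1"`.
#' @return A `spectrum_set` with unit-norm rows.
#' @export
vector_normalize <- function(set, norm = c("l2", "l1")) {
  stopifnot(inherits(set, "spectrum_set"))
  norm <- match.arg(norm)
  nr <- if (norm == "l2") {
    sqrt(rowSums(set$intensities^2))
  } else {
    rowSums(abs(set$intensities))
  }
  zero <- nr == 0
  if (any(zero)) {
    stop("degenerate spectrum: zero-norm row for specimen ",
         set$specimen_ids[zero][1], call. = FALSE)
  }
  spectrum_set(set$grid, set$intensities / nr, set$specimen_ids, set$scan_index)
}

#' Truncate a spectrum set to an analysis window
#'
#' Keeps channels with `low <= shift <= high` (closed interval; endpoints on
#' the grid are retained).
#'
#' @param set A `spectrum_set`.
#' @param window Length-2 numeric `c(low, high)` in cm^-1.
#' @return A `spectrum_set` on the truncated grid.
#' @export
truncate_window <- function(set, window) {
  stopifnot(inherits(set, "spectrum_set"), length(window) == 2L)
  keep <- set$grid >= window[1] & set$grid <= window[2]
  if (!any(keep)) {
    stop(sprintf("window error: [%g, %g] contains no grid channels",
                 window[1], window[2]), call. = FALSE)
  }
  spectrum_set(set$grid[keep], set$intensities[, keep, drop = FALSE],
               set$specimen_ids, set$scan_index)
}

#' Run the full preprocessing chain on raw scans
#'
#' Baseline-corrects each scan, averages replicates per specimen, and
#' vector-normalizes the averaged spectra — in that order. Window truncation
#' is not applied here; it is the last step before chemometrics (see
#' [truncate_window()]), so that both the full-range and windowed views of
#' the same preprocessed data are available.
#'
#' @param scans List of `raman_spectrum`, or a `spectrum_set` of raw scans.
#' @param config A [preprocess_config()].
#' @param grid Common grid used when `scans` is a list.
#' @return A `spectrum_set`, one normalized row per specimen.
#' @export
preprocess_pipeline <- function(scans, config = preprocess_config(),
                                grid = default_grid()) {
  set <- if (inherits(scans, "spectrum_set")) scans else assemble_set(scans, grid)
  corrected <- set$intensities
  for (i in seq_len(nrow(corrected))) {
    sp <- raman_spectrum(set$grid, set$intensities[i, ],
                         set$specimen_ids[i],
                         ifelse(is.na(set$scan_index[i]), 1L, set$scan_index[i]))
    corrected[i, ] <- sp$intensities - fit_baseline(sp, config)
  }
  out <- spectrum_set(set$grid, corrected, set$specimen_ids, set$scan_index)
  out <- average_replicates(out)
  if (config$normalize) out <- vector_normalize(out, config$norm)
  out
}
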