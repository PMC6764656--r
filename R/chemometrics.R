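#' Mean and standard-deviation envelope of a spectrum set
#'
#' Per-channel mean and sample standard deviation (n-1 denominator) — the
#' "range of normal" envelope for overlaid urine spectra.
#'
#' @param set A `spectrum_set` with at least 2 rows.
#' @return A data.frame with columns `shift`, `mean`, `sd`.
#' @export
summarize_spectra <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  if (nrow(set$intensities) < 2L) {
    stop("insufficient data: need >= 2 spectra to summarize", call. = FALSE)
  }
  data.frame(
    shift = set$grid,
    mean = colMeans(set$intensities),
    sd = apply(set$intensities, 2, stats::sd)
  )
}

#' Principal component analysis of preprocessed spectra
#'
#' Mean-centered (no variance scaling: rows are already vector-normalized)
#' decomposition via singular values. Deterministic up to component sign;
#' the sign of each loading is fixed so that its largest-magnitude channel
#' is positive, making stored models reproducible bit-for-bit.
#'
#' @param set A `spectrum_set` with >= 2 rows and >= 2 channels.
#' @return An object of class `pca_model` with fields `mean_spectrum`,
#'   `loadings` (channels x components, orthonormal columns), `scores`
#'   (specimens x components), `variance_fraction`, `grid`, `specimen_ids`.
#' @export
fit_pca <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  n <- nrow(set$intensities)
  if (n < 2L || ncol(set$intensities) < 2L) {
    stop("insufficient data: PCA needs >= 2 rows and >= 2 channels", call. = FALSE)
  }
  pc <- stats::prcomp(set$intensities, center = TRUE, scale. = FALSE)
  k <- min(n - 1L, ncol(set$intensities))
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  ev <- pc$sdev^2
  vf <- ev[seq_len(k)] / sum(ev)
  # sign convention: largest-|.| channel of each loading is positive
  for (j in seq_len(k)) {
    i_star <- which.max(abs(loadings[, j]))
    if (loadings[i_star, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(NULL, paste0("PC", seq_len(k)))
  dimnames(scores) <- list(set$specimen_ids, paste0("PC", seq_len(k)))
  structure(
    list(mean_spectrum = colMeans(set$intensities), loadings = loadings,
         scores = scores, variance_fraction = vf, grid = set$grid,
         specimen_ids = set$specimen_ids),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  k4 <- min(4L, length(x$variance_fraction))
  cat(sprintf("<pca_model> %d specimens x %d channels; first %d PCs: %.1f%% variance\n",
              nrow(x$scores), length(x$grid), k4,
              100 * sum(x$variance_fraction[seq_len(k4)])))
  invisible(x)
}

#' Project new spectra into a fitted PCA score space
#'
#' Centers by the model's mean spectrum and projects onto the loadings.
#'
#' @param model A `pca_model`.
#' @param x Numeric matrix (rows = spectra) or vector on the model's grid.
#' @param n_pcs Number of leading components to keep (default: all).
#' @return Score matrix (rows x n_pcs).
#' @export
project_scores <- function(model, x, n_pcs = ncol(model$loadings)) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$mean_spectrum)) {
    stop("dimension error: spectrum has ", ncol(x), " channels; model expects ",
         length(model$mean_spectrum), call. = FALSE)
  }
  sweep(x, 2, model$mean_spectrum) %*% model$loadings[, seq_len(n_pcs), drop = FALSE]
}

#' Smallest number of components reaching a variance target
#'
#' @param variance_fraction Per-component variance fractions, non-increasing.
#' @param target Cumulative-variance target in (0, 1].
#' @return Smallest k with cumulative fraction >= target.
#' @export
select_n_pcs <- function(variance_fraction, target) {
  stopifnot(target > 0, target <= 1)
  cum <- cumsum(variance_fraction)
  k <- which(cum >= target - 1e-12)[1]
  if (is.na(k)) {
    stop(sprintf("coverage error: components explain %.4f < target %.4f",
                 cum[length(cum)], target), call. = FALSE)
  }
  k
}

#' Attribute dataset variance to Raman shifts via PCA loadings
#'
#' Ranks channels by absolute loading weight within each component, and
#' combines components into one ranking by weighting |loading| with the
#' component's variance fraction — identifying which Raman bands drive the
#' spread among specimens.
#'
#' @param model A `pca_model`.
#' @param n_pcs Number of leading components to attribute.
#' @return A list with `per_component` (data.frame `shift`, `component`,
#'   `weight`, ranked within component) and `combined` (data.frame `shift`,
#'   `weight`, ranked overall).
#' @export
loading_attribution <- function(model, n_pcs = 4L) {
  stopifnot(inherits(model, "pca_model"))
  n_pcs <- as.integer(n_pcs)
  if (n_pcs > ncol(model$loadings)) {
    stop("n_pcs exceeds available components", call. = FALSE)
  }
  per <- do.call(rbind, lapply(seq_len(n_pcs), function(j) {
    w <- abs(model$loadings[, j])
    ord <- order(w, decreasing = TRUE)
    data.frame(shift = model$grid[ord], component = j, weight = w[ord])
  }))
  comb <- as.numeric(abs(model$loadings[, seq_len(n_pcs), drop = FALSE]) %*%
                       model$variance_fraction[seq_len(n_pcs)])
  ord <- order(comb, decreasing = TRUE)
  list(per_component = per,
       combined = data.frame(shift = model$grid[ord], weight = comb[ord]))
}

#' Fit a discriminant model on leading PCA scores (DAPC)
#'
#' Linear discriminant on the first `n_pcs` score coordinates: per-class
#' means, pooled within-class covariance, and class priors. The pooled
#' covariance gets a minimal ridge (1e-8 x trace/dim on the diagonal) so
#' near-singular high-tier fits remain computable — deliberately small, so
#' overfitting at high variance tiers stays observable rather than being
#' regularized away.
#'
#' @param pca A `pca_model`.
#' @param labels Class label per specimen, aligned to `pca$specimen_ids`
#'   (a named vector is matched by name; an unnamed one by position).
#' @param n_pcs Number of leading components to use.
#' @param priors `"frequency"` (empirical class frequencies, the default) or
#'   `"uniform"`.
#' @return An object of class `dapc_model`.
#' @export
fit_dapc <- function(pca, labels, n_pcs, priors = c("frequency", "uniform")) {
  stopifnot(inherits(pca, "pca_model"))
  priors <- match.arg(priors)
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 1L || n_pcs > ncol(pca$scores)) {
    stop("n_pcs must be in 1..", ncol(pca$scores), call. = FALSE)
  }
  if (!is.null(names(labels))) labels <- labels[pca$specimen_ids]
  labels <- as.character(labels)
  if (length(labels) != nrow(pca$scores) || anyNA(labels)) {
    stop("labels must cover every specimen in the PCA", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("class-size error: need >= 2 classes", call. = FALSE)
  }
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) {
    stop("class-size error: class `", names(counts)[counts < 2][1],
         "` has < 2 specimens", call. = FALSE)
  }
  s <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(s[labels == cl, , drop = FALSE])
  }))
  rownames(means) <- classes
  pooled <- matrix(0, n_pcs, n_pcs)
  for (cl in classes) {
    sc <- s[labels == cl, , drop = FALSE]
    pooled <- pooled + crossprod(sweep(sc, 2, colMeans(sc)))
  }
  pooled <- pooled / (nrow(s) - length(classes))
  ridge <- 1e-8 * sum(diag(pooled)) / n_pcs
  pooled <- pooled + diag(ridge, n_pcs)
  ch <- tryCatch(chol(pooled), error = function(e) NULL)
  if (is.null(ch)) {
    stop("conditioning error: pooled covariance singular after regularization",
         call. = FALSE)
  }
  pr <- if (priors == "frequency") as.numeric(counts) / sum(counts)
        else rep(1 / length(classes), length(classes))
  structure(
    list(pca = pca, n_pcs = n_pcs, classes = classes, class_means = means,
         pooled_covariance = pooled, chol_cov = ch, priors = pr),
    class = "dapc_model"
  )
}

#' @export
print.dapc_model <- function(x, ...) {
  cat(sprintf("<dapc_model> %d classes (%s), %d PCs\n",
              length(x$classes), paste(x$classes, collapse = ", "), x$n_pcs))
  invisible(x)
}

#' Predict class membership from a DAPC model
#'
#' Gaussian linear-discriminant posteriors with the shared pooled covariance.
#' Input may be raw spectra on the model's grid (projected through the PCA)
#' or score vectors already in PC space. Ties in posterior are broken toward
#' the first class in lexicographic order.
#'
#' @param model A `dapc_model`.
#' @param x Numeric matrix or vector: spectra (channels matching the PCA
#'   grid) or scores (>= `n_pcs` columns).
#' @return A list with `label` (character vector) and `posterior`
#'   (rows x classes matrix, rows summing to 1).
#' @export
predict_dapc <- function(model, x) {
  stopifnot(inherits(model, "dapc_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  p_chan <- length(model$pca$mean_spectrum)
  s <- if (ncol(x) == p_chan) {
    project_scores(model$pca, x, model$n_pcs)
  } else if (ncol(x) >= model$n_pcs) {
    x[, seq_len(model$n_pcs), drop = FALSE]
  } else {
    stop("dimension error: input has ", ncol(x),
         " columns; expected ", p_chan, " channels or >= ", model$n_pcs,
         " scores", call. = FALSE)
  }
  K <- length(model$classes)
  loglik <- matrix(0, nrow(s), K)
  for (k in seq_len(K)) {
    d <- sweep(s, 2, model$class_means[k, ])
    z <- backsolve(model$chol_cov, t(d), transpose = TRUE)
    loglik[, k] <- -0.5 * colSums(z^2) + log(model$priors[k])
  }
  m <- apply(loglik, 1, max)
  post <- exp(loglik - m)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  list(label = model$classes[max.col(post, ties.method = "first")],
       posterior = post)
}
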