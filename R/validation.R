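#' Confusion-matrix summary metrics
#'
#' Accuracy, sensitivity (true positive rate), and specificity (true
#' negative rate) from raw counts. Fractions are returned unrounded; report
#' rendering rounds to whole percents (half away from zero) via
#' [format_percent()].
#'
#' @param tp,fn,tn,fp Nonnegative counts; the total must be positive.
#' @return An object of class `confusion_metrics`: the four counts plus
#'   `accuracy`, `sensitivity`, `specificity` (NA where the denominator is
#'   zero).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("empty confusion: total count is zero", call. = FALSE)
  structure(
    list(tp = tp, fn = fn, tn = tn, fp = fp,
         accuracy = (tp + tn) / total,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("accuracy %s  sensitivity %s  specificity %s  (tp=%d fn=%d tn=%d fp=%d)\n",
              format_percent(x$accuracy), format_percent(x$sensitivity),
              format_percent(x$specificity), x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Render a fraction as a whole percent, rounding half away from zero
#'
#' @param x Fraction in [0, 1] (NA allowed).
#' @return Character like "72%".
#' @export
format_percent <- function(x) {
  ifelse(is.na(x), "n/a", paste0(floor(abs(x) * 100 + 0.5) * sign(x), "%"))
}

#' One-vs-rest confusion metrics for a multi-class prediction
#'
#' Binarizes with `class` as positive (all other labels pooled as negative)
#' and delegates to [confusion_metrics()].
#'
#' @param true_labels,predicted_labels Character vectors of equal length.
#' @param class The positive class; must appear in `true_labels`.
#' @return A `confusion_metrics`.
#' @export
one_vs_rest_metrics <- function(true_labels, predicted_labels, class) {
  if (!class %in% true_labels) {
    stop("unknown class: `", class, "` absent from true labels", call. = FALSE)
  }
  tpos <- true_labels == class
  ppos <- predicted_labels == class
  confusion_metrics(tp = sum(tpos & ppos), fn = sum(tpos & !ppos),
                    tn = sum(!tpos & !ppos), fp = sum(!tpos & ppos))
}

#' Blind leave-one-out build/test validation of DAPC classification
#'
#' For each specimen: the PCA is refit on the remaining n-1 spectra, the
#' number of components is chosen (a fixed count if `n_pcs` is given,
#' otherwise from the refit variance fractions at the `tier`), a DAPC model
#' is refit, and the held-out spectrum is projected through the fold's PCA
#' and predicted. The held-out row never influences centering, loadings, or
#' discriminant parameters. Entirely deterministic.
#'
#' @param set A preprocessed `spectrum_set` (one row per specimen).
#' @param labels Class label per specimen, aligned to `set$specimen_ids`
#'   (named vectors matched by name).
#' @param positive_class For binary problems, the positive label; if `NULL`,
#'   per-class one-vs-rest metrics are reported.
#' @param tier Variance tier in (0, 1]; the per-fold component count is the
#'   smallest reaching it (may differ across folds).
#' @param n_pcs Explicit component count used in every fold (overrides
#'   `tier`).
#' @param priors Passed to [fit_dapc()].
#' @return An object of class `loo_result`: `predictions` (data.frame
#'   `specimen_id`, `true`, `predicted`, `posterior`, `fold_n_pcs`),
#'   `metrics` (a `confusion_metrics`, or a named list of them, one per
#'   class), `n_pcs_mode`, `tier`.
#' @export
loo_validate <- function(set, labels, positive_class = NULL, tier = NULL,
                         n_pcs = NULL, priors = "frequency") {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.null(tier) && is.null(n_pcs)) {
    stop("give either `tier` or `n_pcs`", call. = FALSE)
  }
  if (!is.null(names(labels))) labels <- labels[set$specimen_ids]
  labels <- as.character(labels)
  n <- nrow(set$intensities)
  if (length(labels) != n || anyNA(labels)) {
    stop("labels must cover every specimen", call. = FALSE)
  }
  counts <- table(labels)
  if (length(counts) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(counts < 3L)) {
    stop("fold degeneracy: class `", names(counts)[counts < 3][1],
         "` has < 3 members, so a fold would drop below 2", call. = FALSE)
  }
  if (!is.null(positive_class) && !positive_class %in% labels) {
    stop("unknown positive_class `", positive_class, "`", call. = FALSE)
  }
  pred <- character(n)
  postr <- numeric(n)
  fold_k <- integer(n)
  for (i in seq_len(n)) {
    train <- subset_rows(set, -i)
    pca_i <- fit_pca(train)
    k <- if (!is.null(n_pcs)) {
      min(as.integer(n_pcs), ncol(pca_i$scores))
    } else {
      select_n_pcs(pca_i$variance_fraction, tier)
    }
    dapc_i <- fit_dapc(pca_i, labels[-i], k, priors = priors)
    p <- predict_dapc(dapc_i, set$intensities[i, ])
    pred[i] <- p$label
    postr[i] <- p$posterior[1, p$label]
    fold_k[i] <- k
  }
  predictions <- data.frame(specimen_id = set$specimen_ids, true = labels,
                            predicted = pred, posterior = postr,
                            fold_n_pcs = fold_k, stringsAsFactors = FALSE)
  metrics <- if (!is.null(positive_class)) {
    one_vs_rest_metrics(labels, pred, positive_class)
  } else {
    cls <- sort(unique(labels))
    stats::setNames(lapply(cls, function(cl) {
      one_vs_rest_metrics(labels, pred, cl)
    }), cls)
  }
  mode_k <- as.integer(names(sort(table(fold_k), decreasing = TRUE))[1])
  structure(
    list(predictions = predictions, metrics = metrics,
         n_pcs_mode = mode_k, tier = tier),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  acc <- mean(x$predictions$true == x$predictions$predicted)
  cat(sprintf("<loo_result> %d folds, modal n_pcs %d, accuracy %s\n",
              nrow(x$predictions), x$n_pcs_mode, format_percent(acc)))
  if (inherits(x$metrics, "confusion_metrics")) {
    print(x$metrics)
  } else {
    for (cl in names(x$metrics)) {
      cat(sprintf("  %-12s ", cl)); print(x$metrics[[cl]])
    }
  }
  invisible(x)
}
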