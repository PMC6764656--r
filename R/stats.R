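#' Control point in PC-score space
#'
#' Mean of the control specimens' score vectors. Control scans are
#' preprocessed identically to urine specimens and included in the PCA fit,
#' so specimen and control live in one coordinate system; their replicate
#' scores are averaged here.
#'
#' @param pca A `pca_model` whose fit included the control rows.
#' @param control_ids Specimen ids flagged `is_control` in the metadata.
#' @return Numeric score vector (one entry per component).
#' @export
control_scores <- function(pca, control_ids) {
  stopifnot(inherits(pca, "pca_model"))
  idx <- which(pca$specimen_ids %in% control_ids)
  if (length(idx) == 0L) {
    stop("missing control: no control rows in the PCA fit", call. = FALSE)
  }
  colMeans(pca$scores[idx, , drop = FALSE])
}

#' Total principal component distance (TPD)
#'
#' Euclidean distance between a specimen's and the control's leading PC
#' scores: sqrt(sum_{i=1..n_pcs} (P_u,i - P_control,i)^2). The default uses
#' the first four components, which capture over 95% of dataset variance in
#' normal urine.
#'
#' @param scores_u,scores_control Score vectors with >= `n_pcs` entries.
#' @param n_pcs Number of leading components (default 4).
#' @return Nonnegative scalar.
#' @export
tpd <- function(scores_u, scores_control, n_pcs = 4L) {
  n_pcs <- as.integer(n_pcs)
  if (length(scores_u) < n_pcs || length(scores_control) < n_pcs) {
    stop("dimension error: fewer than ", n_pcs, " components available",
         call. = FALSE)
  }
  d <- scores_u[seq_len(n_pcs)] - scores_control[seq_len(n_pcs)]
  sqrt(sum(d^2))
}

#' Total spectral distance (TSD)
#'
#' Euclidean distance between a specimen's and the control's full normalized
#' spectra over the analysis window.
#'
#' @param spectrum_u,spectrum_control Normalized intensity rows on the same
#'   grid/window.
#' @return Nonnegative scalar.
#' @export
tsd <- function(spectrum_u, spectrum_control) {
  if (length(spectrum_u) != length(spectrum_control)) {
    stop("dimension error: rows are on different grids", call. = FALSE)
  }
  sqrt(sum((spectrum_u - spectrum_control)^2))
}

#' Per-specimen distance table against the control
#'
#' Computes TPD (in PC-score space) and TSD (in channel space) for every
#' non-control specimen of a preprocessed, windowed set.
#'
#' @param set The preprocessed, windowed `spectrum_set` the PCA was fit on
#'   (controls included).
#' @param pca The `pca_model` fitted on `set`.
#' @param metadata Metadata table with `specimen_id` and `is_control`.
#' @param n_pcs Components used for TPD (default 4).
#' @return data.frame with columns `specimen_id`, `tpd`, `tsd`, `n_pcs_used`.
#' @export
distance_table <- function(set, pca, metadata, n_pcs = 4L) {
  stopifnot(inherits(set, "spectrum_set"), inherits(pca, "pca_model"))
  control_ids <- metadata$specimen_id[metadata$is_control]
  sc <- control_scores(pca, control_ids)
  ctrl_idx <- which(set$specimen_ids %in% control_ids)
  if (length(ctrl_idx) == 0L) stop("missing control rows in set", call. = FALSE)
  ctrl_row <- colMeans(set$intensities[ctrl_idx, , drop = FALSE])
  keep <- which(!set$specimen_ids %in% control_ids)
  data.frame(
    specimen_id = set$specimen_ids[keep],
    tpd = vapply(keep, function(i) tpd(pca$scores[i, ], sc, n_pcs), numeric(1)),
    tsd = vapply(keep, function(i) tsd(set$intensities[i, ], ctrl_row), numeric(1)),
    n_pcs_used = as.integer(n_pcs),
    stringsAsFactors = FALSE
  )
}

#' Two-way ANOVA on a per-specimen response
#'
#' Linear-model decomposition with the requested sum-of-squares type:
#' sequential (I) via `anova(lm(...))`, or partial (II/III) via
#' `car::Anova`. Type III uses sum-to-zero contrasts. F and p come from the
#' error mean square. p-values below 1e-12 are never reported as 0; render
#' with [format_p()].
#'
#' @param y Numeric response, one value per specimen (e.g. TPD).
#' @param factor_a,factor_b Factor labels (coerced to factor; birth year
#'   enters as a categorical factor).
#' @param include_interaction Include the A:B term?
#' @param ss_type `"I"`, `"II"`, or `"III"`. Default: II without the
#'   interaction, III with it (unbalanced data).
#' @param factor_names Length-2 character, names used in the table.
#' @return An object of class `anova_table`: data.frame rows (source,
#'   sum_sq, df, mean_sq, F, p) including Error and Total, plus attributes
#'   `ss_type` and `include_interaction`.
#' @export
two_way_anova <- function(y, factor_a, factor_b, include_interaction = FALSE,
                          ss_type = NULL, factor_names = c("A", "B")) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  stopifnot(length(y) == length(a), length(y) == length(b))
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop("each factor needs >= 2 levels", call. = FALSE)
  }
  if (is.null(ss_type)) ss_type <- if (include_interaction) "III" else "II"
  ss_type <- match.arg(ss_type, c("I", "II", "III"))
  d <- data.frame(y = y, A = a, B = b)
  form <- if (include_interaction) y ~ A * B else y ~ A + B
  contr <- if (ss_type == "III") {
    list(A = "contr.sum", B = "contr.sum")
  } else {
    list(A = "contr.treatment", B = "contr.treatment")
  }
  fit <- stats::lm(form, data = d, contrasts = contr)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    if (any(!grepl(":", aliased, fixed = TRUE))) {
      # a confounded main effect cannot be decomposed at all
      stop("rank deficiency: aliased terms ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    # empty cells alias only interaction contrasts (a singular design, the
    # norm for unbalanced factorial data); partial SS are not estimable, so
    # fall back to the sequential decomposition which drops the aliased
    # columns
    ss_type <- "I"
  }
  av <- if (ss_type == "I") {
    stats::anova(fit)
  } else {
    # a zero residual SS (degenerate noiseless input) trips car's guard; the
    # sequential decomposition is exact there and equals II/III when the
    # extra terms carry no SS
    tryCatch(car::Anova(fit, type = ss_type),
             error = function(e) {
               if (grepl("residual sum of squares is 0", conditionMessage(e))) {
                 # expected for noiseless input; F/p are overwritten below
                 suppressWarnings(stats::anova(fit))
               } else {
                 stop(e)
               }
             })
  }
  tab <- data.frame(source = rownames(av), sum_sq = av$`Sum Sq`, df = av$Df,
                    F = av$`F value`, p = av$`Pr(>F)`, stringsAsFactors = FALSE)
  # a zero error mean square leaves F undefined: report NaN, not Inf
  err_ms <- tab$sum_sq[tab$source == "Residuals"] /
    max(tab$df[tab$source == "Residuals"], 1L)
  if (length(err_ms) == 1L && err_ms <= 1e-20 * max(mean(y^2), 1e-300)) {
    tab$F[tab$source != "Residuals"] <- NaN
    tab$p[tab$source != "Residuals"] <- NA_real_
  }
  tab <- tab[tab$source != "(Intercept)", , drop = FALSE]
  tab$source[tab$source == "A"] <- factor_names[1]
  tab$source[tab$source == "B"] <- factor_names[2]
  tab$source[tab$source == "A:B"] <- paste(factor_names, collapse = ":")
  tab$source[tab$source == "Residuals"] <- "Error"
  # Total row: SS about the grand mean with n-1 df (the conventional layout)
  total_ss <- sum((y - mean(y))^2)
  tab <- rbind(tab, data.frame(source = "Total", sum_sq = total_ss,
                               df = length(y) - 1L, F = NA_real_, p = NA_real_))
  tab$mean_sq <- ifelse(tab$df > 0 & tab$source != "Total",
                        tab$sum_sq / tab$df, NA_real_)
  tab <- tab[, c("source", "sum_sq", "df", "mean_sq", "F", "p")]
  rownames(tab) <- NULL
  structure(tab, class = c("anova_table", "data.frame"),
            ss_type = ss_type, include_interaction = include_interaction,
            n = length(y))
}

#' Two-step interaction protocol for the two-way ANOVA
#'
#' Fits the model with the interaction first; if the interaction is not
#' significant at `alpha`, refits without it and reports that table as the
#' final one — mirroring the usual test-then-drop protocol for a two-factor
#' design.
#'
#' @inheritParams two_way_anova
#' @param alpha Significance level for keeping the interaction.
#' @return List with `interaction_p`, `with_interaction` (anova_table),
#'   `final` (anova_table), `interaction_kept` (logical).
#' @export
anova_two_step <- function(y, factor_a, factor_b, alpha = 0.05,
                           factor_names = c("A", "B")) {
  full <- two_way_anova(y, factor_a, factor_b, include_interaction = TRUE,
                        factor_names = factor_names)
  ip <- full$p[full$source == paste(factor_names, collapse = ":")]
  keep <- is.finite(ip) && ip < alpha
  final <- if (keep) {
    full
  } else {
    two_way_anova(y, factor_a, factor_b, include_interaction = FALSE,
                  factor_names = factor_names)
  }
  list(interaction_p = ip, with_interaction = full, final = final,
       interaction_kept = keep)
}

#' Render a p-value, flooring at 1e-12
#'
#' @param p Numeric p-value.
#' @return Character; values below 1e-12 render as "<1e-12".
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "n/a", ifelse(p < 1e-12, "<1e-12", format(p, digits = 3)))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted p per group pair, using the one-way error mean
#' square; unbalanced groups use the Tukey-Kramer average-1/n rule (as
#' implemented by `TukeyHSD` on a one-way `aov` fit).
#'
#' @param y Numeric response.
#' @param groups Group labels, each group with >= 2 members.
#' @param alpha Level for the `significant` flag.
#' @return data.frame with columns `group_i`, `group_j`, `mean_diff`,
#'   `adjusted_p`, `significant`.
#' @export
tukey_hsd <- function(y, groups, alpha = 0.05) {
  g <- factor(groups)
  stopifnot(length(y) == length(g))
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop("group-size error: group `", names(sizes)[sizes < 2][1],
         "` has < 2 members", call. = FALSE)
  }
  fit <- stats::aov(y ~ g, data = data.frame(y = y, g = g))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group_i = vapply(pairs, `[`, character(1), 2),
    group_j = vapply(pairs, `[`, character(1), 1),
    mean_diff = -tk[, "diff"],
    adjusted_p = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-group TPD summary (mean, sd, range)
#'
#' Arithmetic mean, sample standard deviation (n-1), and range of a distance
#' statistic per group — the per-donor summary layout of a longitudinal
#' collection. Single-member groups report `NA` sd and a collapsed range.
#'
#' @param distances data.frame with at least `specimen_id` and `tpd` (or the
#'   column named by `value`).
#' @param group Vector of group labels aligned to the rows of `distances`.
#' @param value Name of the summarized column (default "tpd").
#' @return data.frame with `group`, `n`, `mean`, `sd`, `min`, `max`, and a
#'   rendered `summary` ("mean +/- sd") and `range` ("min - max").
#' @export
tpd_summary <- function(distances, group, value = "tpd") {
  stopifnot(value %in% names(distances), length(group) == nrow(distances))
  out <- do.call(rbind, lapply(split(distances[[value]], group), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               min = min(v), max = max(v))
  }))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$summary <- sprintf("%.3g ± %.3g", out$mean, out$sd)
  out$summary[is.na(out$sd)] <- sprintf("%.3g ± n/a", out$mean[is.na(out$sd)])
  out$range <- sprintf("%.3g − %.3g", out$min, out$max)
  out
}
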