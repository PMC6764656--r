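#' Construct a single Raman scan
#'
#' A `raman_spectrum` holds one scan: a strictly increasing Raman-shift axis
#' (cm^-1), the detector intensities (arbitrary units), and provenance
#' (specimen id and scan replicate index).
#'
#' @param shifts Numeric vector of Raman shifts in cm^-1, strictly increasing.
#' @param intensities Numeric vector of intensities, same length as `shifts`.
#' @param specimen_id Character scalar identifying the specimen.
#' @param scan_index Integer replicate index, >= 1.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(shifts, intensities, specimen_id, scan_index = 1L) {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  if (length(shifts) != length(intensities)) {
    stop("`shifts` and `intensities` must have equal length", call. = FALSE)
  }
  if (length(shifts) < 2L) {
    stop("a spectrum needs at least 2 channels", call. = FALSE)
  }
  if (anyNA(shifts) || anyNA(intensities) ||
      !all(is.finite(shifts)) || !all(is.finite(intensities))) {
    stop("shifts and intensities must be finite", call. = FALSE)
  }
  if (any(diff(shifts) <= 0)) {
    stop("`shifts` must be strictly increasing", call. = FALSE)
  }
  scan_index <- as.integer(scan_index)
  if (length(scan_index) != 1L || is.na(scan_index) || scan_index < 1L) {
    stop("`scan_index` must be a single integer >= 1", call. = FALSE)
  }
  structure(
    list(shifts = shifts, intensities = intensities,
         specimen_id = as.character(specimen_id), scan_index = scan_index),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s:%d, %d channels, %g-%g cm^-1\n",
              x$specimen_id, x$scan_index, length(x$shifts),
              min(x$shifts), max(x$shifts)))
  invisible(x)
}

#' Default working Raman-shift grid
#'
#' The instrument window is 250-1950 cm^-1; the working grid oversamples the
#' 8 cm^-1 spectral resolution at a 2 cm^-1 step (851 channels).
#'
#' @param low,high Window limits in cm^-1.
#' @param step Grid spacing in cm^-1.
#' @return Numeric vector of shifts.
#' @export
default_grid <- function(low = 250, high = 1950, step = 2) {
  seq(low, high, by = step)
}

#' Construct an aligned spectrum set
#'
#' A `spectrum_set` is an intensity matrix on a common shift grid, one row
#' per scan (or per specimen, after replicate averaging). Row identity is the
#' (specimen_id, scan_index) pair; pairs must be unique. Downstream
#' operations pair rows to metadata by `specimen_id`, never by position.
#'
#' @param grid Common Raman-shift axis, strictly increasing.
#' @param intensities Numeric matrix, one row per scan, `length(grid)` columns.
#' @param specimen_ids Character vector of row specimen ids.
#' @param scan_index Integer vector of scan replicate indices, or `NA` after
#'   replicate averaging (then `specimen_ids` must be unique).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(grid, intensities, specimen_ids, scan_index = NA_integer_) {
  grid <- as.numeric(grid)
  intensities <- as.matrix(intensities)
  specimen_ids <- as.character(specimen_ids)
  if (any(diff(grid) <= 0)) stop("`grid` must be strictly increasing", call. = FALSE)
  if (nrow(intensities) != length(specimen_ids)) {
    stop("one specimen_id per matrix row required", call. = FALSE)
  }
  if (ncol(intensities) != length(grid)) {
    stop("matrix column count must match grid length", call. = FALSE)
  }
  if (!all(is.finite(intensities))) stop("intensities must be finite", call. = FALSE)
  scan_index <- as.integer(rep_len(scan_index, length(specimen_ids)))
  key <- ifelse(is.na(scan_index), specimen_ids,
                paste(specimen_ids, scan_index, sep = ":"))
  if (anyDuplicated(key)) {
    stop("duplicate rows: ", paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(intensities) <- list(key, NULL)
  structure(
    list(grid = grid, intensities = intensities,
         specimen_ids = specimen_ids, scan_index = scan_index),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d rows (%d specimens) x %d channels, %g-%g cm^-1\n",
              nrow(x$intensities), length(unique(x$specimen_ids)),
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$intensities)

#' Subset rows of a spectrum set
#'
#' @param set A `spectrum_set`.
#' @param i Row index (logical, integer, or negative integer).
#' @return A `spectrum_set` with the selected rows.
#' @export
subset_rows <- function(set, i) {
  stopifnot(inherits(set, "spectrum_set"))
  spectrum_set(set$grid, set$intensities[i, , drop = FALSE],
               set$specimen_ids[i], set$scan_index[i])
}

#' Read a matrix of Raman scans from CSV
#'
#' Two dialects are supported. `wide`: first column `raman_shift_cm-1`,
#' remaining columns one scan each, headed `<specimen_id>:<scan_index>`.
#' `long`: columns `specimen_id,scan_index,raman_shift_cm-1,intensity`.
#' Rows are sorted into ascending shift order per scan.
#'
#' @param path CSV file path.
#' @param dialect `"wide"` or `"long"`.
#' @return List of `raman_spectrum`, one per scan.
#' @export
read_scan_matrix <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (names(df)[1] != "raman_shift_cm-1") {
      stop("wide dialect requires first column `raman_shift_cm-1`, got `",
           names(df)[1], "`", call. = FALSE)
    }
    shifts <- df[[1]]
    .check_numeric_column(shifts, names(df)[1])
    ord <- order(shifts)
    shifts <- shifts[ord]
    if (anyDuplicated(shifts)) {
      stop("format error: repeated Raman shift value ",
           shifts[duplicated(shifts)][1], call. = FALSE)
    }
    scans <- lapply(names(df)[-1], function(col) {
      .check_numeric_column(df[[col]], col)
      id_idx <- .split_scan_header(col)
      raman_spectrum(shifts, df[[col]][ord], id_idx$specimen_id, id_idx$scan_index)
    })
    scans
  } else {
    need <- c("specimen_id", "scan_index", "raman_shift_cm-1", "intensity")
    if (!all(need %in% names(df))) {
      stop("long dialect requires columns ", paste(need, collapse = ","),
           call. = FALSE)
    }
    .check_numeric_column(df[["raman_shift_cm-1"]], "raman_shift_cm-1")
    .check_numeric_column(df[["intensity"]], "intensity")
    key <- paste(df$specimen_id, df$scan_index, sep = ":")
    lapply(unique(key), function(k) {
      g <- df[key == k, , drop = FALSE]
      ord <- order(g[["raman_shift_cm-1"]])
      sh <- g[["raman_shift_cm-1"]][ord]
      if (anyDuplicated(sh)) {
        stop("format error: repeated Raman shift value for scan ", k, call. = FALSE)
      }
      raman_spectrum(sh, g[["intensity"]][ord],
                     g$specimen_id[1], as.integer(g$scan_index[1]))
    })
  }
}

.check_numeric_column <- function(x, name) {
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(x)))))[1]
    stop("parse error: non-numeric cell in column `", name, "`, row ",
         if (is.na(bad)) "?" else bad, call. = FALSE)
  }
  if (anyNA(x)) {
    stop("parse error: missing value in column `", name, "`, row ",
         which(is.na(x))[1], call. = FALSE)
  }
  invisible(TRUE)
}

.split_scan_header <- function(col) {
  pos <- regexpr(":[0-9]+$", col)
  if (pos < 0) {
    stop("scan column header must be `<specimen_id>:<scan_index>`, got `",
         col, "`", call. = FALSE)
  }
  list(specimen_id = substr(col, 1L, pos - 1L),
       scan_index = as.integer(substr(col, pos + 1L, nchar(col))))
}

#' Write a spectrum set as a wide CSV
#'
#' Inverse of [read_scan_matrix()] with `dialect = "wide"`: first column
#' `raman_shift_cm-1`, one column per row of the set headed
#' `<specimen_id>:<scan_index>`.
#'
#' @param set A `spectrum_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_matrix <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  idx <- ifelse(is.na(set$scan_index), 1L, set$scan_index)
  out <- data.frame(set$grid, t(set$intensities), check.names = FALSE)
  names(out) <- c("raman_shift_cm-1", paste(set$specimen_ids, idx, sep = ":"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a target grid by linear interpolation
#'
#' Channels outside the source range are never extrapolated; a grid that
#' extends beyond the source range is an error.
#'
#' @param spectrum A `raman_spectrum`.
#' @param grid Target shift axis, within the source range.
#' @return A `raman_spectrum` on `grid`.
#' @export
resample_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  grid <- as.numeric(grid)
  lo <- min(spectrum$shifts); hi <- max(spectrum$shifts)
  if (min(grid) < lo || max(grid) > hi) {
    stop(sprintf("range error: grid [%g, %g] extends beyond source [%g, %g]",
                 min(grid), max(grid), lo, hi), call. = FALSE)
  }
  y <- stats::approx(spectrum$shifts, spectrum$intensities, xout = grid,
                     method = "linear", ties = "ordered")$y
  raman_spectrum(grid, y, spectrum$specimen_id, spectrum$scan_index)
}

#' Assemble scans into an aligned spectrum set
#'
#' Each scan is resampled onto the common grid; rows keep the input order.
#'
#' @param spectra Non-empty list of `raman_spectrum`.
#' @param grid Common shift axis (default [default_grid()]).
#' @return A `spectrum_set`, one row per (specimen, scan).
#' @export
assemble_set <- function(spectra, grid = default_grid()) {
  if (length(spectra) == 0L) stop("`spectra` must be non-empty", call. = FALSE)
  res <- lapply(spectra, resample_to_grid, grid = grid)
  spectrum_set(
    grid,
    do.call(rbind, lapply(res, `[[`, "intensities")),
    vapply(res, `[[`, character(1), "specimen_id"),
    vapply(res, `[[`, integer(1), "scan_index")
  )
}

#' Read and validate a specimen metadata table
#'
#' The CSV must have exactly the columns
#' `specimen_id,donor_id,sex,birth_year,collection_date,menstruation,is_control`
#' (case-sensitive). Booleans are parsed from true/false/0/1. Validation:
#' unique specimen ids; sex in {F, M}; `menstruation` may be true only for
#' female, non-control rows.
#'
#' @param path CSV file path.
#' @return A validated `data.frame`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a specimen metadata table already in memory
#'
#' @param df Data frame with the metadata columns of [read_metadata()].
#' @return The validated data frame, with parsed types.
#' @export
validate_metadata <- function(df) {
  need <- c("specimen_id", "donor_id", "sex", "birth_year", "collection_date",
            "menstruation", "is_control")
  if (!identical(sort(names(df)), sort(need))) {
    stop("metadata must have exactly columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df <- df[, need]
  df$specimen_id <- as.character(df$specimen_id)
  df$donor_id <- as.character(df$donor_id)
  df$sex <- as.character(df$sex)
  df$birth_year <- as.integer(df$birth_year)
  df$menstruation <- .parse_bool(df$menstruation, "menstruation")
  df$is_control <- .parse_bool(df$is_control, "is_control")
  dup <- duplicated(df$specimen_id)
  if (any(dup)) {
    stop("validation error: duplicate specimen_id `", df$specimen_id[dup][1],
         "` (row ", which(dup)[1], ")", call. = FALSE)
  }
  bad_sex <- which(!df$sex %in% c("F", "M"))
  if (length(bad_sex)) {
    stop("validation error: unknown sex code `", df$sex[bad_sex[1]],
         "` (row ", bad_sex[1], ")", call. = FALSE)
  }
  bad_mens <- which(df$menstruation & (df$sex != "F" | df$is_control))
  if (length(bad_mens)) {
    stop("validation error: menstruation=true requires sex=F and is_control=false",
         " (row ", bad_mens[1], ")", call. = FALSE)
  }
  df
}

.parse_bool <- function(x, name) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "1")] <- TRUE
  out[x %in% c("false", "0")] <- FALSE
  if (anyNA(out)) {
    stop("validation error: column `", name, "` must be true/false/0/1 (row ",
         which(is.na(out))[1], ")", call. = FALSE)
  }
  out
}
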