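#' Construct a case-by-feature table with binary outcome labels
#'
#' @param x Numeric matrix, cases in rows, features in columns (named).
#' @param labels Binary vector (1 = pCR, 0 = residual disease), one per row.
#' @param case_ids Optional character case identifiers.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(x, labels, case_ids = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    stop("one label per case is required", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1 (1 = pCR)", call. = FALSE)
  if (is.null(case_ids)) case_ids <- sprintf("case_%04d", seq_len(nrow(x)))
  rownames(x) <- case_ids
  structure(list(x = x, labels = labels, case_ids = as.character(case_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cases (%d pCR) x %d features, %d missing values\n",
              nrow(x$x), sum(x$labels), ncol(x$x), sum(is.na(x$x))))
  invisible(x)
}

#' Extract the feature bank for every case of a cohort
#'
#' Optionally resamples each case in-plane first, then applies
#' [extract_bank()] case by case.
#'
#' @param cohort A `synthetic_cohort`, or a list with elements `cases`
#'   (list of [volume_with_mask()]) and `labels`.
#' @param config A [bank_config()].
#' @param target_spacing_mm If non-`NULL`, planar resampling target applied
#'   to every case before extraction (the study uses 0.548 mm).
#' @return A [feature_table()].
#' @export
cohort_feature_table <- function(cohort, config = bank_config(),
                                 target_spacing_mm = NULL) {
  stopifnot(is.list(cohort$cases), length(cohort$cases) == length(cohort$labels))
  rows <- lapply(cohort$cases, function(v) {
    if (!is.null(target_spacing_mm)) v <- resample_planar(v, target_spacing_mm)
    extract_bank(v, config)
  })
  feature_table(do.call(rbind, rows), cohort$labels)
}

#' Drop unusably sparse features and impute the remainder
#'
#' Features missing in more than `max_missing_frac` of cases are dropped;
#' remaining missing values are replaced by the feature median. Dropped
#' feature ids are recorded in the `dropped_features` attribute.
#'
#' @param table A [feature_table()].
#' @param max_missing_frac Missingness tolerance per feature (default 0.2).
#' @return A complete [feature_table()].
#' @export
clean_feature_table <- function(table, max_missing_frac = 0.2) {
  stopifnot(inherits(table, "feature_table"))
  frac <- colMeans(is.na(table$x))
  keep <- frac <= max_missing_frac
  x <- table$x[, keep, drop = FALSE]
  for (j in which(colSums(is.na(x)) > 0)) {
    med <- stats::median(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- med
  }
  out <- feature_table(x, table$labels, table$case_ids)
  attr(out, "dropped_features") <- colnames(table$x)[!keep]
  out
}
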