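#' @title Stability-based univariate feature selection
#' @description The study's ad-hoc iterative selection: the merged cohort is
#'   split into eight stratified folds; each feature is tested univariately
#'   (Wilcoxon Mann-Whitney, or Welch's t-test when both classes look normal)
#'   on each of the eight leave-one-fold-out subsets; features significant
#'   (p < 0.05) in at least five of the eight subsets form the stable set,
#'   which is then pruned so that every surviving pair has absolute Pearson
#'   correlation below 0.6. No multiple-testing correction is applied, as in
#'   the study; selection is performed once on the full merged table, before
#'   model cross-validation, so the optimistic bias of that design is
#'   inherited deliberately and documented in the run report.
#' @name selection
NULL

#' Stratified fold assignment
#'
#' Deals each class (shuffled under the seed) into the fold currently holding
#' the fewest cases, so fold sizes differ by at most one and class
#' proportions per fold are within one case of each other.
#'
#' @param labels Binary outcome vector.
#' @param k Number of folds (default 8).
#' @param seed Integer seed.
#' @return Integer fold assignment in `1:k`, one per case.
#' @export
make_folds <- function(labels, k = 8, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (any(table(factor(labels, levels = 0:1)) < k))
    stop(sprintf("each class needs at least %d cases for %d-fold stratification",
                 k, k), call. = FALSE)
  fold <- integer(n)
  withr::with_seed(seed, {
    sizes <- integer(k)
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      for (i in idx) {
        f <- which.min(sizes)
        fold[i] <- f
        sizes[f] <- sizes[f] + 1L
      }
    }
  })
  fold
}

#' Univariate two-group p-value with a normality gate
#'
#' When both classes have at least 8 cases and both pass Shapiro-Wilk at
#' alpha = 0.05, a two-sided Welch t-test is used; otherwise the two-sided
#' Wilcoxon Mann-Whitney test (exact for small tie-free samples, otherwise
#' the tie-corrected normal approximation). Constant data returns p = 1 by
#' convention.
#'
#' @param values Numeric feature values, one per case.
#' @param labels Binary outcome vector.
#' @return A p-value in (0, 1\].
#' @export
univariate_p <- function(values, labels) {
  labels <- as.integer(labels)
  g0 <- values[labels == 0L]
  g1 <- values[labels == 1L]
  if (length(g0) == 0L || length(g1) == 0L)
    stop("both classes must be present", call. = FALSE)
  if (stats::sd(values) == 0) return(1)
  normal <- FALSE
  if (min(length(g0), length(g1)) >= 8L) {
    sw <- function(g) tryCatch(stats::shapiro.test(g)$p.value,
                               error = function(e) 0)
    normal <- sw(g0) > 0.05 && sw(g1) > 0.05
  }
  p <- if (normal) stats::t.test(g0, g1)$p.value
       else suppressWarnings(stats::wilcox.test(g0, g1)$p.value)
  if (!is.finite(p)) 1 else min(max(p, .Machine$double.xmin), 1)
}

#' Significance votes across leave-one-fold-out subsets
#'
#' For each of the `k` subsets obtained by dropping one fold, every feature
#' is tested with [univariate_p()] on the retained cases; its vote count is
#' the number of subsets where p < `alpha`.
#'
#' @param table A complete [feature_table()].
#' @param folds Integer fold assignment from [make_folds()].
#' @param alpha Significance level per subset (default 0.05).
#' @return List with `votes` (named integer, 0..k), `p_matrix`
#'   (features x subsets) and `median_p` (per-feature median over subsets).
#' @export
stability_votes <- function(table, folds, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"),
            length(folds) == nrow(table$x))
  k <- max(folds)
  p_mat <- matrix(NA_real_, ncol(table$x), k,
                  dimnames = list(colnames(table$x), paste0("drop_fold_", 1:k)))
  for (f in seq_len(k)) {
    keep <- folds != f
    lab <- table$labels[keep]
    xs <- table$x[keep, , drop = FALSE]
    p_mat[, f] <- apply(xs, 2, univariate_p, labels = lab)
  }
  votes <- rowSums(p_mat < alpha)
  list(votes = stats::setNames(as.integer(votes), rownames(p_mat)),
       p_matrix = p_mat,
       median_p = apply(p_mat, 1, stats::median))
}

#' Features passing the stability threshold
#'
#' @param votes Named integer vote counts (or the list from
#'   [stability_votes()]).
#' @param min_votes Minimum vote count to retain (default 5 of 8).
#' @return Character vector of feature ids, order-preserving.
#' @export
select_stable <- function(votes, min_votes = 5) {
  if (is.list(votes)) votes <- votes$votes
  names(votes)[votes >= min_votes]
}

#' Greedy Pearson-correlation pruning of the stable set
#'
#' Features are visited in order of ascending priority (by default the
#' median p-value over the leave-one-fold-out subsets; ties broken by
#' descending vote count, then feature id) and accepted iff their absolute
#' Pearson correlation with every already-accepted feature is below `r_max`.
#'
#' @param table A complete [feature_table()].
#' @param stable_set Character vector of candidate feature ids.
#' @param r_max Pairwise correlation bound (default 0.6).
#' @param median_p,votes Optional named priority vectors (see above); without
#'   them candidates are visited in the given order.
#' @return Character vector: the pruned final set.
#' @export
prune_correlated <- function(table, stable_set, r_max = 0.6,
                             median_p = NULL, votes = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (length(stable_set) == 0L) return(character(0))
  ord <- if (!is.null(median_p)) {
    v <- if (!is.null(votes)) votes[stable_set] else rep(0L, length(stable_set))
    stable_set[order(median_p[stable_set], -v, stable_set)]
  } else stable_set
  accepted <- character(0)
  for (f in ord) {
    if (length(accepted) == 0L) { accepted <- f; next }
    r <- suppressWarnings(
      abs(stats::cor(table$x[, f], table$x[, accepted, drop = FALSE])))
    r[is.na(r)] <- 0
    if (all(r < r_max)) accepted <- c(accepted, f)
  }
  accepted
}

#' Run the full stability selection stage
#'
#' @param table A complete [feature_table()].
#' @param k Number of folds (default 8).
#' @param alpha Per-subset significance level (default 0.05).
#' @param min_votes Stability threshold (default 5).
#' @param r_max Pearson pruning bound (default 0.6).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `selection_report`: fold assignment, votes,
#'   per-feature median p, stable set, pruned final set and the parameters.
#' @export
select_features <- function(table, k = 8, alpha = 0.05, min_votes = 5,
                            r_max = 0.6, seed = 1L) {
  folds <- make_folds(table$labels, k, seed)
  sv <- stability_votes(table, folds, alpha)
  stable <- select_stable(sv$votes, min_votes)
  pruned <- prune_correlated(table, stable, r_max,
                             median_p = sv$median_p, votes = sv$votes)
  structure(
    list(fold_assignment = stats::setNames(folds, table$case_ids),
         votes = sv$votes, median_p = sv$median_p,
         stable_set = stable, pruned_set = pruned,
         params = list(k = k, alpha = alpha, min_votes = min_votes,
                       r_max = r_max),
         seed = as.integer(seed)),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf(
    "<selection_report> %d features voted, %d stable (>= %d/%d votes), %d after |r| < %.2f pruning\n",
    length(x$votes), length(x$stable_set), x$params$min_votes, x$params$k,
    length(x$pruned_set), x$params$r_max))
  if (length(x$pruned_set))
    cat("final set:", paste(utils::head(x$pruned_set, 10), collapse = ", "),
        if (length(x$pruned_set) > 10) "...\n" else "\n")
  invisible(x)
}
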