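test_that("stratified folds balance size and class composition", {
  lab80 <- rep(c(0L, 1L), 40)
  f <- make_folds(lab80, k = 8, seed = 1)
  expect_true(all(table(f) == 10))
  expect_true(all(table(f, lab80) == 5))

  lab183 <- rep(c(0L, 1L), c(109, 74))
  f183 <- make_folds(lab183, k = 8, seed = 2)
  expect_setequal(as.integer(table(f183)), c(22L, 23L))
  # class proportions per fold within one case
  per_fold_pos <- table(f183, lab183)[, "1"]
  expect_lte(max(per_fold_pos) - min(per_fold_pos), 1)

  expect_identical(make_folds(lab183, 8, seed = 7),
                   make_folds(lab183, 8, seed = 7))
  expect_error(make_folds(rep(c(0L, 1L), c(100, 5)), k = 8), "at least")
})

test_that("univariate test switches between rank and t statistics appropriately", {
  # exact small-sample WMW: only C(6,3) = 20 rank assignments, min p = 2/20
  expect_equal(univariate_p(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3)), 0.1)

  # constant data is uninformative by convention
  expect_equal(univariate_p(rep(5, 20), rep(c(0, 1), 10)), 1)

  # perfect separation at n = 20 is decisively significant
  expect_lt(univariate_p(c(rnorm(10), rnorm(10) + 50), rep(c(0, 1), each = 10)),
            1e-3)

  # normal-looking classes at n >= 8 take the Welch t branch
  x <- withr::with_seed(3, c(rnorm(30), rnorm(30) + 0.5))
  lab <- rep(c(0L, 1L), each = 30)
  stopifnot(shapiro.test(x[1:30])$p.value > 0.05,
            shapiro.test(x[31:60])$p.value > 0.05)
  expect_equal(univariate_p(x, lab), t.test(x[1:30], x[31:60])$p.value)

  # heavily skewed classes take the rank branch
  y <- withr::with_seed(4, c(rexp(30), rexp(30) * 1.5))
  stopifnot(shapiro.test(y[1:30])$p.value < 0.05)
  expect_equal(univariate_p(y, lab),
               suppressWarnings(wilcox.test(y[1:30], y[31:60])$p.value))

  expect_error(univariate_p(rnorm(5), rep(0L, 5)), "both classes")
})

test_that("leave-one-fold-out voting is calibrated and deterministic", {
  ft <- generate_feature_table(120, 500, n_informative = 2, effect_size = 3,
                               seed = 5)
  folds <- make_folds(ft$labels, 8, seed = 6)
  sv <- stability_votes(ft, folds)
  # overwhelming effects win every subset
  expect_identical(unname(sv$votes[c("f0001", "f0002")]), c(8L, 8L))
  # null features average about k * alpha votes
  null_votes <- sv$votes[-(1:2)]
  expect_gt(mean(null_votes), 0.1)
  expect_lt(mean(null_votes), 0.8)
  # few null features reach the stability threshold
  expect_lt(mean(null_votes >= 5), 0.05)
  expect_identical(sv$votes, stability_votes(ft, folds)$votes)
  expect_identical(dim(sv$p_matrix), c(500L, 8L))
})

test_that("the stability threshold is a strict at-least-five rule", {
  votes <- c(a = 8L, b = 5L, c = 4L, d = 0L)
  expect_identical(select_stable(votes), c("a", "b"))
  expect_identical(select_stable(votes, min_votes = 1), c("a", "b", "c"))
  expect_identical(select_stable(c(x = 8L, y = 8L)), c("x", "y"))
})

test_that("correlation pruning removes redundant features under |r| < 0.6", {
  n <- 500
  base <- withr::with_seed(8, rnorm(n))
  x <- cbind(f1 = base, f2 = base, f3 = -base,
             f4 = withr::with_seed(9, rnorm(n)),
             f5 = withr::with_seed(10, rnorm(n)))
  ft <- feature_table(x, rep(c(0L, 1L), n / 2))

  # identical and anti-correlated duplicates: exactly one survivor
  expect_length(prune_correlated(ft, c("f1", "f2")), 1)
  expect_length(prune_correlated(ft, c("f1", "f3")), 1)

  # independent noise columns all survive at n = 500
  kept <- prune_correlated(ft, c("f1", "f4", "f5"))
  expect_setequal(kept, c("f1", "f4", "f5"))

  # result always satisfies the pairwise bound
  ftb <- generate_feature_table(300, 40, seed = 12, block_size = 4,
                                block_rho = 0.8)
  kept_b <- prune_correlated(ftb, colnames(ftb$x))
  if (length(kept_b) > 1) {
    cm <- abs(cor(ftb$x[, kept_b]))
    expect_lt(max(cm[upper.tri(cm)]), 0.6)
  }
  # priority ordering: lower median p wins the survivor slot
  mp <- c(f1 = 0.5, f2 = 0.001)
  expect_identical(prune_correlated(ft, c("f1", "f2"), median_p = mp), "f2")
})

test_that("selection is invariant to case order given the same fold assignment", {
  ft <- generate_feature_table(96, 50, n_informative = 3, effect_size = 1.5,
                               seed = 14)
  folds <- make_folds(ft$labels, 8, seed = 15)
  sv <- stability_votes(ft, folds)

  perm <- withr::with_seed(16, sample(96))
  ftp <- feature_table(ft$x[perm, ], ft$labels[perm], ft$case_ids[perm])
  svp <- stability_votes(ftp, folds[perm])
  expect_identical(sv$votes, svp$votes)
  expect_equal(sv$median_p, svp$median_p)
  expect_identical(
    prune_correlated(ft, select_stable(sv), median_p = sv$median_p),
    prune_correlated(ftp, select_stable(svp), median_p = svp$median_p))
})

test_that("stability voting is stricter than a single-pass significance screen", {
  ft <- generate_feature_table(180, 500, seed = 18)   # pure null
  single_pass <- sum(apply(ft$x, 2, univariate_p, labels = ft$labels) < 0.05)
  sel <- select_features(ft, seed = 19)
  expect_lte(length(sel$stable_set), single_pass)
  expect_lte(length(sel$pruned_set), length(sel$stable_set))
})
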