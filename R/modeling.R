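#' @title Classifier zoo and repeated cross-validated model selection
#' @description Fifteen classifiers spanning trees, discriminant methods,
#'   nearest neighbours/centroids, logistic and penalised regression, partial
#'   least squares, neural networks, random forests and a polynomial-kernel
#'   SVM are trained on the selected features and compared by mean held-out
#'   AUC over 3 repeats of stratified 8-fold cross-validation (24 ROC curves
#'   per classifier). Every classifier emits class-1 probabilities; models
#'   whose native output is a margin are wrapped with a monotone logistic
#'   calibration fitted on the training folds. The winner (highest mean AUC;
#'   ties to lower SD, then roster order) is refit on the full dataset.
#' @name modeling
NULL

#' The classifier roster
#'
#' @return Data frame with the roster `key`, a human-readable `label` and the
#'   backing implementation.
#' @export
classifier_roster <- function() {
  data.frame(
    key = c("C5TREE", "DT", "HDDA", "KNN", "LOGREG", "NB", "NN", "PAM",
            "PDA", "PLS", "RF_DEF", "RF_GRID", "RF_RAND", "SDA", "SVM"),
    label = c("Decision tree", "Boosted decision trees",
              "High dimensional discriminant analysis",
              "K-nearest neighbours", "Logistic regression", "Naive Bayes",
              "Neural network", "Nearest shrunken centroids",
              "Penalised (ridge) logistic discriminant",
              "Partial least squares classifier",
              "Random forest (default parameters)",
              "Random forest (grid search)", "Random forest (random search)",
              "Shrinkage discriminant analysis",
              "Support vector machine (polynomial kernel)"),
    backend = c("rpart", "xgboost", "mclust::MclustDA", "caret::knn3",
                "stats::glm", "e1071::naiveBayes", "nnet", "radiopcr (NSC)",
                "glmnet (alpha = 0)", "mixOmics::plsda", "randomForest",
                "randomForest", "randomForest", "radiopcr (diagonal DA)",
                "e1071::svm"),
    stringsAsFactors = FALSE
  )
}

#' Default random-forest hyperparameters
#'
#' The study's winning configuration: 500 trees with
#' `mtry = floor(sqrt(p))` candidate variables per split (4 for the 19
#' selected features).
#'
#' @param p Number of selected features (>= 1).
#' @return List with `ntree` and `mtry`.
#' @export
rf_default_hyperparams <- function(p) {
  stopifnot(p >= 1)
  list(ntree = 500L, mtry = max(1L, as.integer(floor(sqrt(p)))))
}

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

# logistic (Platt) calibration of raw scores into probabilities
platt_calibrate <- function(train_scores, y) {
  df <- data.frame(s = as.numeric(train_scores), y = as.integer(y == "pos"))
  g <- tryCatch(
    suppressWarnings(stats::glm(y ~ s, data = df, family = stats::binomial())),
    error = function(e) NULL)
  function(s) {
    if (is.null(g)) {
      r <- range(df$s)
      if (r[2] > r[1]) clamp01((s - r[1]) / (r[2] - r[1])) else rep(0.5, length(s))
    } else clamp01(stats::predict(g, data.frame(s = as.numeric(s)),
                                  type = "response"))
  }
}

# --- in-package discriminant implementations --------------------------------

# nearest shrunken centroids; shrinkage chosen by internal 3-fold CV accuracy
nsc_fit <- function(x, y, deltas = c(0, 0.5, 1, 1.5, 2, 2.5)) {
  classes <- levels(y)
  n <- nrow(x); p <- ncol(x)
  overall <- colMeans(x)
  pooled_var <- numeric(p)
  cent <- matrix(0, length(classes), p, dimnames = list(classes, colnames(x)))
  for (k in classes) {
    xc <- x[y == k, , drop = FALSE]
    cent[k, ] <- colMeans(xc)
    pooled_var <- pooled_var + colSums(sweep(xc, 2, cent[k, ])^2)
  }
  s <- sqrt(pooled_var / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / table(y)[classes] - 1 / n)
  d <- sweep(sweep(cent, 2, overall), 2, s + s0, "/") / as.numeric(mk)
  shrink <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)
  score_fun <- function(delta, xx) {
    dk <- shrink(d, delta)
    ck <- sweep(sweep(dk, 2, s + s0, "*") * as.numeric(mk), 2, overall, "+")
    prior <- as.numeric(table(y)[classes]) / n
    disc <- sapply(classes, function(k)
      -rowSums(sweep(xx, 2, ck[k, ])^2 / matrix((s + s0)^2, nrow(xx), p,
                                                byrow = TRUE)) / 2 +
        log(prior[match(k, classes)]))
    matrix(disc, nrow(xx), length(classes), dimnames = list(NULL, classes))
  }
  folds <- if (min(table(y)) >= 3) make_folds(as.integer(y == "pos"), 3,
                                              seed = 7L) else NULL
  acc <- vapply(deltas, function(delta) {
    if (is.null(folds)) {
      pred <- classes[max.col(score_fun(delta, x))]
      mean(pred == y)
    } else {
      mean(vapply(1:3, function(f) {
        tr <- folds != f
        fit <- nsc_refit(x[tr, , drop = FALSE], y[tr], delta)
        pred <- classes[max.col(nsc_score(fit, x[!tr, , drop = FALSE]))]
        mean(pred == y[!tr])
      }, numeric(1)))
    }
  }, numeric(1))
  best <- deltas[which.max(acc)]
  structure(list(refit = nsc_refit(x, y, best), delta = best,
                 classes = classes), class = "radiopcr_nsc")
}

nsc_refit <- function(x, y, delta) {
  classes <- levels(y)
  n <- nrow(x); p <- ncol(x)
  overall <- colMeans(x)
  pooled_var <- numeric(p)
  cent <- matrix(0, length(classes), p, dimnames = list(classes, colnames(x)))
  for (k in classes) {
    xc <- x[y == k, , drop = FALSE]
    cent[k, ] <- colMeans(xc)
    pooled_var <- pooled_var + colSums(sweep(xc, 2, cent[k, ])^2)
  }
  s <- sqrt(pooled_var / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / table(y)[classes] - 1 / n)
  d <- sweep(sweep(cent, 2, overall), 2, s + s0, "/") / as.numeric(mk)
  dk <- sign(d) * pmax(abs(d) - delta, 0)
  ck <- sweep(sweep(dk, 2, s + s0, "*") * as.numeric(mk), 2, overall, "+")
  list(centroids = ck, scale = s + s0,
       prior = as.numeric(table(y)[classes]) / n, classes = classes)
}

nsc_score <- function(fit, xx) {
  p <- ncol(xx)
  disc <- sapply(fit$classes, function(k)
    -rowSums(sweep(xx, 2, fit$centroids[k, ])^2 /
               matrix(fit$scale^2, nrow(xx), p, byrow = TRUE)) / 2 +
      log(fit$prior[match(k, fit$classes)]))
  matrix(disc, nrow(xx), length(fit$classes),
         dimnames = list(NULL, fit$classes))
}

# diagonal discriminant analysis with variance shrinkage toward the mean
dda_fit <- function(x, y, lambda = 0.25) {
  classes <- levels(y)
  n <- nrow(x)
  cent <- t(sapply(classes, function(k) colMeans(x[y == k, , drop = FALSE])))
  pooled <- colSums(do.call(rbind, lapply(classes, function(k) {
    xc <- x[y == k, , drop = FALSE]
    colSums(sweep(xc, 2, colMeans(xc))^2)
  }))) / (n - length(classes))
  v <- (1 - lambda) * pooled + lambda * mean(pooled)
  v <- pmax(v, 1e-10)
  list(centroids = cent, var = v,
       prior = as.numeric(table(y)[classes]) / n, classes = classes)
}

dda_prob <- function(fit, xx) {
  disc <- sapply(fit$classes, function(k)
    -rowSums(sweep(xx, 2, fit$centroids[k, ])^2 /
               matrix(fit$var, nrow(xx), ncol(xx), byrow = TRUE)) / 2 +
      log(fit$prior[match(k, fit$classes)]))
  disc <- matrix(disc, nrow(xx), length(fit$classes),
                 dimnames = list(NULL, fit$classes))
  e <- exp(disc - apply(disc, 1, max))
  e / rowSums(e)
}

# oob-error tuning for the searched random forests
rf_tuned_fit <- function(x, y, candidates) {
  errs <- vapply(candidates, function(m) {
    rf <- randomForest::randomForest(x, y, ntree = 200, mtry = m)
    rf$err.rate[nrow(rf$err.rate), "OOB"]
  }, numeric(1))
  best <- candidates[which.min(errs)]
  randomForest::randomForest(x, y, ntree = 500, mtry = best)
}

# --- backend registry -------------------------------------------------------

fit_classifier <- function(key, x, y, seed = 1L) {
  stopifnot(key %in% classifier_roster()$key)
  x <- as.matrix(x)
  p <- ncol(x)
  withr::with_seed(seed, switch(
    key,
    C5TREE = {
      d <- data.frame(x, check.names = TRUE); d$.y <- y
      m <- rpart::rpart(.y ~ ., data = d, method = "class")
      list(predict = function(nx)
        clamp01(stats::predict(m, data.frame(nx, check.names = TRUE))[, "pos"]))
    },
    DT = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "pos"),
                                     nthread = 1)
      m <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = dtrain, nrounds = 60, verbose = 0)
      list(predict = function(nx) clamp01(stats::predict(m, as.matrix(nx))))
    },
    HDDA = {
      # MclustDA resolves its model-step functions on the search path, so the
      # namespace must be attached during both fit and prediction
      m <- withr::with_package("mclust", quietly = TRUE,
        mclust::MclustDA(x, y, modelType = "EDDA", verbose = FALSE))
      list(predict = function(nx)
        clamp01(withr::with_package("mclust", quietly = TRUE,
          stats::predict(m, as.matrix(nx))$z[, "pos"])))
    },
    KNN = {
      m <- caret::knn3(x, y, k = min(7L, nrow(x) - 1L))
      list(predict = function(nx)
        clamp01(stats::predict(m, as.matrix(nx), type = "prob")[, "pos"]))
    },
    LOGREG = {
      d <- data.frame(x, check.names = TRUE); d$.y <- as.integer(y == "pos")
      m <- suppressWarnings(
        stats::glm(.y ~ ., data = d, family = stats::binomial()))
      list(predict = function(nx) clamp01(suppressWarnings(
        stats::predict(m, data.frame(nx, check.names = TRUE),
                       type = "response"))))
    },
    NB = {
      m <- e1071::naiveBayes(x, y)
      list(predict = function(nx)
        clamp01(stats::predict(m, as.matrix(nx), type = "raw",
                               eps = 1e-9)[, "pos"]))
    },
    NN = {
      ctr <- colMeans(x); scl <- pmax(apply(x, 2, stats::sd), 1e-8)
      xs <- scale(x, ctr, scl)
      m <- nnet::nnet(xs, as.numeric(y == "pos"), size = 5, decay = 0.1,
                      maxit = 300, trace = FALSE, entropy = TRUE,
                      MaxNWts = 10000)
      list(predict = function(nx)
        clamp01(stats::predict(m, scale(as.matrix(nx), ctr, scl))))
    },
    PAM = {
      m <- nsc_fit(x, y)
      list(predict = function(nx) {
        disc <- nsc_score(m$refit, as.matrix(nx))
        e <- exp(disc - apply(disc, 1, max))
        clamp01((e / rowSums(e))[, "pos"])
      })
    },
    PDA = {
      xx <- if (p < 2L) cbind(x, .pad = 0) else x
      cv <- glmnet::cv.glmnet(xx, as.numeric(y == "pos"),
                              family = "binomial", alpha = 0, nfolds = 3)
      list(predict = function(nx) {
        nx <- as.matrix(nx)
        if (p < 2L) nx <- cbind(nx, .pad = 0)
        clamp01(stats::predict(cv, nx, s = "lambda.min", type = "response"))
      })
    },
    PLS = {
      ncomp <- max(1L, min(2L, p, nrow(x) - 2L))
      m <- mixOmics::plsda(x, y, ncomp = ncomp)
      raw_train <- stats::predict(m, x)$predict[, "pos", ncomp]
      cal <- platt_calibrate(raw_train, y)
      list(predict = function(nx)
        cal(stats::predict(m, as.matrix(nx))$predict[, "pos", ncomp]))
    },
    RF_DEF = {
      hp <- rf_default_hyperparams(p)
      m <- randomForest::randomForest(x, y, ntree = hp$ntree, mtry = hp$mtry)
      list(predict = function(nx)
        clamp01(stats::predict(m, as.matrix(nx), type = "prob")[, "pos"]))
    },
    RF_GRID = {
      cand <- unique(pmax(1L, round(seq(1, p, length.out = min(10L, p)))))
      m <- rf_tuned_fit(x, y, cand)
      list(predict = function(nx)
        clamp01(stats::predict(m, as.matrix(nx), type = "prob")[, "pos"]))
    },
    RF_RAND = {
      cand <- unique(sample(seq_len(p), min(10L, p), replace = p < 10L))
      m <- rf_tuned_fit(x, y, cand)
      list(predict = function(nx)
        clamp01(stats::predict(m, as.matrix(nx), type = "prob")[, "pos"]))
    },
    SDA = {
      m <- dda_fit(x, y)
      list(predict = function(nx) clamp01(dda_prob(m, as.matrix(nx))[, "pos"]))
    },
    SVM = {
      m <- e1071::svm(x, y, kernel = "polynomial", degree = 3, coef0 = 1,
                      probability = TRUE, scale = apply(x, 2, stats::sd) > 0)
      list(predict = function(nx) {
        pr <- stats::predict(m, as.matrix(nx), probability = TRUE)
        clamp01(attr(pr, "probabilities")[, "pos"])
      })
    }
  ))
}

prepare_xy <- function(table, features = NULL) {
  x <- table$x
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  if (ncol(x) == 0L) stop("no features to model", call. = FALSE)
  orig <- colnames(x)
  colnames(x) <- sprintf("V%03d", seq_len(ncol(x)))
  y <- factor(ifelse(table$labels == 1L, "pos", "neg"), levels = c("neg", "pos"))
  list(x = x, y = y, feature_names = orig)
}

#' Held-out AUCs from repeated stratified cross-validation
#'
#' For each repeat a fresh stratified k-fold partition is drawn; the
#' classifier is trained on k-1 folds and scores the held-out fold, giving
#' `repeats * k` ROC AUCs (24 with the defaults). A classifier failure on a
#' fold is recorded as a missing AUC with a warning, never imputed.
#'
#' @param table A complete [feature_table()] (already restricted to the
#'   selected features, or use `features`).
#' @param key Roster key, see [classifier_roster()].
#' @param features Optional character subset of feature ids.
#' @param k Folds per repeat (default 8).
#' @param repeats Number of repeats (default 3).
#' @param seed Integer seed; fold partitions and model fits derive from it.
#' @return Named numeric vector of length `repeats * k` in (repeat, fold)
#'   order, with attribute `"fold_seeds"`.
#' @export
repeated_cv_auc <- function(table, key, features = NULL, k = 8, repeats = 3,
                            seed = 1L) {
  d <- prepare_xy(table, features)
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, repeats * (k + 1L)))
  aucs <- stats::setNames(
    rep(NA_real_, repeats * k),
    as.vector(t(outer(1:repeats, 1:k, function(r, f) sprintf("r%d.f%d", r, f)))))
  for (r in seq_len(repeats)) {
    rep_seed <- seeds[(r - 1L) * (k + 1L) + 1L]
    folds <- make_folds(as.integer(d$y == "pos"), k, rep_seed)
    for (f in seq_len(k)) {
      tr <- folds != f
      fit_seed <- seeds[(r - 1L) * (k + 1L) + 1L + f]
      res <- tryCatch({
        m <- fit_classifier(key, d$x[tr, , drop = FALSE], d$y[tr], fit_seed)
        sc <- m$predict(d$x[!tr, , drop = FALSE])
        auc_score(sc, as.integer(d$y[!tr] == "pos"))
      }, error = function(e) {
        warning(sprintf("%s failed on repeat %d fold %d: %s",
                        key, r, f, conditionMessage(e)), call. = FALSE)
        NA_real_
      })
      aucs[sprintf("r%d.f%d", r, f)] <- res
    }
  }
  attr(aucs, "fold_seeds") <- seeds[seq(1L, by = k + 1L, length.out = repeats)]
  aucs
}

#' Evaluate a roster of classifiers under a common CV scheme
#'
#' All classifiers see the same fold partitions (same seed), making the mean
#' AUCs directly comparable.
#'
#' @inheritParams repeated_cv_auc
#' @param keys Roster keys to evaluate (default: the full roster).
#' @return Named list of AUC vectors, one per key.
#' @export
evaluate_classifiers <- function(table, keys = classifier_roster()$key,
                                 features = NULL, k = 8, repeats = 3,
                                 seed = 1L) {
  stats::setNames(lapply(keys, function(key)
    repeated_cv_auc(table, key, features, k, repeats, seed)), keys)
}

#' Rank classifiers by mean cross-validated AUC
#'
#' Mean and sample SD over the held-out AUCs per classifier; the winner has
#' the highest mean (ties: lower SD, then roster order). All classifiers
#' failing on every fold is an error.
#'
#' @param auc_list Named list of AUC vectors from [evaluate_classifiers()].
#' @return Object of class `model_selection_report` with the ranking table
#'   (reported to two decimals in the print method), the raw AUCs and the
#'   winner key.
#' @export
summarize_and_rank <- function(auc_list) {
  stopifnot(length(auc_list) >= 1L)
  roster <- classifier_roster()$key
  keys <- names(auc_list)
  mean_auc <- vapply(auc_list, function(a) mean(a, na.rm = TRUE), numeric(1))
  sd_auc <- vapply(auc_list, function(a) stats::sd(a[!is.na(a)]), numeric(1))
  n_eval <- vapply(auc_list, function(a) sum(!is.na(a)), numeric(1))
  if (all(n_eval == 0)) stop("every classifier failed", call. = FALSE)
  mean_auc[n_eval == 0] <- NA_real_
  ord <- order(-mean_auc, sd_auc, match(keys, roster), na.last = TRUE)
  ranking <- data.frame(model = keys, mean_auc = mean_auc, sd_auc = sd_auc,
                        n_evals = as.integer(n_eval),
                        row.names = NULL)[ord, ]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, auc = auc_list,
                 winner = ranking$model[1]),
            class = "model_selection_report")
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat("<model_selection_report>\n")
  r <- x$ranking
  cat(sprintf("%-8s %-9s %s\n", "Model", "Mean AUC", "SD (AUC)"))
  for (i in seq_len(nrow(r)))
    cat(sprintf("%-8s %-9s %s\n", r$model[i],
                sprintf("%.2f", r$mean_auc[i]), sprintf("%.2f", r$sd_auc[i])))
  cat("winner:", x$winner, "\n")
  invisible(x)
}

#' Fit the winning classifier on the full dataset
#'
#' @param table A complete [feature_table()].
#' @param key Roster key of the winner.
#' @param features Optional character subset of feature ids.
#' @param seed Integer seed.
#' @return Object of class `radiopcr_model`: the fitted backend, the
#'   training-set class-1 probability scores, the feature names and the seed.
#' @export
fit_final <- function(table, key, features = NULL, seed = 1L) {
  d <- prepare_xy(table, features)
  if (length(unique(d$y)) < 2L)
    stop("cannot fit on a single-class dataset", call. = FALSE)
  m <- fit_classifier(key, d$x, d$y, seed)
  scores <- stats::setNames(as.numeric(m$predict(d$x)), table$case_ids)
  structure(list(key = key, model = m, scores = scores,
                 feature_names = d$feature_names, seed = as.integer(seed)),
            class = "radiopcr_model")
}

#' @export
predict.radiopcr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  colnames(newdata) <- sprintf("V%03d", seq_len(ncol(newdata)))
  as.numeric(object$model$predict(newdata))
}
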