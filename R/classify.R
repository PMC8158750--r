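# Classifier training and evaluation: class balancing by random
# undersampling, systematic 10-fold (intra-subject) and leave-one-subject-
# out (inter-subject) paradigms, and the six confusion-matrix metrics.

#' Random undersampling to balance classes
#'
#' Keeps every row of the minority class and draws, without replacement, an
#' equally sized seeded subsample of each other class. Applied to training
#' folds only; test folds are never rebalanced.
#'
#' @param X feature matrix (matrix or data.frame).
#' @param y class labels (one per row), at least two classes present.
#' @param seed integer seed.
#' @return list with `X`, `y` and the retained row `indices`.
#' @export
undersample <- function(X, y, seed = 1L) {
  tab <- table(y)
  if (length(tab) < 2L) stop_invalid("undersample() needs two classes")
  n_min <- min(tab)
  idx <- with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      rows <- which(y == cl)
      if (length(rows) > n_min) sort(sample(rows, n_min)) else rows
    }), use.names = FALSE)
  })
  idx <- sort(idx)
  list(X = X[idx, , drop = FALSE], y = y[idx], indices = idx)
}

#' Systematic-sampling k-fold splits
#'
#' After a seeded random ordering within each class, the item at position i
#' is assigned to fold `((i - 1) mod k) + 1` (systematic sampling), so
#' folds are disjoint, exhaustive, and class proportions match the global
#' proportions within one item per class.
#'
#' @param labels class labels, length n >= k.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return list of `k` integer vectors of test indices.
#' @export
kfold_splits <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (n < k) stop_invalid("need at least k observations")
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in unique(labels)) {
      rows <- sample(which(labels == cl))
      for (i in seq_along(rows)) {
        f <- (i - 1L) %% k + 1L
        folds[[f]] <- c(folds[[f]], rows[i])
      }
    }
  })
  lapply(folds, sort)
}

#' Leave-one-subject-out splits
#'
#' One fold per distinct subject: the fold's test set is that subject's
#' rows, training is everyone else, so train and test never share a
#' subject.
#'
#' @param subject_ids subject identifier per row; >= 2 distinct subjects.
#' @return named list of integer test-index vectors, one per subject.
#' @export
loso_splits <- function(subject_ids) {
  subs <- unique(subject_ids)
  if (length(subs) < 2L) stop_invalid("LOSO needs at least 2 subjects")
  setNames(lapply(subs, function(s) which(subject_ids == s)), subs)
}

#' Fit a classifier and predict hard labels
#'
#' Standardizes features using training-fold statistics only, fits the
#' requested model on the (balanced) training set and returns hard VF/NVF
#' labels for the test rows. `"lr"` is logistic regression (IRLS via
#' `stats::glm.fit`); `"rf"` is a bagged random forest of `ntree` Gini
#' CART trees with `mtry` random features per node.
#'
#' @param train_x,train_y training features (rows) and labels; both classes
#'   must be present.
#' @param test_x test features.
#' @param model `"rf"` or `"lr"`.
#' @param seed integer seed (bootstrap and feature sampling).
#' @param positive label of the positive class (default `"VF"`).
#' @param ntree,mtry,min_node,max_depth random-forest hyperparameters;
#'   `mtry` defaults to `floor(sqrt(p))`.
#' @return character vector of predicted labels (`positive` / `"NVF"`).
#' @export
fit_predict <- function(train_x, train_y, test_x, model = c("rf", "lr"),
                        seed = 1L, positive = "VF", ntree = 100L,
                        mtry = NULL, min_node = 1L, max_depth = 25L) {
  model <- match.arg(model)
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  y01 <- as.integer(train_y == positive)
  if (length(unique(y01)) < 2L) {
    stop_invalid("training set must contain both classes")
  }
  mu <- colMeans(train_x)
  sds <- apply(train_x, 2, sd)
  sds[sds == 0] <- 1
  Ztr <- sweep(sweep(train_x, 2, mu), 2, sds, `/`)
  Zte <- sweep(sweep(test_x, 2, mu), 2, sds, `/`)
  prob <- if (model == "lr") {
    fit <- suppressWarnings(
      glm.fit(cbind(1, Ztr), y01, family = binomial()))
    beta <- ifelse(is.na(coef(fit)), 0, coef(fit))
    as.numeric(stats::plogis(cbind(1, Zte) %*% beta))
  } else {
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(Ztr))))
    with_seed(seed, {
      n <- nrow(Ztr)
      trees <- lapply(seq_len(ntree), function(b) {
        grow_tree_cpp(Ztr, y01, sample.int(n, n, replace = TRUE) - 1L,
                      as.integer(mtry), as.integer(min_node),
                      as.integer(max_depth))
      })
      predict_forest_cpp(trees, Zte)
    })
  }
  ifelse(prob >= 0.5, positive, "NVF")
}

#' Confusion counts with VF as the positive class
#'
#' @param truth,predicted label vectors of equal length.
#' @param positive positive-class label (default `"VF"`).
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(truth, predicted, positive = "VF") {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' The six evaluation metrics from confusion counts
#'
#' Sensitivity, specificity, precision, F1, balanced accuracy and the
#' Matthews correlation coefficient. Any metric whose denominator is zero
#' is defined as 0 (logged via message).
#'
#' @param counts named vector with `TP`, `FP`, `FN`, `TN` (total > 0).
#' @return named numeric vector `c(SEN, SPE, PRE, F1, bACC, MCC)`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]]); tn <- as.numeric(counts[["TN"]])
  if (tp + fp + fn + tn <= 0) stop_invalid("empty confusion matrix")
  safe <- function(num, den, what) {
    if (den == 0) {
      message("metric ", what, ": zero denominator, defined as 0")
      return(0)
    }
    num / den
  }
  sen <- safe(tp, tp + fn, "SEN")
  spe <- safe(tn, tn + fp, "SPE")
  pre <- safe(tp, tp + fp, "PRE")
  f1 <- safe(2 * sen * pre, sen + pre, "F1")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "MCC")
  c(SEN = sen, SPE = spe, PRE = pre, F1 = f1, bACC = (sen + spe) / 2,
    MCC = mcc)
}

#' Evaluate a classifier on a feature matrix
#'
#' Runs the chosen evaluation paradigm `repeats` times with derived seeds.
#' Each repeat regenerates the splits, undersamples every training fold,
#' fits, predicts the untouched test fold, pools the confusion counts over
#' folds, and computes the six metrics; the report aggregates their mean
#' and SD over repeats.
#'
#' @param X feature matrix data.frame with `subject_id` and `label`
#'   columns (labels `VF` / `SR` / `MA`; non-VF labels are the negative
#'   class).
#' @param feature_idx integer indices into the 22-feature order (default
#'   the fixed 13-feature subset).
#' @param model `"rf"` or `"lr"`.
#' @param paradigm `"kfold10"` or `"loso"`.
#' @param repeats number of repetitions (default 10).
#' @param seed master seed.
#' @param k folds for the k-fold paradigm.
#' @param ... passed to [fit_predict()].
#' @return object of class `bcg_report`: per-repeat metrics, pooled
#'   confusion counts, and `mean` / `sd` aggregates.
#' @export
evaluate <- function(X, feature_idx = select_features("paper"),
                     model = c("rf", "lr"),
                     paradigm = c("kfold10", "loso"), repeats = 10L,
                     seed = 1L, k = 10L, ...) {
  model <- match.arg(model)
  paradigm <- match.arg(paradigm)
  if (repeats < 1L) stop_invalid("repeats must be >= 1")
  feats <- FEATURE_NAMES[feature_idx]
  M <- as.matrix(X[, feats, drop = FALSE])
  y <- ifelse(X$label == "VF", "VF", "NVF")
  per_repeat <- matrix(NA_real_, nrow = repeats, ncol = 6L,
                       dimnames = list(NULL, c("SEN", "SPE", "PRE", "F1",
                                               "bACC", "MCC")))
  counts_total <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (r in seq_len(repeats)) {
    rs <- derive_seed(seed, r)
    folds <- if (paradigm == "kfold10") {
      kfold_splits(y, k = k, seed = rs)
    } else {
      loso_splits(X$subject_id)
    }
    counts <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
    for (fi in seq_along(folds)) {
      test <- folds[[fi]]
      train <- setdiff(seq_along(y), test)
      if (length(unique(y[train])) < 2L || length(test) == 0L) next
      bal <- undersample(M[train, , drop = FALSE], y[train],
                         seed = derive_seed(rs, fi))
      pred <- fit_predict(bal$X, bal$y, M[test, , drop = FALSE],
                          model = model, seed = derive_seed(rs, 1000L + fi),
                          ...)
      counts <- counts + confusion_counts(y[test], pred)
    }
    per_repeat[r, ] <- classification_metrics(counts)
    counts_total <- counts_total + counts
  }
  agg_sd <- apply(per_repeat, 2, sd)
  if (repeats == 1L) agg_sd[] <- 0
  structure(list(paradigm = paradigm, model = model, repeats = repeats,
                 feature_idx = feature_idx, per_repeat = per_repeat,
                 counts = counts_total,
                 mean = colMeans(per_repeat), sd = agg_sd),
            class = "bcg_report")
}

#' @export
print.bcg_report <- function(x, ...) {
  cat(sprintf("<bcg_report> %s / %s, %d repeat(s), %d feature(s)\n",
              toupper(x$model), x$paradigm, x$repeats,
              length(x$feature_idx)))
  for (m in names(x$mean)) {
    cat(sprintf("  %-4s %.3f (%.3f)\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}
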