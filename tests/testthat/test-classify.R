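test_that("undersampling balances classes and keeps the minority intact", {
  withr::with_seed(37, {
    X <- matrix(rnorm(120 * 2), 120, 2)
    y <- rep(c("NVF", "VF"), c(100, 20))
    bal <- undersample(X, y, seed = 1)
    expect_identical(unname(table(bal$y)["VF"]), 20L)
    expect_identical(unname(table(bal$y)["NVF"]), 20L)
    expect_true(all(which(y == "VF") %in% bal$indices))
    # already balanced -> unchanged
    bal2 <- undersample(X[81:120, ], y[81:120], seed = 1)
    expect_identical(bal2$indices, 1:40)
    expect_error(undersample(X, rep("VF", 120)),
                 class = "bcgvf_invalid_argument")
    # seeded: reproducible
    expect_identical(undersample(X, y, seed = 7)$indices,
                     undersample(X, y, seed = 7)$indices)
  })
})

test_that("systematic k-fold splits are disjoint, exhaustive, stratified", {
  y <- rep(c("NVF", "VF"), c(120, 20))   # 6:1
  folds <- kfold_splits(y, k = 10, seed = 3)
  expect_length(folds, 10L)
  expect_identical(sort(unlist(folds)), seq_along(y))
  expect_identical(unique(lengths(folds)), 14L)
  for (f in folds) {
    expect_identical(sum(y[f] == "VF"), 2L)   # 20/10 exactly
  }
  # uneven case: within one item of the global proportion
  y2 <- rep(c("A", "B"), c(57, 43))
  for (f in kfold_splits(y2, k = 10, seed = 1)) {
    expect_lte(abs(sum(y2[f] == "A") - 5.7), 1)
  }
  expect_error(kfold_splits(y[1:5], k = 10),
               class = "bcgvf_invalid_argument")
})

test_that("LOSO folds never share subjects between train and test", {
  subs <- rep(sprintf("S%02d", 1:23), each = 4)
  folds <- loso_splits(subs)
  expect_length(folds, 23L)
  expect_identical(sort(unlist(folds, use.names = FALSE)), seq_along(subs))
  for (f in folds) {
    expect_length(intersect(subs[f], subs[-f]), 0L)
  }
  expect_error(loso_splits(rep("S01", 10)), class = "bcgvf_invalid_argument")
})

test_that("fit_predict separates linearly separable data", {
  withr::with_seed(41, {
    n <- 60L
    X <- rbind(matrix(rnorm(n, -3), n / 2, 2), matrix(rnorm(n, 3), n / 2, 2))
    y <- rep(c("VF", "NVF"), each = n / 2)
    Xt <- rbind(matrix(rnorm(20, -3), 10, 2), matrix(rnorm(20, 3), 10, 2))
    yt <- rep(c("VF", "NVF"), each = 10)
    expect_identical(fit_predict(X, y, Xt, model = "lr"), yt)
    expect_identical(fit_predict(X, y, Xt, model = "rf", seed = 2), yt)
    # RF is seeded-reproducible
    expect_identical(fit_predict(X, y, Xt, model = "rf", seed = 9),
                     fit_predict(X, y, Xt, model = "rf", seed = 9))
    expect_error(fit_predict(X, rep("VF", n), Xt),
                 class = "bcgvf_invalid_argument")
  })
})

test_that("label-permuted training yields chance-level balanced accuracy", {
  withr::with_seed(43, {
    n <- 200L
    X <- matrix(rnorm(n * 4), n, 4)
    baccs <- replicate(20, {
      y <- sample(rep(c("VF", "NVF"), each = n / 2))
      tr <- sample(n, n / 2)
      pred <- fit_predict(X[tr, ], y[tr], X[-tr, ], model = "rf",
                          seed = sample.int(1e6, 1), ntree = 30)
      classification_metrics(confusion_counts(y[-tr], pred))[["bACC"]]
    })
    expect_lt(abs(mean(baccs) - 0.5), 0.1)
  })
})

test_that("metrics match hand-evaluated formulas and the random oracle", {
  m <- classification_metrics(c(TP = 50, FP = 0, FN = 0, TN = 50))
  expect_equal(unname(m), rep(1, 6))

  m2 <- classification_metrics(c(TP = 90, FP = 20, FN = 10, TN = 80))
  expect_equal(m2[["SEN"]], 0.9)
  expect_equal(m2[["SPE"]], 0.8)
  expect_equal(m2[["PRE"]], 0.8182, tolerance = 1e-4)
  expect_equal(m2[["F1"]], 0.8571, tolerance = 1e-4)
  expect_equal(m2[["bACC"]], 0.85)
  expect_equal(m2[["MCC"]], 0.7035, tolerance = 1e-4)

  # degenerate: everything predicted positive
  suppressMessages({
    m3 <- classification_metrics(c(TP = 10, FP = 30, FN = 0, TN = 0))
  })
  expect_equal(m3[["SEN"]], 1)
  expect_equal(m3[["SPE"]], 0)
  expect_equal(m3[["MCC"]], 0)

  withr::with_seed(47, {
    for (i in 1:1000) {
      cc <- stats::setNames(as.numeric(sample(0:40, 4, replace = TRUE)),
                            c("TP", "FP", "FN", "TN"))
      if (sum(cc) == 0) cc["TP"] <- 1
      got <- suppressMessages(classification_metrics(cc))
      tp <- cc[["TP"]]; fp <- cc[["FP"]]; fn <- cc[["FN"]]; tn <- cc[["TN"]]
      sen <- if (tp + fn > 0) tp / (tp + fn) else 0
      spe <- if (tn + fp > 0) tn / (tn + fp) else 0
      pre <- if (tp + fp > 0) tp / (tp + fp) else 0
      f1 <- if (sen + pre > 0) 2 * sen * pre / (sen + pre) else 0
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
      expect_equal(unname(got),
                   c(sen, spe, pre, f1, (sen + spe) / 2, mcc),
                   tolerance = 1e-12)
      expect_equal(got[["bACC"]], (got[["SEN"]] + got[["SPE"]]) / 2)
    }
  })
})

test_that("evaluate produces a seeded, well-formed report", {
  X <- fixture_features()
  rep1 <- evaluate(X, model = "rf", paradigm = "kfold10", repeats = 2,
                   seed = 5, ntree = 30)
  rep2 <- evaluate(X, model = "rf", paradigm = "kfold10", repeats = 2,
                   seed = 5, ntree = 30)
  expect_identical(rep1$per_repeat, rep2$per_repeat)
  expect_identical(names(rep1$mean), c("SEN", "SPE", "PRE", "F1", "bACC",
                                       "MCC"))
  expect_equal(rep1$mean[["bACC"]],
               (rep1$mean[["SEN"]] + rep1$mean[["SPE"]]) / 2,
               tolerance = 1e-12)
  expect_identical(sum(rep1$counts), 2L * nrow(X))  # tests never resampled

  one <- evaluate(X, model = "lr", paradigm = "loso", repeats = 1, seed = 2)
  expect_true(all(one$sd == 0))
  expect_error(evaluate(X, repeats = 0), class = "bcgvf_invalid_argument")
})
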