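test_that("Mann-Whitney p matches exact enumeration on small samples", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6)), 0.1)
  withr::with_seed(19, {
    for (i in 1:5) {
      a <- rnorm(4); b <- rnorm(5)
      expect_equal(mann_whitney(a, b), mw_enum_oracle(a, b),
                   tolerance = 1e-12)
      expect_equal(mann_whitney(a, b), mann_whitney(b, a))
    }
  })
  x <- c(1, 2, 3, 4)
  expect_equal(mann_whitney(x, x), 1)
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "bcgvf_invalid_argument")
})

test_that("BY adjustment matches the step-down oracle and is unclipped", {
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3))
  withr::with_seed(23, {
    for (m in c(1L, 3L, 5L, 8L)) {
      p <- runif(m)
      expect_equal(by_adjust(p), by_oracle(p), tolerance = 1e-12)
    }
  })
  # adjusted >= raw, and may exceed 1
  p <- c(0.9, 0.95, 0.2)
  adj <- by_adjust(p)
  expect_true(all(adj >= p))
  expect_gt(max(adj), 1)
  expect_error(by_adjust(c(0.5, 1.2)), class = "bcgvf_invalid_argument")
})

test_that("BY reproduces the published column adjustments", {
  # VF-MA relevance column: 16 features below 0.001 plus six printed raw
  # p-values; the printed adjusted values follow from the column-wise BY
  # with m = 22
  vf_ma <- c(rep(5e-4, 16), 0.0051, 0.0081, 0.1206, 0.1519, 0.2470, 0.7387)
  adj <- by_adjust(vf_ma)[17:22]
  published <- c(0.0241, 0.0367, 0.5154, 0.6168, 0.9551, 2.7266)
  # within 5e-4 absolute of the printed table (raw inputs are 4-decimal
  # roundings of unrounded values)
  expect_true(all(abs(adj - published) < 5e-4))
  expect_equal(round(adj[3], 4), 0.5154)           # exact at 4 decimals

  sr_ma <- c(rep(5e-4, 20), 0.1460, 0.8447)
  adj2 <- by_adjust(sr_ma)[21:22]
  expect_equal(round(adj2[1], 4), 0.5645)
  expect_lt(abs(adj2[2] - 3.1175), 5e-4)
})

test_that("feature correlation handles exact and degenerate columns", {
  withr::with_seed(29, {
    base <- rnorm(100)
    M <- cbind(a = base, b = base, c = -base, d = rnorm(100))
    R <- feature_correlation(M, colnames(M))
    expect_equal(R["a", "b"], 1)
    expect_equal(R["a", "c"], -1)
    expect_true(isSymmetric(R))
    expect_equal(unname(diag(R)), rep(1, 4))

    # independent noise decorrelates
    N <- matrix(rnorm(1000 * 3), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
    Rn <- feature_correlation(N, colnames(N))
    expect_lt(max(abs(Rn[upper.tri(Rn)])), 0.1)

    # zero-variance column: correlations zeroed, logged
    Z <- cbind(u = rnorm(50), v = rep(1, 50))
    expect_message(Rz <- feature_correlation(Z, colnames(Z)), "zero-variance")
    expect_equal(Rz["u", "v"], 0)
    expect_equal(Rz["v", "v"], 1)
  })
})

test_that("feature clustering uses sqrt(2(1-r)) average linkage", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.95
  dimnames(R) <- list(letters[1:3], letters[1:3])
  cl <- cluster_features(R, cut_height = 1)
  expect_identical(length(unique(cl$clusters)), 2L)
  expect_identical(cl$clusters[["a"]], cl$clusters[["b"]])
  expect_equal(cl$dist["a", "b"], sqrt(2 * 0.05))
  expect_equal(cl$dist["a", "c"], sqrt(2))
  expect_true(all(diag(cl$dist) == 0))

  # invariance to feature ordering (up to label permutation)
  perm <- c(3, 1, 2)
  cl2 <- cluster_features(R[perm, perm], cut_height = 1)
  for (i in letters[1:3]) for (j in letters[1:3]) {
    expect_identical(cl$clusters[[i]] == cl$clusters[[j]],
                     cl2$clusters[[i]] == cl2$clusters[[j]])
  }
})

test_that("paper-mode selection returns the fixed 13-feature subset", {
  idx <- select_features("paper")
  expect_identical(idx, c(1L, 2L, 3L, 4L, 7L, 10L, 11L, 14L, 16L, 17L,
                          19L, 21L, 22L))
  expect_length(idx, 13L)
  expect_false(13L %in% idx)   # PI_mean: not significant for VF vs SR
})

test_that("data-driven selection keeps a lone MA separator", {
  # constructed matrix: feature 22 (RM) alone separates MA; features 1-2
  # separate VF from SR; the rest is noise
  withr::with_seed(31, {
    n <- 60L
    lab <- rep(c("VF", "SR", "MA"), each = n / 3)
    M <- matrix(rnorm(n * 22), n, 22, dimnames = list(NULL, bcgvf:::FEATURE_NAMES))
    M[lab == "VF", 1] <- M[lab == "VF", 1] - 4
    M[lab == "VF", 2] <- M[lab == "VF", 2] + 4
    M[lab == "MA", 22] <- M[lab == "MA", 22] + 8
    X <- cbind(data.frame(subject_id = "s", label = lab, t0 = 0L),
               as.data.frame(M))
    idx <- select_features("data_driven", X)
    expect_true(22L %in% idx)
    expect_true(1L %in% idx || 2L %in% idx)
  })
  expect_error(select_features("data_driven"),
               class = "bcgvf_invalid_argument")
})

test_that("relevance table separates classes on real synthetic features", {
  X <- fixture_features()
  rel <- relevance_table(X)
  expect_true(all(rel$p_adj >= rel$p))
  expect_identical(nrow(rel), 66L)   # 22 features x 3 pairs
  sc1 <- rel[rel$feature == "SC_mean" & rel$pair == "VF-SR", ]
  expect_lt(sc1$p_adj, 0.05)
  rm22 <- rel[rel$feature == "RM" & rel$pair == "VF-MA", ]
  expect_lt(rm22$p_adj, 0.05)
})
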