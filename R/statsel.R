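# Feature relevance testing (Mann-Whitney U + Benjamini-Yekutieli FDR
# control), redundancy analysis (correlation + average-linkage clustering)
# and feature-subset selection.

PAPER_FEATURE_SUBSET <- c(1L, 2L, 3L, 4L, 7L, 10L, 11L, 14L, 16L, 17L,
                          19L, 21L, 22L)

#' Mann-Whitney U test p-value
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of equal location.
#' Uses the exact null distribution for small untied samples
#' (m + n <= 20), and the normal approximation with tie correction
#' otherwise.
#'
#' @param a,b numeric samples, each non-empty.
#' @return two-sided p-value.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop_invalid("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 20L
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up BY adjustment valid under arbitrary dependence:
#' \eqn{q_{(i)} = m\, c(m)\, p_{(i)} / i} with
#' \eqn{c(m) = \sum_{k=1}^m 1/k}, followed by the step-down minimum
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} q_{(j)}}. Adjusted values are
#' deliberately **not** clipped at 1 (they may exceed 1), matching how the
#' adjustment is reported alongside raw p-values.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return adjusted values, in input order.
#' @export
by_adjust <- function(pvals) {
  if (!length(pvals)) stop_invalid("pvals must be non-empty")
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals))) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  cm <- sum(1 / seq_len(m))
  o <- order(pvals)
  q <- m * cm * pvals[o] / seq_len(m)
  adj <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Relevance table for a feature matrix
#'
#' For each feature and each class pair (VF-SR, VF-MA, SR-MA), the raw
#' Mann-Whitney p-value and its BY-adjusted value (adjusted per class-pair
#' column, m = number of features).
#'
#' @param X feature matrix data.frame (columns `label` + features).
#' @param features feature column names (default the 22 standard names).
#' @return data.frame with columns `feature`, `pair`, `p`, `p_adj`.
#' @export
relevance_table <- function(X, features = FEATURE_NAMES) {
  pairs <- list(c("VF", "SR"), c("VF", "MA"), c("SR", "MA"))
  pairs <- Filter(function(p) all(p %in% X$label), pairs)
  if (!length(pairs)) stop_invalid("need at least two classes present")
  out <- do.call(rbind, lapply(pairs, function(pr) {
    p <- vapply(features, function(f) {
      mann_whitney(X[[f]][X$label == pr[1]], X[[f]][X$label == pr[2]])
    }, numeric(1))
    data.frame(feature = features, pair = paste(pr, collapse = "-"),
               p = p, p_adj = by_adjust(p), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Feature-feature Pearson correlation matrix
#'
#' Features are z-scored first; a zero-variance feature gets zero
#' correlations (and unit diagonal) with a message.
#'
#' @param X feature matrix data.frame or numeric matrix of feature columns.
#' @param features feature column names when `X` is a data.frame.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
feature_correlation <- function(X, features = FEATURE_NAMES) {
  M <- if (is.data.frame(X)) as.matrix(X[, features, drop = FALSE]) else X
  if (nrow(M) < 3L) stop_invalid("need at least 3 observations")
  sds <- apply(M, 2, sd)
  flat <- sds == 0
  if (any(flat)) {
    message("zero-variance feature(s): ",
            paste(colnames(M)[flat], collapse = ", "))
  }
  Z <- scale(M[, , drop = FALSE])
  R <- suppressWarnings(cor(Z))
  R[is.na(R)] <- 0
  diag(R) <- 1
  R
}

#' Hierarchical clustering of features by correlation distance
#'
#' Converts the correlation matrix to the Euclidean distance between
#' z-scored features, \eqn{d_{ij} = \sqrt{2 (1 - r_{ij})}} (option
#' `"one_minus_abs"` uses \eqn{1 - |r|}), and agglomerates by average
#' linkage. Cluster labels are produced at `cut_height`.
#'
#' @param R correlation matrix from [feature_correlation()].
#' @param cut_height dendrogram cut height (default 1, i.e. r = 0.5 under
#'   the default distance).
#' @param distance `"sqrt_two_one_minus_r"` (default) or
#'   `"one_minus_abs"`.
#' @return list with `tree` (hclust), `clusters` (named integer vector)
#'   and `dist` (the distance matrix).
#' @export
cluster_features <- function(R, cut_height = 1,
                             distance = c("sqrt_two_one_minus_r",
                                          "one_minus_abs")) {
  distance <- match.arg(distance)
  D <- switch(distance,
              sqrt_two_one_minus_r = sqrt(pmax(2 * (1 - R), 0)),
              one_minus_abs = 1 - abs(R))
  diag(D) <- 0
  tree <- hclust(as.dist(D), method = "average")
  list(tree = tree, clusters = cutree(tree, h = cut_height), dist = D)
}

#' Select the classifier feature subset
#'
#' `mode = "paper"` returns the fixed 13-feature subset
#' (1, 2, 3, 4, 7, 10, 11, 14, 16, 17, 19, 21, 22 in the standard feature
#' order). `mode = "data_driven"` re-runs the selection logic on a supplied
#' feature matrix: features whose BY-adjusted p-value for both VF contrasts
#' (VF-SR and VF-MA) exceeds `fdr` are dropped unless they are the only
#' usable separator in their cluster, and within each correlation cluster
#' only the features with the smallest worst-case adjusted p are retained
#' (up to `per_cluster`).
#'
#' @param mode `"paper"` or `"data_driven"`.
#' @param X feature matrix data.frame (required for `data_driven`).
#' @param fdr FDR level (default 0.05).
#' @param cut_height clustering cut height (default 1).
#' @param per_cluster maximum representatives kept per cluster (default 2).
#' @return sorted integer indices into the 22-feature order.
#' @export
select_features <- function(mode = c("paper", "data_driven"), X = NULL,
                            fdr = 0.05, cut_height = 1, per_cluster = 2L) {
  mode <- match.arg(mode)
  if (mode == "paper") return(PAPER_FEATURE_SUBSET)
  if (is.null(X)) stop_invalid("data_driven selection needs a feature matrix")
  rel <- relevance_table(X)
  vf_rel <- rel[rel$pair %in% c("VF-SR", "VF-MA"), ]
  # worst-case adjusted p over the VF contrasts a feature must serve
  worst <- tapply(vf_rel$p_adj, vf_rel$feature, max)[FEATURE_NAMES]
  best <- tapply(vf_rel$p_adj, vf_rel$feature, min)[FEATURE_NAMES]
  cl <- cluster_features(feature_correlation(X), cut_height)$clusters
  keep <- logical(length(FEATURE_NAMES))
  for (g in unique(cl)) {
    members <- which(cl == g)
    sig <- members[best[members] <= fdr]
    if (!length(sig)) next
    ord <- sig[order(worst[sig], best[sig])]
    keep[ord[seq_len(min(per_cluster, length(ord)))]] <- TRUE
  }
  sort(which(keep))
}
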