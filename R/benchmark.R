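## Evaluation harness: agglomerative clustering sweeps scored by the
## variance ratio criterion and adjusted mutual information, and
## K-nearest-neighbor classification with stratified cross-validation
## scored by AUC / recall / precision / F1.

#' Variance Ratio Criterion (Calinski-Harabasz score)
#'
#' Between-cluster over within-cluster dispersion with the standard
#' `(n - c) / (c - 1)` normalization.
#'
#' @param x numeric coordinate matrix (observations in rows).
#' @param clusters integer/factor cluster assignment.
#' @export
varianceRatioCriterion <- function(x, clusters) {
  x <- as.matrix(x)
  cl <- as.integer(factor(clusters))
  n <- nrow(x); k <- max(cl)
  if (k < 2L || k >= n) .stopf("need 2 <= clusters < n")
  grand <- colMeans(x)
  between <- 0; within <- 0
  for (g in seq_len(k)) {
    xg <- x[cl == g, , drop = FALSE]
    cg <- colMeans(xg)
    between <- between + nrow(xg) * sum((cg - grand)^2)
    within <- within + sum(sweep(xg, 2L, cg)^2)
  }
  (between / (k - 1)) / (within / (n - k))
}

#' Adjusted Mutual Information
#'
#' Chance-corrected agreement between two partitions:
#' `(MI - E[MI]) / (mean(H(U), H(V)) - E[MI])` with the expected mutual
#' information under the permutation (hypergeometric) model. Invariant
#' under cluster relabeling; 1 only at perfect agreement, ~0 for
#' independent partitions.
#'
#' @param a,b two assignment vectors of equal length.
#' @export
adjustedMutualInformation <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  ct <- table(a, b)
  ai <- rowSums(ct); bj <- colSums(ct)
  Hu <- -sum((ai / n)[ai > 0] * log((ai / n)[ai > 0]))
  Hv <- -sum((bj / n)[bj > 0] * log((bj / n)[bj > 0]))
  if (Hu == 0 && Hv == 0) return(1)        # both partitions trivial
  nz <- which(ct > 0, arr.ind = TRUE)
  nij <- ct[nz]
  mi <- sum((nij / n) * log(n * nij / (ai[nz[, 1]] * bj[nz[, 2]])))
  ## expected MI under random permutations of the labels
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1L, ai[i] + bj[j] - n); hi <- min(ai[i], bj[j])
      if (hi < lo) next
      v <- lo:hi
      logp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
        lgamma(n - ai[i] + 1) + lgamma(n - bj[j] + 1) -
        lgamma(n + 1) - lgamma(v + 1) - lgamma(ai[i] - v + 1) -
        lgamma(bj[j] - v + 1) - lgamma(n - ai[i] - bj[j] + v + 1)
      emi <- emi + sum((v / n) * log(n * v / (ai[i] * bj[j])) * exp(logp))
    }
  }
  denom <- (Hu + Hv) / 2 - emi
  if (denom == 0) return(0)
  (mi - emi) / denom
}

#' Agglomerative clustering sweep
#'
#' Average-linkage agglomerative clustering across a grid of cluster
#' counts; each solution is scored by the variance ratio criterion and by
#' adjusted mutual information against ground-truth labels. When the input
#' is a precomputed distance matrix, VRC (which needs coordinates) is
#' computed in a classical multidimensional-scaling embedding of dimension
#' `min(n - 1, 50)`.
#'
#' @param x feature matrix, or a symmetric distance matrix with
#'   `distance = TRUE`.
#' @param labels ground-truth labels for AMI.
#' @param counts cluster counts (default an even grid over 5..100).
#' @param distance is `x` a precomputed distance matrix?
#' @return data.frame (n_clusters, vrc, ami); cluster assignments attached
#'   as attribute `"assignments"`.
#' @export
clusterSweep <- function(x, labels, counts = seq(5L, 100L, by = 5L),
                         distance = FALSE) {
  counts <- sort(unique(as.integer(counts)))
  n <- nrow(x)
  d <- if (distance) stats::as.dist(x) else stats::dist(x)
  hc <- stats::hclust(d, method = "average")
  coords <- if (distance) {
    suppressWarnings(stats::cmdscale(d, k = min(n - 1L, 50L)))
  } else as.matrix(x)
  ok <- counts < n
  if (any(!ok)) .warnf("skipping cluster counts >= n (%d)", n)
  counts <- counts[ok]
  assignments <- list()
  res <- lapply(counts, function(cc) {
    cl <- stats::cutree(hc, k = cc)
    assignments[[as.character(cc)]] <<- cl
    data.frame(n_clusters = cc,
               vrc = varianceRatioCriterion(coords, cl),
               ami = adjustedMutualInformation(cl, labels))
  })
  out <- do.call(rbind, res)
  attr(out, "assignments") <- assignments
  out
}

#' Per-class classification metrics
#'
#' AUC by the one-vs-rest rank statistic (midrank ties, so a constant score
#' gives 0.5); recall, precision and F1 from argmax predictions. Classes
#' absent from the truth get `NA` AUC rather than a number.
#'
#' @param scores matrix `n x K` of per-class scores, colnames = classes.
#' @param labels true class per row.
#' @return data.frame with one row per class plus a `"macro"` row
#'   (unweighted means over classes present in the truth).
#' @export
classificationMetrics <- function(scores, labels) {
  classes <- colnames(scores)
  stopifnot(!is.null(classes))
  labels <- as.character(labels)
  pred <- classes[max.col(scores, ties.method = "first")]
  rows <- lapply(classes, function(cl) {
    pos <- labels == cl
    auc <- if (any(pos) && any(!pos)) .aucRank(scores[, cl], pos) else NA_real_
    tp <- sum(pred == cl & pos); fp <- sum(pred == cl & !pos)
    fn <- sum(pred != cl & pos)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (any(pos)) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(class = cl, auc = auc, recall = recall,
               precision = precision, f1 = f1)
  })
  out <- do.call(rbind, rows)
  present <- out$class %in% labels
  macro <- data.frame(class = "macro",
                      auc = mean(out$auc[present], na.rm = TRUE),
                      recall = mean(out$recall[present], na.rm = TRUE),
                      precision = mean(out$precision[present]),
                      f1 = mean(out$f1[present]))
  rbind(out, macro)
}

#' K-nearest-neighbor classification with stratified cross-validation
#'
#' Instance-based classification on a precomputed distance matrix. Folds
#' are stratified by class; a test clone's class scores are the
#' neighbor-vote fractions among its k nearest training clones (a clone is
#' never its own neighbor; distance ties at the k-boundary break by clone
#' index). k values exceeding the training-fold size are capped with a
#' warning.
#'
#' @param D symmetric distance matrix.
#' @param labels class per clone; every class needs >= `nFolds` members.
#' @param kValues neighbor counts to sweep (default an even grid 1..500,
#'   capped at the data size).
#' @param nFolds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return long data.frame (k, fold, class, metric, value) including
#'   `"macro"` rows.
#' @export
knnClassifyCV <- function(D, labels, kValues = NULL, nFolds = 5L, seed = 1L) {
  n <- nrow(D)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < nFolds))
    .stopf("class %s has fewer members than folds", names(tab)[which.min(tab)])
  if (is.null(kValues))
    kValues <- unique(pmin(round(seq(1, 500, length.out = 25)), n - 1L))
  classes <- sort(unique(labels))
  folds <- integer(n)
  .withSeed(.childSeed(seed, "knnfolds"), {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  max_train <- n - max(table(folds))
  if (any(kValues > max_train))
    .warnf("capping k at the training-fold size (%d)", max_train)
  out <- list()
  for (f in seq_len(nFolds)) {
    test <- which(folds == f); train <- which(folds != f)
    kv <- unique(pmin(kValues, length(train)))
    ord_all <- lapply(test, function(t)
      train[order(D[t, train], train)])           # ties break by clone index
    for (k in kv) {
      scores <- matrix(0, length(test), length(classes),
                       dimnames = list(NULL, classes))
      for (ti in seq_along(test)) {
        nb <- labels[ord_all[[ti]][seq_len(k)]]
        scores[ti, ] <- tabulate(match(nb, classes), length(classes)) / k
      }
      m <- classificationMetrics(scores, labels[test])
      long <- do.call(rbind, lapply(c("auc", "recall", "precision", "f1"),
        function(metric) data.frame(k = k, fold = f, class = m$class,
                                    metric = metric, value = m[[metric]])))
      out[[length(out) + 1L]] <- long
    }
  }
  do.call(rbind, out)
}

#' Macro-AUC summary of a KNN sweep
#' @param sweep output of [knnClassifyCV()]
#' @return data.frame (k, macro_auc) averaged over folds.
#' @export
knnMacroAuc <- function(sweep) {
  sub <- sweep[sweep$class == "macro" & sweep$metric == "auc", ]
  agg <- stats::aggregate(value ~ k, data = sub, FUN = mean)
  names(agg) <- c("k", "macro_auc")
  agg
}
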