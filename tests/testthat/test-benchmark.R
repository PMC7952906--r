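test_that("variance ratio criterion reproduces the tabulated hand case", {
  x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  cl <- c(1, 1, 2, 2)
  # between = 100, within = 1, times (n-c)/(c-1) = 2  ->  200
  expect_equal(varianceRatioCriterion(x, cl), 200)

  # invariance under global translation and rotation
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xr <- sweep(x %*% R, 2, c(5, -3), "+")
  expect_equal(varianceRatioCriterion(xr, cl), 200)
})

test_that("adjusted mutual information has its fixed points and invariances", {
  set.seed(2)
  a <- sample(1:3, 60, replace = TRUE)
  expect_equal(adjustedMutualInformation(a, a), 1)
  # relabeling invariance
  expect_equal(adjustedMutualInformation(a, c(3, 1, 2)[a]), 1)
  # single cluster vs informative labels: no information
  expect_equal(adjustedMutualInformation(rep(1, 60), a), 0)
  # independent partitions: near zero (chance-corrected), well below 1
  b <- sample(1:3, 60, replace = TRUE)
  expect_lt(abs(adjustedMutualInformation(a, b)), 0.2)
})

test_that("cluster sweep scores solutions and skips infeasible counts", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 6), ncol = 2))
  labels <- rep(c("a", "b"), each = 20)
  sw <- clusterSweep(x, labels, counts = c(2L, 5L, 10L))
  expect_equal(sw$n_clusters, c(2L, 5L, 10L))
  expect_equal(sw$ami[1], 1)          # the 2-cluster cut recovers the labels
  expect_true(all(is.finite(sw$vrc)))
  expect_warning(clusterSweep(x, labels, counts = c(2L, 40L)), "skipping")

  # distance-matrix input agrees on AMI with feature input
  swd <- clusterSweep(as.matrix(dist(x)), labels, counts = c(2L, 5L),
                      distance = TRUE)
  expect_equal(swd$ami[1], 1)
})

test_that("classification metrics match exhaustive pair counting", {
  # one-hot truth
  scores <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8))
  colnames(scores) <- c("x", "y")
  m <- classificationMetrics(scores, c("x", "x", "y"))
  expect_equal(m$auc[m$class == "x"], 1)
  expect_equal(m$f1[m$class == "macro"], 1)

  # constant scores -> 0.5 by the midrank convention
  const <- matrix(0.5, 6, 2, dimnames = list(NULL, c("x", "y")))
  mc <- classificationMetrics(const, rep(c("x", "y"), 3))
  expect_equal(mc$auc[mc$class == "x"], 0.5)

  # 6-instance hand case: AUC = correctly ordered pairs / total pairs
  s <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.9)
  y <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  pairs_ok <- 0; total <- 0
  for (i in which(y)) for (j in which(!y)) {
    total <- total + 1
    pairs_ok <- pairs_ok + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  sc <- cbind(neg = 1 - s, pos = s)
  m2 <- classificationMetrics(sc, ifelse(y, "pos", "neg"))
  expect_equal(m2$auc[m2$class == "pos"], pairs_ok / total)

  # single-class truth -> AUC absent, not a number
  m3 <- classificationMetrics(sc, rep("pos", 6))
  expect_true(is.na(m3$auc[m3$class == "neg"]))
})

test_that("KNN cross-validation matches a brute-force sort-and-vote oracle", {
  set.seed(9)
  n <- 30L
  x <- rbind(matrix(rnorm(30, 0), ncol = 2), matrix(rnorm(30, 3), ncol = 2))
  labels <- rep(c("a", "b"), each = 15)
  D <- as.matrix(dist(x))
  sw <- knnClassifyCV(D, labels, kValues = c(1L, 3L, 7L), nFolds = 5L, seed = 2L)

  # reconstruct the folds exactly as the implementation draws them
  folds <- integer(n)
  tcrlearn:::.withSeed(tcrlearn:::.childSeed(2L, "knnfolds"), {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(1:5, length(idx))
    }
  })
  for (k in c(1L, 3L, 7L)) for (f in 1:5) {
    test <- which(folds == f); train <- which(folds != f)
    scores <- t(vapply(test, function(t_) {
      nb <- train[order(D[t_, train], train)][1:k]
      c(a = mean(labels[nb] == "a"), b = mean(labels[nb] == "b"))
    }, numeric(2)))
    want <- classificationMetrics(scores, labels[test])
    got <- sw[sw$k == k & sw$fold == f & sw$metric == "auc", ]
    expect_equal(got$value[got$class == "macro"],
                 want$auc[want$class == "macro"])
  }

  # a test clone identical to one training clone, k = 1 -> score 1
  D1 <- as.matrix(dist(c(0, 0.001, 5, 5.001, 10, 10.001)))
  sw1 <- knnClassifyCV(D1, c("a", "a", "b", "b", "c", "c"), kValues = 1L,
                       nFolds = 2L, seed = 1L)
  rec <- sw1[sw1$metric == "recall" & sw1$class == "macro", "value"]
  expect_true(all(rec == 1))

  # perfectly separated geometry -> AUC 1 at k below class size
  expect_true(all(sw1[sw1$metric == "auc" & sw1$class == "macro", "value"] == 1))

  # oversized k is capped with a warning
  expect_warning(knnClassifyCV(D1, c("a", "a", "b", "b", "c", "c"),
                               kValues = 50L, nFolds = 2L), "capping")
  expect_error(knnClassifyCV(D1, c("a", "a", "a", "a", "b", "b"),
                             nFolds = 5L), "fewer members")
})
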