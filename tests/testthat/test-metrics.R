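# Classification metrics, ranking metrics, and annotation-consensus tools.

test_that("confusion-count metrics follow the printed formulas", {
  m <- classificationMetrics(c(TP = 50, TN = 30, FP = 10, FN = 10))
  expect_equal(m$acc, 0.8)
  expect_equal(m$precision, 50 / 60, tolerance = 1e-4)
  expect_equal(m$recall, 50 / 60, tolerance = 1e-4)
  expect_equal(m$f1, 50 / 60, tolerance = 1e-4)
  # perfect predictor
  p <- classificationMetrics(c(TP = 7, TN = 13, FP = 0, FN = 0))
  expect_equal(unlist(p[c("acc", "precision", "recall", "f1")]),
               c(acc = 1, precision = 1, recall = 1, f1 = 1))
})

test_that("per-label counting agrees with an independent loop oracle", {
  set.seed(10)
  n <- 60; L <- 5
  pred <- matrix(rbinom(n * L, 1, 0.4), n)
  truth <- matrix(rbinom(n * L, 1, 0.4), n)
  cc <- tonguenet:::confusion_counts(pred, truth)
  for (j in seq_len(L)) {
    tp <- tn <- fp <- fn <- 0
    for (i in seq_len(n)) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
      if (pred[i, j] == 0 && truth[i, j] == 0) tn <- tn + 1
      if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
      if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
    }
    expect_equal(unlist(cc[j, ]), c(TP = tp, TN = tn, FP = fp, FN = fn))
    expect_equal(cc$TP[j] + cc$TN[j] + cc$FP[j] + cc$FN[j], n)
  }
})

test_that("macro-F1 is invariant under label permutation", {
  set.seed(11)
  pred <- matrix(rbinom(200, 1, 0.5), 40)
  truth <- matrix(rbinom(200, 1, 0.5), 40)
  f <- classificationMetrics(tonguenet:::confusion_counts(pred, truth))$f1
  perm <- sample(5)
  fp <- classificationMetrics(
    tonguenet:::confusion_counts(pred[, perm], truth[, perm]))$f1
  expect_equal(f, fp)
})

test_that("average precision matches hand and brute-force PR evaluation", {
  expect_equal(averagePrecision(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1.0)
  expect_equal(averagePrecision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2, tolerance = 1e-12)
  # brute force: precision at each positive rank
  set.seed(12)
  for (rep in 1:20) {
    sc <- runif(30)
    y <- rbinom(30, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    ord <- order(sc, decreasing = TRUE)
    ys <- y[ord]
    brute <- mean(vapply(which(ys == 1), function(k) sum(ys[1:k]) / k,
                         numeric(1)))
    expect_equal(averagePrecision(sc, y), brute)
  }
})

test_that("mAP is the unweighted mean of per-class APs", {
  set.seed(13)
  sc <- matrix(runif(90), 30)
  y <- matrix(rbinom(90, 1, 0.5), 30)
  y[, 2] <- 0  # class without positives is skipped
  aps <- c(averagePrecision(sc[, 1], y[, 1]),
           averagePrecision(sc[, 3], y[, 3]))
  expect_equal(suppressWarnings(mapScore(sc, y)), mean(aps))
})

test_that("AUC equals the pairwise concordance statistic", {
  expect_equal(aucScore(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(aucScore(rep(0.5, 10), rep(0:1, 5)), 0.5)
  set.seed(14)
  for (rep in 1:100) {
    n <- sample(10:200, 1)
    sc <- round(runif(n), 2)      # ties likely
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    pos <- sc[y == 1]; neg <- sc[y == 0]
    conc <- 0
    for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
    expect_equal(aucScore(sc, y), conc / (length(pos) * length(neg)))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  sc <- runif(80); y <- rbinom(80, 1, 0.5)
  expect_equal(aucScore(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))))
})

test_that("Cohen's kappa matches hand computation and statistical behaviour", {
  expect_equal(cohensKappa(c(1, 0, 1, 1), c(1, 0, 1, 1)), 1.0)
  # counts: both-yes 20, both-no 60, a-only 10, b-only 10
  a <- c(rep(1, 20), rep(0, 60), rep(1, 10), rep(0, 10))
  b <- c(rep(1, 20), rep(0, 60), rep(0, 10), rep(1, 10))
  po <- 0.8; pe <- 0.3 * 0.3 + 0.7 * 0.7
  expect_equal(cohensKappa(a, b), (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(round(cohensKappa(a, b), 4), 0.5238)
  set.seed(16)
  x <- rbinom(1e4, 1, 0.5); y <- rbinom(1e4, 1, 0.5)
  expect_lt(abs(cohensKappa(x, y)), 0.05)
})

test_that("consensus filter keeps exactly the unanimous samples", {
  a <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE)
  expect_true(all(consensusFilter(a, a, a)))
  b <- a; b[1, 2] <- 1 - b[1, 2]
  expect_equal(consensusFilter(a, a, b), c(FALSE, TRUE))
  set.seed(17)
  n <- 200
  a1 <- matrix(rbinom(n * 3, 1, 0.5), n)
  a2 <- a1; a3 <- a1
  flip <- sample(n, 70)
  a2[flip, 1] <- 1 - a2[flip, 1]
  keep <- consensusFilter(a1, a2, a3)
  expect_equal(sum(keep), n - 70)
  # kappa on kept samples is exactly 1 between any pair
  expect_equal(cohensKappa(a1[keep, ], a2[keep, ]), 1)
})

test_that("audit subsample is seeded and sized by the ceiling rule", {
  ids <- 1:100
  s <- auditSample(ids, 0.10, seed = 42)
  expect_length(s, 10)
  expect_true(all(s %in% ids))
  expect_equal(s, auditSample(ids, 0.10, seed = 42))
  expect_setequal(auditSample(ids, 1.0, seed = 1), ids)
  expect_length(auditSample(integer(0), 0.1), 0)
})
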