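# two Gaussian classes shifted by `delta` on every feature
separableFeatures <- function(n, p, delta, seed) {
  set.seed(seed)
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  x[y == "high", ] <- x[y == "high", ] + delta
  list(x = x, y = y)
}

test_that("the high/low label uses a strict homework cutoff", {
  ad <- data.frame(participant_id = c("a", "b", "c"), group = "meditation",
                   homework = c(12L, 10L, 0L), attendance = c(4L, 3L, 1L))
  lab <- labelBinarize(ad, cutoff = 10L)
  expect_identical(as.character(lab$label), c("high", "low", "low"))
  expect_identical(levels(lab$label), c("low", "high"))
})

test_that("the stratified hold-out split respects proportions and determinism", {
  yBal <- factor(rep(c("low", "high"), 24), levels = c("low", "high"))
  sp <- holdoutSplit(yBal, 0.25, seed = 1)
  expect_length(sp$heldout, 12L)
  expect_identical(as.integer(table(yBal[sp$heldout])), c(6L, 6L))
  expect_length(intersect(sp$train, sp$heldout), 0L)
  expect_setequal(c(sp$train, sp$heldout), seq_along(yBal))

  yUnbal <- factor(c(rep("high", 28), rep("low", 23)), levels = c("low", "high"))
  sp2 <- holdoutSplit(yUnbal, 0.25, seed = 2)
  expect_length(sp2$heldout, 13L)
  counts <- table(yUnbal[sp2$heldout])
  expect_lte(abs(counts[["high"]] - 0.25 * 28), 1)
  expect_lte(abs(counts[["low"]] - 0.25 * 23), 1)

  expect_identical(holdoutSplit(yUnbal, 0.25, seed = 7),
                   holdoutSplit(yUnbal, 0.25, seed = 7))
  expect_error(holdoutSplit(factor(c("low", "high", "high")), 0.25, 1),
               class = "adh_classTooSmall")
})

test_that("ROC curves reproduce hand-counted operating points", {
  res <- rocCurve(c(0.9, 0.8, 0.4, 0.2), c("high", "low", "high", "low"))
  expect_equal(res$auc, 0.75)                 # 3 of 4 concordant pairs
  expect_equal(res$curve$fpr[1], 0)
  expect_equal(res$curve$tpr[1], 0)
  expect_equal(res$curve$fpr[nrow(res$curve)], 1)
  expect_equal(res$curve$tpr[nrow(res$curve)], 1)
  expect_true(all(diff(res$curve$fpr) >= 0))
  expect_true(all(diff(res$curve$tpr) >= 0))

  perfect <- rocCurve(c(0.9, 0.8, 0.3, 0.1), c("high", "high", "low", "low"))
  expect_equal(perfect$auc, 1)
  flat <- rocCurve(rep(0.5, 6), rep(c("high", "low"), 3))
  expect_equal(flat$auc, 0.5)
  expect_error(rocCurve(1:3, rep("high", 3)), class = "adh_oneClass")
})

test_that("trapezoidal AUC equals the concordance-count oracle", {
  set.seed(91)
  for (rep in 1:300) {
    n <- sample(4:25, 1)
    labels <- sample(c("high", "low"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))   # rounding forces ties
    expect_equal(rocCurve(scores, labels)$auc, oracleAUC(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(97)
  for (rep in 1:20) {
    n <- 30
    labels <- factor(sample(c("high", "low"), n, replace = TRUE),
                     levels = c("low", "high"))
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores,
      levels = c("low", "high"), direction = "<", quiet = TRUE)))
    expect_equal(rocCurve(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("backward elimination keeps planted signal and discards redundancy", {
  # informative feature retained across seeded runs
  kept <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 30
    y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
    x <- cbind(sig = ifelse(y == "high", 1.6, -1.6) + rnorm(n),
               matrix(rnorm(n * 5), n, 5,
                      dimnames = list(NULL, paste0("noise", 1:5))))
    "sig" %in% backwardElimination(x, y, seed = s)$features
  }, logical(1))
  expect_gte(mean(kept), 0.9)

  # exactly one of a duplicated informative pair survives
  for (s in 1:4) {
    set.seed(s)
    n <- 30
    y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
    sig <- ifelse(y == "high", 1.6, -1.6) + rnorm(n)
    x <- cbind(sigA = sig, sigB = sig,
               matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("n1", "n2"))))
    res <- backwardElimination(x, y, seed = s)
    expect_identical(sum(c("sigA", "sigB") %in% res$features), 1L)
  }
})

test_that("backward elimination stop conditions hold on degenerate input", {
  set.seed(95)
  n <- 24
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  x1 <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "only"))
  expect_warning(res1 <- backwardElimination(x1, y, seed = 1),
                 class = "adh_singleFeature")
  expect_identical(res1$features, "only")

  # pure-noise tables run down to the configured floor (frozen seeded runs)
  for (s in 1:2) {
    set.seed(s)
    x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    res <- backwardElimination(x, y, seed = s, minFeatures = 2L)
    expect_identical(length(res$features), 2L)
    expect_setequal(c(res$features, res$eliminated), colnames(x))
  }
})

test_that("well-separated classes give near-perfect held-out AUC for every classifier", {
  d <- separableFeatures(60, 4, delta = 6, seed = 101)
  sp <- holdoutSplit(d$y, 0.25, seed = 101)
  rep <- trainAndEvaluate(d$x[sp$train, ], d$y[sp$train],
                          d$x[sp$heldout, ], d$y[sp$heldout], runConfig())
  for (clf in rep$classifiers) {
    expect_gte(clf$auc, 0.95)
    expect_gte(clf$cvMean, 0.9)
  }
  expect_identical(length(rep$classifiers), 4L)
  expect_length(rep$classifiers$random_forest$cvScores, 5L)
})

test_that("deterministic classifiers repeat identical scores across seeds", {
  d <- separableFeatures(24, 3, delta = 1, seed = 102)
  sp <- holdoutSplit(d$y, 0.25, seed = 102)
  rep <- trainAndEvaluate(d$x[sp$train, ], d$y[sp$train],
                          d$x[sp$heldout, ], d$y[sp$heldout], runConfig())
  for (name in c("adaboost", "decision_tree", "naive_bayes")) {
    cv <- rep$classifiers[[name]]$cvScores
    expect_true(all(cv == cv[1]))
    expect_identical(rep$classifiers[[name]]$cvHalfWidth, 0)
  }
})

test_that("a single-class hold-out set yields a missing AUC, not a crash", {
  d <- separableFeatures(20, 2, delta = 2, seed = 103)
  held <- which(d$y == "high")[1:3]
  train <- setdiff(seq_along(d$y), held)
  wrn <- capture_warnings(
    rep <- trainAndEvaluate(d$x[train, ], d$y[train],
                            d$x[held, ], d$y[held],
                            runConfig(seeds = 1L)))
  expect_length(wrn, 4L)   # one degenerate-hold-out warning per classifier
  expect_true(all(grepl("single class", wrn)))
  expect_true(all(is.na(vapply(rep$classifiers, `[[`, 0, "auc"))))
})

test_that("selecting features outside the folds inflates null accuracy (leakage guard)", {
  nbLoocv <- function(x, y, k, leak) {
    n <- nrow(x)
    correct <- logical(n)
    if (leak) sel <- order(-abs(stats::cor(x, as.numeric(y) == 2)))[1:k]
    for (i in seq_len(n)) {
      if (!leak)
        sel <- order(-abs(stats::cor(x[-i, ], as.numeric(y[-i]) == 2)))[1:k]
      fit <- e1071::naiveBayes(x[-i, sel, drop = FALSE], y[-i])
      correct[i] <- predict(fit, x[i, sel, drop = FALSE]) == y[i]
    }
    mean(correct)
  }
  inflation <- vapply(1:8, function(s) {
    set.seed(s)
    n <- 30
    y <- factor(rep(c("low", "high"), 15)[sample(n)], levels = c("low", "high"))
    x <- matrix(rnorm(n * 40), n, 40)
    nbLoocv(x, y, 3, leak = TRUE) - nbLoocv(x, y, 3, leak = FALSE)
  }, numeric(1))
  expect_gt(mean(inflation), 0.05)
})

test_that("held-out AUC degrades as class separation shrinks", {
  cfg <- runConfig(seeds = 1L)
  meanAuc <- vapply(c(2.5, 1.2, 0.3), function(delta) {
    mean(vapply(1:12, function(s) {
      d <- separableFeatures(20, 3, delta, seed = 600 + s)
      sp <- holdoutSplit(d$y, 0.25, seed = s)
      rep <- trainAndEvaluate(d$x[sp$train, ], d$y[sp$train],
                              d$x[sp$heldout, ], d$y[sp$heldout], cfg,
                              crossValidate = FALSE)
      mean(vapply(rep$classifiers, `[[`, 0, "auc"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanAuc) < 0))
})
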