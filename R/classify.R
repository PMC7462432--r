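#' Binary adherence labels
#'
#' Participants who completed strictly more than `cutoff` homework
#' assignments form the "high" class; everyone else is "low". The boundary
#' itself (homework equal to the cutoff) is low.
#'
#' @param adherence Adherence data.frame.
#' @param cutoff Homework cutoff (default 10).
#' @return data.frame with `participant_id` and `label` (factor, levels
#'   low < high).
#' @export
#' @examples
#' ad <- data.frame(participant_id = c("a", "b"), group = "meditation",
#'                  homework = c(10L, 12L), attendance = c(3L, 4L))
#' labelBinarize(ad)$label  # low, high
labelBinarize <- function(adherence, cutoff = 10L) {
  data.frame(
    participant_id = adherence$participant_id,
    label = factor(ifelse(adherence$homework > cutoff, "high", "low"),
                   levels = c("low", "high"))
  )
}

#' Assemble a classifier feature table from nodal metrics
#'
#' One column per (robust node, metric) pair, holding that node's metric
#' value at the reference threshold; one row per participant. The robust
#' sets come from [nodalScan()] on clustering and degree.
#'
#' @param metricTable Long metric table from [cohortMetrics()].
#' @param robust Named list mapping metric name to a character vector of
#'   node labels (or a `robustNodes` data.frame with a `node` column).
#' @param threshold Reference threshold the features are read at.
#' @return Numeric matrix participants x features, with a `provenance`
#'   attribute recording (feature, node, metric, threshold).
#' @export
buildFeatureTable <- function(metricTable, robust, threshold = 0.35) {
  stopifnot(is.list(robust), length(robust) >= 1L)
  prov <- do.call(rbind, lapply(names(robust), function(m) {
    nodes <- robust[[m]]
    if (is.data.frame(nodes)) nodes <- nodes$node
    if (length(nodes) == 0L) return(NULL)
    data.frame(node = nodes, metric = m)
  }))
  if (is.null(prov) || nrow(prov) == 0L)
    adhStop("emptyFeatureSet", "no robust nodes to build features from")
  tab <- metricTable[abs(metricTable$threshold - threshold) < 1e-9 &
                     metricTable$scope != "GLOBAL", ]
  if (nrow(tab) == 0L)
    adhStop("badThreshold", "threshold %s not present in the metric table",
            format(threshold))
  ids <- unique(tab$participant_id)
  x <- matrix(NA_real_, length(ids), nrow(prov),
              dimnames = list(ids, paste(prov$node, prov$metric, sep = ".")))
  for (k in seq_len(nrow(prov))) {
    sub <- tab[tab$metric == prov$metric[k] & tab$scope == prov$node[k], ]
    x[, k] <- sub$value[match(ids, sub$participant_id)]
  }
  if (anyNA(x))
    adhStop("missingFeature", "missing metric values for some features")
  prov$feature <- colnames(x)
  prov$threshold <- threshold
  attr(x, "provenance") <- prov
  x
}

#' Stratified hold-out split
#'
#' Randomly selects `round(fraction * n)` participants as the hold-out set
#' while preserving the class proportions as closely as integer counts
#' allow (largest-remainder apportionment per class). Deterministic given
#' `seed`.
#'
#' @param labels Factor of class labels.
#' @param fraction Hold-out fraction (default 0.25, a quarter).
#' @param seed Seed for the random selection.
#' @return List with integer index vectors `train` and `heldout`.
#' @export
holdoutSplit <- function(labels, fraction = 0.25, seed = 1L) {
  labels <- as.factor(labels)
  sizes <- table(labels)
  if (length(sizes) < 2L || any(sizes < 2L))
    adhStop("classTooSmall", "both classes need at least 2 members")
  n <- length(labels)
  total <- round(fraction * n)
  exact <- fraction * as.numeric(sizes)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    cut <- order(exact - base)[seq_len(-rem)]
    base[cut] <- pmax(base[cut] - 1, 0)
  }
  set.seed(seed)
  held <- integer(0)
  for (k in seq_along(sizes)) {
    idx <- which(labels == names(sizes)[k])
    held <- c(held, sort(sample(idx, base[k])))
  }
  held <- sort(held)
  list(train = setdiff(seq_len(n), held), heldout = held)
}

# --- classifier registry -----------------------------------------------
# Each entry fits on (matrix, factor) and scores P(positive class), where
# the positive class is the second factor level ("high").

.adaboostFit <- function(x, y, nRounds = 50L) {
  d <- as.data.frame(x)
  n <- nrow(d)
  w <- rep(1 / n, n)
  pos <- levels(y)[2L]
  yi <- ifelse(y == pos, 1, -1)
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2, xval = 0)
  for (m in seq_len(nRounds)) {
    dd <- cbind(d, .y = y)
    fit <- rpart::rpart(.y ~ ., data = dd, weights = w, method = "class",
                        control = ctrl)
    pred <- ifelse(predict(fit, d, type = "class") == pos, 1, -1)
    err <- sum(w * (pred != yi))
    if (err >= 0.5) {            # weak learner no better than chance: stop
      if (m == 1L) { stumps[[1L]] <- fit; alphas[1L] <- 0 }
      break
    }
    # cap the weight of a perfect stump so the margin stays finite
    a <- if (err <= 0) 10 else 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    alphas[m] <- a
    if (err <= 0) break
    w <- w * exp(-a * yi * pred)
    w <- w / sum(w)
  }
  structure(list(stumps = stumps, alphas = alphas, positive = pos),
            class = "adhAdaboost")
}

.adaboostMargin <- function(model, x) {
  d <- as.data.frame(x)
  f <- rep(0, nrow(d))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(predict(model$stumps[[m]], d, type = "class") ==
                     model$positive, 1, -1)
    f <- f + model$alphas[m] * pred
  }
  f
}

.classifierRegistry <- function() {
  list(
    random_forest = list(
      deterministic = FALSE,
      fit = function(x, y) randomForest::randomForest(x = x, y = y,
                                                      ntree = 100L),
      score = function(model, x)
        unname(predict(model, newdata = x, type = "prob")[, "high"])
    ),
    adaboost = list(
      deterministic = TRUE,
      fit = function(x, y) .adaboostFit(x, y),
      score = function(model, x)
        1 / (1 + exp(-2 * .adaboostMargin(model, x)))
    ),
    decision_tree = list(
      deterministic = TRUE,
      fit = function(x, y) {
        d <- cbind(as.data.frame(x), .y = y)
        # xval = 0: no internal CV; pruning is not used, so the cp table
        # would be dead weight in every LOOCV fold
        rpart::rpart(.y ~ ., data = d, method = "class",
                     control = rpart::rpart.control(xval = 0))
      },
      score = function(model, x)
        unname(predict(model, as.data.frame(x), type = "prob")[, "high"])
    ),
    naive_bayes = list(
      deterministic = TRUE,
      fit = function(x, y) e1071::naiveBayes(x = as.data.frame(x), y = y),
      score = function(model, x)
        unname(predict(model, as.data.frame(x), type = "raw")[, "high"])
    )
  )
}

# LOOCV accuracy of one classifier; the fold layout is deterministic, the
# seed only drives classifier-internal randomness.
.loocvAccuracy <- function(x, y, clf, seed) {
  n <- nrow(x)
  correct <- logical(n)
  pos <- levels(y)[2L]
  for (i in seq_len(n)) {
    set.seed(deriveSeed(seed, 311L, i))
    fit <- clf$fit(x[-i, , drop = FALSE], y[-i])
    sc <- clf$score(fit, x[i, , drop = FALSE])
    correct[i] <- (sc >= 0.5) == (y[i] == pos)
  }
  mean(correct)
}

#' Backward feature elimination with a random-forest filter
#'
#' Greedy elimination: at each step the leave-one-out accuracy of a
#' 100-tree random forest is evaluated with each single feature removed;
#' the feature whose removal gives the best (or least-harmed) accuracy is
#' dropped as long as accuracy does not decrease, stopping otherwise or at
#' `minFeatures`. Run it on the training partition only; selecting
#' features on data that includes the hold-out set leaks information.
#'
#' @param x Numeric feature matrix (rows participants).
#' @param y Factor of labels (levels low < high).
#' @param seed Seed driving the forest's internal randomness.
#' @param minFeatures Minimum number of features to retain.
#' @param nTree Trees per forest (reference protocol: 100).
#' @return List with `features` (kept, in column order), `eliminated`
#'   (drop order) and `accuracy` (LOOCV accuracy of the kept set).
#' @export
backwardElimination <- function(x, y, seed = 1L, minFeatures = 2L,
                                nTree = 100L) {
  y <- as.factor(y)
  if (ncol(x) < 2L) {
    adhWarn("singleFeature", "only one feature supplied; nothing to eliminate")
    return(list(features = colnames(x), eliminated = character(0),
                accuracy = NA_real_))
  }
  rf <- list(
    fit = function(xs, ys) randomForest::randomForest(x = xs, y = ys,
                                                      ntree = nTree),
    score = function(model, xs)
      unname(predict(model, newdata = xs, type = "prob")[, levels(y)[2L]])
  )
  current <- colnames(x)
  eliminated <- character(0)
  step <- 0L
  accFull <- .loocvAccuracy(x[, current, drop = FALSE], y, rf,
                            deriveSeed(seed, 401L, step))
  while (length(current) > minFeatures) {
    step <- step + 1L
    cand <- vapply(seq_along(current), function(j) {
      .loocvAccuracy(x[, current[-j], drop = FALSE], y, rf,
                     deriveSeed(seed, 401L, step, j))
    }, numeric(1))
    best <- which.max(cand)
    if (cand[best] < accFull) break
    eliminated <- c(eliminated, current[best])
    current <- current[-best]
    accFull <- cand[best]
  }
  list(features = current, eliminated = eliminated, accuracy = accFull)
}

#' ROC curve and AUC from scores
#'
#' Standard threshold sweep over the predicted scores: each point is the
#' (false-positive rate, true-positive rate) of predicting "positive" for
#' scores at or above a cut. The curve starts at (0, 0), ends at (1, 1),
#' and the AUC (trapezoidal rule) equals the Mann-Whitney concordance
#' probability, ties counting one half.
#'
#' @param scores Numeric predicted scores (higher = more positive).
#' @param labels Class labels; `positive` names the positive class.
#' @param positive The positive class (default "high").
#' @return List with `curve` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
#' @examples
#' rocCurve(c(0.9, 0.8, 0.4, 0.2),
#'          c("high", "low", "high", "low"))$auc  # 0.75
rocCurve <- function(scores, labels, positive = "high") {
  isPos <- as.character(labels) == positive
  nPos <- sum(isPos)
  nNeg <- sum(!isPos)
  if (nPos == 0L || nNeg == 0L)
    adhStop("oneClass", "ROC requires at least one member of each class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  yp <- isPos[o]
  # collapse tied scores into single cut points
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(yp)[last]
  fp <- cumsum(!yp)[last]
  curve <- data.frame(
    fpr = c(0, fp / nNeg),
    tpr = c(0, tp / nPos),
    threshold = c(Inf, s[last])
  )
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  list(curve = curve, auc = auc)
}

#' Train the four classifiers and evaluate on a hold-out set
#'
#' For each of random forest, AdaBoost, decision tree and naive Bayes:
#' leave-one-out cross-validation accuracy on the training set once per
#' configured seed (the fold layout is deterministic; seeds drive
#' classifier-internal randomness, so deterministic classifiers repeat the
#' same score), the mean with a 95% normal-approximation half-width, a fit
#' on the full training set per seed evaluated on the hold-out set, and a
#' ROC/AUC from the seed-averaged hold-out scores. The pooled mean over
#' all classifier x seed cross-validation scores is also reported.
#'
#' @param xTrain,yTrain Training features and labels (both classes
#'   present).
#' @param xHeld,yHeld Hold-out features and labels.
#' @param cfg A [RunConfig-class]; `cfg@seeds` are the repetition seeds.
#' @param crossValidate Compute the LOOCV scores (default). Turning this
#'   off skips cross-validation and reports only the held-out evaluation,
#'   for simulation studies that consume nothing but the AUC.
#' @return A `ClassifierReport` (S3 list): per classifier `cvScores`,
#'   `cvMean`, `cvHalfWidth`, `heldoutAccuracy`, `heldoutScores`, `roc`,
#'   `auc`; plus `pooledCvMean`. AUC is `NA` when the hold-out set has a
#'   single class.
#' @export
trainAndEvaluate <- function(xTrain, yTrain, xHeld, yHeld,
                             cfg = runConfig(), crossValidate = TRUE) {
  yTrain <- factor(yTrain, levels = c("low", "high"))
  yHeld <- factor(yHeld, levels = c("low", "high"))
  if (nlevels(droplevels(yTrain)) < 2L)
    adhStop("classTooSmall", "training set must contain both classes")
  seeds <- cfg@seeds
  registry <- .classifierRegistry()
  pos <- "high"
  degenerateHeld <- length(unique(yHeld)) < 2L
  report <- list()
  for (name in names(registry)) {
    clf <- registry[[name]]
    if (!crossValidate) {
      cv <- rep(NA_real_, length(seeds))
    } else if (clf$deterministic) {
      one <- .loocvAccuracy(xTrain, yTrain, clf, seeds[1L])
      cv <- rep(one, length(seeds))
    } else {
      cv <- vapply(seeds, function(s) .loocvAccuracy(xTrain, yTrain, clf, s),
                   numeric(1))
    }
    heldAcc <- numeric(length(seeds))
    scoreMat <- matrix(NA_real_, length(yHeld), length(seeds))
    for (k in seq_along(seeds)) {
      set.seed(deriveSeed(seeds[k], 907L))
      fit <- clf$fit(xTrain, yTrain)
      sc <- clf$score(fit, xHeld)
      scoreMat[, k] <- sc
      heldAcc[k] <- mean((sc >= 0.5) == (yHeld == pos))
    }
    meanScores <- rowMeans(scoreMat)
    if (degenerateHeld) {
      adhWarn("degenerateHeldout",
              "hold-out set has a single class; AUC undefined for '%s'", name)
      roc <- NULL
      auc <- NA_real_
    } else {
      rc <- rocCurve(meanScores, yHeld, positive = pos)
      roc <- rc$curve
      auc <- rc$auc
    }
    halfWidth <- if (!crossValidate) NA_real_
      else if (length(cv) > 1L)
        stats::qnorm(0.975) * stats::sd(cv) / sqrt(length(cv)) else 0
    report[[name]] <- list(
      cvScores = cv, cvMean = mean(cv), cvHalfWidth = halfWidth,
      heldoutAccuracy = mean(heldAcc), heldoutScores = meanScores,
      roc = roc, auc = auc
    )
  }
  out <- list(
    classifiers = report,
    pooledCvMean = if (crossValidate)
      mean(unlist(lapply(report, `[[`, "cvScores"))) else NA_real_,
    nTrain = nrow(xTrain), nHeldout = nrow(xHeld),
    seeds = seeds
  )
  class(out) <- "ClassifierReport"
  out
}

#' @export
print.ClassifierReport <- function(x, ...) {
  cat(sprintf("ClassifierReport: %d train / %d held out, %d seeds\n",
              x$nTrain, x$nHeldout, length(x$seeds)))
  for (name in names(x$classifiers)) {
    c0 <- x$classifiers[[name]]
    cat(sprintf("  %-14s cv %.3f +/- %.3f  heldout %.3f  AUC %s\n",
                name, c0$cvMean, c0$cvHalfWidth, c0$heldoutAccuracy,
                ifelse(is.na(c0$auc), "NA", sprintf("%.3f", c0$auc))))
  }
  cat(sprintf("  pooled CV mean over all classifier x seed scores: %.3f\n",
              x$pooledCvMean))
  invisible(x)
}
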