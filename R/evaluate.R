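#' Precision, recall and F1 from raw counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)` (harmonic mean),
#' with `F1 = 0` when both P and R are 0. When a denominator is zero the
#' corresponding metric is undefined and returned as `NA` with a warning —
#' never silently coerced to 0.
#'
#' @param tp,fp,fn non-negative counts of true positives, false positives and
#'   false negatives.
#' @return named numeric: `precision`, `recall`, `f1`.
#' @examples
#' precisionRecallF1(tp = 3, fp = 1, fn = 2)
#' @export
precisionRecallF1 <- function(tp, fp, fn) {
  stopInvalid(any(c(tp, fp, fn) < 0), "counts must be non-negative")
  p <- if (tp + fp == 0) {
    warning("precision undefined: tp + fp = 0"); NA_real_
  } else tp / (tp + fp)
  r <- if (tp + fn == 0) {
    warning("recall undefined: tp + fn = 0"); NA_real_
  } else tp / (tp + fn)
  f1 <- if (is.na(p) || is.na(r)) NA_real_
        else if (p + r == 0) 0
        else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Confusion matrix
#'
#' Entry (i, j) counts the items whose true class is `labels[i]` and whose
#' predicted class is `labels[j]`.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param labels ordered class names (default: sorted union of observed
#'   labels). Any label outside this set is an error.
#' @return integer matrix with `labels` as dimnames.
#' @examples
#' confusionMatrix(c("a", "a", "b"), c("a", "b", "b"))
#' @export
confusionMatrix <- function(yTrue, yPred, labels = NULL) {
  stopInvalid(length(yTrue) != length(yPred),
              "yTrue and yPred must have equal length")
  if (is.null(labels)) labels <- sort(unique(c(yTrue, yPred)))
  unknown <- setdiff(unique(c(yTrue, yPred)), labels)
  stopInvalid(length(unknown) > 0,
              paste("unknown label(s):", paste(unknown, collapse = ", ")))
  cm <- table(factor(yTrue, levels = labels), factor(yPred, levels = labels))
  m <- matrix(as.integer(cm), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  m
}

#' Support-weighted average of per-class scores
#'
#' `sum(score * support) / sum(support)` — the "Avg/total" row of the
#' evaluation tables.
#'
#' @param scores per-class metric values.
#' @param supports per-class record counts; total must be positive.
#' @return numeric scalar.
#' @examples
#' weightedAverage(c(0.95, 0.84), c(230, 80))
#' @export
weightedAverage <- function(scores, supports) {
  stopInvalid(length(scores) != length(supports),
              "scores and supports must have equal length")
  stopInvalid(sum(supports) <= 0, "total support must be positive")
  sum(scores * supports) / sum(supports)
}

#' Full evaluation report from labels
#'
#' Builds the confusion matrix and derives per-class precision, recall, F1
#' and support (one-vs-rest per class), plus their support-weighted averages.
#'
#' @inheritParams confusionMatrix
#' @return an [EvaluationReport].
#' @examples
#' evaluationReport(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
#' @export
evaluationReport <- function(yTrue, yPred, labels = NULL) {
  cm <- confusionMatrix(yTrue, yPred, labels)
  labels <- rownames(cm)
  per <- do.call(rbind, lapply(seq_along(labels), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    prf <- suppressWarnings(precisionRecallF1(tp, fp, fn))
    data.frame(precision = prf[["precision"]], recall = prf[["recall"]],
               f1 = prf[["f1"]], support = sum(cm[i, ]))
  }))
  rownames(per) <- labels
  w <- c(precision = weightedAverage(per$precision, per$support),
         recall = weightedAverage(per$recall, per$support),
         f1 = weightedAverage(per$f1, per$support))
  new("EvaluationReport", labels = labels, confusion = cm, perClass = per,
      weighted = w, nTotal = as.integer(sum(cm)))
}

#' @describeIn EvaluationReport-class print the report in the standard
#'   precision | recall | F1 | #recs layout with an Avg/total row
#' @param object an EvaluationReport
#' @export
setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (", object@nTotal, " items)\n", sep = "")
  tab <- rbind(
    round(object@perClass[, c("precision", "recall", "f1")], 2),
    `Avg/total` = round(object@weighted, 2))
  tab$`#recs` <- c(object@perClass$support, object@nTotal)
  print(tab)
})

#' Macro (unweighted) average of per-class scores in a report
#'
#' @param report an [EvaluationReport].
#' @return named numeric: macro precision, recall, f1.
#' @export
macroAverage <- function(report) {
  colMeans(report@perClass[, c("precision", "recall", "f1")])
}

#' Repeated random-split cross-validation with standard classifiers
#'
#' The baseline protocol: the dataset is shuffled once with `seed`, then
#' `nFolds` independent random splits each hold out `holdoutFrac` of the data;
#' the named model is fit on the remainder with fixed hyperparameters and
#' accuracy is measured on the held-out part. Note this is repeated random
#' sub-sampling, not partitioned k-fold. Reproducible bit-for-bit given
#' `(X, y, model, seed)`.
#'
#' Frozen hyperparameters: `svm` = RBF kernel, cost 1, no re-scaling (the
#'   features are already unit-norm spectra), `gamma = 1/(p * var(X))`
#'   ([e1071::svm]);
#' `random_forest` = 200 trees ([randomForest::randomForest]);
#' `extra_trees` = 200 trees, extratrees split rule ([ranger::ranger]);
#' `gradient_boosting` = 50 rounds, depth 3, eta 0.3, single thread
#' ([xgboost::xgboost]).
#'
#' @param X numeric feature matrix, rows = events.
#' @param y class labels (coerced to factor; >= 2 classes).
#' @param model one of `"svm"`, `"random_forest"`, `"extra_trees"`,
#'   `"gradient_boosting"`.
#' @param nFolds number of random splits (default 10).
#' @param holdoutFrac held-out fraction per split (default 0.20).
#' @param seed integer RNG seed.
#' @return list with `meanAccuracy`, `foldAccuracies`, `model`, `nFolds`,
#'   `holdoutFrac`, `seed`.
#' @export
crossvalClassify <- function(X, y,
                             model = c("svm", "random_forest", "extra_trees",
                                       "gradient_boosting"),
                             nFolds = 10L, holdoutFrac = 0.20, seed = 1L) {
  model <- tryCatch(match.arg(model),
                    error = function(e) stop("unknown model name: ",
                                             paste(model, collapse = "/"),
                                             call. = FALSE))
  y <- factor(y)
  stopInvalid(nlevels(y) < 2, "need at least 2 classes")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)
  stopInvalid(length(y) != n, "X and y sizes differ")
  nTest <- max(1L, round(holdoutFrac * n))
  stopInvalid(nTest >= n, "holdout leaves no training data")
  accs <- withSeed(seed, {
    perm <- sample.int(n)   # one global shuffle before any classification
    X <- X[perm, , drop = FALSE]
    y <- y[perm]
    vapply(seq_len(nFolds), function(i) {
      test <- sample.int(n, nTest)
      xtr <- X[-test, , drop = FALSE]; ytr <- droplevels(y[-test])
      xte <- X[test, , drop = FALSE]
      stopInvalid(nlevels(ytr) < 2, "a split lost a class; use more samples")
      pred <- switch(model,
        svm = {
          gma <- 1 / (ncol(xtr) * max(var(as.vector(xtr)), .Machine$double.eps))
          fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1,
                            gamma = gma, scale = FALSE)
          as.character(predict(fit, xte))
        },
        random_forest = {
          fit <- randomForest::randomForest(xtr, ytr, ntree = 200)
          as.character(predict(fit, xte))
        },
        extra_trees = {
          fit <- ranger::ranger(x = xtr, y = ytr, num.trees = 200,
                                splitrule = "extratrees",
                                num.random.splits = 1, num.threads = 1,
                                seed = sample.int(1e9, 1))
          as.character(predict(fit, data = xte, num.threads = 1)$predictions)
        },
        gradient_boosting = {
          lv <- levels(ytr)
          dtr <- xgboost::xgb.DMatrix(xtr, label = as.integer(ytr) - 1)
          params <- list(max_depth = 3, eta = 0.3, nthread = 1)
          if (length(lv) == 2) {
            fit <- xgboost::xgb.train(c(params, objective = "binary:logistic"),
                                      dtr, nrounds = 50, verbose = 0)
            lv[as.integer(predict(fit, xgboost::xgb.DMatrix(xte)) > 0.5) + 1]
          } else {
            fit <- xgboost::xgb.train(
              c(params, list(objective = "multi:softmax",
                             num_class = length(lv))),
              dtr, nrounds = 50, verbose = 0)
            lv[predict(fit, xgboost::xgb.DMatrix(xte)) + 1]
          }
        })
      mean(pred == as.character(y[test]))
    }, numeric(1))
  })
  list(meanAccuracy = mean(accs), foldAccuracies = accs, model = model,
       nFolds = nFolds, holdoutFrac = holdoutFrac, seed = seed)
}
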