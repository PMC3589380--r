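# Supramodal analyses: the combined classifier, the knock-out mask, the
# exclusion/restriction re-evaluations, cross-condition generalization and
# motor-pantomime classification.

# train/test split of a condition for one fold
.fold_split <- function(cd, f) {
  tr <- cd$foldId != f
  X <- .cond_X(cd, f)
  list(Xtr = X[tr, , drop = FALSE], ytr = cd$y[tr],
       Xte = X[!tr, , drop = FALSE], yte = cd$y[!tr],
       subjTe = cd$info$subjectId[!tr])
}

# accuracy null by retraining on permuted training labels; kernels are
# precomputed so each permutation costs one small SMO solve
.perm_accuracy_p <- function(Xtr, ytr, Xte, yte, featureSet, observed,
                             nPerm, seed, tol = 1e-6) {
  Ktr <- tcrossprod(Xtr[, featureSet, drop = FALSE])
  Kte <- Xte[, featureSet, drop = FALSE] %*% t(Xtr[, featureSet, drop = FALSE])
  C <- 1 / mean(diag(Ktr))
  score <- function(y_perm) {
    fit <- .svm_solve_kernel(Ktr, y_perm, C, tol = tol)
    pred <- ifelse(drop(Kte %*% (fit$alpha * y_perm)) + fit$bias >= 0, 1, -1)
    mean(pred == yte)
  }
  permutationTest(observed, ytr, score, nPerm = nPerm, seed = seed)
}

#' Train the combined supramodal classifier
#'
#' Pools the training examples of all conditions of the best fold and runs
#' the same recursive feature elimination procedure on the pooled data; the
#' best-iteration classifier is returned together with its discriminative
#' map and its accuracy on the pooled test examples of that fold. The
#' pooled set keeps each condition's balanced examples as-is, so classes
#' remain balanced by construction.
#'
#' @param condData named list of condition bundles (see [conditionData()]).
#' @param bestFold fold index selected by [nestedCV()].
#' @param grid a \linkS4class{VoxelGrid}.
#' @param config an \linkS4class{RFEConfig}.
#' @return list with `model` (a \linkS4class{LinearModel}), `map` (a
#'   \linkS4class{DiscriminativeMap}), `featureSet`, `accuracy` (pooled
#'   test accuracy), `trace` (the pooled \linkS4class{RFETrace}) and
#'   `nTrain`/`nTest` bookkeeping counts.
#' @export
trainSupramodal <- function(condData, bestFold, grid, config = RFEConfig()) {
  splits <- lapply(condData, .fold_split, f = bestFold)
  Xtr <- do.call(rbind, lapply(splits, `[[`, "Xtr"))
  ytr <- unlist(lapply(splits, `[[`, "ytr"), use.names = FALSE)
  Xte <- do.call(rbind, lapply(splits, `[[`, "Xte"))
  yte <- unlist(lapply(splits, `[[`, "yte"), use.names = FALSE)
  trace <- runRFE(Xtr, ytr, Xte, yte, grid, config)
  it <- .argmax_last(trace@accuracies)
  set <- trace@featureSets[[it]]
  model <- svmTrain(Xtr, ytr, featureIdx = set, tol = config@tol)
  list(model = model, map = makeMap(model, grid), featureSet = set,
       accuracy = trace@accuracies[it], trace = trace,
       nTrain = nrow(Xtr), nTest = nrow(Xte))
}

#' Knock-out mask of the supramodal classifier
#'
#' The discriminative voxels selected by the combined supramodal
#' classifier, used both for exclusion (removing them from the
#' per-condition best maps) and for restriction (rebuilding classifiers on
#' them alone).
#'
#' @param x the result of [trainSupramodal()], a
#'   \linkS4class{DiscriminativeMap} or a \linkS4class{LinearModel}.
#' @return sorted integer vector of voxel indices.
#' @export
knockoutMask <- function(x) {
  if (is.list(x) && !is.null(x$featureSet)) return(sort(as.integer(x$featureSet)))
  if (is(x, "DiscriminativeMap") || is(x, "LinearModel"))
    return(sort(featureIndices(x)))
  stop("cannot derive a knock-out mask from this object")
}

# per-subject test accuracy of a model on one condition's test fold
.per_subject_accuracy <- function(model, cd, f) {
  sp <- .fold_split(cd, f)
  pred <- predict(model, sp$Xte)
  acc <- tapply(pred == sp$yte, sp$subjTe, mean)
  data.frame(subjectId = names(acc), accuracy = as.numeric(acc),
             row.names = NULL)
}

#' Re-evaluate a condition after excluding the knock-out voxels
#'
#' Removes the knock-out voxels from each condition's best discriminative
#' map and retrains that condition's classifier on the surviving features
#' (training data of the best fold), reporting the best-fold test accuracy
#' and, optionally, a permutation p-value. If no features survive the
#' exclusion the result is a defined chance accuracy of 0.5 with
#' `empty = TRUE`.
#'
#' @param ncv an `"ncvResult"` from [nestedCV()].
#' @param condData the condition bundles used to fit `ncv`.
#' @param knockout integer voxel set from [knockoutMask()].
#' @param grid a \linkS4class{VoxelGrid}.
#' @param config an \linkS4class{RFEConfig}.
#' @param nPerm permutations for the accuracy p-value; 0 skips the test.
#' @param seed integer seed or `NULL`.
#' @return named list per condition: `featureSet` (surviving voxels),
#'   `accuracy`, `pPermutation`, `empty`, `model`, `perSubject`.
#' @export
evaluateExcluding <- function(ncv, condData, knockout, grid,
                              config = RFEConfig(), nPerm = 0, seed = NULL) {
  f <- ncv$bestFold
  best <- ncv$foldRecords[[f]]$best
  out <- lapply(names(condData), function(cn) {
    surv <- setdiff(best[[cn]]$featureSet, knockout)
    if (!length(surv)) {
      warning("exclusion left no features for condition ", cn,
              "; accuracy defined as 0.5")
      return(list(featureSet = integer(0), accuracy = 0.5,
                  pPermutation = NA_real_, empty = TRUE, model = NULL,
                  perSubject = NULL))
    }
    cd <- condData[[cn]]
    sp <- .fold_split(cd, f)
    model <- svmTrain(sp$Xtr, sp$ytr, featureIdx = surv, tol = config@tol)
    acc <- accuracyScore(predict(model, sp$Xte), sp$yte)
    pp <- if (nPerm > 0)
      .perm_accuracy_p(sp$Xtr, sp$ytr, sp$Xte, sp$yte, surv, acc, nPerm,
                       seed, config@tol)$pValue else NA_real_
    list(featureSet = sort(as.integer(surv)), accuracy = acc,
         pPermutation = pp, empty = FALSE, model = model,
         perSubject = .per_subject_accuracy(model, cd, f))
  })
  names(out) <- names(condData)
  out
}

#' Accuracy of a model on another condition's test examples
#'
#' Applies a classifier trained on one condition to the best-fold test
#' examples of another condition or group (the across-stimulus-category and
#' across-group evaluation). With `testCond` equal to the training
#' condition this is the within-condition accuracy.
#'
#' @param model a \linkS4class{LinearModel}.
#' @param testCond a condition bundle (see [conditionData()]).
#' @param bestFold fold index whose test subset is evaluated.
#' @return accuracy in `[0, 1]`.
#' @export
crossConditionAccuracy <- function(model, testCond, bestFold) {
  sp <- .fold_split(testCond, bestFold)
  if (max(featureIndices(model)) > ncol(sp$Xte))
    stop("model features are outside the test feature space")
  accuracyScore(predict(model, sp$Xte), sp$yte)
}

#' Within- and across-condition accuracy table
#'
#' Evaluates one trained classifier per condition on every condition's
#' best-fold test examples: the diagonal holds within-condition accuracies
#' and the off-diagonal cells the across-stimulus-category / across-group
#' generalization. Each cell optionally carries a label-permutation
#' p-value (the null retrains the row's classifier on its own training
#' data with permuted labels and re-applies it to the column's test set).
#'
#' @param models named list of \linkS4class{LinearModel}s, one per training
#'   condition (names must match `condData`).
#' @param condData named list of condition bundles.
#' @param bestFold fold index.
#' @param nPerm permutations per cell; 0 skips the tests.
#' @param seed integer seed or `NULL`.
#' @return data.frame with columns `train`, `test`, `accuracy`,
#'   `pPermutation`, `nTest`.
#' @export
accuracyTable <- function(models, condData, bestFold, nPerm = 0, seed = NULL) {
  stopifnot(all(names(models) %in% names(condData)))
  rows <- list()
  cell_seed <- 0L
  for (tr_cn in names(models)) {
    model <- models[[tr_cn]]
    if (is.null(model)) next
    sp_tr <- .fold_split(condData[[tr_cn]], bestFold)
    for (te_cn in names(condData)) {
      sp_te <- .fold_split(condData[[te_cn]], bestFold)
      acc <- accuracyScore(predict(model, sp_te$Xte), sp_te$yte)
      pp <- NA_real_
      if (nPerm > 0) {
        cell_seed <- cell_seed + 1L
        pp <- .perm_accuracy_p(sp_tr$Xtr, sp_tr$ytr, sp_te$Xte, sp_te$yte,
                               featureIndices(model), acc, nPerm,
                               if (is.null(seed)) NULL else seed + cell_seed)$pValue
      }
      rows[[length(rows) + 1L]] <-
        data.frame(train = tr_cn, test = te_cn, accuracy = acc,
                   pPermutation = pp, nTest = length(sp_te$yte))
    }
  }
  do.call(rbind, rows)
}

#' Rebuild classifiers restricted to the knock-out map
#'
#' Restricts the volume of interest to the knock-out voxels only, retrains
#' one classifier per condition on them (best-fold training data), and
#' fills the full within/across accuracy table.
#'
#' @inheritParams evaluateExcluding
#' @return list with `models` (per condition) and `table` (see
#'   [accuracyTable()]).
#' @export
evaluateRestricted <- function(condData, bestFold, knockout,
                               config = RFEConfig(), nPerm = 0, seed = NULL) {
  knockout <- sort(as.integer(knockout))
  if (!length(knockout)) stop("the knock-out mask is empty")
  models <- lapply(condData, function(cd) {
    sp <- .fold_split(cd, bestFold)
    svmTrain(sp$Xtr, sp$ytr, featureIdx = knockout, tol = config@tol)
  })
  list(models = models,
       table = accuracyTable(models, condData, bestFold, nPerm, seed))
}

#' Classify motor pantomimes as actions
#'
#' Applies a trained action/non-action classifier to motor-pantomime
#' examples (test-only: pantomimes never enter a training set) and reports
#' the fraction labelled "action", together with a label-permutation
#' p-value (the null retrains with permuted training labels and measures
#' the fraction on the same pantomimes) and an exact binomial p-value
#' against a chance fraction of 0.5.
#'
#' @param model a \linkS4class{LinearModel}.
#' @param pantX numeric matrix of pantomime examples (examples x voxels),
#'   scaled consistently with the model's training condition.
#' @param Xtr,ytr the model's training data (needed for the permutation
#'   null); omit both to skip the permutation test.
#' @param nPerm permutations; 0 skips the permutation test.
#' @param seed integer seed or `NULL`.
#' @return list with `fraction`, `pPermutation`, `pBinomial`, `n`.
#' @export
classifyPantomime <- function(model, pantX, Xtr = NULL, ytr = NULL,
                              nPerm = 0, seed = NULL) {
  pantX <- as.matrix(pantX)
  if (!nrow(pantX)) stop("no pantomime examples to classify")
  frac <- mean(predict(model, pantX) == 1)
  n <- nrow(pantX)
  pp <- NA_real_
  if (nPerm > 0) {
    stopifnot(!is.null(Xtr), !is.null(ytr))
    set <- featureIndices(model)
    Ktr <- tcrossprod(Xtr[, set, drop = FALSE])
    Kp <- pantX[, set, drop = FALSE] %*% t(Xtr[, set, drop = FALSE])
    C <- 1 / mean(diag(Ktr))
    score <- function(y_perm) {
      fit <- .svm_solve_kernel(Ktr, y_perm, C, tol = 1e-6)
      mean(drop(Kp %*% (fit$alpha * y_perm)) + fit$bias >= 0)
    }
    pp <- permutationTest(frac, ytr, score, nPerm = nPerm, seed = seed)$pValue
  }
  list(fraction = frac, pPermutation = pp,
       pBinomial = binomialTest(round(frac * n), n, 0.5, "greater"), n = n)
}

#' Wilcoxon + Fisher comparison of whole-map and knocked-out classifiers
#'
#' Tests, per condition, whether excluding the knock-out voxels changed the
#' within-condition accuracy, pairing the per-subject best-fold test
#' accuracies of the whole-map and excluded classifiers in a Wilcoxon
#' signed-rank test, and aggregates the per-condition p-values with
#' Fisher's method.
#'
#' @param whole named list per condition with a `perSubject` data.frame
#'   (e.g. assembled from [nestedCV()] best models).
#' @param excluded result of [evaluateExcluding()].
#' @return list with `perCondition` (data.frame: condition, meanWhole,
#'   meanExcluded, pWilcoxon) and `pFisher`.
#' @export
knockoutComparison <- function(whole, excluded) {
  conds <- names(whole)
  rows <- lapply(conds, function(cn) {
    a <- whole[[cn]]$perSubject
    b <- excluded[[cn]]$perSubject
    if (is.null(a) || is.null(b))
      return(data.frame(condition = cn, meanWhole = NA, meanExcluded = NA,
                        pWilcoxon = NA))
    stopifnot(identical(a$subjectId, b$subjectId))
    data.frame(condition = cn, meanWhole = mean(a$accuracy),
               meanExcluded = mean(b$accuracy),
               pWilcoxon = wilcoxonSignedRank(a$accuracy, b$accuracy))
  })
  per <- do.call(rbind, rows)
  list(perCondition = per,
       pFisher = fisherCombine(per$pWilcoxon[!is.na(per$pWilcoxon)]))
}
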