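# Recursive feature elimination with 3D cluster correction, nested inside
# k-fold cross-validation, ending in best-fold selection.

#' Remove small isolated clusters from a voxel set
#'
#' Keeps the union of connected components of at least `minSize` voxels,
#' removing small isolated clusters; the output is always a subset of the
#' input. Connectivity defaults to face adjacency (6 neighbours), the
#' nearest-neighbour convention; edge and corner adjacency are available.
#'
#' @param voxels integer vector of linear voxel indices (possibly empty).
#' @param grid a \linkS4class{VoxelGrid}.
#' @param minSize minimum component size kept.
#' @param connectivity `"faces"`, `"faces+edges"` or `"faces+edges+corners"`.
#' @return sorted integer vector of surviving voxel indices.
#' @examples
#' g <- VoxelGrid(c(4, 4, 1))
#' clusterCorrect(c(1, 2, 16), g, minSize = 2)  # drops the isolated voxel
#' @export
clusterCorrect <- function(voxels, grid, minSize, connectivity = "faces") {
  stopifnot(is(grid, "VoxelGrid"), minSize >= 1)
  voxels <- sort(unique(as.integer(voxels)))
  if (!length(voxels)) return(integer(0))
  if (min(voxels) < 1L || max(voxels) > nVoxels(grid))
    stop("voxel index outside the grid")
  pairs <- .neighbour_pairs(grid, voxels, connectivity)
  inset <- integer(nVoxels(grid))
  inset[voxels] <- seq_along(voxels)
  keep <- inset[pairs[, "to"]] > 0L
  g <- igraph::make_empty_graph(n = length(voxels), directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(inset[pairs[keep, "from"]],
                                    inset[pairs[keep, "to"]]))
  comp <- igraph::components(g)
  voxels[comp$csize[comp$membership] >= minSize]
}

#' One elimination step
#'
#' Discards the `ceiling(fraction * |set|)` features with the smallest
#' absolute weights (at least one, so the elimination loop always
#' terminates; ties in `|w|` are broken by removing the lower voxel index
#' first), then applies the cluster correction. The output is a strict
#' subset of the input.
#'
#' @param weights numeric weight vector over `featureSet` (or a
#'   \linkS4class{LinearModel} trained on exactly `featureSet`).
#' @param featureSet integer voxel indices the weights refer to.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param config an \linkS4class{RFEConfig}.
#' @return sorted integer vector of surviving voxel indices.
#' @export
eliminateStep <- function(weights, featureSet, grid, config = RFEConfig()) {
  if (is(weights, "LinearModel")) {
    if (!identical(sort(weights@featureIdx), sort(as.integer(featureSet))))
      stop("model was not trained on exactly this feature set")
    featureSet <- weights@featureIdx
    weights <- weights@weights
  }
  featureSet <- as.integer(featureSet)
  if (length(weights) != length(featureSet))
    stop("one weight per feature required")
  if (!length(featureSet)) return(integer(0))
  n_rm <- max(1L, ceiling(config@eliminationFraction * length(featureSet)))
  ord <- order(abs(weights), featureSet)
  kept <- featureSet[-ord[seq_len(min(n_rm, length(featureSet)))]]
  clusterCorrect(kept, grid, config@minClusterVoxels, config@connectivity)
}

#' Run one recursive feature elimination
#'
#' Starting from `featureSet`, repeatedly: train a soft-margin linear SVM on
#' the surviving features (with the data-driven `C` recomputed from the
#' surviving-feature training submatrix), record its accuracy on the test
#' examples, then discard the lowest-|weight| features and apply the
#' cluster correction — until the feature set is empty. The recorded
#' accuracy of an iteration is measured before that iteration's
#' elimination.
#'
#' The Gram matrix of the training data is computed once and downdated by a
#' rank-r update at each elimination, so the full run costs little more
#' than a single kernel evaluation.
#'
#' @param Xtrain,Xtest numeric matrices, examples x voxels over the full
#'   grid; train and test must hold disjoint stimuli.
#' @param ytrain,ytest labels (see [svmTrain()]).
#' @param grid a \linkS4class{VoxelGrid}.
#' @param config an \linkS4class{RFEConfig}.
#' @param featureSet initial voxel set; defaults to all voxels.
#' @return an \linkS4class{RFETrace}.
#' @export
runRFE <- function(Xtrain, ytrain, Xtest, ytest, grid, config = RFEConfig(),
                   featureSet = seq_len(ncol(Xtrain))) {
  Xtrain <- as.matrix(Xtrain); Xtest <- as.matrix(Xtest)
  stopifnot(ncol(Xtrain) == ncol(Xtest), ncol(Xtrain) == nVoxels(grid))
  ytrain <- .as_y(ytrain); ytest <- .as_y(ytest)
  feats <- sort(unique(as.integer(featureSet)))
  K <- tcrossprod(Xtrain[, feats, drop = FALSE])
  Kte <- Xtest[, feats, drop = FALSE] %*% t(Xtrain[, feats, drop = FALSE])
  sets <- list(); accs <- numeric(0)
  while (length(feats) > 0L) {
    msq <- mean(diag(K))
    if (msq <= 1e-12) break  # nothing left to train on (all-zero features)
    C <- 1 / msq
    fit <- .svm_solve_kernel(K, ytrain, C, tol = config@tol)
    av <- fit$alpha * ytrain
    pred <- ifelse(drop(Kte %*% av) + fit$bias >= 0, 1, -1)
    sets[[length(sets) + 1L]] <- feats
    accs <- c(accs, mean(pred == ytest))
    w <- drop(crossprod(Xtrain[, feats, drop = FALSE], av))
    nxt <- eliminateStep(w, feats, grid, config)
    rm_idx <- setdiff(feats, nxt)
    if (length(nxt)) {
      K <- K - tcrossprod(Xtrain[, rm_idx, drop = FALSE])
      Kte <- Kte - Xtest[, rm_idx, drop = FALSE] %*%
        t(Xtrain[, rm_idx, drop = FALSE])
    }
    feats <- nxt
  }
  new("RFETrace", featureSets = sets, accuracies = accs)
}

# accuracy ties are resolved toward the most pruned model: feature-set
# sizes decrease strictly over iterations, so the last maximum is the
# smallest feature set achieving the best accuracy
.argmax_last <- function(x) max(which(x == max(x)))

# example matrix of a condition for fold f: fold-wise scaled variants
# (scalingMode = "fold") carry one matrix per fold in cd$Xfold
.cond_X <- function(cd, f) {
  if (is.null(cd$Xfold)) cd$X else cd$Xfold[[f]]
}

# bundle the per-condition matrices a cross-validated run needs
.condition_data <- function(bps, folds) {
  info <- exampleInfo(bps)
  list(X = betaMatrix(bps), y = .as_y(info$classLabel), info = info,
       foldId = foldOf(folds, info))
}

#' Assemble per-condition classification data
#'
#' Convenience bundle consumed by [nestedCV()] and the knock-out analyses:
#' the scaled example matrix, -1/+1 labels, example metadata and the fold
#' index of every example.
#'
#' @param bps a balanced, scaled \linkS4class{BetaPatternSet} of one
#'   condition.
#' @param folds a stimulus-level fold assignment from [makeFolds()].
#' @return list with elements `X`, `y`, `info`, `foldId`.
#' @export
conditionData <- function(bps, folds) {
  stopifnot(is(bps, "BetaPatternSet"))
  if (!isScaled(bps))
    warning("condition data are not tanh-scaled")
  .condition_data(bps, folds)
}

#' Nested cross-validation with recursive feature elimination
#'
#' For every fold and every condition, runs [runRFE()] with the fold's
#' training subsets and records the iteration of highest test accuracy
#' (ties resolved toward the most pruned feature set). The best fold is the one whose mean
#' best accuracy across conditions is highest; all subsequent supramodal
#' and knock-out analyses are restricted to that fold's classifiers. The
#' summary reports the mean and standard deviation of the per-fold best
#' accuracies for each condition.
#'
#' By default the best iteration is chosen per classifier; with
#' `jointIteration = TRUE` a single shared iteration index maximizing the
#' mean accuracy across conditions is used instead.
#'
#' @param condData named list of condition bundles from [conditionData()],
#'   all sharing the fold structure (fold index `f` means: test on fold `f`).
#' @param grid a \linkS4class{VoxelGrid}.
#' @param config an \linkS4class{RFEConfig}.
#' @param jointIteration select one shared RFE iteration across conditions.
#' @return list of class `"ncvResult"` with elements `foldRecords` (one
#'   record per fold: `fold`, `traces`, `best` per condition with
#'   `featureSet`, `accuracy`, `iteration`, `model`), `bestFold`, `summary`
#'   (data.frame: condition, meanAccuracy, sdAccuracy), `grid`, `config`.
#' @export
nestedCV <- function(condData, grid, config = RFEConfig(),
                     jointIteration = FALSE) {
  stopifnot(length(condData) >= 1, !is.null(names(condData)))
  k <- config@kFolds
  for (cd in condData)
    if (!all(sort(unique(cd$foldId)) == seq_len(k)))
      stop("every condition must use folds 1..", k)
  foldRecords <- vector("list", k)
  for (f in seq_len(k)) {
    traces <- lapply(condData, function(cd) {
      tr <- cd$foldId != f
      Xf <- .cond_X(cd, f)
      runRFE(Xf[tr, , drop = FALSE], cd$y[tr],
             Xf[!tr, , drop = FALSE], cd$y[!tr], grid, config)
    })
    if (jointIteration) {
      n_it <- min(vapply(traces, function(t) length(t@accuracies), 1L))
      mean_acc <- rowMeans(vapply(traces,
                                  function(t) t@accuracies[seq_len(n_it)],
                                  numeric(n_it)))
      it <- .argmax_last(mean_acc)
      best_it <- setNames(rep(it, length(traces)), names(traces))
    } else {
      best_it <- vapply(traces, function(t) .argmax_last(t@accuracies), 1L)
    }
    best <- lapply(names(traces), function(cn) {
      tr <- traces[[cn]]; it <- best_it[[cn]]
      set <- tr@featureSets[[it]]
      cd <- condData[[cn]]
      train <- cd$foldId != f
      model <- svmTrain(.cond_X(cd, f)[train, , drop = FALSE], cd$y[train],
                        featureIdx = set, tol = config@tol)
      list(featureSet = set, accuracy = tr@accuracies[it], iteration = it,
           model = model)
    })
    names(best) <- names(traces)
    foldRecords[[f]] <- list(fold = f, traces = traces, best = best,
                             meanBest = mean(vapply(best, `[[`, 0, "accuracy")))
  }
  mean_best <- vapply(foldRecords, `[[`, 0, "meanBest")
  acc_mat <- vapply(foldRecords,
                    function(fr) vapply(fr$best, `[[`, 0, "accuracy"),
                    numeric(length(condData)))
  acc_mat <- matrix(acc_mat, nrow = length(condData),
                    dimnames = list(names(condData), NULL))
  res <- list(foldRecords = foldRecords, bestFold = which.max(mean_best),
              summary = data.frame(condition = names(condData),
                                   meanAccuracy = rowMeans(acc_mat),
                                   sdAccuracy = apply(acc_mat, 1, sd),
                                   row.names = NULL),
              grid = grid, config = config)
  class(res) <- "ncvResult"
  res
}

#' @export
print.ncvResult <- function(x, ...) {
  cat(sprintf("Nested CV (%d folds), best fold: %d\n",
              x$config@kFolds, x$bestFold))
  s <- x$summary
  best <- x$foldRecords[[x$bestFold]]$best
  s$bestFoldAccuracy <- vapply(best, `[[`, 0, "accuracy")[s$condition]
  s$bestFoldVoxels <- vapply(best, function(b) length(b$featureSet),
                             1L)[s$condition]
  print(s, row.names = FALSE)
  invisible(x)
}

#' Discriminative map of a trained model
#'
#' Carries the model's weight vector over its feature set together with the
#' weights standardized to zero mean and unit variance across the set (the
#' z-scores conventionally used to colour discriminative maps); a singleton
#' set has z-weight 0.
#'
#' @param model a \linkS4class{LinearModel} with a non-empty feature set.
#' @param grid a \linkS4class{VoxelGrid}.
#' @return a \linkS4class{DiscriminativeMap}.
#' @export
makeMap <- function(model, grid) {
  stopifnot(is(model, "LinearModel"), is(grid, "VoxelGrid"))
  w <- model@weights
  if (!length(w)) stop("cannot map an empty feature set")
  z <- if (length(w) >= 2L && sd(w) > 0) (w - mean(w)) / sd(w) else rep(0, length(w))
  new("DiscriminativeMap", featureIdx = model@featureIdx, weights = w,
      zWeights = z, grid = grid)
}
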