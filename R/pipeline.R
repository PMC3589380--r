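# End-to-end experiment: balancing -> scaling -> folds -> nested CV + RFE ->
# supramodal classifier -> knock-out analyses -> pantomime classification.

#' Pipeline configuration
#'
#' Bundles every tunable of the full experiment. The defaults are the
#' desk-scale synthetic configuration: 20 examples per class per subject
#' after balancing, 4 folds, 2% elimination per iteration and a
#' grid-proportional minimum cluster size of 5 voxels suited to a 12^3
#' grid (use 150 voxels, the whole-brain convention, for real 2 mm
#' group-space data), 99 permutations. `scalingMode` `"condition"` fits the
#' tanh scaling once on each condition's full balanced matrix before fold
#' splitting (the classical preprocessing order, which leaks test-example
#' statistics into scaling and is kept for fidelity); `"fold"` refits the
#' scaling on each fold's training examples only.
#'
#' @param targetPerClass examples per class per subject after balancing.
#' @param eliminationFraction,minClusterVoxels,connectivity,kFolds,tol
#'   passed to [RFEConfig()].
#' @param nPerm permutations per accuracy test.
#' @param scalingMode `"condition"` or `"fold"`.
#' @param jointIteration see [nestedCV()].
#' @param seed master seed; all stage seeds are derived from it.
#' @return list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(targetPerClass = 20, eliminationFraction = 0.02,
                           minClusterVoxels = 5, connectivity = "faces",
                           kFolds = 4, tol = 1e-6, nPerm = 99,
                           scalingMode = c("condition", "fold"),
                           jointIteration = FALSE, seed = 1) {
  cfg <- list(targetPerClass = targetPerClass,
              rfe = RFEConfig(eliminationFraction, minClusterVoxels,
                              connectivity, kFolds, tol),
              nPerm = nPerm, scalingMode = match.arg(scalingMode),
              jointIteration = isTRUE(jointIteration),
              seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' @export
print.pipelineConfig <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat("  target per class:", x$targetPerClass, "  scaling:", x$scalingMode,
      "  nPerm:", x$nPerm, "  seed:", x$seed, "\n  ")
  show(x$rfe)
  invisible(x)
}

# balanced, scaled, fold-indexed bundle for one condition
.prepare_condition <- function(raw, folds, config, seed_bal) {
  bal <- balanceClasses(raw, config$targetPerClass, seed = seed_bal)
  info <- exampleInfo(bal)
  foldId <- foldOf(folds, info)
  y <- .as_y(info$classLabel)
  if (config$scalingMode == "condition") {
    sc <- scaleTanh(bal)
    list(X = betaMatrix(sc), y = y, info = info, foldId = foldId,
         scaler = S4Vectors::metadata(sc)$scalingStats)
  } else {
    braw <- SummarizedExperiment::assay(bal, "beta")
    Xfold <- vector("list", config$rfe@kFolds)
    scalers <- vector("list", config$rfe@kFolds)
    for (f in seq_len(config$rfe@kFolds)) {
      st <- .voxel_stats(braw[, foldId != f, drop = FALSE])
      z <- (braw - st$mean) / ifelse(st$sd > 0, st$sd, 1)
      z[st$sd == 0, ] <- 0
      Xfold[[f]] <- t(tanh(z))
      scalers[[f]] <- st
    }
    list(X = t(braw), Xfold = Xfold, y = y, info = info, foldId = foldId,
         scalerFold = scalers)
  }
}

#' Prepare all experimental conditions
#'
#' Splits a raw dataset into the three classification conditions
#' (sighted/visual, sighted/auditory, blind/auditory), balances each at the
#' stimulus level, fits the tanh scaling, and assigns stratified
#' stimulus-level folds. The auditory stimulus set receives a single fold
#' assignment shared by the sighted and blind auditory conditions, so a
#' sound is never simultaneously a training stimulus in one group and a
#' test stimulus in the other during cross-group evaluation.
#'
#' @param dataset an unscaled \linkS4class{BetaPatternSet} covering all
#'   conditions (e.g. from [generateExamples()] or [readDataset()]).
#' @param config a [pipelineConfig()].
#' @return named list of condition bundles (see [conditionData()]), with
#'   the fold tables in `attr(, "folds")`.
#' @export
prepareConditions <- function(dataset, config = pipelineConfig()) {
  stopifnot(is(dataset, "BetaPatternSet"))
  if (isScaled(dataset))
    stop("prepareConditions() expects unscaled beta patterns")
  seed <- config$seed
  raw <- list(
    sighted_visual = subsetCondition(dataset, "sighted", "visual"),
    sighted_auditory = subsetCondition(dataset, "sighted", "auditory"),
    blind_auditory = subsetCondition(dataset, "blind", "auditory"))
  aud_info <- exampleInfo(raw$sighted_auditory)
  vis_info <- exampleInfo(raw$sighted_visual)
  folds <- list(
    auditory = makeFolds(aud_info$stimulusId, aud_info$classLabel,
                         k = config$rfe@kFolds, seed = seed + 21L),
    visual = makeFolds(vis_info$stimulusId, vis_info$classLabel,
                       k = config$rfe@kFolds, seed = seed + 22L))
  cond <- list(
    sighted_visual = .prepare_condition(raw$sighted_visual, folds$visual,
                                        config, seed + 11L),
    sighted_auditory = .prepare_condition(raw$sighted_auditory,
                                          folds$auditory, config, seed + 12L),
    blind_auditory = .prepare_condition(raw$blind_auditory, folds$auditory,
                                        config, seed + 13L))
  attr(cond, "folds") <- folds
  cond
}

#' Fit the nested-CV RFE classifiers
#'
#' Runs balancing, scaling, fold assignment and the nested cross-validated
#' recursive feature elimination for the three conditions.
#'
#' @inheritParams prepareConditions
#' @return list of class `"supraFit"` with `conditions`, `ncv`, `grid`,
#'   `config`.
#' @export
runFit <- function(dataset, config = pipelineConfig()) {
  grid <- voxelGrid(dataset)
  cond <- prepareConditions(dataset, config)
  ncv <- nestedCV(cond, grid, config$rfe,
                  jointIteration = config$jointIteration)
  out <- list(conditions = cond, ncv = ncv, grid = grid, config = config)
  class(out) <- "supraFit"
  out
}

# pantomime examples of one group (optionally one session) scaled with a
# condition's fitted statistics
.scaled_pantomimes <- function(dataset, group, cond, bestFold,
                               session = NULL) {
  pant <- pantomimeSet(dataset, group)
  if (!is.null(session)) {
    keep <- exampleInfo(pant)$session == session
    if (!any(keep)) stop("no pantomimes for session ", session)
    pant <- pant[, keep]
  }
  st <- if (!is.null(cond$scaler)) cond$scaler else cond$scalerFold[[bestFold]]
  b <- SummarizedExperiment::assay(pant, "beta")
  z <- (b - st$mean) / ifelse(st$sd > 0, st$sd, 1)
  z[st$sd == 0, ] <- 0
  t(tanh(z))
}

# pantomime classification rows for a set of models under one variant label
.pantomime_rows <- function(variant, models, dataset, cond, bestFold,
                            nPerm, seed, groups = c("sighted", "blind")) {
  rows <- list(); i <- 0L
  for (cn in names(models)) {
    model <- models[[cn]]
    if (is.null(model)) next
    sp <- .fold_split(cond[[cn]], bestFold)
    for (grp in groups) {
      i <- i + 1L
      px <- .scaled_pantomimes(dataset, grp, cond[[cn]], bestFold)
      res <- classifyPantomime(model, px, sp$Xtr, sp$ytr, nPerm = nPerm,
                               seed = if (is.null(seed)) NULL else seed + i)
      rows[[length(rows) + 1L]] <-
        data.frame(variant = variant, classifier = cn, pantomimeGroup = grp,
                   fraction = res$fraction, pPermutation = res$pPermutation,
                   pBinomial = res$pBinomial, n = res$n)
    }
  }
  do.call(rbind, rows)
}

#' Run the supramodal and knock-out analyses
#'
#' Starting from a fitted nested CV, trains the combined supramodal
#' classifier on the best fold's pooled training data, derives the
#' knock-out mask, and produces the three accuracy-table variants
#' (whole-map, after exclusion of the knock-out voxels, restricted to the
#' knock-out voxels), the Wilcoxon + Fisher comparison of whole-map versus
#' excluded within-condition accuracies, and the motor-pantomime
#' classification under all three variants plus the supramodal classifier
#' itself.
#'
#' @param fit a `"supraFit"` from [runFit()].
#' @param dataset the raw dataset the fit was computed from (needed for the
#'   pantomime examples).
#' @return list of class `"supraResult"`; see the fields of the individual
#'   stage functions.
#' @export
runKnockout <- function(fit, dataset) {
  stopifnot(inherits(fit, "supraFit"))
  config <- fit$config; grid <- fit$grid
  cond <- fit$conditions; ncv <- fit$ncv
  f <- ncv$bestFold
  nPerm <- config$nPerm; seed <- config$seed

  supra <- trainSupramodal(cond, f, grid, config$rfe)
  splits <- lapply(cond, .fold_split, f = f)
  supra$pPermutation <- .perm_accuracy_p(
    do.call(rbind, lapply(splits, `[[`, "Xtr")),
    unlist(lapply(splits, `[[`, "ytr"), use.names = FALSE),
    do.call(rbind, lapply(splits, `[[`, "Xte")),
    unlist(lapply(splits, `[[`, "yte"), use.names = FALSE),
    supra$featureSet, supra$accuracy, nPerm, seed + 90L,
    config$rfe@tol)$pValue
  ko <- knockoutMask(supra)

  best <- ncv$foldRecords[[f]]$best
  whole_models <- lapply(best, `[[`, "model")
  whole <- lapply(names(cond), function(cn)
    list(accuracy = best[[cn]]$accuracy,
         perSubject = .per_subject_accuracy(whole_models[[cn]], cond[[cn]], f)))
  names(whole) <- names(cond)

  tab_whole <- accuracyTable(whole_models, cond, f, nPerm, seed + 100L)
  excl <- evaluateExcluding(ncv, cond, ko, grid, config$rfe, nPerm = 0)
  excl_models <- lapply(excl, `[[`, "model")
  tab_excl <- accuracyTable(excl_models[!vapply(excl_models, is.null, TRUE)],
                            cond, f, nPerm, seed + 200L)
  restr <- evaluateRestricted(cond, f, ko, config$rfe, nPerm, seed + 300L)
  ko_test <- knockoutComparison(whole, excl)

  pant <- rbind(
    .pantomime_rows("whole_map", whole_models, dataset, cond, f, nPerm,
                    seed + 400L),
    .pantomime_rows("excluded", excl_models, dataset, cond, f, nPerm,
                    seed + 500L),
    .pantomime_rows("restricted", restr$models, dataset, cond, f, nPerm,
                    seed + 600L))
  # the combined classifier itself, on the sighted pantomimes by session
  sp_all <- list(
    Xtr = do.call(rbind, lapply(splits, `[[`, "Xtr")),
    ytr = unlist(lapply(splits, `[[`, "ytr"), use.names = FALSE))
  i <- 0L
  for (ss in c("visual", "auditory")) {
    i <- i + 1L
    ref_cond <- if (ss == "visual") cond$sighted_visual else cond$sighted_auditory
    px <- .scaled_pantomimes(dataset, "sighted", ref_cond, f, session = ss)
    res <- classifyPantomime(supra$model, px, sp_all$Xtr, sp_all$ytr,
                             nPerm = nPerm, seed = seed + 700L + i)
    pant <- rbind(pant, data.frame(
      variant = paste0("supramodal_", ss, "_session"),
      classifier = "supramodal", pantomimeGroup = "sighted",
      fraction = res$fraction, pPermutation = res$pPermutation,
      pBinomial = res$pBinomial, n = res$n))
  }

  out <- list(ncv = ncv, bestFold = f, supramodal = supra, knockout = ko,
              tables = list(whole_map = tab_whole, excluded = tab_excl,
                            restricted = restr$table),
              excluded = excl, restricted = restr,
              knockoutTest = ko_test, pantomime = pant,
              grid = grid, config = config)
  class(out) <- "supraResult"
  out
}

#' Run the complete pipeline
#'
#' [runFit()] followed by [runKnockout()].
#'
#' @inheritParams prepareConditions
#' @return a `"supraResult"`, with the fit stored in `$fit`.
#' @export
runPipeline <- function(dataset, config = pipelineConfig()) {
  fit <- runFit(dataset, config)
  res <- runKnockout(fit, dataset)
  res$fit <- fit
  res
}

#' @export
print.supraResult <- function(x, ...) {
  cat("Supramodal MVPA result (best fold:", x$bestFold, ")\n\n")
  cat("Within/across accuracy, whole map:\n")
  print(x$tables$whole_map, row.names = FALSE, digits = 3)
  cat(sprintf("\nSupramodal classifier: accuracy %.3f (p = %.4g), %d voxels\n",
              x$supramodal$accuracy, x$supramodal$pPermutation,
              length(x$knockout)))
  cat(sprintf("Knock-out exclusion, Wilcoxon + Fisher p = %.4g\n",
              x$knockoutTest$pFisher))
  invisible(x)
}
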