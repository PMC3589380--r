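# Assembly: turn raw beta examples into balanced, scaled, fold-assigned
# classification matrices, one per experimental condition.

#' Extract one experimental condition
#'
#' @param x a \linkS4class{BetaPatternSet}.
#' @param group `"sighted"` or `"blind"`.
#' @param modality `"auditory"` or `"visual"`; the (blind, visual) pair is
#'   invalid because blind subjects receive no visual stimuli.
#' @return `subsetCondition()` returns the action/non-action examples of the
#'   condition; `pantomimeSet()` returns the motor-pantomime examples of a
#'   group (both sessions).
#' @export
subsetCondition <- function(x, group, modality) {
  stopifnot(is(x, "BetaPatternSet"))
  group <- match.arg(group, .GROUP_LEVELS)
  modality <- match.arg(modality, c("auditory", "visual"))
  if (group == "blind" && modality == "visual")
    stop("the (blind, visual) condition does not exist: ",
         "blind subjects have no visual stimuli")
  cd <- SummarizedExperiment::colData(x)
  keep <- cd$group == group & cd$modality == modality &
    cd$classLabel != "pantomime"
  if (!any(keep)) stop("no examples for condition ", group, "/", modality)
  x[, keep]
}

#' @rdname subsetCondition
#' @export
pantomimeSet <- function(x, group) {
  stopifnot(is(x, "BetaPatternSet"))
  group <- match.arg(group, .GROUP_LEVELS)
  cd <- SummarizedExperiment::colData(x)
  keep <- cd$group == group & cd$classLabel == "pantomime"
  if (!any(keep)) stop("no pantomime examples for group ", group)
  x[, keep]
}

#' Balance classes by stimulus-level up/down-sampling
#'
#' Equalizes the per-subject class counts of one condition at
#' `targetPerClass` examples per class: a class with too few stimuli is
#' upsampled by duplicating stimuli chosen uniformly at random without
#' replacement until the target is reached (exact doubling is the special
#' case of a class at half the target), and a class with too many stimuli is
#' downsampled to a random subset. Both choices are made once at the
#' stimulus level and applied identically to every subject of the condition,
#' so a stimulus is either present (or duplicated) for all subjects or for
#' none. Duplicated examples carry `duplicateOf` pointing at their original
#' and a derived `stimulusId` (`<original>_dup<k>`).
#'
#' Balancing never changes the voxel dimension, and equal class counts make
#' the chance level of the downstream classifier exactly 50%.
#'
#' @param x a \linkS4class{BetaPatternSet} holding a single condition (one
#'   group, one perceptual modality, no pantomimes).
#' @param targetPerClass examples per class per subject after balancing.
#' @param seed integer seed or `NULL`.
#' @return a balanced \linkS4class{BetaPatternSet}; the input is returned
#'   unchanged when both classes already sit at the target.
#' @export
balanceClasses <- function(x, targetPerClass = 20, seed = NULL) {
  stopifnot(is(x, "BetaPatternSet"), targetPerClass >= 1)
  info <- exampleInfo(x)
  if (any(info$classLabel == "pantomime"))
    stop("pantomime examples cannot be balanced: they are test-only")
  if (length(unique(info$modality)) != 1L || length(unique(info$group)) != 1L)
    stop("balanceClasses() expects a single condition")
  if (any(!is.na(info$duplicateOf)))
    stop("input already contains upsampled duplicates")
  ids <- lapply(c(action = "action", non_action = "non_action"), function(cl)
    unique(info$stimulusId[info$classLabel == cl]))
  if (any(lengths(ids) == 0L))
    stop("both classes must be present")
  if (all(lengths(ids) == targetPerClass)) return(x)

  .with_seed(seed, function() {
    keep_cols <- rep(TRUE, ncol(x))
    dup_cols <- integer(0); dup_of <- character(0); dup_id <- character(0)
    for (cl in names(ids)) {
      cl_ids <- ids[[cl]]
      n <- length(cl_ids)
      if (n > targetPerClass) {
        kept <- sample(cl_ids, targetPerClass)
        keep_cols[info$stimulusId %in% setdiff(cl_ids, kept)] <- FALSE
      } else if (n < targetPerClass) {
        deficit <- targetPerClass - n
        pool <- character(0); round <- 0L
        while (length(pool) < deficit) {  # whole rounds, then a random subset
          take <- min(deficit - length(pool), n)
          pool <- c(pool, sample(cl_ids, take))
          round <- round + 1L
        }
        dup_round <- stats::ave(seq_along(pool), pool, FUN = seq_along)
        for (d in seq_along(pool)) {
          cols <- which(info$stimulusId == pool[d])
          dup_cols <- c(dup_cols, cols)
          dup_of <- c(dup_of, rep(pool[d], length(cols)))
          dup_id <- c(dup_id, rep(sprintf("%s_dup%d", pool[d], dup_round[d]),
                                  length(cols)))
        }
      }
    }
    beta <- SummarizedExperiment::assay(x, "beta")
    new_beta <- cbind(beta[, keep_cols, drop = FALSE],
                      beta[, dup_cols, drop = FALSE])
    new_info <- rbind(info[keep_cols, , drop = FALSE],
                      within(info[dup_cols, , drop = FALSE], {
                        duplicateOf <- dup_of
                        stimulusId <- dup_id
                      }))
    out <- BetaPatternSet(new_beta, new_info, voxelGrid(x), scaled = isScaled(x))
    chk <- table(exampleInfo(out)$subjectId, exampleInfo(out)$classLabel)
    stopifnot(all(chk == targetPerClass))
    out
  })
}

# per-voxel mean/sd of a beta assay (sample sd; NA-free input)
.voxel_stats <- function(beta) {
  n <- ncol(beta)
  m <- rowMeans(beta)
  s2 <- if (n > 1) (rowSums(beta^2) - n * m^2) / (n - 1) else rep(0, nrow(beta))
  s2[s2 < 0] <- 0
  list(mean = m, sd = sqrt(s2))
}

#' Hyperbolic-tangent scaling of beta patterns
#'
#' Standardizes every voxel across examples (subtract the voxel mean, divide
#' by the voxel standard deviation) and applies an elementwise hyperbolic
#' tangent, bringing all response magnitudes strictly into (-1, +1) while
#' preserving the per-voxel rank order of examples and damping outliers.
#' Zero-variance voxels map to 0. Double scaling is refused.
#'
#' The fitted per-voxel statistics are stored in `metadata()$scalingStats`;
#' pass them back via `stats` to scale held-out examples (e.g. motor
#' pantomimes) consistently with a training condition.
#'
#' @param x an unscaled \linkS4class{BetaPatternSet}.
#' @param stats optional list with `mean` and `sd` per voxel, as produced by
#'   a previous `scaleTanh()` run; when supplied these statistics are used
#'   instead of refitting.
#' @return a scaled \linkS4class{BetaPatternSet}.
#' @export
scaleTanh <- function(x, stats = NULL) {
  stopifnot(is(x, "BetaPatternSet"))
  if (isScaled(x)) stop("input is already scaled; double scaling is forbidden")
  beta <- SummarizedExperiment::assay(x, "beta")
  if (is.null(stats)) stats <- .voxel_stats(beta)
  stopifnot(length(stats$mean) == nrow(beta), length(stats$sd) == nrow(beta))
  z <- (beta - stats$mean) / ifelse(stats$sd > 0, stats$sd, 1)
  z[stats$sd == 0, ] <- 0
  out <- BetaPatternSet(tanh(z), exampleInfo(x), voxelGrid(x), scaled = TRUE)
  S4Vectors::metadata(out)$scalingStats <- stats
  out
}

#' Stratified stimulus-level fold assignment
#'
#' Splits the stimuli of a condition into `k` subsets stratified by class:
#' within each class the per-fold counts differ by at most one. The fold
#' unit is the stimulus, not the example, so an example set pooled across
#' subjects never has the same stimulus on both sides of a fold, and
#' upsampled duplicates inherit the fold of their original (see [foldOf()]).
#'
#' @param stimulusIds character vector of stimulus ids (duplicates and
#'   repeated ids are collapsed; ids of upsampled copies are resolved to
#'   their originals by the caller).
#' @param classLabels class label per entry of `stimulusIds`.
#' @param k number of folds.
#' @param seed integer seed or `NULL`.
#' @return a data.frame with columns `stimulusId`, `classLabel`, `fold`.
#' @export
makeFolds <- function(stimulusIds, classLabels, k = 4, seed = NULL) {
  df <- unique(data.frame(stimulusId = as.character(stimulusIds),
                          classLabel = as.character(classLabels),
                          stringsAsFactors = FALSE))
  if (anyDuplicated(df$stimulusId))
    stop("a stimulus id appears with two different class labels")
  .with_seed(seed, function() {
    out <- lapply(split(df, df$classLabel), function(d) {
      n <- nrow(d)
      if (n < k) stop("fewer stimuli (", n, ") than folds (", k,
                      ") in class ", d$classLabel[1])
      d$fold <- sample(rep(seq_len(k), length.out = n))
      d
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Fold index of each example
#'
#' Maps the examples of a balanced set onto a stimulus-level fold
#' assignment; upsampled duplicates take their original's fold.
#'
#' @param folds a fold assignment from [makeFolds()].
#' @param info example metadata (a data.frame with `stimulusId` and
#'   `duplicateOf`), or a \linkS4class{BetaPatternSet}.
#' @return integer fold index per example.
#' @export
foldOf <- function(folds, info) {
  if (is(info, "BetaPatternSet")) info <- exampleInfo(info)
  sid <- ifelse(is.na(info$duplicateOf), info$stimulusId, info$duplicateOf)
  m <- match(sid, folds$stimulusId)
  if (anyNA(m))
    stop("stimuli without a fold assignment: ",
         paste(unique(sid[is.na(m)]), collapse = ", "))
  folds$fold[m]
}
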