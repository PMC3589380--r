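#' @name supraMVPA-accessors
#' @title Accessors for supraMVPA classes
#' @param x,object an object of the documented class.
#' @param ... further arguments (unused).
NULL

#' @rdname supraMVPA-accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("betaMatrix", function(x) standardGeneric("betaMatrix"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("exampleInfo", function(x) standardGeneric("exampleInfo"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("informativeSets", function(x) standardGeneric("informativeSets"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("effectSizes", function(x) standardGeneric("effectSizes"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("featureIndices", function(x) standardGeneric("featureIndices"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("mapWeights", function(x) standardGeneric("mapWeights"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("mapZWeights", function(x) standardGeneric("mapZWeights"))

#' @rdname supraMVPA-accessors
#' @export
setGeneric("traceTable", function(x) standardGeneric("traceTable"))

#' @rdname supraMVPA-accessors
#' @export
setMethod("nVoxels", "VoxelGrid", function(x) prod(x@dims))

#' @rdname supraMVPA-accessors
#' @export
setMethod("nVoxels", "BetaPatternSet", function(x) nrow(x))

#' @rdname supraMVPA-accessors
#' @export
setMethod("voxelGrid", "BetaPatternSet",
          function(x) S4Vectors::metadata(x)$grid)

#' @rdname supraMVPA-accessors
#' @export
setMethod("voxelGrid", "GroundTruth", function(x) x@grid)

#' @rdname supraMVPA-accessors
#' @export
setMethod("voxelGrid", "DiscriminativeMap", function(x) x@grid)

#' @describeIn supraMVPA-accessors beta patterns as an examples x voxels
#'   matrix (the orientation classifiers consume).
#' @export
setMethod("betaMatrix", "BetaPatternSet",
          function(x) t(SummarizedExperiment::assay(x, "beta")))

#' @rdname supraMVPA-accessors
#' @export
setMethod("exampleInfo", "BetaPatternSet",
          function(x) as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname supraMVPA-accessors
#' @export
setMethod("isScaled", "BetaPatternSet",
          function(x) isTRUE(S4Vectors::metadata(x)$scaled))

#' @describeIn supraMVPA-accessors named list of the ground-truth voxel sets.
#' @export
setMethod("informativeSets", "GroundTruth", function(x) x@sets)

#' @rdname supraMVPA-accessors
#' @export
setMethod("effectSizes", "GroundTruth", function(x) x@effectSize)

#' @rdname supraMVPA-accessors
#' @export
setMethod("featureIndices", "LinearModel", function(x) x@featureIdx)

#' @rdname supraMVPA-accessors
#' @export
setMethod("featureIndices", "DiscriminativeMap", function(x) x@featureIdx)

#' @rdname supraMVPA-accessors
#' @export
setMethod("mapWeights", "DiscriminativeMap", function(x) x@weights)

#' @rdname supraMVPA-accessors
#' @export
setMethod("mapZWeights", "DiscriminativeMap", function(x) x@zWeights)

#' @describeIn supraMVPA-accessors per-iteration summary of an RFE run as a
#'   data.frame with columns `iteration`, `nFeatures`, `accuracy`.
#' @export
setMethod("traceTable", "RFETrace", function(x) {
  data.frame(iteration = seq_along(x@accuracies),
             nFeatures = lengths(x@featureSets),
             accuracy = x@accuracies)
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels (%g x %g x %g mm)\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth on", paste(object@grid@dims, collapse = " x "), "grid\n")
  for (nm in names(object@sets))
    cat(sprintf("  %-8s %3d voxels, effect %.3g\n", nm,
                length(object@sets[[nm]]), object@effectSize[[nm]]))
})

setMethod("show", "BetaPatternSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("BetaPatternSet: %d examples x %d voxels (%s)\n",
              ncol(object), nrow(object),
              if (isScaled(object)) "tanh-scaled" else "unscaled"))
  tab <- table(paste(cd$group, cd$modality), cd$classLabel)
  print(tab)
  invisible(object)
})

setMethod("show", "LinearModel", function(object) {
  cat(sprintf("LinearModel: %d features, C = %.4g, bias = %.4g, objective = %.4g\n",
              length(object@weights), object@cParam, object@bias,
              object@objective))
})

setMethod("show", "RFETrace", function(object) {
  n <- length(object@accuracies)
  cat(sprintf("RFETrace: %d iterations, %d -> %d features, best accuracy %.3f\n",
              n, if (n) length(object@featureSets[[1]]) else 0L,
              if (n) length(object@featureSets[[n]]) else 0L,
              if (n) max(object@accuracies) else NA_real_))
})

setMethod("show", "DiscriminativeMap", function(object) {
  cat(sprintf("DiscriminativeMap: %d voxels on %s grid, |w| in [%.3g, %.3g]\n",
              length(object@featureIdx),
              paste(object@grid@dims, collapse = " x "),
              min(abs(object@weights)), max(abs(object@weights))))
})

setMethod("show", "DesignSpec", function(object) {
  cat(sprintf(paste0(
    "DesignSpec: %d sighted + %d blind subjects\n",
    "  sounds: %d action / %d non-action; videos: %d action / %d non-action\n",
    "  pantomime: %d per subject per session; noise sd %.3g, subject offset sd %.3g\n"),
    object@nSighted, object@nBlind, object@nActionSounds,
    object@nNonactionSounds, object@nActionVideos, object@nNonactionVideos,
    object@nPantomime, object@noiseSd, object@subjectOffsetSd))
})

setMethod("show", "RFEConfig", function(object) {
  cat(sprintf(
    "RFEConfig: eliminate %.3g%%/iteration, cluster >= %d voxels (%s), %d folds\n",
    100 * object@eliminationFraction, object@minClusterVoxels,
    object@connectivity, object@kFolds))
})
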