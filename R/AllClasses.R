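#' Voxel grid geometry
#'
#' A rectangular 3D voxel grid. Voxels are addressed either by integer
#' coordinates `(x, y, z)` with `x` varying fastest, or by the corresponding
#' 1-based linear index, with a bijective mapping between the two.
#'
#' @slot dims integer triple `(nx, ny, nz)`, all at least 1.
#' @slot voxelSize positive real triple, voxel edge lengths in millimetres.
#'   Defaults to isometric 2 mm voxels, the resampling convention used for
#'   group-level pattern analyses.
#' @export
setClass("VoxelGrid",
  representation(dims = "integer", voxelSize = "numeric"),
  validity = function(object) {
    if (length(object@dims) != 3L || any(is.na(object@dims)) || any(object@dims < 1L))
      return("dims must be three integers >= 1")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      return("voxelSize must be three positive reals")
    TRUE
  }
)

#' @param dims integer triple `(nx, ny, nz)`.
#' @param voxelSize voxel edge lengths in mm.
#' @return `VoxelGrid()` returns a validated \linkS4class{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(c(12, 12, 12))
#' nVoxels(g)
#' @rdname VoxelGrid-class
#' @export
VoxelGrid <- function(dims, voxelSize = c(2, 2, 2)) {
  new("VoxelGrid", dims = as.integer(dims), voxelSize = as.numeric(voxelSize))
}

#' Ground truth of a synthetic dataset
#'
#' The informative voxel sets planted by the synthetic generator: a shared
#' (supramodal) set carrying the action/non-action contrast in every
#' modality, plus auditory-only, visual-only and motor-only sets. Sets are
#' pairwise disjoint unions of face-connected components. Per-set effect
#' sizes give the mean beta difference (action minus non-action, in BOLD
#' units) at member voxels.
#'
#' @slot sets named list (`shared`, `auditory`, `visual`, `motor`) of sorted
#'   integer voxel indices.
#' @slot effectSize named numeric, one effect per set.
#' @slot clusterSpec named list of component sizes as requested.
#' @slot grid the \linkS4class{VoxelGrid} the indices refer to.
#' @export
setClass("GroundTruth",
  representation(sets = "list", effectSize = "numeric",
                 clusterSpec = "list", grid = "VoxelGrid"),
  validity = function(object) {
    nm <- c("shared", "auditory", "visual", "motor")
    if (!identical(names(object@sets), nm))
      return("sets must be named shared/auditory/visual/motor")
    if (!all(nm %in% names(object@effectSize)))
      return("effectSize must be named for every set")
    idx <- unlist(object@sets, use.names = FALSE)
    if (anyDuplicated(idx)) return("informative sets must be pairwise disjoint")
    nv <- prod(object@grid@dims)
    if (length(idx) && (min(idx) < 1L || max(idx) > nv))
      return("voxel indices outside the grid")
    TRUE
  }
)

#' Set of labelled beta patterns
#'
#' The central data container: a [SummarizedExperiment::SummarizedExperiment]
#' whose single `"beta"` assay holds one per-stimulus beta pattern per column
#' (voxels in rows), with example metadata as column data (`classLabel`,
#' `modality`, `group`, `subjectId`, `stimulusId`, `duplicateOf`, `session`)
#' and the \linkS4class{VoxelGrid} plus scaling state in `metadata()`.
#'
#' Invariants enforced by the validity method: all values finite; pantomime
#' examples are exactly the motor-modality examples; `duplicateOf` is set
#' only on upsampled copies; once scaled, every value lies strictly in
#' (-1, 1).
#'
#' @export
setClass("BetaPatternSet", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
      return("assay 'beta' is required")
    need <- c("classLabel", "modality", "group", "subjectId", "stimulusId",
              "duplicateOf", "session")
    cd <- SummarizedExperiment::colData(object)
    if (!all(need %in% colnames(cd)))
      return(paste("missing colData columns:",
                   paste(setdiff(need, colnames(cd)), collapse = ", ")))
    if (!all(cd$classLabel %in% .CLASS_LEVELS)) return("unknown class label")
    if (!all(cd$modality %in% .MODALITY_LEVELS)) return("unknown modality")
    if (!all(cd$group %in% .GROUP_LEVELS)) return("unknown group")
    if (!identical(cd$classLabel == "pantomime", cd$modality == "motor"))
      return("pantomime examples must be exactly the motor-modality examples")
    b <- SummarizedExperiment::assay(object, "beta")
    if (!all(is.finite(b))) return("beta values must be finite")
    md <- S4Vectors::metadata(object)
    if (!is(md$grid, "VoxelGrid")) return("metadata()$grid must be a VoxelGrid")
    if (nrow(b) != prod(md$grid@dims))
      return("number of rows must equal the number of grid voxels")
    if (isTRUE(md$scaled) && nrow(b) > 0 && ncol(b) > 0 && max(abs(b)) >= 1)
      return("scaled values must lie strictly in (-1, 1)")
    TRUE
  }
)

#' @param beta numeric matrix, voxels x examples.
#' @param info data.frame of example metadata with columns `classLabel`,
#'   `modality`, `group`, `subjectId`, `stimulusId` and optionally
#'   `duplicateOf` (NA unless the example is an upsampled copy) and
#'   `session` (defaults to the modality; pantomime examples record the
#'   session type they were interleaved with).
#' @param grid a \linkS4class{VoxelGrid}.
#' @param scaled logical, whether `beta` already holds tanh-scaled values.
#' @return `BetaPatternSet()` returns a validated \linkS4class{BetaPatternSet}.
#' @rdname BetaPatternSet-class
#' @export
BetaPatternSet <- function(beta, info, grid, scaled = FALSE) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  if (is.null(info$duplicateOf)) info$duplicateOf <- NA_character_
  if (is.null(info$session)) info$session <- info$modality
  core <- c("classLabel", "modality", "group", "subjectId", "stimulusId",
            "duplicateOf", "session")
  info <- info[, c(core, setdiff(names(info), core)), drop = FALSE]
  beta <- as.matrix(beta)
  if (ncol(beta) != nrow(info))
    stop("ncol(beta) must equal nrow(info)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    colData = S4Vectors::DataFrame(info),
    metadata = list(grid = grid, scaled = isTRUE(scaled))
  )
  new("BetaPatternSet", se)
}

#' Trained soft-margin linear classifier
#'
#' Weight vector, bias and regularization constant of a binary linear SVM,
#' i.e. the minimizer of `1/2 ||w||^2 + C * sum_i hinge(1 - y_i (w x_i + b))`.
#' The decision value of an example `x` restricted to `featureIdx` is
#' `w . x + b`; positive decision values are labelled `+1` ("action"), and a
#' decision value of exactly zero resolves to `+1`.
#'
#' @slot weights numeric weight vector over the feature set.
#' @slot bias numeric scalar.
#' @slot cParam positive regularization constant C.
#' @slot objective value of the primal objective at the solution.
#' @slot featureIdx integer voxel indices the model was trained on.
#' @export
setClass("LinearModel",
  representation(weights = "numeric", bias = "numeric", cParam = "numeric",
                 objective = "numeric", featureIdx = "integer"),
  validity = function(object) {
    if (length(object@weights) != length(object@featureIdx))
      return("weights and featureIdx must have equal length")
    if (length(object@bias) != 1L || !is.finite(object@bias))
      return("bias must be a finite scalar")
    if (length(object@cParam) != 1L || !(object@cParam > 0))
      return("cParam must be a positive scalar")
    TRUE
  }
)

#' Trace of one recursive feature elimination run
#'
#' Ordered per-iteration record of the surviving voxel set and the test
#' accuracy of the classifier trained on it. Feature-set sizes decrease
#' strictly; the run terminates when elimination (with cluster correction)
#' empties the set.
#'
#' @slot featureSets list of integer voxel-index vectors, one per iteration.
#' @slot accuracies numeric test accuracies in `[0, 1]`, one per iteration.
#' @export
setClass("RFETrace",
  representation(featureSets = "list", accuracies = "numeric"),
  validity = function(object) {
    ns <- lengths(object@featureSets)
    if (length(ns) != length(object@accuracies))
      return("one accuracy per iteration required")
    if (length(ns) > 1 && any(diff(ns) >= 0))
      return("feature-set sizes must be strictly decreasing")
    if (length(object@accuracies) &&
        (any(!is.finite(object@accuracies)) ||
         any(object@accuracies < 0 | object@accuracies > 1)))
      return("accuracies must be finite and in [0, 1]")
    TRUE
  }
)

#' Discriminative map of a trained classifier
#'
#' A selected voxel subset with its SVM weights and the weights standardized
#' to zero mean and unit variance over the set (z-scores, as conventionally
#' displayed on discriminative maps). A singleton set has z-weight 0.
#'
#' @slot featureIdx integer voxel indices.
#' @slot weights numeric weights per voxel.
#' @slot zWeights standardized weights per voxel.
#' @slot grid the \linkS4class{VoxelGrid}.
#' @export
setClass("DiscriminativeMap",
  representation(featureIdx = "integer", weights = "numeric",
                 zWeights = "numeric", grid = "VoxelGrid"),
  validity = function(object) {
    k <- length(object@featureIdx)
    if (k == 0L) return("feature set must be non-empty")
    if (length(object@weights) != k || length(object@zWeights) != k)
      return("weights, zWeights and featureIdx must have equal length")
    if (k >= 2L) {
      if (abs(mean(object@zWeights)) > 1e-6) return("zWeights must have mean 0")
      if (sd(object@zWeights) > 0 && abs(sd(object@zWeights) - 1) > 1e-6)
        return("zWeights must have unit standard deviation")
    }
    TRUE
  }
)

#' Study design of the synthetic generator
#'
#' Counts and noise levels emulating a sighted/blind by auditory/visual
#' action decoding study: 14 sighted and 8 blind subjects; 20 action and 10
#' non-action sound samples heard by every subject; 23 action and 11
#' non-action videos seen by the sighted subjects only; 10 motor-pantomime
#' trials per subject per session type (auditory sessions for everyone,
#' visual sessions for the sighted). Blind subjects receive no visual
#' stimuli.
#'
#' @slot nSighted,nBlind subject counts.
#' @slot nActionSounds,nNonactionSounds auditory stimulus counts.
#' @slot nActionVideos,nNonactionVideos visual stimulus counts (sighted only).
#' @slot nPantomime pantomime trials per subject per session type.
#' @slot noiseSd standard deviation of the additive Gaussian voxel noise.
#' @slot subjectOffsetSd standard deviation of the per-subject scalar offset
#'   added to all voxels.
#' @export
setClass("DesignSpec",
  representation(nSighted = "integer", nBlind = "integer",
                 nActionSounds = "integer", nNonactionSounds = "integer",
                 nActionVideos = "integer", nNonactionVideos = "integer",
                 nPantomime = "integer", noiseSd = "numeric",
                 subjectOffsetSd = "numeric"),
  validity = function(object) {
    cnt <- c(object@nSighted, object@nBlind, object@nActionSounds,
             object@nNonactionSounds, object@nActionVideos,
             object@nNonactionVideos, object@nPantomime)
    if (any(is.na(cnt)) || any(cnt < 0L)) return("all counts must be >= 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@subjectOffsetSd < 0) return("subjectOffsetSd must be >= 0")
    TRUE
  }
)

#' @param nSighted,nBlind,nActionSounds,nNonactionSounds,nActionVideos,nNonactionVideos,nPantomime
#'   design counts, see slots.
#' @param noiseSd,subjectOffsetSd noise levels, see slots.
#' @return `DesignSpec()` returns a validated \linkS4class{DesignSpec}.
#' @rdname DesignSpec-class
#' @export
DesignSpec <- function(nSighted = 14, nBlind = 8, nActionSounds = 20,
                       nNonactionSounds = 10, nActionVideos = 23,
                       nNonactionVideos = 11, nPantomime = 10,
                       noiseSd = 0.5, subjectOffsetSd = 0.3) {
  new("DesignSpec", nSighted = as.integer(nSighted), nBlind = as.integer(nBlind),
      nActionSounds = as.integer(nActionSounds),
      nNonactionSounds = as.integer(nNonactionSounds),
      nActionVideos = as.integer(nActionVideos),
      nNonactionVideos = as.integer(nNonactionVideos),
      nPantomime = as.integer(nPantomime),
      noiseSd = noiseSd, subjectOffsetSd = subjectOffsetSd)
}

#' Recursive feature elimination settings
#'
#' @slot eliminationFraction fraction of surviving features discarded per
#'   iteration (lowest absolute weights first); at least one feature is
#'   always removed so the loop terminates.
#' @slot minClusterVoxels minimum connected-component size kept by the
#'   cluster correction. The whole-brain convention is 150 voxels (1200 uL
#'   of isometric 2 mm voxels); desk-scale synthetic grids use a
#'   grid-proportional value instead (see [pipelineConfig()]).
#' @slot connectivity 3D neighbourhood: `"faces"` (6 neighbours, the
#'   nearest-neighbour convention), `"faces+edges"` (18) or
#'   `"faces+edges+corners"` (26).
#' @slot kFolds number of outer cross-validation folds.
#' @slot tol solver tolerance on the KKT gap of the SVM dual.
#' @export
setClass("RFEConfig",
  representation(eliminationFraction = "numeric", minClusterVoxels = "integer",
                 connectivity = "character", kFolds = "integer", tol = "numeric"),
  validity = function(object) {
    if (!(object@eliminationFraction > 0 && object@eliminationFraction < 1))
      return("eliminationFraction must be in (0, 1)")
    if (object@minClusterVoxels < 1L) return("minClusterVoxels must be >= 1")
    if (!object@connectivity %in% c("faces", "faces+edges", "faces+edges+corners"))
      return("unknown connectivity")
    if (object@kFolds < 2L) return("kFolds must be >= 2")
    TRUE
  }
)

#' @param eliminationFraction,minClusterVoxels,connectivity,kFolds,tol see slots.
#' @return `RFEConfig()` returns a validated \linkS4class{RFEConfig}.
#' @rdname RFEConfig-class
#' @export
RFEConfig <- function(eliminationFraction = 0.02, minClusterVoxels = 150,
                      connectivity = "faces", kFolds = 4, tol = 1e-6) {
  new("RFEConfig", eliminationFraction = eliminationFraction,
      minClusterVoxels = as.integer(minClusterVoxels),
      connectivity = connectivity, kFolds = as.integer(kFolds), tol = tol)
}
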