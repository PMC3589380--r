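# Dataset and report I/O: NIfTI volumes + tab-separated metadata for beta
# patterns, YAML experiment configuration, JSON/TSV/NIfTI reports.

.META_COLS <- c("file", "class", "modality", "group", "subject", "stimulus",
                "duplicate_of", "session")

#' Write a beta-pattern dataset to disk
#'
#' One NIfTI volume per example plus a tab-separated metadata table
#' (`metadata.tsv`, columns `file`, `class`, `modality`, `group`,
#' `subject`, `stimulus`, `duplicate_of`, `session`) and a small
#' `dataset.json` with the grid geometry and scaling state. The ground
#' truth, when given, is stored as an integer-labelled NIfTI mask
#' (1 = shared, 2 = auditory, 3 = visual, 4 = motor) plus
#' `ground_truth.json`.
#'
#' @param x a \linkS4class{BetaPatternSet}.
#' @param dir output directory (created if needed).
#' @param truth optional \linkS4class{GroundTruth}.
#' @return the directory, invisibly.
#' @export
writeDataset <- function(x, dir, truth = NULL) {
  stopifnot(is(x, "BetaPatternSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- voxelGrid(x)
  beta <- SummarizedExperiment::assay(x, "beta")
  info <- exampleInfo(x)
  files <- sprintf("example_%04d.nii.gz", seq_len(ncol(beta)))
  for (i in seq_len(ncol(beta))) {
    vol <- array(beta[, i], dim = grid@dims)
    RNifti::writeNifti(RNifti::asNifti(vol, list(pixdim = c(0, grid@voxelSize,
                                                            rep(0, 4)))),
                       file.path(dir, files[i]))
  }
  meta <- data.frame(file = files, class = info$classLabel,
                     modality = info$modality, group = info$group,
                     subject = info$subjectId, stimulus = info$stimulusId,
                     duplicate_of = ifelse(is.na(info$duplicateOf), "",
                                           info$duplicateOf),
                     session = info$session, stringsAsFactors = FALSE)
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(dims = grid@dims, voxel_size_mm = grid@voxelSize,
                            scaled = isScaled(x), n_examples = ncol(beta)),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(truth)) {
    lab <- integer(nVoxels(grid))
    for (i in seq_along(truth@sets)) lab[truth@sets[[i]]] <- i
    RNifti::writeNifti(array(lab, dim = grid@dims),
                       file.path(dir, "ground_truth_mask.nii.gz"))
    jsonlite::write_json(list(sets = truth@sets,
                              effect_size = as.list(truth@effectSize)),
                         file.path(dir, "ground_truth.json"), digits = NA)
  }
  invisible(dir)
}

#' Read a beta-pattern dataset from disk
#'
#' Inverse of [writeDataset()]: restores the \linkS4class{BetaPatternSet}
#' from the NIfTI volumes and the metadata table, with distinct errors for
#' an empty directory, missing volumes, inconsistent grid dimensions and
#' unknown labels.
#'
#' @param dir dataset directory.
#' @return a \linkS4class{BetaPatternSet}.
#' @export
readDataset <- function(dir) {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path))
    stop("no examples found: missing ", meta_path)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  if (!nrow(meta)) stop("no examples found: empty metadata table")
  if (!all(.META_COLS %in% colnames(meta)))
    stop("metadata table lacks columns: ",
         paste(setdiff(.META_COLS, colnames(meta)), collapse = ", "))
  dj_path <- file.path(dir, "dataset.json")
  dj <- if (file.exists(dj_path)) jsonlite::read_json(dj_path) else NULL
  missing <- !file.exists(file.path(dir, meta$file))
  if (any(missing))
    stop("missing example volumes: ",
         paste(head(meta$file[missing], 3), collapse = ", "))
  vols <- lapply(file.path(dir, meta$file), RNifti::readNifti)
  dims <- vapply(vols, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(dims)) != 1L)
    stop("dimension mismatch between example volumes: ",
         paste(unique(dims), collapse = " vs "))
  d3 <- dim(vols[[1]])
  vsz <- if (!is.null(dj$voxel_size_mm)) unlist(dj$voxel_size_mm) else {
    px <- RNifti::pixdim(vols[[1]])
    if (length(px) >= 3 && all(px[1:3] > 0)) px[1:3] else c(2, 2, 2)
  }
  grid <- VoxelGrid(d3, vsz)
  beta <- vapply(vols, as.numeric, numeric(prod(d3)))
  bad_class <- setdiff(unique(meta$class), .CLASS_LEVELS)
  if (length(bad_class)) stop("unknown class label: ",
                              paste(bad_class, collapse = ", "))
  bad_mod <- setdiff(unique(meta$modality), .MODALITY_LEVELS)
  if (length(bad_mod)) stop("unknown modality: ",
                            paste(bad_mod, collapse = ", "))
  bad_grp <- setdiff(unique(meta$group), .GROUP_LEVELS)
  if (length(bad_grp)) stop("unknown group: ", paste(bad_grp, collapse = ", "))
  info <- data.frame(classLabel = meta$class, modality = meta$modality,
                     group = meta$group, subjectId = meta$subject,
                     stimulusId = meta$stimulus,
                     duplicateOf = ifelse(meta$duplicate_of == "",
                                          NA_character_, meta$duplicate_of),
                     session = meta$session, stringsAsFactors = FALSE)
  BetaPatternSet(beta, info, grid, scaled = isTRUE(dj$scaled))
}

#' Export a discriminative map as NIfTI volumes
#'
#' Writes two volumes, one holding the raw weights and one the z-scored
#' weights, with zeros outside the map's voxel set.
#'
#' @param map a \linkS4class{DiscriminativeMap}.
#' @param prefix output path prefix; `<prefix>_weights.nii.gz` and
#'   `<prefix>_zscores.nii.gz` are written.
#' @return character vector of the two file paths, invisibly.
#' @export
writeMap <- function(map, prefix) {
  stopifnot(is(map, "DiscriminativeMap"))
  d <- map@grid@dims
  out <- character(2)
  for (i in 1:2) {
    vol <- numeric(prod(d))
    vol[map@featureIdx] <- if (i == 1) map@weights else map@zWeights
    out[i] <- paste0(prefix, c("_weights", "_zscores")[i], ".nii.gz")
    RNifti::writeNifti(array(vol, dim = d), out[i])
  }
  invisible(out)
}

# flatten an accuracy table / data.frame for the JSON report
.df_to_json <- function(df) lapply(seq_len(nrow(df)), function(i)
  as.list(df[i, , drop = FALSE]))

#' Write the experiment report
#'
#' Renders a completed pipeline result into `report.json` (pipeline
#' version, seed, configuration hash, all accuracy tables and tests),
#' tab-separated tables mirroring the within/across accuracy tables and
#' the pantomime classification, the RFE traces of the best fold, and
#' NIfTI volumes of the supramodal discriminative map and the knock-out
#' mask. Two runs with the same configuration and seed produce
#' byte-identical JSON reports.
#'
#' @param result a `"supraResult"` from [runKnockout()] or [runPipeline()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeReport <- function(result, dir) {
  stopifnot(inherits(result, "supraResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  report <- list(
    pipeline = "supraMVPA",
    version = as.character(packageVersion("supraMVPA")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    best_fold = result$bestFold,
    ncv_summary = .df_to_json(result$ncv$summary),
    tables = lapply(result$tables, .df_to_json),
    supramodal = list(accuracy = result$supramodal$accuracy,
                      p_permutation = result$supramodal$pPermutation,
                      n_voxels = length(result$knockout)),
    knockout_test = list(
      per_condition = .df_to_json(result$knockoutTest$perCondition),
      p_fisher = result$knockoutTest$pFisher),
    pantomime = .df_to_json(result$pantomime))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(result$tables))
    write.table(result$tables[[nm]], file.path(dir, paste0("table_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$pantomime, file.path(dir, "pantomime.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$ncv$summary, file.path(dir, "ncv_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  f <- result$bestFold
  for (cn in names(result$ncv$foldRecords[[f]]$traces))
    write.table(traceTable(result$ncv$foldRecords[[f]]$traces[[cn]]),
                file.path(dir, sprintf("trace_%s_fold%d.tsv", cn, f)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  writeMap(result$supramodal$map, file.path(dir, "supramodal_map"))
  komask <- numeric(nVoxels(result$grid))
  komask[result$knockout] <- 1
  RNifti::writeNifti(array(komask, dim = result$grid@dims),
                     file.path(dir, "knockout_mask.nii.gz"))
  invisible(dir)
}

# configuration schema: allowed keys per section
.CONFIG_SCHEMA <- list(
  seed = NA, scenario = NA,
  grid = c("dims", "voxel_size_mm"),
  design = c("n_sighted", "n_blind", "n_action_sounds", "n_nonaction_sounds",
             "n_action_videos", "n_nonaction_videos", "n_pantomime",
             "noise_sd", "subject_offset_sd"),
  effects = c("shared", "auditory", "visual", "motor"),
  clusters = c("shared", "auditory", "visual", "motor"),
  pipeline = c("target_per_class", "elimination_fraction",
               "min_cluster_voxels", "connectivity", "k_folds", "tol",
               "n_perm", "scaling_mode", "joint_iteration"))

#' Read and validate an experiment configuration
#'
#' Loads a YAML experiment description with sections `seed`, `scenario`,
#' `grid`, `design`, `effects`, `clusters` and `pipeline`; unknown keys at
#' any level are rejected with an error naming the key. Values omitted
#' fall back to the package defaults ([DesignSpec()], [pipelineConfig()],
#' the scenario's effect sizes).
#'
#' @param path a YAML file.
#' @return list of class `"experimentConfig"` with elements `grid`,
#'   `design`, `effects`, `clusterSpec`, `scenario`, `pipeline` (a
#'   [pipelineConfig()]) and `seed`.
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), names(.CONFIG_SCHEMA))
  if (length(bad)) stop("unknown configuration key: ",
                        paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    allowed <- .CONFIG_SCHEMA[[sec]]
    if (!identical(allowed, NA) && length(names(raw[[sec]]))) {
      bad <- setdiff(names(raw[[sec]]), allowed)
      if (length(bad)) stop("unknown configuration key in '", sec, "': ",
                            paste(bad, collapse = ", "))
    }
  }
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  grid <- VoxelGrid(
    if (!is.null(raw$grid$dims)) unlist(raw$grid$dims) else c(12, 12, 12),
    if (!is.null(raw$grid$voxel_size_mm)) unlist(raw$grid$voxel_size_mm)
    else c(2, 2, 2))
  dget <- function(key, default) {
    v <- raw$design[[key]]
    if (is.null(v)) default else v
  }
  design <- DesignSpec(
    nSighted = dget("n_sighted", 14), nBlind = dget("n_blind", 8),
    nActionSounds = dget("n_action_sounds", 20),
    nNonactionSounds = dget("n_nonaction_sounds", 10),
    nActionVideos = dget("n_action_videos", 23),
    nNonactionVideos = dget("n_nonaction_videos", 11),
    nPantomime = dget("n_pantomime", 10),
    noiseSd = dget("noise_sd", 0.5),
    subjectOffsetSd = dget("subject_offset_sd", 0.3))
  scenario <- if (!is.null(raw$scenario)) raw$scenario else "shared"
  effects <- switch(scenario,
    recovery = c(shared = 1, auditory = 1, visual = 1, motor = 1),
    modality = c(shared = 0, auditory = 1, visual = 1, motor = 1),
    shared = c(shared = 0.15, auditory = 0.08, visual = 0.08, motor = 0.15),
    stop("unknown scenario: ", scenario))
  if (!is.null(raw$effects))
    effects[names(raw$effects)] <- unlist(raw$effects)
  clusterSpec <- list(shared = 40L, auditory = 30L, visual = 30L, motor = 30L)
  if (!is.null(raw$clusters))
    clusterSpec[names(raw$clusters)] <- lapply(raw$clusters, as.integer)
  pget <- function(key, default) {
    v <- raw$pipeline[[key]]
    if (is.null(v)) default else v
  }
  pipeline <- pipelineConfig(
    targetPerClass = pget("target_per_class", 20),
    eliminationFraction = pget("elimination_fraction", 0.02),
    minClusterVoxels = pget("min_cluster_voxels", 5),
    connectivity = pget("connectivity", "faces"),
    kFolds = pget("k_folds", 4), tol = pget("tol", 1e-6),
    nPerm = pget("n_perm", 99),
    scalingMode = pget("scaling_mode", "condition"),
    jointIteration = pget("joint_iteration", FALSE), seed = seed)
  out <- list(grid = grid, design = design, effects = effects,
              clusterSpec = clusterSpec, scenario = scenario,
              pipeline = pipeline, seed = seed)
  class(out) <- "experimentConfig"
  out
}

#' Simulate a dataset from an experiment configuration
#'
#' Generates the ground truth and the example set described by an
#' experiment configuration and writes them as a NIfTI + metadata dataset.
#'
#' @param config an `"experimentConfig"` from [readExperimentConfig()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
runSimulate <- function(config, dir) {
  stopifnot(inherits(config, "experimentConfig"))
  gt <- generateGroundTruth(config$grid, config$clusterSpec, config$effects,
                            seed = config$seed)
  ds <- generateExamples(gt, config$design, seed = config$seed + 1L)
  writeDataset(ds, dir, truth = gt)
}

#' @rdname writeReport
#' @export
runReport <- function(result, dir) writeReport(result, dir)
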