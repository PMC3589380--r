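# Shared fixtures, built in code. The heavier end-to-end objects are
# computed once per session and cached.

# a down-scaled study: 8^3 grid, smaller clusters, 6 + 4 subjects
small_study <- function(seed = 1,
                        effects = c(shared = 0.5, auditory = 0.3,
                                    visual = 0.3, motor = 0.5),
                        design = DesignSpec(nSighted = 6, nBlind = 4,
                                            nPantomime = 5)) {
  grid <- VoxelGrid(c(8, 8, 8))
  gt <- generateGroundTruth(grid,
                            clusterSpec = list(shared = 15, auditory = 10,
                                               visual = 10, motor = 10),
                            effectSize = effects, seed = seed)
  ds <- generateExamples(gt, design, seed = seed + 1L)
  list(dataset = ds, truth = gt, grid = grid, design = design)
}

# a single-condition BetaPatternSet with the given per-class stimulus counts
tiny_condition <- function(nAction = 6, nNonaction = 3, nSubjects = 2,
                           nVoxels = 12, seed = 1, group = "sighted",
                           modality = "auditory") {
  set.seed(seed)
  stim <- data.frame(
    stimulusId = c(sprintf("act_%02d", seq_len(nAction)),
                   sprintf("env_%02d", seq_len(nNonaction))),
    classLabel = rep(c("action", "non_action"), c(nAction, nNonaction)))
  info <- do.call(rbind, lapply(sprintf("p%02d", seq_len(nSubjects)),
    function(sb) data.frame(classLabel = stim$classLabel,
                            modality = modality, group = group,
                            subjectId = sb, stimulusId = stim$stimulusId)))
  beta <- matrix(rnorm(nVoxels * nrow(info)), nVoxels)
  BetaPatternSet(beta, info, VoxelGrid(c(nVoxels, 1, 1)))
}

.fixture_cache <- new.env(parent = emptyenv())

# one small end-to-end pipeline run shared by the supramodal and io tests
cached_small_result <- function() {
  if (is.null(.fixture_cache$res)) {
    st <- small_study(seed = 7)
    cfg <- pipelineConfig(seed = 7, nPerm = 19, minClusterVoxels = 3)
    .fixture_cache$study <- st
    .fixture_cache$cfg <- cfg
    .fixture_cache$fit <- runFit(st$dataset, cfg)
    .fixture_cache$res <- runKnockout(.fixture_cache$fit, st$dataset)
  }
  list(study = .fixture_cache$study, cfg = .fixture_cache$cfg,
       fit = .fixture_cache$fit, res = .fixture_cache$res)
}
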