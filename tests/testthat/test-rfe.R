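test_that("cluster correction keeps exactly the large connected components", {
  g <- VoxelGrid(c(10, 10, 10))
  expect_identical(clusterCorrect(integer(0), g, minSize = 5), integer(0))

  # a full 3x3x3 block survives at its own size and dies above it
  co <- as.matrix(expand.grid(2:4, 2:4, 2:4))
  block <- voxelIndex(g, co)
  expect_setequal(clusterCorrect(block, g, minSize = 27), block)
  expect_identical(clusterCorrect(block, g, minSize = 28), integer(0))

  # output is always a subset of the input
  set.seed(1)
  idx <- sample(1000, 120)
  out <- clusterCorrect(idx, g, minSize = 3)
  expect_true(all(out %in% idx))
})

test_that("cluster correction agrees with the dilation-labelling oracle", {
  g <- VoxelGrid(c(8, 8, 8))
  set.seed(2)
  for (i in 1:40) {
    idx <- sample(512, sample(20:220, 1))
    conn <- sample(c("faces", "faces+edges", "faces+edges+corners"), 1)
    ms <- sample(1:8, 1)
    expect_identical(clusterCorrect(idx, g, minSize = ms, connectivity = conn),
                     oracle_cluster_correct(idx, c(8, 8, 8), ms, conn))
  }
})

test_that("one elimination step removes the right count with deterministic ties", {
  g <- VoxelGrid(c(100, 1, 1))
  cfg1 <- RFEConfig(minClusterVoxels = 1)  # isolate the count rule
  # 100 features at 2% -> exactly 2 removed
  set.seed(3)
  w <- runif(100) + 0.1
  out <- eliminateStep(w, 1:100, g, cfg1)
  expect_length(out, 98)
  expect_setequal(setdiff(1:100, out), order(abs(w))[1:2])
  # ceiling with a floor of one: 10 features -> 1 removed
  out10 <- eliminateStep(w[1:10], 1:10, g, cfg1)
  expect_length(out10, 9)
  # all-equal weights: the lowest voxel indices go first
  out_tie <- eliminateStep(rep(1, 50), 51:100, g, cfg1)
  expect_identical(setdiff(51:100, out_tie), 51L)
  # output is a strict subset
  expect_true(all(out %in% 1:100) && length(out) < 100)
})

test_that("an RFE run shrinks strictly to exhaustion and records valid accuracies", {
  st <- small_study(seed = 13)
  cfg <- pipelineConfig(seed = 13, minClusterVoxels = 3)
  cond <- prepareConditions(st$dataset, cfg)
  cd <- cond$blind_auditory
  tr <- cd$foldId != 1
  trace <- runRFE(cd$X[tr, ], cd$y[tr], cd$X[!tr, ], cd$y[!tr], st$grid,
                  cfg$rfe)
  ns <- lengths(trace@featureSets)
  expect_true(all(diff(ns) < 0))
  expect_identical(ns[1], 512L)
  expect_lte(ns[length(ns)], cfg$rfe@eliminationFraction * 512 + 1)
  expect_true(all(trace@accuracies >= 0 & trace@accuracies <= 1))
  # deterministic: same inputs give the identical trace
  trace2 <- runRFE(cd$X[tr, ], cd$y[tr], cd$X[!tr, ], cd$y[!tr], st$grid,
                   cfg$rfe)
  expect_identical(traceTable(trace), traceTable(trace2))
})

test_that("RFE recovers a planted cluster when accuracy does not saturate", {
  # moderate effect so that test accuracy stays off ceiling and the
  # best-accuracy iteration is identifiable
  res <- vapply(1:6, function(s) {
    grid <- VoxelGrid(c(10, 10, 10))
    gt <- generateGroundTruth(grid, clusterSpec = list(shared = 27),
                              effectSize = c(shared = 0.3), seed = s)
    S <- informativeSets(gt)$shared
    set.seed(s + 100)
    mk <- function(n) {
      X <- matrix(rnorm(2 * n * 1000, sd = 0.5), 2 * n)
      y <- rep(c(1, -1), each = n)
      X[y == 1, S] <- X[y == 1, S] + 0.3
      list(X = X, y = y)
    }
    tr <- mk(80); te <- mk(40)
    trace <- runRFE(tr$X, tr$y, te$X, te$y, grid,
                    RFEConfig(minClusterVoxels = 5))
    best <- trace@featureSets[[max(which(trace@accuracies ==
                                           max(trace@accuracies)))]]
    jaccard(best, S)
  }, 0)
  expect_gte(median(res), 0.5)
})

test_that("nested CV selects a best fold and reports exact fold means", {
  sr <- cached_small_result()
  ncv <- sr$fit$ncv
  k <- sr$cfg$rfe@kFolds
  expect_length(ncv$foldRecords, k)
  expect_true(ncv$bestFold %in% seq_len(k))
  # the selection criterion is the across-condition mean of per-fold bests
  mean_best <- vapply(ncv$foldRecords, function(fr)
    mean(vapply(fr$best, `[[`, 0, "accuracy")), 0)
  expect_identical(ncv$bestFold, which.max(mean_best))
  expect_equal(ncv$foldRecords[[1]]$meanBest, mean_best[1])
  # summary mean/sd are the plain statistics of the per-fold bests
  for (cn in ncv$summary$condition) {
    accs <- vapply(ncv$foldRecords, function(fr) fr$best[[cn]]$accuracy, 0)
    row <- ncv$summary[ncv$summary$condition == cn, ]
    expect_equal(row$meanAccuracy, mean(accs))
    expect_equal(row$sdAccuracy, sd(accs))
  }
  # each best model was trained on exactly its recorded feature set
  b <- ncv$foldRecords[[ncv$bestFold]]$best[[1]]
  expect_identical(sort(featureIndices(b$model)), sort(b$featureSet))
  expect_equal(b$iteration,
               max(which(ncv$foldRecords[[ncv$bestFold]]$traces[[1]]@accuracies ==
                         b$accuracy)))
})

test_that("pure-noise data stay at chance through the full selection", {
  st <- small_study(seed = 17,
                    effects = c(shared = 0, auditory = 0, visual = 0,
                                motor = 0),
                    design = DesignSpec(nSighted = 4, nBlind = 3,
                                        nPantomime = 0))
  cfg <- pipelineConfig(seed = 17, minClusterVoxels = 3)
  cond <- prepareConditions(st$dataset, cfg)
  ncv <- nestedCV(cond["blind_auditory"], st$grid, cfg$rfe)
  f <- ncv$bestFold
  best <- ncv$foldRecords[[f]]$best$blind_auditory
  cd <- cond$blind_auditory
  tr <- cd$foldId != f
  p <- permutationTest(best$accuracy, cd$y[tr], function(yp) {
    m <- svmTrain(cd$X[tr, ], yp, featureIdx = best$featureSet)
    accuracyScore(predict(m, cd$X[!tr, ]), cd$y[!tr])
  }, nPerm = 49, seed = 18)$pValue
  expect_gt(p, 0.05)
})

test_that("discriminative maps standardize weights and round-trip through NIfTI", {
  m1 <- new("LinearModel", weights = 0.7, bias = 0, cParam = 1,
            objective = 0, featureIdx = 5L)
  g <- VoxelGrid(c(4, 4, 4))
  map1 <- makeMap(m1, g)
  expect_identical(mapZWeights(map1), 0)  # singleton
  set.seed(19)
  m2 <- new("LinearModel", weights = rnorm(12), bias = 0, cParam = 1,
            objective = 0, featureIdx = sort(sample(64L, 12)))
  map2 <- makeMap(m2, g)
  expect_equal(mean(mapZWeights(map2)), 0, tolerance = 1e-12)
  expect_equal(sd(mapZWeights(map2)), 1, tolerance = 1e-12)
  expect_error(makeMap(new("LinearModel", weights = numeric(0), bias = 0,
                           cParam = 1, objective = 0,
                           featureIdx = integer(0)), g), "empty")
  # NIfTI round trip preserves the voxel membership bit-exactly
  td <- withr::local_tempdir()
  files <- writeMap(map2, file.path(td, "map"))
  vol <- RNifti::readNifti(file.path(td, "map_weights.nii.gz"))
  expect_identical(sort(which(vol != 0)), featureIndices(map2))
  expect_equal(vol[featureIndices(map2)], mapWeights(map2), tolerance = 1e-7,
               ignore_attr = TRUE)
})
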