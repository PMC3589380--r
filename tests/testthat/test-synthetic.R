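test_that("ground-truth clusters are placed with the requested sizes, connected and disjoint", {
  grid <- VoxelGrid(c(10, 10, 10))

  # vacuous case
  gt0 <- generateGroundTruth(grid, clusterSpec = list(), seed = 1)
  expect_true(all(lengths(informativeSets(gt0)) == 0))

  # one 27-voxel shared blob: exact size, one face-connected component
  gt1 <- generateGroundTruth(grid, clusterSpec = list(shared = 27), seed = 2)
  S <- informativeSets(gt1)$shared
  expect_length(S, 27)
  lab <- oracle_components(S, c(10, 10, 10))
  expect_identical(max(lab), 1L)

  # multiple sets, several components each, pairwise disjoint and in-grid
  gt2 <- generateGroundTruth(grid,
                             clusterSpec = list(shared = c(10, 10),
                                                auditory = 10, visual = 10,
                                                motor = 8),
                             seed = 3)
  sets <- informativeSets(gt2)
  expect_identical(lengths(sets), c(shared = 20L, auditory = 10L,
                                    visual = 10L, motor = 8L))
  all_idx <- unlist(sets)
  expect_identical(anyDuplicated(all_idx), 0L)
  expect_true(all(all_idx >= 1 & all_idx <= 1000))
  expect_identical(max(oracle_components(sets$shared, c(10, 10, 10))), 2L)

  # impossible request errors out
  expect_error(generateGroundTruth(VoxelGrid(c(2, 2, 2)),
                                   clusterSpec = list(shared = 20), seed = 1),
               "too small|fit")
})

test_that("example counts are a deterministic function of the design", {
  st <- small_study(seed = 5)
  info <- exampleInfo(st$dataset)
  d <- st$design
  per_subj <- table(info$subjectId, info$classLabel, info$modality)
  aud <- info[info$modality == "auditory", ]
  expect_true(all(table(aud$subjectId, aud$classLabel)[, "action"] == 20))
  expect_true(all(table(aud$subjectId, aud$classLabel)[, "non_action"] == 10))
  vis <- info[info$modality == "visual", ]
  expect_identical(unique(info$group[info$modality == "visual"]), "sighted")
  expect_true(all(table(vis$subjectId, vis$classLabel)[, "action"] == 23))
  expect_true(all(table(vis$subjectId, vis$classLabel)[, "non_action"] == 11))
  # pantomimes: one per (subject, session, index); blind have no visual session
  pant <- info[info$classLabel == "pantomime", ]
  expect_identical(nrow(pant[pant$group == "sighted", ]), 6L * 2L * 5L)
  expect_identical(nrow(pant[pant$group == "blind", ]), 4L * 5L)
  expect_true(all(pant$modality == "motor"))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- small_study(seed = 11)
  b <- small_study(seed = 11)
  expect_identical(SummarizedExperiment::assay(a$dataset, "beta"),
                   SummarizedExperiment::assay(b$dataset, "beta"))
  c <- small_study(seed = 12)
  expect_false(identical(SummarizedExperiment::assay(a$dataset, "beta"),
                         SummarizedExperiment::assay(c$dataset, "beta")))
})

test_that("planted effects appear with the configured size and location", {
  # degenerate case: no noise, no offsets, no effects -> all zeros
  grid <- VoxelGrid(c(4, 4, 4))
  gt0 <- generateGroundTruth(grid, clusterSpec = list(shared = 8),
                             effectSize = c(shared = 0), seed = 1)
  ds0 <- generateExamples(gt0, DesignSpec(nSighted = 2, nBlind = 1,
                                          nPantomime = 2, noiseSd = 0,
                                          subjectOffsetSd = 0), seed = 2)
  expect_true(all(SummarizedExperiment::assay(ds0, "beta") == 0))

  # empirical action minus non-action difference at shared voxels ~ effect
  st <- small_study(seed = 21,
                    effects = c(shared = 1, auditory = 0, visual = 0,
                                motor = 0),
                    design = DesignSpec(nSighted = 10, nBlind = 10,
                                        nPantomime = 0, noiseSd = 0.1))
  X <- betaMatrix(st$dataset)
  info <- exampleInfo(st$dataset)
  S <- informativeSets(st$truth)$shared
  dmean <- mean(colMeans(X[info$classLabel == "action", S, drop = FALSE]) -
                colMeans(X[info$classLabel == "non_action", S, drop = FALSE]))
  expect_lt(abs(dmean - 1), 0.05)
  # null voxels carry no class difference
  null_vox <- setdiff(seq_len(nVoxels(st$dataset)),
                      unlist(informativeSets(st$truth)))
  dnull <- mean(colMeans(X[info$classLabel == "action", null_vox]) -
                colMeans(X[info$classLabel == "non_action", null_vox]))
  expect_lt(abs(dnull), 0.05)
})

test_that("informative-set membership is recoverable by a two-sample t statistic", {
  # n per class = 100, effect 1, noise 0.5: t at shared voxels clears the
  # largest null-voxel t by a wide margin
  grid <- VoxelGrid(c(8, 8, 8))
  gt <- generateGroundTruth(grid, clusterSpec = list(shared = 15),
                            effectSize = c(shared = 1), seed = 31)
  S <- informativeSets(gt)$shared
  set.seed(32)
  n <- 100
  X <- matrix(rnorm(2 * n * 512, sd = 0.5), 2 * n)
  X[seq_len(n), S] <- X[seq_len(n), S] + 1
  tstat <- vapply(seq_len(512), function(v)
    t.test(X[seq_len(n), v], X[n + seq_len(n), v])$statistic, 0)
  expect_gt(min(tstat[S]), max(tstat[-S]))
})

test_that("the haemodynamic kernel peaks mid-trial and integrates positively", {
  k <- gammaKernel(5)
  expect_gt(sum(k), 0)
  expect_true(which.max(k) %in% 2:4)
  expect_equal(k[3], 1)  # normalized peak at the third volume
})

test_that("sparse-run simulation is linear in the amplitude", {
  expect_true(all(simulateSparseRun(c(0, 0), noiseSd = 0) == 0))
  r <- simulateSparseRun(2, noiseSd = 0)
  expect_equal(drop(r), 2 * gammaKernel(5), ignore_attr = TRUE)
  r2 <- simulateSparseRun(c(1, -3), noiseSd = 0)
  expect_equal(r2[2, ], -3 * gammaKernel(5), ignore_attr = TRUE)
})

test_that("deconvolution recovers amplitudes and averages volumes 2-4", {
  amps <- c(a = 1.5, b = -2, c = 0.5)
  series <- as.vector(t(simulateSparseRun(amps, noiseSd = 0)))
  out <- deconvolveBetas(series, names(amps))
  expect_equal(out$beta, amps * mean(gammaKernel(5)[2:4]), tolerance = 1e-9)

  # averaging indices are exactly volumes 2, 3, 4 (1-based): feed a series
  # whose per-volume betas are known constants
  per_vol <- c(10, 20, 30, 40, 50)
  series2 <- rep(per_vol, 3)
  out2 <- deconvolveBetas(series2, c("s1", "s1", "s1"))
  expect_equal(unname(out2$beta), mean(per_vol[2:4]))
  expect_equal(unname(out2$betaByVolume["s1", , 1]), per_vol)
})

test_that("deconvolution least squares matches the normal-equations oracle", {
  set.seed(41)
  ids <- sample(c("s1", "s2", "s3", "s4"), 20, replace = TRUE)
  ids[1:4] <- c("s1", "s2", "s3", "s4")
  Y <- matrix(rnorm(20 * 5 * 6), 20 * 5, 6)
  out <- deconvolveBetas(Y, ids, nVolumesPerTrial = 5)
  # independent reconstruction of the FIR design + normal equations
  stims <- unique(ids)
  X <- matrix(0, 100, length(stims) * 5)
  for (t in seq_along(ids)) {
    s <- match(ids[t], stims)
    X[cbind((t - 1) * 5 + 1:5, (s - 1) * 5 + 1:5)] <- 1
  }
  cf <- solve(crossprod(X), crossprod(X, Y))
  man <- t(sapply(seq_along(stims), function(s)
    colMeans(cf[(s - 1) * 5 + 2:4, , drop = FALSE])))
  expect_equal(unname(out$beta), unname(man), tolerance = 1e-10)
})

test_that("rank-deficient deconvolution designs are refused", {
  series <- rnorm(10)
  expect_error(deconvolveBetas(series, c("s1", "s1"), nVolumesPerTrial = 3),
               "at least 4 volumes")
  # duplicated time courses cannot happen with the FIR builder, but a
  # mismatched series length can
  expect_error(deconvolveBetas(rnorm(11), c("s1", "s1")), "rows per trial")
})
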