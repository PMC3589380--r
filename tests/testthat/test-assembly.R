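test_that("upsampling doubles a half-sized class and flags duplicates", {
  x <- tiny_condition(nAction = 20, nNonaction = 10, nSubjects = 3)
  b <- balanceClasses(x, targetPerClass = 20, seed = 1)
  info <- exampleInfo(b)
  tab <- table(info$subjectId, info$classLabel)
  expect_true(all(tab == 20))
  dup <- info[!is.na(info$duplicateOf), ]
  # 10 -> 20 is exact doubling: every non-action stimulus duplicated once
  expect_identical(sort(unique(dup$duplicateOf)),
                   sort(unique(info$stimulusId[info$classLabel == "non_action" &
                                               is.na(info$duplicateOf)])))
  # duplicated values are copies of their original's pattern, per subject
  one <- dup[1, ]
  orig_col <- which(info$stimulusId == one$duplicateOf &
                    info$subjectId == one$subjectId)
  dup_col <- which(info$stimulusId == one$stimulusId &
                   info$subjectId == one$subjectId)
  bm <- SummarizedExperiment::assay(b, "beta")
  expect_identical(bm[, orig_col], bm[, dup_col])
})

test_that("balancing downsamples, handles uneven deficits, and is stimulus-consistent", {
  # 23 action / 11 non-action (the video counts): down to 20, up to 20
  x <- tiny_condition(nAction = 23, nNonaction = 11, nSubjects = 4,
                      modality = "visual")
  b <- balanceClasses(x, targetPerClass = 20, seed = 2)
  info <- exampleInfo(b)
  expect_true(all(table(info$subjectId, info$classLabel) == 20))
  # the same stimuli are kept/duplicated for every subject
  per_subj <- split(info$stimulusId, info$subjectId)
  expect_true(all(vapply(per_subj, function(s)
    setequal(s, per_subj[[1]]), TRUE)))
  # voxel dimension untouched
  expect_identical(nrow(b), nrow(x))
})

test_that("already balanced input is returned unchanged and errors are explicit", {
  x <- tiny_condition(nAction = 5, nNonaction = 5, nSubjects = 2)
  expect_identical(balanceClasses(x, targetPerClass = 5, seed = 1), x)
  one_class <- x[, exampleInfo(x)$classLabel == "action"]
  expect_error(balanceClasses(one_class, 5), "both classes")
})

test_that("tanh scaling bounds, degenerate voxels and rank preservation", {
  x <- tiny_condition(nAction = 25, nNonaction = 25, nSubjects = 1,
                      nVoxels = 20, seed = 3)
  beta <- SummarizedExperiment::assay(x, "beta")
  beta[7, ] <- 4.2  # constant voxel
  x <- BetaPatternSet(beta, exampleInfo(x), voxelGrid(x))
  s <- scaleTanh(x)
  sm <- SummarizedExperiment::assay(s, "beta")
  expect_true(isScaled(s))
  expect_true(all(sm > -1 & sm < 1))
  expect_true(all(sm[7, ] == 0))
  # per-voxel rank order of examples preserved (50 examples x 20 voxels)
  for (v in c(1, 5, 20))
    expect_identical(order(sm[v, ]), order(beta[v, ]))
  expect_error(scaleTanh(s), "already scaled")
})

test_that("fold assignment is stratified, exhaustive and seed-reproducible", {
  ids <- sprintf("s%02d", 1:30)
  cls <- rep(c("action", "non_action"), c(20, 10))
  f <- makeFolds(ids, cls, k = 4, seed = 9)
  expect_setequal(f$stimulusId, ids)
  expect_identical(anyDuplicated(f$stimulusId), 0L)
  tab <- table(f$classLabel, f$fold)
  expect_true(all(tab["action", ] == 5))  # 20 stimuli over 4 folds
  expect_true(max(tab["non_action", ]) - min(tab["non_action", ]) <= 1)
  expect_identical(f, makeFolds(ids, cls, k = 4, seed = 9))
  expect_error(makeFolds(ids[1:22], cls[1:22], k = 4), "fewer stimuli")
})

test_that("upsampled duplicates never straddle the train/test split of any fold", {
  x <- tiny_condition(nAction = 20, nNonaction = 10, nSubjects = 2, seed = 4)
  b <- balanceClasses(x, targetPerClass = 20, seed = 5)
  info_orig <- exampleInfo(x)
  f <- makeFolds(info_orig$stimulusId, info_orig$classLabel, k = 4, seed = 6)
  fid <- foldOf(f, b)
  info <- exampleInfo(b)
  # exhaustive audit: resolve each example to its source stimulus; a source
  # stimulus must sit in exactly one fold
  src <- ifelse(is.na(info$duplicateOf), info$stimulusId, info$duplicateOf)
  for (k in 1:4) {
    test_src <- unique(src[fid == k])
    train_src <- unique(src[fid != k])
    expect_length(intersect(test_src, train_src), 0)
  }
})
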