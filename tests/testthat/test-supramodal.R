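test_that("the supramodal classifier pools the best fold's training data", {
  sr <- cached_small_result()
  res <- sr$res
  f <- res$bestFold
  cond <- sr$fit$conditions
  n_train <- sum(vapply(cond, function(cd) sum(cd$foldId != f), 0))
  n_test <- sum(vapply(cond, function(cd) sum(cd$foldId == f), 0))
  expect_equal(res$supramodal$nTrain, n_train)
  expect_equal(res$supramodal$nTest, n_test)
  expect_identical(knockoutMask(res$supramodal),
                   sort(featureIndices(res$supramodal$model)))
  expect_true(all(res$knockout >= 1 &
                  res$knockout <= nVoxels(sr$study$grid)))
})

test_that("a shared-signal supramodal map prefers the shared set over modality sets", {
  sr <- cached_small_result()
  gt <- informativeSets(sr$study$truth)
  ko <- sr$res$knockout
  expect_gte(jaccard(ko, gt$shared), jaccard(ko, gt$auditory))
  expect_gte(jaccard(ko, gt$shared), jaccard(ko, gt$visual))
})

test_that("excluding a mask disjoint from the best set changes nothing", {
  sr <- cached_small_result()
  ncv <- sr$fit$ncv
  cond <- sr$fit$conditions
  f <- ncv$bestFold
  best <- ncv$foldRecords[[f]]$best
  used <- sort(unique(unlist(lapply(best, `[[`, "featureSet"))))
  disjoint <- setdiff(seq_len(nVoxels(sr$study$grid)), used)[1:5]
  out <- evaluateExcluding(ncv, cond, disjoint, sr$study$grid, sr$cfg$rfe)
  for (cn in names(cond))
    expect_equal(out[[cn]]$accuracy, best[[cn]]$accuracy)
})

test_that("an exclusion that empties the map yields the defined chance result", {
  sr <- cached_small_result()
  ncv <- sr$fit$ncv
  cond <- sr$fit$conditions
  everything <- seq_len(nVoxels(sr$study$grid))
  w <- capture_warnings(out <- evaluateExcluding(ncv, cond, everything,
                                                 sr$study$grid, sr$cfg$rfe))
  expect_length(w, 3)
  expect_true(all(grepl("no features", w)))
  expect_equal(out$sighted_visual$accuracy, 0.5)
  expect_true(out$sighted_visual$empty)
})

test_that("the accuracy table covers all train/test pairs with the diagonal within-condition", {
  sr <- cached_small_result()
  tab <- sr$res$tables$whole_map
  expect_identical(nrow(tab), 9L)
  expect_identical(sort(unique(tab$train)), sort(names(sr$fit$conditions)))
  f <- sr$res$bestFold
  best <- sr$fit$ncv$foldRecords[[f]]$best
  for (cn in names(best)) {
    diag_cell <- tab[tab$train == cn & tab$test == cn, ]
    expect_equal(diag_cell$accuracy, best[[cn]]$accuracy)
  }
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(tab$pPermutation > 0 & tab$pPermutation <= 1))
})

test_that("cross-condition evaluation is the identity on its own condition", {
  sr <- cached_small_result()
  f <- sr$res$bestFold
  cond <- sr$fit$conditions
  best <- sr$fit$ncv$foldRecords[[f]]$best
  m <- best$sighted_auditory$model
  expect_equal(crossConditionAccuracy(m, cond$sighted_auditory, f),
               best$sighted_auditory$accuracy)
  # feature mismatch is an explicit error
  shrunk <- cond$sighted_auditory
  shrunk$X <- shrunk$X[, seq_len(max(featureIndices(m)) - 1)]
  expect_error(crossConditionAccuracy(m, shrunk, f), "feature")
})

test_that("restricted retraining fills the table and behaves sanely on training data", {
  sr <- cached_small_result()
  restr <- sr$res$restricted
  expect_identical(nrow(restr$table), 9L)
  for (cn in names(restr$models))
    expect_identical(sort(featureIndices(restr$models[[cn]])),
                     sr$res$knockout)
  # optimism direction: accuracy on own training examples >= test accuracy
  f <- sr$res$bestFold
  cd <- sr$fit$conditions$sighted_auditory
  tr <- cd$foldId != f
  m <- restr$models$sighted_auditory
  train_acc <- accuracyScore(predict(m, cd$X[tr, ]), cd$y[tr])
  test_acc <- restr$table[restr$table$train == "sighted_auditory" &
                          restr$table$test == "sighted_auditory", "accuracy"]
  expect_gte(train_acc, test_acc)
})

test_that("feature bookkeeping is consistent across the three analysis variants", {
  sr <- cached_small_result()
  f <- sr$res$bestFold
  best <- sr$fit$ncv$foldRecords[[f]]$best
  ko <- sr$res$knockout
  for (cn in names(best)) {
    surviving <- sr$res$excluded[[cn]]$featureSet
    expect_length(intersect(surviving, ko), 0)
    expect_true(all(surviving %in% best[[cn]]$featureSet))
    expect_true(all(c(ko, surviving) %in% union(best[[cn]]$featureSet, ko)))
  }
})

test_that("pantomime classification reports fractions and both tests", {
  sr <- cached_small_result()
  pant <- sr$res$pantomime
  expect_true(all(pant$fraction >= 0 & pant$fraction <= 1))
  expect_true(all(pant$pBinomial > 0 & pant$pBinomial <= 1))
  expect_identical(sum(pant$variant == "whole_map"), 6L)
  # a degenerate always-action model labels every pantomime as action
  m <- new("LinearModel", weights = rep(0, 3), bias = 1, cParam = 1,
           objective = 0, featureIdx = 1:3)
  out <- classifyPantomime(m, matrix(rnorm(30), 10))
  expect_equal(out$fraction, 1)
  expect_error(classifyPantomime(m, matrix(0, 0, 3)), "no pantomime")
})

test_that("zero-signal pantomimes are labelled action at chance rate", {
  # mirrors the pipeline setting: training features are centred per voxel
  # (as tanh scaling produces), so a signal-free pattern sits midway
  # between the class means
  set.seed(31)
  fr <- replicate(50, {
    X <- matrix(rnorm(60 * 20), 60)
    y <- rep(c(1, -1), 30)
    X[, 1:4] <- X[, 1:4] + outer(y, rep(0.5, 4))
    m <- svmTrain(X, y)
    classifyPantomime(m, matrix(rnorm(50 * 20), 50))$fraction
  })
  expect_lt(abs(mean(fr) - 0.5), 0.05)
})

test_that("the whole-vs-excluded comparison pairs per-subject accuracies", {
  sr <- cached_small_result()
  kt <- sr$res$knockoutTest
  expect_identical(nrow(kt$perCondition), 3L)
  expect_true(all(kt$perCondition$pWilcoxon > 0 &
                  kt$perCondition$pWilcoxon <= 1))
  expect_equal(kt$pFisher, fisherCombine(kt$perCondition$pWilcoxon))
  # per-subject frames cover every subject of the condition exactly once
  ex <- sr$res$excluded$blind_auditory$perSubject
  expect_identical(sort(ex$subjectId),
                   sort(unique(sr$fit$conditions$blind_auditory$info$subjectId)))
})
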