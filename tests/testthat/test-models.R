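test_that("the default hyperparameter grid enumerates 400 cells", {
  cells <- gridCells(hyperGrid())
  expect_equal(nrow(cells), 5 * 4 * 5 * 2 * 2)
  expect_equal(anyDuplicated(cells), 0L)
  # lexicographic order: batch size varies slowest
  expect_true(!is.unsorted(cells$batchSize))
  expect_error(hyperGrid(batchSizes = integer(0)), "nonempty")
})

test_that("documented presets carry the selected cells per task", {
  p3 <- mlpPresetThreeClass()
  expect_equal(p3[c("batchSize", "nodes", "layers", "learningRate", "solver")],
               list(batchSize = 16L, nodes = 150L, layers = 4L,
                    learningRate = 1e-3, solver = "adam"))
  p1 <- mlpPresetStage1()
  expect_equal(p1$batchSize, 8L)
  expect_equal(p1$layers, 1L)
  p2 <- mlpPresetStage2()
  expect_equal(p2$batchSize, 16L)
  expect_equal(p2$layers, 1L)
})

test_that("the MLP separates Gaussian blobs and yields proper probabilities", {
  set.seed(15)
  n <- 100
  X <- rbind(matrix(rnorm(n * 4, mean = 2), n, 4),
             matrix(rnorm(n * 4, mean = -2), n, 4))
  y <- factor(rep(c("a", "b"), each = n))
  params <- mlpParams(batchSize = 16L, nodes = 20L, layers = 2L, seed = 7L)
  model <- fitMLP(X, y, params)
  P <- predict(model, X)
  expect_equal(unname(rowSums(P)), rep(1, 2 * n), tolerance = 1e-6)
  acc <- mean(predict(model, X, type = "class") == y)
  expect_gt(acc, 0.95)
  # determinism
  model2 <- fitMLP(X, y, params)
  expect_identical(predict(model2, X), P)
  expect_error(fitMLP(cbind(c(1, NA)), factor(c("a", "b")), params), "finite")
  expect_error(fitMLP(X, factor(rep("a", 2 * n)), params), "2 classes")
})

test_that("grid search evaluates every cell and picks the trainable one", {
  set.seed(19)
  n <- 60
  X <- rbind(matrix(rnorm(n * 3, mean = 1.5), n, 3),
             matrix(rnorm(n * 3, mean = -1.5), n, 3))
  y <- factor(rep(c("a", "b"), each = n))
  # single-cell grid returns that cell
  g1 <- hyperGrid(batchSizes = 16L, nodes = 10L, layers = 1L,
                  learningRates = 1e-3, solvers = "adam")
  best1 <- gridSearchMLP(X, y, g1, innerFolds = 2L, seed = 3L)
  expect_equal(best1$nodes, 10L)
  expect_equal(nrow(attr(best1, "scores")), 1L)
  # two cells differing only in learning rate; the vanishing rate cannot
  # train, so the other must win (verified against the per-cell scores)
  g2 <- hyperGrid(batchSizes = 16L, nodes = 10L, layers = 1L,
                  learningRates = c(1e-3, 1e-12), solvers = "adam")
  best2 <- gridSearchMLP(X, y, g2, innerFolds = 2L, seed = 3L)
  scores <- attr(best2, "scores")
  expect_equal(nrow(scores), 2L) # exhaustive: product of axis sizes
  expect_equal(best2$learningRate, 1e-3)
  expect_gt(scores$score[scores$learningRate == 1e-3],
            scores$score[scores$learningRate == 1e-12])
  expect_identical(best2$learningRate,
                   scores$learningRate[which.max(scores$score)])
})

test_that("labels recode to primary-vs-rest", {
  expect_equal(as.character(recodePrimary(c("GBM", "LYM", "MET", "GBM"), "GBM")),
               c("yes", "no", "no", "yes"))
  expect_equal(as.character(recodePrimary(c("GBM", "GBM"), "GBM")),
               c("yes", "yes"))
  expect_length(recodePrimary(character(0), "GBM"), 0)
  expect_error(recodePrimary(c("LYM", "MET"), "GBM"), "not present")
})

test_that("minority upsampling equalizes training counts and nothing else", {
  set.seed(25)
  X <- matrix(rnorm(128 * 3), 128, 3)
  y <- factor(rep(c("MET", "LYM"), c(96, 32)))
  up <- upsampleMinority(X, y, seed = 5L)
  expect_equal(as.vector(table(up$y)), c(96, 96))
  # original rows untouched and first in the output
  expect_identical(up$X[1:128, ], X)
  expect_identical(up$indices[1:128], 1:128)
  # appended rows are all minority resamples
  expect_true(all(y[up$indices[-(1:128)]] == "LYM"))
  # determinism
  up2 <- upsampleMinority(X, y, seed = 5L)
  expect_identical(up$indices, up2$indices)
  # already balanced: unchanged
  yb <- factor(rep(c("a", "b"), each = 10))
  upb <- upsampleMinority(X[1:20, ], yb, seed = 1L)
  expect_identical(upb$X, X[1:20, ])
  expect_error(upsampleMinority(X, factor(rep("MET", 128)), 1L), "2 observed")
})

test_that("the two-stage fit refits encoders per stage on the right samples", {
  spec <- tinyCohortSpec(seed = 41L)
  cohort <- generateCohort(spec)
  blocks <- preprocessedBlocks(cohort)
  labels <- tumorClass(cohort)
  model <- fitTwoStage(blocks, labels, latentDim = 3L,
                       aeConfig = fastConfig(maxEpochs = 20L),
                       primaryClass = "GBM", seed = 13L)
  expect_s4_class(model, "TwoStageModel")
  expect_equal(model@stage2$classes, c("LYM", "MET"))
  # encoders are refit per stage: different training data, different weights
  expect_false(identical(model@stage1$encoders$whole@net,
                         model@stage2$encoders$whole@net))
  expect_equal(sort(model@stage1$classifier$classes), c("no", "yes"))
  expect_equal(model@stage2$classifier$classes, c("LYM", "MET"))
  expect_error(fitTwoStage(blocks, droplevels(labels[labels != "LYM"]),
                           latentDim = 3L, seed = 1L),
               "3 classes")
})

test_that("cascade prediction matches a manual trace of deterministic stubs", {
  model <- stubTwoStageModel()
  # 6 samples x 2 one-column mask blocks; feature1 drives stage 1,
  # feature2 drives stage 2
  f1 <- c(1, -1, 1, -1, -1, 1)
  f2 <- c(1, 1, -1, -1, 1, -1)
  blocks <- list(whole = cbind(f1), enhancing = cbind(f2))
  pred <- predictTwoStage(model, blocks)
  # manual propagation: f1>0 -> GBM; else f2>0 -> LYM else MET
  expect_equal(as.character(pred$final_label),
               c("GBM", "LYM", "GBM", "MET", "LYM", "GBM"))
  expect_equal(pred$stage1_label, c("yes", "no", "yes", "no", "no", "yes"))
  # stage-1 positives are final and carry no stage-2 score
  expect_true(all(is.na(pred$stage2_score[pred$stage1_label == "yes"])))
  # closure: every sample gets exactly one in-alphabet label
  expect_false(anyNA(pred$final_label))
  expect_true(all(pred$final_label %in% c("GBM", "LYM", "MET")))
  # conservation: stage-1 yes + stage-2 routed = n
  expect_equal(sum(pred$stage1_label == "yes") +
                 sum(!is.na(pred$stage2_label)), 6L)

  # boundary: stage 1 claims everything, stage 2 receives the empty set
  blocksAllYes <- list(whole = cbind(rep(1, 4)), enhancing = cbind(rep(1, 4)))
  predAll <- predictTwoStage(model, blocksAllYes)
  expect_true(all(predAll$final_label == "GBM"))
  expect_true(all(is.na(predAll$stage2_label)))
})

test_that("an oracle first stage confines errors to the secondary classes", {
  # feature1 exactly encodes GBM membership, so stage 1 is an oracle;
  # the composite then errs only between LYM and MET
  truth <- factor(rep(c("GBM", "LYM", "MET"), each = 4),
                  levels = c("GBM", "LYM", "MET"))
  f1 <- ifelse(truth == "GBM", 1, -1)
  set.seed(6)
  f2 <- rnorm(12) # stage 2 is an arbitrary rule
  blocks <- list(whole = cbind(f1), enhancing = cbind(f2))
  pred <- predictTwoStage(stubTwoStageModel(), blocks)
  conf <- confusionCounts(pred$final_label, truth, levels(truth))
  expect_equal(sum(conf["GBM", c("LYM", "MET")]), 0L)
  expect_equal(sum(conf[c("LYM", "MET"), "GBM"]), 0L)
  # composite accuracy = (perfect primary + stage-2 binary accuracy) share
  stage2Acc <- mean(pred$final_label[truth != "GBM"] ==
                      as.character(truth[truth != "GBM"]))
  expect_equal(confusionAccuracy(conf), (4 + 8 * stage2Acc) / 12)
})
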