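test_that("stratified CV plans partition every repeat to within one per class", {
  labels <- rep(c("GBM", "LYM", "MET"), c(93, 40, 120))
  plan <- makeCVPlan(labels, k = 5, repeats = 5, seed = 1L)
  assign <- foldAssignments(plan)
  expect_equal(dim(assign), c(253L, 5L))
  for (r in 1:5) {
    # folds partition the samples
    expect_setequal(unique(assign[, r]), 1:5)
    tab <- table(labels, assign[, r])
    # 40 LYM / 5 folds divides exactly: every fold has exactly 8
    expect_true(all(tab["LYM", ] == 8))
    ideal <- c(93, 40, 120) / 5
    expect_true(all(abs(sweep(tab, 1, ideal)) <= 1))
  }
  # different seeds give different partitions
  plan2 <- makeCVPlan(labels, k = 5, repeats = 5, seed = 2L)
  expect_false(identical(assign, foldAssignments(plan2)))
  # same seed reproduces
  expect_identical(assign, foldAssignments(makeCVPlan(labels, 5, 5, 1L)))
  expect_error(makeCVPlan(c("a", "a", "b"), k = 3), "fewer than k")
})

test_that("binary AUC equals exhaustive pairwise concordance", {
  expect_equal(rocAucBinary(c(0.9, 0.8, 0.3), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(rocAucBinary(c(0.4, 0.6), c(TRUE, FALSE)), 0)
  expect_equal(rocAucBinary(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(rocAucBinary(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # property: random fixtures (with ties) up to n = 50 match the
  # brute-force pair enumeration oracle
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(rocAucBinary(scores, pos), bruteForceAuc(scores, pos))
  }
})

test_that("binary AUC agrees with an independent ROC implementation", {
  set.seed(99)
  scores <- rnorm(80)
  pos <- runif(80) < 0.4
  expect_equal(
    rocAucBinary(scores, pos),
    as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                   direction = "<", levels = c(FALSE, TRUE))))
  )
})

test_that("one-vs-rest AUC: separable, null, and brute-force cases", {
  # perfectly separated three-class scores
  truth <- factor(rep(c("a", "b", "c"), each = 4))
  P <- matrix(0.05, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  P[cbind(1:12, as.integer(truth))] <- 0.9
  res <- ovrAuc(P, truth)
  expect_true(all(res$perClass == 1))
  expect_equal(res$micro, 1)
  # permuted labels: micro AUC ~ 0.5
  set.seed(7)
  n <- 3000
  S <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  S <- S / rowSums(S)
  lab <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  expect_lt(abs(ovrAuc(S, lab)$micro - 0.5), 0.03)
  # 6-sample fixture equals brute-force per-class concordance
  S6 <- matrix(c(0.7, 0.2, 0.1,
                 0.3, 0.4, 0.3,
                 0.2, 0.5, 0.3,
                 0.1, 0.1, 0.8,
                 0.5, 0.3, 0.2,
                 0.3, 0.3, 0.4), 6, 3, byrow = TRUE,
               dimnames = list(NULL, c("a", "b", "c")))
  lab6 <- factor(c("a", "b", "b", "c", "a", "c"))
  res6 <- ovrAuc(S6, lab6)
  for (cl in c("a", "b", "c")) {
    expect_equal(res6$perClass[[cl]], bruteForceAuc(S6[, cl], lab6 == cl))
  }
  expect_equal(res6$micro,
               bruteForceAuc(as.vector(S6), as.vector(sapply(c("a", "b", "c"),
                                                             function(cl) lab6 == cl))))
  expect_error(ovrAuc(S6[, 1:2], lab6), "alphabet")
})

test_that("micro precision, recall and F1 collapse to accuracy", {
  truth <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  pred <- c("a", "a", "b", "b", "b", "c", "c", "a", "c")
  res <- microPRF(pred, truth)
  # hand-counted: every class has TP 2, FP 1, FN 1
  expect_equal(res$perClass$Pr, rep(2 / 3, 3))
  expect_equal(res$perClass$Rc, rep(2 / 3, 3))
  expect_equal(res$perClass$F1, rep(2 / 3, 3))
  expect_equal(unname(res$micro), rep(2 / 3, 3))
  # identity property on random single-label prediction sets
  for (seed in 1:10) {
    set.seed(seed)
    t2 <- sample(c("x", "y", "z"), 40, replace = TRUE)
    p2 <- sample(c("x", "y", "z"), 40, replace = TRUE)
    r2 <- microPRF(p2, t2)
    acc <- mean(p2 == t2)
    expect_equal(unname(r2$micro), rep(acc, 3))
  }
  perfect <- microPRF(truth, truth)
  expect_true(all(unlist(perfect$micro) == 1))
  expect_error(microPRF(character(0), character(0)), "nonempty")
})

test_that("confusion matrices count true rows against predicted columns", {
  truth <- c("a", "a", "b")
  m <- confusionCounts(c("a", "b", "b"), truth, c("a", "b"))
  expect_equal(as.vector(m), c(1L, 0L, 1L, 1L))
  expect_equal(confusionAccuracy(m), 2 / 3)
  # identity predictions: diagonal, accuracy 1
  mi <- confusionCounts(truth, truth, c("a", "b"))
  expect_equal(sum(mi) - sum(diag(mi)), 0L)
  expect_equal(confusionAccuracy(mi), 1)
  # all wrong
  mw <- confusionCounts(c("b", "b", "a"), truth, c("a", "b"))
  expect_equal(confusionAccuracy(mw), 0)
  expect_error(confusionCounts(c("a", "z"), c("a", "b"), c("a", "b")),
               "alphabet")
})

test_that("three-class CV produces a Table-style report deterministically", {
  spec <- tinyCohortSpec(seed = 51L)
  cohort <- generateCohort(spec)
  rep1 <- runCVThreeClass(cohort, latentDims = c(2L, 3L),
                          aeConfig = fastConfig(maxEpochs = 30L),
                          mlpParams = mlpParams(nodes = 30L, layers = 2L),
                          k = 3L, repeats = 2L, seed = 19L)
  m <- metricsTable(rep1)
  # one row block per latent setting, classes + ALL
  expect_setequal(unique(m$Setting), c("AE 2 latent", "AE 3 latent"))
  for (s in unique(m$Setting)) {
    expect_setequal(m$Class[m$Setting == s], c("GBM", "LYM", "MET", "ALL"))
  }
  expect_true(all(m$AUC >= 0 & m$AUC <= 1))
  # separable tiny cohort trains to useful performance
  expect_gt(m$AUC[m$Setting == "AE 3 latent" & m$Class == "ALL"], 0.8)
  # fold records cover repeats x folds
  fr <- foldRecords(rep1)
  expect_setequal(unique(fr$fold), 1:3)
  expect_setequal(unique(fr$rep), 1:2)
  # identical master seed reproduces the whole report
  rep2 <- runCVThreeClass(cohort, latentDims = c(2L, 3L),
                          aeConfig = fastConfig(maxEpochs = 30L),
                          mlpParams = mlpParams(nodes = 30L, layers = 2L),
                          k = 3L, repeats = 2L, seed = 19L)
  expect_identical(metricsTable(rep1), metricsTable(rep2))
  expect_identical(confusionMatrices(rep1), confusionMatrices(rep2))
})

test_that("two-stage CV conserves every held-out sample exactly once", {
  spec <- tinyCohortSpec(seed = 61L)
  cohort <- generateCohort(spec)
  rep1 <- runCVTwoStage(cohort, latentDim = 3L,
                        aeConfig = fastConfig(maxEpochs = 30L),
                        stage1Params = mlpParams(nodes = 30L, layers = 1L,
                                                 batchSize = 8L),
                        stage2Params = mlpParams(nodes = 30L, layers = 1L),
                        k = 3L, repeats = 1L, seed = 23L)
  conf <- confusionMatrices(rep1)
  # with one repeat, the combined matrix accounts for each sample once
  expect_equal(unname(rowSums(conf$combined)),
               as.vector(table(tumorClass(cohort))))
  expect_equal(sum(conf$combined), ncol(cohort))
  # stage-1 matrix pools the same samples in recoded form
  expect_equal(sum(conf$stage1), ncol(cohort))
  # stage-2 matrix covers exactly the true-secondary samples
  expect_equal(sum(conf$stage2), sum(tumorClass(cohort) != "GBM"))
  m <- metricsTable(rep1)
  expect_setequal(unique(m$Setting), c("Stage 1", "Stage 2", "Combined"))
  # combined AUC is deliberately absent (hard labels only)
  expect_true(all(is.na(m$AUC[m$Setting == "Combined"])))
  expect_false(anyNA(m$AUC[m$Setting == "Stage 2"]))
})
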