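test_that("encoder widths halve then compress, with a mirrored decoder", {
  spec <- buildAutoencoder(535, 15)
  expect_equal(spec$encoderWidths, c(535L, 267L, 15L))
  expect_equal(spec$decoderWidths, c(15L, 267L, 535L))
  expect_equal(buildAutoencoder(4, 2)$encoderWidths, c(4L, 2L, 2L))
  expect_equal(buildAutoencoder(11, 3)$encoderWidths, c(11L, 5L, 3L)) # floor
  expect_error(buildAutoencoder(10, 11), "latentDim")
  expect_error(buildAutoencoder(10, 0), "latentDim")
  # mirror symmetry for arbitrary dimensions; code layer is the only
  # linear hidden layer
  for (seed in 1:5) {
    set.seed(seed)
    D <- sample(3:200, 1)
    d <- sample(seq_len(D), 1)
    s <- buildAutoencoder(D, d)
    expect_identical(s$decoderWidths, rev(s$encoderWidths))
    expect_identical(which(!s$rectify), length(s$encoderWidths) - 1L)
  }
})

test_that("reconstruction error is the per-cell mean squared difference", {
  # zero-output model on the 2x2 fixture [[0,1],[1,0]] -> 0.5
  ae2 <- zeroReconstructionAE(2)
  expect_equal(reconstructionError(ae2, matrix(c(0, 1, 1, 0), 2, 2)), 0.5)
  # zero-output model on a standardized unit-variance fixture -> ~1
  set.seed(8)
  X <- matrix(rnorm(400 * 3), 400, 3)
  X <- applyStandardizer(X, fitStandardizer(X))
  ae3 <- zeroReconstructionAE(3)
  expect_equal(reconstructionError(ae3, X), 1, tolerance = 1e-9)
  expect_error(reconstructionError(ae3, matrix(0, 2, 5)), "columns")
})

test_that("training is seed-deterministic and rejects missing cells", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30, 8)
  a1 <- trainAutoencoder(X, 2, fastConfig(seed = 11L))
  a2 <- trainAutoencoder(X, 2, fastConfig(seed = 11L))
  expect_identical(a1@lossHistory, a2@lossHistory)
  expect_identical(a1@net, a2@net)
  a3 <- trainAutoencoder(X, 2, fastConfig(seed = 12L))
  expect_false(identical(a1@lossHistory, a3@lossHistory))
  Xna <- X
  Xna[1, 1] <- NA
  expect_error(trainAutoencoder(Xna, 2, fastConfig()), "impute")
  expect_error(trainAutoencoder(X[1, , drop = FALSE], 2, fastConfig()),
               "2 samples")
})

test_that("reconstruction approaches the truncated-SVD oracle on low-rank blocks", {
  # rank-2 signal in 16 columns; the rank-d SVD reconstruction is the
  # best any rank-d code can do, so the trained error must sit at or
  # above it (minus tolerance), and should land near it
  set.seed(21)
  n <- 150
  Z <- matrix(rnorm(n * 2), n, 2)
  W <- matrix(rnorm(2 * 16) / sqrt(2), 2, 16)
  X <- Z %*% W + matrix(rnorm(n * 16, sd = 0.3), n, 16)
  X <- applyStandardizer(X, fitStandardizer(X))
  # narrow blocks improve slowly per epoch: give the optimizer room
  cfg <- trainConfig(maxEpochs = 800L, patience = 60L, minDelta = 1e-5,
                     seed = 3L)
  ae <- trainAutoencoder(X, 2, cfg)
  oracle <- svdMSE(X, 2)
  expect_gte(ae@finalError, oracle - 0.02)
  expect_lt(ae@finalError, 0.2)
  expect_lt(ae@finalError, oracle + 0.1)
})

test_that("capacity is monotone: larger bottlenecks reconstruct no worse", {
  set.seed(13)
  X <- matrix(rnorm(80 * 6), 80, 6)
  X <- applyStandardizer(X, fitStandardizer(X))
  errs <- vapply(c(2L, 4L, 6L), function(d) {
    trainAutoencoder(X, d, trainConfig(seed = 5L))@finalError
  }, numeric(1))
  expect_true(all(diff(errs) <= 0.05)) # tolerance for optimization noise
  # full-width bottleneck reconstructs essentially everything
  expect_lt(errs[3], errs[1] + 0.05)
})

test_that("latent-size selection takes the smallest sub-threshold candidate", {
  curve <- c(`1` = 0.5, `2` = 0.3, `3` = 0.19, `4` = 0.15)
  sel <- selectLatentSize(curve, 0.2)
  expect_equal(sel$selected, 3L)
  expect_true(sel$met)
  # no candidate qualifies: argmin, flagged
  sel2 <- selectLatentSize(c(`1` = 0.9, `2` = 0.5, `3` = 0.7), 0.2)
  expect_equal(sel2$selected, 2L)
  expect_false(sel2$met)
  expect_error(selectLatentSize(numeric(0)), "empty")
})

test_that("the latent search recovers a small intrinsic rank", {
  spec <- tinyCohortSpec(seed = 17L, rank = 2L, fpc = 8L) # 16-col blocks
  cohort <- generateCohort(spec)
  block <- preprocessedBlocks(cohort)$whole
  res <- searchLatentSize(block, 1:6, threshold = 0.2,
                          config = trainConfig(maxEpochs = 600L,
                                               patience = 40L,
                                               minDelta = 1e-5, seed = 2L),
                          maskName = "whole")
  expect_s4_class(res, "LatentSearchResult")
  expect_true(res@metThreshold)
  expect_lte(res@selectedD, 4L)
  expect_lt(res@curve[[as.character(res@selectedD)]], 0.2)
  # curve decreasing within optimization tolerance
  expect_true(all(diff(res@curve) <= 0.05))
  # the returned model is the one refit at the selected size
  expect_equal(res@model@spec$latentDim, res@selectedD)
  expect_error(searchLatentSize(block, integer(0)), "empty")
  expect_error(searchLatentSize(block, 1:99), "candidates")
})

test_that("per-mask codes concatenate in declared mask order", {
  spec <- tinyCohortSpec(seed = 23L)
  cohort <- generateCohort(spec)
  blocks <- preprocessedBlocks(cohort)
  models <- lapply(names(blocks), function(m) {
    trainAutoencoder(blocks[[m]], 3L, fastConfig(seed = 4L, maxEpochs = 20L), m)
  })
  names(models) <- names(blocks)
  Z <- encodeConcat(models, blocks)
  expect_equal(dim(Z), c(86L, 6L))
  expect_identical(colnames(Z),
                   c(paste0("whole.L", 1:3), paste0("enhancing.L", 1:3)))
  # single mask
  Z1 <- encodeConcat(models["whole"], blocks["whole"])
  expect_equal(ncol(Z1), 3L)
  expect_error(encodeConcat(models["whole"], blocks), "no model")
})

test_that("2-D manifolds separate well-separated classes and clip to [-15, 15]", {
  spec <- tinyCohortSpec(seed = 29L,
                         classEffect = c(GBM = 5, LYM = 5, MET = 5),
                         rank = 2L, fpc = 8L)
  cohort <- generateCohort(spec)
  block <- preprocessedBlocks(cohort)$whole
  lab <- tumorClass(cohort)
  png <- withr::local_tempfile(fileext = ".png")
  man <- manifold2d(block, lab, fastConfig(seed = 6L, maxEpochs = 100L),
                    path = png, maskName = "whole")
  expect_equal(ncol(man$coords), 2L)
  expect_true(file.exists(png))
  built <- ggplot2::ggplot_build(man$plot)
  expect_equal(built$layout$coord$limits$x, c(-15, 15))
  expect_equal(built$layout$coord$limits$y, c(-15, 15))
  # GBM and MET centroids separate beyond the mean within-class spread
  cg <- colMeans(man$coords[lab == "GBM", ])
  cm <- colMeans(man$coords[lab == "MET", ])
  spread <- mean(c(
    sqrt(rowSums(sweep(man$coords[lab == "GBM", ], 2, cg)^2)),
    sqrt(rowSums(sweep(man$coords[lab == "MET", ], 2, cm)^2))
  ))
  expect_gt(sqrt(sum((cg - cm)^2)), spread)
  expect_error(manifold2d(block[, 1, drop = FALSE]), "2 feature")
})

test_that("compiled gradients agree with the reference implementation", {
  # R reference backward pass against central finite differences on a
  # small autoencoder with a linear bottleneck
  set.seed(33)
  X <- matrix(rnorm(12 * 5), 12, 5)
  spec <- buildAutoencoder(5, 2)
  layers <- withr::with_seed(1L, radlatent:::.nnInit(spec$widths))
  g <- radlatent:::.nnGradients(layers, X, X, "identity", spec$rectify)
  eps <- 1e-6
  for (li in c(1L, length(layers))) {
    for (probe in list(c(1, 1), c(2, 2))) {
      pert <- layers
      pert[[li]]$W[probe[1], probe[2]] <- pert[[li]]$W[probe[1], probe[2]] + eps
      up <- radlatent:::.nnLoss(pert, X, X, "identity", spec$rectify)
      pert[[li]]$W[probe[1], probe[2]] <- pert[[li]]$W[probe[1], probe[2]] - 2 * eps
      down <- radlatent:::.nnLoss(pert, X, X, "identity", spec$rectify)
      expect_equal(g[[li]]$W[probe[1], probe[2]], (up - down) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
  # the compiled trainer reports exactly the loss of the weights it returns
  fit <- radlatent:::.nnTrain(X, X, spec$widths, "identity", batchSize = 4L,
                              maxEpochs = 5L, patience = 2L, seed = 2L,
                              rectify = spec$rectify)
  expect_equal(radlatent:::.nnLoss(fit$layers, X, X, "identity", spec$rectify),
               fit$history[length(fit$history)], tolerance = 1e-12)
})
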