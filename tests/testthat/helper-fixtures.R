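# Shared fixtures: everything is generated in code at test time.

# small two-mask cohort spec for fast end-to-end runs
tinyCohortSpec <- function(seed = 1L,
                           classCounts = c(GBM = 30L, LYM = 20L, MET = 36L),
                           classEffect = c(GBM = 2.5, LYM = 1.0, MET = 2.5),
                           rank = 3L, fpc = 4L, noiseSd = 0.3) {
  cohortSpec(
    classCounts = classCounts,
    masks = c("whole", "enhancing"),
    sequences = c("T1W", "ADC"),
    featuresPerCombination = fpc,
    intrinsicRank = rank,
    classEffect = classEffect,
    noiseSd = noiseSd,
    seed = seed
  )
}

# standardize + impute every mask block of a cohort (fit on all rows; for
# exploratory/latent tests, not CV)
preprocessedBlocks <- function(cohort, strategy = "mean") {
  lapply(splitByMask(cohort), function(b) {
    p <- suppressWarnings(fitStandardizer(b))
    imputeFeatures(applyStandardizer(b, p), strategy)
  })
}

# short training config for tests where convergence depth is irrelevant
fastConfig <- function(seed = 1L, maxEpochs = 60L) {
  trainConfig(maxEpochs = maxEpochs, patience = 10L, seed = seed)
}

# independent oracle: mean-squared error of the rank-k truncated SVD
# reconstruction (the best rank-k linear approximation)
svdMSE <- function(X, k) {
  sv <- svd(X)
  k <- min(k, length(sv$d))
  R <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k) %*%
    t(sv$v[, seq_len(k), drop = FALSE])
  mean((X - R)^2)
}

# independent oracle: AUC by exhaustive enumeration of (positive, negative)
# pairs, ties counted half
bruteForceAuc <- function(scores, positive) {
  ps <- scores[positive]
  ns <- scores[!positive]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

# a fitted autoencoder whose reconstruction is identically zero, for
# closed-form reconstruction-error fixtures
zeroReconstructionAE <- function(ncols) {
  X <- matrix(rnorm(20 * ncols), 20, ncols)
  ae <- trainAutoencoder(X, 1L, trainConfig(maxEpochs = 2L, patience = 1L, seed = 1L))
  ae@net <- lapply(ae@net, function(l) list(W = l$W * 0, b = l$b * 0))
  ae
}

# deterministic stage stubs over raw (unencoded) 2-column blocks:
# stage 1 says "yes" iff the first feature is positive; stage 2 picks the
# first secondary class iff the second feature is positive
stubTwoStageModel <- function(primaryClass = "GBM",
                              classes = c("GBM", "LYM", "MET")) {
  secondary <- setdiff(classes, primaryClass)
  stub1 <- function(X) {
    p <- as.numeric(X[, 1] > 0)
    cbind(no = 1 - p, yes = p)
  }
  stub2 <- function(X) {
    p <- as.numeric(X[, 2] > 0)
    m <- cbind(p, 1 - p)
    colnames(m) <- secondary
    m
  }
  twoStageModel(primaryClass, classes,
                stage1 = list(encoders = NULL, classifier = stub1),
                stage2 = list(encoders = NULL, classifier = stub2))
}
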