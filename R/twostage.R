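#' Recode labels to primary-vs-rest
#'
#' @param labels Multiclass labels.
#' @param primaryClass Label to treat as the stage-1 target.
#' @return Factor with levels `c("no", "yes")`; `"yes"` for the primary
#'   class, `"no"` for every other label.
#' @examples
#' recodePrimary(c("GBM", "LYM", "MET", "GBM"), "GBM")
#' @export
recodePrimary <- function(labels, primaryClass) {
  labels <- as.factor(labels)
  if (length(labels) && !primaryClass %in% levels(labels)) {
    stop(sprintf("primary class '%s' not present in the label alphabet",
                 primaryClass))
  }
  factor(ifelse(labels == primaryClass, "yes", "no"), levels = c("no", "yes"))
}

#' Upsample the minority class of a binary training set
#'
#' Keeps every original row and appends minority rows resampled with
#' replacement until both classes have equal counts. Majority rows are
#' untouched. Apply to training folds only — the held-out fold is always
#' evaluated on the true class distribution.
#'
#' @param X Feature matrix (samples x features).
#' @param y Binary labels (exactly two observed classes).
#' @param seed Integer seed for the resampling draw.
#' @return List with `X`, `y` and `indices` (row indices into the input,
#'   length `2 * max(class count)`).
#' @export
upsampleMinority <- function(X, y, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("upsampling requires exactly 2 observed classes")
  tab <- table(y)
  if (any(tab == 0L)) stop("a class with 0 rows cannot be upsampled")
  minority <- names(tab)[which.min(tab)]
  deficit <- max(tab) - min(tab)
  extra <- if (deficit > 0) {
    pool <- which(y == minority)
    withr::with_seed(seed, pool[sample.int(length(pool), deficit, replace = TRUE)])
  } else {
    integer(0)
  }
  idx <- c(seq_along(y), extra)
  list(X = X[idx, , drop = FALSE], y = y[idx], indices = idx)
}

#' Assemble a two-stage model from fitted parts
#'
#' Low-level constructor used by [fitTwoStage()] and by tests that inject
#' deterministic stub classifiers. `encoders` may be `NULL` in either
#' stage, meaning the raw concatenated blocks are used unencoded; a
#' classifier may be any object with a `predict` method returning a
#' per-class probability matrix, or a plain function of the feature matrix.
#'
#' @param primaryClass Stage-1 target class.
#' @param classes All class labels in order.
#' @param stage1,stage2 Lists with elements `encoders` and `classifier`
#'   (stage 2 additionally `classes`, defaulting to the secondary labels).
#' @param seed Integer seed to record.
#' @return A [TwoStageModel-class].
#' @export
twoStageModel <- function(primaryClass, classes, stage1, stage2, seed = 1L) {
  if (is.null(stage2$classes)) {
    stage2$classes <- setdiff(classes, primaryClass)
  }
  new("TwoStageModel",
      primaryClass = primaryClass,
      classes = classes,
      stage1 = stage1,
      stage2 = stage2,
      seed = as.integer(seed))
}

# encode per-mask blocks with a stage's encoders (identity when NULL)
.stageEncode <- function(stage, blocks) {
  if (is.null(stage$encoders)) {
    do.call(cbind, blocks)
  } else {
    encodeConcat(stage$encoders, blocks)
  }
}

#' Fit the two-stage multiclass-decomposition cascade
#'
#' Stage 1: per-mask autoencoders are fit to all training samples, the
#' codes concatenated, and a binary MLP fit to the primary-vs-rest recoded
#' labels. Stage 2: primary-class samples are removed, the minority
#' secondary class is upsampled to parity, fresh per-mask autoencoders are
#' fit to the upsampled rows, and a second binary MLP distinguishes the two
#' secondary classes. Both stages use the same latent size per mask.
#'
#' @param blocks Named list of standardized, imputed per-mask training
#'   matrices (all with the same rows).
#' @param labels Three-class training labels aligned with the block rows.
#' @param latentDim Bottleneck size per mask (default 15).
#' @param aeConfig [trainConfig()] for the autoencoders.
#' @param stage1Params,stage2Params [mlpParams()] for the two binary MLPs
#'   (defaults: the documented stage presets).
#' @param primaryClass Stage-1 target (default `"GBM"`).
#' @param seed Master seed; every stochastic part derives its own seed.
#' @return A [TwoStageModel-class].
#' @export
fitTwoStage <- function(blocks, labels, latentDim = 15L,
                        aeConfig = trainConfig(),
                        stage1Params = mlpPresetStage1(),
                        stage2Params = mlpPresetStage2(),
                        primaryClass = "GBM", seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 3L) {
    stop(sprintf("two-stage decomposition needs all 3 classes present, got %d",
                 nlevels(labels)))
  }
  classes <- levels(labels)
  if (!primaryClass %in% classes) {
    stop(sprintf("primary class '%s' not among labels", primaryClass))
  }
  fitStageEncoders <- function(stageBlocks, tag) {
    encs <- lapply(names(stageBlocks), function(m) {
      cfg <- aeConfig
      cfg$seed <- deriveSeed(seed, sprintf("%s/ae/%s", tag, m))
      trainAutoencoder(stageBlocks[[m]], latentDim, cfg, maskName = m)
    })
    names(encs) <- names(stageBlocks)
    encs
  }

  # stage 1: all samples, recoded labels
  enc1 <- fitStageEncoders(blocks, "stage1")
  Z1 <- encodeConcat(enc1, blocks)
  y1 <- recodePrimary(labels, primaryClass)
  p1 <- stage1Params
  p1$seed <- deriveSeed(seed, "stage1/mlp")
  clf1 <- fitMLP(Z1, y1, p1)

  # stage 2: secondary classes only, minority upsampled, fresh encoders
  secondary <- labels != primaryClass
  upBlocks <- lapply(blocks, function(b) b[secondary, , drop = FALSE])
  y2 <- droplevels(labels[secondary])
  up <- upsampleMinority(upBlocks[[1L]], y2,
                         seed = deriveSeed(seed, "stage2/upsample"))
  upBlocks <- lapply(upBlocks, function(b) b[up$indices, , drop = FALSE])
  y2 <- up$y
  enc2 <- fitStageEncoders(upBlocks, "stage2")
  Z2 <- encodeConcat(enc2, upBlocks)
  p2 <- stage2Params
  p2$seed <- deriveSeed(seed, "stage2/mlp")
  clf2 <- fitMLP(Z2, y2, p2)

  twoStageModel(
    primaryClass = primaryClass,
    classes = classes,
    stage1 = list(encoders = enc1, classifier = clf1),
    stage2 = list(encoders = enc2, classifier = clf2,
                  classes = setdiff(classes, primaryClass)),
    seed = seed
  )
}

#' Predict with the two-stage cascade
#'
#' Stage 1 scores every sample; samples with positive-class probability
#' at or above the threshold receive the primary class and are final.
#' Every remaining sample — including stage-1 false negatives, which carry
#' through and can only receive a secondary label — is routed to stage 2
#' and labeled with its binary decision. Each sample receives exactly one
#' final label.
#'
#' @param model A [TwoStageModel-class].
#' @param blocks Named list of per-mask test matrices, preprocessed with
#'   training-fold statistics.
#' @param threshold Stage-1 decision threshold on the "yes" probability
#'   (default 0.5).
#' @return `data.frame` with `stage1_score` (P(primary)), `stage1_label`
#'   (`"yes"`/`"no"`), `stage2_score` (P(second secondary class), `NA` for
#'   samples decided at stage 1), `stage2_label` and `final_label`.
#' @export
predictTwoStage <- function(model, blocks, threshold = 0.5) {
  stopifnot(is(model, "TwoStageModel"))
  Z1 <- .stageEncode(model@stage1, blocks)
  P1 <- .classifierProb(model@stage1$classifier, Z1, classes = c("no", "yes"))
  s1 <- P1[, "yes"]
  s1Label <- ifelse(s1 >= threshold, "yes", "no")
  n <- length(s1)

  final <- rep(NA_character_, n)
  final[s1Label == "yes"] <- model@primaryClass
  s2Score <- rep(NA_real_, n)
  s2Label <- rep(NA_character_, n)

  route <- which(s1Label == "no")
  if (length(route)) {
    routeBlocks <- lapply(blocks, function(b) b[route, , drop = FALSE])
    Z2 <- .stageEncode(model@stage2, routeBlocks)
    cls2 <- model@stage2$classes
    P2 <- .classifierProb(model@stage2$classifier, Z2, classes = cls2)
    # argmax with ties toward the earlier secondary class
    pick <- cls2[max.col(P2, ties.method = "first")]
    s2Score[route] <- P2[, cls2[2L]]
    s2Label[route] <- pick
    final[route] <- pick
  }
  data.frame(
    stage1_score = s1,
    stage1_label = s1Label,
    stage2_score = s2Score,
    stage2_label = s2Label,
    final_label = factor(final, levels = model@classes),
    stringsAsFactors = FALSE
  )
}

setMethod("show", "TwoStageModel", function(object) {
  cat(sprintf("TwoStageModel: stage 1 = %s vs rest; stage 2 = %s\n",
              object@primaryClass,
              paste(object@stage2$classes, collapse = " vs ")))
})
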