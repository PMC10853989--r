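# shared per-fold plumbing: split a cohort's mask blocks into train/test
# and preprocess with training-fold statistics only
.foldBlocks <- function(blocks, trainIdx, testIdx, imputation, flagValue) {
  trainBlocks <- lapply(blocks, function(b) b[trainIdx, , drop = FALSE])
  testBlocks <- lapply(blocks, function(b) b[testIdx, , drop = FALSE])
  .preprocessBlocks(trainBlocks, testBlocks, strategy = imputation,
                    flagValue = flagValue)
}

# fit one autoencoder per mask on the training blocks
.fitFoldEncoders <- function(trainBlocks, latentDim, aeConfig, seed, tag) {
  encs <- lapply(names(trainBlocks), function(m) {
    cfg <- aeConfig
    cfg$seed <- deriveSeed(seed, sprintf("%s/ae/%s", tag, m))
    trainAutoencoder(trainBlocks[[m]], latentDim, cfg, maskName = m)
  })
  names(encs) <- names(trainBlocks)
  encs
}

#' Cross-validated evaluation of the three-class pipeline
#'
#' For every repeat and fold: standardization and imputation are fit on
#' the training rows only; one autoencoder per mask is fit to the
#' preprocessed training block; both folds are encoded and concatenated;
#' an MLP is fit to the encoded training fold and scores the held-out
#' fold. Per-class and micro-averaged one-vs-rest AUC, precision, recall
#' and F1 are aggregated over all `repeats * k` fold evaluations. One
#' result block is produced per requested latent setting; `latentDims = NA`
#' requests the uncompressed "Full set" (MLP on all standardized features).
#'
#' @param cohort A [RadiomicCohort-class].
#' @param latentDims Integer vector of latent sizes per mask (default 15);
#'   may include `NA` for the full-feature baseline.
#' @param aeConfig [trainConfig()] for the per-fold autoencoders.
#' @param mlpParams [mlpParams()] for the classifier (default: the
#'   documented three-class preset).
#' @param k,repeats Cross-validation plan (default 5 x 5).
#' @param imputation Imputation strategy after standardization.
#' @param flagValue Sentinel for the `"flag"` strategy.
#' @param seed Master seed; folds, autoencoders and MLPs derive their own.
#' @return An [EvaluationReport-class].
#' @export
runCVThreeClass <- function(cohort, latentDims = 15L,
                            aeConfig = trainConfig(),
                            mlpParams = mlpPresetThreeClass(),
                            k = 5L, repeats = 5L,
                            imputation = c("mean", "zero", "flag"),
                            flagValue = -9999,
                            seed = 1L) {
  imputation <- match.arg(imputation)
  stopifnot(is(cohort, "RadiomicCohort"))
  labels <- tumorClass(cohort)
  classes <- levels(labels)
  blocks <- splitByMask(cohort)
  plan <- makeCVPlan(labels, k = k, repeats = repeats,
                     seed = deriveSeed(seed, "cv/plan"))
  assign <- foldAssignments(plan)

  records <- list()
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (setting in latentDims) {
    settingName <- if (is.na(setting)) "Full set" else sprintf("AE %d latent", setting)
    for (r in seq_len(repeats)) {
      for (f in seq_len(k)) {
        tag <- sprintf("%s/rep%d/fold%d", settingName, r, f)
        trainIdx <- which(assign[, r] != f)
        testIdx <- which(assign[, r] == f)
        prep <- .foldBlocks(blocks, trainIdx, testIdx, imputation, flagValue)
        if (is.na(setting)) {
          Ztr <- do.call(cbind, prep$train)
          Zte <- do.call(cbind, prep$test)
        } else {
          encs <- .fitFoldEncoders(prep$train, setting, aeConfig, seed, tag)
          Ztr <- encodeConcat(encs, prep$train)
          Zte <- encodeConcat(encs, prep$test)
        }
        p <- mlpParams
        p$seed <- deriveSeed(seed, paste0(tag, "/mlp"))
        model <- tryCatch(fitMLP(Ztr, labels[trainIdx], p),
                          error = function(e) {
                            stop(sprintf("[%s] MLP fit failed: %s", tag,
                                         conditionMessage(e)))
                          })
        P <- predict(model, Zte)
        pred <- predict(model, Zte, type = "class")
        truth <- labels[testIdx]
        auc <- ovrAuc(P, truth)
        prf <- microPRF(pred, truth)
        confusion <- confusion + confusionCounts(pred, truth, classes)
        rec <- rbind(
          do.call(rbind, lapply(classes, function(cl) {
            pc <- prf$perClass[prf$perClass$class == cl, ]
            .foldRecord(r, f, settingName, cl,
                        c("AUC", "Pr", "Rc", "F1"),
                        c(auc$perClass[[cl]], pc$Pr, pc$Rc, pc$F1))
          })),
          .foldRecord(r, f, settingName, "ALL",
                      c("AUC", "Pr", "Rc", "F1"),
                      c(auc$micro, prf$micro[["Pr"]], prf$micro[["Rc"]],
                        prf$micro[["F1"]]))
        )
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  records <- do.call(rbind, records)
  new("EvaluationReport",
      model = "Three-Class MLP",
      metrics = .aggregateRecords(records, "Three-Class MLP"),
      confusion = list(combined = confusion),
      folds = records,
      k = as.integer(k), repeats = as.integer(repeats),
      seed = as.integer(seed))
}

#' Cross-validated evaluation of the two-stage cascade
#'
#' Per fold, [fitTwoStage()] is fit on the preprocessed training rows and
#' the held-out fold is evaluated three ways: (a) stage-1 binary metrics
#' against the primary-vs-rest recoded truth; (b) stage-2 binary metrics
#' on the held-out samples whose *true* class is secondary, scored by the
#' stage-2 pipeline directly (no stage-1 carry-through, so only the
#' classes the stage trained on are involved); and (c) the combined
#' cascade against the three-class truth *with* carry-through — stage-1
#' positives are final, everything else gets a secondary label. The
#' combined block reports no AUC: the cascade emits hard labels, and
#' stage scores are not comparable across routes (exported per fold for
#' inspection instead). Confusion matrices for all three views are summed
#' over folds and repeats.
#'
#' @inheritParams runCVThreeClass
#' @param latentDim Single latent size per mask used by both stages.
#' @param stage1Params,stage2Params [mlpParams()] for the two binary MLPs.
#' @param primaryClass Stage-1 target class (default `"GBM"`).
#' @param threshold Stage-1 decision threshold (default 0.5).
#' @return An [EvaluationReport-class] with settings `Stage 1`, `Stage 2`
#'   and `Combined`, and confusion matrices `stage1`, `stage2`, `combined`.
#' @export
runCVTwoStage <- function(cohort, latentDim = 15L,
                          aeConfig = trainConfig(),
                          stage1Params = mlpPresetStage1(),
                          stage2Params = mlpPresetStage2(),
                          primaryClass = "GBM",
                          threshold = 0.5,
                          k = 5L, repeats = 5L,
                          imputation = c("mean", "zero", "flag"),
                          flagValue = -9999,
                          seed = 1L) {
  imputation <- match.arg(imputation)
  stopifnot(is(cohort, "RadiomicCohort"))
  labels <- tumorClass(cohort)
  classes <- levels(labels)
  if (!primaryClass %in% classes) {
    stop(sprintf("primary class '%s' not among cohort labels", primaryClass))
  }
  secondaryClasses <- setdiff(classes, primaryClass)
  blocks <- splitByMask(cohort)
  plan <- makeCVPlan(labels, k = k, repeats = repeats,
                     seed = deriveSeed(seed, "cv/plan"))
  assign <- foldAssignments(plan)

  records <- list()
  conf1 <- matrix(0L, 2, 2, dimnames = list(true = c("no", "yes"),
                                            predicted = c("no", "yes")))
  conf2 <- matrix(0L, 2, 2, dimnames = list(true = secondaryClasses,
                                            predicted = secondaryClasses))
  confC <- matrix(0L, length(classes), length(classes),
                  dimnames = list(true = classes, predicted = classes))
  for (r in seq_len(repeats)) {
    for (f in seq_len(k)) {
      tag <- sprintf("twostage/rep%d/fold%d", r, f)
      trainIdx <- which(assign[, r] != f)
      testIdx <- which(assign[, r] == f)
      prep <- .foldBlocks(blocks, trainIdx, testIdx, imputation, flagValue)
      model <- tryCatch(
        fitTwoStage(prep$train, labels[trainIdx], latentDim = latentDim,
                    aeConfig = aeConfig, stage1Params = stage1Params,
                    stage2Params = stage2Params, primaryClass = primaryClass,
                    seed = deriveSeed(seed, tag)),
        error = function(e) {
          stop(sprintf("[%s] two-stage fit failed: %s", tag,
                       conditionMessage(e)))
        })
      pred <- predictTwoStage(model, prep$test, threshold = threshold)
      truth <- labels[testIdx]

      # (a) stage 1 vs recoded truth
      y1 <- recodePrimary(truth, primaryClass)
      auc1 <- rocAucBinary(pred$stage1_score, y1 == "yes")
      prf1 <- microPRF(pred$stage1_label, y1)
      conf1 <- conf1 + confusionCounts(pred$stage1_label, y1, c("no", "yes"))
      pcPrimary <- prf1$perClass[prf1$perClass$class == "yes", ]
      pcRest <- prf1$perClass[prf1$perClass$class == "no", ]
      records[[length(records) + 1L]] <- rbind(
        .foldRecord(r, f, "Stage 1", primaryClass,
                    c("AUC", "Pr", "Rc", "F1"),
                    c(auc1, pcPrimary$Pr, pcPrimary$Rc, pcPrimary$F1)),
        .foldRecord(r, f, "Stage 1", "REST",
                    c("Pr", "Rc", "F1"),
                    c(pcRest$Pr, pcRest$Rc, pcRest$F1))
      )

      # (b) stage 2 on true-secondary samples, no carry-through
      sec <- which(truth %in% secondaryClasses)
      if (length(sec) && all(secondaryClasses %in% truth[sec])) {
        secBlocks <- lapply(prep$test, function(b) b[sec, , drop = FALSE])
        Z2 <- .stageEncode(model@stage2, secBlocks)
        P2 <- .classifierProb(model@stage2$classifier, Z2,
                              classes = secondaryClasses)
        pred2 <- secondaryClasses[max.col(P2, ties.method = "first")]
        truth2 <- factor(as.character(truth[sec]), levels = secondaryClasses)
        prf2 <- microPRF(pred2, truth2)
        conf2 <- conf2 + confusionCounts(pred2, truth2, secondaryClasses)
        for (cl in secondaryClasses) {
          pc <- prf2$perClass[prf2$perClass$class == cl, ]
          records[[length(records) + 1L]] <- .foldRecord(
            r, f, "Stage 2", cl, c("AUC", "Pr", "Rc", "F1"),
            c(rocAucBinary(P2[, cl], truth2 == cl), pc$Pr, pc$Rc, pc$F1))
        }
      }

      # (c) combined cascade with carry-through; hard labels only, no AUC
      prfC <- microPRF(pred$final_label, truth)
      confC <- confC + confusionCounts(pred$final_label, truth, classes)
      records[[length(records) + 1L]] <- .foldRecord(
        r, f, "Combined", "ALL", c("Pr", "Rc", "F1"),
        c(prfC$micro[["Pr"]], prfC$micro[["Rc"]], prfC$micro[["F1"]]))
      for (cl in classes) {
        pc <- prfC$perClass[prfC$perClass$class == cl, ]
        records[[length(records) + 1L]] <- .foldRecord(
          r, f, "Combined", cl, c("Pr", "Rc", "F1"),
          c(pc$Pr, pc$Rc, pc$F1))
      }
    }
  }
  records <- do.call(rbind, records)
  new("EvaluationReport",
      model = "Two-Stage",
      metrics = .aggregateRecords(records, "Two-Stage"),
      confusion = list(stage1 = conf1, stage2 = conf2, combined = confC),
      folds = records,
      k = as.integer(k), repeats = as.integer(repeats),
      seed = as.integer(seed))
}
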