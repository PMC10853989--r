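#' Build a repeated stratified k-fold cross-validation plan
#'
#' Per repeat, each class's samples are shuffled and dealt round-robin over
#' the folds, so every fold's class count is within one of `n_class / k`.
#' Deterministic given the seed; every class must have at least `k`
#' members.
#'
#' @param labels Per-sample class labels.
#' @param k Folds per repeat (default 5).
#' @param repeats Number of independent partitions (default 5).
#' @param seed Integer seed.
#' @return A [CVPlan-class].
#' @examples
#' plan <- makeCVPlan(rep(c("GBM", "LYM", "MET"), c(93, 40, 120)), seed = 1)
#' table(foldAssignments(plan)[, 1]) # five folds of 50/51/51/51/50
#' @export
makeCVPlan <- function(labels, k = 5L, repeats = 5L, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  k <- as.integer(k)
  repeats <- as.integer(repeats)
  small <- table(labels) < k
  if (any(small)) {
    stop(sprintf("class '%s' has fewer than k = %d members",
                 names(which(small))[1], k))
  }
  n <- length(labels)
  assignments <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    repSeed <- deriveSeed(seed, sprintf("cvplan/rep%d", r))
    assignments[, r] <- withr::with_seed(repSeed, {
      fold <- integer(n)
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        # rotate the starting fold per class so remainders spread out
        start <- sample.int(k, 1L)
        fold[idx] <- ((seq_along(idx) - 1L + start - 1L) %% k) + 1L
      }
      fold
    })
  }
  new("CVPlan", k = k, repeats = repeats, assignments = assignments,
      labels = labels, seed = as.integer(seed))
}

#' Fold assignments of a CV plan
#'
#' @param plan A [CVPlan-class].
#' @return Integer matrix (samples x repeats) of fold indices.
#' @export
foldAssignments <- function(plan) {
  stopifnot(is(plan, "CVPlan"))
  plan@assignments
}

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan: %d-fold x %d repeats over %d samples (%d classes), seed %d\n",
              object@k, object@repeats, length(object@labels),
              nlevels(object@labels), object@seed))
})

#' Binary ROC AUC by rank concordance
#'
#' Equals the Mann-Whitney statistic `P(score+ > score-) + 0.5 P(tie)`,
#' computed from midranks so ties get half credit.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Logical vector (or coercible factor against `positive`).
#' @param positive The positive level when `labels` is not logical.
#' @return AUC in [0, 1].
#' @examples
#' rocAucBinary(c(0.9, 0.8, 0.3), c(TRUE, TRUE, FALSE)) # 1
#' rocAucBinary(c(0.4, 0.6), c(TRUE, FALSE))            # 0
#' @export
rocAucBinary <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels)) {
    labels <- as.factor(labels)
    if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
    labels <- labels == positive
  }
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores) # midranks handle ties
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' One-vs-rest multiclass AUC
#'
#' Per class, the binary AUC of that class's score column against the
#' indicator `label == class`; the micro-average pools every
#' (sample, class) pair of the flattened score matrix against the one-hot
#' truth.
#'
#' @param scores Numeric matrix (samples x classes), columns named by class.
#' @param labels Per-sample true labels.
#' @return List with `perClass` (named numeric) and `micro` (numeric).
#' @export
ovrAuc <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (is.null(colnames(scores)) || !all(classes %in% colnames(scores))) {
    stop("score columns must cover the label alphabet")
  }
  perClass <- vapply(classes, function(cl) {
    rocAucBinary(scores[, cl], labels == cl)
  }, numeric(1))
  oneHot <- .oneHot(labels)
  micro <- rocAucBinary(as.vector(scores[, classes]),
                        as.vector(oneHot[, classes]) > 0)
  list(perClass = perClass, micro = micro)
}

#' Per-class and micro-averaged precision / recall / F1
#'
#' Per class, one-vs-rest precision, recall and F1; the micro average
#' pools TP/FP/FN over classes. For single-label multiclass predictions
#' micro precision, recall and F1 all equal accuracy.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return List with `perClass` (data.frame class/Pr/Rc/F1) and `micro`
#'   (named numeric Pr/Rc/F1). Undefined ratios (empty denominator) are 0.
#' @export
microPRF <- function(predicted, truth) {
  if (!length(truth) || length(predicted) != length(truth)) {
    stop("predicted and truth must be nonempty and of equal length")
  }
  classes <- levels(as.factor(truth))
  predicted <- factor(as.character(predicted),
                      levels = union(classes, unique(as.character(predicted))))
  truth <- factor(as.character(truth), levels = levels(predicted))
  safe <- function(num, den) if (den == 0) 0 else num / den
  rows <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    pr <- safe(tp, tp + fp)
    rc <- safe(tp, tp + fn)
    f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    data.frame(class = cl, Pr = pr, Rc = rc, F1 = f1)
  })
  tp <- sum(vapply(classes, function(cl) sum(predicted == cl & truth == cl), numeric(1)))
  fp <- sum(vapply(classes, function(cl) sum(predicted == cl & truth != cl), numeric(1)))
  fn <- sum(vapply(classes, function(cl) sum(predicted != cl & truth == cl), numeric(1)))
  pr <- safe(tp, tp + fp)
  rc <- safe(tp, tp + fn)
  f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  list(perClass = do.call(rbind, rows), micro = c(Pr = pr, Rc = rc, F1 = f1))
}

#' Confusion matrix and its accuracy
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param predicted,truth Label vectors.
#' @param classes Label alphabet fixing the row/column order; defaults to
#'   the union of levels.
#' @return Integer matrix.
#' @examples
#' m <- confusionCounts(c("a", "b", "b"), c("a", "b", "a"), c("a", "b"))
#' confusionAccuracy(m) # 2/3
#' @export
confusionCounts <- function(predicted, truth, classes = NULL) {
  if (is.null(classes)) {
    classes <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  }
  bad <- setdiff(unique(c(as.character(predicted), as.character(truth))), classes)
  if (length(bad)) {
    stop(sprintf("labels outside the declared alphabet: %s",
                 paste(bad, collapse = ", ")))
  }
  m <- table(true = factor(truth, levels = classes),
             predicted = factor(predicted, levels = classes))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  m
}

#' @rdname confusionCounts
#' @param m A square confusion matrix (rows true, columns predicted).
#' @export
confusionAccuracy <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  sum(diag(m)) / sum(m)
}

# ----------------------------------------------------- report construction

# one tidy record block for a fold evaluation
.foldRecord <- function(rep, fold, setting, class, metric, value) {
  data.frame(rep = rep, fold = fold, setting = setting, class = class,
             metric = metric, value = value, stringsAsFactors = FALSE)
}

# aggregate tidy fold records (mean + sd over repeats x folds) into the
# Model / Setting / Class / AUC / Pr / Rc / F1 layout
.aggregateRecords <- function(records, model) {
  keys <- unique(records[, c("setting", "class")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$setting == keys$setting[i] &
                     records$class == keys$class[i], ]
    out <- data.frame(Model = model, Setting = keys$setting[i],
                      Class = keys$class[i], stringsAsFactors = FALSE)
    for (met in c("AUC", "Pr", "Rc", "F1")) {
      v <- sub$value[sub$metric == met]
      out[[met]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(met, "_sd")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' @rdname metricsTable
#' @export
setMethod("metricsTable", "EvaluationReport", function(x) x@metrics)

#' @rdname confusionMatrices
#' @export
setMethod("confusionMatrices", "EvaluationReport", function(x) x@confusion)

#' @rdname foldRecords
#' @export
setMethod("foldRecords", "EvaluationReport", function(x) x@folds)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s]: %d-fold x %d repeats, seed %d\n",
              object@model, object@k, object@repeats, object@seed))
  m <- object@metrics
  print(m[, c("Model", "Setting", "Class", "AUC", "Pr", "Rc", "F1")],
        digits = 3, row.names = FALSE)
})

#' Write an evaluation report to disk
#'
#' Emits `report.csv` and `report.json` (Model / Setting / Class / AUC /
#' Pr / Rc / F1 rows), one `confusion_<name>.csv` per confusion matrix,
#' and `folds.csv` with the tidy per-fold records.
#'
#' @param report An [EvaluationReport-class].
#' @param path Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- character(0)
  f <- file.path(path, "report.csv")
  data.table::fwrite(metricsTable(report), f)
  files <- c(files, f)
  f <- file.path(path, "report.json")
  jsonlite::write_json(
    list(model = report@model, k = report@k, repeats = report@repeats,
         seed = report@seed, metrics = metricsTable(report)),
    f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  for (nm in names(confusionMatrices(report))) {
    f <- file.path(path, sprintf("confusion_%s.csv", nm))
    m <- confusionMatrices(report)[[nm]]
    utils::write.csv(as.data.frame(m), f)
    files <- c(files, f)
  }
  f <- file.path(path, "folds.csv")
  data.table::fwrite(foldRecords(report), f)
  files <- c(files, f)
  invisible(files)
}
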