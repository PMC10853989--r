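#' @importFrom methods setGeneric setClass setMethod setValidity new validObject is slot
#' @importFrom stats rnorm runif rbinom sd predict
NULL

#' Sample-by-feature matrix of a cohort
#'
#' @param x A [RadiomicCohort-class].
#' @return Numeric matrix, samples in rows, radiomic features in columns
#'   (missing mask blocks as `NA`).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Tumor class labels of a cohort
#'
#' @param x A [RadiomicCohort-class].
#' @return Factor of per-sample labels (e.g. GBM / LYM / MET).
#' @export
setGeneric("tumorClass", function(x) standardGeneric("tumorClass"))

#' ROI mask names, in declared order
#'
#' @param x A [RadiomicCohort-class] or [CohortSpec-class].
#' @return Character vector of mask names.
#' @export
setGeneric("maskNames", function(x) standardGeneric("maskNames"))

#' MRI sequence names, in declared order
#'
#' @param x A [RadiomicCohort-class] or [CohortSpec-class].
#' @return Character vector of sequence names.
#' @export
setGeneric("sequenceNames", function(x) standardGeneric("sequenceNames"))

#' Per-feature metadata (mask, sequence, feature name)
#'
#' @param x A [RadiomicCohort-class].
#' @return A `data.frame` with one row per feature column.
#' @export
setGeneric("featureMeta", function(x) standardGeneric("featureMeta"))

#' Sample-by-mask block missingness indicators
#'
#' @param x A [RadiomicCohort-class].
#' @return Logical matrix, samples in rows, masks in columns; `TRUE` where
#'   the sample's whole mask block is missing.
#' @export
setGeneric("missingBlocks", function(x) standardGeneric("missingBlocks"))

#' Extract the sub-table for one ROI mask
#'
#' @param x A [RadiomicCohort-class].
#' @param mask Mask name.
#' @return Numeric matrix, samples in rows, that mask's feature columns (all
#'   sequences) in original order.
#' @export
setGeneric("maskBlock", function(x, mask) standardGeneric("maskBlock"))

#' Aggregated metrics table of an evaluation report
#'
#' @param x An [EvaluationReport-class].
#' @return A `data.frame` in Model / Setting / Class / AUC / Pr / Rc / F1
#'   layout, with dispersion (sd over fold evaluations) alongside each mean.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' Confusion matrices of an evaluation report
#'
#' @param x An [EvaluationReport-class].
#' @return Named list of integer confusion matrices (rows = true class,
#'   columns = predicted class), summed over all folds and repeats.
#' @export
setGeneric("confusionMatrices", function(x) standardGeneric("confusionMatrices"))

#' Per-fold metric records of an evaluation report
#'
#' @param x An [EvaluationReport-class].
#' @return Tidy `data.frame` (repeat, fold, setting, class, metric, value).
#' @export
setGeneric("foldRecords", function(x) standardGeneric("foldRecords"))
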