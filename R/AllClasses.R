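#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------- CohortSpec

#' Specification of a synthetic radiomic cohort
#'
#' Describes the dimensional structure (masks x sequences x features per
#' combination), class composition, latent class-separation geometry, noise
#' level and per-(mask, class) block-missingness rates of a simulated
#' radiomic study. Build one with [cohortSpec()].
#'
#' @slot classCounts Named integer vector, samples per tumor class.
#' @slot masks Character vector of ROI mask names, in order.
#' @slot sequences Character vector of MRI sequence names, in order.
#' @slot featuresPerCombination Integer, radiomic features per
#'   (mask, sequence) combination.
#' @slot intrinsicRank Named integer vector, latent dimensionality of each
#'   mask's low-rank signal.
#' @slot classEffect Named numeric vector, magnitude of each class's latent
#'   mean offset (controls class separability).
#' @slot noiseSd Positive numeric, standard deviation of the isotropic
#'   feature noise added on top of the low-rank signal.
#' @slot missingRates Numeric matrix (masks x classes) of probabilities that
#'   a sample of that class is missing that whole mask block.
#' @slot seed Integer seed; same spec + seed reproduces the cohort exactly.
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    classCounts = "integer",
    masks = "character",
    sequences = "character",
    featuresPerCombination = "integer",
    intrinsicRank = "integer",
    classEffect = "numeric",
    noiseSd = "numeric",
    missingRates = "matrix",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  cc <- object@classCounts
  if (is.null(names(cc)) || anyNA(cc) || any(cc < 0)) {
    msgs <- c(msgs, "classCounts: must be named, non-missing and >= 0")
  }
  if (sum(cc) <= 0) msgs <- c(msgs, "classCounts: total sample count must be > 0")
  if (length(object@masks) < 1 || anyDuplicated(object@masks)) {
    msgs <- c(msgs, "masks: need at least one unique mask name")
  }
  if (length(object@sequences) < 1 || anyDuplicated(object@sequences)) {
    msgs <- c(msgs, "sequences: need at least one unique sequence name")
  }
  fpc <- object@featuresPerCombination
  if (length(fpc) != 1L || is.na(fpc) || fpc < 1) {
    msgs <- c(msgs, "featuresPerCombination: must be a single integer >= 1")
  }
  blockWidth <- length(object@sequences) * fpc
  ir <- object@intrinsicRank
  if (!setequal(names(ir), object@masks)) {
    msgs <- c(msgs, "intrinsicRank: must be named by mask")
  } else {
    if (any(ir < 1)) msgs <- c(msgs, "intrinsicRank: every rank must be >= 1")
    if (any(ir > blockWidth)) {
      msgs <- c(msgs, sprintf(
        "intrinsicRank: rank exceeds per-mask block width (%d)", blockWidth))
    }
  }
  if (!setequal(names(object@classEffect), names(cc))) {
    msgs <- c(msgs, "classEffect: must be named by class")
  }
  if (length(object@noiseSd) != 1L || is.na(object@noiseSd) || object@noiseSd <= 0) {
    msgs <- c(msgs, "noiseSd: must be a single positive number")
  }
  mr <- object@missingRates
  if (!identical(rownames(mr), object@masks) ||
      !setequal(colnames(mr), names(cc))) {
    msgs <- c(msgs, "missingRates: must be a masks x classes matrix")
  } else if (anyNA(mr) || any(mr < 0) || any(mr > 1)) {
    msgs <- c(msgs, "missingRates: every rate must be in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

# ------------------------------------------------------------ RadiomicCohort

#' Radiomic feature cohort
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding one `radiomics` assay (features in rows, samples in columns) with
#' per-feature metadata (`mask`, `sequence`, `feature_name`) in `rowData`,
#' and per-sample tumor class plus block-missingness indicators in
#' `colData`. A sample that lacks an ROI mask is missing *all* of that
#' mask's feature columns (stored as `NA`), never a subset; this block
#' structure is enforced by the validity method.
#'
#' Build one with the [RadiomicCohort()] constructor (samples-in-rows
#' orientation, as in the CSV interchange format), simulate one with
#' [generateCohort()], or load one with [readCohort()].
#'
#' @seealso [featureMatrix()], [tumorClass()], [maskBlock()], [splitByMask()]
#' @export
setClass("RadiomicCohort", contains = "SummarizedExperiment")

setValidity("RadiomicCohort", function(object) {
  msgs <- character()
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  need <- c("mask", "sequence", "feature_name")
  if (!all(need %in% colnames(rd))) {
    return(sprintf("rowData must contain columns: %s", paste(need, collapse = ", ")))
  }
  if (!"label" %in% colnames(cd)) return("colData must contain a 'label' column")
  if (!"missing_block" %in% colnames(cd)) {
    return("colData must contain a 'missing_block' indicator matrix")
  }
  masks <- unique(as.character(rd$mask))
  mb <- cd$missing_block
  if (!is.matrix(mb) || !identical(colnames(mb), masks)) {
    return("missing_block must be a sample x mask logical matrix in mask order")
  }
  # each (mask, sequence) combination must contribute the same number of
  # feature columns
  combo <- table(as.character(rd$mask), as.character(rd$sequence))
  if (length(unique(as.vector(combo))) > 1) {
    msgs <- c(msgs, "each (mask, sequence) combination must contribute equally many features")
  }
  # block missingness: all-or-none per (sample, mask), consistent with the
  # indicator matrix
  a <- SummarizedExperiment::assay(object, "radiomics")
  for (m in masks) {
    rows <- which(as.character(rd$mask) == m)
    naCount <- colSums(is.na(a[rows, , drop = FALSE]))
    partial <- naCount > 0 & naCount < length(rows)
    if (any(partial)) {
      msgs <- c(msgs, sprintf(
        "mask '%s': samples with partially missing blocks (e.g. sample %d)",
        m, which(partial)[1]))
    } else if (!all((naCount == length(rows)) == mb[, m])) {
      msgs <- c(msgs, sprintf(
        "mask '%s': missing_block indicators disagree with NA pattern", m))
    }
  }
  if (length(msgs)) msgs else TRUE
})

# --------------------------------------------------------- FittedAutoencoder

#' A trained per-mask autoencoder
#'
#' Holds the mirrored encoder/decoder weights, the layer-width
#' specification, and the per-epoch training-loss history of one
#' autoencoder, as produced by [trainAutoencoder()].
#'
#' @slot spec List with `encoderWidths` and `decoderWidths` (see
#'   [buildAutoencoder()]).
#' @slot net Opaque list of layer weights (internal engine format).
#' @slot lossHistory Numeric vector, full-training-set mean-squared
#'   reconstruction error after each epoch.
#' @slot finalError Numeric, last entry of `lossHistory`.
#' @slot maskName Character, which ROI mask the model was fit to.
#' @slot config The [trainConfig()] used.
#' @export
setClass("FittedAutoencoder",
  representation(
    spec = "list",
    net = "list",
    lossHistory = "numeric",
    finalError = "numeric",
    maskName = "character",
    config = "list"
  )
)

setValidity("FittedAutoencoder", function(object) {
  msgs <- character()
  if (length(object@lossHistory) < 1) {
    msgs <- c(msgs, "lossHistory must have at least one epoch")
  } else if (!isTRUE(all.equal(object@finalError,
                               object@lossHistory[length(object@lossHistory)]))) {
    msgs <- c(msgs, "finalError must equal the last lossHistory entry")
  }
  if (!is.null(object@config$maxEpochs) &&
      length(object@lossHistory) > object@config$maxEpochs) {
    msgs <- c(msgs, "lossHistory longer than maxEpochs")
  }
  if (length(msgs)) msgs else TRUE
})

# -------------------------------------------------------- LatentSearchResult

#' Result of a latent-dimension grid search
#'
#' Reconstruction-error curve over candidate bottleneck sizes, the selected
#' dimension (smallest candidate whose error falls below the threshold, else
#' the argmin), and the model refit at the selected size. Produced by
#' [searchLatentSize()].
#'
#' @slot curve Named numeric vector, candidate latent size -> final training
#'   mean-squared reconstruction error.
#' @slot selectedD Integer, chosen latent dimension.
#' @slot threshold Numeric, acceptability threshold on the error.
#' @slot metThreshold Logical, whether any candidate met the threshold.
#' @slot model The [FittedAutoencoder-class] at `selectedD` (or `NULL`).
#' @export
setClass("LatentSearchResult",
  representation(
    curve = "numeric",
    selectedD = "integer",
    threshold = "numeric",
    metThreshold = "logical",
    model = "ANY"
  )
)

setValidity("LatentSearchResult", function(object) {
  msgs <- character()
  if (!as.character(object@selectedD) %in% names(object@curve)) {
    msgs <- c(msgs, "selectedD must be one of the candidates in the curve")
  } else if (object@metThreshold &&
             !(object@curve[[as.character(object@selectedD)]] < object@threshold)) {
    msgs <- c(msgs, "metThreshold is TRUE but the selected error is not below threshold")
  }
  if (length(msgs)) msgs else TRUE
})

# ------------------------------------------------------------- TwoStageModel

#' Two-stage multiclass-decomposition classifier
#'
#' Stage 1 is a binary primary-class-vs-rest classifier (with its own
#' per-mask encoders); stage 2 distinguishes the two secondary classes
#' (fresh per-mask encoders, minority class upsampled during training).
#' At prediction time, samples called positive by stage 1 receive the
#' primary class and are never revised; all remaining samples — including
#' stage-1 false negatives, which carry through — are labeled by stage 2.
#' Produced by [fitTwoStage()] or assembled directly with [twoStageModel()].
#'
#' @slot primaryClass Character, the stage-1 target class.
#' @slot classes Character vector of all class labels, in label order.
#' @slot stage1 List with `encoders` (named list of
#'   [FittedAutoencoder-class], or `NULL` for identity encoding) and
#'   `classifier`.
#' @slot stage2 List with `encoders`, `classifier` and `classes` (the two
#'   secondary labels).
#' @slot seed Integer seed the fit was derived from.
#' @export
setClass("TwoStageModel",
  representation(
    primaryClass = "character",
    classes = "character",
    stage1 = "list",
    stage2 = "list",
    seed = "integer"
  )
)

setValidity("TwoStageModel", function(object) {
  msgs <- character()
  if (!object@primaryClass %in% object@classes) {
    msgs <- c(msgs, "primaryClass must be one of classes")
  }
  if (!setequal(object@stage2$classes, setdiff(object@classes, object@primaryClass))) {
    msgs <- c(msgs, "stage2 classes must be all classes minus the primary class")
  }
  if (is.null(object@stage1$classifier) || is.null(object@stage2$classifier)) {
    msgs <- c(msgs, "both stages need a classifier")
  }
  if (length(msgs)) msgs else TRUE
})

# ------------------------------------------------------------------- CVPlan

#' Repeated stratified cross-validation plan
#'
#' Fold assignments for `repeats` independent stratified `k`-fold
#' partitions of a labeled sample set. Within every repeat each class is
#' spread over the folds to within one sample of `n_class / k`. Produced by
#' [makeCVPlan()].
#'
#' @slot k Integer, folds per repeat.
#' @slot repeats Integer, number of repeats.
#' @slot assignments Integer matrix (samples x repeats) of fold indices in
#'   `1..k`.
#' @slot labels Factor of the stratifying labels.
#' @slot seed Integer seed.
#' @export
setClass("CVPlan",
  representation(
    k = "integer",
    repeats = "integer",
    assignments = "matrix",
    labels = "factor",
    seed = "integer"
  )
)

setValidity("CVPlan", function(object) {
  msgs <- character()
  a <- object@assignments
  if (nrow(a) != length(object@labels)) {
    msgs <- c(msgs, "assignments rows must match labels length")
  }
  if (ncol(a) != object@repeats) msgs <- c(msgs, "assignments columns must match repeats")
  if (length(a) && (min(a) < 1 || max(a) > object@k)) {
    msgs <- c(msgs, "fold indices must lie in 1..k")
  }
  # stratification: per repeat, per fold, each class within +/-1 of n_c / k
  if (!length(msgs)) {
    for (r in seq_len(ncol(a))) {
      tab <- table(object@labels, factor(a[, r], levels = seq_len(object@k)))
      ideal <- as.numeric(table(object@labels)) / object@k
      if (any(abs(sweep(tab, 1, ideal)) > 1 + 1e-9)) {
        msgs <- c(msgs, sprintf("repeat %d: fold class counts deviate by more than 1", r))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

# --------------------------------------------------------- EvaluationReport

#' Cross-validated evaluation report
#'
#' Aggregated per-class and micro-averaged ("ALL") AUC / precision / recall
#' / F1 over all fold evaluations, confusion matrices (for the two-stage
#' architecture: stage 1, stage 2 and the combined cascade), and the raw
#' per-fold records. Produced by [runCVThreeClass()] and [runCVTwoStage()].
#'
#' @slot model Character, model family label (e.g. `"Three-Class MLP"`).
#' @slot metrics `data.frame` in Model / Setting / Class / metric layout.
#' @slot confusion Named list of confusion matrices (rows = true class,
#'   columns = predicted), counts summed over all repeats and folds.
#' @slot folds Tidy `data.frame` of per-fold metric records.
#' @slot k,repeats Integers, the cross-validation plan dimensions.
#' @slot seed Integer master seed of the run.
#' @export
setClass("EvaluationReport",
  representation(
    model = "character",
    metrics = "data.frame",
    confusion = "list",
    folds = "data.frame",
    k = "integer",
    repeats = "integer",
    seed = "integer"
  )
)

setValidity("EvaluationReport", function(object) {
  m <- object@metrics
  need <- c("Model", "Setting", "Class", "AUC", "Pr", "Rc", "F1")
  if (!all(need %in% colnames(m))) {
    return(sprintf("metrics must contain columns: %s", paste(need, collapse = ", ")))
  }
  vals <- unlist(m[, c("AUC", "Pr", "Rc", "F1")])
  vals <- vals[!is.na(vals)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    return("all metric values must lie in [0, 1]")
  }
  TRUE
})
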