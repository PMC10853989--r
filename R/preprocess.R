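#' Fit z-score standardization parameters
#'
#' Computes per-column mean and population standard deviation (divisor `n`)
#' over *observed* values only, so missing mask blocks do not contribute.
#' Constant columns (sd 0) and all-missing columns are flagged degenerate
#' and mapped to divisor 1; all-missing columns additionally get mean 0 and
#' raise a warning. Inside cross-validation these parameters must be fit on
#' the training rows only and frozen for the held-out fold.
#'
#' @param features Numeric matrix (samples x features), possibly with `NA`.
#' @return An object of class `StandardizationParams`: list with `mean`,
#'   `sd` (as computed), `divisor` (sd with degenerate columns mapped to 1),
#'   `nObs` (observed values per column) and `degenerate` (logical).
#' @examples
#' p <- fitStandardizer(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' p$mean # 2, 5
#' p$sd   # 0.8165, 0
#' @export
fitStandardizer <- function(features) {
  features <- as.matrix(features)
  nObs <- colSums(!is.na(features))
  mu <- colMeans(features, na.rm = TRUE)
  # population sd: sqrt(mean((x - mu)^2)) over observed cells
  sq <- colMeans(sweep(features, 2, mu)^2, na.rm = TRUE)
  s <- sqrt(sq)
  allMissing <- nObs == 0
  if (any(allMissing)) {
    warning(sprintf("%d all-missing column(s): standardization degenerate (mean 0, sd 1)",
                    sum(allMissing)))
    mu[allMissing] <- 0
    s[allMissing] <- NA_real_
  }
  degenerate <- allMissing | (!is.na(s) & s == 0)
  divisor <- ifelse(degenerate | is.na(s), 1, s)
  structure(
    list(mean = mu, sd = ifelse(is.na(s), 0, s), divisor = divisor,
         nObs = nObs, degenerate = degenerate),
    class = "StandardizationParams"
  )
}

#' @export
print.StandardizationParams <- function(x, ...) {
  cat(sprintf("StandardizationParams: %d columns (%d degenerate)\n",
              length(x$mean), sum(x$degenerate)))
  invisible(x)
}

#' Apply frozen standardization parameters
#'
#' `(x - mean) / divisor` per column; missing cells stay missing. Applying
#' training-fold parameters to a held-out fold deliberately leaves its
#' column means nonzero — the parameters are never refit.
#'
#' @param features Numeric matrix with the same columns the params were fit on.
#' @param params A `StandardizationParams` from [fitStandardizer()].
#' @return Standardized matrix of the same shape.
#' @export
applyStandardizer <- function(features, params) {
  features <- as.matrix(features)
  if (ncol(features) != length(params$mean)) {
    stop(sprintf("column mismatch: %d columns vs params for %d",
                 ncol(features), length(params$mean)))
  }
  sweep(sweep(features, 2, params$mean), 2, params$divisor, "/")
}

#' Impute missing cells of a standardized matrix
#'
#' Strategies: `"mean"` fills 0 — on the z-scored scale the training-column
#' mean *is* 0, so mean imputation and zero-fill coincide after
#' standardization; `"zero"` fills 0; `"flag"` fills a sentinel (default
#' -9999). Standardize first ([applyStandardizer()]), then impute.
#'
#' @param features Standardized numeric matrix, possibly with `NA`.
#' @param strategy One of `"mean"`, `"zero"`, `"flag"`.
#' @param flagValue Sentinel used by the flag strategy.
#' @return The matrix with no missing cells; unchanged if it had none.
#' @export
imputeFeatures <- function(features, strategy = c("mean", "zero", "flag"),
                           flagValue = -9999) {
  strategy <- match.arg(strategy)
  features <- as.matrix(features)
  if (!anyNA(features)) return(features)
  fill <- switch(strategy, mean = 0, zero = 0, flag = flagValue)
  features[is.na(features)] <- fill
  features
}

#' Partition a cohort's features into per-mask blocks
#'
#' @param cohort A [RadiomicCohort-class].
#' @return Named list (mask order as declared) of samples x features
#'   matrices; the blocks partition the cohort's columns exactly.
#' @examples
#' cohort <- generateCohort(cohortSpec(
#'   classCounts = c(GBM = 4L, LYM = 3L, MET = 4L),
#'   featuresPerCombination = 2L, intrinsicRank = 1L, seed = 3L))
#' lengths(lapply(splitByMask(cohort), colnames)) # 10 features per mask
#' @export
splitByMask <- function(cohort) {
  stopifnot(is(cohort, "RadiomicCohort"))
  fm <- featureMeta(cohort)
  if (anyNA(fm$mask)) stop("feature column without mask metadata")
  masks <- maskNames(cohort)
  X <- featureMatrix(cohort)
  blocks <- lapply(masks, function(m) X[, fm$mask == m, drop = FALSE])
  names(blocks) <- masks
  blocks
}

# standardize + impute a list of train/test blocks with training-fold
# statistics only; returns list(train=, test=) of complete matrices
.preprocessBlocks <- function(trainBlocks, testBlocks = NULL,
                              strategy = "mean", flagValue = -9999) {
  out <- list(train = list(), test = list(), params = list())
  for (m in names(trainBlocks)) {
    p <- suppressWarnings(fitStandardizer(trainBlocks[[m]]))
    out$params[[m]] <- p
    out$train[[m]] <- imputeFeatures(
      applyStandardizer(trainBlocks[[m]], p), strategy, flagValue)
    if (!is.null(testBlocks)) {
      out$test[[m]] <- imputeFeatures(
        applyStandardizer(testBlocks[[m]], p), strategy, flagValue)
    }
  }
  out
}
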