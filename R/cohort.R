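#' Default per-(mask, class) block-missingness rates
#'
#' Fractions of samples per class missing each whole ROI-mask block, as
#' tabulated for the retrospective three-class brain-tumor cohort the
#' generator emulates. Necrotic masks are frequently absent for lymphoma
#' (85%) and metastasis (36.7%) because those tumors often lack a
#' segmentable necrotic core.
#'
#' @param masks,classes Names for the matrix dimensions.
#' @return Numeric matrix (masks x classes) of probabilities.
#' @export
defaultMissingRates <- function(masks = c("whole", "enhancing", "necrotic", "edema"),
                                classes = c("GBM", "LYM", "MET")) {
  m <- matrix(
    c(
      0.0538, 0.10, 0.0167,  # whole
      0.0538, 0.10, 0.0083,  # enhancing
      0.0538, 0.85, 0.3670,  # necrotic
      0.0538, 0.10, 0.0083   # edema
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("whole", "enhancing", "necrotic", "edema"),
                    c("GBM", "LYM", "MET"))
  )
  if (!all(masks %in% rownames(m)) || !all(classes %in% colnames(m))) {
    stop("defaultMissingRates are only tabulated for the standard masks and classes")
  }
  m[masks, classes, drop = FALSE]
}

#' Construct a synthetic-cohort specification
#'
#' Defaults reproduce the structure of the retrospective study the package
#' emulates: 253 samples (93 GBM, 40 LYM, 120 MET), 4 ROI masks x 5 MRI
#' sequences x 107 radiomic features = 2,140 features per sample (535 per
#' mask), block missingness at the tabulated per-(mask, class) rates, and a
#' low-rank latent structure (rank 15 per mask) in which GBM and MET are
#' well separated while LYM sits weakly between them.
#'
#' Per mask, a sample of class `c` draws a latent vector
#' `z ~ N(effect[c] * u_c, I_r)` (with fixed orthogonal unit directions
#' `u_c`), and its features are `W z + noise`, `W` a seeded random loading
#' matrix. Larger `classEffect` values move the class centroids apart in
#' every mask's feature space.
#'
#' @param classCounts Named vector of samples per class.
#' @param masks,sequences Mask / sequence names, in order.
#' @param featuresPerCombination Features per (mask, sequence) combination.
#' @param intrinsicRank Latent rank per mask; a single number is recycled.
#' @param classEffect Named vector of latent-mean magnitudes per class.
#' @param noiseSd Standard deviation of the additive feature noise.
#' @param missingRates Masks x classes probability matrix; defaults to
#'   [defaultMissingRates()] for the standard names, 0 otherwise.
#' @param seed Integer seed.
#' @return A validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec()
#' sum(spec@classCounts) # 253
#' @export
cohortSpec <- function(classCounts = c(GBM = 93L, LYM = 40L, MET = 120L),
                       masks = c("whole", "enhancing", "necrotic", "edema"),
                       sequences = c("T1W", "T2W", "FLAIR", "ADC", "T1-CE"),
                       featuresPerCombination = 107L,
                       intrinsicRank = 15L,
                       classEffect = c(GBM = 2.5, LYM = 1.0, MET = 2.5),
                       noiseSd = 0.3,
                       missingRates = NULL,
                       seed = 1L) {
  classCounts <- structure(as.integer(classCounts), names = names(classCounts))
  if (length(intrinsicRank) == 1L && is.null(names(intrinsicRank))) {
    intrinsicRank <- structure(rep(as.integer(intrinsicRank), length(masks)),
                               names = masks)
  } else {
    intrinsicRank <- structure(as.integer(intrinsicRank), names = names(intrinsicRank))
  }
  if (is.null(missingRates)) {
    classes <- names(classCounts)
    if (all(masks %in% rownames(defaultMissingRates())) &&
        all(classes %in% colnames(defaultMissingRates()))) {
      missingRates <- defaultMissingRates(masks, classes)
    } else {
      missingRates <- matrix(0, length(masks), length(classes),
                             dimnames = list(masks, classes))
    }
  }
  new("CohortSpec",
      classCounts = classCounts,
      masks = as.character(masks),
      sequences = as.character(sequences),
      featuresPerCombination = as.integer(featuresPerCombination),
      intrinsicRank = intrinsicRank,
      classEffect = classEffect,
      noiseSd = as.numeric(noiseSd),
      missingRates = missingRates,
      seed = as.integer(seed))
}

# fixed orthogonal latent directions for the class means: class 1 -> +e1,
# class 2 -> +e2 (or +e1 when rank 1), class 3 -> -e1, further classes
# cycle through the remaining axes
.classDirections <- function(classes, rank) {
  dirs <- matrix(0, length(classes), rank)
  for (i in seq_along(classes)) {
    if (i == 1L) {
      dirs[i, 1] <- 1
    } else if (i == 2L) {
      dirs[i, min(2L, rank)] <- 1
    } else if (i == 3L) {
      dirs[i, 1] <- -1
    } else {
      dirs[i, ((i - 1L) %% rank) + 1L] <- (-1)^(i %/% 2L)
    }
  }
  rownames(dirs) <- classes
  dirs
}

#' Construct a RadiomicCohort from its parts
#'
#' @param features Numeric matrix, samples in rows, features in columns.
#'   Missing mask blocks are `NA`; within one sample a mask's columns must
#'   be all missing or all observed.
#' @param labels Vector/factor of per-sample tumor classes.
#' @param featureMeta `data.frame` with columns `mask`, `sequence`,
#'   `feature_name`, one row per feature column.
#' @param sampleIds Optional character vector of sample identifiers.
#' @return A validated [RadiomicCohort-class].
#' @export
RadiomicCohort <- function(features, labels, featureMeta, sampleIds = NULL) {
  features <- as.matrix(features)
  if (nrow(featureMeta) != ncol(features)) {
    stop("featureMeta must have one row per feature column")
  }
  if (length(labels) != nrow(features)) {
    stop("labels must have one entry per sample (row)")
  }
  if (is.null(sampleIds)) sampleIds <- sprintf("S%04d", seq_len(nrow(features)))
  masks <- unique(as.character(featureMeta$mask))
  mb <- matrix(FALSE, nrow(features), length(masks),
               dimnames = list(NULL, masks))
  for (m in masks) {
    cols <- which(as.character(featureMeta$mask) == m)
    naCount <- rowSums(is.na(features[, cols, drop = FALSE]))
    if (any(naCount > 0 & naCount < length(cols))) {
      bad <- which(naCount > 0 & naCount < length(cols))[1]
      stop(sprintf("sample %d ('%s') has a partially missing '%s' block",
                   bad, sampleIds[bad], m))
    }
    mb[, m] <- naCount == length(cols)
  }
  colnames(features) <- paste0(featureMeta$mask, "__", featureMeta$sequence,
                               "__", featureMeta$feature_name)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(radiomics = t(features)),
    rowData = S4Vectors::DataFrame(featureMeta),
    colData = S4Vectors::DataFrame(
      label = factor(labels),
      missing_block = I(mb),
      row.names = sampleIds
    )
  )
  new("RadiomicCohort", se)
}

#' Simulate a radiomic cohort
#'
#' Draws a seeded synthetic cohort with the structure described by a
#' [CohortSpec-class]: per mask, class-dependent low-rank Gaussian latent
#' factors mapped through a random loading matrix plus isotropic noise, then
#' whole mask blocks deleted per the spec's (mask, class) missingness
#' rates. The same spec (including seed) always reproduces the identical
#' cohort.
#'
#' @param spec A [CohortSpec-class], e.g. [cohortSpec()].
#' @return A [RadiomicCohort-class] with `sum(classCounts)` samples and
#'   `length(masks) * length(sequences) * featuresPerCombination` features.
#' @examples
#' cohort <- generateCohort(cohortSpec(
#'   classCounts = c(GBM = 8L, LYM = 4L, MET = 10L),
#'   featuresPerCombination = 3L, intrinsicRank = 2L, seed = 7L))
#' dim(featureMatrix(cohort)) # 22 x 60
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  classes <- names(spec@classCounts)
  n <- sum(spec@classCounts)
  labels <- factor(rep(classes, spec@classCounts), levels = classes)
  blockWidth <- length(spec@sequences) * spec@featuresPerCombination
  D <- length(spec@masks) * blockWidth

  featureMeta <- data.frame(
    mask = rep(spec@masks, each = blockWidth),
    sequence = rep(rep(spec@sequences, each = spec@featuresPerCombination),
                   times = length(spec@masks)),
    feature_name = rep(sprintf("f%d", seq_len(spec@featuresPerCombination)),
                       times = length(spec@masks) * length(spec@sequences)),
    stringsAsFactors = FALSE
  )

  features <- withr::with_seed(spec@seed, {
    X <- matrix(NA_real_, n, D)
    col0 <- 0L
    for (m in spec@masks) {
      r <- spec@intrinsicRank[[m]]
      dirs <- .classDirections(classes, r)
      # loadings scaled so each feature's signal variance is ~1
      W <- matrix(rnorm(r * blockWidth, sd = 1 / sqrt(r)), r, blockWidth)
      Z <- matrix(rnorm(n * r), n, r)
      mu <- dirs[as.character(labels), , drop = FALSE] *
        spec@classEffect[as.character(labels)]
      Xm <- (Z + mu) %*% W +
        matrix(rnorm(n * blockWidth, sd = spec@noiseSd), n, blockWidth)
      # delete whole blocks per (mask, class) missingness rate
      drop <- runif(n) < spec@missingRates[m, as.character(labels)]
      Xm[drop, ] <- NA_real_
      X[, col0 + seq_len(blockWidth)] <- Xm
      col0 <- col0 + blockWidth
    }
    X
  })

  ids <- sprintf("%s_%03d", as.character(labels),
                 unlist(lapply(spec@classCounts, seq_len)))
  RadiomicCohort(features, labels, featureMeta, sampleIds = ids)
}

# -------------------------------------------------------------- accessors

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "RadiomicCohort", function(x) {
  t(SummarizedExperiment::assay(x, "radiomics"))
})

#' @rdname tumorClass
#' @export
setMethod("tumorClass", "RadiomicCohort", function(x) {
  SummarizedExperiment::colData(x)$label
})

#' @rdname maskNames
#' @export
setMethod("maskNames", "RadiomicCohort", function(x) {
  unique(as.character(SummarizedExperiment::rowData(x)$mask))
})

#' @rdname maskNames
#' @export
setMethod("maskNames", "CohortSpec", function(x) x@masks)

#' @rdname sequenceNames
#' @export
setMethod("sequenceNames", "RadiomicCohort", function(x) {
  unique(as.character(SummarizedExperiment::rowData(x)$sequence))
})

#' @rdname sequenceNames
#' @export
setMethod("sequenceNames", "CohortSpec", function(x) x@sequences)

#' @rdname featureMeta
#' @export
setMethod("featureMeta", "RadiomicCohort", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname missingBlocks
#' @export
setMethod("missingBlocks", "RadiomicCohort", function(x) {
  mb <- SummarizedExperiment::colData(x)$missing_block
  m <- as.matrix(mb)
  rownames(m) <- colnames(x)
  m
})

#' @rdname maskBlock
#' @export
setMethod("maskBlock", "RadiomicCohort", function(x, mask) {
  rd <- SummarizedExperiment::rowData(x)
  if (!mask %in% rd$mask) stop(sprintf("unknown mask '%s'", mask))
  rows <- which(as.character(rd$mask) == mask)
  t(SummarizedExperiment::assay(x, "radiomics")[rows, , drop = FALSE])
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:",
      sprintf("%d samples (%s)", sum(object@classCounts),
              paste(sprintf("%s=%d", names(object@classCounts),
                            object@classCounts), collapse = ", ")), "\n")
  cat(sprintf("  %d masks x %d sequences x %d features = %d features/sample\n",
              length(object@masks), length(object@sequences),
              object@featuresPerCombination,
              length(object@masks) * length(object@sequences) *
                object@featuresPerCombination))
  cat(sprintf("  intrinsic rank: %s; noise sd %.3g; seed %d\n",
              paste(object@intrinsicRank, collapse = "/"),
              object@noiseSd, object@seed))
})

setMethod("show", "RadiomicCohort", function(object) {
  cat(sprintf("RadiomicCohort: %d samples x %d features (%d masks x %d sequences)\n",
              ncol(object), nrow(object),
              length(maskNames(object)), length(sequenceNames(object))))
  tab <- table(tumorClass(object))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  mb <- missingBlocks(object)
  cat("  missing blocks:",
      paste(sprintf("%s=%.1f%%", colnames(mb), 100 * colMeans(mb)),
            collapse = ", "), "\n")
})
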