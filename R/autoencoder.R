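#' Autoencoder layer-width specification
#'
#' The encoder is a shallow fully connected stack that first halves the
#' input width (integer division) and then compresses to the bottleneck;
#' the decoder mirrors it exactly. For the standard 535-feature mask block
#' the encoder widths are 535 -> 267 -> d. Hidden units are rectifiers; the
#' output layer is linear, appropriate for reconstructing z-scored values
#' under a mean-squared loss.
#'
#' @param inputDim Number of input features (block width).
#' @param latentDim Bottleneck size, `1 <= latentDim <= inputDim`.
#' @return List with `encoderWidths`, `decoderWidths`, `widths` (the full
#'   mirrored stack) and `latentDim`.
#' @examples
#' buildAutoencoder(535, 15)$encoderWidths # 535 267 15
#' buildAutoencoder(11, 3)$encoderWidths   # 11 5 3
#' @export
buildAutoencoder <- function(inputDim, latentDim) {
  .assertScalarNumber(inputDim, "inputDim", lower = 1)
  .assertScalarNumber(latentDim, "latentDim", lower = 1, upper = inputDim)
  inputDim <- as.integer(inputDim)
  latentDim <- as.integer(latentDim)
  half <- max(1L, inputDim %/% 2L)
  enc <- c(inputDim, half, latentDim)
  dec <- rev(enc)
  widths <- c(enc, dec[-1L])
  # hidden layers are rectified except the bottleneck code layer, which is
  # linear so codes can take either sign
  rectify <- rep(TRUE, length(widths) - 2L)
  rectify[length(enc) - 1L] <- FALSE
  list(
    encoderWidths = enc,
    decoderWidths = dec,
    widths = widths,
    latentDim = latentDim,
    rectify = rectify
  )
}

#' Training configuration for autoencoders and MLPs
#'
#' @param maxEpochs Maximum training epochs (default 250).
#' @param learningRate Adam/SGD step size (default 1e-3).
#' @param batchSize Minibatch size (default 32).
#' @param patience Early-stopping patience: training stops once the
#'   full-training-set loss has failed to improve by more than `minDelta`
#'   for this many consecutive epochs.
#' @param minDelta Minimum loss improvement that resets the patience counter.
#' @param solver `"adam"` or `"sgd"`.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return A list of class `TrainConfig`.
#' @export
trainConfig <- function(maxEpochs = 250L, learningRate = 1e-3, batchSize = 32L,
                        patience = 10L, minDelta = 1e-4,
                        solver = c("adam", "sgd"), seed = 1L) {
  solver <- match.arg(solver)
  .assertScalarNumber(maxEpochs, "maxEpochs", lower = 1)
  .assertScalarNumber(patience, "patience", lower = 1, upper = maxEpochs - 1)
  structure(
    list(maxEpochs = as.integer(maxEpochs), learningRate = learningRate,
         batchSize = as.integer(batchSize), patience = as.integer(patience),
         minDelta = minDelta, solver = solver, seed = as.integer(seed)),
    class = c("TrainConfig", "list")
  )
}

#' Train a per-mask autoencoder
#'
#' Fits the mirrored autoencoder of [buildAutoencoder()] to a standardized,
#' fully imputed feature block by minimising the mean-squared
#' reconstruction error with minibatch Adam (or SGD), recording the
#' full-training-set loss each epoch and stopping early once it ceases to
#' improve. Identical inputs and seed reproduce the identical fit.
#'
#' @param block Numeric matrix (samples x features), standardized and with
#'   no missing cells.
#' @param latentDim Bottleneck size.
#' @param config A [trainConfig()].
#' @param maskName Optional mask label stored on the model.
#' @return A [FittedAutoencoder-class].
#' @export
trainAutoencoder <- function(block, latentDim, config = trainConfig(),
                             maskName = "") {
  block <- as.matrix(block)
  if (anyNA(block)) {
    stop("block contains missing cells: standardize and impute before training")
  }
  if (nrow(block) < 2L) stop("need at least 2 samples to train")
  spec <- buildAutoencoder(ncol(block), latentDim)
  fit <- .nnTrain(block, block, spec$widths,
                  output = "identity",
                  batchSize = config$batchSize,
                  learningRate = config$learningRate,
                  solver = config$solver,
                  maxEpochs = config$maxEpochs,
                  patience = config$patience,
                  minDelta = config$minDelta,
                  seed = config$seed,
                  rectify = spec$rectify)
  new("FittedAutoencoder",
      spec = spec,
      net = fit$layers,
      lossHistory = fit$history,
      finalError = fit$history[length(fit$history)],
      maskName = as.character(maskName),
      config = unclass(config))
}

#' Mean-squared reconstruction error of an autoencoder on data
#'
#' Mean over all cells of the squared difference between the input and its
#' reconstruction, on the (standardized) scale of the inputs.
#'
#' @param model A [FittedAutoencoder-class].
#' @param data Numeric matrix with `inputDim` columns.
#' @return A single nonnegative number.
#' @export
reconstructionError <- function(model, data) {
  data <- as.matrix(data)
  if (ncol(data) != model@spec$encoderWidths[1]) {
    stop(sprintf("data has %d columns, model expects %d",
                 ncol(data), model@spec$encoderWidths[1]))
  }
  recon <- .nnPredict(model@net, data, "identity", model@spec$rectify)
  mean((data - recon)^2)
}

#' Encode a feature block to its latent representation
#'
#' Runs only the encoder half (first two weight layers) of a fitted
#' autoencoder.
#'
#' @param model A [FittedAutoencoder-class].
#' @param data Numeric matrix with `inputDim` columns.
#' @return Numeric matrix (samples x latentDim).
#' @export
encodeFeatures <- function(model, data) {
  data <- as.matrix(data)
  if (ncol(data) != model@spec$encoderWidths[1]) {
    stop(sprintf("data has %d columns, model expects %d",
                 ncol(data), model@spec$encoderWidths[1]))
  }
  encLayers <- model@net[seq_len(length(model@spec$encoderWidths) - 1L)]
  # bottleneck activations are taken pre-rectifier (linear code layer)
  A <- data
  for (i in seq_along(encLayers)) {
    Z <- sweep(A %*% encLayers[[i]]$W, 2, encLayers[[i]]$b, "+")
    A <- if (i < length(encLayers)) pmax(Z, 0) else Z
  }
  A
}

#' Pick the latent size from a reconstruction-error curve
#'
#' The smallest candidate whose error falls below the threshold; if none
#' qualifies, the argmin of the curve with `met = FALSE`.
#'
#' @param curve Named numeric vector, candidate -> error.
#' @param threshold Acceptability threshold (default 0.2).
#' @return List with `selected` (integer) and `met` (logical).
#' @examples
#' selectLatentSize(c(`1` = 0.5, `2` = 0.3, `3` = 0.19, `4` = 0.15)) # 3
#' @export
selectLatentSize <- function(curve, threshold = 0.2) {
  if (!length(curve)) stop("empty error curve")
  d <- as.integer(names(curve))
  ord <- order(d)
  d <- d[ord]
  curve <- curve[ord]
  ok <- which(curve < threshold)
  if (length(ok)) {
    list(selected = d[ok[1L]], met = TRUE)
  } else {
    list(selected = d[which.min(curve)], met = FALSE)
  }
}

#' Grid-search the bottleneck size of a per-mask autoencoder
#'
#' Trains one autoencoder per candidate latent dimension and selects the
#' smallest dimension whose final training reconstruction error falls below
#' the threshold (dimensional parsimony); if no candidate qualifies, the
#' argmin is returned with `metThreshold = FALSE`.
#'
#' @param block Standardized, imputed feature block (samples x features).
#' @param candidates Integer vector of bottleneck sizes (default 1:50).
#' @param threshold Reconstruction-error threshold (default 0.2).
#' @param config A [trainConfig()]; each candidate trains with a seed
#'   derived from `config$seed` and the candidate size.
#' @param maskName Optional mask label.
#' @return A [LatentSearchResult-class] holding the full error curve, the
#'   selection, and the fitted model at the selected size.
#' @export
searchLatentSize <- function(block, candidates = 1:50, threshold = 0.2,
                             config = trainConfig(), maskName = "") {
  if (!length(candidates)) stop("empty candidate range")
  block <- as.matrix(block)
  if (any(candidates < 1) || any(candidates > ncol(block))) {
    stop(sprintf("candidates must lie in [1, %d]", ncol(block)))
  }
  candidates <- sort(unique(as.integer(candidates)))
  models <- vector("list", length(candidates))
  curve <- numeric(length(candidates))
  names(curve) <- candidates
  for (i in seq_along(candidates)) {
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, sprintf("latent/%s/d%d", maskName,
                                                candidates[i]))
    models[[i]] <- trainAutoencoder(block, candidates[i], cfg, maskName)
    curve[i] <- models[[i]]@finalError
  }
  sel <- selectLatentSize(curve, threshold)
  new("LatentSearchResult",
      curve = curve,
      selectedD = as.integer(sel$selected),
      threshold = threshold,
      metThreshold = sel$met,
      model = models[[match(sel$selected, candidates)]])
}

#' Concatenate per-mask latent encodings
#'
#' Encodes each mask's (preprocessed) feature block with its fitted
#' autoencoder and column-binds the codes in the declared mask order; with
#' the default four masks at 15 latents each this yields the 60-column
#' compressed feature matrix used by the classifiers.
#'
#' @param models Named list of [FittedAutoencoder-class], one per mask.
#' @param blocks Named list of matrices with matching names and widths.
#' @return Numeric matrix (samples x sum of latent dims); columns named
#'   `<mask>.L<k>`.
#' @export
encodeConcat <- function(models, blocks) {
  if (is.null(names(models)) || is.null(names(blocks))) {
    stop("models and blocks must be named by mask")
  }
  missing <- setdiff(names(blocks), names(models))
  if (length(missing)) {
    stop(sprintf("no model for mask(s): %s", paste(missing, collapse = ", ")))
  }
  out <- lapply(names(blocks), function(m) {
    Z <- encodeFeatures(models[[m]], blocks[[m]])
    colnames(Z) <- sprintf("%s.L%d", m, seq_len(ncol(Z)))
    Z
  })
  do.call(cbind, out)
}

#' Two-dimensional latent manifold of a feature block
#'
#' Trains a bottleneck-2 autoencoder on a standardized, imputed block and
#' returns the per-sample 2-D codes together with a class-colored scatter
#' plot whose axes are clipped to [-15, 15] (codes can fall outside through
#' outlier mappings; the clip eases visual comparison across masks).
#'
#' @param block Standardized, imputed feature block with at least 2 columns.
#' @param labels Optional per-sample class labels for coloring.
#' @param config A [trainConfig()].
#' @param path Optional PNG path; when given the plot is written there.
#' @param maskName Optional title label.
#' @return List with `coords` (samples x 2), `plot` (a ggplot object) and
#'   `model` (the fitted autoencoder).
#' @export
manifold2d <- function(block, labels = NULL, config = trainConfig(),
                       path = NULL, maskName = "") {
  block <- as.matrix(block)
  if (ncol(block) < 2L) stop("need at least 2 feature columns for a 2-D manifold")
  model <- trainAutoencoder(block, 2L, config, maskName)
  coords <- encodeFeatures(model, block)
  colnames(coords) <- c("L1", "L2")
  df <- data.frame(L1 = coords[, 1], L2 = coords[, 2])
  df$class <- if (is.null(labels)) factor("all") else factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$L1, y = .data$L2,
                                        color = .data$class)) +
    ggplot2::geom_point(alpha = 0.8, size = 1.6) +
    ggplot2::coord_cartesian(xlim = c(-15, 15), ylim = c(-15, 15)) +
    ggplot2::labs(title = sprintf("2-D latent manifold %s", maskName),
                  x = "latent 1", y = "latent 2") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 150)
  }
  list(coords = coords, plot = p, model = model)
}

setMethod("show", "FittedAutoencoder", function(object) {
  cat(sprintf("FittedAutoencoder%s: widths %s, %d epochs, final MSE %.4f\n",
              if (nzchar(object@maskName)) paste0(" [", object@maskName, "]") else "",
              paste(object@spec$encoderWidths, collapse = "-"),
              length(object@lossHistory), object@finalError))
})

setMethod("show", "LatentSearchResult", function(object) {
  cat(sprintf("LatentSearchResult: %d candidates, selected d=%d (error %.4f, threshold %s %.2f)\n",
              length(object@curve), object@selectedD,
              object@curve[[as.character(object@selectedD)]],
              if (object@metThreshold) "met" else "NOT met", object@threshold))
})
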