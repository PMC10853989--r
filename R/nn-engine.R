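# Minimal dense feedforward network engine.
#
# Supports the two architectures the pipeline needs:
#   * autoencoders: identity output, mean-squared-error loss;
#   * MLP classifiers: softmax output, cross-entropy loss.
# Hidden activations are rectifiers throughout. Optimizers: Adam
# (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) and plain SGD. Training is
# minibatch with per-epoch reshuffling; the epoch-level loss recorded in
# the history is the full-training-set loss, and early stopping triggers
# when that loss has not improved by more than minDelta for patience
# consecutive epochs. All randomness (initialisation, shuffling) is drawn
# under the caller's seed, so identical inputs + seed give identical fits.

.nnInit <- function(widths) {
  # He initialisation, appropriate for rectifier hidden units
  layers <- vector("list", length(widths) - 1L)
  for (i in seq_along(layers)) {
    fanIn <- widths[i]
    layers[[i]] <- list(
      W = matrix(rnorm(fanIn * widths[i + 1L], sd = sqrt(2 / fanIn)),
                 fanIn, widths[i + 1L]),
      b = rep(0, widths[i + 1L])
    )
  }
  layers
}

.nnForward <- function(layers, X, output = c("identity", "softmax"),
                       rectify = NULL) {
  output <- match.arg(output)
  L <- length(layers)
  if (is.null(rectify)) rectify <- rep(TRUE, L - 1L)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (i in seq_len(L)) {
    Z <- acts[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2, layers[[i]]$b, "+")
    if (i < L) {
      acts[[i + 1L]] <- if (rectify[i]) pmax(Z, 0) else Z
    } else {
      acts[[i + 1L]] <- switch(output,
        identity = Z,
        softmax = {
          Z <- Z - apply(Z, 1, max) # row-wise stabilisation
          E <- exp(Z)
          E / rowSums(E)
        })
    }
  }
  acts
}

.nnPredict <- function(layers, X, output = "identity", rectify = NULL) {
  acts <- .nnForward(layers, X, output, rectify)
  acts[[length(acts)]]
}

.nnLoss <- function(layers, X, Y, output = "identity", rectify = NULL) {
  P <- .nnPredict(layers, X, output, rectify)
  if (output == "identity") {
    mean((P - Y)^2)
  } else {
    -mean(rowSums(Y * log(pmax(P, 1e-12))))
  }
}

# gradient of the epoch loss for one minibatch; for MSE the per-cell mean
# convention matches .nnLoss (mean over n * p cells)
.nnGradients <- function(layers, X, Y, output, rectify = NULL) {
  L <- length(layers)
  if (is.null(rectify)) rectify <- rep(TRUE, L - 1L)
  acts <- .nnForward(layers, X, output, rectify)
  n <- nrow(X)
  grads <- vector("list", L)
  P <- acts[[L + 1L]]
  delta <- if (output == "identity") {
    2 * (P - Y) / (n * ncol(Y))
  } else {
    (P - Y) / n # softmax + cross-entropy shortcut
  }
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(
      W = crossprod(acts[[i]], delta),
      b = colSums(delta)
    )
    if (i > 1L) {
      delta <- delta %*% t(layers[[i]]$W)
      if (rectify[i - 1L]) delta[acts[[i]] <= 0] <- 0 # rectifier derivative
    }
  }
  grads
}

# Training runs in compiled code (src/nn.cpp) for speed; weight
# initialisation and batch shuffles draw from R's RNG there, so wrapping
# the call in with_seed() makes the whole fit reproducible. The R-level
# .nnForward/.nnGradients above are the slow reference path kept for
# gradient cross-checks in the test suite.
.nnTrain <- function(X, Y, widths,
                     output = c("identity", "softmax"),
                     batchSize = 32L,
                     learningRate = 1e-3,
                     solver = c("adam", "sgd"),
                     maxEpochs = 250L,
                     patience = 10L,
                     minDelta = 1e-4,
                     seed = 1L,
                     rectify = NULL) {
  output <- match.arg(output)
  solver <- match.arg(solver)
  stopifnot(nrow(X) >= 2L, maxEpochs >= 1L, patience < maxEpochs)
  if (is.null(rectify)) rectify <- rep(TRUE, length(widths) - 2L)
  fit <- withr::with_seed(seed, {
    .cppNnTrain(X, Y, as.integer(widths), output == "softmax",
                as.logical(rectify),
                as.integer(batchSize), learningRate, solver,
                as.integer(maxEpochs), as.integer(patience), minDelta)
  })
  list(layers = fit$layers, history = as.numeric(fit$history), output = output,
       rectify = rectify)
}
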