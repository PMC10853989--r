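#' Hyperparameter grid for MLP model selection
#'
#' Defaults are the exhaustive grid used for model selection: batch sizes
#' {8, 16, 32, 64, 128}, hidden layouts (nodes in {50, 100, 150, 200} x
#' layers in 1..5, every hidden layer the same width), learning rates
#' {1e-3, 1e-4} and solvers {adam, sgd} — 400 cells in total.
#'
#' @param batchSizes,nodes,layers,learningRates,solvers Grid axes.
#' @return A list of class `HyperGrid`.
#' @export
hyperGrid <- function(batchSizes = c(8L, 16L, 32L, 64L, 128L),
                      nodes = c(50L, 100L, 150L, 200L),
                      layers = 1:5,
                      learningRates = c(1e-3, 1e-4),
                      solvers = c("adam", "sgd")) {
  axes <- list(batchSizes = batchSizes, nodes = nodes, layers = layers,
               learningRates = learningRates, solvers = solvers)
  if (any(!lengths(axes))) stop("every grid axis must be nonempty")
  structure(axes, class = c("HyperGrid", "list"))
}

#' Enumerate the cells of a hyperparameter grid
#'
#' Cells are listed in a fixed lexicographic order (batch size varying
#' slowest, then nodes, layers, learning rate, solver); grid-search ties
#' are broken toward the earliest cell in this order.
#'
#' @param grid A [hyperGrid()].
#' @return `data.frame` with one row per cell.
#' @export
gridCells <- function(grid) {
  cells <- expand.grid(
    solver = grid$solvers,
    learningRate = grid$learningRates,
    layers = grid$layers,
    nodes = grid$nodes,
    batchSize = grid$batchSizes,
    stringsAsFactors = FALSE
  )
  # expand.grid varies the first column fastest; flip to lexicographic
  cells[, rev(colnames(cells))]
}

#' MLP hyperparameters
#'
#' @param batchSize Minibatch size.
#' @param nodes Width of every hidden layer.
#' @param layers Number of hidden layers.
#' @param learningRate Optimizer step size.
#' @param solver `"adam"` or `"sgd"`.
#' @param maxEpochs Training epoch cap (early stopping applies).
#' @param seed Integer seed.
#' @return A list of class `MLPParams`.
#' @export
mlpParams <- function(batchSize = 16L, nodes = 150L, layers = 4L,
                      learningRate = 1e-3, solver = c("adam", "sgd"),
                      maxEpochs = 200L, seed = 1L) {
  solver <- match.arg(solver)
  structure(
    list(batchSize = as.integer(batchSize), nodes = as.integer(nodes),
         layers = as.integer(layers), learningRate = learningRate,
         solver = solver, maxEpochs = as.integer(maxEpochs),
         seed = as.integer(seed)),
    class = c("MLPParams", "list")
  )
}

#' Documented best-parameter presets
#'
#' The cells selected by the exhaustive grid search for each predictive
#' task, shipped as defaults so the pipeline can skip re-searching: the
#' three-class MLP uses batch 16, hidden (150, 4), learning rate 1e-3,
#' Adam; both binary stages use a single hidden layer of 150 nodes (stage 1
#' with batch 8, stage 2 with batch 16).
#'
#' @param seed Integer seed stored on the params.
#' @return An `MLPParams` list.
#' @export
mlpPresetThreeClass <- function(seed = 1L) {
  mlpParams(batchSize = 16L, nodes = 150L, layers = 4L,
            learningRate = 1e-3, solver = "adam", seed = seed)
}

#' @rdname mlpPresetThreeClass
#' @export
mlpPresetStage1 <- function(seed = 1L) {
  mlpParams(batchSize = 8L, nodes = 150L, layers = 1L,
            learningRate = 1e-3, solver = "adam", seed = seed)
}

#' @rdname mlpPresetThreeClass
#' @export
mlpPresetStage2 <- function(seed = 1L) {
  mlpParams(batchSize = 16L, nodes = 150L, layers = 1L,
            learningRate = 1e-3, solver = "adam", seed = seed)
}

#' Fit a multilayer-perceptron classifier
#'
#' Rectifier hidden layers of equal width, softmax output, cross-entropy
#' loss, minibatch Adam/SGD with early stopping. Deterministic given the
#' seed in `params`.
#'
#' @param X Complete, finite numeric matrix (samples x features).
#' @param y Class labels (factor or coercible).
#' @param params An [mlpParams()] list.
#' @return A `FittedMLP` object; [predict()] returns a per-class
#'   probability matrix with rows summing to 1.
#' @export
fitMLP <- function(X, y, params = mlpPresetThreeClass()) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("X must be complete and finite")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes in y")
  Y <- .oneHot(y)
  widths <- c(ncol(X), rep(params$nodes, params$layers), nlevels(y))
  fit <- .nnTrain(X, Y, widths,
                  output = "softmax",
                  batchSize = params$batchSize,
                  learningRate = params$learningRate,
                  solver = params$solver,
                  maxEpochs = params$maxEpochs,
                  patience = 10L,
                  minDelta = 1e-4,
                  seed = params$seed)
  structure(
    list(net = fit$layers, classes = levels(y), params = params,
         lossHistory = fit$history),
    class = "FittedMLP"
  )
}

#' @export
predict.FittedMLP <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  P <- .nnPredict(object$net, as.matrix(newdata), "softmax")
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  # argmax with probability ties broken toward the earlier class label
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.FittedMLP <- function(x, ...) {
  cat(sprintf("FittedMLP: %d classes (%s), hidden (%d x %d), %s, %d epochs\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              x$params$nodes, x$params$layers, x$params$solver,
              length(x$lossHistory)))
  invisible(x)
}

# classifier score interface: returns a per-class probability matrix; a
# plain function can stand in for a fitted model (used for deterministic
# stubs in the staged-pipeline contracts)
.classifierProb <- function(classifier, X, classes = NULL) {
  P <- if (is.function(classifier)) classifier(X) else predict(classifier, X)
  P <- as.matrix(P)
  if (!is.null(classes)) {
    if (is.null(colnames(P))) colnames(P) <- classes
    P <- P[, classes, drop = FALSE]
  }
  P
}

#' Exhaustive grid search for MLP hyperparameters
#'
#' Scores every grid cell by stratified inner cross-validation on the
#' training data (mean micro-averaged one-vs-rest AUC over the inner
#' folds) and returns the best cell; ties go to the earliest cell in the
#' fixed lexicographic grid order. Deterministic given `seed`.
#'
#' @param X Complete feature matrix (samples x features).
#' @param y Class labels, at least two classes.
#' @param grid A [hyperGrid()].
#' @param innerFolds Folds of the inner stratified CV (default 3).
#' @param seed Integer seed; fold assignment and every cell's fit derive
#'   their own seeds from it.
#' @return The winning `MLPParams`, with the per-cell score table attached
#'   as `attr(, "scores")` (one row per evaluated cell).
#' @export
gridSearchMLP <- function(X, y, grid = hyperGrid(), innerFolds = 3L, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("need at least 2 classes in y")
  cells <- gridCells(grid)
  plan <- makeCVPlan(y, k = innerFolds, repeats = 1L,
                     seed = deriveSeed(seed, "gridsearch/plan"))
  folds <- foldAssignments(plan)[, 1L]
  scores <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    aucs <- numeric(innerFolds)
    for (f in seq_len(innerFolds)) {
      tr <- folds != f
      params <- mlpParams(batchSize = cell$batchSize, nodes = cell$nodes,
                          layers = cell$layers,
                          learningRate = cell$learningRate,
                          solver = cell$solver,
                          seed = deriveSeed(seed, sprintf("gridsearch/cell%d/fold%d",
                                                          ci, f)))
      model <- fitMLP(X[tr, , drop = FALSE], y[tr], params)
      P <- predict(model, X[!tr, , drop = FALSE])
      aucs[f] <- ovrAuc(P, y[!tr])$micro
    }
    scores[ci] <- mean(aucs)
  }
  best <- which.max(scores) # which.max returns the first maximum: tie rule
  cell <- cells[best, ]
  out <- mlpParams(batchSize = cell$batchSize, nodes = cell$nodes,
                   layers = cell$layers, learningRate = cell$learningRate,
                   solver = cell$solver, seed = seed)
  attr(out, "scores") <- cbind(cells, score = scores)
  out
}
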