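#' Configuration of a full pipeline run
#'
#' Collects everything one end-to-end run needs: a cohort source (a
#' [CohortSpec-class] to simulate, or a directory to read with
#' [readCohort()]), the preprocessing and latent settings, the classifier
#' architecture, the cross-validation plan and the master seed. All
#' randomness flows from the single seed via [deriveSeed()].
#'
#' @param cohortSpec A [CohortSpec-class] to simulate from, or `NULL` when
#'   `cohortPath` is given.
#' @param cohortPath Directory holding a written cohort (ignored when
#'   `cohortSpec` is given).
#' @param architecture `"three_class"` or `"two_stage"`.
#' @param latentDims Latent size(s) per mask for the evaluation (default 15).
#' @param latentCandidates Optional integer range; when given, a
#'   reconstruction-error grid search over these candidates is run per mask
#'   (exploratory, on the full preprocessed data) and its curves exported.
#' @param threshold Reconstruction-error threshold for the search.
#' @param imputation Imputation strategy (`"mean"`, `"zero"`, `"flag"`).
#' @param aeConfig A [trainConfig()].
#' @param mlpParams [mlpParams()] for the three-class MLP.
#' @param stage1Params,stage2Params [mlpParams()] for the cascade stages.
#' @param primaryClass Stage-1 target class.
#' @param k,repeats Cross-validation dimensions.
#' @param manifolds Logical; also export per-mask 2-D manifold plots and
#'   coordinates (exploratory, fit on all preprocessed data).
#' @param evaluate Logical; run the cross-validated evaluation (disable to
#'   stop after simulation / search / manifolds).
#' @param seed Master seed (required; no silent nondeterminism).
#' @param outDir Output directory for [runPipeline()].
#' @return A validated list of class `RunConfig`.
#' @export
runConfig <- function(cohortSpec = NULL,
                      cohortPath = NULL,
                      architecture = c("three_class", "two_stage"),
                      latentDims = 15L,
                      latentCandidates = NULL,
                      threshold = 0.2,
                      imputation = c("mean", "zero", "flag"),
                      aeConfig = trainConfig(),
                      mlpParams = mlpPresetThreeClass(),
                      stage1Params = mlpPresetStage1(),
                      stage2Params = mlpPresetStage2(),
                      primaryClass = "GBM",
                      k = 5L, repeats = 5L,
                      manifolds = FALSE,
                      evaluate = TRUE,
                      seed = 1L,
                      outDir = tempfile("radlatent_run_")) {
  architecture <- match.arg(architecture)
  imputation <- match.arg(imputation)
  if (is.null(cohortSpec) && is.null(cohortPath)) {
    stop("provide either cohortSpec (simulate) or cohortPath (load)")
  }
  if (!is.null(cohortSpec)) validObject(cohortSpec)
  if (is.null(cohortSpec) && !dir.exists(cohortPath)) {
    stop(sprintf("cohortPath '%s' does not exist", cohortPath))
  }
  .assertScalarNumber(seed, "seed")
  structure(
    list(cohortSpec = cohortSpec, cohortPath = cohortPath,
         architecture = architecture, latentDims = latentDims,
         latentCandidates = latentCandidates, threshold = threshold,
         imputation = imputation, aeConfig = aeConfig,
         mlpParams = mlpParams, stage1Params = stage1Params,
         stage2Params = stage2Params, primaryClass = primaryClass,
         k = as.integer(k), repeats = as.integer(repeats),
         manifolds = manifolds, evaluate = isTRUE(evaluate),
         seed = as.integer(seed), outDir = outDir),
    class = c("RunConfig", "list")
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> optional latent search and
#' manifolds -> cross-validated training and evaluation -> report, writing
#' every artifact plus a log with per-stage timings and seeds into the
#' configured output directory. Re-running the identical configuration
#' reproduces all numeric outputs byte-for-byte.
#'
#' Files written: `cohort/` (when simulated), `search_<mask>.csv` latent
#' curves (when searched), `manifold_<mask>.{csv,png}` (when requested),
#' `report.csv` / `report.json` / `confusion_*.csv` / `folds.csv`,
#' `log.txt`, and `provenance.json` carrying the config hash and master
#' seed that every output of the run is keyed by.
#'
#' @param config A [runConfig()].
#' @return The output directory, invisibly; the
#'   [EvaluationReport-class] is attached as `attr(, "report")`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logFile <- file.path(outDir, "log.txt")
  cat(sprintf("radlatent run, master seed %d\n", config$seed), file = logFile)
  stamp <- function(stage, t0) {
    cat(sprintf("%-14s %8.2fs\n", stage, as.numeric(Sys.time()) - t0),
        file = logFile, append = TRUE)
  }

  hash <- .configHash(unclass(config)[setdiff(names(config), "outDir")])
  jsonlite::write_json(
    list(config_hash = hash, seed = config$seed,
         architecture = config$architecture,
         imputation = config$imputation,
         latentDims = config$latentDims,
         k = config$k, repeats = config$repeats),
    file.path(outDir, "provenance.json"), auto_unbox = TRUE)

  # ---- cohort ----
  t0 <- as.numeric(Sys.time())
  cohort <- tryCatch({
    if (!is.null(config$cohortSpec)) {
      spec <- config$cohortSpec
      spec@seed <- deriveSeed(config$seed, "cohort")
      ch <- generateCohort(spec)
      writeCohort(ch, file.path(outDir, "cohort"))
      ch
    } else {
      readCohort(config$cohortPath)
    }
  }, error = function(e) {
    stop(sprintf("stage 'cohort' failed: %s", conditionMessage(e)))
  })
  stamp("cohort", t0)

  # ---- exploratory latent search / manifolds (fit on all data, labeled
  # exploratory: CV evaluation below refits everything per training fold) ----
  if (!is.null(config$latentCandidates) || isTRUE(config$manifolds)) {
    t0 <- as.numeric(Sys.time())
    blocks <- splitByMask(cohort)
    prep <- .preprocessBlocks(blocks, strategy = config$imputation)
    if (!is.null(config$latentCandidates)) {
      for (m in names(prep$train)) {
        cfg <- config$aeConfig
        cfg$seed <- deriveSeed(config$seed, sprintf("search/%s", m))
        res <- searchLatentSize(prep$train[[m]], config$latentCandidates,
                                config$threshold, cfg, maskName = m)
        data.table::fwrite(
          data.frame(d = as.integer(names(res@curve)), error = res@curve,
                     selected = as.integer(names(res@curve)) == res@selectedD),
          file.path(outDir, sprintf("search_%s.csv", m)))
      }
      stamp("latent-search", t0)
    }
    if (isTRUE(config$manifolds)) {
      t0 <- as.numeric(Sys.time())
      for (m in names(prep$train)) {
        cfg <- config$aeConfig
        cfg$seed <- deriveSeed(config$seed, sprintf("manifold/%s", m))
        man <- manifold2d(prep$train[[m]], tumorClass(cohort), cfg,
                          path = file.path(outDir, sprintf("manifold_%s.png", m)),
                          maskName = m)
        data.table::fwrite(
          data.frame(sample_id = rownames(featureMatrix(cohort)),
                     L1 = man$coords[, 1], L2 = man$coords[, 2],
                     class = as.character(tumorClass(cohort))),
          file.path(outDir, sprintf("manifold_%s.csv", m)))
      }
      stamp("manifolds", t0)
    }
  }

  # ---- cross-validated evaluation ----
  if (!isTRUE(config$evaluate)) {
    return(invisible(outDir))
  }
  t0 <- as.numeric(Sys.time())
  report <- if (config$architecture == "three_class") {
    runCVThreeClass(cohort, latentDims = config$latentDims,
                    aeConfig = config$aeConfig, mlpParams = config$mlpParams,
                    k = config$k, repeats = config$repeats,
                    imputation = config$imputation,
                    seed = deriveSeed(config$seed, "evaluate"))
  } else {
    runCVTwoStage(cohort, latentDim = config$latentDims[1L],
                  aeConfig = config$aeConfig,
                  stage1Params = config$stage1Params,
                  stage2Params = config$stage2Params,
                  primaryClass = config$primaryClass,
                  k = config$k, repeats = config$repeats,
                  imputation = config$imputation,
                  seed = deriveSeed(config$seed, "evaluate"))
  }
  stamp("evaluate", t0)

  t0 <- as.numeric(Sys.time())
  writeReport(report, outDir)
  stamp("report", t0)

  out <- outDir
  attr(out, "report") <- report
  invisible(out)
}
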