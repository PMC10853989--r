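#' Write a cohort to CSV with a JSON metadata sidecar
#'
#' Writes `cohort.csv` (one row per sample: `sample_id`, `label`, then one
#' column per feature named `<mask>__<sequence>__<feature>`; missing cells
#' are empty) and `cohort.meta.json` (mask/sequence/feature column metadata
#' plus class counts, for provenance) into a directory.
#'
#' @param cohort A [RadiomicCohort-class].
#' @param path Directory to write into (created if needed).
#' @return Invisibly, the paths of the two files written.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "RadiomicCohort"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  csv <- file.path(path, "cohort.csv")
  meta <- file.path(path, "cohort.meta.json")

  X <- featureMatrix(cohort)
  dt <- data.table::data.table(
    sample_id = rownames(X),
    label = as.character(tumorClass(cohort))
  )
  feat <- data.table::as.data.table(X)
  dt <- cbind(dt, feat)
  data.table::fwrite(dt, csv, na = "", quote = FALSE)

  fm <- featureMeta(cohort)
  jsonlite::write_json(
    list(
      format = "radlatent-cohort/1",
      n_samples = nrow(X),
      classes = levels(tumorClass(cohort)),
      class_counts = as.list(table(tumorClass(cohort))),
      masks = maskNames(cohort),
      sequences = sequenceNames(cohort),
      columns = fm
    ),
    meta, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv = csv, meta = meta))
}

#' Read a cohort written by [writeCohort()]
#'
#' @param path Directory containing `cohort.csv` and `cohort.meta.json`.
#' @return A [RadiomicCohort-class]; labels, column metadata, values and
#'   missing cells round-trip from [writeCohort()].
#' @export
readCohort <- function(path) {
  csv <- file.path(path, "cohort.csv")
  meta <- file.path(path, "cohort.meta.json")
  if (!file.exists(csv) || !file.exists(meta)) {
    stop(sprintf("cohort not found under '%s' (need cohort.csv and cohort.meta.json)",
                 path))
  }
  info <- tryCatch(jsonlite::read_json(meta, simplifyVector = TRUE),
                   error = function(e) {
                     stop(sprintf("malformed metadata sidecar '%s': %s",
                                  meta, conditionMessage(e)))
                   })
  fm <- as.data.frame(info$columns)
  need <- c("mask", "sequence", "feature_name")
  if (!all(need %in% colnames(fm))) {
    stop(sprintf("metadata sidecar '%s' lacks column metadata fields (%s)",
                 meta, paste(need, collapse = ", ")))
  }
  dt <- data.table::fread(csv, na.strings = "", colClasses = list(
    character = c("sample_id", "label")))
  if (!all(c("sample_id", "label") %in% colnames(dt))) {
    stop(sprintf("malformed '%s': first columns must be sample_id,label", csv))
  }
  expected <- paste0(fm$mask, "__", fm$sequence, "__", fm$feature_name)
  got <- setdiff(colnames(dt), c("sample_id", "label"))
  if (!identical(got, expected)) {
    bad <- which(got != expected[seq_along(got)])[1]
    stop(sprintf("malformed '%s': feature columns disagree with sidecar (column %s)",
                 csv, if (is.na(bad)) length(got) + 2L else bad + 2L))
  }
  X <- as.matrix(dt[, setdiff(colnames(dt), c("sample_id", "label")),
                    with = FALSE])
  storage.mode(X) <- "double"
  labels <- if (!is.null(info$classes)) {
    factor(dt$label, levels = info$classes)
  } else {
    dt$label
  }
  RadiomicCohort(X, labels, fm, sampleIds = dt$sample_id)
}
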