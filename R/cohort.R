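#' Construct a VitalsCohort
#'
#' @param features Numeric matrix (records x predictors) whose columns cover
#'   [predictorNames()] (any order; reordered to canonical order).
#' @param labels Character or factor vector of classes (`"low"`/`"high"`),
#'   one per record.
#' @param pef Optional numeric vector of raw PEF values (L/min). When labels
#'   are not supplied they are derived from `pef` via [deriveLabel()].
#' @param provenance `"real"`, `"synthetic"` or `"simulated"`.
#' @param dropped Number of records removed during cleaning (bookkeeping).
#' @return A [VitalsCohort-class] object.
#' @examples
#' m <- matrix(rnorm(50), 5, 10, dimnames = list(NULL, predictorNames()))
#' VitalsCohort(m, labels = c("low", "high", "low", "low", "high"))
#' @export
VitalsCohort <- function(features, labels = NULL, pef = NULL,
                         provenance = "real", dropped = 0L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    stop("'features' must have column names")
  cn <- .normalizeName(colnames(features))
  if (anyNA(cn))
    stop("unrecognised feature columns: ",
         paste(colnames(features)[is.na(cn)], collapse = ", "))
  colnames(features) <- cn
  missing <- setdiff(predictorNames(), cn)
  if (length(missing))
    stop("missing predictor columns: ", paste(missing, collapse = ", "))
  features <- features[, predictorNames(), drop = FALSE]
  rownames(features) <- NULL
  storage.mode(features) <- "double"
  if (is.null(labels)) {
    if (is.null(pef)) stop("supply 'labels' or 'pef' to derive them")
    labels <- deriveLabel(pef)
  }
  labels <- factor(as.character(labels), levels = .CLASS_LEVELS)
  if (anyNA(labels)) stop("labels must be 'low' or 'high'")
  if (length(labels) != nrow(features))
    stop("one label per record is required")
  cd <- DataFrame(class = labels)
  if (!is.null(pef)) cd$pef <- as.numeric(pef)
  se <- SummarizedExperiment(
    assays = list(vitals = t(features)),
    colData = cd
  )
  metadata(se) <- list(provenance = provenance, dropped = as.integer(dropped))
  new("VitalsCohort", se)
}

#' Accessors for VitalsCohort
#'
#' `featureMatrix()` returns the records-by-predictors numeric matrix;
#' `classLabels()` the class factor; `pefValues()` raw PEF values (or `NULL`);
#' `cohortProvenance()` the provenance tag; `nRecords()` the record count.
#'
#' @param x A [VitalsCohort-class].
#' @return See individual descriptions.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "VitalsCohort"))
  t(assay(x, "vitals"))
}

#' @rdname featureMatrix
#' @export
classLabels <- function(x) colData(x)$class

#' @rdname featureMatrix
#' @export
pefValues <- function(x) {
  if ("pef" %in% colnames(colData(x))) colData(x)$pef else NULL
}

#' @rdname featureMatrix
#' @export
cohortProvenance <- function(x) metadata(x)$provenance

#' @rdname featureMatrix
#' @export
nRecords <- function(x) ncol(x)

setMethod("show", "VitalsCohort", function(object) {
  tab <- table(classLabels(object))
  cat(sprintf("VitalsCohort: %d records x %d predictors (%s)\n",
              nRecords(object), nrow(object), cohortProvenance(object)))
  cat(sprintf("  class: low=%d high=%d%s\n", tab[["low"]], tab[["high"]],
              if (!is.null(pefValues(object))) "; raw PEF stored" else ""))
  d <- metadata(object)$dropped
  if (!is.null(d) && d > 0L)
    cat(sprintf("  %d record(s) dropped during cleaning\n", d))
})

#' Read a vital-sign dataset from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row containing the 11
#' canonical features (case/space-insensitive; common aliases such as
#' "Diastolic Blood Pressure" are recognised) or the 10 predictors plus a
#' `class` column. When a `pef` column is present and no label column, labels
#' are derived with [deriveLabel()]. Records with any missing predictor value
#' are dropped (listwise deletion) and the drop count is recorded in the
#' cohort metadata and reported with a message.
#'
#' @param path CSV file path.
#' @param provenance Provenance tag for the resulting cohort.
#' @return A [VitalsCohort-class].
#' @seealso [writeVitals()]
#' @export
readVitals <- function(path, provenance = "real") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  cn <- .normalizeName(colnames(df))
  keep <- !is.na(cn)
  df <- df[, keep, drop = FALSE]
  colnames(df) <- cn[keep]
  if (anyDuplicated(colnames(df)))
    stop("duplicated columns after header normalisation: ",
         paste(unique(colnames(df)[duplicated(colnames(df))]), collapse = ", "))
  missing <- setdiff(predictorNames(), colnames(df))
  if (length(missing))
    stop("schema error - missing required column(s): ",
         paste(missing, collapse = ", "))
  hasPef <- "pef" %in% colnames(df)
  hasClass <- ".class" %in% colnames(df)
  if (!hasPef && !hasClass)
    stop("schema error - need a 'pef' column or a class/label column")
  num <- predictorNames()
  if (hasPef) num <- c(num, "pef")
  for (cc in num) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  need <- df[, predictorNames(), drop = FALSE]
  complete <- stats::complete.cases(need)
  if (hasPef && !hasClass) complete <- complete & !is.na(df$pef)
  nDropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  if (nrow(df) == 0L) stop("no complete records left after cleaning")
  if (nDropped > 0L)
    message(nDropped, " record(s) dropped due to missing values")
  labels <- if (hasClass) tolower(trimws(as.character(df$.class)))
            else deriveLabel(df$pef)
  VitalsCohort(as.matrix(df[, predictorNames(), drop = FALSE]),
               labels = labels,
               pef = if (hasPef) df$pef else NULL,
               provenance = provenance, dropped = nDropped)
}

#' Write a vital-sign dataset to CSV
#'
#' Writes the canonical comma-separated dialect: UTF-8, header row, `.`
#' decimal separator, values printed with 6 significant digits. Columns follow
#' the canonical feature order (with `pef` included when the cohort carries
#' raw PEF values) plus a final `class` column. A written file read back with
#' [readVitals()] reproduces the cohort bit-stably at that precision.
#'
#' @param x A [VitalsCohort-class].
#' @param path Output file path.
#' @param digits Significant digits for numeric output.
#' @return `path`, invisibly.
#' @export
writeVitals <- function(x, path, digits = 6) {
  stopifnot(is(x, "VitalsCohort"))
  m <- signif(featureMatrix(x), digits)
  out <- as.data.frame(m)
  pef <- pefValues(x)
  if (!is.null(pef)) {
    out$pef <- signif(pef, digits)
    out <- out[, vitalFeatures()]
  }
  out$class <- as.character(classLabels(x))
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
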