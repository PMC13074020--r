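#' Construct a CohortTable
#'
#' @param values numeric matrix, patients x features, with `NA` for missing
#'   cells. Row names are patient identifiers, column names feature names.
#' @param modality character vector (length = number of features, or a single
#'   label recycled) mapping each feature to its modality.
#' @param outcome optional binary 0/1 vector (length = number of patients).
#' @param batch optional character vector of batch/center labels.
#'
#' @return A [CohortTable-class] object.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("P", 1:4), paste0("f", 1:3)))
#' ct <- CohortTable(m, modality = "CLIN", outcome = c(0, 1, 0, 1))
#' @export
CohortTable <- function(values, modality, outcome = NULL, batch = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)))
    stop("patient identifiers (row names) are required")
  if (is.null(colnames(values)))
    stop("feature names (column names) are required")
  modality <- rep_len(as.character(modality), ncol(values))
  cd <- DataFrame(row.names = rownames(values))
  if (!is.null(outcome)) {
    if (length(outcome) != nrow(values))
      stop("outcome length must equal patient count")
    cd$outcome <- as.numeric(outcome)
  }
  if (!is.null(batch)) {
    if (length(batch) != nrow(values))
      stop("batch length must equal patient count")
    cd$batch <- as.character(batch)
  }
  se <- SummarizedExperiment(
    assays  = SimpleList(values = t(values)),
    rowData = DataFrame(modality = modality, row.names = colnames(values)),
    colData = cd
  )
  new("CohortTable", se)
}

#' @rdname CohortTable
#' @param x,object a `CohortTable`.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @describeIn CohortTable patients x features numeric matrix (transpose of
#'   the stored assay).
#' @export
setMethod("featureMatrix", "CohortTable", function(x) t(assay(x, "values")))

#' @rdname CohortTable
#' @export
setGeneric("patientIDs", function(x) standardGeneric("patientIDs"))

#' @describeIn CohortTable patient identifiers.
#' @export
setMethod("patientIDs", "CohortTable", function(x) colnames(x))

#' @describeIn CohortTable patient identifiers of a loaded block.
#' @export
setMethod("patientIDs", "ModalityBlock", function(x) x@patientIDs)

#' @rdname CohortTable
#' @export
setGeneric("featureModality", function(x) standardGeneric("featureModality"))

#' @describeIn CohortTable named character: modality per feature.
#' @export
setMethod("featureModality", "CohortTable", function(x) {
  stats::setNames(as.character(rowData(x)$modality), rownames(x))
})

#' @rdname CohortTable
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' @describeIn CohortTable binary outcome vector (or NULL when absent).
#' @export
setMethod("outcomes", "CohortTable", function(x) {
  oc <- colData(x)$outcome
  if (is.null(oc)) NULL else stats::setNames(as.numeric(oc), colnames(x))
})

#' @rdname CohortTable
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))

#' @describeIn CohortTable batch/center labels (or NULL when absent).
#' @export
setMethod("batchLabels", "CohortTable", function(x) {
  b <- colData(x)$batch
  if (is.null(b)) NULL else stats::setNames(as.character(b), colnames(x))
})

#' Replace or set the outcome / batch annotations
#'
#' @param x a `CohortTable`.
#' @param value numeric 0/1 vector (`outcomes<-`) or character vector
#'   (`batchLabels<-`), length = patient count.
#' @return the modified `CohortTable`.
#' @rdname cohort-setters
#' @export
setGeneric("outcomes<-", function(x, value) standardGeneric("outcomes<-"))

#' @rdname cohort-setters
#' @export
setMethod("outcomes<-", "CohortTable", function(x, value) {
  colData(x)$outcome <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname cohort-setters
#' @export
setGeneric("batchLabels<-", function(x, value) standardGeneric("batchLabels<-"))

#' @rdname cohort-setters
#' @export
setMethod("batchLabels<-", "CohortTable", function(x, value) {
  colData(x)$batch <- as.character(value)
  validObject(x)
  x
})

setMethod("show", "CohortTable", function(object) {
  mods <- table(featureModality(object))
  cat("CohortTable:", ncol(object), "patients,", nrow(object), "features\n")
  cat("  modalities:",
      paste(sprintf("%s(%d)", names(mods), as.integer(mods)), collapse = ", "),
      "\n")
  oc <- outcomes(object)
  if (!is.null(oc))
    cat(sprintf("  outcome: %d/%d positive (prevalence %.3f)\n",
                sum(oc == 1, na.rm = TRUE), sum(!is.na(oc)),
                mean(oc, na.rm = TRUE)))
  b <- batchLabels(object)
  if (!is.null(b))
    cat("  batches:", paste(names(table(b)), table(b), sep = ":",
                            collapse = ", "), "\n")
  nm <- sum(is.na(assay(object, "values")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nm,
              100 * nm / length(assay(object, "values"))))
})

setMethod("show", "ModalityBlock", function(object) {
  cat(sprintf("ModalityBlock '%s': %d patients x %d features\n",
              object@modality, nrow(object@values), ncol(object@values)))
})

setMethod("show", "ConsensusSignature", function(object) {
  sel <- object@scores[object@scores$selected, , drop = FALSE]
  cat(sprintf("ConsensusSignature (%s stage): %d features retained of %d scored\n",
              object@stage, nrow(sel), nrow(object@scores)))
  if (nrow(sel)) {
    top <- utils::head(sel, 5)
    cat(paste(sprintf("  %-28s %s  imp %.4f  stab %.2f", top$feature,
                      top$modality, top$mean_abs_attribution, top$stability),
              collapse = "\n"), "\n")
    if (nrow(sel) > 5) cat("  ...\n")
  }
})

setMethod("show", "HarmonizationModel", function(object) {
  cat(sprintf("HarmonizationModel: %d features, reference batch '%s', %d batch(es)\n",
              length(object@featureNames), object@referenceBatch,
              length(object@batchEffects)))
  if (length(object@passthrough))
    cat("  passthrough (zero-variance in reference):",
        length(object@passthrough), "feature(s)\n")
})

setMethod("show", "MissingnessPolicy", function(object) {
  cat(sprintf("MissingnessPolicy: threshold %.3f, %d flagged, %d dropped\n",
              object@threshold, length(object@flagged), length(object@dropped)))
})

setMethod("show", "AvatarBundle", function(object) {
  cat("AvatarBundle\n")
  cat(sprintf("  signature: %d features\n",
              sum(object@signature@scores$selected)))
  cat(sprintf("  decision threshold: %.4f (training prevalence %.3f)\n",
              object@threshold, object@baseRate))
  cat(sprintf("  base value (log-odds): %.4f; seed %d\n",
              object@baseValue, object@seed))
})

setMethod("show", "LocalExplanation", function(object) {
  cat(sprintf("LocalExplanation for %s: p = %.4f (threshold %.4f%s)\n",
              object@patientID, object@probability, object@threshold,
              if (object@borderline) ", BORDERLINE" else ""))
  top <- utils::head(object@contributions, 5)
  cat(paste(sprintf("  %-28s value %8.3f  phi %+.4f", top$feature,
                    top$value, top$attribution), collapse = "\n"), "\n")
})

#' Signature feature names
#'
#' @param x a [ConsensusSignature-class] or [AvatarBundle-class].
#' @return character vector of retained feature names, in importance order.
#' @export
setGeneric("signatureFeatures", function(x) standardGeneric("signatureFeatures"))

#' @rdname signatureFeatures
#' @export
setMethod("signatureFeatures", "ConsensusSignature", function(x) {
  x@scores$feature[x@scores$selected]
})

#' @rdname signatureFeatures
#' @export
setMethod("signatureFeatures", "AvatarBundle", function(x) {
  signatureFeatures(x@signature)
})

#' Subset a CohortTable to a feature set
#'
#' @param x a `CohortTable`.
#' @param features character vector of feature names to keep (order kept).
#' @return a `CohortTable` restricted to `features`.
#' @export
keepFeatures <- function(x, features) {
  missing <- setdiff(features, rownames(x))
  if (length(missing))
    stop("features absent from the table: ", paste(missing, collapse = ", "))
  x[features, ]
}
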