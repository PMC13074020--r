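#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

#' CohortTable: integrated multi-modal patient-by-feature container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one assay `"values"` (features in rows, patients in columns, missing cells
#' as `NA`), a `modality` annotation per feature in `rowData`, and optional
#' `outcome` (binary 0/1) and `batch` (center label) columns in `colData`.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @seealso [CohortTable()], [integrateModalities()], [generateCohort()]
#' @export
setClass("CohortTable", contains = "SummarizedExperiment")

setValidity("CohortTable", function(object) {
  msg <- character()
  if (!("values" %in% assayNames(object)))
    msg <- c(msg, "assay 'values' is required")
  if (is.null(rowData(object)$modality))
    msg <- c(msg, "rowData must carry a 'modality' column")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "patient identifiers must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature names must be unique")
  oc <- colData(object)$outcome
  if (!is.null(oc) && !all(oc[!is.na(oc)] %in% c(0, 1)))
    msg <- c(msg, "outcome must be binary 0/1 (NA allowed)")
  if (length(msg)) msg else TRUE
})

#' ModalityBlock: one loaded per-modality table
#'
#' @slot modality single modality label.
#' @slot patientIDs character vector of unique patient identifiers.
#' @slot values numeric matrix, patients x features (missing permitted).
#' @export
setClass("ModalityBlock", representation(
  modality   = "character",
  patientIDs = "character",
  values     = "matrix"
))

setValidity("ModalityBlock", function(object) {
  msg <- character()
  if (length(object@modality) != 1L) msg <- c(msg, "one modality label required")
  if (anyDuplicated(object@patientIDs))
    msg <- c(msg, "duplicate patient identifiers")
  if (nrow(object@values) != length(object@patientIDs))
    msg <- c(msg, "row count must equal patient id count")
  if (ncol(object@values) > 0 && anyDuplicated(colnames(object@values)))
    msg <- c(msg, "duplicate feature names")
  if (length(msg)) msg else TRUE
})

#' HarmonizationModel: reference-batch empirical-Bayes batch correction
#'
#' Per-feature reference location/scale estimated on the reference batch,
#' plus shrunken per-batch additive (`gamma`) and multiplicative (`delta2`)
#' effects. The reference batch is fixed at identity (gamma 0, delta2 1).
#'
#' @slot featureNames features the model covers.
#' @slot alpha,sigma reference-batch mean and SD per feature.
#' @slot batchEffects named list; per batch a list with `gamma`, `delta2`
#'   (numeric per feature), `n`, and hyperprior summaries `gbar`, `tau2`,
#'   `lambda`, `theta`.
#' @slot referenceBatch reference batch label.
#' @slot passthrough features flagged zero-variance in the reference batch
#'   and passed through unharmonized.
#' @export
setClass("HarmonizationModel", representation(
  featureNames   = "character",
  alpha          = "numeric",
  sigma          = "numeric",
  batchEffects   = "list",
  referenceBatch = "character",
  passthrough    = "character"
))

setValidity("HarmonizationModel", function(object) {
  msg <- character()
  if (length(object@alpha) != length(object@featureNames) ||
      length(object@sigma) != length(object@featureNames))
    msg <- c(msg, "alpha/sigma length must match featureNames")
  for (b in names(object@batchEffects)) {
    eff <- object@batchEffects[[b]]
    if (any(eff$delta2 <= 0, na.rm = TRUE))
      msg <- c(msg, sprintf("non-positive delta2 in batch '%s'", b))
  }
  ref <- object@referenceBatch
  if (ref %in% names(object@batchEffects)) {
    eff <- object@batchEffects[[ref]]
    if (any(eff$gamma != 0) || any(eff$delta2 != 1))
      msg <- c(msg, "reference batch must have gamma = 0, delta2 = 1")
  }
  if (length(msg)) msg else TRUE
})

#' MissingnessPolicy: indicator/imputation policy learned on training data
#'
#' @slot threshold missing-fraction threshold; a feature is flagged when its
#'   training missing fraction strictly exceeds it.
#' @slot indicatorSuffix suffix appended to flagged features' indicator
#'   columns (default `"_ismissing"`).
#' @slot imputeValues named numeric: training-learned impute value per
#'   flagged feature (median of observed training values).
#' @slot flagged features that received an indicator.
#' @slot dropped features 100% missing in training, removed.
#' @export
setClass("MissingnessPolicy", representation(
  threshold       = "numeric",
  indicatorSuffix = "character",
  imputeValues    = "numeric",
  flagged         = "character",
  dropped         = "character"
))

setValidity("MissingnessPolicy", function(object) {
  msg <- character()
  if (object@threshold < 0 || object@threshold > 1)
    msg <- c(msg, "threshold must lie in [0, 1]")
  if (!all(object@flagged %in% names(object@imputeValues)))
    msg <- c(msg, "every flagged feature needs a learned impute value")
  if (length(msg)) msg else TRUE
})

#' MissingnessAudit: per-feature missingness bookkeeping
#'
#' @slot table data.frame with columns `feature`, `missing_fraction`,
#'   `flagged`, `impute_value`.
#' @slot events data.frame of removal events (`indicator`, `original`,
#'   `reason`).
#' @export
setClass("MissingnessAudit", representation(
  table  = "data.frame",
  events = "data.frame"
))

#' ConsensusSignature: retained multi-modal feature signature
#'
#' @slot stage `"unimodal"` or `"multimodal"`.
#' @slot scores data.frame ordered by descending `mean_abs_attribution`:
#'   columns `feature`, `modality`, `mean_abs_attribution`, `stability`,
#'   `selected`.
#' @export
setClass("ConsensusSignature", representation(
  stage  = "character",
  scores = "data.frame"
))

setValidity("ConsensusSignature", function(object) {
  msg <- character()
  need <- c("feature", "modality", "mean_abs_attribution", "stability",
            "selected")
  if (!all(need %in% names(object@scores)))
    msg <- c(msg, paste("scores must have columns:", paste(need, collapse = ", ")))
  else {
    s <- object@scores
    if (is.unsorted(rev(s$mean_abs_attribution)))
      msg <- c(msg, "scores must be ordered by descending importance")
    if (any(s$stability < 0 | s$stability > 1))
      msg <- c(msg, "stability must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' AvatarBundle: the deployable per-patient predictive bundle
#'
#' Packages everything needed to score and explain a new patient: the fitted
#' boosted ensemble, the consensus signature, the harmonization model, the
#' missingness policy, and the training-derived decision threshold and
#' attribution base value (log-odds).
#'
#' @slot modelRaw raw bytes of the serialized boosted ensemble.
#' @slot signature [ConsensusSignature-class].
#' @slot harmonization [HarmonizationModel-class] (may cover zero features
#'   when no radiomic modality is present).
#' @slot missingness [MissingnessPolicy-class].
#' @slot threshold decision threshold probability in (0, 1).
#' @slot baseRate training outcome prevalence.
#' @slot baseValue training mean margin (log-odds), the force-plot baseline.
#' @slot params named list of learner parameters used.
#' @slot fingerprint short hash of configuration for provenance.
#' @slot seed integer seed the bundle was trained under.
#' @export
setClass("AvatarBundle", representation(
  modelRaw      = "raw",
  signature     = "ConsensusSignature",
  harmonization = "HarmonizationModel",
  missingness   = "MissingnessPolicy",
  threshold     = "numeric",
  baseRate      = "numeric",
  baseValue     = "numeric",
  params        = "list",
  fingerprint   = "character",
  seed          = "integer"
))

setValidity("AvatarBundle", function(object) {
  msg <- character()
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "decision threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' LocalExplanation: additive per-feature decomposition of one prediction
#'
#' @slot patientID patient identifier.
#' @slot baseValue training mean margin (log-odds).
#' @slot contributions data.frame (`feature`, `value`, `attribution`)
#'   ordered by descending absolute attribution; log-odds space.
#' @slot margin final model margin; `baseValue + sum(attribution)`.
#' @slot probability `plogis(margin)`.
#' @slot threshold decision threshold the bundle carries.
#' @slot borderline TRUE when `|probability - threshold|` is below the
#'   configured borderline margin.
#' @export
setClass("LocalExplanation", representation(
  patientID     = "character",
  baseValue     = "numeric",
  contributions = "data.frame",
  margin        = "numeric",
  probability   = "numeric",
  threshold     = "numeric",
  borderline    = "logical"
))
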