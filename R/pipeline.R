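#' Fingerprint a settings list
#'
#' MD5 of the canonical serialized settings, for provenance stamping of
#' bundles and reports.
#' @param settings named list.
#' @return 32-character hex string.
#' @keywords internal
configFingerprint <- function(settings) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(settings[order(names(settings))],
                              auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

emptyHarmonizationModel <- function() {
  new("HarmonizationModel",
      featureNames = character(0),
      alpha = stats::setNames(numeric(0), character(0)),
      sigma = stats::setNames(numeric(0), character(0)),
      batchEffects = list(), referenceBatch = "TRAIN",
      passthrough = character(0))
}

#' Train a deployable avatar bundle end to end
#'
#' Orchestrates the full training workflow on an annotated cohort:
#' reference-batch harmonization of radiomic modalities (the training
#' cohort, or its largest batch, is the reference), missingness policy
#' fitting and application, two-tier dual-metric feature selection, the
#' indicator-dominance guard (removal of dominant missingness indicators
#' plus their originals, followed by re-selection on the pruned feature
#' space), optional surrogate-based hyperparameter search, final model
#' training, and derivation of the Youden decision threshold from
#' out-of-fold cross-validated training predictions.
#'
#' @param table training [CohortTable-class] with outcomes.
#' @param settings settings list ([pipelineDefaults()]).
#' @return list with `bundle` (the [AvatarBundle-class]), `selection`
#'   (two-tier results), `removalEvents` (indicator-dominance removals),
#'   `missingnessAudit`, `oof` (out-of-fold training predictions) and
#'   `tuneTrace` (when a search ran).
#' @export
trainAvatar <- function(table, settings = pipelineDefaults()) {
  y <- outcomes(table)
  if (is.null(y) || anyNA(y)) stop("training requires complete outcomes")
  seed <- as.integer(settings$seed)

  # --- harmonization reference statistics (radiomic modalities only) -----
  mods <- featureModality(table)
  harmFeats <- names(mods)[mods %in% settings$harmonizeModalities]
  b <- batchLabels(table)
  if (length(harmFeats)) {
    X <- featureMatrix(table)
    if (!is.null(b) && length(unique(b)) > 1) {
      ref <- names(which.max(table(b)))
      hm <- fitCombat(X[, harmFeats, drop = FALSE], b, ref)
      X[, harmFeats] <- applyCombat(hm, X[, harmFeats, drop = FALSE], b)
      assay(table, "values") <- t(X)
    } else {
      hm <- fitCombat(X[, harmFeats, drop = FALSE],
                      rep("TRAIN", nrow(X)), "TRAIN")
      hm@referenceBatch <- "TRAIN"
    }
  } else {
    hm <- emptyHarmonizationModel()
  }

  # --- missingness policy ------------------------------------------------
  mp <- fitMissingnessPolicy(table, settings$missingThreshold)
  work <- applyMissingnessPolicy(mp$policy, table)

  # --- two-tier selection + indicator-dominance guard --------------------
  sp <- selectionParams(nFolds = settings$nFolds, topK = settings$topK,
                        importanceQuantile = settings$importanceQuantile,
                        stabilityThreshold = settings$stabilityThreshold,
                        seed = seed)
  sel <- twoTierSelect(work, y, sp)
  guard <- auditSignature(sel$signature, mp$policy)
  removalEvents <- guard$events
  if (nrow(removalEvents)) {
    drop <- unique(stats::na.omit(c(removalEvents$indicator,
                                    removalEvents$original)))
    keep <- setdiff(rownames(work), drop)
    work <- work[keep, ]
    sel <- twoTierSelect(work, y, sp)
  }
  signature <- sel$signature
  sigFeats <- signatureFeatures(signature)
  Xsel <- featureMatrix(work)[, sigFeats, drop = FALSE]

  # --- learner parameters ------------------------------------------------
  tuneTrace <- NULL
  if (!is.null(settings$searchBudget) && settings$searchBudget >= 5) {
    tuned <- tuneModel(Xsel, y, searchSpace(budget = settings$searchBudget),
                       nFolds = settings$nFolds, seed = seed)
    params <- tuned$params
    tuneTrace <- tuned$trace
  } else {
    params <- defaultModelParams(seed)
  }

  # --- decision threshold from out-of-fold training predictions ----------
  folds <- stratifiedFolds(y, settings$nFolds, seed = seed)
  oofP <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    bst <- trainModel(Xsel[tr, , drop = FALSE], y[tr], params)
    oofP[!tr] <- stats::predict(
      bst, xgboost::xgb.DMatrix(Xsel[!tr, , drop = FALSE], missing = NA))
  }
  threshold <- youdenThreshold(oofP, y)

  # --- final fit ---------------------------------------------------------
  model <- trainModel(Xsel, y, params)
  attr0 <- attributeShap(model, Xsel)
  fq <- lapply(sigFeats, function(f)
    stats::quantile(Xsel[, f], c(0.01, 0.99), na.rm = TRUE, names = FALSE))
  names(fq) <- sigFeats

  bundle <- new("AvatarBundle",
                modelRaw = xgboost::xgb.save.raw(model),
                signature = signature,
                harmonization = hm,
                missingness = mp$policy,
                threshold = threshold,
                baseRate = mean(y),
                baseValue = attr0$baseValue,
                params = c(unclass(params),
                           list(featureQuantiles = fq)),
                fingerprint = configFingerprint(settings),
                seed = seed)
  list(bundle = bundle, selection = sel, removalEvents = removalEvents,
       missingnessAudit = mp$audit,
       oof = data.frame(patient_id = patientIDs(table), probability = oofP,
                        outcome = y, fold = folds,
                        stringsAsFactors = FALSE),
       tuneTrace = tuneTrace)
}

#' Load, integrate and annotate a cohort from a settings list
#'
#' Loads each configured modality CSV/TSV, outer-joins them, and attaches
#' outcome and batch columns from the configured outcome file (a CSV with
#' the id column plus outcome/batch columns).
#'
#' @param settings list from [readPipelineConfig()]; `modalities` maps
#'   modality names to file paths, `outcomeFile` points to the annotation
#'   CSV.
#' @return an annotated [CohortTable-class].
#' @export
loadCohort <- function(settings) {
  if (!length(settings$modalities)) stop("no modalities configured")
  blocks <- mapply(function(path, name)
    loadModality(path, name, idColumn = settings$idColumn),
    settings$modalities, names(settings$modalities), SIMPLIFY = FALSE)
  ct <- integrateModalities(unname(blocks))
  if (!is.null(settings$outcomeFile)) {
    ann <- utils::read.csv(settings$outcomeFile, stringsAsFactors = FALSE)
    idx <- match(patientIDs(ct), ann[[settings$idColumn]])
    if (settings$outcomeColumn %in% names(ann))
      colData(ct)$outcome <- as.numeric(ann[[settings$outcomeColumn]][idx])
    if (settings$batchColumn %in% names(ann))
      colData(ct)$batch <- as.character(ann[[settings$batchColumn]][idx])
  }
  ct
}
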