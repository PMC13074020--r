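#' Indicator column name for a feature
#'
#' The suffix is inserted before the modality suffix so the indicator stays
#' grouped with its original feature's modality (e.g. `smoking.CLIN` ->
#' `smoking_ismissing.CLIN`).
#' @keywords internal
indicatorName <- function(feature, suffix = "_ismissing") {
  ifelse(grepl("\\.[^.]+$", feature),
         sub("\\.([^.]+)$", paste0(suffix, ".\\1"), feature),
         paste0(feature, suffix))
}

#' Fit a missingness policy on the training cohort
#'
#' A feature whose training missing fraction *strictly exceeds* `threshold`
#' is flagged: it receives a binary indicator column and its missing cells
#' are imputed with the training median of observed values. Features below
#' the threshold are left missing for the boosted learner's native handling.
#' Features 100% missing have no defined impute value and are dropped with a
#' logged event.
#'
#' @param table training [CohortTable-class].
#' @param threshold missing-fraction threshold in `[0, 1]` (default 0.05).
#' @param indicatorSuffix indicator suffix (default `"_ismissing"`).
#' @return list with `policy` ([MissingnessPolicy-class]) and `audit`
#'   ([MissingnessAudit-class]).
#' @export
fitMissingnessPolicy <- function(table, threshold = 0.05,
                                 indicatorSuffix = "_ismissing") {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  X <- featureMatrix(table)
  frac <- colMeans(is.na(X))
  flagged <- names(frac)[frac > threshold & frac < 1]
  dropped <- names(frac)[frac >= 1]
  impute <- vapply(flagged, function(f)
    stats::median(X[, f], na.rm = TRUE), numeric(1))
  audit <- data.frame(
    feature = colnames(X),
    missing_fraction = unname(frac),
    flagged = colnames(X) %in% flagged,
    impute_value = unname(impute[match(colnames(X), names(impute))]),
    stringsAsFactors = FALSE)
  events <- if (length(dropped))
    data.frame(indicator = NA_character_, original = dropped,
               reason = "feature entirely missing in training; dropped",
               stringsAsFactors = FALSE)
  else
    data.frame(indicator = character(0), original = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(policy = new("MissingnessPolicy", threshold = threshold,
                    indicatorSuffix = indicatorSuffix,
                    imputeValues = impute, flagged = flagged,
                    dropped = dropped),
       audit = new("MissingnessAudit", table = audit, events = events))
}

#' Apply a fitted missingness policy
#'
#' Creates the training-defined indicator columns (1 = cell was missing) and
#' imputes flagged features with the TRAINING-learned values, never the new
#' table's statistics. Unflagged features keep their missing cells. The
#' operation is idempotent: existing indicator columns are left untouched
#' and already-imputed features have nothing left to impute.
#'
#' @param policy a [MissingnessPolicy-class].
#' @param table a [CohortTable-class] to transform.
#' @return the transformed `CohortTable`.
#' @export
applyMissingnessPolicy <- function(policy, table) {
  absent <- setdiff(c(policy@flagged, policy@dropped), rownames(table))
  if (length(absent))
    stop("policy feature(s) absent from table: ",
         paste(absent, collapse = ", "))
  if (length(policy@dropped))
    table <- table[setdiff(rownames(table), policy@dropped), ]
  X <- featureMatrix(table)
  mods <- featureModality(table)
  addCols <- list(); addMods <- character(0)
  for (f in policy@flagged) {
    ind <- indicatorName(f, policy@indicatorSuffix)
    if (!(ind %in% colnames(X))) {
      addCols[[ind]] <- as.numeric(is.na(X[, f]))
      addMods[ind] <- mods[[f]]
    }
    X[is.na(X[, f]), f] <- policy@imputeValues[[f]]
  }
  if (length(addCols)) {
    X <- cbind(X, do.call(cbind, addCols))
    mods <- c(mods, addMods)
  }
  out <- CohortTable(X, modality = mods[colnames(X)],
                     outcome = outcomes(table), batch = batchLabels(table))
  out
}

#' Remove dominant missingness indicators from a signature
#'
#' An indicator is "dominant" when it is retained in the consensus
#' signature. Retaining it would let the model exploit systematic
#' non-recording patterns, so both the indicator and its original feature
#' are removed and the event logged; re-running selection and refitting on
#' the pruned feature space is the caller's responsibility.
#'
#' @param signature a [ConsensusSignature-class].
#' @param policy the [MissingnessPolicy-class] that created the indicators.
#' @return list with `signature` (pruned) and `events` (data.frame
#'   `indicator`, `original`, `reason`).
#' @export
auditSignature <- function(signature, policy) {
  scores <- signature@scores
  indMap <- stats::setNames(policy@flagged,
                            indicatorName(policy@flagged,
                                          policy@indicatorSuffix))
  retained <- scores$feature[scores$selected]
  dominant <- intersect(retained, names(indMap))
  events <- data.frame(indicator = character(0), original = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  for (ind in dominant) {
    orig <- indMap[[ind]]
    if (orig %in% scores$feature) {
      reason <- "indicator dominant in signature; indicator and original removed"
    } else {
      reason <- "indicator dominant; original absent, indicator removed"
      warning("original feature '", orig, "' absent while removing '",
              ind, "'")
    }
    events <- rbind(events, data.frame(indicator = ind, original = orig,
                                       reason = reason,
                                       stringsAsFactors = FALSE))
    scores <- scores[!(scores$feature %in% c(ind, orig)), , drop = FALSE]
  }
  list(signature = new("ConsensusSignature", stage = signature@stage,
                       scores = scores),
       events = events)
}

#' Serialize a missingness audit as JSON
#'
#' @param audit a [MissingnessAudit-class].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeMissingnessAudit <- function(audit, path) {
  jsonlite::write_json(list(table = audit@table, events = audit@events),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
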