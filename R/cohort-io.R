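#' Load a per-modality table from CSV/TSV
#'
#' The delimiter is sniffed from the file extension (`.tsv`/`.txt` = tab,
#' otherwise comma). Cells equal to a missing token become `NA`; any other
#' non-numeric cell is rejected. Feature names are suffixed
#' `".<modality>"` at load time so names are globally unique after
#' integration.
#'
#' @param path file path.
#' @param name modality label.
#' @param idColumn name of the patient-identifier column (default
#'   `"patient_id"`).
#' @param missingTokens cell values mapped to `NA`.
#' @return a [ModalityBlock-class].
#' @export
loadModality <- function(path, name, idColumn = "patient_id",
                         missingTokens = c("", "NA", "NaN", "nan")) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!(idColumn %in% names(df)))
    stop("id column '", idColumn, "' absent from ", path)
  ids <- df[[idColumn]]
  if (anyDuplicated(ids))
    stop("duplicate patient id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  feat <- df[setdiff(names(df), idColumn)]
  mat <- matrix(NA_real_, nrow(df), length(feat),
                dimnames = list(ids, paste0(names(feat), ".", name)))
  for (j in seq_along(feat)) {
    v <- trimws(feat[[j]])
    v[v %in% missingTokens] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell in column '%s' of %s (e.g. row %d: '%s')",
                   names(feat)[j], path, bad[1], v[bad[1]]))
    mat[, j] <- num
  }
  new("ModalityBlock", modality = name, patientIDs = ids, values = mat)
}

#' Integrate modality blocks by outer join on patient identifiers
#'
#' The patient set is the union of all block id sets; cells for patients
#' absent from a modality become missing. The feature-to-modality map is
#' recorded in `rowData`.
#'
#' @param blocks list of [ModalityBlock-class] objects.
#' @return a [CohortTable-class] without outcome/batch annotations.
#' @export
integrateModalities <- function(blocks) {
  if (!length(blocks)) stop("at least one modality block is required")
  allFeat <- unlist(lapply(blocks, function(b) colnames(b@values)))
  if (anyDuplicated(allFeat))
    stop("feature name collision after modality suffixing: ",
         paste(unique(allFeat[duplicated(allFeat)]), collapse = ", "))
  ids <- unique(unlist(lapply(blocks, patientIDs)))
  X <- matrix(NA_real_, length(ids), length(allFeat),
              dimnames = list(ids, allFeat))
  modality <- character(length(allFeat))
  names(modality) <- allFeat
  for (b in blocks) {
    if (ncol(b@values) == 0) next
    X[b@patientIDs, colnames(b@values)] <- b@values
    modality[colnames(b@values)] <- b@modality
  }
  CohortTable(X, modality = modality)
}

#' Stratified cross-validation fold assignment
#'
#' Patients are shuffled within each outcome class under the seed and dealt
#' round-robin over folds, so per-fold class counts differ by at most one
#' from perfect stratification.
#'
#' @param outcome binary 0/1 vector.
#' @param nFolds number of folds (>= 2, at most the minority-class count).
#' @param seed integer seed.
#' @return integer vector of fold indices in `0:(nFolds - 1)`.
#' @export
stratifiedFolds <- function(outcome, nFolds = 5L, seed = 1L) {
  outcome <- as.numeric(outcome)
  if (anyNA(outcome)) stop("outcome may not contain NA for fold assignment")
  tab <- table(outcome)
  if (length(tab) < 2) stop("both outcome classes must be present")
  if (nFolds < 2) stop("nFolds must be >= 2")
  if (nFolds > min(tab))
    stop("nFolds exceeds the minority-class count (", min(tab), ")")
  set.seed(seed)
  fold <- integer(length(outcome))
  for (cl in names(tab)) {
    idx <- sample(which(outcome == as.numeric(cl)))
    fold[idx] <- rep_len(seq_len(nFolds) - 1L, length(idx))
  }
  fold
}

#' Load a gene-set collection from a GMT file
#'
#' Each line is `name TAB description TAB gene ids...`. Duplicate genes
#' within a set are deduplicated; sets left empty are dropped with a
#' warning; a line with fewer than three fields is an error.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
loadGeneSets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (fewer than 3 fields): ",
           substr(ln, 1, 60))
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("dropping empty gene set '", parts[1], "'")
      next
    }
    sets[[parts[1]]] <- genes
  }
  sets
}

#' Read a pipeline configuration from YAML
#'
#' Settings mirror [pipelineDefaults()]; any key absent from the file keeps
#' its default. Modality paths are given as a named map `modalities:
#' {NAME: path}`.
#'
#' @param path YAML file.
#' @return a named list of settings.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(pipelineDefaults(), cfg)
  if (out$nFolds < 2) stop("nFolds must be >= 2")
  for (k in c("stabilityThreshold", "importanceQuantile",
              "missingThreshold")) {
    if (out[[k]] < 0 || out[[k]] > 1) stop(k, " must lie in [0, 1]")
  }
  out
}

#' Default pipeline settings
#'
#' @return named list: fold count, selection thresholds, missingness
#'   threshold, hyperparameter-search budget, harmonized modalities, seed.
#' @export
pipelineDefaults <- function() {
  list(
    modalities = list(),
    outcomeColumn = "outcome",
    batchColumn = "batch",
    idColumn = "patient_id",
    nFolds = 5L,
    topK = 20L,
    importanceQuantile = 0.5,
    stabilityThreshold = 0.6,
    missingThreshold = 0.05,
    harmonizeModalities = c("CT", "PET"),
    searchBudget = 0L,
    borderlineMargin = 0.05,
    seed = 1L,
    outputDir = "."
  )
}
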