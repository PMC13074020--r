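#' Selection parameters for the two-tier screening procedure
#'
#' @param nFolds cross-validation folds (default 5).
#' @param topK per-fold rank cutoff for the stability score (default 20,
#'   the size of a typical consensus signature).
#' @param importanceQuantile a feature must reach this quantile of the
#'   nonzero mean-attribution distribution (default 0.5).
#' @param stabilityThreshold minimum fraction of folds in which the feature
#'   ranks in the per-fold top `topK` (default 0.6).
#' @param learner screening-model parameters: modest fixed settings (depth
#'   3, 200 trees, learning rate 0.1) chosen for stable rankings rather
#'   than per-fold tuning.
#' @param optimize when TRUE (the default) the multimodal stage optimizes
#'   the two thresholds by nested fold-held-out search with the
#'   one-standard-error parsimony rule ([optimizeThresholds()]); when
#'   FALSE the fixed thresholds above are used throughout.
#' @param seed integer seed.
#' @return named list of class `"SelectionParams"`.
#' @export
selectionParams <- function(nFolds = 5L, topK = 20L,
                            importanceQuantile = 0.5,
                            stabilityThreshold = 0.6,
                            learner = list(max_depth = 3, eta = 0.1,
                                           nrounds = 200),
                            optimize = TRUE,
                            seed = 1L) {
  stopifnot(topK >= 1, nFolds >= 2,
            importanceQuantile >= 0, importanceQuantile <= 1,
            stabilityThreshold >= 0, stabilityThreshold <= 1)
  structure(list(nFolds = as.integer(nFolds), topK = as.integer(topK),
                 importanceQuantile = importanceQuantile,
                 stabilityThreshold = stabilityThreshold,
                 learner = learner, optimize = isTRUE(optimize),
                 seed = as.integer(seed)),
            class = "SelectionParams")
}

# shared booster fit; missing cells routed natively by the tree learner
fitBooster <- function(X, y, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, missing = NA)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  full <- utils::modifyList(
    list(objective = "binary:logistic", nthread = 1,
         scale_pos_weight = if (npos > 0) nneg / npos else 1,
         seed = seed),
    params[setdiff(names(params), c("nrounds", "seed"))])
  set.seed(seed)
  xgboost::xgb.train(params = full, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

#' Per-fold held-out mean absolute Shapley attributions
#'
#' For each fold a boosted-tree screening model is fit on the training
#' partition only; exact tree-ensemble Shapley attributions (log-odds
#' space) are computed on the held-out partition and summarized as the mean
#' absolute attribution per feature. Held-out labels never touch the fit,
#' so importance rewards generalization rather than memorization.
#'
#' @param table a [CohortTable-class] (missing cells permitted).
#' @param outcome binary 0/1 vector aligned with the table's patients.
#' @param folds integer fold assignment from [stratifiedFolds()].
#' @param params a [selectionParams()].
#' @return numeric matrix, folds x features.
#' @export
foldAttributions <- function(table, outcome, folds,
                             params = selectionParams()) {
  X <- featureMatrix(table)
  outcome <- as.numeric(outcome)
  stopifnot(length(outcome) == nrow(X), length(folds) == nrow(X))
  nF <- length(unique(folds))
  imp <- matrix(0, nF, ncol(X),
                dimnames = list(NULL, colnames(X)))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(outcome[tr])) < 2)
      stop("fold ", f, " leaves a single-class training partition")
    bst <- fitBooster(X[tr, , drop = FALSE], outcome[tr], params$learner,
                      params$learner$nrounds, seed = params$seed + f)
    dte <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], missing = NA)
    phi <- stats::predict(bst, dte, predcontrib = TRUE)
    phi <- phi[, colnames(X), drop = FALSE]   # drop the intercept column
    imp[f + 1L, ] <- colMeans(abs(phi))
  }
  imp
}

#' Dual-metric feature scores: mean attribution and cross-fold stability
#'
#' Stability is the fraction of folds in which the feature ranks within the
#' per-fold top `topK` by mean absolute attribution; ties at rank `topK`
#' are broken by feature-name lexicographic order so scoring is
#' deterministic.
#'
#' @param foldImportances folds x features matrix from [foldAttributions()].
#' @param topK per-fold rank cutoff.
#' @return data.frame (`feature`, `mean_abs_attribution`, `stability`)
#'   ordered by descending importance, ties lexicographic.
#' @export
scoreFeatures <- function(foldImportances, topK = 20L) {
  stopifnot(nrow(foldImportances) >= 2)
  feats <- colnames(foldImportances)
  nF <- nrow(foldImportances)
  k <- min(topK, length(feats))
  inTop <- matrix(FALSE, nF, length(feats), dimnames = list(NULL, feats))
  for (f in seq_len(nF)) {
    ord <- order(-foldImportances[f, ], feats)
    inTop[f, feats[ord[seq_len(k)]]] <- TRUE
  }
  meanImp <- colMeans(foldImportances)
  out <- data.frame(feature = feats,
                    mean_abs_attribution = unname(meanImp),
                    stability = unname(colMeans(inTop)),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_abs_attribution, out$feature), , drop = FALSE]
}

#' Unimodal dual-metric selection within one modality
#'
#' A feature is retained iff its mean absolute attribution reaches the
#' configured quantile of the *nonzero* importance distribution AND its
#' stability reaches the stability threshold.
#'
#' @param scores data.frame from [scoreFeatures()].
#' @param params a [selectionParams()].
#' @param modality modality label recorded on the result.
#' @return a [ConsensusSignature-class] with stage `"unimodal"`.
#' @export
unimodalSelect <- function(scores, params = selectionParams(),
                           modality = NA_character_) {
  nz <- scores$mean_abs_attribution[scores$mean_abs_attribution > 0]
  if (!length(nz)) {
    warning("all importances are zero; empty selection")
    cut <- Inf
  } else {
    cut <- stats::quantile(nz, params$importanceQuantile, names = FALSE)
  }
  sel <- scores$mean_abs_attribution >= cut &
    scores$stability >= params$stabilityThreshold &
    scores$mean_abs_attribution > 0
  sc <- data.frame(feature = scores$feature,
                   modality = modality,
                   mean_abs_attribution = scores$mean_abs_attribution,
                   stability = scores$stability,
                   selected = sel, stringsAsFactors = FALSE)
  new("ConsensusSignature", stage = "unimodal", scores = sc)
}

#' Optimize the dual-metric thresholds by nested fold-held-out search
#'
#' Grid search over (importance quantile, stability threshold) pairs.
#' Each cell is scored by leave-one-fold-out evaluation: features are
#' selected from the attribution rows of the *other* folds only, a model is
#' fit on those folds and its AUC measured on the held-out fold. Because
#' plain AUC maximization provably favors over-selection (spuriously stable
#' features carry genuine within-sample signal), the chosen cell is the one
#' giving the SMALLEST full-data selection whose mean held-out AUC lies
#' within one standard error of the best cell (the one-standard-error
#' parsimony rule); ties prefer the stricter stability then importance
#' gate.
#'
#' @param table [CohortTable-class] restricted to the candidate features.
#' @param outcome binary outcome vector.
#' @param foldImportances folds x features matrix from [foldAttributions()].
#' @param folds the fold assignment the importances were computed under.
#' @param params a [selectionParams()].
#' @param grid data.frame with columns `importanceQuantile`,
#'   `stabilityThreshold`; default crosses {0.5, 0.75} x {0.6, 0.8, 1.0}.
#' @return list with `importanceQuantile`, `stabilityThreshold` (the chosen
#'   cell) and `trace` (per-cell held-out AUC and selection size).
#' @export
optimizeThresholds <- function(table, outcome, foldImportances, folds,
                               params = selectionParams(),
                               grid = expand.grid(
                                 importanceQuantile = c(0.5, 0.75),
                                 stabilityThreshold = c(0.6, 0.8, 1.0))) {
  X <- featureMatrix(table)
  y <- as.numeric(outcome)
  foldIDs <- sort(unique(folds))
  cellStats <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- selectionParams(nFolds = params$nFolds, topK = params$topK,
                          importanceQuantile = grid$importanceQuantile[i],
                          stabilityThreshold = grid$stabilityThreshold[i],
                          learner = params$learner, seed = params$seed)
    aucs <- rep(NA_real_, length(foldIDs))
    for (k in seq_along(foldIDs)) {
      f <- foldIDs[k]
      sc <- scoreFeatures(foldImportances[-(k), , drop = FALSE],
                          params$topK)
      sel <- signatureFeatures(suppressWarnings(unimodalSelect(sc, sp)))
      if (!length(sel)) next
      tr <- folds != f
      bst <- fitBooster(X[tr, sel, drop = FALSE], y[tr], sp$learner,
                        sp$learner$nrounds, seed = params$seed + f)
      p <- stats::predict(
        bst, xgboost::xgb.DMatrix(X[!tr, sel, drop = FALSE], missing = NA))
      aucs[k] <- aucMW(p, y[!tr])
    }
    full <- signatureFeatures(suppressWarnings(unimodalSelect(
      scoreFeatures(foldImportances, params$topK), sp)))
    list(auc = mean(aucs, na.rm = TRUE),
         se = stats::sd(aucs, na.rm = TRUE) /
           sqrt(sum(!is.na(aucs))),
         size = length(full))
  })
  trace <- cbind(grid,
                 heldout_auc = vapply(cellStats, `[[`, numeric(1), "auc"),
                 se = vapply(cellStats, `[[`, numeric(1), "se"),
                 size = vapply(cellStats, `[[`, numeric(1), "size"))
  ok <- is.finite(trace$heldout_auc) & trace$size > 0
  if (!any(ok))
    return(list(importanceQuantile = params$importanceQuantile,
                stabilityThreshold = params$stabilityThreshold,
                trace = trace))
  best <- which.max(ifelse(ok, trace$heldout_auc, -Inf))
  cutoff <- trace$heldout_auc[best] -
    (if (is.finite(trace$se[best])) trace$se[best] else 0)
  admitted <- which(ok & trace$heldout_auc >= cutoff)
  pick <- admitted[order(trace$size[admitted],
                         -trace$stabilityThreshold[admitted],
                         -trace$importanceQuantile[admitted])][1]
  list(importanceQuantile = trace$importanceQuantile[pick],
       stabilityThreshold = trace$stabilityThreshold[pick],
       trace = trace)
}

#' Multimodal re-selection on the aggregated unimodal survivors
#'
#' Re-runs the same dual-metric cross-validated procedure on the table
#' restricted to all features retained by the unimodal stage, yielding the
#' final consensus signature.
#'
#' @param table [CohortTable-class] restricted to the retained features.
#' @param outcome binary outcome vector.
#' @param params a [selectionParams()].
#' @return a [ConsensusSignature-class] with stage `"multimodal"`.
#' @export
multimodalSelect <- function(table, outcome, params = selectionParams()) {
  if (nrow(table) < 1)
    stop("no features survived the unimodal stage; relax the importance ",
         "or stability thresholds")
  folds <- stratifiedFolds(outcome, params$nFolds, seed = params$seed)
  imp <- foldAttributions(table, outcome, folds, params)
  if (params$optimize) {
    thr <- optimizeThresholds(table, outcome, imp, folds, params)
    params <- selectionParams(
      nFolds = params$nFolds, topK = params$topK,
      importanceQuantile = thr$importanceQuantile,
      stabilityThreshold = thr$stabilityThreshold,
      learner = params$learner, optimize = FALSE, seed = params$seed)
  }
  scores <- scoreFeatures(imp, params$topK)
  sig <- unimodalSelect(scores, params)
  mods <- featureModality(table)
  sig@scores$modality <- unname(mods[sig@scores$feature])
  new("ConsensusSignature", stage = "multimodal", scores = sig@scores)
}

#' Two-tier feature selection across modalities
#'
#' Stage one screens each modality independently under cross-validation
#' with the dual importance/stability metric; stage two aggregates all
#' survivors and re-screens them jointly to capture synergistic cross-modal
#' predictors.
#'
#' @param table full [CohortTable-class].
#' @param outcome binary outcome vector.
#' @param params a [selectionParams()].
#' @return list with `unimodal` (named list of stage-one signatures per
#'   modality) and `signature` (the final multimodal
#'   [ConsensusSignature-class]).
#' @export
twoTierSelect <- function(table, outcome, params = selectionParams()) {
  mods <- featureModality(table)
  folds <- stratifiedFolds(outcome, params$nFolds, seed = params$seed)
  uni <- list()
  survivors <- character(0)
  for (m in unique(mods)) {
    sub <- table[names(mods)[mods == m], ]
    imp <- foldAttributions(sub, outcome, folds, params)
    scores <- scoreFeatures(imp, params$topK)
    sig <- suppressWarnings(unimodalSelect(scores, params, modality = m))
    uni[[m]] <- sig
    survivors <- c(survivors, signatureFeatures(sig))
  }
  if (!length(survivors))
    stop("no features survived the unimodal stage; relax the importance ",
         "or stability thresholds")
  final <- multimodalSelect(keepFeatures(table, survivors), outcome, params)
  list(unimodal = uni, signature = final)
}

#' Write feature scores / a signature as TSV
#'
#' @param signature a [ConsensusSignature-class].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
writeSignature <- function(signature, path) {
  utils::write.table(signature@scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
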