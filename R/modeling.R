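#' Hyperparameter search space for the boosted-tree classifier
#'
#' @param learning_rate bounds, searched log-uniformly.
#' @param max_depth integer bounds.
#' @param subsample,colsample_bytree bounds, uniform.
#' @param n_trees integer bounds.
#' @param min_child_weight bounds, uniform.
#' @param budget total number of parameter evaluations (>= 5).
#' @return named list of class `"SearchSpace"`.
#' @export
searchSpace <- function(learning_rate = c(0.01, 0.3),
                        max_depth = c(2L, 6L),
                        subsample = c(0.5, 1.0),
                        colsample_bytree = c(0.5, 1.0),
                        n_trees = c(100L, 600L),
                        min_child_weight = c(1, 10),
                        budget = 50L) {
  sp <- list(learning_rate = learning_rate, max_depth = max_depth,
             subsample = subsample, colsample_bytree = colsample_bytree,
             n_trees = n_trees, min_child_weight = min_child_weight,
             budget = as.integer(budget))
  for (p in setdiff(names(sp), "budget"))
    if (!(length(sp[[p]]) == 2 && all(is.finite(sp[[p]])) &&
          sp[[p]][1] < sp[[p]][2]))
      stop("bounds for ", p, " must be finite with low < high")
  structure(sp, class = "SearchSpace")
}

# decode a unit-cube point into learner parameters
decodePoint <- function(u, space) {
  lr <- exp(log(space$learning_rate[1]) +
              u[1] * diff(log(space$learning_rate)))
  depth <- space$max_depth[1] +
    min(floor(u[2] * (diff(space$max_depth) + 1)), diff(space$max_depth))
  ss <- space$subsample[1] + u[3] * diff(space$subsample)
  cs <- space$colsample_bytree[1] + u[4] * diff(space$colsample_bytree)
  nt <- space$n_trees[1] +
    min(floor(u[5] * (diff(space$n_trees) + 1)), diff(space$n_trees))
  mcw <- space$min_child_weight[1] + u[6] * diff(space$min_child_weight)
  list(eta = lr, max_depth = as.integer(depth), subsample = ss,
       colsample_bytree = cs, nrounds = as.integer(nt),
       min_child_weight = mcw)
}

cvAUC <- function(X, y, learner, folds, seed) {
  aucs <- numeric(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    bst <- fitBooster(X[tr, , drop = FALSE], y[tr],
                      learner[setdiff(names(learner), "nrounds")],
                      learner$nrounds, seed = seed + f)
    p <- stats::predict(bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE],
                                                  missing = NA))
    aucs <- c(aucs, aucMW(p, y[!tr]))
  }
  mean(aucs)
}

#' Surrogate-based sequential hyperparameter search
#'
#' Sequential model-based optimization maximizing mean stratified-CV AUC:
#' an initial Latin-hypercube design covers the space, then a random-forest
#' surrogate proposes each next evaluation by expected improvement over the
#' incumbent. Deterministic under `seed`; every evaluation is logged in the
#' returned trace. A pure random-search fallback is available via
#' `method = "random"` for constrained settings.
#'
#' @param table [CohortTable-class] restricted to the selected features (or
#'   a patients x features matrix).
#' @param outcome binary outcome vector.
#' @param space a [searchSpace()].
#' @param nFolds stratified CV folds used inside the search.
#' @param seed integer seed.
#' @param method `"smbo"` (default) or `"random"`.
#' @return list with `params` (best learner parameters, class
#'   `"ModelParams"`) and `trace` (data.frame of all evaluations).
#' @export
tuneModel <- function(table, outcome, space = searchSpace(), nFolds = 5L,
                      seed = 1L, method = c("smbo", "random")) {
  method <- match.arg(method)
  if (space$budget < 5)
    stop("search budget must be >= 5 to fit a surrogate")
  X <- if (is(table, "CohortTable")) featureMatrix(table) else table
  y <- as.numeric(outcome)
  folds <- stratifiedFolds(y, nFolds, seed = seed)
  d <- 6L
  nInit <- if (method == "random") space$budget
           else max(5L, min(space$budget, as.integer(ceiling(space$budget / 3))))
  set.seed(seed)
  U <- lhs::randomLHS(nInit, d)
  evalsU <- matrix(NA_real_, 0, d)
  trace <- NULL
  scores <- numeric(0)
  evalOne <- function(u) {
    pars <- decodePoint(u, space)
    auc <- cvAUC(X, y, pars, folds, seed)
    trace <<- rbind(trace, cbind(as.data.frame(pars), cv_auc = auc))
    evalsU <<- rbind(evalsU, u)
    scores <<- c(scores, auc)
  }
  for (i in seq_len(nInit)) evalOne(U[i, ])
  if (method == "smbo") {
    for (it in seq_len(space$budget - nInit)) {
      df <- as.data.frame(evalsU); names(df) <- paste0("u", seq_len(d))
      df$y <- scores
      rf <- ranger::ranger(y ~ ., data = df, num.trees = 200,
                           seed = seed + it, num.threads = 1)
      set.seed(seed + 1000L + it)
      cand <- matrix(stats::runif(256 * d), 256, d)
      cdf <- as.data.frame(cand); names(cdf) <- paste0("u", seq_len(d))
      pr <- stats::predict(rf, cdf, predict.all = TRUE,
                           num.threads = 1)$predictions
      mu <- rowMeans(pr)
      sdv <- apply(pr, 1, stats::sd)
      best <- max(scores)
      z <- ifelse(sdv > 0, (mu - best) / sdv, 0)
      ei <- ifelse(sdv > 0,
                   (mu - best) * stats::pnorm(z) + sdv * stats::dnorm(z),
                   pmax(mu - best, 0))
      evalOne(cand[which.max(ei), ])
    }
  }
  ibest <- which.max(scores)
  pars <- decodePoint(evalsU[ibest, ], space)
  trace$iteration <- seq_len(nrow(trace))
  list(params = structure(c(pars, list(seed = as.integer(seed))),
                          class = "ModelParams"),
       trace = trace)
}

#' Default learner parameters (used when no search is run)
#'
#' @param seed integer seed.
#' @return a `"ModelParams"` list.
#' @export
defaultModelParams <- function(seed = 1L) {
  structure(list(eta = 0.1, max_depth = 3L, subsample = 0.8,
                 colsample_bytree = 0.8, nrounds = 200L,
                 min_child_weight = 1, seed = as.integer(seed)),
            class = "ModelParams")
}

#' Train the boosted-tree classifier
#'
#' Gradient-boosted decision trees with native missing-value routing:
#' missing cells are permitted in the input and no imputation happens here.
#' Class imbalance is handled by weighting the positive class by the
#' negative/positive count ratio. Reproducible under the seed carried in
#' `params`.
#'
#' @param table [CohortTable-class] or patients x features matrix.
#' @param outcome binary outcome vector (both classes required).
#' @param params a `"ModelParams"` list ([defaultModelParams()] or
#'   [tuneModel()]`$params`).
#' @return a fitted `xgb.Booster`.
#' @export
trainModel <- function(table, outcome, params = defaultModelParams()) {
  X <- if (is(table, "CohortTable")) featureMatrix(table) else table
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2) stop("single-class outcome")
  fitBooster(X,
             y,
             params[setdiff(names(params), c("nrounds", "seed"))],
             params$nrounds, seed = params$seed)
}

avatarModel <- function(bundle) xgboost::xgb.load.raw(bundle@modelRaw)

# align a table to the bundle's signature: policy applied, signature
# columns extracted in training order
bundleMatrix <- function(bundle, table) {
  table <- applyMissingnessPolicy(bundle@missingness, table)
  feats <- signatureFeatures(bundle)
  absent <- setdiff(feats, rownames(table))
  if (length(absent))
    stop("signature feature(s) absent from table: ",
         paste(absent, collapse = ", "))
  featureMatrix(table)[, feats, drop = FALSE]
}

#' Predict risk probabilities with a deployed avatar bundle
#'
#' Applies the bundle's missingness policy (training-learned impute values),
#' then computes the ensemble margin and probability for each patient. No
#' batch harmonization is performed; use [predictExternal()] for
#' prospective or external cohorts with batch structure.
#'
#' @param bundle an [AvatarBundle-class].
#' @param table a [CohortTable-class] containing the signature features
#'   (missing cells allowed).
#' @return data.frame: `patient_id`, `probability`, `margin`, `path`.
#' @export
predictRisk <- function(bundle, table) {
  X <- bundleMatrix(bundle, table)
  margin <- parsedMargins(parsedBundleModel(bundle), X)
  data.frame(patient_id = rownames(X),
             probability = unname(stats::plogis(margin)),
             margin = unname(margin),
             path = "full", stringsAsFactors = FALSE)
}

# parse (and memoize within the call chain) the bundle's ensemble
parsedBundleModel <- function(bundle) {
  parseTreeEnsemble(avatarModel(bundle), signatureFeatures(bundle))
}

#' Predict external patients via leave-one-out harmonization
#'
#' Each patient's radiomic signature features are harmonized against their
#' own batch with the patient excluded from the parameter fit
#' ([harmonizeLOO()]), then scored by the bundle's ensemble. Patients in
#' batches too small for the leave-one-out fit take the flagged fallback
#' path (reference standardization only).
#'
#' @param bundle an [AvatarBundle-class].
#' @param table external [CohortTable-class] with batch labels.
#' @param minOthers minimum other batch members for the LOO fit.
#' @return data.frame: `patient_id`, `probability`, `margin`, `path`
#'   (`"loo"` or `"fallback"` per patient).
#' @export
predictExternal <- function(bundle, table, minOthers = 3L) {
  b <- batchLabels(table)
  if (is.null(b)) stop("external prediction requires batch labels")
  hm <- bundle@harmonization
  harmFeats <- intersect(rownames(table), hm@featureNames)
  X <- featureMatrix(table)
  path <- stats::setNames(rep("loo", nrow(X)), rownames(X))
  if (length(harmFeats)) {
    H <- X[, harmFeats, drop = FALSE]
    for (id in rownames(X)) {
      res <- harmonizeLOO(hm, H, b, id, minOthers = minOthers)
      X[id, harmFeats] <- res$row[harmFeats]
      path[id] <- res$path
    }
  }
  ct <- CohortTable(X, modality = featureModality(table),
                    outcome = outcomes(table), batch = b)
  out <- predictRisk(bundle, ct)
  out$path <- unname(path[out$patient_id])
  out
}

#' Persist / restore an AvatarBundle as a directory
#'
#' The ensemble is written in the learner's native binary format with JSON
#' sidecars for the signature, harmonization model, missingness policy and
#' decision metadata.
#'
#' @param bundle an [AvatarBundle-class].
#' @param dir bundle directory.
#' @return `dir` (save) or the restored bundle (load).
#' @export
saveAvatarBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBin(bundle@modelRaw, file.path(dir, "model.ubj"))
  utils::write.table(bundle@signature@scores, file.path(dir, "signature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeHarmonizationModel(bundle@harmonization,
                          file.path(dir, "harmonization.json"))
  pol <- bundle@missingness
  jsonlite::write_json(
    list(threshold = pol@threshold, indicator_suffix = pol@indicatorSuffix,
         impute_values = as.list(pol@imputeValues), flagged = pol@flagged,
         dropped = pol@dropped),
    file.path(dir, "missingness.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(threshold = bundle@threshold, base_rate = bundle@baseRate,
         base_value = bundle@baseValue, params = bundle@params,
         fingerprint = bundle@fingerprint, seed = bundle@seed,
         signature_stage = bundle@signature@stage),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveAvatarBundle
#' @export
loadAvatarBundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  sc <- utils::read.table(file.path(dir, "signature.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  pol <- jsonlite::read_json(file.path(dir, "missingness.json"),
                             simplifyVector = TRUE)
  raw <- readBin(file.path(dir, "model.ubj"), "raw",
                 file.size(file.path(dir, "model.ubj")))
  new("AvatarBundle",
      modelRaw = raw,
      signature = new("ConsensusSignature",
                      stage = meta$signature_stage, scores = sc),
      harmonization = readHarmonizationModel(
        file.path(dir, "harmonization.json")),
      missingness = new("MissingnessPolicy",
                        threshold = pol$threshold,
                        indicatorSuffix = pol$indicator_suffix,
                        imputeValues = unlist(pol$impute_values) %||%
                          stats::setNames(numeric(0), character(0)),
                        flagged = as.character(pol$flagged %||% character(0)),
                        dropped = as.character(pol$dropped %||% character(0))),
      threshold = meta$threshold, baseRate = meta$base_rate,
      baseValue = meta$base_value, params = as.list(meta$params),
      fingerprint = meta$fingerprint, seed = as.integer(meta$seed))
}
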