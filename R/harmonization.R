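#' Fit reference-batch empirical-Bayes batch correction (ComBat)
#'
#' Features are standardized against the reference batch's per-feature mean
#' and SD; per-batch location/scale effects on the standardized scale are
#' then shrunk by parametric empirical Bayes (normal prior on location,
#' inverse-gamma on scale, hyperparameters by method of moments, iterative
#' conditional updates to tolerance 1e-4, at most 100 iterations). The
#' reference batch is forced to identity, so reference rows pass through
#' unchanged on application.
#'
#' Features with zero variance in the reference batch are flagged and passed
#' through unharmonized with a warning. Missing cells are ignored in all
#' estimates and stay missing on application.
#'
#' @param x numeric matrix, patients x features (missing permitted).
#' @param batch character vector of batch labels per patient.
#' @param referenceBatch label of the reference (training) batch.
#' @return a [HarmonizationModel-class].
#' @export
fitCombat <- function(x, batch, referenceBatch) {
  stopifnot(is.matrix(x), length(batch) == nrow(x))
  batch <- as.character(batch)
  if (!(referenceBatch %in% batch))
    stop("reference batch '", referenceBatch, "' has no patients")
  sizes <- table(batch)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    stop("batch(es) with < 2 patients (", paste(small, collapse = ", "),
         "): use the leave-one-out fallback (harmonizeLOO) instead")

  ref <- x[batch == referenceBatch, , drop = FALSE]
  alpha <- colMeans(ref, na.rm = TRUE)
  # population (1/n) variance, the classic ComBat standardization convention
  sigma <- apply(ref, 2, function(v) {
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2))
  })
  passthrough <- colnames(x)[!is.finite(sigma) | sigma <= 0]
  if (length(passthrough))
    warning("zero-variance feature(s) in reference batch passed through ",
            "unharmonized: ", paste(passthrough, collapse = ", "))
  usable <- setdiff(colnames(x), passthrough)

  effects <- list()
  for (b in unique(batch)) {
    if (b == referenceBatch) {
      effects[[b]] <- list(
        gamma = stats::setNames(rep(0, length(usable)), usable),
        delta2 = stats::setNames(rep(1, length(usable)), usable),
        n = sum(batch == b), gbar = 0, tau2 = 0, lambda = NA_real_,
        theta = NA_real_)
      next
    }
    z <- sweep(sweep(x[batch == b, usable, drop = FALSE], 2, alpha[usable]),
               2, sigma[usable], "/")
    effects[[b]] <- ebBatchEffect(z)
    effects[[b]]$n <- sum(batch == b)
  }

  new("HarmonizationModel",
      featureNames = colnames(x),
      alpha = alpha, sigma = sigma,
      batchEffects = effects,
      referenceBatch = referenceBatch,
      passthrough = passthrough)
}

# Empirical-Bayes location/scale estimates for one batch of standardized
# data (rows = patients, cols = features). Returns gamma (additive) and
# delta2 (multiplicative, variance scale) per feature plus hyperpriors.
ebBatchEffect <- function(z, tol = 1e-4, maxIter = 100L) {
  nObs <- colSums(!is.na(z))
  gammaHat <- colMeans(z, na.rm = TRUE)
  d2Hat <- apply(z, 2, stats::var, na.rm = TRUE)
  d2Hat[!is.finite(d2Hat) | d2Hat < 1e-8] <- 1e-8

  gbar <- mean(gammaHat)
  tau2 <- stats::var(gammaHat)
  m <- mean(d2Hat); s2 <- stats::var(d2Hat)
  if (length(gammaHat) < 2 || !is.finite(tau2) || tau2 <= 0 ||
      !is.finite(s2) || s2 <= 0) {
    # degenerate hyperprior (single feature or identical moments): no
    # shrinkage, use the direct estimates
    return(list(gamma = gammaHat, delta2 = d2Hat, gbar = gbar,
                tau2 = tau2, lambda = NA_real_, theta = NA_real_))
  }
  lambda <- (2 * s2 + m^2) / s2
  theta <- (m * s2 + m^3) / s2

  gStar <- gammaHat
  dStar <- d2Hat
  for (it in seq_len(maxIter)) {
    gNew <- (nObs * tau2 * gammaHat + dStar * gbar) / (nObs * tau2 + dStar)
    sum2 <- colSums(sweep(z, 2, gNew)^2, na.rm = TRUE)
    dNew <- (theta + 0.5 * sum2) / (nObs / 2 + lambda - 1)
    change <- max(abs(gNew - gStar), abs(dNew - dStar))
    gStar <- gNew; dStar <- dNew
    if (change < tol) break
  }
  list(gamma = gStar, delta2 = dStar, gbar = gbar, tau2 = tau2,
       lambda = lambda, theta = theta)
}

#' Apply a fitted harmonization model
#'
#' Each cell is mapped `x' = sigma * (z - gamma) / sqrt(delta2) + alpha`
#' with `z = (x - alpha) / sigma` and the batch's shrunken effects.
#' Reference-batch rows and passthrough features are returned unchanged;
#' missing cells stay missing.
#'
#' @param model a [HarmonizationModel-class].
#' @param x patients x features matrix; features must match the model.
#' @param batch batch label per row; all labels must be known to the model.
#' @return the harmonized matrix.
#' @export
applyCombat <- function(model, x, batch) {
  stopifnot(is.matrix(x), length(batch) == nrow(x))
  batch <- as.character(batch)
  feats <- intersect(colnames(x), model@featureNames)
  if (!length(feats)) stop("no model features present in the matrix")
  unknown <- setdiff(unique(batch), names(model@batchEffects))
  if (length(unknown))
    stop("unknown batch label(s): ", paste(unknown, collapse = ", "))
  usable <- setdiff(feats, model@passthrough)
  out <- x
  for (b in unique(batch)) {
    rows <- which(batch == b)
    eff <- model@batchEffects[[b]]
    f <- intersect(usable, names(eff$gamma))
    z <- sweep(sweep(x[rows, f, drop = FALSE], 2, model@alpha[f]),
               2, model@sigma[f], "/")
    zAdj <- sweep(sweep(z, 2, eff$gamma[f]), 2, sqrt(eff$delta2[f]), "/")
    out[rows, f] <- sweep(sweep(zAdj, 2, model@sigma[f], "*"),
                          2, model@alpha[f], "+")
  }
  out
}

#' Leakage-free leave-one-out harmonization of a single patient
#'
#' Batch effects are estimated on the patient's batch *excluding the patient
#' themselves* (standardized against the training reference statistics), and
#' the resulting transform is applied to the patient's row. The fitted batch
#' parameters are a pure function of the other batch members, so perturbing
#' the test patient's own values cannot change them.
#'
#' When the batch minus the test patient has fewer than `minOthers` members,
#' the function falls back to reference standardization only (the identity
#' transform in the original feature space) and flags the path.
#'
#' @param model a [HarmonizationModel-class] providing the training
#'   reference statistics (its batch effects are not used).
#' @param x external patients x features matrix.
#' @param batch batch label per row of `x`.
#' @param patient row name of the patient to harmonize.
#' @param minOthers minimum number of other batch members (default 3).
#' @return list with `row` (named harmonized feature vector), `gamma`,
#'   `delta2` (fitted batch effects, `NULL` on fallback) and `path`
#'   (`"loo"` or `"fallback"`).
#' @export
harmonizeLOO <- function(model, x, batch, patient, minOthers = 3L) {
  stopifnot(is.matrix(x))
  if (!(patient %in% rownames(x))) stop("unknown patient: ", patient)
  batch <- as.character(batch)
  i <- match(patient, rownames(x))
  others <- which(batch == batch[i])
  others <- setdiff(others, i)
  feats <- intersect(colnames(x), model@featureNames)
  usable <- setdiff(feats, model@passthrough)
  row <- x[i, feats]

  if (length(others) < minOthers) {
    return(list(row = row, gamma = NULL, delta2 = NULL, path = "fallback"))
  }
  z <- sweep(sweep(x[others, usable, drop = FALSE], 2, model@alpha[usable]),
             2, model@sigma[usable], "/")
  eff <- ebBatchEffect(z)
  zi <- (row[usable] - model@alpha[usable]) / model@sigma[usable]
  zAdj <- (zi - eff$gamma[usable]) / sqrt(eff$delta2[usable])
  row[usable] <- zAdj * model@sigma[usable] + model@alpha[usable]
  list(row = row, gamma = eff$gamma, delta2 = eff$delta2, path = "loo")
}

#' Serialize / restore a HarmonizationModel as JSON
#'
#' @param model a [HarmonizationModel-class].
#' @param path output JSON file.
#' @return `path` (write) or the restored model (read).
#' @export
writeHarmonizationModel <- function(model, path) {
  obj <- list(
    feature_names = model@featureNames,
    alpha = as.list(model@alpha), sigma = as.list(model@sigma),
    reference_batch = model@referenceBatch,
    passthrough = model@passthrough,
    batches = lapply(model@batchEffects, function(e)
      list(gamma = as.list(e$gamma), delta2 = as.list(e$delta2), n = e$n))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHarmonizationModel
#' @export
readHarmonizationModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  eff <- lapply(obj$batches, function(e)
    list(gamma = unlist(e$gamma), delta2 = unlist(e$delta2), n = e$n))
  new("HarmonizationModel",
      featureNames = obj$feature_names,
      alpha = unlist(obj$alpha), sigma = unlist(obj$sigma),
      batchEffects = eff,
      referenceBatch = obj$reference_batch,
      passthrough = as.character(obj$passthrough %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
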