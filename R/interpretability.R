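#' Exact tree-ensemble Shapley attributions for a table of patients
#'
#' Additive per-feature attributions in log-odds (margin) space via the
#' polynomial-time tree algorithm; for every patient
#' `base_value + sum(attributions) = margin` (local accuracy). Additivity
#' holds only in margin space, so displayed probabilities are obtained
#' through the logistic link.
#'
#' @param model an `xgb.Booster`, a `"ParsedEnsemble"` or an
#'   [AvatarBundle-class].
#' @param x patients x features matrix matching the model's inputs
#'   (missing cells allowed).
#' @return list of class `"AttributionMatrix"`: `attributions` (patients x
#'   features), `baseValue` (the ensemble expectation over training data,
#'   log-odds), `space`.
#' @export
attributeShap <- function(model, x) {
  stopifnot(is.matrix(x))
  if (is(model, "AvatarBundle")) model <- avatarModel(model)
  parsed <- if (inherits(model, "ParsedEnsemble")) model
            else parseTreeEnsemble(model, colnames(x))
  phi <- parsedShap(parsed, x)
  structure(list(attributions = phi[, parsed$featureNames, drop = FALSE],
                 baseValue = unname(phi[1, "BIAS"]),
                 space = "log-odds"),
            class = "AttributionMatrix")
}

#' Global feature ranking by mean absolute attribution
#'
#' @param attr an `"AttributionMatrix"` from [attributeShap()].
#' @return data.frame (`feature`, `mean_abs_attribution`) in descending
#'   order, ties broken lexicographically.
#' @export
rankGlobal <- function(attr) {
  m <- colMeans(abs(attr$attributions))
  out <- data.frame(feature = names(m), mean_abs_attribution = unname(m),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_attribution, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stump-based clinical threshold discovery
#'
#' Fits a depth-1 regression tree of the attribution on the feature value:
#' the cutoff is the squared-error-optimal split, placed at the midpoint
#' between adjacent distinct values, found by an exhaustive scan. A rule is
#' only emitted when the split reduces the total SSE by at least
#' `sseGate` (default 5%), suppressing spurious cutoffs on noise.
#'
#' @param values feature values (one per patient).
#' @param attributions matching Shapley attributions.
#' @param feature feature name recorded on the rule.
#' @param minPoints minimum number of non-missing pairs (default 10).
#' @param sseGate minimum relative SSE reduction (default 0.05).
#' @return a list of class `"ThresholdRule"` (`feature`, `cutoff`,
#'   `direction`, `mean_left`, `mean_right`, `n_left`, `n_right`,
#'   `sse_reduction`), or `NULL` when no rule qualifies.
#' @export
stumpThreshold <- function(values, attributions, feature = NA_character_,
                           minPoints = 10L, sseGate = 0.05) {
  ok <- !is.na(values) & !is.na(attributions)
  v <- values[ok]; a <- attributions[ok]
  if (length(v) < minPoints) return(NULL)
  if (length(unique(v)) < 2) return(NULL)
  sse0 <- sum((a - mean(a))^2)
  if (sse0 == 0) return(NULL)

  ord <- order(v)
  v <- v[ord]; a <- a[ord]
  n <- length(a)
  cs <- cumsum(a); cs2 <- cumsum(a^2)
  tot <- cs[n]; tot2 <- cs2[n]
  # split after position i (left = 1..i) allowed only between distinct values
  iCand <- which(v[-n] < v[-1])
  sseL <- cs2[iCand] - cs[iCand]^2 / iCand
  nR <- n - iCand
  sseR <- (tot2 - cs2[iCand]) - (tot - cs[iCand])^2 / nR
  sse <- sseL + sseR
  best <- iCand[which.min(sse)]          # which.min takes the first (smallest
  reduction <- 1 - min(sse) / sse0       # cutoff) on ties
  if (reduction < sseGate) return(NULL)
  cutoff <- (v[best] + v[best + 1]) / 2
  meanL <- cs[best] / best
  meanR <- (tot - cs[best]) / (n - best)
  structure(list(feature = feature, cutoff = cutoff,
                 direction = if (meanR > meanL) "above_raises_risk"
                             else "below_raises_risk",
                 mean_left = meanL, mean_right = meanR,
                 n_left = best, n_right = n - best,
                 sse_reduction = reduction),
            class = "ThresholdRule")
}

#' @export
print.ThresholdRule <- function(x, ...) {
  cat(sprintf("ThresholdRule: %s %s %.4g (phi %.3f -> %.3f; n %d|%d)\n",
              x$feature,
              if (x$direction == "above_raises_risk") ">" else "<",
              x$cutoff, x$mean_left, x$mean_right, x$n_left, x$n_right))
  invisible(x)
}

#' Stump thresholds for every signature feature
#'
#' @param bundle an [AvatarBundle-class].
#' @param table training-like [CohortTable-class] to attribute.
#' @param ... passed to [stumpThreshold()].
#' @return named list of `"ThresholdRule"` (features without a qualifying
#'   rule are omitted).
#' @export
signatureThresholds <- function(bundle, table, ...) {
  X <- bundleMatrix(bundle, table)
  attr <- attributeShap(bundle, X)
  rules <- list()
  for (f in colnames(X)) {
    r <- stumpThreshold(X[, f], attr$attributions[, f], feature = f, ...)
    if (!is.null(r)) rules[[f]] <- r
  }
  rules
}

#' Local force-style explanation for one patient
#'
#' Attributions for a single row in log-odds space, sorted by descending
#' absolute attribution, with the bundle's decision threshold attached so a
#' borderline flag can be raised when the probability hovers near it.
#'
#' @param bundle an [AvatarBundle-class].
#' @param table a [CohortTable-class] containing the patient.
#' @param patient patient identifier.
#' @param borderlineMargin flag width around the threshold (default 0.05).
#' @return a [LocalExplanation-class].
#' @export
localExplain <- function(bundle, table, patient, borderlineMargin = 0.05) {
  X <- bundleMatrix(bundle, table)
  if (!(patient %in% rownames(X))) stop("unknown patient: ", patient)
  row <- X[patient, , drop = FALSE]
  attr <- attributeShap(bundle, row)
  phi <- attr$attributions[1, ]
  margin <- attr$baseValue + sum(phi)
  prob <- stats::plogis(margin)
  contrib <- data.frame(feature = names(phi),
                        value = unname(row[1, names(phi)]),
                        attribution = unname(phi),
                        stringsAsFactors = FALSE)
  contrib <- contrib[order(-abs(contrib$attribution), contrib$feature), ]
  rownames(contrib) <- NULL
  new("LocalExplanation", patientID = patient,
      baseValue = attr$baseValue, contributions = contrib,
      margin = margin, probability = prob,
      threshold = bundle@threshold,
      borderline = abs(prob - bundle@threshold) < borderlineMargin)
}

#' Individual conditional expectation (what-if) curve
#'
#' Predictions for one patient with a single feature substituted over a
#' grid while all other variables are held constant. The default grid is 25
#' points spanning the training 1st to 99th percentile of the feature
#' (stored in the bundle), with the observed value marked.
#'
#' @param bundle an [AvatarBundle-class].
#' @param table a [CohortTable-class] containing the patient.
#' @param patient patient identifier.
#' @param feature signature feature to vary.
#' @param grid numeric grid; defaults as above.
#' @return list of class `"ICECurve"`: `patient`, `feature`, `grid`,
#'   `probability`, `observed`, `observed_probability`.
#' @export
iceCurve <- function(bundle, table, patient, feature, grid = NULL) {
  feats <- signatureFeatures(bundle)
  if (!(feature %in% feats)) stop("feature not in signature: ", feature)
  X <- bundleMatrix(bundle, table)
  if (!(patient %in% rownames(X))) stop("unknown patient: ", patient)
  if (is.null(grid)) {
    q <- bundle@params$featureQuantiles[[feature]]
    if (is.null(q)) {
      v <- X[, feature]
      q <- stats::quantile(v, c(0.01, 0.99), na.rm = TRUE, names = FALSE)
    }
    grid <- seq(q[1], q[2], length.out = 25)
  }
  if (!length(grid)) stop("grid must be non-empty")
  row <- X[patient, , drop = FALSE]
  G <- row[rep(1, length(grid)), , drop = FALSE]
  G[, feature] <- grid
  parsed <- parsedBundleModel(bundle)
  p <- stats::plogis(parsedMargins(parsed, G))
  obs <- stats::plogis(parsedMargins(parsed, row))
  structure(list(patient = patient, feature = feature, grid = grid,
                 probability = unname(p),
                 observed = unname(row[1, feature]),
                 observed_probability = unname(obs)),
            class = "ICECurve")
}

#' @export
print.ICECurve <- function(x, ...) {
  cat(sprintf("ICECurve: %s over %s (%d points), observed %.4g -> p %.4f\n",
              x$patient, x$feature, length(x$grid), x$observed,
              x$observed_probability))
  invisible(x)
}
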