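#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Computed via midranks, which equals the pair-counting statistic
#' `(#concordant + 0.5 * #tied) / (#pos * #neg)` exactly, including ties.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @return the AUC.
#' @export
aucMW <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples positives and negatives separately (so every resample keeps
#' both classes) and returns the percentile interval at level `1 - alpha`.
#'
#' @param scores,labels as in [aucMW()].
#' @param B bootstrap replicates (>= 100; default 2000).
#' @param alpha two-sided error level (default 0.05).
#' @param seed integer seed.
#' @return numeric `c(low, high)`.
#' @export
bootstrapCI <- function(scores, labels, B = 2000L, alpha = 0.05, seed = 1L) {
  if (B < 100) stop("B must be >= 100")
  labels <- as.numeric(labels)
  ipos <- which(labels == 1); ineg <- which(labels == 0)
  if (!length(ipos) || !length(ineg)) stop("both classes must be present")
  set.seed(seed)
  stat <- vapply(seq_len(B), function(b) {
    i <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
    aucMW(scores[i], labels[i])
  }, numeric(1))
  stats::quantile(stat, c(alpha / 2, 1 - alpha / 2), names = FALSE)
}

# candidate thresholds: midpoints between consecutive distinct sorted
# scores, plus one extreme below the minimum and one above the maximum
youdenCandidates <- function(scores) {
  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  lo <- if (s[1] > 0) s[1] / 2 else s[1] - 1
  hi <- if (s[length(s)] < 1) (s[length(s)] + 1) / 2 else s[length(s)] + 1
  c(lo, mids, hi)
}

#' Youden-optimal decision threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` under the classification
#' rule "positive iff score >= threshold" over midpoints between
#' consecutive distinct scores plus the extremes; ties are broken toward
#' the smallest such threshold.
#'
#' @param scores,labels as in [aucMW()].
#' @return the threshold.
#' @export
youdenThreshold <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  cand <- youdenCandidates(scores)
  J <- vapply(cand, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  if (max(J) <= 0 && length(unique(scores)) == 1)
    warning("all scores identical; J = 0 everywhere")
  cand[which(J == max(J))[1]]
}

#' Sensitivity, specificity and accuracy at a threshold
#'
#' Classification rule: predict positive iff `score >= threshold` (the same
#' rule used by [youdenThreshold()] and [decisionCurve()]).
#'
#' @param scores,labels as in [aucMW()].
#' @param threshold decision threshold in (0, 1).
#' @return named numeric: `sensitivity`, `specificity`, `accuracy`.
#' @export
confusionMetrics <- function(scores, labels, threshold) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present for sensitivity and specificity")
  pred <- as.numeric(scores >= threshold)
  c(sensitivity = mean(pred[labels == 1] == 1),
    specificity = mean(pred[labels == 0] == 0),
    accuracy = mean(pred == labels))
}

#' Reliability (calibration) curve over quantile bins
#'
#' Predictions are cut at their quantiles into `nBins` half-open bins
#' `[lo, hi)` (last bin closed); each bin reports its mean predicted
#' probability, observed event frequency and count. Bins are merged when
#' quantile boundaries coincide, so counts always sum to `n`.
#'
#' @param scores,labels as in [aucMW()].
#' @param nBins number of quantile bins (default 10; reduced with a warning
#'   when `n < nBins`).
#' @return data.frame: `lo`, `hi`, `mean_predicted`, `observed`, `count`.
#' @export
calibrationCurve <- function(scores, labels, nBins = 10L) {
  if (nBins < 2) stop("nBins must be >= 2")
  labels <- as.numeric(labels)
  n <- length(scores)
  if (n < nBins) {
    warning("fewer observations than bins; using ", n, " bins")
    nBins <- n
  }
  br <- unique(stats::quantile(scores, probs = seq(0, 1, length.out = nBins + 1),
                               names = FALSE))
  if (length(br) < 2) br <- c(br, br + 1e-9)
  idx <- findInterval(scores, br, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- do.call(rbind, lapply(sort(unique(idx)), function(k) {
    sel <- idx == k
    data.frame(lo = br[k], hi = br[k + 1],
               mean_predicted = mean(scores[sel]),
               observed = mean(labels[sel]),
               count = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' Decision curve analysis: net benefit over a threshold grid
#'
#' `nb_model(t) = TP(t)/N - FP(t)/N * t/(1-t)` with positive iff
#' `score >= t`; the treat-all strategy has
#' `nb = pi - (1 - pi) * t/(1-t)` and treat-none is identically zero.
#'
#' @param scores,labels as in [aucMW()].
#' @param tGrid threshold grid in (0, 1); default 0.01 to 0.60 by 0.01, the
#'   clinically relevant range for a roughly 20%-prevalence decision.
#' @return data.frame: `threshold`, `nb_model`, `nb_treat_all`,
#'   `nb_treat_none`.
#' @export
decisionCurve <- function(scores, labels,
                          tGrid = seq(0.01, 0.60, by = 0.01)) {
  if (any(tGrid <= 0 | tGrid >= 1)) stop("thresholds must lie in (0, 1)")
  labels <- as.numeric(labels)
  n <- length(labels)
  pi <- mean(labels)
  out <- do.call(rbind, lapply(tGrid, function(t) {
    pos <- scores >= t
    tp <- sum(pos & labels == 1) / n
    fp <- sum(pos & labels == 0) / n
    data.frame(threshold = t,
               nb_model = tp - fp * t / (1 - t),
               nb_treat_all = pi - (1 - pi) * t / (1 - t),
               nb_treat_none = 0)
  }))
  rownames(out) <- NULL
  out
}

#' Full clinical-utility evaluation report
#'
#' Discrimination (AUC with stratified bootstrap CI), threshold metrics at
#' the supplied decision threshold, a quantile-binned reliability curve and
#' a decision curve, as one list.
#'
#' @param scores,labels as in [aucMW()].
#' @param threshold decision threshold (e.g. the training Youden cutoff).
#' @param B bootstrap replicates for the CI.
#' @param nBins calibration bins.
#' @param tGrid decision-curve threshold grid.
#' @param seed integer seed for the bootstrap.
#' @return list of class `"EvaluationReport"`.
#' @export
evaluateModel <- function(scores, labels, threshold, B = 2000L,
                          nBins = 10L, tGrid = seq(0.01, 0.60, by = 0.01),
                          seed = 1L) {
  labels <- as.numeric(labels)
  ci <- bootstrapCI(scores, labels, B = B, seed = seed)
  cm <- confusionMetrics(scores, labels, threshold)
  structure(list(
    auc = aucMW(scores, labels),
    ci = ci,
    decision_threshold = threshold,
    sensitivity = unname(cm["sensitivity"]),
    specificity = unname(cm["specificity"]),
    accuracy = unname(cm["accuracy"]),
    calibration = calibrationCurve(scores, labels, nBins),
    dca = decisionCurve(scores, labels, tGrid),
    n = length(labels),
    prevalence = mean(labels)), class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: n = %d, prevalence %.3f\n", x$n,
              x$prevalence))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci[1], x$ci[2]))
  cat(sprintf("  threshold %.4f: sens %.3f, spec %.3f, acc %.3f\n",
              x$decision_threshold, x$sensitivity, x$specificity,
              x$accuracy))
  invisible(x)
}

#' Write an evaluation report as JSON (+ TSV curves)
#'
#' @param report an `"EvaluationReport"`.
#' @param path output JSON path; calibration and decision curves are also
#'   written next to it as TSV.
#' @return `path`, invisibly.
#' @export
writeEvaluationReport <- function(report, path) {
  jsonlite::write_json(
    list(auc = report$auc, ci_low = report$ci[1], ci_high = report$ci[2],
         decision_threshold = report$decision_threshold,
         sensitivity = report$sensitivity,
         specificity = report$specificity, accuracy = report$accuracy,
         n = report$n, prevalence = report$prevalence),
    path, auto_unbox = TRUE, digits = NA)
  base <- sub("\\.json$", "", path)
  utils::write.table(report$calibration, paste0(base, "_calibration.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$dca, paste0(base, "_dca.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
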