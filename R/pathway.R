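#' Rank-based single-sample pathway enrichment scores
#'
#' A rank-based single-sample enrichment score in the ssGSEA style, used
#' here as a declared substitute for the kernel-density GSVA estimator. Per
#' sample, genes are ranked by expression descending (ties broken by gene
#' name for determinism); the score is the sum over all positions of the
#' weighted in-set empirical CDF (weights = rank value to the power
#' `alpha`, normalized over the set) minus the uniform out-of-set CDF.
#' Scores depend on the per-sample expression ranks only, so they are
#' invariant under any strictly monotone per-sample transform.
#'
#' @param expression genes x samples numeric matrix (>= 2 genes).
#' @param geneSets named list of gene-id vectors; sets with fewer than 2
#'   genes present in the matrix are dropped with a warning.
#' @param alpha rank-weight exponent (default 0.25).
#' @return samples x pathways numeric matrix of enrichment scores.
#' @export
ssEnrichment <- function(expression, geneSets, alpha = 0.25) {
  stopifnot(is.matrix(expression), nrow(expression) >= 2)
  genes <- rownames(expression)
  if (is.null(genes)) stop("expression must have gene row names")
  usable <- list()
  for (nm in names(geneSets)) {
    present <- intersect(unique(geneSets[[nm]]), genes)
    if (length(present) < 2) {
      warning("dropping gene set '", nm, "' (<2 genes present)")
      next
    }
    usable[[nm]] <- present
  }
  if (!length(usable)) stop("no usable gene sets")
  nG <- length(genes)
  scores <- matrix(NA_real_, ncol(expression), length(usable),
                   dimnames = list(colnames(expression), names(usable)))
  for (s in seq_len(ncol(expression))) {
    ord <- order(-expression[, s], genes)     # descending, ties by name
    rankVal <- (nG:1)^alpha                   # weight of position 1..nG
    inSet <- matrix(FALSE, nG, length(usable))
    for (k in seq_along(usable))
      inSet[match(usable[[k]], genes[ord]), k] <- TRUE
    for (k in seq_along(usable)) {
      w <- rankVal * inSet[, k]
      pIn <- cumsum(w) / sum(w)
      nOut <- nG - sum(inSet[, k])
      pOut <- if (nOut == 0) rep(0, nG) else cumsum(!inSet[, k]) / nOut
      scores[s, k] <- sum(pIn - pOut)
    }
  }
  structure(scores, alpha = alpha)
}

#' Correlate pathway enrichment scores with predicted risk
#'
#' Pearson correlation (Spearman behind `method`) of each pathway's
#' per-sample enrichment score against the model's predicted risk
#' probability, with two-sided p-values and Benjamini-Hochberg adjustment
#' across all tested pathways. Pathways with a constant score vector have
#' an undefined correlation: they are reported with a degenerate flag and
#' excluded from the adjustment.
#'
#' @param scores samples x pathways matrix from [ssEnrichment()].
#' @param risk named per-sample risk probabilities; sample ids must match.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame (`pathway`, `r`, `p`, `p_adj`, `n`, `degenerate`)
#'   sorted by adjusted p.
#' @export
correlateRisk <- function(scores, risk, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(rownames(scores), names(risk))
  if (length(common) < 4) stop("at least 4 paired samples are required")
  s <- scores[common, , drop = FALSE]
  r <- risk[common]
  out <- do.call(rbind, lapply(colnames(s), function(pw) {
    x <- s[, pw]
    if (stats::sd(x) == 0 || stats::sd(r) == 0)
      return(data.frame(pathway = pw, r = NA_real_, p = NA_real_,
                        n = length(common), degenerate = TRUE))
    ct <- stats::cor.test(x, r, method = method, exact = FALSE)
    data.frame(pathway = pw, r = unname(ct$estimate), p = ct$p.value,
               n = length(common), degenerate = FALSE)
  }))
  out$p_adj <- NA_real_
  ok <- !out$degenerate
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out <- out[order(out$p_adj, out$p, out$pathway, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("pathway", "r", "p", "p_adj", "n", "degenerate")]
}
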