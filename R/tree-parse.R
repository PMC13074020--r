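#' Parse a fitted boosted ensemble into plain tree arrays
#'
#' Extracts every tree's split features, float thresholds, child pointers,
#' leaf values and covers, plus the ensemble's intercept in margin space.
#' This representation drives the package's double-precision margin
#' evaluation and exact Shapley attribution; split routing uses the same
#' float32 comparisons as the learner, so leaf membership is identical.
#'
#' @param model a fitted `xgb.Booster` (binary logistic objective).
#' @param featureNames feature-name vector defining the column order the
#'   parsed ensemble will expect.
#' @return list of class `"ParsedEnsemble"` with `trees` and `base`
#'   (the margin-space intercept).
#' @keywords internal
parseTreeEnsemble <- function(model, featureNames) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  cfg <- xgboost::xgb.config(model)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  base <- stats::qlogis(as.numeric(cfg$learner$learner_model_param$base_score))

  used <- setdiff(unique(dt$Feature), "Leaf")
  unknown <- setdiff(used, featureNames)
  if (length(unknown))
    stop("model features absent from the table: ",
         paste(unknown, collapse = ", "))

  nodeOf <- function(id) {
    out <- rep(-1L, length(id))
    ok <- !is.na(id)
    out[ok] <- as.integer(sub("^\\d+-", "", id[ok]))
    out
  }
  trees <- lapply(split(dt, dt$Tree), function(d) {
    d <- d[order(d$Node), , drop = FALSE]
    leaf <- d$Feature == "Leaf"
    feature <- rep(-1L, nrow(d))
    feature[!leaf] <- match(d$Feature[!leaf], featureNames) - 1L
    list(feature = feature,
         split = ifelse(leaf, 0, d$Split),
         yes = nodeOf(d$Yes), no = nodeOf(d$No),
         missing = nodeOf(d$Missing),
         value = ifelse(leaf, d$Gain, 0),
         cover = d$Cover)
  })
  structure(list(trees = unname(trees), base = base,
                 featureNames = featureNames),
            class = "ParsedEnsemble")
}

# double-precision margins for a patients x features matrix whose columns
# cover the parsed ensemble's feature set
parsedMargins <- function(parsed, x) {
  x <- x[, parsed$featureNames, drop = FALSE]
  m <- treeMarginsCpp(parsed$trees, x, parsed$base)
  stats::setNames(as.numeric(m), rownames(x))
}

parsedShap <- function(parsed, x) {
  x <- x[, parsed$featureNames, drop = FALSE]
  phi <- treeShapCpp(parsed$trees, x, parsed$base)
  dimnames(phi) <- list(rownames(x), c(parsed$featureNames, "BIAS"))
  phi
}
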