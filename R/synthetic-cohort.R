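#' Simulation configuration for synthetic multi-modal cohorts
#'
#' Describes the study conditions the generator emulates: multi-modal blocks
#' of differing dimensionality, a minority-class binary outcome, non-linear
#' threshold effects and interactions on the log-odds scale, per-center batch
#' shifts in radiomic features, systematically missing clinical values, and a
#' small expression submatrix whose planted pathway activity tracks risk.
#'
#' Defaults mirror a clinically node-negative lung-cancer staging cohort:
#' 437 patients, 20 clinical + 128 PET/CT radiomic features, outcome
#' prevalence 0.19, one clinical feature missing not at random.
#'
#' @param nPatients number of patients.
#' @param modalities named integer vector: features per modality.
#' @param nInformative named integer vector: informative features per
#'   modality (first features of each block carry signal).
#' @param effectSize coefficient magnitude for linear informative features
#'   (signs alternate within a modality).
#' @param thresholdEffects `NULL` or data.frame with columns `feature`,
#'   `changepoint`, `step`: the feature contributes `step * (x > changepoint)`
#'   instead of a linear term.
#' @param interactions `NULL` or data.frame with columns `feature1`,
#'   `feature2`, `coefficient`: product terms on the log-odds scale.
#' @param targetPrevalence target outcome prevalence in (0, 1).
#' @param batch list: `nBatches`, per-batch `shift` (in SD units) and
#'   `scale` vectors, and `modalities` affected (radiomic blocks by default).
#' @param missingness `NULL` or data.frame with columns `feature`,
#'   `mechanism` (`"MCAR"`, `"MAR"`, `"MNAR"`), `rate`, and optionally
#'   `condFeature` (MAR conditioning feature).
#' @param expression list: `nGenes`, `subsetSize` (patients with expression),
#'   `nSets`, `setSize`, `effect` (planted pathway shift per SD of risk).
#' @param seed default integer seed.
#'
#' @return A validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nPatients = 437,
                             modalities = c(CLIN = 20, CT = 64, PET = 64),
                             nInformative = c(CLIN = 3, CT = 4, PET = 3),
                             effectSize = 0.8,
                             thresholdEffects = NULL,
                             interactions = NULL,
                             targetPrevalence = 0.19,
                             batch = list(nBatches = 1, shift = 0, scale = 1,
                                          modalities = c("CT", "PET")),
                             missingness = data.frame(
                               feature = "clin01.CLIN", mechanism = "MNAR",
                               rate = 0.15),
                             expression = list(nGenes = 500, subsetSize = 20,
                                               nSets = 50, setSize = 20,
                                               effect = 1.5),
                             seed = 1L) {
  cfg <- list(nPatients = as.integer(nPatients),
              modalities = modalities, nInformative = nInformative,
              effectSize = effectSize, thresholdEffects = thresholdEffects,
              interactions = interactions,
              targetPrevalence = targetPrevalence, batch = batch,
              missingness = missingness, expression = expression,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

validateSimulationConfig <- function(cfg) {
  stopifnot(cfg$nPatients >= 1)
  if (is.null(names(cfg$modalities)) || anyDuplicated(names(cfg$modalities)))
    stop("modalities must be a uniquely named vector")
  if (cfg$targetPrevalence <= 0 || cfg$targetPrevalence >= 1)
    stop("targetPrevalence must lie in (0, 1)")
  common <- intersect(names(cfg$nInformative), names(cfg$modalities))
  if (any(cfg$nInformative[common] > cfg$modalities[common]))
    stop("nInformative may not exceed the modality's feature count")
  if (!is.null(cfg$missingness) && nrow(cfg$missingness) &&
      any(cfg$missingness$rate < 0 | cfg$missingness$rate > 1))
    stop("missingness rates must lie in [0, 1]")
  b <- cfg$batch
  if (!is.null(b) && b$nBatches > 1) {
    if (length(rep_len(b$shift, b$nBatches)) < 1)
      stop("batch shift must be supplied")
  }
  invisible(TRUE)
}

simFeatureNames <- function(modality, n) {
  sprintf("%s%02d.%s", tolower(modality), seq_len(n), modality)
}

#' Generate a synthetic multi-modal cohort with known planted structure
#'
#' Features are drawn as independent standard Gaussian blocks (a declared
#' stand-in for real radiomic distributions). The outcome is Bernoulli with
#' `plogis(c + sum_j beta_j g_j(x_j) + interactions)`, `g_j` identity or a
#' step at a configured changepoint; the intercept `c` is tuned by bisection
#' so the expected prevalence is within 1e-3 of `targetPrevalence`. Batch
#' effects and missingness are then injected per the configuration.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed (defaults to `config$seed`).
#'
#' @return list with elements `cohort` (a [CohortTable-class]) and `truth`
#'   (informative features, coefficients, changepoints, batch parameters,
#'   true linear predictor and probability per patient).
#' @examples
#' sim <- generateCohort(simulationConfig(nPatients = 100), seed = 1)
#' sim$cohort
#' @export
generateCohort <- function(config, seed = config$seed) {
  validateSimulationConfig(config)
  set.seed(seed)
  n <- config$nPatients
  ids <- sprintf("P%04d", seq_len(n))

  blocks <- lapply(names(config$modalities), function(m) {
    k <- config$modalities[[m]]
    mat <- matrix(stats::rnorm(n * k), n, k,
                  dimnames = list(ids, simFeatureNames(m, k)))
    mat
  })
  X <- do.call(cbind, blocks)
  modality <- rep(names(config$modalities), times = config$modalities)

  # linear informative effects: first nInformative features of each block,
  # alternating sign so risk has both drivers and protectors
  beta <- numeric(0)
  for (m in names(config$modalities)) {
    ni <- if (m %in% names(config$nInformative)) config$nInformative[[m]] else 0L
    if (ni > 0) {
      nm <- simFeatureNames(m, config$modalities[[m]])[seq_len(ni)]
      b <- rep_len(config$effectSize, ni) * rep_len(c(1, -1), ni)
      beta <- c(beta, stats::setNames(b, nm))
    }
  }

  eta <- rep(0, n)
  stepFeats <- character(0)
  changepoints <- numeric(0)
  if (!is.null(config$thresholdEffects) && nrow(config$thresholdEffects)) {
    te <- config$thresholdEffects
    absent <- setdiff(te$feature, colnames(X))
    if (length(absent))
      stop("thresholdEffects reference unknown features: ",
           paste(absent, collapse = ", "))
    for (i in seq_len(nrow(te))) {
      eta <- eta + te$step[i] * (X[, te$feature[i]] > te$changepoint[i])
      stepFeats <- c(stepFeats, te$feature[i])
      changepoints <- c(changepoints,
                        stats::setNames(te$changepoint[i], te$feature[i]))
    }
    # a feature with a pure step effect keeps no linear term
    beta <- beta[setdiff(names(beta), te$feature)]
  }
  if (length(beta))
    eta <- eta + as.vector(X[, names(beta), drop = FALSE] %*% beta)
  if (!is.null(config$interactions) && nrow(config$interactions)) {
    ia <- config$interactions
    absent <- setdiff(c(ia$feature1, ia$feature2), colnames(X))
    if (length(absent))
      stop("interactions reference unknown features: ",
           paste(absent, collapse = ", "))
    for (i in seq_len(nrow(ia)))
      eta <- eta + ia$coefficient[i] * X[, ia$feature1[i]] * X[, ia$feature2[i]]
  }

  intercept <- tunePrevalenceIntercept(eta, config$targetPrevalence)
  p <- stats::plogis(intercept + eta)
  y <- stats::rbinom(n, 1, p)

  ct <- CohortTable(X, modality = modality, outcome = y)

  batchParams <- NULL
  if (!is.null(config$batch) && config$batch$nBatches > 1) {
    ct <- injectBatchEffects(ct, config$batch, seed = seed + 1L)
    batchParams <- data.frame(
      batch = paste0("B", seq_len(config$batch$nBatches)),
      shift = rep_len(config$batch$shift, config$batch$nBatches),
      scale = rep_len(config$batch$scale, config$batch$nBatches))
  }
  if (!is.null(config$missingness) && nrow(config$missingness))
    ct <- injectMissingness(ct, config$missingness, seed = seed + 2L)

  truth <- list(
    informativeFeatures = union(names(beta), stepFeats),
    trueCoefficients = beta,
    trueChangepoints = changepoints,
    intercept = intercept,
    batchParams = batchParams,
    linearPredictor = stats::setNames(intercept + eta, ids),
    trueProbability = stats::setNames(p, ids),
    enrichedPathways = character(0))
  list(cohort = ct, truth = truth)
}

#' Tune the outcome-model intercept by bisection
#'
#' Finds `c` with `mean(plogis(c + eta)) = target` to within 1e-3; the map is
#' strictly increasing in `c`, so bisection always converges when the target
#' is attainable within floating bounds.
#'
#' @param eta linear predictor without intercept.
#' @param target desired expected prevalence in (0, 1).
#' @return the tuned intercept.
#' @keywords internal
tunePrevalenceIntercept <- function(eta, target) {
  f <- function(c) mean(stats::plogis(c + eta)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("infeasible target prevalence: intercept out of floating bounds")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < 1e-3) return(mid)
    if (v < 0) lo <- mid else hi <- mid
  }
  mid
}

#' Inject per-batch location/scale shifts into radiomic modalities
#'
#' Affected features are transformed `x -> scale_b * x + shift_b * SD(x)`
#' within each batch, where `SD(x)` is the feature's pooled pre-transform
#' standard deviation. Unaffected modalities are untouched. When the table
#' carries no batch labels they are assigned by a seeded balanced draw.
#'
#' @param table a [CohortTable-class].
#' @param spec list with `nBatches`, `shift`, `scale` (each recycled to
#'   `nBatches`; the first batch is conventionally 0/1), and `modalities`.
#' @param seed seed for batch-label assignment.
#' @return the transformed `CohortTable` with `batch` labels set.
#' @export
injectBatchEffects <- function(table, spec, seed = 1L) {
  unknown <- setdiff(spec$modalities, unique(featureModality(table)))
  if (length(unknown))
    stop("unknown modality in batch spec: ", paste(unknown, collapse = ", "))
  nB <- spec$nBatches
  b <- batchLabels(table)
  if (is.null(b)) {
    set.seed(seed)
    b <- paste0("B", sample(rep_len(seq_len(nB), ncol(table))))
    batchLabels(table) <- b
  }
  shifts <- rep_len(spec$shift, nB)
  scales <- rep_len(spec$scale, nB)
  X <- featureMatrix(table)
  affected <- names(featureModality(table))[
    featureModality(table) %in% spec$modalities]
  sds <- apply(X[, affected, drop = FALSE], 2, stats::sd, na.rm = TRUE)
  lv <- paste0("B", seq_len(nB))
  for (i in seq_len(nB)) {
    rows <- which(b == lv[i])
    if (!length(rows)) next
    X[rows, affected] <- sweep(
      sweep(X[rows, affected, drop = FALSE], 2, scales[i], `*`),
      2, shifts[i] * sds, `+`)
  }
  assay(table, "values") <- t(X)
  table
}

#' Inject missingness under MCAR, MAR or MNAR mechanisms
#'
#' MCAR masks cells uniformly at the given rate. MAR masks conditional on
#' another observed feature's quantile (top half carries all the mass). MNAR
#' masks conditional on the outcome, preferentially when the outcome is 0
#' (systematic non-recording for less aggressively profiled patients); the
#' outcome-1 rate is one third of the outcome-0 rate, scaled so the overall
#' expected rate matches `rate`.
#'
#' @param table a [CohortTable-class]; MNAR requires outcomes.
#' @param spec data.frame with columns `feature`, `mechanism`, `rate` and
#'   optionally `condFeature` for MAR rows.
#' @param seed integer seed.
#' @return the masked `CohortTable`.
#' @export
injectMissingness <- function(table, spec, seed = 1L) {
  if (any(spec$rate < 0 | spec$rate > 1))
    stop("missingness rate outside [0, 1]")
  absent <- setdiff(spec$feature, rownames(table))
  if (length(absent))
    stop("missingness spec references unknown features: ",
         paste(absent, collapse = ", "))
  set.seed(seed)
  X <- featureMatrix(table)
  n <- nrow(X)
  for (i in seq_len(nrow(spec))) {
    f <- spec$feature[i]; r <- spec$rate[i]
    if (r == 0) next
    mech <- toupper(spec$mechanism[i])
    p <- switch(mech,
      MCAR = rep(r, n),
      MAR = {
        cf <- spec$condFeature[i]
        if (is.null(cf) || is.na(cf))
          stop("MAR requires a condFeature")
        z <- X[, cf]
        top <- z >= stats::median(z, na.rm = TRUE)
        if (r <= 0.5) ifelse(top, 2 * r, 0)
        else ifelse(top, 1, 2 * r - 1)
      },
      MNAR = {
        y <- outcomes(table)
        if (is.null(y)) stop("MNAR requires outcomes")
        pi1 <- mean(y == 1)
        p0 <- r / ((1 - pi1) + pi1 / 3)
        ifelse(y == 1, min(1, p0 / 3), min(1, p0))
      },
      stop("unknown mechanism: ", mech))
    mask <- stats::runif(n) < p
    X[mask, f] <- NA
  }
  assay(table, "values") <- t(X)
  table
}

#' Generate a synthetic expression submatrix with planted pathway signal
#'
#' Log-scale expression is Gaussian noise around gene baselines; genes of
#' each planted gene set receive a mean shift proportional to the patient's
#' standardized risk score (positive for the planted "up" set, negative for
#' the planted "down" set). Gene sets are emitted as a named list compatible
#' with GMT round-tripping via [writeGmt()].
#'
#' @param config a [simulationConfig()] (only `$expression` is used).
#' @param riskScores named per-patient risk probabilities; a seeded subset of
#'   `subsetSize` patients receives expression.
#' @param seed integer seed.
#' @return list with `expression` (genes x samples matrix), `geneSets`
#'   (named list of gene-id vectors) and `truth` (`enrichedPathways` with
#'   their planted effect signs).
#' @export
generateExpression <- function(config, riskScores, seed = config$seed) {
  ex <- config$expression
  if (ex$setSize > ex$nGenes) stop("setSize may not exceed nGenes")
  if (ex$subsetSize > length(riskScores))
    stop("subsetSize may not exceed the number of risk scores")
  set.seed(seed)
  samples <- sort(sample(names(riskScores), ex$subsetSize))
  risk <- riskScores[samples]
  z <- if (stats::sd(risk) > 0) as.vector(scale(risk)) else rep(0, length(risk))

  genes <- sprintf("GENE%04d", seq_len(ex$nGenes))
  mu <- stats::rnorm(ex$nGenes, 6, 1)
  expr <- matrix(stats::rnorm(ex$nGenes * ex$subsetSize), ex$nGenes,
                 ex$subsetSize, dimnames = list(genes, samples)) + mu

  nPlanted <- if (ex$effect != 0) 2L else 0L
  planted <- if (nPlanted) c("PLANTED_UP", "PLANTED_DN") else character(0)
  effects <- if (nPlanted) c(ex$effect, -ex$effect) else numeric(0)
  setNamesAll <- c(planted,
                   sprintf("NULL_SET_%02d", seq_len(ex$nSets - nPlanted)))
  geneSets <- vector("list", ex$nSets)
  names(geneSets) <- setNamesAll
  pool <- genes
  for (i in seq_len(nPlanted)) {   # planted sets get dedicated genes
    geneSets[[i]] <- sort(sample(pool, ex$setSize))
    pool <- setdiff(pool, geneSets[[i]])
  }
  for (i in seq(from = nPlanted + 1L, length.out = ex$nSets - nPlanted))
    geneSets[[i]] <- sort(sample(genes, ex$setSize))

  for (i in seq_len(nPlanted))
    expr[geneSets[[i]], ] <- expr[geneSets[[i]], ] +
      matrix(effects[i] * z, ex$setSize, ex$subsetSize, byrow = TRUE)

  list(expression = expr, geneSets = geneSets,
       truth = list(enrichedPathways = stats::setNames(effects, planted),
                    samples = samples))
}

#' Write a gene-set collection in GMT format
#'
#' @param geneSets named list of gene-id character vectors.
#' @param path output file.
#' @param description description field per set (recycled).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(geneSets, path, description = "synthetic") {
  lines <- vapply(names(geneSets), function(nm) {
    paste(c(nm, rep_len(description, 1), geneSets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a CohortTable as per-modality CSV files
#'
#' One CSV per modality with `patient_id` as first column; the modality
#' suffix is stripped from feature names so that [loadModality()] +
#' [integrateModalities()] round-trips the table. Outcome and batch labels
#' (when present) are written to `outcome.csv`.
#'
#' @param table a [CohortTable-class].
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
exportCohort <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mods <- featureModality(table)
  X <- featureMatrix(table)
  files <- character(0)
  for (m in unique(mods)) {
    cols <- names(mods)[mods == m]
    sub <- X[, cols, drop = FALSE]
    colnames(sub) <- sub(paste0("\\.", m, "$"), "", colnames(sub))
    df <- data.frame(patient_id = rownames(X), sub, check.names = FALSE)
    f <- file.path(dir, paste0(m, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, na = "NA")
    files <- c(files, f)
  }
  oc <- outcomes(table); b <- batchLabels(table)
  if (!is.null(oc) || !is.null(b)) {
    df <- data.frame(patient_id = patientIDs(table))
    if (!is.null(oc)) df$outcome <- as.integer(oc)
    if (!is.null(b)) df$batch <- b
    f <- file.path(dir, "outcome.csv")
    utils::write.csv(df, f, row.names = FALSE, na = "NA")
    files <- c(files, f)
  }
  invisible(files)
}

#' Canonical planted-signal benchmark configuration
#'
#' The package's standard simulation benchmark: 10 informative of 150
#' features across three modalities (3 clinical, 4 CT, 3 PET), outcome
#' prevalence 0.19, no missingness. The `"train"` role is a single-center
#' cohort of 600 patients; the `"external"` role is a 300-patient
#' two-center cohort whose second center carries a planted 1.5 SD shift
#' and 1.5x scale on the radiomic modalities, so unharmonized inference is
#' measurably degraded.
#'
#' @param role `"train"` or `"external"`.
#' @param seed integer seed stored in the configuration.
#' @return a [simulationConfig()].
#' @export
benchmarkConfig <- function(role = c("train", "external"), seed = 1L) {
  role <- match.arg(role)
  simulationConfig(
    nPatients = if (role == "train") 600L else 300L,
    modalities = c(CLIN = 50, CT = 50, PET = 50),
    nInformative = c(CLIN = 3, CT = 4, PET = 3),
    effectSize = 0.8,
    targetPrevalence = 0.19,
    batch = if (role == "train")
      list(nBatches = 1, shift = 0, scale = 1,
           modalities = c("CT", "PET"))
    else
      list(nBatches = 2, shift = c(0, 1.5), scale = c(1, 1.5),
           modalities = c("CT", "PET")),
    missingness = NULL,
    seed = as.integer(seed))
}
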