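test_that("generation is byte-identical under a fixed seed", {
  cfg <- tinyCohortConfig(n = 120, seed = 11)
  a <- generateCohort(cfg, seed = 5)
  b <- generateCohort(cfg, seed = 5)
  expect_identical(featureMatrix(a$cohort), featureMatrix(b$cohort))
  expect_identical(outcomes(a$cohort), outcomes(b$cohort))
  expect_identical(a$truth, b$truth)
  c <- generateCohort(cfg, seed = 6)
  expect_false(identical(featureMatrix(a$cohort), featureMatrix(c$cohort)))
})

test_that("prevalence tuning hits the target and degenerates gracefully", {
  cfg <- tinyCohortConfig(n = 2000, seed = 2)
  cfg$targetPrevalence <- 0.19
  sim <- generateCohort(cfg, seed = 2)
  prev <- mean(outcomes(sim$cohort))
  expect_gte(prev, 0.17)
  expect_lte(prev, 0.21)
  # bisection oracle: expected prevalence at the tuned intercept
  eta <- sim$truth$linearPredictor - sim$truth$intercept
  expect_lt(abs(mean(plogis(sim$truth$intercept + eta)) - 0.19), 1e-3)

  # all-zero effects: intercept alone must still hit the target
  cfg0 <- tinyCohortConfig(n = 2000, seed = 3)
  cfg0$nInformative <- c(CLIN = 0, CT = 0, PET = 0)
  sim0 <- generateCohort(cfg0, seed = 3)
  expect_length(sim0$truth$informativeFeatures, 0)
  expect_lt(abs(mean(outcomes(sim0$cohort)) - 0.2), 0.03)
})

test_that("with zero effects a fitted model has chance-level test AUC", {
  cfg <- tinyCohortConfig(n = 5000, seed = 4)
  cfg$nInformative <- c(CLIN = 0, CT = 0, PET = 0)
  sim <- generateCohort(cfg, seed = 4)
  y <- outcomes(sim$cohort)
  tr <- seq_len(2500); te <- setdiff(seq_along(y), tr)
  X <- featureMatrix(sim$cohort)
  bst <- trainModel(X[tr, ], y[tr], defaultModelParams(seed = 4))
  p <- predict(bst, xgboost::xgb.DMatrix(X[te, ], missing = NA))
  auc <- aucMW(p, y[te])
  expect_gte(auc, 0.45)
  expect_lte(auc, 0.55)
})

test_that("batch injection shifts group means as configured and spares excluded modalities", {
  cfg <- tinyCohortConfig(n = 400, seed = 7)
  sim <- generateCohort(cfg, seed = 7)
  spec <- list(nBatches = 2, shift = c(0, 2), scale = c(1, 1),
               modalities = c("CT", "PET"))
  before <- featureMatrix(sim$cohort)
  shifted <- injectBatchEffects(sim$cohort, spec, seed = 7)
  b <- batchLabels(shifted)
  after <- featureMatrix(shifted)

  mods <- featureModality(shifted)
  ctFeats <- names(mods)[mods == "CT"]
  gaps <- vapply(ctFeats, function(f) {
    (mean(after[b == "B2", f]) - mean(after[b == "B1", f])) / sd(before[, f])
  }, numeric(1))
  expect_lt(abs(median(gaps) - 2), 0.3)
  clinFeats <- names(mods)[mods == "CLIN"]
  expect_identical(after[, clinFeats], before[, clinFeats])

  # identity spec leaves the table unchanged
  same <- injectBatchEffects(sim$cohort,
                             list(nBatches = 2, shift = 0, scale = 1,
                                  modalities = c("CT", "PET")), seed = 7)
  expect_equal(featureMatrix(same), before)
  expect_error(
    injectBatchEffects(sim$cohort,
                       list(nBatches = 2, shift = 1, scale = 1,
                            modalities = "MRI"), seed = 1),
    "unknown modality")
})

test_that("missingness mechanisms respect their rates and conditioning", {
  cfg <- tinyCohortConfig(n = 1000, seed = 8)
  sim <- generateCohort(cfg, seed = 8)

  # rate 0: nothing masked
  z <- injectMissingness(sim$cohort,
                         data.frame(feature = "clin03.CLIN",
                                    mechanism = "MCAR", rate = 0), seed = 1)
  expect_identical(featureMatrix(z), featureMatrix(sim$cohort))

  # MCAR 0.1: overall fraction within binomial tolerance
  mc <- injectMissingness(sim$cohort,
                          data.frame(feature = "clin03.CLIN",
                                     mechanism = "MCAR", rate = 0.1),
                          seed = 2)
  frac <- mean(is.na(featureMatrix(mc)[, "clin03.CLIN"]))
  expect_gte(frac, 0.08); expect_lte(frac, 0.12)

  # MNAR 0.3 tied to outcome=0: missing more often among controls
  mn <- injectMissingness(sim$cohort,
                          data.frame(feature = "clin03.CLIN",
                                     mechanism = "MNAR", rate = 0.3),
                          seed = 3)
  miss <- is.na(featureMatrix(mn)[, "clin03.CLIN"])
  y <- outcomes(sim$cohort)
  expect_gt(mean(miss[y == 0]), mean(miss[y == 1]))
  expect_lt(abs(mean(miss) - 0.3), 0.02 + 2 * sqrt(0.3 * 0.7 / 1000))

  # MAR conditions on another feature's quantile
  ma <- injectMissingness(sim$cohort,
                          data.frame(feature = "clin03.CLIN",
                                     mechanism = "MAR", rate = 0.2,
                                     condFeature = "clin04.CLIN"),
                          seed = 4)
  miss <- is.na(featureMatrix(ma)[, "clin03.CLIN"])
  cond <- featureMatrix(sim$cohort)[, "clin04.CLIN"]
  expect_gt(mean(miss[cond >= median(cond)]), mean(miss[cond < median(cond)]))
  expect_error(
    injectMissingness(sim$cohort,
                      data.frame(feature = "clin03.CLIN",
                                 mechanism = "MCAR", rate = 1.2), seed = 1),
    "rate")
})

test_that("expression generator plants pathway signal proportional to risk", {
  cfg <- tinyCohortConfig(n = 60, seed = 9)
  risk <- setNames(runif(60, 0.05, 0.9), sprintf("P%04d", 1:60))

  ex <- generateExpression(cfg, risk, seed = 9)
  ex2 <- generateExpression(cfg, risk, seed = 9)
  expect_identical(ex$expression, ex2$expression)
  expect_length(ex$geneSets, cfg$expression$nSets)

  r <- risk[colnames(ex$expression)]
  up <- colMeans(ex$expression[ex$geneSets$PLANTED_UP, ])
  dn <- colMeans(ex$expression[ex$geneSets$PLANTED_DN, ])
  expect_gt(cor(up, r), 0)
  expect_lt(cor(dn, r), 0)

  # no planted effect: no set's mean tracks risk beyond chance
  cfg0 <- cfg; cfg0$expression$effect <- 0
  ex0 <- generateExpression(cfg0, risk, seed = 10)
  r0 <- risk[colnames(ex0$expression)]
  cors <- vapply(ex0$geneSets, function(g)
    cor(colMeans(ex0$expression[g, ]), r0), numeric(1))
  # Fisher bound: |r| for n=20 null pairs rarely exceeds 0.6
  expect_lt(max(abs(cors)), 0.65)

  cfgBad <- cfg; cfgBad$expression$setSize <- 10000
  expect_error(generateExpression(cfgBad, risk, seed = 1), "setSize")
})
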