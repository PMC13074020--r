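test_that("attributions are additive in log-odds space for every patient", {
  fx <- bundleFixture()
  X <- RiskAvatar:::bundleMatrix(fx$fit$bundle, fx$sim$cohort)
  bst <- RiskAvatar:::avatarModel(fx$fit$bundle)
  attr <- attributeShap(bst, X)
  margins <- RiskAvatar:::parsedMargins(
    RiskAvatar:::parsedBundleModel(fx$fit$bundle), X)
  resid <- abs(attr$baseValue + rowSums(attr$attributions) - margins)
  expect_lt(max(resid), 1e-6)
  expect_identical(attr$space, "log-odds")
})

test_that("authored attributions agree with the learner's own algorithm", {
  fx <- bundleFixture()
  X <- RiskAvatar:::bundleMatrix(fx$fit$bundle, fx$sim$cohort)
  bst <- RiskAvatar:::avatarModel(fx$fit$bundle)
  attr <- attributeShap(bst, X)
  ph <- predict(bst, xgboost::xgb.DMatrix(X, missing = NA),
                predcontrib = TRUE)
  expect_lt(max(abs(attr$attributions - ph[, colnames(X)])), 1e-4)
  expect_lt(abs(attr$baseValue - ph[1, "(Intercept)"]), 1e-5)
  m2 <- predict(bst, xgboost::xgb.DMatrix(X, missing = NA),
                outputmargin = TRUE)
  expect_lt(max(abs(RiskAvatar:::parsedMargins(
    RiskAvatar:::parseTreeEnsemble(bst, colnames(X)), X) - m2)), 1e-4)
})

test_that("a single-stump model attributes everything to its one feature", {
  set.seed(61)
  X <- matrix(rnorm(200), 200, 2,
              dimnames = list(sprintf("P%03d", 1:200), c("a", "b")))
  y <- as.numeric(X[, "a"] > 0)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 1, eta = 1,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 1, verbose = 0)
  attr <- attributeShap(bst, X)
  margins <- predict(bst, xgboost::xgb.DMatrix(X), outputmargin = TRUE)
  expect_equal(unname(attr$attributions[, "a"]),
               unname(margins - attr$baseValue), tolerance = 1e-6)
  expect_true(all(attr$attributions[, "b"] == 0))
})

test_that("global ranking is permutation-invariant with zeros ranked last", {
  fx <- bundleFixture()
  X <- RiskAvatar:::bundleMatrix(fx$fit$bundle, fx$sim$cohort)
  attr <- attributeShap(fx$fit$bundle, X)
  rk <- rankGlobal(attr)
  expect_true(!is.unsorted(rev(rk$mean_abs_attribution)))

  perm <- sample(nrow(X))
  attrP <- attr
  attrP$attributions <- attr$attributions[perm, , drop = FALSE]
  expect_identical(rankGlobal(attrP), rk)

  # the planted dominant features outrank the noise
  top3 <- rk$feature[1:3]
  expect_true(any(top3 %in% c("clin01.CLIN", "clin02.CLIN", "ct01.CT",
                              "ct02.CT", "pet01.PET", "pet02.PET")))
})

test_that("stump threshold matches the exhaustive-scan oracle", {
  set.seed(62)
  # planted step at 0
  for (i in 1:10) {
    x <- runif(200, -1, 1)
    a <- ifelse(x > 0, 1, -1)
    r <- stumpThreshold(x, a, feature = "f")
    xs <- sort(x)
    gap <- max(diff(xs))
    expect_false(is.null(r))
    expect_lte(abs(r$cutoff), gap)
    expect_identical(r$direction, "above_raises_risk")
    expect_equal(r$cutoff, stumpOracle(x, a))
    expect_equal(r$n_left + r$n_right, 200)
  }
  # oracle equivalence on noisy fixtures (including emission decisions)
  for (i in 1:30) {
    x <- rnorm(80)
    a <- 0.5 * (x > 0.3) + rnorm(80, sd = 0.4)
    mine <- stumpThreshold(x, a)
    orc <- stumpOracle(x, a)
    if (is.null(orc)) expect_null(mine)
    else expect_equal(mine$cutoff, orc)
  }
  # monotone linear relation: direction follows the slope sign
  x <- seq(-2, 2, length.out = 100)
  r <- stumpThreshold(x, -0.8 * x)
  expect_identical(r$direction, "below_raises_risk")

  expect_null(stumpThreshold(rep(1, 50), rnorm(50)))       # constant x
  expect_null(stumpThreshold(rnorm(5), rnorm(5)))          # too few points
  expect_null(stumpThreshold(rnorm(50), rep(2, 50)))       # constant phi
})

test_that("pure-noise attributions rarely emit a rule", {
  set.seed(63)
  emitted <- 0L
  for (i in 1:40) {
    x <- rnorm(200)
    a <- rnorm(200)
    if (!is.null(stumpThreshold(x, a))) emitted <- emitted + 1L
  }
  expect_lte(emitted / 40, 0.10)
})

test_that("local explanations satisfy the additive contract", {
  fx <- bundleFixture()
  ex <- localExplain(fx$fit$bundle, fx$sim$cohort, "P0005")
  expect_s4_class(ex, "LocalExplanation")
  expect_lt(abs(ex@baseValue + sum(ex@contributions$attribution) -
                  ex@margin), 1e-6)
  expect_equal(ex@probability, plogis(ex@margin), tolerance = 1e-9)
  expect_true(!is.unsorted(rev(abs(ex@contributions$attribution))))

  # identical patients explain identically; base is a training constant
  ex2 <- localExplain(fx$fit$bundle, fx$sim$cohort, "P0005")
  expect_equal(ex@contributions, ex2@contributions)

  X <- featureMatrix(fx$sim$cohort)
  X["P0005", signatureFeatures(fx$fit$bundle)[1]] <- 99
  ctP <- CohortTable(X, modality = featureModality(fx$sim$cohort))
  exP <- localExplain(fx$fit$bundle, ctP, "P0005")
  expect_equal(exP@baseValue, ex@baseValue)
  expect_false(isTRUE(all.equal(exP@contributions$attribution,
                                ex@contributions$attribution)))

  # borderline flag fires iff |p - threshold| < margin
  expect_identical(ex@borderline,
                   abs(ex@probability - ex@threshold) < 0.05)
})

test_that("ICE curves pass through the observed prediction and track steps", {
  fx <- bundleFixture()
  feat <- signatureFeatures(fx$fit$bundle)[1]
  obsP <- predictRisk(fx$fit$bundle, fx$sim$cohort)
  pat <- "P0011"

  cv <- iceCurve(fx$fit$bundle, fx$sim$cohort, pat, feat)
  expect_length(cv$grid, 25)
  expect_equal(cv$observed_probability,
               obsP$probability[obsP$patient_id == pat], tolerance = 1e-9)

  # single-point grid at the observed value equals the prediction
  cv1 <- iceCurve(fx$fit$bundle, fx$sim$cohort, pat, feat,
                  grid = cv$observed)
  expect_equal(cv1$probability, cv1$observed_probability, tolerance = 1e-9)

  expect_error(iceCurve(fx$fit$bundle, fx$sim$cohort, pat, "nope"),
               "signature")
  expect_error(iceCurve(fx$fit$bundle, fx$sim$cohort, pat, feat,
                        grid = numeric(0)), "non-empty")
})

test_that("ICE localizes a planted changepoint to within one grid step", {
  cfg <- tinyCohortConfig(n = 500, seed = 64)
  cfg$thresholdEffects <- data.frame(feature = "pet01.PET",
                                     changepoint = 0.3, step = 3)
  sim <- generateCohort(cfg)
  st <- pipelineDefaults(); st$seed <- 64; st$topK <- 10
  fit <- trainAvatar(sim$cohort, st)
  expect_true("pet01.PET" %in% signatureFeatures(fit$bundle))
  hits <- 0L; tries <- 0L
  for (pat in patientIDs(sim$cohort)[1:5]) {
    cv <- iceCurve(fit$bundle, sim$cohort, pat, "pet01.PET",
                   grid = seq(-1.5, 1.5, length.out = 31))
    j <- which.max(abs(diff(cv$probability)))
    stepAt <- (cv$grid[j] + cv$grid[j + 1]) / 2
    tries <- tries + 1L
    if (abs(stepAt - 0.3) <= diff(cv$grid[1:2])) hits <- hits + 1L
  }
  expect_gte(hits, tries - 1L)
})
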