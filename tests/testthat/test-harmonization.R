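# planted two-batch radiomic matrix: batch B gets +shift SD and x scale
plantedBatches <- function(nPerBatch = 100, nFeat = 20, shift = 2,
                           scale = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * nPerBatch
  X <- matrix(rnorm(n * nFeat, sd = rep(runif(nFeat, 0.5, 2), each = n)),
              n, nFeat,
              dimnames = list(sprintf("P%03d", 1:n),
                              sprintf("f%02d", 1:nFeat)))
  batch <- rep(c("A", "B"), each = nPerBatch)
  sds <- apply(X, 2, sd)
  idx <- batch == "B"
  X[idx, ] <- sweep(sweep(X[idx, , drop = FALSE], 2, scale, `*`),
                    2, shift * sds, `+`)
  list(X = X, batch = batch)
}

test_that("single reference batch is an identity transform", {
  set.seed(3)
  X <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("P%02d", 1:20), paste0("f", 1:10)))
  m <- fitCombat(X, rep("A", 20), "A")
  out <- applyCombat(m, X, rep("A", 20))
  expect_lt(max(abs(out - X)), 1e-10)
})

test_that("planted shift and scale are removed on the affected batch", {
  pb <- plantedBatches(nPerBatch = 100, nFeat = 40, shift = 2, scale = 2,
                       seed = 5)
  m <- fitCombat(pb$X, pb$batch, "A")
  out <- applyCombat(m, pb$X, pb$batch)

  gapBefore <- abs(colMeans(pb$X[pb$batch == "B", ]) -
                     colMeans(pb$X[pb$batch == "A", ]))
  gapAfter <- abs(colMeans(out[pb$batch == "B", ]) -
                    colMeans(out[pb$batch == "A", ]))
  reduction <- 1 - gapAfter / gapBefore
  vr <- apply(out[pb$batch == "B", ], 2, var) /
    apply(out[pb$batch == "A", ], 2, var)
  expect_gte(mean(reduction >= 0.9), 0.95)
  expect_gte(mean(vr >= 0.8 & vr <= 1.25), 0.95)
  # reference rows untouched
  expect_lt(max(abs(out[pb$batch == "A", ] - pb$X[pb$batch == "A", ])),
            1e-10)
})

test_that("authored transform matches the established EB implementation", {
  skip_if_not_installed("sva")
  pb <- plantedBatches(nPerBatch = 50, nFeat = 30, shift = 1.5,
                       scale = 1.5, seed = 7)
  m <- fitCombat(pb$X, pb$batch, "A")
  mine <- applyCombat(m, pb$X, pb$batch)
  ref <- t(suppressMessages(
    sva::ComBat(t(pb$X), batch = pb$batch, ref.batch = "A")))
  expect_lt(max(abs(mine - ref)), 0.05)
  expect_gt(cor(as.vector(mine), as.vector(ref)), 0.9999)
})

test_that("degenerate inputs are flagged or rejected", {
  set.seed(9)
  X <- matrix(rnorm(120), 12, 10,
              dimnames = list(sprintf("P%02d", 1:12), paste0("f", 1:10)))
  X[, 1] <- 1  # zero variance in reference
  batch <- rep(c("A", "B"), each = 6)
  expect_warning(m <- fitCombat(X, batch, "A"), "zero-variance")
  expect_identical(m@passthrough, "f1")
  out <- applyCombat(m, X, batch)
  expect_identical(out[, "f1"], X[, "f1"])

  expect_error(fitCombat(X, c(rep("A", 11), "B"), "A"), "LOO")

  # missing cells pass through missing
  Xna <- X; Xna[2, 3] <- NA; Xna[3, ] <- NA
  mm <- suppressWarnings(fitCombat(Xna, batch, "A"))
  o <- applyCombat(mm, Xna, batch)
  expect_true(is.na(o[2, 3]))
  expect_true(all(is.na(o[3, ])))

  expect_error(applyCombat(m, X, rep("Z", 12)), "unknown batch")
})

test_that("refitting harmonized data moves it less than the first pass", {
  pb <- plantedBatches(nPerBatch = 80, nFeat = 25, shift = 2, scale = 1.5,
                       seed = 11)
  m1 <- fitCombat(pb$X, pb$batch, "A")
  h1 <- applyCombat(m1, pb$X, pb$batch)
  m2 <- fitCombat(h1, pb$batch, "A")
  h2 <- applyCombat(m2, h1, pb$batch)
  shift1 <- mean(abs(h1 - pb$X))
  shift2 <- mean(abs(h2 - h1))
  expect_lt(shift2, shift1)
})

test_that("leave-one-out fit provably excludes the test patient", {
  pb <- plantedBatches(nPerBatch = 30, nFeat = 15, shift = 1, scale = 1.3,
                       seed = 13)
  train <- pb$X[pb$batch == "A", ]
  ext <- pb$X[pb$batch == "B", ]
  m <- fitCombat(train, rep("TRAIN", nrow(train)), "TRAIN")

  id <- rownames(ext)[5]
  r1 <- harmonizeLOO(m, ext, rep("B", nrow(ext)), id)
  pert <- ext
  pert[id, ] <- pert[id, ] + 10
  r2 <- harmonizeLOO(m, pert, rep("B", nrow(ext)), id)
  expect_identical(r1$gamma, r2$gamma)
  expect_identical(r1$delta2, r2$delta2)
  expect_false(identical(r1$row, r2$row))
  expect_equal(r1$path, "loo")
})

test_that("tiny batches fall back to reference standardization", {
  set.seed(15)
  train <- matrix(rnorm(200), 20, 10,
                  dimnames = list(sprintf("T%02d", 1:20), paste0("f", 1:10)))
  m <- fitCombat(train, rep("TRAIN", 20), "TRAIN")
  ext <- matrix(rnorm(30), 3, 10,
                dimnames = list(c("E1", "E2", "E3"), paste0("f", 1:10)))
  r <- harmonizeLOO(m, ext, rep("B", 3), "E1")
  expect_equal(r$path, "fallback")
  expect_equal(r$row, ext["E1", ])
})

test_that("LOO converges to the full-batch transform as the batch grows", {
  set.seed(17)
  train <- matrix(rnorm(4000), 200, 20,
                  dimnames = list(sprintf("T%03d", 1:200), paste0("f", 1:20)))
  m <- fitCombat(train, rep("TRAIN", 200), "TRAIN")
  med <- vapply(c(10, 30, 100), function(nb) {
    ext <- matrix(rnorm(nb * 20, mean = 0.8, sd = 1.2), nb, 20,
                  dimnames = list(sprintf("E%03d", 1:nb), paste0("f", 1:20)))
    full <- applyCombat(fitCombat(rbind(train, ext),
                                  c(rep("TRAIN", 200), rep("B", nb)),
                                  "TRAIN"),
                        ext, rep("B", nb))
    looDiff <- vapply(rownames(ext), function(id) {
      r <- harmonizeLOO(m, ext, rep("B", nb), id)
      median(abs(r$row - full[id, ]))
    }, numeric(1))
    median(looDiff)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("with no batch effect LOO stays close to the full-batch transform", {
  set.seed(19)
  train <- matrix(rnorm(3000), 150, 20,
                  dimnames = list(sprintf("T%03d", 1:150), paste0("f", 1:20)))
  ext <- matrix(rnorm(2000), 100, 20,
                dimnames = list(sprintf("E%03d", 1:100), paste0("f", 1:20)))
  m <- fitCombat(train, rep("TRAIN", 150), "TRAIN")
  full <- applyCombat(fitCombat(rbind(train, ext),
                                c(rep("TRAIN", 150), rep("B", 100)),
                                "TRAIN"),
                      ext, rep("B", 100))
  sds <- apply(train, 2, sd)
  diffs <- vapply(rownames(ext), function(id) {
    r <- harmonizeLOO(m, ext, rep("B", 100), id)
    median(abs(r$row - full[id, ]) / sds)
  }, numeric(1))
  expect_lt(median(diffs), 0.05)

  # identity limit: as the planted batch effect shrinks to zero, the mean
  # absolute adjustment shrinks with it
  adj <- vapply(c(2, 0.5, 0), function(shift) {
    extS <- ext + shift
    fullS <- applyCombat(fitCombat(rbind(train, extS),
                                   c(rep("TRAIN", 150), rep("B", 100)),
                                   "TRAIN"),
                         extS, rep("B", 100))
    mean(abs(fullS - extS))
  }, numeric(1))
  expect_true(all(diff(adj) < 0))
})

test_that("harmonization model JSON round-trips", {
  pb <- plantedBatches(nPerBatch = 20, nFeat = 8, seed = 21)
  m <- fitCombat(pb$X, pb$batch, "A")
  f <- tempfile(fileext = ".json")
  writeHarmonizationModel(m, f)
  m2 <- readHarmonizationModel(f)
  expect_equal(m2@alpha, m@alpha)
  expect_equal(m2@batchEffects$B$gamma, m@batchEffects$B$gamma)
  out1 <- applyCombat(m, pb$X, pb$batch)
  out2 <- applyCombat(m2, pb$X, pb$batch)
  expect_equal(out1, out2)
})
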