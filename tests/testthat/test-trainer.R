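test_that("the joint objective weights network losses against the clustering term", {
  expect_equal(totalLoss(1, 2, 7, lambda = 1), 3)        # Luce vanishes
  expect_equal(totalLoss(1, 2, 3, lambda = 0.6), 3.0)
  expect_equal(totalLoss(0, 0, 5, lambda = 0.2), 4)
  expect_error(totalLoss(1, Inf, 1, 0.5), class = "dgclValidationError")
  expect_error(totalLoss(1, 1, 1, 0), class = "dgclValidationError")
})

test_that("the learning-rate schedule is constant then step-decayed", {
  cfg <- trainConfig()
  expect_equal(learningRate(0, cfg), 0.01)
  expect_equal(learningRate(29, cfg), 0.01)
  expect_equal(learningRate(49, cfg), 0.01)
  expect_equal(learningRate(50, cfg), 0.001)
  expect_equal(learningRate(70, cfg), 1e-4)
  expect_error(learningRate(-1, cfg), class = "dgclValidationError")
})

test_that("churn ratio counts label disagreements", {
  expect_equal(churnRatio(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(churnRatio(c(1, 2), c(2, 1)), 1)
  expect_equal(churnRatio(c(0, 1, 1, 0), c(0, 1, 0, 0)), 0.25)
  expect_error(churnRatio(1:3, 1:4), class = "dgclValidationError")
})

test_that("train configuration enforces its invariants", {
  expect_error(trainConfig(lambda = 1.5), class = "dgclConfigError")
  expect_error(trainConfig(momentum = 0), class = "dgclConfigError")
  expect_error(trainConfig(knnK = 64, batchSize = 64),
               class = "dgclConfigError")
  expect_error(trainConfig(nClusters = 1), class = "dgclConfigError")
  expect_error(trainConfig(clusterAlgo = "dbscan"), class = "dgclConfigError")
})

test_that("a training step updates the batch rows and reports all losses", {
  ds <- tinyBlobs(n = 24, size = 16)
  m <- tinyModel()
  fused <- dgclust:::fusedFeaturesAll(m, ds@images, 12L, 4L)
  mem <- initMemory(fused, 3, m = 0.5, seed = 1)
  cfg <- trainConfig(nClusters = 3, batchSize = 12, knnK = 4, epochs = 1,
                     seed = 1)
  idx <- 1:12
  before <- mem$ms@features
  set.seed(2)
  st <- trainStep(m, mem$ms, mem$mc, ds@images[, , , idx, drop = FALSE],
                  idx, cfg, lr = 0.01)
  expect_named(st$losses, c("luc", "lug", "luce", "total"))
  expect_true(all(is.finite(st$losses)))
  expect_true(all(st$losses[c("luc", "lug", "luce")] >= 0))
  expect_equal(st$losses[["total"]],
               totalLoss(st$losses[["luc"]], st$losses[["lug"]],
                         st$losses[["luce"]], cfg@lambda))
  # batch rows moved, the rest untouched, all unit norm
  expect_false(isTRUE(all.equal(st$ms@features[idx, ], before[idx, ])))
  expect_identical(st$ms@features[13:24, ], before[13:24, ])
  expect_true(all(abs(sqrt(rowSums(st$ms@features^2)) - 1) < 1e-6))
  expect_error(trainStep(m, mem$ms, mem$mc, ds@images[, , , idx, drop = FALSE],
                         20:31, cfg, lr = 0.01), class = "dgclStateError")
})

test_that("training is deterministic given the seed and logs per-epoch records", {
  ds <- tinyBlobs(n = 30, size = 16)
  cfg <- trainConfig(nClusters = 3, batchSize = 15, knnK = 3, epochs = 3,
                     seed = 5)
  f1 <- dgclFit(ds, cfg, tinyEncoderSpec())
  f2 <- dgclFit(ds, cfg, tinyEncoderSpec())
  expect_equal(churnLog(f1), churnLog(f2))
  expect_identical(f1@sampleMemory@features, f2@sampleMemory@features)
  cl <- churnLog(f1)
  expect_equal(nrow(cl), 3)
  expect_true(all(c("epoch", "luc", "lug", "luce", "total", "churn",
                    "msAccuracy") %in% names(cl)))
  expect_true(all(cl$churn >= 0 & cl$churn <= 1))
  expect_equal(cl$reassigned / 30, cl$churn)
})

test_that("a zero-epoch fit returns the initialised state with an empty log", {
  ds <- tinyBlobs(n = 18, size = 16)
  cfg <- trainConfig(nClusters = 3, batchSize = 9, knnK = 3, epochs = 0,
                     seed = 2)
  fit <- dgclFit(ds, cfg, tinyEncoderSpec())
  expect_s4_class(fit, "DgclFit")
  expect_equal(nrow(churnLog(fit)), 0)
  expect_true(all(abs(sqrt(rowSums(fit@sampleMemory@features^2)) - 1) < 1e-6))
})

test_that("the graph-ablated (DCCL) pipeline honours every loss contract", {
  ds <- tinyBlobs(n = 24, size = 16)
  cfg <- trainConfig(nClusters = 3, batchSize = 12, knnK = 4, epochs = 2,
                     seed = 3, dcclMode = TRUE)
  fit <- dgclFit(ds, cfg, tinyEncoderSpec())
  # fused space is the Euclidean feature alone
  expect_equal(ncol(fit@sampleMemory@features), 16L)
  cl <- churnLog(fit)
  expect_true(all(is.finite(unlist(cl[, c("luc", "lug", "luce", "total")]))))
  expect_equal(cl$total, 0.6 * (cl$luc + cl$lug) + 0.4 * cl$luce,
               tolerance = 1e-12)
})

test_that("different seeds give different trajectories but keep invariants", {
  ds <- tinyBlobs(n = 24, size = 16)
  mkfit <- function(s) dgclFit(ds, trainConfig(nClusters = 3, batchSize = 12,
                                               knnK = 3, epochs = 2, seed = s),
                               tinyEncoderSpec())
  fa <- mkfit(1)
  fb <- mkfit(2)
  expect_false(identical(fa@sampleMemory@features, fb@sampleMemory@features))
  for (f in list(fa, fb)) {
    expect_true(all(abs(sqrt(rowSums(f@sampleMemory@features^2)) - 1) < 1e-6))
  }
})

test_that("checkpoints round-trip through a directory", {
  ds <- tinyBlobs(n = 18, size = 16)
  cfg <- trainConfig(nClusters = 3, batchSize = 9, knnK = 3, epochs = 2,
                     seed = 4)
  fit <- dgclFit(ds, cfg, tinyEncoderSpec())
  dir <- withr::local_tempdir()
  saveCheckpoint(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("model.rds", "config.yaml",
                                               "churn_log.jsonl",
                                               "pseudo_labels.csv")))))
  back <- loadCheckpoint(dir)
  expect_equal(churnLog(back), churnLog(fit))
  r1 <- evaluateModel(fit, ds)
  r2 <- evaluateModel(back, ds)
  expect_equal(r1@accuracy, r2@accuracy)
  expect_error(loadCheckpoint(file.path(dir, "nope")), class = "dgclIOError")
})
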