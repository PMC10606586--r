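test_that("matched accuracy is 1 for any relabelling of the truth", {
  truth <- withr::with_seed(30, sample(0:3, 40, replace = TRUE))
  perm <- c(2L, 0L, 3L, 1L)
  pred <- perm[truth + 1L]
  ha <- hungarianAccuracy(pred, truth)
  expect_equal(ha$accuracy, 1)
  # the recovered mapping inverts the relabelling
  expect_equal(ha$mapping[perm + 1L], 0:3)
})

test_that("matched accuracy equals the brute-force best over all bijections", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      nC <- sample(2:5, 1)
      nL <- sample(2:5, 1)
      n <- sample(10:60, 1)
      pred <- sample(seq_len(nC) * 10L, n, replace = TRUE)
      labels <- sample(seq_len(nL), n, replace = TRUE)
      expect_equal(hungarianAccuracy(pred, labels)$accuracy,
                   bruteBestMatch(pred, labels))
    }
  })
})

test_that("matched accuracy is invariant to cluster-id permutations and degenerate inputs behave", {
  pred <- withr::with_seed(32, sample(0:2, 30, replace = TRUE))
  labels <- withr::with_seed(33, sample(0:2, 30, replace = TRUE))
  acc <- hungarianAccuracy(pred, labels)$accuracy
  perm <- c(1L, 2L, 0L)
  expect_equal(hungarianAccuracy(perm[pred + 1L], labels)$accuracy, acc)
  # a constant prediction scores the modal class share
  expect_equal(hungarianAccuracy(rep(7L, 30), labels)$accuracy,
               max(table(labels)) / 30)
  expect_error(hungarianAccuracy(integer(0), integer(0)),
               class = "dgclValidationError")
  expect_error(hungarianAccuracy(1:3, 1:4), class = "dgclValidationError")
})

test_that("NMI and ARI hit their analytic endpoints", {
  a <- rep(0:2, each = 10)
  expect_equal(nmiScore(a, a), 1)
  expect_equal(ariScore(a, a), 1)
  # relabelling leaves both unchanged
  b <- c(2L, 0L, 1L)[a + 1L]
  expect_equal(nmiScore(a, b), 1)
  expect_equal(ariScore(a, b), 1)
  # a constant partition carries no information
  expect_equal(nmiScore(a, rep(1L, 30)), 0)
  expect_equal(ariScore(a, rep(1L, 30)), 0)
  expect_error(nmiScore(1:3, 1:4), class = "dgclValidationError")
  expect_error(ariScore(1:3, 1:4), class = "dgclValidationError")
})

test_that("NMI and ARI agree with reference implementations", {
  skip_if_not_installed("mclust")
  withr::with_seed(34, {
    for (rep in 1:15) {
      n <- sample(20:80, 1)
      a <- sample(0:sample(1:4, 1), n, replace = TRUE)
      b <- sample(0:sample(1:4, 1), n, replace = TRUE)
      expect_equal(ariScore(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
      # NMI oracle from first principles on the joint table
      tab <- table(a, b) / n
      pa <- rowSums(tab); pb <- colSums(tab)
      nz <- tab > 0
      mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
      hx <- -sum(pa[pa > 0] * log(pa[pa > 0]))
      hy <- -sum(pb[pb > 0] * log(pb[pb > 0]))
      expect_equal(nmiScore(a, b), max(0, min(1, mi / ((hx + hy) / 2))),
                   tolerance = 1e-12)
    }
  })
})

test_that("binary metrics match hand-tallied confusion counts", {
  pred <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  true <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)  # TP 3, FN 1, FP 2, TN 4
  bm <- binaryMetrics(pred, true)
  expect_equal(bm$sensitivity, 3 / 4)
  expect_equal(bm$specificity, 4 / 6)
  expect_equal(bm$accuracy, 7 / 10)
  # accuracy = prevalence * sensitivity + (1 - prevalence) * specificity
  prev <- mean(true)
  expect_equal(bm$accuracy, prev * bm$sensitivity + (1 - prev) * bm$specificity)
  # single-class truth: undefined rate is NA, the other is still scored
  one <- binaryMetrics(c(1, 0, 1), c(1, 1, 1))
  expect_equal(one$sensitivity, 2 / 3)
  expect_true(is.na(one$specificity))
  expect_error(binaryMetrics(c(0, 2), c(0, 1)), class = "dgclValidationError")
})

test_that("rank AUC matches the pairwise-comparison definition", {
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_equal(rocAuc(c(0.5, 0.5, 0.5), c(0, 1, 0)), 0.5)  # all ties
  expect_true(is.na(rocAuc(c(0.2, 0.4), c(1, 1))))
  withr::with_seed(35, {
    for (rep in 1:15) {
      n <- sample(10:50, 1)
      s <- round(rnorm(n), 1)  # coarse rounding forces ties
      y <- rbinom(n, 1, 0.4)
      if (sum(y) == 0 || sum(y) == n) y[1:2] <- c(0, 1)
      pos <- s[y == 1]; neg <- s[y == 0]
      cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
      expect_equal(rocAuc(s, y), mean(cmp), tolerance = 1e-12)
      # invariance under a strictly monotone transform of the scores
      expect_equal(rocAuc(exp(s), y), rocAuc(s, y), tolerance = 1e-12)
    }
  })
})

test_that("rank AUC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  withr::with_seed(36, {
    for (rep in 1:5) {
      s <- rnorm(40)
      y <- rbinom(40, 1, 0.5)
      if (sum(y) == 0 || sum(y) == 40) y[1:2] <- c(0, 1)
      ref <- suppressMessages(as.numeric(pROC::auc(y, s,
                                                   direction = "<",
                                                   quiet = TRUE)))
      expect_equal(rocAuc(s, y), ref, tolerance = 1e-12)
    }
  })
})

test_that("model evaluation is deterministic and degrades gracefully without labels", {
  ds <- tinyBlobs(n = 24, size = 16)
  cfg <- trainConfig(nClusters = 3, batchSize = 12, knnK = 3, epochs = 2,
                     seed = 6)
  fit <- dgclFit(ds, cfg, tinyEncoderSpec())
  r1 <- evaluateModel(fit, ds)
  r2 <- evaluateModel(fit, ds)
  expect_s4_class(r1, "MetricsReport")
  expect_equal(r1@accuracy, r2@accuracy)
  expect_equal(r1@auc, r2@auc)
  expect_gte(r1@accuracy, 1 / 3)  # never below the constant-prediction floor
  expect_equal(length(r1@clusterToClassMap), 3L)
  # unlabeled evaluation: all scored metrics NA, with a note
  unlab <- labeledImageSet(ds@images, rep(NA_integer_, 24))
  ru <- evaluateModel(fit, unlab)
  expect_true(is.na(ru@accuracy) && is.na(ru@auc) && is.na(ru@nmi))
  expect_true(any(grepl("labels absent", ru@notes)))
})
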