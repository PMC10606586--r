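test_that("k-means recovers the exhaustively optimal 2-partition", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  km <- kmeansClust(x, 2, seed = 1)
  expect_equal(sort(km$centroids[, 1]), c(0.05, 10.05))
  expect_equal(km$inertia, 0.01)
  expect_equal(km$labels[1], km$labels[2])
  expect_equal(km$labels[3], km$labels[4])
  expect_false(km$labels[1] == km$labels[3])

  # C = N: every point its own centroid, zero inertia
  kmN <- kmeansClust(x, 4, seed = 2)
  expect_equal(kmN$inertia, 0)
  expect_equal(sort(kmN$centroids[, 1]), c(0, 0.1, 10, 10.1))

  expect_error(kmeansClust(x, 5), class = "dgclConfigError")
})

test_that("k-means inertia is competitive with the reference implementation", {
  for (s in 1:10) {
    x <- withr::with_seed(s, {
      centers <- matrix(rnorm(3 * 4, sd = 4), 3, 4)
      centers[rep(1:3, each = 30), ] + matrix(rnorm(90 * 4, sd = 0.5), 90, 4)
    })
    ours <- kmeansClust(x, 3, seed = s)$inertia
    ref <- withr::with_seed(s, stats::kmeans(x, 3, nstart = 10,
                                             iter.max = 100)$tot.withinss)
    expect_lte(ours, 1.01 * ref)
  }
})

test_that("memory initialisation stores unit-norm features at a k-means fixed point", {
  feats <- withr::with_seed(3, matrix(rnorm(40 * 6), 40, 6) +
                              2 * matrix(rnorm(8 * 6), 8, 6)[rep(1:8, 5), ])
  mem1 <- initMemory(feats, 4, m = 0.5, seed = 9)
  mem2 <- initMemory(feats, 4, m = 0.5, seed = 9)
  expect_identical(mem1$ms@features, mem2$ms@features)
  expect_identical(mem1$ms@labels, mem2$ms@labels)
  expect_equal(sqrt(rowSums(mem1$ms@features^2)), rep(1, 40),
               tolerance = 1e-9)
  # at the fixed point each centroid is the mean of its members
  refreshed <- refreshCentroids(mem1$ms, previous = mem1$mc)
  expect_equal(refreshed@centroids, mem1$mc@centroids, tolerance = 1e-9)
})

test_that("momentum updates mix, renormalise and leave other rows untouched", {
  ms <- new("SampleMemory", features = rbind(c(1, 0), c(0, 1), c(1, 0)),
            labels = c(0L, 1L, 0L), momentum = 0.5)
  # hand-worked case: stored (1,0), new (0,2), m = 0.5
  out <- momentumUpdate(ms, 1L, matrix(c(0, 2), 1, 2), m = 0.5)
  expect_equal(out@features[1, ], c(sqrt(2) / 2, sqrt(2) / 2))
  expect_equal(out@features[2:3, ], ms@features[2:3, ])
  # m = 1: exact replacement by the normalised new feature
  rep1 <- momentumUpdate(ms, 2L, matrix(c(3, 4), 1, 2), m = 1)
  expect_equal(rep1@features[2, ], c(0.6, 0.8))
  # m -> 0: stored row (numerically) unchanged
  rep0 <- momentumUpdate(ms, 1L, matrix(c(0, 1), 1, 2), m = 1e-12)
  expect_equal(rep0@features[1, ], c(1, 0), tolerance = 1e-9)
  expect_error(momentumUpdate(ms, 1L, matrix(0, 1, 2)),
               class = "dgclValidationError")
  expect_error(momentumUpdate(ms, 9L, matrix(1, 1, 2)),
               class = "dgclStateError")
})

test_that("repeated random momentum updates preserve unit norms", {
  ms <- new("SampleMemory", features = randomUnitRows(50, 8, 1),
            labels = rep(0:4, 10), momentum = 0.5)
  withr::with_seed(2, {
    for (i in 1:200) {
      idx <- sample(50, 5)
      ms <- momentumUpdate(ms, idx, matrix(rnorm(5 * 8), 5, 8))
    }
  })
  expect_true(all(abs(sqrt(rowSums(ms@features^2)) - 1) < 1e-6))
})

test_that("nearest-centroid assignment matches brute force with low-index ties", {
  cen <- rbind(c(0, 0), c(2, 0), c(4, 0))
  expect_equal(assignPseudoLabels(rbind(c(4, 0)), cen), 2L)
  expect_equal(assignPseudoLabels(rbind(c(1, 0)), cen), 0L)  # midpoint tie
  expect_equal(assignPseudoLabels(rbind(c(3, 0)), cen), 1L)

  feats <- withr::with_seed(12, matrix(rnorm(100 * 4), 100, 4))
  cen4 <- withr::with_seed(13, matrix(rnorm(5 * 4), 5, 4))
  got <- assignPseudoLabels(feats, cen4)
  brute <- apply(feats, 1, function(f) {
    which.min(colSums((t(cen4) - f)^2)) - 1L
  })
  expect_identical(got, as.integer(brute))
  expect_error(assignPseudoLabels(matrix(NaN, 1, 4), cen4),
               class = "dgclValidationError")
})

test_that("centroid refresh is a per-cluster mean with continuity for empties", {
  ms <- new("SampleMemory", features = rbind(c(1, 0), c(0, 1)),
            labels = c(0L, 0L), momentum = 0.5)
  prev <- new("CentroidMemory", centroids = rbind(c(1, 0), c(0.3, 0.7)),
              refreshPeriod = 10L, unit = "epoch")
  out <- refreshCentroids(ms, previous = prev)
  expect_equal(out@centroids[1, ], c(0.5, 0.5))
  expect_equal(out@centroids[2, ], c(0.3, 0.7))  # empty cluster kept

  feats <- randomUnitRows(60, 5, 14)
  labs <- withr::with_seed(15, sample(0:3, 60, replace = TRUE))
  msr <- new("SampleMemory", features = feats, labels = labs, momentum = 0.5)
  got <- refreshCentroids(msr, C = 4)
  oracle <- t(sapply(0:3, function(c0) colMeans(feats[labs == c0, , drop = FALSE])))
  expect_lt(max(abs(got@centroids - oracle)), 1e-10)
})

test_that("class weights are inverse counts normalised to sum C", {
  expect_equal(classWeights(c(0L, 0L, 1L, 1L), 2), c(1, 1))
  expect_equal(classWeights(c(0L, 1L, 1L, 1L, 1L), 2), c(1.6, 0.4))
  withr::with_seed(16, {
    for (i in 1:10) {
      C <- sample(2:6, 1)
      labs <- sample(0:(C - 1), 40, replace = TRUE)
      w <- classWeights(labs, C)
      expect_equal(sum(w), C)
      # permuting class identities permutes the weights identically
      perm <- sample(C) - 1L
      wp <- classWeights(perm[labs + 1L], C)
      expect_equal(wp[perm + 1L], w)
    }
  })
  expect_error(classWeights(c(0L, 5L), 3), class = "dgclValidationError")
})

test_that("assign + refresh iterated on static features is Lloyd's algorithm", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      feats <- randomUnitRows(80, 6, 170 + rep)
      km0 <- dgclust:::kmeansSingle(feats, 3, seed = 300 + rep, maxIter = 1)
      # start both from the same one-step state and iterate
      ms <- new("SampleMemory", features = feats, labels = km0$labels,
                momentum = 0.5)
      mc <- new("CentroidMemory", centroids = km0$centroids,
                refreshPeriod = 10L, unit = "epoch")
      inertias <- numeric(0)
      for (it in 1:100) {
        mc <- refreshCentroids(ms, previous = mc)
        newLab <- assignPseudoLabels(feats, mc)
        d2 <- dgclust:::sqDistToCentroids(feats, mc@centroids)
        inertias <- c(inertias, sum(d2[cbind(1:80, newLab + 1L)]))
        if (all(newLab == ms@labels)) break
        ms@labels <- newLab
      }
      expect_true(all(diff(inertias) <= 1e-10))
      ref <- dgclust:::kmeansSingle(feats, 3, seed = 300 + rep, maxIter = 100)
      expect_identical(ms@labels, ref$labels)
    }
  })
})

test_that("fuzzy c-means satisfies membership, monotonicity and the crisp limit", {
  feats <- withr::with_seed(18, {
    ctr <- matrix(c(0, 0, 6, 0, 0, 6), 3, 2, byrow = TRUE)
    ctr[rep(1:3, each = 25), ] + matrix(rnorm(75 * 2, sd = 0.3), 75, 2)
  })
  fcm <- fuzzyCMeans(feats, 3, fuzzifier = 2, seed = 4)
  expect_equal(rowSums(fcm$membership), rep(1, 75), tolerance = 1e-9)
  expect_true(all(diff(fcm$objective) <= 1e-8 * max(1, fcm$objective[1])))
  # near-crisp fuzzifier recovers the k-means partition on separated blobs
  crisp <- fuzzyCMeans(feats, 3, fuzzifier = 1.05, seed = 4)
  km <- kmeansClust(feats, 3, seed = 4)
  expect_equal(hungarianAccuracy(crisp$labels, km$labels)$accuracy, 1)
  # objective non-increasing on unstructured data too
  noise <- withr::with_seed(19, matrix(rnorm(60 * 3), 60, 3))
  obj <- fuzzyCMeans(noise, 4, fuzzifier = 2, seed = 5)$objective
  expect_true(all(diff(obj) <= 1e-8 * max(1, obj[1])))
  # a sample sitting exactly on a centroid receives full membership
  exact <- fuzzyCMeans(rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5)), 2,
                       fuzzifier = 2, seed = 6)
  expect_true(all(apply(exact$membership, 1, max) > 1 - 1e-9))
  expect_error(fuzzyCMeans(feats, 3, fuzzifier = 1), class = "dgclConfigError")
})

test_that("fuzzy c-means agrees with the e1071 reference on its objective", {
  skip_if_not_installed("e1071")
  feats <- withr::with_seed(20, {
    ctr <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
    ctr[rep(1:2, each = 30), ] + matrix(rnorm(60 * 2, sd = 0.4), 60, 2)
  })
  ours <- fuzzyCMeans(feats, 2, fuzzifier = 2, seed = 7)
  ref <- withr::with_seed(7, e1071::cmeans(feats, 2, m = 2, iter.max = 200))
  # recompute the reference objective sum_i sum_c u_ic^m * d_ic^2 from the
  # fitted membership and centres (e1071 reports it divided by n)
  d2 <- t(apply(feats, 1, function(f) colSums((t(ref$centers) - f)^2)))
  refObj <- sum(ref$membership^2 * d2)
  expect_lte(min(ours$objective), 1.01 * refObj)
  # and the converged centres agree up to cluster order
  ourC <- ours$centroids[order(ours$centroids[, 1]), ]
  refC <- ref$centers[order(ref$centers[, 1]), ]
  dimnames(refC) <- NULL
  expect_equal(ourC, refC, tolerance = 1e-4)
})
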