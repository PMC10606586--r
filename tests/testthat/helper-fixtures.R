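# Shared fixtures: tiny models and datasets built in code.

tinyEncoderSpec <- function(dropoutRate = 0.5) {
  encoderSpec(featureDim = 16L, hiddenDim = 16L, graphDim = 8L,
              channels = c(4L, 6L, 8L), dropoutRate = dropoutRate)
}

tinyModel <- function(C = 3L, size = 16L, dccl = FALSE, dropoutRate = 0.5) {
  withr::with_seed(99, buildModel(c(size, size, 1L), C,
                                  tinyEncoderSpec(dropoutRate), dccl))
}

tinyImages <- function(n = 8L, size = 16L, seed = 5L) {
  withr::with_seed(seed, array(runif(size * size * n), c(size, size, 1L, n)))
}

tinyBlobs <- function(n = 60L, C = 3L, size = 16L, separation = 5,
                      noiseSd = 0.05, seed = 7L) {
  makeBlobImages(syntheticSpec(nSamples = n, nClusters = C, imageSize = size,
                               separation = separation, noiseSd = noiseSd,
                               seed = seed))
}

# brute-force weighted cross-entropy of a softmax over logits (per-sample
# loop; independent of the package's vectorised path)
ceOracle <- function(logits, labels, w) {
  tot <- 0
  for (i in seq_len(nrow(logits))) {
    z <- logits[i, ]
    p <- exp(z) / sum(exp(z))
    tot <- tot + -w[labels[i] + 1] * log(p[labels[i] + 1])
  }
  tot / nrow(logits)
}

# unit-norm random rows
randomUnitRows <- function(n, d, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), n, d)
    x / sqrt(rowSums(x^2))
  })
}

# all permutations of a small vector (base R, no extra packages)
allPerms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in allPerms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# brute-force best matched accuracy over all cluster-to-class bijections
bruteBestMatch <- function(pred, labels) {
  pu <- sort(unique(pred))
  lu <- sort(unique(labels))
  best <- 0
  if (length(pu) <= length(lu)) {
    for (p in allPerms(seq_along(lu))) {
      sel <- p[seq_len(length(pu))]
      best <- max(best, sum(lu[sel][match(pred, pu)] == labels))
    }
  } else {
    for (p in allPerms(seq_along(pu))) {
      cls <- rep(NA_integer_, length(pu))
      cls[p[seq_len(length(lu))]] <- lu
      m <- cls[match(pred, pu)]
      best <- max(best, sum(!is.na(m) & m == labels))
    }
  }
  best / length(labels)
}
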