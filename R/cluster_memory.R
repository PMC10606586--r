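# Dynamic memory stores: sample memory Ms (unit-norm fused features +
# pseudo-labels, momentum-mixed online) and centroid memory Mc (per-cluster
# means on a refresh schedule), k-means initialisation with k-means++
# seeding, nearest-centroid relabelling, inverse-cluster-size class weights,
# and a fuzzy c-means variant.

# squared Euclidean distances between rows of x (n x d) and rows of cen (C x d)
sqDistToCentroids <- function(x, cen) {
  d2 <- outer(rowSums(x * x), rowSums(cen * cen), "+") - 2 * tcrossprod(x, cen)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding (deterministic under the current RNG state)
kmeansPlusPlusInit <- function(x, C) {
  n <- nrow(x)
  centers <- matrix(0, C, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- sqDistToCentroids(x, centers[1, , drop = FALSE])[, 1]
  for (c0 in seq_len(C - 1)) {
    tot <- sum(d2)
    i <- if (tot <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2 / tot)
    centers[c0 + 1, ] <- x[i, ]
    d2 <- pmin(d2, sqDistToCentroids(x, x[i, , drop = FALSE])[, 1])
  }
  centers
}

#' K-means clustering (k-means++ seeding, Lloyd iterations)
#'
#' Deterministic given `seed`. Inertia (within-cluster sum of squared
#' distances) is non-increasing across iterations; empty clusters keep their
#' previous centroid.
#'
#' @param features n x d numeric matrix (n >= C).
#' @param C number of clusters.
#' @param seed integer RNG seed for the seeding step.
#' @param maxIter maximum Lloyd iterations.
#' @param nstart number of k-means++ restarts; the solution with the lowest
#'   inertia is kept.
#' @return list with `labels` (0-based), `centroids` (C x d), `inertia`,
#'   and `iterations`.
#' @export
kmeansClust <- function(features, C, seed = 1L, maxIter = 100L, nstart = 5L) {
  best <- NULL
  for (s in seq_len(nstart)) {
    cand <- kmeansSingle(features, C, seed + (s - 1L) * 7919L, maxIter)
    if (is.null(best) || cand$inertia < best$inertia) best <- cand
  }
  best
}

kmeansSingle <- function(features, C, seed, maxIter) {
  features <- as.matrix(features)
  if (nrow(features) < C) {
    configError(sprintf("need at least C=%d samples, got %d", C,
                        nrow(features)))
  }
  assertFinite(features, "features")
  centers <- withSeed(seed, kmeansPlusPlusInit(features, C))
  labels <- integer(nrow(features))
  for (it in seq_len(maxIter)) {
    d2 <- sqDistToCentroids(features, centers)
    newLabels <- max.col(-d2, ties.method = "first") - 1L
    if (it > 1 && all(newLabels == labels)) {
      labels <- newLabels
      break
    }
    labels <- newLabels
    for (c0 in seq_len(C) - 1L) {
      memb <- labels == c0
      if (any(memb)) {
        centers[c0 + 1L, ] <- colMeans(features[memb, , drop = FALSE])
      }
    }
  }
  d2 <- sqDistToCentroids(features, centers)
  labels <- max.col(-d2, ties.method = "first") - 1L
  inertia <- sum(d2[cbind(seq_len(nrow(features)), labels + 1L)])
  list(labels = labels, centroids = centers, inertia = inertia,
       iterations = it)
}

#' Initialise the dynamic memory stores
#'
#' L2-normalises the fused features, clusters them (k-means by default, fuzzy
#' c-means hardened by argmax membership as the variant), and returns the
#' sample memory (normalised features + initial pseudo-labels) and the
#' centroid memory (cluster centroids).
#'
#' @param fusedFeatures N x d matrix of fused representations.
#' @param C number of clusters.
#' @param m memory momentum in (0, 1].
#' @param seed RNG seed for the clustering initialisation.
#' @param clusterAlgo `"kmeans"` or `"fcm"`.
#' @param fuzzifier FCM fuzzifier (> 1), used for `"fcm"`.
#' @param refreshPeriod,refreshUnit centroid refresh schedule recorded in the
#'   centroid memory.
#' @return list with elements `ms` ([SampleMemory-class]) and `mc`
#'   ([CentroidMemory-class]).
#' @export
initMemory <- function(fusedFeatures, C, m = 0.5, seed = 1L,
                       clusterAlgo = c("kmeans", "fcm"), fuzzifier = 2,
                       refreshPeriod = 10L, refreshUnit = "epoch") {
  clusterAlgo <- match.arg(clusterAlgo)
  assertFinite(fusedFeatures, "fused features")
  feats <- l2NormalizeRows(as.matrix(fusedFeatures))
  if (clusterAlgo == "kmeans") {
    km <- kmeansClust(feats, C, seed = seed)
    labels <- km$labels
    cen <- km$centroids
  } else {
    fcm <- fuzzyCMeans(feats, C, fuzzifier = fuzzifier, seed = seed)
    labels <- fcm$labels
    # store crisp per-cluster means of the hardened labels, not the fuzzy
    # centroids: the centroid memory's refresh rule is the crisp mean, and
    # fuzzy centroids (shrunk toward the global mean) would break the
    # fixed-point property mc == refreshCentroids(ms) at initialisation
    cen <- fcm$centroids
    for (c0 in seq_len(C)) {
      rows <- labels == (c0 - 1L)
      if (any(rows)) cen[c0, ] <- colMeans(feats[rows, , drop = FALSE])
    }
  }
  ms <- new("SampleMemory", features = feats, labels = as.integer(labels),
            momentum = as.numeric(m))
  mc <- new("CentroidMemory", centroids = cen,
            refreshPeriod = as.integer(refreshPeriod),
            unit = refreshUnit)
  list(ms = ms, mc = mc)
}

#' Momentum update of the sample memory
#'
#' For each index i: the incoming feature is L2-normalised, mixed as
#' `m * new + (1 - m) * stored`, and the result re-normalised to unit
#' length. Rows not indexed are untouched. `m = 1` replaces the stored row
#' with the normalised new feature.
#'
#' @param ms a [SampleMemory-class].
#' @param indices 1-based row indices to update.
#' @param newFeatures matrix of incoming features, one row per index.
#' @param m momentum coefficient in (0, 1]; defaults to the memory's own.
#' @return the updated [SampleMemory-class].
#' @export
momentumUpdate <- function(ms, indices, newFeatures, m = ms@momentum) {
  indices <- as.integer(indices)
  if (any(indices < 1L) || any(indices > nrow(ms@features))) {
    stateError("batch indices outside the sample memory")
  }
  newFeatures <- as.matrix(newFeatures)
  if (nrow(newFeatures) != length(indices)) {
    validationError("one new feature row per index required")
  }
  if (m <= 0 || m > 1) validationError("momentum m must lie in (0, 1]")
  newn <- l2NormalizeRows(newFeatures, "new features")
  mixed <- m * newn + (1 - m) * ms@features[indices, , drop = FALSE]
  feats <- ms@features
  feats[indices, ] <- l2NormalizeRows(mixed, "mixed features")
  new("SampleMemory", features = feats, labels = ms@labels,
      momentum = ms@momentum)
}

#' Nearest-centroid pseudo-label assignment
#'
#' Label = argmin over centroids of the squared Euclidean distance; ties go
#' to the lowest centroid index.
#'
#' @param features n x d matrix.
#' @param mc a [CentroidMemory-class] or a C x d centroid matrix.
#' @return 0-based integer labels.
#' @export
assignPseudoLabels <- function(features, mc) {
  cen <- if (methods::is(mc, "CentroidMemory")) mc@centroids else as.matrix(mc)
  features <- as.matrix(features)
  if (ncol(features) != ncol(cen)) {
    validationError("feature width must equal centroid width")
  }
  assertFinite(features, "features")
  d2 <- sqDistToCentroids(features, cen)
  max.col(-d2, ties.method = "first") - 1L
}

#' Refresh the centroid memory from the sample memory
#'
#' Centroid c becomes the mean of the stored features currently
#' pseudo-labelled c. A cluster with no members keeps its previous centroid
#' row (continuity of the dynamic store), which requires `previous`.
#'
#' @param ms a [SampleMemory-class].
#' @param C number of clusters (defaults to the previous memory's).
#' @param previous the current [CentroidMemory-class] (source of empty-cluster
#'   rows and of the refresh schedule).
#' @return a new [CentroidMemory-class].
#' @export
refreshCentroids <- function(ms, C = NULL, previous = NULL) {
  if (is.null(C)) {
    if (is.null(previous)) configError("provide C or a previous centroid memory")
    C <- nrow(previous@centroids)
  }
  cen <- matrix(NA_real_, C, ncol(ms@features))
  for (c0 in seq_len(C) - 1L) {
    memb <- ms@labels == c0
    if (any(memb)) {
      cen[c0 + 1L, ] <- colMeans(ms@features[memb, , drop = FALSE])
    } else if (!is.null(previous)) {
      cen[c0 + 1L, ] <- previous@centroids[c0 + 1L, ]
    } else {
      validationError(sprintf(
        "cluster %d is empty and no previous centroid memory was given", c0))
    }
  }
  new("CentroidMemory", centroids = cen,
      refreshPeriod = if (is.null(previous)) 10L else previous@refreshPeriod,
      unit = if (is.null(previous)) "epoch" else previous@unit)
}

#' Inverse-cluster-size class weights
#'
#' Weight of class c is proportional to `1 / max(count_c, 1)`, normalised so
#' the weights sum to C. Balances the pseudo-label cross-entropy against
#' uneven cluster sizes.
#'
#' @param labels 0-based integer labels in `[0, C)`.
#' @param C number of classes.
#' @return numeric vector of length C summing to C.
#' @examples
#' classWeights(c(0L, 1L, 1L, 1L, 1L), 2)  # 1.6 0.4
#' @export
classWeights <- function(labels, C) {
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= C)) {
    validationError(sprintf("labels must lie in [0, %d)", C))
  }
  counts <- tabulate(labels + 1L, nbins = C)
  raw <- 1 / pmax(counts, 1)
  C * raw / sum(raw)
}

#' Fuzzy c-means clustering
#'
#' Standard alternating updates: memberships from inverse-distance ratios
#' with exponent `2 / (fuzzifier - 1)`, centroids as membership^fuzzifier
#' weighted means. A sample at zero distance from a centroid receives full
#' membership in (the first) such centroid. The objective
#' `sum(u^fuzzifier * d^2)` is recorded once per iteration and is
#' non-increasing.
#'
#' @param features n x d matrix.
#' @param C number of clusters.
#' @param fuzzifier fuzzifier (> 1), default 2.
#' @param seed RNG seed (k-means++ centroid seeding).
#' @param maxIter maximum iterations.
#' @param tol stop when the objective improves by less than `tol`.
#' @return list with `membership` (n x C, rows sum to 1), `centroids`,
#'   `labels` (argmax membership, 0-based), `objective` (per-iteration
#'   values).
#' @export
fuzzyCMeans <- function(features, C, fuzzifier = 2, seed = 1L,
                        maxIter = 100L, tol = 1e-8) {
  if (fuzzifier <= 1) configError("fuzzifier must be > 1")
  features <- as.matrix(features)
  if (nrow(features) < C) {
    configError(sprintf("need at least C=%d samples, got %d", C,
                        nrow(features)))
  }
  assertFinite(features, "features")
  cen <- withSeed(seed, kmeansPlusPlusInit(features, C))
  expo <- 2 / (fuzzifier - 1)
  objective <- numeric(0)
  U <- NULL
  for (it in seq_len(maxIter)) {
    d2 <- sqDistToCentroids(features, cen)
    U <- membershipFromDistances(d2, expo)
    Um <- U^fuzzifier
    objective <- c(objective, sum(Um * d2))
    cen <- crossprod(Um, features) / colSums(Um)
    if (it > 1 &&
        abs(objective[it - 1] - objective[it]) <= tol * max(1, objective[1])) {
      break
    }
  }
  d2 <- sqDistToCentroids(features, cen)
  U <- membershipFromDistances(d2, expo)
  list(membership = U, centroids = cen,
       labels = max.col(U, ties.method = "first") - 1L,
       objective = objective)
}

membershipFromDistances <- function(d2, expo) {
  n <- nrow(d2)
  C <- ncol(d2)
  U <- matrix(0, n, C)
  zero <- d2 <= .Machine$double.eps
  hasZero <- rowSums(zero) > 0
  if (any(hasZero)) {
    first <- max.col(zero[hasZero, , drop = FALSE], ties.method = "first")
    U[cbind(which(hasZero), first)] <- 1
  }
  if (any(!hasZero)) {
    r <- d2[!hasZero, , drop = FALSE]^(-expo / 2) # (1/d)^{2/(m-1)} on d^2 scale
    U[!hasZero, ] <- r / rowSums(r)
  }
  U
}
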