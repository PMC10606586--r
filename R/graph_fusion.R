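# The topological branch: per-batch KNN graph over the Euclidean features,
# symmetric-normalised propagation, a two-layer graph convolution producing
# h^g, concatenation with h^c, and the fusion-level weighted cross-entropy.

#' Pairwise Euclidean distance matrix
#'
#' @param features n x d numeric matrix (n >= 2).
#' @return symmetric n x n matrix with zero diagonal; entry (j, l) is
#'   the L2 norm of row j minus row l.
#' @examples
#' pairwiseDistances(rbind(c(0, 0), c(3, 4)))  # off-diagonal 5
#' @export
pairwiseDistances <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) validationError("need at least 2 feature rows")
  assertFinite(features, "features")
  sq <- rowSums(features * features)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(features)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Binary k-nearest-neighbour adjacency
#'
#' Row j carries a 1 at the k smallest-distance off-diagonal columns (ties
#' broken toward the lower column index; a sample is never its own
#' neighbour).
#'
#' @param dist symmetric distance matrix (e.g. [pairwiseDistances()]).
#' @param k neighbour count, `1 <= k <= n - 1`.
#' @return n x n 0/1 matrix with every row summing to k; attribute `k`.
#' @export
knnAdjacency <- function(dist, k) {
  n <- nrow(dist)
  if (k < 1 || k > n - 1) {
    configError(sprintf("k must lie in [1, %d], got %g", n - 1, k))
  }
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dj <- dist[j, ]
    dj[j] <- Inf
    # stable ascending order; ties resolved to the lower column index
    nb <- order(dj, seq_len(n))[seq_len(k)]
    A[j, nb] <- 1
  }
  attr(A, "k") <- as.integer(k)
  A
}

#' Symmetric-normalised propagation matrix
#'
#' Symmetrises the adjacency (`max(A, t(A))`), adds self-loops, and applies
#' the standard spectral normalisation
#' `D^{-1/2} (A_sym + I) D^{-1/2}` where `D` is the degree of `A_sym + I`.
#'
#' @param adj n x n 0/1 adjacency (e.g. [knnAdjacency()]).
#' @return dense n x n propagation matrix.
#' @export
normalizeAdjacency <- function(adj) {
  As <- pmax(adj, t(adj)) + diag(nrow(adj))
  dinv <- 1 / sqrt(rowSums(As))
  As * outer(dinv, dinv)
}

# GCN forward with caches: H' = relu(Ahat H W1), Hg = relu(Ahat H' W2)
gcnForwardCache <- function(model, hc, adjNorm) {
  ah <- adjNorm %*% hc
  z1 <- ah %*% model$gcn1$W
  h1 <- pmax(z1, 0)
  ah1 <- adjNorm %*% h1
  z2 <- ah1 %*% model$gcn2$W
  hg <- pmax(z2, 0)
  list(hg = hg, cache = list(ah = ah, z1 = z1, h1 = h1, ah1 = ah1, z2 = z2,
                             adjNorm = adjNorm))
}

gcnBackward <- function(model, cache, dhg) {
  dz2 <- dhg * (cache$z2 > 0)
  dW2 <- crossprod(cache$ah1, dz2)
  dh1 <- (cache$adjNorm %*% dz2) %*% t(model$gcn2$W)
  dz1 <- dh1 * (cache$z1 > 0)
  dW1 <- crossprod(cache$ah, dz1)
  list(dW1 = dW1, dW2 = dW2)
}

#' Two-layer graph convolution
#'
#' `H' = relu(Ahat %*% H %*% W1)`, `Hg = relu(Ahat %*% H' %*% W2)`.
#'
#' @param model a model state from [buildModel()].
#' @param hc n x featureDim Euclidean features.
#' @param adjNorm n x n propagation matrix from [normalizeAdjacency()].
#' @return n x graphDim matrix of topological features.
#' @export
gcnForward <- function(model, hc, adjNorm) {
  if (nrow(adjNorm) != nrow(hc) || ncol(adjNorm) != nrow(hc)) {
    validationError("adjacency size must match the number of feature rows")
  }
  gcnForwardCache(model, hc, adjNorm)$hg
}

#' Fuse Euclidean and graph features
#'
#' Row-wise concatenation, Euclidean block first.
#'
#' @param hc n x d_c matrix.
#' @param hg n x d_g matrix.
#' @return n x (d_c + d_g) matrix.
#' @export
fuseFeatures <- function(hc, hg) {
  if (nrow(hc) != nrow(hg)) {
    validationError("hc and hg must have the same number of rows")
  }
  cbind(hc, hg)
}

#' Weighted pseudo-label cross-entropy of the fusion head
#'
#' Cross-entropy of the C-way prediction layer on the fused representation
#' against the pseudo-labels, weighted per pseudo-class, averaged over the
#' batch.
#'
#' @param model a model state from [buildModel()].
#' @param fused n x fusedDim matrix ([fuseFeatures()] output, or h^c alone in
#'   DCCL mode).
#' @param pseudoLabels 0-based integers in `[0, C)`.
#' @param classWeights per-class weights (length C); defaults to 1.
#' @return non-negative scalar loss.
#' @export
fusionLoss <- function(model, fused, pseudoLabels,
                       classWeights = rep(1, model$C)) {
  if (ncol(fused) != nrow(model$fuseHead$W)) {
    validationError(sprintf(
      "fused width %d does not match the fusion head input width %d",
      ncol(fused), nrow(model$fuseHead$W)))
  }
  logits <- linearForward(model$fuseHead, fused)
  weightedCeLoss(logits, as.integer(pseudoLabels), classWeights)$loss
}

# one SGD step on the graph branch + fusion head (Eq-5 loss); the Euclidean
# features enter as constants. Returns updated model, loss, fused features.
graphStep <- function(model, hc, labels, w, lr, lambda, k, sgdMom) {
  if (model$dccl) {
    fused <- hc
    logits <- linearForward(model$fuseHead, fused)
    ce <- weightedCeLoss(logits, labels, w)
    gHead <- linearBackward(model$fuseHead, fused, lambda * ce$dlogits)
    model$fuseHead <- sgdUpdate(model$fuseHead, gHead$dW, gHead$db, lr, sgdMom)
    return(list(model = model, loss = ce$loss, fused = fused))
  }
  n <- nrow(hc)
  kEff <- min(k, n - 1L)
  adjNorm <- normalizeAdjacency(knnAdjacency(pairwiseDistances(hc), kEff))
  gf <- gcnForwardCache(model, hc, adjNorm)
  fused <- fuseFeatures(hc, gf$hg)
  logits <- linearForward(model$fuseHead, fused)
  ce <- weightedCeLoss(logits, labels, w)
  gHead <- linearBackward(model$fuseHead, fused, lambda * ce$dlogits)
  dg <- ncol(gf$hg)
  dhg <- gHead$dx[, ncol(hc) + seq_len(dg), drop = FALSE]
  gg <- gcnBackward(model, gf$cache, dhg)
  model$fuseHead <- sgdUpdate(model$fuseHead, gHead$dW, gHead$db, lr, sgdMom)
  model$gcn2 <- sgdUpdate(model$gcn2, gg$dW2, NULL, lr, sgdMom)
  model$gcn1 <- sgdUpdate(model$gcn1, gg$dW1, NULL, lr, sgdMom)
  list(model = model, loss = ce$loss, fused = fused)
}

# fused features in inference mode for a batch of images (per-batch graph)
fusedForward <- function(model, x, k) {
  h <- encodeEuclidean(model, x, train = FALSE)
  if (model$dccl) return(h)
  n <- nrow(h)
  kEff <- min(k, n - 1L)
  if (kEff < 1L) return(fuseFeatures(h, matrix(0, n, model$spec@graphDim)))
  adjNorm <- normalizeAdjacency(knnAdjacency(pairwiseDistances(h), kEff))
  fuseFeatures(h, gcnForward(model, h, adjNorm))
}
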