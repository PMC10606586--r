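# Scoring clusterings against held labels: Hungarian-matched accuracy,
# NMI / ARI, binary screening metrics (sensitivity, specificity, accuracy)
# and rank-based ROC-AUC.

# O(n^3) Hungarian algorithm (potentials + augmenting paths) for a square
# cost matrix; returns the column assigned to each row (minimum total cost).
hungarianSolve <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j+1] = row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Hungarian-matched clustering accuracy
#'
#' Accuracy under the cluster-to-class bijection that maximises the total
#' number of matches (optimal assignment on the confusion matrix) — the
#' standard protocol for scoring an unsupervised clustering against class
#' labels.
#'
#' @param predClusters predicted cluster ids (any integer coding).
#' @param labels ground-truth class labels (any integer coding).
#' @return list with `accuracy` and `mapping` — an integer vector giving, for
#'   each distinct cluster id (in sorted order), the matched class label
#'   (`NA` for clusters matched to padding).
#' @export
hungarianAccuracy <- function(predClusters, labels) {
  if (length(predClusters) == 0 || length(predClusters) != length(labels)) {
    validationError("need equal-length, non-empty label vectors")
  }
  pu <- sort(unique(predClusters))
  lu <- sort(unique(labels))
  conf <- table(factor(predClusters, levels = pu),
                factor(labels, levels = lu))
  conf <- matrix(as.numeric(conf), nrow = length(pu))
  n <- max(length(pu), length(lu))
  full <- matrix(0, n, n)
  full[seq_len(length(pu)), seq_len(length(lu))] <- conf
  assign <- hungarianSolve(max(full) - full)
  matched <- sum(full[cbind(seq_len(n), assign)])
  mapping <- rep(NA_integer_, length(pu))
  ok <- assign[seq_len(length(pu))] <= length(lu)
  mapping[ok] <- as.integer(lu[assign[seq_len(length(pu))][ok]])
  list(accuracy = matched / length(labels), mapping = mapping)
}

#' Normalized mutual information of two labelings
#'
#' Mutual information divided by the arithmetic mean of the two label
#' entropies; 1 for identical partitions (up to relabelling), 0 for
#' independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return NMI in [0, 1].
#' @export
nmiScore <- function(a, b) {
  if (length(a) != length(b)) validationError("labelings must match in length")
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha + hb == 0) return(1)
  denom <- (ha + hb) / 2
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index of two labelings
#'
#' Pair-counting agreement corrected for chance.
#'
#' @param a,b equal-length label vectors.
#' @return ARI (1 identical, ~0 random).
#' @export
ariScore <- function(a, b) {
  if (length(a) != length(b)) validationError("labelings must match in length")
  tab <- table(a, b)
  n <- length(a)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(0)
  (sumij - expected) / (maxidx - expected)
}

#' Binary screening metrics
#'
#' Sensitivity = TP/(TP+FN) among abnormal, specificity = TN/(TN+FP) among
#' normal, accuracy = (TP+TN)/n. When the truth contains a single class the
#' undefined rate is returned as `NA` rather than an error.
#'
#' @param predBinary predicted 0/1 labels.
#' @param trueBinary ground-truth 0/1 labels.
#' @return list with `sensitivity`, `specificity`, `accuracy`.
#' @export
binaryMetrics <- function(predBinary, trueBinary) {
  if (length(predBinary) != length(trueBinary)) {
    validationError("prediction and truth must match in length")
  }
  if (!all(predBinary %in% 0:1) || !all(trueBinary %in% 0:1)) {
    validationError("labels must be binary 0/1")
  }
  tp <- sum(predBinary == 1 & trueBinary == 1)
  fn <- sum(predBinary == 0 & trueBinary == 1)
  tn <- sum(predBinary == 0 & trueBinary == 0)
  fp <- sum(predBinary == 1 & trueBinary == 0)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(trueBinary)
  )
}

#' ROC area under the curve (Mann-Whitney rank statistic)
#'
#' Probability that a random abnormal sample scores higher than a random
#' normal one, with ties counted half (midranks).
#'
#' @param scores real-valued abnormality scores.
#' @param trueBinary ground-truth 0/1 labels.
#' @return AUC in [0, 1]; `NA` if the truth has a single class.
#' @export
rocAuc <- function(scores, trueBinary) {
  if (length(scores) != length(trueBinary)) {
    validationError("scores and truth must match in length")
  }
  if (!all(trueBinary %in% 0:1)) validationError("truth must be binary 0/1")
  npos <- sum(trueBinary == 1)
  nneg <- sum(trueBinary == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[trueBinary == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate a fitted model on a labelled image set
#'
#' Runs inference (deterministic: dropout off, running batch statistics),
#' assigns each sample to its nearest stored centroid, matches clusters to
#' classes by Hungarian assignment, and reports clustering metrics plus the
#' binary normal/abnormal screening metrics obtained by collapsing matched
#' classes with [gradeToBinary()]. The ROC score of a sample is
#' `dN / (dN + dA)` — its distance to the nearest normal-side centroid over
#' the sum with the nearest abnormal-side distance (recorded in `notes`).
#'
#' @param fit a [DgclFit-class].
#' @param dataset a [LabeledImageSet-class]; labels required for the scored
#'   metrics (a fully unlabelled set yields an all-`NA` report).
#' @param normalClass the grade treated as normal (default 0).
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(fit, dataset, normalClass = 0L) {
  if (!methods::is(fit, "DgclFit")) configError("fit must be a DgclFit")
  cen <- fit@centroidMemory@centroids
  fused <- fusedFeaturesAll(fit@model, dataset@images,
                            fit@config@batchSize, fit@config@knnK)
  if (ncol(fused) != ncol(cen)) {
    configError("checkpoint centroid width does not match the model output")
  }
  fused <- l2NormalizeRows(fused)
  pred <- assignPseudoLabels(fused, cen)
  truth <- trueLabels(dataset)
  notes <- "ROC score: dNormal / (dNormal + dAbnormal) over matched centroids"
  if (any(is.na(truth))) {
    return(new("MetricsReport", accuracy = NA_real_, sensitivity = NA_real_,
               specificity = NA_real_, binaryAccuracy = NA_real_,
               auc = NA_real_, nmi = NA_real_, ari = NA_real_,
               clusterToClassMap = rep(NA_integer_, nrow(cen)),
               notes = c(notes, "labels absent: scored metrics omitted")))
  }
  ha <- hungarianAccuracy(pred, truth)
  nmi <- nmiScore(pred, truth)
  ari <- ariScore(pred, truth)
  # map every centroid id (0-based) to a class, then collapse to binary
  predIds <- sort(unique(pred))
  mapOfCluster <- rep(NA_integer_, nrow(cen))
  mapOfCluster[predIds + 1L] <- ha$mapping
  mappedClass <- mapOfCluster[pred + 1L]
  predBin <- gradeToBinary(mappedClass, normalClass)
  truthBin <- gradeToBinary(truth, normalClass)
  bm <- binaryMetrics(predBin, truthBin)
  normalSide <- which(!is.na(mapOfCluster) & mapOfCluster == normalClass)
  abnormalSide <- which(!is.na(mapOfCluster) & mapOfCluster != normalClass)
  auc <- NA_real_
  if (length(normalSide) && length(abnormalSide)) {
    d2 <- sqDistToCentroids(fused, cen)
    dN <- sqrt(apply(d2[, normalSide, drop = FALSE], 1, min))
    dA <- sqrt(apply(d2[, abnormalSide, drop = FALSE], 1, min))
    score <- dN / pmax(dN + dA, .Machine$double.eps)
    auc <- rocAuc(score, truthBin)
  } else {
    notes <- c(notes, "all clusters matched to one side: AUC omitted")
  }
  new("MetricsReport", accuracy = ha$accuracy,
      sensitivity = bm$sensitivity, specificity = bm$specificity,
      binaryAccuracy = bm$accuracy, auc = auc, nmi = nmi, ari = ari,
      clusterToClassMap = mapOfCluster, notes = notes)
}
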