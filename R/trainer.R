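# Training loop: concurrent network update and cluster evolution. Each batch
# updates, in order: the CNN branch on the weighted pseudo-label
# cross-entropy; the graph branch + fusion head on the fusion-level
# cross-entropy (per-batch KNN graph); the sample memory by momentum mixing;
# and the batch's pseudo-labels by nearest-centroid reassignment. Centroids
# refresh on their schedule. The joint objective is
# lambda * (Luc + Lug) + (1 - lambda) * Luce, where Luce is the mean squared
# distance of stored features to their assigned centroids (an assignment
# criterion, tracked as a value; centroids move by refresh, not by gradient).

#' Joint training objective
#'
#' `lambda * (Luc + Lug) + (1 - lambda) * Luce`: the balance factor weights
#' the two network losses against the clustering consistency term.
#'
#' @param luc CNN-branch cross-entropy.
#' @param lug fusion-branch cross-entropy.
#' @param luce clustering term (mean squared distance to assigned centroids).
#' @param lambda balance factor in (0, 1].
#' @return scalar objective value.
#' @examples
#' totalLoss(1, 2, 3, lambda = 0.6)  # 3
#' @export
totalLoss <- function(luc, lug, luce, lambda) {
  if (!all(is.finite(c(luc, lug, luce)))) {
    validationError("loss components must be finite")
  }
  if (lambda <= 0 || lambda > 1) validationError("lambda must lie in (0, 1]")
  lambda * (luc + lug) + (1 - lambda) * luce
}

#' Learning-rate schedule
#'
#' Constant at `cfg@lr` for the first `lrConstantEpochs` epochs, then
#' multiplied by `lrDecayFactor` every `lrDecayEvery` epochs.
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [TrainConfig-class].
#' @return the learning rate for that epoch.
#' @examples
#' learningRate(0, trainConfig())   # 0.01
#' learningRate(50, trainConfig())  # 0.001
#' @export
learningRate <- function(epoch, cfg) {
  if (epoch < 0) validationError("epoch must be >= 0")
  past <- max(0, epoch - cfg@lrConstantEpochs)
  cfg@lr * cfg@lrDecayFactor^(past %/% cfg@lrDecayEvery)
}

#' Pseudo-label churn ratio
#'
#' Fraction of positions where two label vectors differ; the per-epoch value
#' is the stability diagnostic of the dynamic stores.
#'
#' @param oldLabels,newLabels equal-length label vectors.
#' @return a proportion in [0, 1].
#' @export
churnRatio <- function(oldLabels, newLabels) {
  if (length(oldLabels) != length(newLabels)) {
    validationError("label vectors must have equal length")
  }
  mean(oldLabels != newLabels)
}

#' One concurrent training step on a mini-batch
#'
#' Performs, in order: CNN forward and update (pseudo-label cross-entropy,
#' weighted by the batch's inverse-cluster-size weights); per-batch KNN graph,
#' graph convolution, fusion, and fusion-head/GCN update; momentum update of
#' the sample-memory rows of the batch; nearest-centroid reassignment of
#' those rows' pseudo-labels; and the clustering term Luce at the new
#' assignment.
#'
#' @param model model state from [buildModel()].
#' @param ms a [SampleMemory-class] covering the whole dataset.
#' @param mc a [CentroidMemory-class].
#' @param images (h, w, ch, B) array — the batch's preprocessed images.
#' @param indices 1-based dataset indices of the batch rows.
#' @param cfg a [TrainConfig-class].
#' @param lr learning rate for this step.
#' @return list with `model`, `ms`, `losses` (named: luc, lug, luce, total)
#'   and `reassigned` (count of changed pseudo-labels).
#' @export
trainStep <- function(model, ms, mc, images, indices, cfg, lr) {
  if (!methods::is(ms, "SampleMemory") || !methods::is(mc, "CentroidMemory")) {
    stateError("memory stores are not initialized; run initMemory first")
  }
  indices <- as.integer(indices)
  if (any(indices < 1L) || any(indices > nrow(ms@features))) {
    stateError("batch indices outside the sample memory")
  }
  x <- asImageArray(model, images)
  y <- ms@labels[indices]
  w <- classWeights(y, cfg@nClusters)
  cs <- cnnStep(model, x, y, w, lr, cfg@lambda, cfg@sgdMomentum)
  gs <- graphStep(cs$model, cs$h, y, w, lr, cfg@lambda, cfg@knnK,
                  cfg@sgdMomentum)
  ms <- momentumUpdate(ms, indices, gs$fused, cfg@momentum)
  batchFeats <- ms@features[indices, , drop = FALSE]
  newLab <- assignPseudoLabels(batchFeats, mc)
  reassigned <- sum(newLab != y)
  ms@labels[indices] <- newLab
  luce <- mean(rowSums((batchFeats - mc@centroids[newLab + 1L, ,
                                                  drop = FALSE])^2))
  losses <- c(luc = cs$loss, lug = gs$loss, luce = luce,
              total = totalLoss(cs$loss, gs$loss, luce, cfg@lambda))
  list(model = gs$model, ms = ms, losses = losses, reassigned = reassigned)
}

# inference-mode fused features for a whole image set, in batches
fusedFeaturesAll <- function(model, images, batchSize, k) {
  x <- asImageArray(model, images)
  n <- dim(x)[4]
  out <- matrix(0, n, fusedDim(model))
  starts <- seq(1L, n, by = batchSize)
  for (s in starts) {
    e <- min(s + batchSize - 1L, n)
    out[s:e, ] <- fusedForward(model, x[, , , s:e, drop = FALSE], k)
  }
  out
}

#' Fit the dynamic graph clustering model
#'
#' Initialises the memory stores by clustering the untrained network's fused
#' features, then runs epochs of shuffled concurrent steps ([trainStep()]),
#' refreshing the centroid memory on its schedule and logging losses and the
#' pseudo-label churn ratio per epoch. Training stops at the epoch budget or
#' once the churn ratio stays below `cfg@convergeChurn` for
#' `cfg@convergePatience` consecutive epochs.
#'
#' @param dataset a [LabeledImageSet-class]; labels, when present, are used
#'   only for per-epoch diagnostics, never for training.
#' @param cfg a [TrainConfig-class].
#' @param espec an [EncoderSpec-class].
#' @param logFile optional path; one JSON line per epoch is appended.
#' @return a [DgclFit-class].
#' @export
dgclFit <- function(dataset, cfg = trainConfig(), espec = encoderSpec(),
                    logFile = NULL) {
  if (!methods::is(dataset, "LabeledImageSet")) {
    configError("dataset must be a LabeledImageSet")
  }
  n <- nImages(dataset)
  C <- cfg@nClusters
  if (n < C) configError("need at least nClusters samples")
  set.seed(cfg@seed)
  x <- dataset@images
  model <- buildModel(dim(x)[1:3], C, espec, cfg@dcclMode)

  fused0 <- fusedFeaturesAll(model, x, cfg@batchSize, cfg@knnK)
  mem <- initMemory(fused0, C, m = cfg@momentum, seed = cfg@seed,
                    clusterAlgo = cfg@clusterAlgo, fuzzifier = cfg@fuzzifier,
                    refreshPeriod = cfg@refreshPeriod,
                    refreshUnit = cfg@refreshUnit)
  ms <- mem$ms
  mc <- mem$mc

  truth <- trueLabels(dataset)
  haveTruth <- !any(is.na(truth))
  log <- list()
  calm <- 0L
  step <- 0L
  for (epoch in seq_len(cfg@epochs)) {
    lr <- learningRate(epoch - 1L, cfg)
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg@batchSize)
    reassigned <- 0L
    lsum <- c(luc = 0, lug = 0, luce = 0, total = 0)
    nb <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + cfg@batchSize - 1L, n)]
      if (length(idx) < 2L) next  # a single orphan sample cannot form a graph
      st <- trainStep(model, ms, mc,
                      x[, , , idx, drop = FALSE], idx, cfg, lr)
      model <- st$model
      ms <- st$ms
      reassigned <- reassigned + st$reassigned
      lsum <- lsum + st$losses
      nb <- nb + 1L
      step <- step + 1L
      if (cfg@refreshUnit == "iteration" && step %% cfg@refreshPeriod == 0L) {
        mc <- refreshCentroids(ms, previous = mc)
      }
    }
    if (cfg@refreshUnit == "epoch" && epoch %% cfg@refreshPeriod == 0L) {
      mc <- refreshCentroids(ms, previous = mc)
    }
    ratio <- reassigned / n
    rec <- data.frame(epoch = epoch, lr = lr,
                      luc = lsum[["luc"]] / nb, lug = lsum[["lug"]] / nb,
                      luce = lsum[["luce"]] / nb,
                      total = lsum[["total"]] / nb,
                      reassigned = reassigned, churn = ratio,
                      msAccuracy = if (haveTruth) {
                        hungarianAccuracy(ms@labels, truth)$accuracy
                      } else NA_real_)
    log[[epoch]] <- rec
    if (!is.null(logFile)) {
      cat(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = logFile, append = TRUE)
    }
    calm <- if (ratio < cfg@convergeChurn) calm + 1L else 0L
    if (calm >= cfg@convergePatience) break
  }
  churnLog <- if (length(log)) do.call(rbind, log) else
    data.frame(epoch = integer(), lr = numeric(), luc = numeric(),
               lug = numeric(), luce = numeric(), total = numeric(),
               reassigned = integer(), churn = numeric(),
               msAccuracy = numeric())
  new("DgclFit", model = model, sampleMemory = ms, centroidMemory = mc,
      config = cfg, encoder = espec, churnLog = churnLog, version = 1L)
}

#' Fitted dynamic graph clustering model
#'
#' @slot model opaque network state (backbone, heads, GCN layers).
#' @slot sampleMemory final [SampleMemory-class].
#' @slot centroidMemory final [CentroidMemory-class].
#' @slot config the [TrainConfig-class] used.
#' @slot encoder the [EncoderSpec-class] used.
#' @slot churnLog per-epoch data.frame: losses, churn ratio, diagnostics.
#' @slot version checkpoint format version.
#' @exportClass DgclFit
setClass("DgclFit",
  representation(model = "list", sampleMemory = "SampleMemory",
                 centroidMemory = "CentroidMemory", config = "TrainConfig",
                 encoder = "EncoderSpec", churnLog = "data.frame",
                 version = "integer")
)

setMethod("show", "DgclFit", function(object) {
  nep <- nrow(object@churnLog)
  cat(sprintf("DgclFit: %d epochs trained, C=%d%s\n", nep,
              object@config@nClusters,
              if (object@config@dcclMode) " [DCCL]" else ""))
  if (nep > 0) {
    last <- object@churnLog[nep, ]
    cat(sprintf("  final: total loss %.4f, churn %.3f%s\n", last$total,
                last$churn,
                if (!is.na(last$msAccuracy)) {
                  sprintf(", memory-label accuracy %.3f", last$msAccuracy)
                } else ""))
  }
})

#' Per-epoch training log of a fit
#' @param fit a [DgclFit-class].
#' @return data.frame with one row per epoch.
#' @export
churnLog <- function(fit) fit@churnLog

#' Save / load a checkpoint directory
#'
#' Writes `model.rds` (the full fit), `config.yaml` (hyper-parameters),
#' `churn_log.jsonl` (one JSON record per epoch) and `pseudo_labels.csv`
#' (`sample_id,label`).
#'
#' @param fit a [DgclFit-class].
#' @param dir checkpoint directory (created if absent).
#' @return invisibly, `dir`.
#' @export
saveCheckpoint <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(fit, file.path(dir, "model.rds"))
  cfg <- fit@config
  nm <- methods::slotNames(cfg)
  yaml::write_yaml(stats::setNames(lapply(nm, function(s) {
    methods::slot(cfg, s)
  }), nm), file.path(dir, "config.yaml"))
  logPath <- file.path(dir, "churn_log.jsonl")
  if (file.exists(logPath)) file.remove(logPath)
  cl <- fit@churnLog
  for (i in seq_len(nrow(cl))) {
    cat(jsonlite::toJSON(as.list(cl[i, ]), auto_unbox = TRUE, digits = NA),
        "\n", sep = "", file = logPath, append = TRUE)
  }
  utils::write.csv(
    data.frame(sample_id = seq_along(fit@sampleMemory@labels),
               label = fit@sampleMemory@labels),
    file.path(dir, "pseudo_labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) ioError(sprintf("no checkpoint at %s", dir))
  fit <- readRDS(path)
  if (!methods::is(fit, "DgclFit")) ioError("checkpoint is not a DgclFit")
  fit
}
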