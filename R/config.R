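# Configuration objects: training hyper-parameters, encoder architecture,
# image preprocessing. Defaults follow the published operating point of the
# method (batch 128, C = 5, m = 0.5, lambda = 0.6, k = 4, lr 0.01 held for
# 30 epochs, centroid refresh every 10 epochs).

#' Training configuration
#'
#' @slot batchSize mini-batch size B.
#' @slot nClusters number of clusters C (>= 2).
#' @slot momentum sample-memory momentum m in (0, 1].
#' @slot lambda balance factor in (0, 1]: weight of the network losses
#'   (Luc + Lug) against the clustering term Luce in the joint objective.
#' @slot knnK neighbour count k of the per-batch KNN graph (k < batchSize).
#' @slot lr initial learning rate.
#' @slot lrConstantEpochs epochs at constant `lr` before decay starts.
#' @slot lrDecayEvery,lrDecayFactor step decay schedule after the constant
#'   phase (multiply by `lrDecayFactor` every `lrDecayEvery` epochs).
#' @slot sgdMomentum SGD momentum coefficient.
#' @slot epochs training epoch budget.
#' @slot refreshPeriod centroid-memory refresh period.
#' @slot refreshUnit `"epoch"` or `"iteration"`.
#' @slot seed RNG seed for the whole run.
#' @slot dcclMode logical; `TRUE` disables the graph branch (ablation: the
#'   fused representation is the Euclidean feature alone).
#' @slot clusterAlgo `"kmeans"` or `"fcm"` (fuzzy c-means) for memory
#'   initialisation.
#' @slot fuzzifier FCM fuzzifier (> 1), used when `clusterAlgo = "fcm"`.
#' @slot convergeChurn,convergePatience early-stop rule: stop once the churn
#'   ratio stays below `convergeChurn` for `convergePatience` consecutive
#'   epochs.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    batchSize = "integer", nClusters = "integer", momentum = "numeric",
    lambda = "numeric", knnK = "integer", lr = "numeric",
    lrConstantEpochs = "integer", lrDecayEvery = "integer",
    lrDecayFactor = "numeric", sgdMomentum = "numeric", epochs = "integer",
    refreshPeriod = "integer", refreshUnit = "character", seed = "integer",
    dcclMode = "logical", clusterAlgo = "character", fuzzifier = "numeric",
    convergeChurn = "numeric", convergePatience = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  if (object@lambda <= 0 || object@lambda > 1) {
    return("lambda must lie in (0, 1]")
  }
  if (object@momentum <= 0 || object@momentum > 1) {
    return("momentum must lie in (0, 1]")
  }
  if (object@knnK >= object@batchSize) {
    return("knnK must be smaller than batchSize")
  }
  if (object@knnK < 1L) return("knnK must be >= 1")
  if (object@nClusters < 2L) return("nClusters must be >= 2")
  if (object@batchSize < 2L) return("batchSize must be >= 2")
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (object@lr <= 0) return("lr must be positive")
  if (object@refreshPeriod < 1L) return("refreshPeriod must be >= 1")
  if (!object@refreshUnit %in% c("epoch", "iteration")) {
    return("refreshUnit must be 'epoch' or 'iteration'")
  }
  if (!object@clusterAlgo %in% c("kmeans", "fcm")) {
    return("clusterAlgo must be 'kmeans' or 'fcm'")
  }
  if (object@fuzzifier <= 1) return("fuzzifier must be > 1")
  TRUE
})

#' Create a training configuration
#'
#' Defaults follow the method's published operating point; see
#' [TrainConfig-class] for the meaning of each field.
#'
#' @param batchSize mini-batch size (default 128).
#' @param nClusters number of clusters C (default 5).
#' @param momentum memory momentum m (default 0.5).
#' @param lambda balance factor (default 0.6).
#' @param knnK KNN graph neighbour count (default 4).
#' @param lr initial learning rate (default 0.01).
#' @param lrConstantEpochs constant-lr phase length (default 30).
#' @param lrDecayEvery,lrDecayFactor decay schedule after the constant phase.
#' @param sgdMomentum SGD momentum (default 0.9).
#' @param epochs epoch budget.
#' @param refreshPeriod centroid refresh period (default 10).
#' @param refreshUnit `"epoch"` (default) or `"iteration"`.
#' @param seed RNG seed.
#' @param dcclMode disable the graph branch (default `FALSE`).
#' @param clusterAlgo `"kmeans"` (default) or `"fcm"`.
#' @param fuzzifier FCM fuzzifier (default 2).
#' @param convergeChurn,convergePatience early-stopping rule on the churn
#'   ratio.
#' @return a [TrainConfig-class] object.
#' @examples
#' cfg <- trainConfig(nClusters = 3, batchSize = 64, epochs = 10)
#' @export
trainConfig <- function(batchSize = 128L, nClusters = 5L, momentum = 0.5,
                        lambda = 0.6, knnK = 4L, lr = 0.01,
                        lrConstantEpochs = 30L, lrDecayEvery = 20L,
                        lrDecayFactor = 0.1, sgdMomentum = 0.9, epochs = 30L,
                        refreshPeriod = 10L, refreshUnit = "epoch", seed = 1L,
                        dcclMode = FALSE, clusterAlgo = "kmeans",
                        fuzzifier = 2, convergeChurn = 0.01,
                        convergePatience = 5L) {
  tryCatch(
    new("TrainConfig",
      batchSize = as.integer(batchSize), nClusters = as.integer(nClusters),
      momentum = as.numeric(momentum), lambda = as.numeric(lambda),
      knnK = as.integer(knnK), lr = as.numeric(lr),
      lrConstantEpochs = as.integer(lrConstantEpochs),
      lrDecayEvery = as.integer(lrDecayEvery),
      lrDecayFactor = as.numeric(lrDecayFactor),
      sgdMomentum = as.numeric(sgdMomentum), epochs = as.integer(epochs),
      refreshPeriod = as.integer(refreshPeriod),
      refreshUnit = as.character(refreshUnit), seed = as.integer(seed),
      dcclMode = isTRUE(dcclMode), clusterAlgo = as.character(clusterAlgo),
      fuzzifier = as.numeric(fuzzifier),
      convergeChurn = as.numeric(convergeChurn),
      convergePatience = as.integer(convergePatience)
    ),
    error = function(e) configError(conditionMessage(e))
  )
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    paste0("TrainConfig: B=%d, C=%d, m=%g, lambda=%g, k=%d, lr=%g, ",
           "epochs=%d, refresh every %d %s(s), %s%s\n"),
    object@batchSize, object@nClusters, object@momentum, object@lambda,
    object@knnK, object@lr, object@epochs, object@refreshPeriod,
    object@refreshUnit, object@clusterAlgo,
    if (object@dcclMode) " [DCCL: graph branch off]" else ""
  ))
})

#' Encoder architecture specification
#'
#' @slot backbone one of `"small_cnn"` (three convolution blocks with global
#'   pooling; the desk-scale default), `"resnet50"` or `"alexnet"`. Only
#'   `small_cnn` ships with this build; the large backbones are recognised
#'   names whose construction signals a configuration error.
#' @slot pretrained load pretrained backbone weights if available (ignored by
#'   `small_cnn`).
#' @slot featureDim width of the Euclidean feature h^c after the
#'   dimensionality-reduction head (default 256).
#' @slot hiddenDim hidden width of the reduction head.
#' @slot graphDim width d_g of the graph feature h^g (default 64).
#' @slot dropoutRate dropout probability inside the reduction head, in [0, 1).
#' @slot channels integer vector of the three convolution block widths.
#' @exportClass EncoderSpec
setClass("EncoderSpec",
  representation(
    backbone = "character", featureDim = "integer", hiddenDim = "integer",
    graphDim = "integer", dropoutRate = "numeric", channels = "integer",
    pretrained = "logical"
  )
)

setValidity("EncoderSpec", function(object) {
  if (!object@backbone %in% c("small_cnn", "resnet50", "alexnet")) {
    return("backbone must be one of 'small_cnn', 'resnet50', 'alexnet'")
  }
  if (object@featureDim < 1L) return("featureDim must be positive")
  if (object@graphDim < 1L) return("graphDim must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1) {
    return("dropoutRate must lie in [0, 1)")
  }
  if (length(object@channels) != 3 || any(object@channels < 1L)) {
    return("channels must be three positive block widths")
  }
  TRUE
})

#' Create an encoder specification
#'
#' @param backbone backbone name; only `"small_cnn"` is implemented.
#' @param featureDim Euclidean feature width after reduction (default 256).
#' @param hiddenDim hidden width of the fc-bn-relu-dropout-fc-relu reduction
#'   head (default = `featureDim`).
#' @param graphDim graph feature width d_g (default 64).
#' @param dropoutRate dropout probability (default 0.5).
#' @param channels widths of the three convolution blocks.
#' @param pretrained request pretrained backbone weights (ignored by
#'   `small_cnn`).
#' @return an [EncoderSpec-class].
#' @export
encoderSpec <- function(backbone = "small_cnn", featureDim = 256L,
                        hiddenDim = featureDim, graphDim = 64L,
                        dropoutRate = 0.5, channels = c(8L, 16L, 32L),
                        pretrained = FALSE) {
  tryCatch(
    new("EncoderSpec",
      backbone = backbone, featureDim = as.integer(featureDim),
      hiddenDim = as.integer(hiddenDim), graphDim = as.integer(graphDim),
      dropoutRate = as.numeric(dropoutRate), channels = as.integer(channels),
      pretrained = isTRUE(pretrained)
    ),
    error = function(e) configError(conditionMessage(e))
  )
}

setMethod("show", "EncoderSpec", function(object) {
  cat(sprintf(
    "EncoderSpec: %s [%s] -> reduce to %d dims (hidden %d, dropout %g); graph dim %d\n",
    object@backbone, paste(object@channels, collapse = "-"),
    object@featureDim, object@hiddenDim, object@dropoutRate, object@graphDim
  ))
})

#' Image preprocessing / augmentation configuration
#'
#' Jitter ranges follow standard fundus-photograph augmentation: saturation
#' in [0, 2], contrast in [0.5, 1.2], hue in [-0.6, 0.6], brightness in
#' [0.5, 1.2]; each jitter is applied independently with probability 1/2 per
#' image, with its factor drawn uniformly from the range.
#'
#' @slot targetSize output side length in pixels.
#' @slot cropBlack crop away dark borders before resizing.
#' @slot blackThreshold max-channel intensity below which a pixel counts as
#'   border black.
#' @slot augment enable stochastic augmentation.
#' @slot saturationRange,contrastRange,hueRange,brightnessRange jitter ranges.
#' @slot hflip,vflip,rotate flip / right-angle rotation flags.
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(
    targetSize = "integer", cropBlack = "logical", blackThreshold = "numeric",
    augment = "logical", saturationRange = "numeric",
    contrastRange = "numeric", hueRange = "numeric",
    brightnessRange = "numeric", hflip = "logical", vflip = "logical",
    rotate = "logical"
  )
)

setValidity("PreprocessConfig", function(object) {
  if (object@targetSize < 1L) return("targetSize must be positive")
  rngs <- list(saturationRange = object@saturationRange,
               contrastRange = object@contrastRange,
               hueRange = object@hueRange,
               brightnessRange = object@brightnessRange)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      return(sprintf("%s must be an ordered pair (low <= high)", nm))
    }
  }
  if (object@blackThreshold < 0 || object@blackThreshold > 1) {
    return("blackThreshold must lie in [0, 1]")
  }
  TRUE
})

#' Create a preprocessing configuration
#'
#' @param targetSize output side length (default 224).
#' @param cropBlack crop dark borders first (default `FALSE`).
#' @param blackThreshold border-black intensity threshold (default 0.02).
#' @param augment enable augmentation (default `FALSE`).
#' @param saturationRange,contrastRange,hueRange,brightnessRange jitter
#'   ranges (low, high).
#' @param hflip,vflip,rotate flip / right-angle rotation flags.
#' @return a [PreprocessConfig-class].
#' @export
preprocessConfig <- function(targetSize = 224L, cropBlack = FALSE,
                             blackThreshold = 0.02, augment = FALSE,
                             saturationRange = c(0, 2),
                             contrastRange = c(0.5, 1.2),
                             hueRange = c(-0.6, 0.6),
                             brightnessRange = c(0.5, 1.2),
                             hflip = TRUE, vflip = TRUE, rotate = TRUE) {
  tryCatch(
    new("PreprocessConfig",
      targetSize = as.integer(targetSize), cropBlack = isTRUE(cropBlack),
      blackThreshold = as.numeric(blackThreshold), augment = isTRUE(augment),
      saturationRange = as.numeric(saturationRange),
      contrastRange = as.numeric(contrastRange),
      hueRange = as.numeric(hueRange),
      brightnessRange = as.numeric(brightnessRange),
      hflip = isTRUE(hflip), vflip = isTRUE(vflip), rotate = isTRUE(rotate)
    ),
    error = function(e) configError(conditionMessage(e))
  )
}
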