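#' @import methods
NULL

# ---------------------------------------------------------------------------
# SyntheticSpec
# ---------------------------------------------------------------------------

#' Specification of a synthetic labelled image set
#'
#' Describes a planted-cluster image dataset: `nSamples` images of
#' `imageSize` x `imageSize` pixels drawn from `nClusters` cluster templates,
#' with template intensity scaled by `separation` and i.i.d. Gaussian pixel
#' noise of standard deviation `noiseSd`.
#'
#' @slot nSamples integer, number of images.
#' @slot nClusters integer, number of planted clusters (C).
#' @slot imageSize integer, pixels per side.
#' @slot separation non-negative numeric, inter-cluster signal strength.
#' @slot noiseSd non-negative numeric, pixel noise standard deviation.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    nSamples = "integer", nClusters = "integer", imageSize = "integer",
    separation = "numeric", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  if (length(object@nClusters) != 1 || is.na(object@nClusters) ||
      object@nClusters < 2L) {
    return("nClusters must be a single integer >= 2")
  }
  if (length(object@nSamples) != 1 || is.na(object@nSamples) ||
      object@nSamples < object@nClusters) {
    return("nSamples must be a single integer >= nClusters")
  }
  if (length(object@imageSize) != 1 || is.na(object@imageSize) ||
      object@imageSize < 8L) {
    return("imageSize must be a single integer >= 8")
  }
  if (length(object@separation) != 1 || !is.finite(object@separation) ||
      object@separation < 0) {
    return("separation must be a single non-negative number")
  }
  if (length(object@noiseSd) != 1 || !is.finite(object@noiseSd) ||
      object@noiseSd < 0) {
    return("noiseSd must be a single non-negative number")
  }
  TRUE
})

#' Create a synthetic dataset specification
#'
#' @param nSamples number of images to generate.
#' @param nClusters number of planted clusters (>= 2).
#' @param imageSize image side length in pixels (>= 8).
#' @param separation inter-cluster signal strength; 0 gives pure noise.
#' @param noiseSd standard deviation of additive Gaussian pixel noise.
#' @param seed integer RNG seed.
#' @return a [SyntheticSpec-class] object.
#' @examples
#' spec <- syntheticSpec(nSamples = 30, nClusters = 3, imageSize = 16)
#' @export
syntheticSpec <- function(nSamples, nClusters, imageSize = 32L,
                          separation = 5, noiseSd = 0.05, seed = 1L) {
  obj <- tryCatch(
    new("SyntheticSpec",
      nSamples = as.integer(nSamples), nClusters = as.integer(nClusters),
      imageSize = as.integer(imageSize), separation = as.numeric(separation),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed)
    ),
    error = function(e) configError(conditionMessage(e))
  )
  obj
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d samples, %d clusters, %dx%d px, separation=%g, noiseSd=%g, seed=%d\n",
    object@nSamples, object@nClusters, object@imageSize, object@imageSize,
    object@separation, object@noiseSd, object@seed
  ))
})

# ---------------------------------------------------------------------------
# LabeledImageSet
# ---------------------------------------------------------------------------

#' A stack of images with (optional) ground-truth labels
#'
#' Images are stored as a 4-D numeric array with dimensions
#' (height, width, channels, n); pixel values lie in [0, 1]. Labels are
#' 0-based integers; `NA` marks unlabelled samples (unsupervised mode).
#'
#' @slot images numeric array (h, w, channels, n) with values in [0, 1].
#' @slot labels integer vector of length n (0-based cluster/grade labels).
#' @exportClass LabeledImageSet
setClass("LabeledImageSet",
  representation(images = "array", labels = "integer")
)

setValidity("LabeledImageSet", function(object) {
  d <- dim(object@images)
  if (length(d) != 4) return("images must be a 4-D array (h, w, channels, n)")
  if (length(object@labels) != d[4]) {
    return("labels length must equal the number of images")
  }
  rng <- range(object@images)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8) {
    return("pixel values must lie in [0, 1]")
  }
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && any(lab < 0L)) return("labels must be non-negative")
  TRUE
})

#' Construct a LabeledImageSet
#'
#' @param images 4-D array (h, w, channels, n), or 3-D (h, w, n) for
#'   single-channel stacks.
#' @param labels optional 0-based integer labels (defaults to all `NA`).
#' @return a [LabeledImageSet-class].
#' @export
labeledImageSet <- function(images, labels = NULL) {
  if (length(dim(images)) == 3) {
    d <- dim(images)
    dim(images) <- c(d[1], d[2], 1L, d[3])
  }
  n <- dim(images)[4]
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  new("LabeledImageSet", images = images, labels = as.integer(labels))
}

#' @describeIn labeledImageSet number of images in the set.
#' @param x a `LabeledImageSet`.
#' @export
nImages <- function(x) dim(x@images)[4]

#' Ground-truth labels of an image set
#' @param x a `LabeledImageSet`.
#' @return integer vector (0-based; `NA` where unlabelled).
#' @export
trueLabels <- function(x) x@labels

#' Extract one image from a LabeledImageSet
#' @param x a `LabeledImageSet`.
#' @param i image index.
#' @return numeric array (h, w, channels).
#' @export
getImage <- function(x, i) {
  img <- x@images[, , , i, drop = FALSE]
  array(img, dim(img)[1:3])
}

setMethod("show", "LabeledImageSet", function(object) {
  d <- dim(object@images)
  nlab <- sum(!is.na(object@labels))
  cat(sprintf(
    "LabeledImageSet: %d images of %dx%d px, %d channel(s); %d labelled\n",
    d[4], d[1], d[2], d[3], nlab
  ))
})

# ---------------------------------------------------------------------------
# SampleMemory / CentroidMemory
# ---------------------------------------------------------------------------

#' Dynamic sample memory (Ms)
#'
#' Dataset-wide store of unit-norm fused features together with their current
#' pseudo-labels, updated online by momentum mixing during training.
#'
#' @slot features numeric matrix N x d; every row has unit L2 norm.
#' @slot labels integer vector of length N with values in `[0, C)`.
#' @slot momentum mixing coefficient m in (0, 1].
#' @exportClass SampleMemory
setClass("SampleMemory",
  representation(features = "matrix", labels = "integer", momentum = "numeric")
)

setValidity("SampleMemory", function(object) {
  if (nrow(object@features) != length(object@labels)) {
    return("labels length must equal the number of feature rows")
  }
  if (length(object@momentum) != 1 || object@momentum <= 0 ||
      object@momentum > 1) {
    return("momentum must lie in (0, 1]")
  }
  nrm <- sqrt(rowSums(object@features^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    return("every stored feature row must have unit L2 norm (tol 1e-6)")
  }
  if (any(is.na(object@labels)) || any(object@labels < 0L)) {
    return("pseudo-labels must be non-negative integers")
  }
  TRUE
})

setMethod("show", "SampleMemory", function(object) {
  cat(sprintf(
    "SampleMemory: %d samples x %d dims (unit-norm), momentum m=%g, %d pseudo-classes\n",
    nrow(object@features), ncol(object@features), object@momentum,
    length(unique(object@labels))
  ))
})

#' Stored features of a sample memory
#' @param ms a `SampleMemory`.
#' @return N x d numeric matrix of unit-norm rows.
#' @export
sampleFeatures <- function(ms) ms@features

#' Current pseudo-labels of a sample memory
#' @param ms a `SampleMemory`.
#' @return 0-based integer vector.
#' @export
pseudoLabels <- function(ms) ms@labels

#' Dynamic centroid memory (Mc)
#'
#' Per-cluster mean features used for nearest-centroid relabelling; refreshed
#' on a schedule (every `refreshPeriod` epochs or iterations).
#'
#' @slot centroids numeric matrix C x d.
#' @slot refreshPeriod positive integer refresh period.
#' @slot unit `"epoch"` or `"iteration"`.
#' @exportClass CentroidMemory
setClass("CentroidMemory",
  representation(centroids = "matrix", refreshPeriod = "integer",
                 unit = "character")
)

setValidity("CentroidMemory", function(object) {
  if (nrow(object@centroids) < 2) return("need at least 2 centroids")
  if (any(is.na(object@centroids))) return("centroids must not contain NA")
  if (length(object@refreshPeriod) != 1 || object@refreshPeriod < 1L) {
    return("refreshPeriod must be a positive integer")
  }
  if (!object@unit %in% c("epoch", "iteration")) {
    return("unit must be 'epoch' or 'iteration'")
  }
  TRUE
})

setMethod("show", "CentroidMemory", function(object) {
  cat(sprintf(
    "CentroidMemory: %d centroids x %d dims, refresh every %d %s(s)\n",
    nrow(object@centroids), ncol(object@centroids), object@refreshPeriod,
    object@unit
  ))
})

#' Centroid matrix of a centroid memory
#' @param mc a `CentroidMemory`.
#' @return C x d numeric matrix.
#' @export
centroids <- function(mc) mc@centroids

# ---------------------------------------------------------------------------
# MetricsReport
# ---------------------------------------------------------------------------

#' Clustering / classification evaluation report
#'
#' @slot accuracy Hungarian-matched clustering accuracy in [0, 1].
#' @slot sensitivity,specificity,binaryAccuracy binary screening metrics
#'   (`NA` when undefined, e.g. single-class truth).
#' @slot auc ROC area under the curve (`NA` when undefined).
#' @slot nmi,ari normalized mutual information and adjusted Rand index.
#' @slot clusterToClassMap integer vector: class assigned to each cluster id.
#' @slot notes character; records scoring-rule decisions.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
    binaryAccuracy = "numeric", auc = "numeric", nmi = "numeric",
    ari = "numeric", clusterToClassMap = "integer", notes = "character"
  )
)

setMethod("show", "MetricsReport", function(object) {
  fm <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  cat("MetricsReport\n")
  cat(sprintf("  Hungarian accuracy: %s   NMI: %s   ARI: %s\n",
              fm(object@accuracy), fm(object@nmi), fm(object@ari)))
  cat(sprintf("  binary  SEN: %s  SPE: %s  ACC: %s  AUC: %s\n",
              fm(object@sensitivity), fm(object@specificity),
              fm(object@binaryAccuracy), fm(object@auc)))
  if (length(object@notes)) cat("  notes:", object@notes, sep = "\n    ")
})
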