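# Synthetic image generator with planted cluster structure. Stands in for
# graded fundus-photograph collections: each cluster is a spatial intensity
# template (a position-coded blob pattern) whose strength is controlled by
# `separation`, corrupted by i.i.d. Gaussian pixel noise and clipped to
# [0, 1]. Templates differ in blob position, width and count so the planted
# cue is visible both to pixel-space clustering and to encoders whose global
# pooling discards absolute position.

# Cluster template on an S x S grid, peak intensity 1.
# Cluster c (0-based): a primary Gaussian blob on a circle at angle
# 2*pi*c/C, with cluster-dependent width, plus a half-intensity secondary
# blob opposite the primary for every second cluster.
blobTemplate <- function(c0, C, S) {
  xs <- matrix(rep(seq_len(S), S), S, S)          # row coordinate
  ys <- t(xs)                                     # column coordinate
  ctr <- (S + 1) / 2
  r <- S / 3.2
  gauss <- function(cx, cy, sigma) {
    exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
  }
  theta <- 2 * pi * c0 / C
  sigma <- S * (0.06 + 0.05 * c0 / max(C - 1, 1))
  tpl <- gauss(ctr + r * cos(theta), ctr + r * sin(theta), sigma)
  if (c0 %% 2 == 1) {
    tpl <- tpl + 0.5 * gauss(ctr + (r / 2) * cos(theta + pi),
                             ctr + (r / 2) * sin(theta + pi), sigma * 0.7)
  }
  tpl / max(tpl)
}

#' Generate a synthetic labelled image set with planted clusters
#'
#' Each image is its cluster's template scaled by `0.2 * separation`, plus
#' i.i.d. Gaussian noise of standard deviation `noiseSd`, clipped to [0, 1].
#' Labels are balanced to within one sample. `separation = 0` produces pure
#' noise. The output is bitwise deterministic given the spec's seed.
#'
#' @param spec a [SyntheticSpec-class] from [syntheticSpec()].
#' @return a [LabeledImageSet-class] with ground-truth 0-based labels.
#' @examples
#' set <- makeBlobImages(syntheticSpec(nSamples = 30, nClusters = 3,
#'                                     imageSize = 16))
#' table(trueLabels(set))
#' @export
makeBlobImages <- function(spec) {
  if (!methods::is(spec, "SyntheticSpec")) {
    configError("spec must be a SyntheticSpec object")
  }
  methods::validObject(spec)
  n <- spec@nSamples
  C <- spec@nClusters
  S <- spec@imageSize
  labels <- rep_len(seq_len(C) - 1L, n)     # balanced within +/- 1
  templates <- lapply(seq_len(C) - 1L, blobTemplate, C = C, S = S)
  scale <- 0.2 * spec@separation
  imgs <- withSeed(spec@seed, {
    a <- array(0, dim = c(S, S, 1L, n))
    for (i in seq_len(n)) {
      base <- scale * templates[[labels[i] + 1L]]
      a[, , 1L, i] <- clip01(base + stats::rnorm(S * S, sd = spec@noiseSd))
    }
    a
  })
  new("LabeledImageSet", images = imgs, labels = labels)
}

#' Collapse multi-grade labels to a binary normal/abnormal indicator
#'
#' Mirrors the screening convention for diabetic retinopathy grades: grade 0
#' is "normal", every other grade is "abnormal".
#'
#' @param labels non-negative integer vector of grades/clusters.
#' @param normalClass the grade treated as normal (default 0).
#' @return integer vector of 0 (normal) / 1 (abnormal).
#' @examples
#' gradeToBinary(c(0L, 2L, 0L, 4L))  # 0 1 0 1
#' @export
gradeToBinary <- function(labels, normalClass = 0L) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0L)) {
    validationError("labels must be non-negative integers")
  }
  as.integer(labels != normalClass)
}

#' Export an image set as PNG files plus a CSV label manifest
#'
#' Writes one PNG per image (`img_%05d.png`) and a `manifest.csv` with
#' columns `filename,label` (label empty for unlabelled samples), the format
#' [loadDataset()] reads back.
#'
#' @param x a [LabeledImageSet-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @export
writeImageSet <- function(x, dir) {
  if (!methods::is(x, "LabeledImageSet")) {
    configError("x must be a LabeledImageSet")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nImages(x)
  fnames <- sprintf("img_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    img <- getImage(x, i)
    if (dim(img)[3] == 1L) img <- img[, , 1]
    png::writePNG(img, target = file.path(dir, fnames[i]))
  }
  lab <- x@labels
  manifest <- data.frame(filename = fnames,
                         label = ifelse(is.na(lab), "", as.character(lab)),
                         stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
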