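# The Euclidean branch: a small convolutional backbone (three 3x3
# convolution blocks, each relu + 2x2 average pooling, then global mean+max
# pooling) followed by the fc-bn-relu-dropout-fc-relu dimensionality
# reduction head, and a C-way linear classifier head trained on
# pseudo-labels with inverse-cluster-size weights.

#' Build a model state for training
#'
#' Initialises the convolutional backbone, the dimensionality-reduction head,
#' the pseudo-label classifier head, the two graph-convolution layers and the
#' fusion-level prediction head (He-initialised weights, zero biases).
#'
#' @param inputDim integer (height, width, channels) of preprocessed images;
#'   height and width must be divisible by 8 (three pooling stages).
#' @param nClusters number of clusters C (output width of both heads).
#' @param espec an [EncoderSpec-class].
#' @param dcclMode if `TRUE`, the fusion head takes the Euclidean feature
#'   alone (graph branch ablated).
#' @return an opaque model state list (pass to the encode/loss/step
#'   functions).
#' @export
buildModel <- function(inputDim, nClusters, espec = encoderSpec(),
                       dcclMode = FALSE) {
  methods::validObject(espec)
  if (espec@backbone != "small_cnn") {
    configError(sprintf(
      "backbone '%s' is not available in this build; use 'small_cnn'",
      espec@backbone))
  }
  if (length(inputDim) != 3) {
    configError("inputDim must be (height, width, channels)")
  }
  if (inputDim[1] %% 8 != 0 || inputDim[2] %% 8 != 0) {
    configError("image height and width must be divisible by 8 for small_cnn")
  }
  ch <- espec@channels
  rawDim <- 2L * ch[3]   # global mean + max pooling per channel
  fd <- espec@featureDim
  dg <- espec@graphDim
  list(
    spec = espec, C = as.integer(nClusters), inputDim = as.integer(inputDim),
    dccl = isTRUE(dcclMode), version = 1L,
    conv1 = convInit(inputDim[3], ch[1]),
    conv2 = convInit(ch[1], ch[2]),
    conv3 = convInit(ch[2], ch[3]),
    fc1 = linearInit(rawDim, espec@hiddenDim),
    bn = bnInit(espec@hiddenDim),
    fc2 = linearInit(espec@hiddenDim, fd),
    clsHead = linearInit(fd, nClusters),
    gcn1 = linearInit(fd, dg, bias = FALSE),
    gcn2 = linearInit(dg, dg, bias = FALSE),
    fuseHead = linearInit(fd + if (dcclMode) 0L else dg, nClusters)
  )
}

fusedDim <- function(model) {
  model$spec@featureDim + if (model$dccl) 0L else model$spec@graphDim
}

# images: (h, w, ch, B) array -> backbone features before reduction
convStackForward <- function(model, x) {
  c1 <- convForward(model$conv1, x)
  r1 <- pmax(c1$y, 0)
  p1 <- avgPoolForward(r1)
  c2 <- convForward(model$conv2, p1)
  r2 <- pmax(c2$y, 0)
  p2 <- avgPoolForward(r2)
  c3 <- convForward(model$conv3, p2)
  r3 <- pmax(c3$y, 0)
  gp <- globalPoolForward(r3)
  list(raw = gp$y,
       cache = list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, c3 = c3, r3 = r3,
                    gp = gp))
}

# dimensionality-reduction head: fc - bn - relu - dropout - fc - relu
reduceDimForward <- function(model, raw, train) {
  z1 <- linearForward(model$fc1, raw)
  bn <- bnForward(model$bn, z1, train)
  a1 <- pmax(bn$y, 0)
  dr <- dropoutForward(a1, model$spec@dropoutRate, train)
  z2 <- linearForward(model$fc2, dr$y)
  h <- pmax(z2, 0)
  list(h = h, model = `[[<-`(model, "bn", bn$layer),
       cache = list(raw = raw, z1 = z1, bnc = bn$cache, a1 = a1,
                    mask = dr$mask, drY = dr$y, z2 = z2))
}

reduceDimBackward <- function(model, cache, dh) {
  dz2 <- dh * (cache$z2 > 0)
  g2 <- linearBackward(model$fc2, cache$drY, dz2)
  da1 <- if (is.null(cache$mask)) g2$dx else g2$dx * cache$mask
  dbnY <- da1 * (cache$a1 > 0)
  gb <- bnBackward(model$bn, cache$bnc, dbnY)
  g1 <- linearBackward(model$fc1, cache$raw, gb$dx)
  list(dRaw = g1$dx, fc1 = g1, bn = gb, fc2 = g2)
}

convStackBackward <- function(model, cache, dRaw) {
  dxr3 <- globalPoolBackward(cache$gp, dRaw)
  dc3 <- dxr3 * (cache$c3$y > 0)
  g3 <- convBackward(model$conv3, cache$c3, dc3)
  dp2 <- avgPoolBackward(g3$dx, dim(cache$r2))
  dc2 <- dp2 * (cache$c2$y > 0)
  g2 <- convBackward(model$conv2, cache$c2, dc2)
  dp1 <- avgPoolBackward(g2$dx, dim(cache$r1))
  dc1 <- dp1 * (cache$c1$y > 0)
  g1 <- convBackward(model$conv1, cache$c1, dc1)
  list(conv1 = g1, conv2 = g2, conv3 = g3)
}

# full Euclidean forward with caches (internal)
encoderForward <- function(model, x, train = FALSE) {
  cs <- convStackForward(model, x)
  rd <- reduceDimForward(model, cs$raw, train)
  list(h = rd$h, model = rd$model,
       cache = list(conv = cs$cache, head = rd$cache))
}

#' Encode images to Euclidean-level features
#'
#' Runs the convolutional backbone and the dimensionality-reduction head. In
#' inference mode (the default) dropout is off and batch statistics come from
#' running averages, so the output is deterministic for fixed weights.
#'
#' @param model a model state from [buildModel()].
#' @param images a [LabeledImageSet-class] or a (h, w, ch, B) array sized for
#'   the backbone.
#' @param train logical; training mode (dropout on, batch statistics).
#' @return B x featureDim numeric matrix (one row per image).
#' @export
encodeEuclidean <- function(model, images, train = FALSE) {
  x <- asImageArray(model, images)
  encoderForward(model, x, train = train)$h
}

asImageArray <- function(model, images) {
  x <- if (methods::is(images, "LabeledImageSet")) images@images else images
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d[1], d[2], 1L, d[3])
  d <- dim(x)
  if (!all(d[1:3] == model$inputDim)) {
    configError(sprintf(
      "images (%s) do not match the backbone input (%s)",
      paste(d[1:3], collapse = "x"),
      paste(model$inputDim, collapse = "x")))
  }
  x
}

#' Apply the dimensionality-reduction head to raw backbone features
#'
#' The head is the stack linear - batch-norm - relu - dropout - linear -
#' relu; outputs are therefore non-negative and have width
#' `featureDim`.
#'
#' @param model a model state from [buildModel()].
#' @param raw matrix of raw backbone features (width = backbone output
#'   width).
#' @param train logical; training mode (dropout active).
#' @return matrix with `featureDim` columns.
#' @export
reduceDim <- function(model, raw, train = FALSE) {
  if (ncol(raw) != nrow(model$fc1$W)) {
    configError(sprintf(
      "raw feature width %d does not match the backbone output width %d",
      ncol(raw), nrow(model$fc1$W)))
  }
  reduceDimForward(model, raw, train)$h
}

#' Weighted pseudo-label cross-entropy of the CNN branch
#'
#' Cross-entropy of the C-way linear classifier head on the Euclidean
#' features against the current pseudo-labels, each sample weighted by its
#' pseudo-class weight, averaged over the batch.
#'
#' @param model a model state from [buildModel()].
#' @param images image array or [LabeledImageSet-class] (batch of B).
#' @param pseudoLabels 0-based integer labels in `[0, C)`, length B.
#' @param classWeights per-class weights (length C); defaults to 1.
#' @param train logical; training-mode forward.
#' @return non-negative scalar loss.
#' @export
cnnClassifierLoss <- function(model, images, pseudoLabels,
                              classWeights = rep(1, model$C), train = FALSE) {
  h <- encodeEuclidean(model, images, train = train)
  logits <- linearForward(model$clsHead, h)
  weightedCeLoss(logits, as.integer(pseudoLabels), classWeights)$loss
}

# one SGD step on the CNN branch (Eq-1 loss); returns updated model, the
# loss value, and the batch's Euclidean features (treated as constant
# downstream)
cnnStep <- function(model, x, labels, w, lr, lambda, sgdMom) {
  fw <- encoderForward(model, x, train = TRUE)
  model <- fw$model
  h <- fw$h
  logits <- linearForward(model$clsHead, h)
  ce <- weightedCeLoss(logits, labels, w)
  dlogits <- lambda * ce$dlogits
  gHead <- linearBackward(model$clsHead, h, dlogits)
  gh <- reduceDimBackward(model, fw$cache$head, gHead$dx)
  gc <- convStackBackward(model, fw$cache$conv, gh$dRaw)
  model$clsHead <- sgdUpdate(model$clsHead, gHead$dW, gHead$db, lr, sgdMom)
  model$fc2 <- sgdUpdate(model$fc2, gh$fc2$dW, gh$fc2$db, lr, sgdMom)
  model$bn <- bnUpdate(model$bn, gh$bn$dgamma, gh$bn$dbeta, lr, sgdMom)
  model$fc1 <- sgdUpdate(model$fc1, gh$fc1$dW, gh$fc1$db, lr, sgdMom)
  model$conv3 <- sgdUpdate(model$conv3, gc$conv3$dW, gc$conv3$db, lr, sgdMom)
  model$conv2 <- sgdUpdate(model$conv2, gc$conv2$dW, gc$conv2$db, lr, sgdMom)
  model$conv1 <- sgdUpdate(model$conv1, gc$conv1$dW, gc$conv1$db, lr, sgdMom)
  list(model = model, loss = ce$loss, h = h)
}
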