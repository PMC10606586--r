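# Image loading, preprocessing and augmentation. Convention: images are
# numeric arrays (height, width, channels) with row-major 0-based pixel
# semantics and values in [0, 1]; crops use half-open intervals internally
# but are returned as plain sub-arrays.

# read a PNG/JPEG into an (h, w, ch) array in [0, 1]
readImageFile <- function(path) {
  if (!file.exists(path)) ioError(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else if (ext %in% c("jpg", "jpeg")) {
      jpeg::readJPEG(path)
    } else {
      # EBImage stores (x = column, y = row); transpose back to (row, col)
      e <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(e)) == 2) t(e) else aperm(e, c(2, 1, 3))
    }
  }, error = function(e) ioError(sprintf("cannot read %s: %s", path,
                                         conditionMessage(e))))
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  if (length(dim(img)) == 3 && dim(img)[3] == 4L) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  }
  clip01(img)
}

ensureHwc <- function(image) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  if (length(dim(image)) != 3) {
    validationError("image must be a matrix or (h, w, channels) array")
  }
  image
}

#' Crop away a dark border
#'
#' Returns the tight bounding box of pixels whose maximum channel intensity
#' exceeds `threshold`; used to remove the black surround of fundus
#' photographs before resizing.
#'
#' @param image numeric array (h, w, channels) or matrix, values in [0, 1].
#' @param threshold max-channel intensity defining "black" (default 0.02).
#' @return the cropped image (same channel count).
#' @export
cropBlackBorder <- function(image, threshold = 0.02) {
  image <- ensureHwc(image)
  maxchan <- apply(image, c(1, 2), max)
  keepRow <- which(apply(maxchan, 1, max) > threshold)
  keepCol <- which(apply(maxchan, 2, max) > threshold)
  if (!length(keepRow) || !length(keepCol)) {
    degenerateError("image is entirely below the black threshold; nothing to crop to")
  }
  image[min(keepRow):max(keepRow), min(keepCol):max(keepCol), , drop = FALSE]
}

# bilinear resize to size x size via EBImage (which is column-major)
resizeBilinear <- function(image, size) {
  image <- ensureHwc(image)
  d <- dim(image)
  if (d[1] == size && d[2] == size) return(image)
  e <- EBImage::Image(aperm(image, c(2, 1, 3)),
                      colormode = if (d[3] == 1) "Grayscale" else "Color")
  out <- EBImage::resize(e, w = size, h = size, filter = "bilinear")
  a <- EBImage::imageData(out)
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1L)
  clip01(aperm(a, c(2, 1, 3)))
}

# colour jitters; each acts on an (h, w, ch) array and clips back to [0, 1]
jitterBrightness <- function(img, f) clip01(img * f)
jitterContrast <- function(img, f) clip01((img - mean(img)) * f + mean(img))
jitterSaturation <- function(img, f) {
  if (dim(img)[3] != 3) return(img)
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  out <- img
  for (ch in 1:3) out[, , ch] <- gray + f * (img[, , ch] - gray)
  clip01(out)
}
jitterHue <- function(img, f) {
  if (dim(img)[3] != 3) return(img)
  d <- dim(img)
  rgb <- matrix(aperm(img, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] + f) %% 1
  col <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
  rgb2 <- grDevices::col2rgb(col) / 255
  aperm(array(rgb2, c(3, d[1], d[2])), c(2, 3, 1))
}

#' Preprocess (and optionally augment) one image
#'
#' Optionally crops dark borders, resizes to `targetSize` x `targetSize`
#' (bilinear), and — when `cfg@augment` is on — applies flips, right-angle
#' rotation and colour jitter, each independently with probability 1/2, with
#' jitter factors drawn uniformly from the configured ranges. Augmentation
#' draws come from R's RNG, so results are deterministic given the RNG state.
#'
#' @param image numeric (h, w, channels) array or matrix in [0, 1].
#' @param cfg a [PreprocessConfig-class].
#' @return numeric array (targetSize, targetSize, channels).
#' @export
preprocessImage <- function(image, cfg = preprocessConfig()) {
  image <- ensureHwc(image)
  if (cfg@cropBlack) {
    image <- tryCatch(cropBlackBorder(image, cfg@blackThreshold),
                      dgclDegenerateError = function(e) image)
  }
  image <- resizeBilinear(image, cfg@targetSize)
  if (cfg@augment) {
    if (cfg@hflip && stats::runif(1) < 0.5) {
      image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
    }
    if (cfg@vflip && stats::runif(1) < 0.5) {
      image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
    }
    if (cfg@rotate) {
      k <- sample(0:3, 1)
      for (r in seq_len(k)) {
        image <- aperm(image, c(2, 1, 3))[rev(seq_len(dim(image)[2])), , ,
                                          drop = FALSE]
      }
    }
    drawIn <- function(rng) stats::runif(1, rng[1], rng[2])
    if (stats::runif(1) < 0.5) {
      image <- jitterBrightness(image, drawIn(cfg@brightnessRange))
    }
    if (stats::runif(1) < 0.5) {
      image <- jitterContrast(image, drawIn(cfg@contrastRange))
    }
    if (dim(image)[3] == 3) {
      if (stats::runif(1) < 0.5) {
        image <- jitterSaturation(image, drawIn(cfg@saturationRange))
      }
      if (stats::runif(1) < 0.5) {
        image <- jitterHue(image, drawIn(cfg@hueRange))
      }
    }
  }
  image
}

#' Read a CSV image manifest
#'
#' @param path CSV with a header and columns `filename` and optionally
#'   `label`.
#' @return data.frame with `filename` (character) and `label` (integer,
#'   `NA` where absent).
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) ioError(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"filename" %in% names(df)) {
    configError("manifest must have a header with a 'filename' column")
  }
  if (nrow(df) == 0) configError("manifest is empty")
  lab <- if ("label" %in% names(df)) {
    suppressWarnings(as.integer(ifelse(df$label == "", NA, df$label)))
  } else {
    rep(NA_integer_, nrow(df))
  }
  data.frame(filename = df$filename, label = lab, stringsAsFactors = FALSE)
}

#' Load a dataset from a manifest of image files
#'
#' Reads every image named in the manifest (paths resolved relative to the
#' manifest's directory), preprocesses each with `cfg`, and returns them in
#' manifest order. Labels are optional; missing labels give an unlabelled
#' (unsupervised) set.
#'
#' @param manifestPath path to a `filename,label` CSV (header required).
#' @param cfg a [PreprocessConfig-class].
#' @return a [LabeledImageSet-class].
#' @export
loadDataset <- function(manifestPath, cfg = preprocessConfig()) {
  mf <- readManifest(manifestPath)
  base <- dirname(manifestPath)
  paths <- ifelse(file.exists(mf$filename), mf$filename,
                  file.path(base, mf$filename))
  missing <- !file.exists(paths)
  if (any(missing)) {
    ioError(sprintf("missing image file(s) in manifest rows: %s",
                    paste(sprintf("%d (%s)", which(missing),
                                  mf$filename[missing]), collapse = ", ")))
  }
  imgs <- lapply(paths, function(p) preprocessImage(readImageFile(p), cfg))
  chs <- vapply(imgs, function(a) dim(a)[3], integer(1))
  if (length(unique(chs)) > 1) {
    # promote grayscale to 3 channels when mixed
    imgs <- lapply(imgs, function(a) {
      if (dim(a)[3] == max(chs)) a else array(rep(a, max(chs)),
                                              c(dim(a)[1:2], max(chs)))
    })
  }
  arr <- array(0, dim = c(cfg@targetSize, cfg@targetSize, dim(imgs[[1]])[3],
                          length(imgs)))
  for (i in seq_along(imgs)) arr[, , , i] <- imgs[[i]]
  new("LabeledImageSet", images = arr, labels = mf$label)
}
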