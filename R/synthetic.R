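#' Synthetic grayscale image generator
#'
#' Renders seeded grayscale images in which the three characteristics control
#' three visually independent factors, mirroring the semantics of a real
#' radiology archive: the organ selects a centrally placed base shape
#' (anatomy), the modality selects a global appearance — background intensity
#' level plus a texture family (acquisition physics), and the disease selects
#' a local lesion motif: bright Gaussian blobs placed in the four interior
#' quadrants according to the bit pattern of the disease index (local
#' pathology). Every lesion site lies inside every organ shape, so the
#' disease factor never interacts with the organ mask.
#'
#' @param modality,organ,disease 1-based category indices
#'   (modality <= 6, organ <= 6, disease <= 15).
#' @param size image side in pixels (>= 16).
#' @param seed integer seed; rendering is fully deterministic given
#'   (indices, size, seed) and leaves the global RNG state untouched.
#' @param noiseLevel standard deviation of additive Gaussian noise in
#'   intensity units; the result is clipped to [0, 1].
#' @return size x size numeric matrix with values in [0, 1].
#' @examples
#' img <- renderImage(2, 2, 4, size = 32, seed = 1)
#' range(img)
#' @export
renderImage <- function(modality, organ, disease, size = 32L, seed = 1L,
                        noiseLevel = 0.05) {
  stopifnot(size >= 16, modality >= 1, organ >= 1, disease >= 1)
  if (modality > 6 || organ > 6 || disease > 15)
    stop("invalid index: the generator supports up to 6 modalities, ",
         "6 organs and 15 diseases")
  withSeed(mixSeed(seed, modality, organ, disease, size), {
    ax <- ((seq_len(size) - (size + 1) / 2) / size) * 2  # [-1, 1]
    xx <- matrix(ax, size, size, byrow = TRUE)           # column coordinate
    yy <- matrix(ax, size, size)                         # row coordinate
    img <- matrix(modalityBackground(modality, size), size, size)
    img <- img + modalityTexture(modality, xx, yy)
    mask <- organMask(organ, size)
    img <- img + 0.15 * mask
    img <- img + diseaseLesion(disease, xx, yy)
    img <- img + matrix(stats::rnorm(size * size, 0, noiseLevel), size, size)
    pmin(pmax(img, 0), 1)
  })
}

# per-modality background level: well separated steps of 0.08
modalityBackground <- function(modality, size) 0.08 + 0.08 * (modality - 1)

# per-modality global texture family (deterministic patterns, no RNG)
modalityTexture <- function(modality, xx, yy) {
  switch(modality,
         0.06 * xx,                                  # smooth lateral gradient
         0.08 * sin(yy * pi * 5),                    # horizontal bands
         0.08 * sin(xx * pi * 5),                    # vertical bands
         0.07 * sin((xx + yy) * pi * 4),             # diagonal grating
         0.07 * sin(xx * pi * 8) * sin(yy * pi * 8), # fine checker
         0.06 * cos(sqrt(xx^2 + yy^2) * pi * 6))     # concentric rings
}

#' Organ shape mask
#'
#' @param organ 1-based organ index (<= 6).
#' @param size image side in pixels.
#' @return size x size 0/1 matrix; 1 inside the organ shape. All shapes
#'   contain the four lesion quadrant sites at (+/-0.33, +/-0.33) in
#'   normalised coordinates.
#' @export
organMask <- function(organ, size) {
  ax <- ((seq_len(size) - (size + 1) / 2) / size) * 2
  xx <- matrix(ax, size, size, byrow = TRUE)
  yy <- matrix(ax, size, size)
  r <- sqrt(xx^2 + yy^2)
  m <- switch(organ,
              r <= 0.62,                                   # disc
              abs(xx) <= 0.62 & abs(yy) <= 0.45,           # wide rectangle
              r >= 0.28 & r <= 0.66,                       # annulus
              (abs(xx) <= 0.38 & abs(yy) <= 0.75) |
                (abs(yy) <= 0.38 & abs(xx) <= 0.75),       # thick cross
              abs(xx) + abs(yy) <= 0.80,                   # diamond
              (xx / 0.70)^2 + (yy / 0.42)^2 <= 1)          # ellipse
  m * 1
}

# lesion motif: bright blobs in quadrants selected by the disease bit pattern
diseaseLesion <- function(disease, xx, yy) {
  les <- matrix(0, nrow(xx), ncol(xx))
  centers <- list(c(-0.33, -0.33), c(-0.33, 0.33), c(0.33, -0.33),
                  c(0.33, 0.33))
  for (q in 1:4) {
    if (bitwAnd(disease, bitwShiftL(1L, q - 1L)) != 0L) {
      cy <- centers[[q]][1]; cx <- centers[[q]][2]
      les <- les + 0.35 * exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * 0.09^2))
    }
  }
  les
}

#' Synthetic dataset configuration
#'
#' @param dictionary a [LabelDictionary-class] declaring the label space and
#'   its valid combinations.
#' @param imageSize image side in pixels.
#' @param nPerCombination images rendered per valid combination (split across
#'   the three subsets).
#' @param splitFractions length-3 positive vector (train, gallery, query)
#'   summing to 1; stratification is per combination.
#' @param seed integer master seed.
#' @param noiseLevel additive Gaussian noise sd in intensity units.
#' @return a list of class "SyntheticConfig".
#' @export
syntheticConfig <- function(dictionary, imageSize = 32L,
                            nPerCombination = 160L,
                            splitFractions = c(train = 0.6, gallery = 0.3,
                                               query = 0.1),
                            seed = 1L, noiseLevel = 0.05) {
  stopifnot(length(splitFractions) == 3, all(splitFractions > 0),
            abs(sum(splitFractions) - 1) < 1e-8, nPerCombination >= 3,
            imageSize >= 16)
  structure(list(dictionary = dictionary, imageSize = as.integer(imageSize),
                 nPerCombination = as.integer(nPerCombination),
                 splitFractions = splitFractions, seed = as.integer(seed),
                 noiseLevel = noiseLevel),
            class = "SyntheticConfig")
}

#' Built-in radiology-style label space
#'
#' Five modalities (MRI, X-ray, CT, US, OCT), four organs (brain, chest,
#' breast, retina) and thirteen diseases, of which exactly fifteen
#' (modality, organ, disease) combinations are valid — e.g. brain MRI carries
#' the three tumour classes, chest is imaged by both X-ray and CT, and the
#' three "normal" findings are organ-specific.
#'
#' @return a [LabelDictionary-class] with lambda = 5, mu = 4, nu = 13 and 15
#'   valid combinations.
#' @export
defaultLabelDictionary <- function() {
  modalities <- c("MRI", "X-ray", "CT", "US", "OCT")
  organs <- c("brain", "chest", "breast", "retina")
  diseases <- c("glioma", "meningioma", "pituitary",
                "pneumonia", "covid", "normal-chest",
                "benign", "malignant", "normal-breast",
                "CNV", "DME", "drusen", "normal-retina")
  cmb <- rbind(
    data.frame(modality = "MRI", organ = "brain",
               disease = c("glioma", "meningioma", "pituitary")),
    data.frame(modality = "X-ray", organ = "chest",
               disease = c("pneumonia", "covid", "normal-chest")),
    data.frame(modality = "CT", organ = "chest",
               disease = c("covid", "normal-chest")),
    data.frame(modality = "US", organ = "breast",
               disease = c("benign", "malignant", "normal-breast")),
    data.frame(modality = "OCT", organ = "retina",
               disease = c("CNV", "DME", "drusen", "normal-retina")))
  labelDictionary(modalities, organs, diseases, cmb)
}

#' Default synthetic dataset configuration
#'
#' The built-in label space ([defaultLabelDictionary()]) at desk scale:
#' 32 x 32 images, 160 images per valid combination, split 60/30/10 into
#' train/gallery/query per combination.
#'
#' @param seed master seed.
#' @return a SyntheticConfig list.
#' @export
defaultSyntheticConfig <- function(seed = 1L) {
  syntheticConfig(defaultLabelDictionary(), seed = seed)
}

# per-combination split counts by largest remainder, so totals are exact
splitCounts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), c("train", "gallery", "query"))
}

#' Generate a synthetic dataset on disk
#'
#' Writes 8-bit grayscale PNGs plus a manifest CSV and the label dictionary
#' YAML. Splits are stratified per valid combination and are disjoint by
#' construction; the whole dataset is reproducible from the config seed.
#'
#' @param config a SyntheticConfig from [syntheticConfig()].
#' @param dir output directory (created if needed); images go to dir/images.
#' @return invisibly, the manifest data.frame (with paths relative to `dir`).
#' @export
generateDataset <- function(config, dir) {
  stopifnot(inherits(config, "SyntheticConfig"))
  imgDir <- file.path(dir, "images")
  dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(imgDir)) stop("cannot create output directory ", imgDir)
  dict <- config$dictionary
  cmb <- validCombinations(dict)
  counts <- splitCounts(config$nPerCombination, config$splitFractions)
  rows <- vector("list", nrow(cmb))
  k <- 0L
  for (ci in seq_len(nrow(cmb))) {
    m <- cmb[ci, 1]; o <- cmb[ci, 2]; d <- cmb[ci, 3]
    splits <- rep(c("train", "gallery", "query"), counts)
    ids <- sprintf("m%d_o%d_d%d_%04d", m, o, d, seq_along(splits))
    paths <- file.path("images", paste0(ids, ".png"))
    for (i in seq_along(splits)) {
      k <- k + 1L
      img <- renderImage(m, o, d, size = config$imageSize,
                         seed = config$seed + k,
                         noiseLevel = config$noiseLevel)
      png::writePNG(img, file.path(dir, paths[i]))
    }
    rows[[ci]] <- data.frame(
      id = ids, path = paths,
      modality = dict@modalities[m], organ = dict@organs[o],
      disease = dict@diseases[d], split = splits,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(dir, "manifest.csv"),
                comment = c("synthetic dataset",
                            "stratification: per-combination",
                            paste0("seed: ", config$seed)))
  writeLabelDictionary(dict, file.path(dir, "dictionary.yml"))
  invisible(manifest)
}

#' Load manifest images into an array
#'
#' @param manifest manifest data.frame.
#' @param dir base directory for relative image paths.
#' @param split optional split name to filter on.
#' @return list with `x`, an (H, W, 1, n) array of intensities in [0, 1],
#'   `ids`, and the filtered `manifest`.
#' @export
loadImages <- function(manifest, dir, split = NULL) {
  if (!is.null(split)) manifest <- manifest[manifest$split == split, ]
  n <- nrow(manifest)
  if (n == 0L) stop("no images selected")
  first <- png::readPNG(file.path(dir, manifest$path[1]))
  if (length(dim(first)) == 3L) first <- first[, , 1]
  H <- nrow(first); W <- ncol(first)
  x <- array(0, c(H, W, 1L, n))
  x[, , 1L, 1L] <- first
  if (n > 1L) for (i in 2:n) {
    im <- png::readPNG(file.path(dir, manifest$path[i]))
    if (length(dim(im)) == 3L) im <- im[, , 1]
    x[, , 1L, i] <- im
  }
  list(x = x, ids = manifest$id, manifest = manifest)
}
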