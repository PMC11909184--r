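#' @useDynLib modhash, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Structured hash-code layout
#'
#' A structured hash code of total length \eqn{K = K_1 + K_2 + K_3} is the
#' horizontal concatenation of three characteristic-specific sub-codes:
#' modality (first \eqn{K_1} bits), organ (next \eqn{K_2}), disease (last
#' \eqn{K_3}). Sub-code lengths are user-chosen, subject to
#' \eqn{K_1 > \lceil\log_2\lambda\rceil} (and likewise for organ and disease),
#' so that each sub-code can in principle separate its categories.
#'
#' @slot K1 integer, modality sub-code length in bits
#' @slot K2 integer, organ sub-code length in bits
#' @slot K3 integer, disease sub-code length in bits
#' @seealso [codeStructure()], [validateCodeStructure()]
#' @exportClass CodeStructure
setClass("CodeStructure",
         representation(K1 = "integer", K2 = "integer", K3 = "integer"))

setValidity("CodeStructure", function(object) {
  k <- c(object@K1, object@K2, object@K3)
  if (any(is.na(k)) || any(k < 1L))
    return("sub-code lengths K1, K2, K3 must be positive integers")
  TRUE
})

#' Construct a CodeStructure
#'
#' @param K1,K2,K3 sub-code lengths in bits for modality, organ, disease.
#' @return a [CodeStructure-class] object.
#' @examples
#' cs <- codeStructure(8, 8, 8)
#' codeLength(cs)
#' @export
codeStructure <- function(K1, K2, K3) {
  new("CodeStructure", K1 = as.integer(K1), K2 = as.integer(K2),
      K3 = as.integer(K3))
}

#' Dictionary of the characteristic label space
#'
#' Holds the category names for the three characteristics (imaging modality,
#' organ, disease) and the set of (modality, organ, disease) triples that
#' actually occur in the archive. Real radiology archives only realise a
#' sparse subset of the full product space (an OCT scan of a chest does not
#' exist), so valid combinations are declared explicitly.
#'
#' @slot modalities character vector of modality names (length lambda)
#' @slot organs character vector of organ names (length mu)
#' @slot diseases character vector of disease names (length nu)
#' @slot combinations integer matrix with columns modality, organ, disease:
#'   the valid triples, 1-based category indices.
#' @exportClass LabelDictionary
setClass("LabelDictionary",
         representation(modalities = "character", organs = "character",
                        diseases = "character", combinations = "matrix"))

setValidity("LabelDictionary", function(object) {
  cmb <- object@combinations
  if (ncol(cmb) != 3L) return("combinations must have 3 columns")
  if (nrow(cmb) < 1L) return("at least one valid combination is required")
  lims <- c(length(object@modalities), length(object@organs),
            length(object@diseases))
  if (any(lims < 2L)) return("each characteristic needs at least 2 categories")
  for (j in 1:3)
    if (any(cmb[, j] < 1L | cmb[, j] > lims[j]))
      return("combination index out of range")
  for (j in 1:3)
    if (!all(seq_len(lims[j]) %in% cmb[, j]))
      return(sprintf("every %s category must appear in a valid combination",
                     c("modality", "organ", "disease")[j]))
  if (anyDuplicated(cmb)) return("duplicate valid combination")
  TRUE
})

#' Construct a LabelDictionary
#'
#' @param modalities,organs,diseases character vectors of category names.
#' @param combinations a data.frame or matrix with columns
#'   `modality`, `organ`, `disease`; entries may be names or 1-based indices.
#' @return a [LabelDictionary-class].
#' @export
labelDictionary <- function(modalities, organs, diseases, combinations) {
  combinations <- as.data.frame(combinations)
  toIdx <- function(x, names) {
    if (is.numeric(x)) as.integer(x) else match(as.character(x), names)
  }
  cmb <- cbind(modality = toIdx(combinations$modality, modalities),
               organ    = toIdx(combinations$organ, organs),
               disease  = toIdx(combinations$disease, diseases))
  if (anyNA(cmb)) stop("unknown category name in combinations")
  storage.mode(cmb) <- "integer"
  new("LabelDictionary", modalities = as.character(modalities),
      organs = as.character(organs), diseases = as.character(diseases),
      combinations = cmb)
}

#' A set of structured binary hash codes
#'
#' Rows are images, columns are bits in \{-1, +1\}, with the column blocks
#' defined by the shared [CodeStructure-class].
#'
#' @slot codes numeric matrix in \{-1, 1\}, one row per image, K columns
#' @slot structure the shared [CodeStructure-class]
#' @slot ids character vector of image ids (unique, row-parallel)
#' @exportClass HashCodeSet
setClass("HashCodeSet",
         representation(codes = "matrix", structure = "CodeStructure",
                        ids = "character"))

setValidity("HashCodeSet", function(object) {
  K <- object@structure@K1 + object@structure@K2 + object@structure@K3
  if (ncol(object@codes) != K)
    return(sprintf("codes have %d columns but structure implies K = %d",
                   ncol(object@codes), K))
  if (length(object@ids) != nrow(object@codes))
    return("ids and code rows differ in length")
  if (anyDuplicated(object@ids)) return("duplicate image ids")
  if (nrow(object@codes) > 0 && !all(object@codes %in% c(-1, 1)))
    return("hash code entries must be -1 or +1")
  TRUE
})

#' Construct a HashCodeSet
#'
#' @param codes matrix in \{-1, 1\}, rows are images.
#' @param structure a [CodeStructure-class].
#' @param ids character image ids; defaults to rownames or seq numbers.
#' @export
hashCodeSet <- function(codes, structure, ids = NULL) {
  codes <- as.matrix(codes)
  if (is.null(ids)) {
    ids <- rownames(codes)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(codes)))
  }
  new("HashCodeSet", codes = codes, structure = structure,
      ids = as.character(ids))
}

#' Gallery index: codes plus characteristic labels
#'
#' The searchable archive: every gallery image's structured hash code together
#' with its (modality, organ, disease) label triple. Labels are used only for
#' evaluation — never to produce a code.
#'
#' @slot codes a [HashCodeSet-class]
#' @slot labels data.frame with integer columns modality, organ, disease,
#'   row-parallel to the codes.
#' @exportClass GalleryIndex
setClass("GalleryIndex",
         representation(codes = "HashCodeSet", labels = "data.frame"))

setValidity("GalleryIndex", function(object) {
  if (nrow(object@labels) != nrow(object@codes@codes))
    return("labels and codes differ in length")
  need <- c("modality", "organ", "disease")
  if (!all(need %in% names(object@labels)))
    return("labels need columns modality, organ, disease")
  TRUE
})

#' Construct a GalleryIndex
#'
#' @param codes a [HashCodeSet-class] of gallery codes.
#' @param labels data.frame with columns modality, organ, disease
#'   (1-based integer category indices), one row per gallery image.
#' @export
galleryIndex <- function(codes, labels) {
  labels <- as.data.frame(labels)[c("modality", "organ", "disease")]
  for (j in seq_along(labels)) labels[[j]] <- as.integer(labels[[j]])
  new("GalleryIndex", codes = codes, labels = labels)
}

#' The deep hashing model
#'
#' A convolutional encoder followed by three identical characteristic
#' sub-networks. Each sub-network maps the shared feature vector to a
#' classification logit vector and a sub-code feature vector; the tanh of the
#' code features, concatenated in (modality, organ, disease) order, is the
#' relaxed hash code, and its sign is the binary code.
#'
#' @slot config list produced by [modelConfig()] (with the traced encoder
#'   layer specification attached).
#' @slot params named list of weight arrays.
#' @exportClass ModHashModel
setClass("ModHashModel", representation(config = "list", params = "list"))

setMethod("show", "CodeStructure", function(object) {
  cat(sprintf("CodeStructure: K1=%d (modality) + K2=%d (organ) + K3=%d (disease) = K=%d bits\n",
              object@K1, object@K2, object@K3,
              object@K1 + object@K2 + object@K3))
})

setMethod("show", "LabelDictionary", function(object) {
  cat(sprintf("LabelDictionary: %d modalities x %d organs x %d diseases, %d valid combinations\n",
              length(object@modalities), length(object@organs),
              length(object@diseases), nrow(object@combinations)))
})

setMethod("show", "HashCodeSet", function(object) {
  cat(sprintf("HashCodeSet: %d codes of %d bits (%d+%d+%d)\n",
              nrow(object@codes), ncol(object@codes),
              object@structure@K1, object@structure@K2, object@structure@K3))
})

setMethod("show", "GalleryIndex", function(object) {
  cat(sprintf("GalleryIndex: %d gallery images, %d-bit structured codes\n",
              nrow(object@labels), ncol(object@codes@codes)))
})

setMethod("show", "ModHashModel", function(object) {
  cfg <- object@config
  cat(sprintf("ModHashModel (%s scale): input %dx%d, feature dim %d, heads (%d, %d, %d) classes, code %d+%d+%d bits\n",
              cfg$scale, cfg$inputSize, cfg$inputSize, cfg$featureDim,
              cfg$lambda, cfg$mu, cfg$nu,
              cfg$structure@K1, cfg$structure@K2, cfg$structure@K3))
})
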