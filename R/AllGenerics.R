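#' Total code length in bits
#' @param x a [CodeStructure-class] or [HashCodeSet-class]
#' @return integer K = K1 + K2 + K3
#' @export
setGeneric("codeLength", function(x) standardGeneric("codeLength"))

#' @rdname codeLength
setMethod("codeLength", "CodeStructure", function(x) x@K1 + x@K2 + x@K3)

#' @rdname codeLength
setMethod("codeLength", "HashCodeSet", function(x) codeLength(x@structure))

#' Extract the code matrix
#' @param x a [HashCodeSet-class] or [GalleryIndex-class]
#' @return numeric matrix in \{-1, 1\}
#' @export
setGeneric("hashCodes", function(x) standardGeneric("hashCodes"))

#' @rdname hashCodes
setMethod("hashCodes", "HashCodeSet", function(x) x@codes)

#' @rdname hashCodes
setMethod("hashCodes", "GalleryIndex", function(x) x@codes@codes)

#' Image ids of a code set or gallery
#' @param x a [HashCodeSet-class] or [GalleryIndex-class]
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
setMethod("sampleIds", "HashCodeSet", function(x) x@ids)

#' @rdname sampleIds
setMethod("sampleIds", "GalleryIndex", function(x) x@codes@ids)

#' Code structure of an object
#' @param x a [HashCodeSet-class], [GalleryIndex-class] or [ModHashModel-class]
#' @export
setGeneric("codeStructureOf", function(x) standardGeneric("codeStructureOf"))

#' @rdname codeStructureOf
setMethod("codeStructureOf", "HashCodeSet", function(x) x@structure)

#' @rdname codeStructureOf
setMethod("codeStructureOf", "GalleryIndex", function(x) x@codes@structure)

#' @rdname codeStructureOf
setMethod("codeStructureOf", "ModHashModel", function(x) x@config$structure)

#' Characteristic labels of a gallery
#' @param x a [GalleryIndex-class]
#' @return data.frame with integer columns modality, organ, disease
#' @export
setGeneric("galleryLabels", function(x) standardGeneric("galleryLabels"))

#' @rdname galleryLabels
setMethod("galleryLabels", "GalleryIndex", function(x) x@labels)

#' Number of categories per characteristic
#' @param x a [LabelDictionary-class]
#' @return named integer vector c(lambda=, mu=, nu=)
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname categoryCounts
setMethod("categoryCounts", "LabelDictionary", function(x) {
  c(lambda = length(x@modalities), mu = length(x@organs),
    nu = length(x@diseases))
})

#' Valid (modality, organ, disease) combinations
#' @param x a [LabelDictionary-class]
#' @return integer matrix with columns modality, organ, disease
#' @export
setGeneric("validCombinations", function(x) standardGeneric("validCombinations"))

#' @rdname validCombinations
setMethod("validCombinations", "LabelDictionary", function(x) x@combinations)
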