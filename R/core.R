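#' Pairwise semantic similarity of two label triples
#'
#' Two images are semantically similar (s = 1) only when all three
#' characteristics — modality, organ and disease — agree; any mismatch gives
#' s = 0. This is the supervision signal for the pairwise Cauchy loss.
#'
#' @param a,b label triples: named vectors/lists with elements
#'   `modality`, `organ`, `disease` (1-based integer indices), or
#'   single-row data.frames.
#' @return integer 0 or 1.
#' @examples
#' pairSimilarity(c(modality = 2, organ = 2, disease = 4),
#'                c(modality = 2, organ = 2, disease = 4))  # 1
#' pairSimilarity(c(modality = 2, organ = 2, disease = 4),
#'                c(modality = 2, organ = 2, disease = 5))  # 0
#' @export
pairSimilarity <- function(a, b) {
  a <- asLabelTriple(a); b <- asLabelTriple(b)
  as.integer(a[["modality"]] == b[["modality"]] &&
             a[["organ"]] == b[["organ"]] &&
             a[["disease"]] == b[["disease"]])
}

asLabelTriple <- function(x) {
  if (is.data.frame(x)) x <- unlist(x[1, c("modality", "organ", "disease")])
  x <- unlist(x)
  need <- c("modality", "organ", "disease")
  if (!all(need %in% names(x))) {
    if (length(x) == 3L) names(x) <- need
    else stop("label triple needs modality, organ, disease")
  }
  x[need]
}

#' Pairwise similarity matrix for a batch of labels
#'
#' @param labels data.frame with integer columns modality, organ, disease.
#' @return n x n 0/1 matrix, 1 where all three characteristics agree.
#' @export
pairSimilarityMatrix <- function(labels) {
  m <- outer(labels$modality, labels$modality, "==")
  o <- outer(labels$organ, labels$organ, "==")
  d <- outer(labels$disease, labels$disease, "==")
  (m & o & d) * 1L
}

#' One-hot encoding of a category index
#'
#' @param index 1-based category index (vectorised).
#' @param n number of categories.
#' @return if `index` has length 1 a 0/1 vector of length n, else a
#'   length(index) x n 0/1 matrix.
#' @export
oneHot <- function(index, n) {
  index <- as.integer(index)
  if (any(index < 1L | index > n)) stop("category index out of range")
  out <- matrix(0L, length(index), n)
  out[cbind(seq_along(index), index)] <- 1L
  if (length(index) == 1L) out[1, ] else out
}

#' Validate sub-code lengths against category counts
#'
#' A sub-code must be longer than the information-theoretic floor for its
#' characteristic: \eqn{K_1 > \lceil\log_2\lambda\rceil},
#' \eqn{K_2 > \lceil\log_2\mu\rceil}, \eqn{K_3 > \lceil\log_2\nu\rceil}.
#'
#' @param lambda,mu,nu category counts (each >= 2).
#' @param structure a [CodeStructure-class].
#' @return `TRUE` if valid, otherwise `FALSE` with attribute `"reason"`
#'   naming the offending sub-code(s).
#' @examples
#' validateCodeStructure(5, 4, 13, codeStructure(8, 8, 8))   # TRUE
#' validateCodeStructure(5, 4, 13, codeStructure(3, 8, 8))   # FALSE: modality
#' @export
validateCodeStructure <- function(lambda, mu, nu, structure) {
  stopifnot(lambda >= 2, mu >= 2, nu >= 2)
  floors <- ceiling(log2(c(lambda, mu, nu)))
  ks <- c(structure@K1, structure@K2, structure@K3)
  bad <- which(!(ks > floors))
  if (length(bad) == 0L) return(TRUE)
  who <- c("modality (K1)", "organ (K2)", "disease (K3)")[bad]
  reason <- sprintf("%s sub-code length %d is not > ceil(log2(%d)) = %d",
                    who, ks[bad], c(lambda, mu, nu)[bad], floors[bad])
  structure(FALSE, reason = reason)
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with header `id,path,modality,organ,disease,split`;
#' labels are human-readable category names, `split` is one of train,
#' gallery, query. Lines starting with `#` are comments.
#'
#' @param path path to the manifest CSV.
#' @return data.frame with character columns.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "path", "modality", "organ", "disease", "split")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  m[need]
}

#' Write a dataset manifest
#' @param manifest data.frame as returned by [readManifest()].
#' @param path output CSV path.
#' @param comment optional comment line(s) written as a `#` header.
#' @export
writeManifest <- function(manifest, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(manifest, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a dataset manifest
#'
#' Checks that the three splits are pairwise disjoint by image id, that every
#' label is a known category forming a declared valid combination, and
#' (optionally) that every image file exists.
#'
#' @param manifest data.frame from [readManifest()].
#' @param dictionary a [LabelDictionary-class].
#' @param dir base directory that relative image paths are resolved against.
#' @param checkFiles logical, verify image files exist.
#' @return invisibly, named integer counts `c(train=, gallery=, query=)`
#'   (U1, U2, U3). Errors describe the first violation found.
#' @export
validateManifest <- function(manifest, dictionary, dir = ".",
                             checkFiles = TRUE) {
  if (anyDuplicated(manifest$id)) {
    dup <- manifest$id[duplicated(manifest$id)][1]
    splits <- unique(manifest$split[manifest$id == dup])
    if (length(splits) > 1L)
      stop("overlapping splits: id '", dup, "' appears in ",
           paste(splits, collapse = " and "))
    stop("duplicate id '", dup, "' within split ", splits)
  }
  if (!all(manifest$split %in% c("train", "gallery", "query")))
    stop("split must be one of train, gallery, query")
  idx <- manifestLabels(manifest, dictionary)  # errors on unknown labels
  cmb <- validCombinations(dictionary)
  key <- paste(idx$modality, idx$organ, idx$disease)
  okKey <- paste(cmb[, 1], cmb[, 2], cmb[, 3])
  if (!all(key %in% okKey)) {
    bad <- which(!(key %in% okKey))[1]
    stop("label combination (", manifest$modality[bad], ", ",
         manifest$organ[bad], ", ", manifest$disease[bad],
         ") is not in the declared valid set")
  }
  if (checkFiles) {
    paths <- file.path(dir, manifest$path)
    miss <- !file.exists(paths)
    if (any(miss)) stop("missing image file: ", paths[which(miss)[1]])
  }
  counts <- c(train = sum(manifest$split == "train"),
              gallery = sum(manifest$split == "gallery"),
              query = sum(manifest$split == "query"))
  invisible(counts)
}

#' Map manifest label names to integer indices
#'
#' @param manifest data.frame with character columns modality, organ, disease
#'   (names or numeric strings).
#' @param dictionary a [LabelDictionary-class].
#' @return data.frame with integer columns modality, organ, disease.
#' @export
manifestLabels <- function(manifest, dictionary) {
  mapOne <- function(x, names, what) {
    idx <- match(x, names)
    num <- suppressWarnings(as.integer(x))
    idx[is.na(idx) & !is.na(num)] <- num[is.na(idx) & !is.na(num)]
    if (anyNA(idx) || any(idx < 1L | idx > length(names), na.rm = TRUE))
      stop("label out of range: unknown ", what, " '",
           x[which(is.na(idx) | idx < 1L | idx > length(names))[1]], "'")
    idx
  }
  data.frame(
    modality = mapOne(manifest$modality, dictionary@modalities, "modality"),
    organ    = mapOne(manifest$organ, dictionary@organs, "organ"),
    disease  = mapOne(manifest$disease, dictionary@diseases, "disease"))
}

#' Read/write a label dictionary as YAML
#'
#' The on-disk form lists the category names per characteristic and the valid
#' combinations by name.
#'
#' @param path YAML file path.
#' @return [readLabelDictionary()]: a [LabelDictionary-class].
#' @export
readLabelDictionary <- function(path) {
  y <- yaml::read_yaml(path)
  cmb <- do.call(rbind, lapply(y$valid_combinations, function(r)
    data.frame(modality = r[[1]], organ = r[[2]], disease = r[[3]])))
  labelDictionary(y$modalities, y$organs, y$diseases, cmb)
}

#' @rdname readLabelDictionary
#' @param dictionary a [LabelDictionary-class] to write.
#' @export
writeLabelDictionary <- function(dictionary, path) {
  cmb <- validCombinations(dictionary)
  yaml::write_yaml(list(
    modalities = dictionary@modalities,
    organs = dictionary@organs,
    diseases = dictionary@diseases,
    valid_combinations = lapply(seq_len(nrow(cmb)), function(i)
      list(dictionary@modalities[cmb[i, 1]],
           dictionary@organs[cmb[i, 2]],
           dictionary@diseases[cmb[i, 3]]))), path)
  invisible(path)
}

# run code under a temporary RNG seed, restoring global RNG state after
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-bit seed mixer for per-image rendering
mixSeed <- function(seed, ...) {
  v <- c(seed %% 1e6, ...)
  acc <- 0
  for (x in v) acc <- (acc * 1103 + as.numeric(x) * 7919 + 13) %% 2147483647
  as.integer(acc)
}
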