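#' Relax code features into [-1, 1]
#'
#' Elementwise hyperbolic tangent, the training-time surrogate for the sign
#' function (sign has zero gradient almost everywhere; tanh does not).
#'
#' @param z numeric vector or matrix of code features.
#' @return tanh(z), same shape, entries strictly inside (-1, 1) for finite z.
#' @export
relaxCode <- function(z) {
  if (any(!is.finite(z))) stop("non-finite code feature")
  tanh(z)
}

#' Binarize a relaxed code
#'
#' Elementwise sign with the fixed tie rule sign(0) := +1, so encoding is
#' deterministic. Idempotent on already-binary codes.
#'
#' @param h numeric vector or matrix with entries in [-1, 1] (any finite
#'   values are accepted; only the sign matters).
#' @return same shape, entries in \{-1, 1\}.
#' @export
binarizeCode <- function(h) {
  out <- ifelse(h >= 0, 1, -1)
  if (!is.null(dim(h))) dim(out) <- dim(h)
  out
}

#' Concatenate three sub-codes into a full structured code
#'
#' Order is fixed as (modality, organ, disease). Works on vectors (one code)
#' or row-parallel matrices.
#'
#' @param h1,h2,h3 modality, organ and disease sub-codes.
#' @param structure optional [CodeStructure-class] to check lengths against.
#' @return the concatenated code (vector or matrix).
#' @export
concatCodes <- function(h1, h2, h3, structure = NULL) {
  toM <- function(h) if (is.null(dim(h))) matrix(h, nrow = 1) else h
  m1 <- toM(h1); m2 <- toM(h2); m3 <- toM(h3)
  if (!is.null(structure) &&
      (ncol(m1) != structure@K1 || ncol(m2) != structure@K2 ||
       ncol(m3) != structure@K3))
    stop("sub-code lengths do not match the code structure")
  out <- cbind(m1, m2, m3)
  if (is.null(dim(h1))) out[1, ] else out
}

subcodeRange <- function(structure, characteristic) {
  k <- match(characteristic, c("modality", "organ", "disease"))
  if (is.na(k)) stop("unknown characteristic '", characteristic, "'")
  starts <- c(0L, structure@K1, structure@K1 + structure@K2)
  lens <- c(structure@K1, structure@K2, structure@K3)
  seq.int(starts[k] + 1L, starts[k] + lens[k])
}

#' Slice one characteristic's sub-code out of a full code
#'
#' @param code full code: vector, matrix (rows = images), or
#'   [HashCodeSet-class].
#' @param characteristic `"modality"`, `"organ"` or `"disease"`.
#' @param structure the [CodeStructure-class]; taken from the object when
#'   `code` is a HashCodeSet.
#' @return the sub-code segment (same container kind as the input; a
#'   HashCodeSet input returns the sub-code matrix).
#' @export
subcodeSlice <- function(code, characteristic, structure = NULL) {
  if (is(code, "HashCodeSet")) {
    structure <- code@structure
    code <- code@codes
  }
  if (is.null(structure)) stop("a CodeStructure is required")
  idx <- subcodeRange(structure, characteristic)
  if (is.null(dim(code))) {
    if (length(code) != codeLength(structure))
      stop("code length does not match structure")
    code[idx]
  } else {
    if (ncol(code) != codeLength(structure))
      stop("code length does not match structure")
    code[, idx, drop = FALSE]
  }
}

#' Write / read a hash-code store
#'
#' One CSV per split with header `id,bits`, where bits is a string over
#' \{+, -\} of length K, plus a sidecar YAML (`<path>.yml`) recording
#' (K1, K2, K3). Round-trips are bit exact.
#'
#' @param codes a [HashCodeSet-class].
#' @param path output CSV path.
#' @export
writeCodes <- function(codes, path) {
  bits <- apply(codes@codes, 1, function(r)
    paste(ifelse(r > 0, "+", "-"), collapse = ""))
  utils::write.csv(data.frame(id = codes@ids, bits = bits), path,
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(K1 = codes@structure@K1, K2 = codes@structure@K2,
                        K3 = codes@structure@K3), paste0(path, ".yml"))
  invisible(path)
}

#' @rdname writeCodes
#' @return [readCodes()]: the restored [HashCodeSet-class].
#' @export
readCodes <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  y <- yaml::read_yaml(paste0(path, ".yml"))
  cs <- codeStructure(y$K1, y$K2, y$K3)
  mat <- t(vapply(strsplit(df$bits, ""), function(ch)
    ifelse(ch == "+", 1, -1), numeric(codeLength(cs))))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1)
  hashCodeSet(mat, cs, df$id)
}
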