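#' Hamming distance between two structured codes
#'
#' Integer count of mismatching positions, computed by direct comparison of
#' the bit vectors (the cosine identity d = (K/2)(1 - cos) is an algebraic
#' equivalence on \{-1, 1\} codes, and is kept as a test, not the
#' implementation).
#'
#' @param b1,b2 codes in \{-1, 1\} of equal length.
#' @return integer in [0, K].
#' @export
hammingDistance <- function(b1, b2) {
  if (length(b1) != length(b2)) stop("code structure mismatch")
  sum(b1 != b2)
}

# query x gallery integer Hamming distance matrix via one crossproduct:
# for +/-1 codes, mismatches = (K - <q, g>) / 2 (exact in double arithmetic)
hammingDistanceMatrix <- function(Q, G) {
  K <- ncol(Q)
  stopifnot(ncol(G) == K)
  (K - tcrossprod(Q, G)) / 2
}

#' Rank the gallery against a query code
#'
#' `mode = "full"` ranks by the full-code Hamming distance; a characteristic
#' mode ranks by that characteristic's sub-code distance only. Ties are
#' broken by gallery insertion order (stable), then the list is truncated at
#' p.
#'
#' @param queryCode numeric code vector (length K) or 1-row matrix.
#' @param index a [GalleryIndex-class].
#' @param p number of items to return (1 <= p <= gallery size).
#' @param mode `"full"`, `"modality"`, `"organ"` or `"disease"`.
#' @param queryId optional id recorded in the result.
#' @return list of class "RetrievalResult" with `queryId`, `rankedIds`,
#'   `rankedIdx` (gallery row numbers), `distances` (non-decreasing) and
#'   `mode`.
#' @export
rankGallery <- function(queryCode, index, p,
                        mode = c("full", "modality", "organ", "disease"),
                        queryId = NA_character_) {
  mode <- match.arg(mode)
  G <- hashCodes(index)
  if (nrow(G) == 0L) stop("empty gallery")
  if (p < 1L || p > nrow(G)) stop("p must be in [1, gallery size]")
  q <- as.numeric(queryCode)
  if (length(q) != ncol(G)) stop("code structure mismatch")
  cs <- codeStructureOf(index)
  if (mode != "full") {
    idx <- subcodeRange(cs, mode)
    q <- q[idx]
    G <- G[, idx, drop = FALSE]
  }
  d <- as.integer(round((length(q) - as.numeric(G %*% q)) / 2))
  ord <- order(d)  # radix sort on integers: stable, ties keep input order
  ord <- ord[seq_len(p)]
  structure(list(queryId = queryId, rankedIds = sampleIds(index)[ord],
                 rankedIdx = ord, distances = d[ord], mode = mode),
            class = "RetrievalResult")
}

#' Write retrieval results as TSV
#'
#' Columns: query_id, rank, gallery_id, distance.
#'
#' @param results a RetrievalResult or list of them.
#' @param path output TSV path.
#' @export
writeRetrievalResults <- function(results, path) {
  if (inherits(results, "RetrievalResult")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(r)
    data.frame(query_id = r$queryId, rank = seq_along(r$rankedIds),
               gallery_id = r$rankedIds, distance = r$distances)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
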