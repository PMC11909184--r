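#' Characteristic specs for evaluation
#'
#' The seven evaluation cases: single characteristics M, O, D, pairs MO, MD,
#' OD, and the full triple MOD.
#'
#' @param spec one of "M", "O", "D", "MO", "MD", "OD", "MOD".
#' @return character vector of required characteristics.
#' @export
characteristicSpec <- function(spec) {
  map <- list(M = "modality", O = "organ", D = "disease",
              MO = c("modality", "organ"), MD = c("modality", "disease"),
              OD = c("organ", "disease"),
              MOD = c("modality", "organ", "disease"))
  out <- map[[spec]]
  if (is.null(out)) stop("unknown characteristic spec '", spec, "'")
  out
}

#' Binary relevance for mAP
#'
#' 1 iff ALL characteristics in the spec match between a retrieved item and
#' the query (so for MOD this is full-label equality); else 0.
#'
#' @param yr,yq label triples (named vectors or 1-row data.frames).
#' @param spec spec string (see [characteristicSpec()]) or a character vector
#'   of characteristics.
#' @return integer 0 or 1.
#' @export
relevanceMap <- function(yr, yq, spec = "MOD") {
  chars <- if (length(spec) == 1L && !spec %in%
               c("modality", "organ", "disease"))
    characteristicSpec(spec) else spec
  if (!all(chars %in% c("modality", "organ", "disease")))
    stop("unknown characteristic spec")
  yr <- asLabelTriple(yr); yq <- asLabelTriple(yq)
  as.integer(all(yr[chars] == yq[chars]))
}

#' Graded relevance gain for nDCG
#'
#' V = the number of characteristics in the spec that match, so V ranges over
#' \{0, ..., |spec|\}: \{0,1,2,3\} for MOD, \{0,1,2\} for pairs, \{0,1\} for
#' singles.
#'
#' @inheritParams relevanceMap
#' @return integer gain.
#' @export
relevanceNdcg <- function(yr, yq, spec = "MOD") {
  chars <- if (length(spec) == 1L && !spec %in%
               c("modality", "organ", "disease"))
    characteristicSpec(spec) else spec
  if (!all(chars %in% c("modality", "organ", "disease")))
    stop("unknown characteristic spec")
  yr <- asLabelTriple(yr); yq <- asLabelTriple(yq)
  as.integer(sum(yr[chars] == yq[chars]))
}

#' Average precision over a top-p relevance sequence
#'
#' AP@p = sum_r P(r) R(r) / sum_r R(r) with P(r) the precision of the top-r
#' prefix. When the top-p window holds no relevant item the ratio is 0/0 and
#' AP is defined as 0 (the standard convention).
#'
#' @param relevances binary 0/1 vector, ranked order, length p.
#' @return AP in [0, 1].
#' @examples
#' averagePrecisionAtP(c(1, 0, 1))  # (1 + 2/3) / 2
#' @export
averagePrecisionAtP <- function(relevances) {
  stopifnot(all(relevances %in% c(0, 1)))
  nrel <- sum(relevances)
  if (nrel == 0) return(0)
  prec <- cumsum(relevances) / seq_along(relevances)
  sum(prec * relevances) / nrel
}

#' Discounted cumulative gain
#'
#' DCG@p = sum_r (2^V(r) - 1) / log2(r + 1), base-2 logarithm.
#'
#' @param gains nonnegative integer gain vector, ranked order.
#' @return DCG >= 0.
#' @examples
#' dcgAtP(c(3, 0, 1))  # 7 + 0 + 1/2
#' @export
dcgAtP <- function(gains) {
  stopifnot(all(gains >= 0))
  if (length(gains) == 0L) return(0)
  sum((2^gains - 1) / log2(seq_along(gains) + 1))
}

#' Normalized DCG
#'
#' DCG of the ranked gains divided by the DCG of the same gains sorted
#' descending (the ideal ordering). When the ideal DCG is 0 — the window
#' holds no relevant item at all — any ordering is ideal and nDCG is defined
#' as 1.
#'
#' @param gains nonnegative integer gain vector, ranked order.
#' @return nDCG in [0, 1].
#' @export
ndcgAtP <- function(gains) {
  ideal <- dcgAtP(sort(gains, decreasing = TRUE))
  if (ideal == 0) return(1)
  dcgAtP(gains) / ideal
}

#' Characteristic-specific retrieval evaluation
#'
#' For every query, ranks the gallery by Hamming distance (full code, or one
#' characteristic's sub-code), then scores the top-p ranked labels under each
#' characteristic spec: binary all-match relevance for mAP and graded
#' match-count gains for nDCG. Reported values are means over the query set.
#'
#' @param queryCodes a [HashCodeSet-class] of query codes (same structure as
#'   the gallery).
#' @param queryLabels data.frame with integer columns modality, organ,
#'   disease, row-parallel to `queryCodes`.
#' @param index a [GalleryIndex-class].
#' @param specs character vector of spec names (default all seven).
#' @param pList integer vector of retrieval depths.
#' @param mode ranking mode passed to the distance computation: `"full"`
#'   (Case-I) or a single characteristic's sub-code (Case-II).
#' @return data.frame of class "EvaluationReport" with columns spec, p, mAP,
#'   nDCG and attribute `perQuery` (list of per-query AP and nDCG matrices).
#' @export
evaluateRetrieval <- function(queryCodes, queryLabels, index,
                              specs = c("M", "O", "D", "MO", "MD", "OD",
                                        "MOD"),
                              pList = c(10L),
                              mode = c("full", "modality", "organ",
                                       "disease")) {
  mode <- match.arg(mode)
  nq <- nrow(hashCodes(queryCodes))
  if (nq == 0L) stop("empty query set")
  stopifnot(nrow(queryLabels) == nq)
  cs <- codeStructureOf(index)
  if (codeLength(queryCodes) != codeLength(cs))
    stop("query and gallery code structures differ")
  Q <- hashCodes(queryCodes)
  G <- hashCodes(index)
  if (mode != "full") {
    idx <- subcodeRange(cs, mode)
    Q <- Q[, idx, drop = FALSE]
    G <- G[, idx, drop = FALSE]
  }
  pList <- as.integer(pList)
  if (any(pList < 1L | pList > nrow(G)))
    stop("p must be within [1, gallery size]")
  D <- hammingDistanceMatrix(Q, G)
  gl <- galleryLabels(index)
  pmax_ <- max(pList)
  # per-query AP/nDCG arrays: [query, spec, p]
  ap <- array(0, c(nq, length(specs), length(pList)),
              dimnames = list(NULL, specs, pList))
  nd <- ap
  for (qi in seq_len(nq)) {
    ord <- order(as.integer(D[qi, ]))[seq_len(pmax_)]  # stable on ties
    rm_ <- gl$modality[ord] == queryLabels$modality[qi]
    ro <- gl$organ[ord] == queryLabels$organ[qi]
    rd <- gl$disease[ord] == queryLabels$disease[qi]
    matches <- cbind(modality = rm_, organ = ro, disease = rd)
    for (si in seq_along(specs)) {
      chars <- characteristicSpec(specs[si])
      sub <- matches[, chars, drop = FALSE]
      rel <- as.integer(rowSums(sub) == length(chars))
      gain <- as.integer(rowSums(sub))
      for (pi in seq_along(pList)) {
        p <- pList[pi]
        ap[qi, si, pi] <- averagePrecisionAtP(rel[seq_len(p)])
        nd[qi, si, pi] <- ndcgAtP(gain[seq_len(p)])
      }
    }
  }
  rows <- expand.grid(spec = specs, p = pList, stringsAsFactors = FALSE)
  rows$mAP <- mapply(function(s, p)
    mean(ap[, s, as.character(p)]), rows$spec, rows$p)
  rows$nDCG <- mapply(function(s, p)
    mean(nd[, s, as.character(p)]), rows$spec, rows$p)
  attr(rows, "perQuery") <- list(AP = ap, nDCG = nd)
  class(rows) <- c("EvaluationReport", class(rows))
  rows
}

#' Write an evaluation report as CSV
#'
#' @param report from [evaluateRetrieval()].
#' @param path output CSV path.
#' @export
writeEvaluationReport <- function(report, path) {
  utils::write.csv(as.data.frame(report)[c("spec", "p", "mAP", "nDCG")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
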