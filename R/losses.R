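#' Loss configuration
#'
#' @param gamma Cauchy scale; the predicted similarity of a pair at Hamming
#'   distance d is gamma / (gamma + d), so gamma is the distance at which
#'   predicted similarity crosses 0.5. Default K/4 when a code length is
#'   supplied.
#' @param alpha quantization weight (default 0.01).
#' @param lossSubset which losses are active, a subset of
#'   c("L1", "L2", "L3"); used by the ablation protocol.
#' @param K optional total code length, used for the gamma default.
#' @return list of class "LossConfig".
#' @export
lossConfig <- function(gamma = NULL, alpha = 0.01,
                       lossSubset = c("L1", "L2", "L3"), K = NULL) {
  if (is.null(gamma)) {
    if (is.null(K)) stop("supply gamma or K (gamma defaults to K/4)")
    gamma <- K / 4
  }
  stopifnot(gamma > 0, alpha >= 0,
            all(lossSubset %in% c("L1", "L2", "L3")))
  structure(list(gamma = gamma, alpha = alpha, lossSubset = lossSubset),
            class = "LossConfig")
}

softmaxRows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Characteristic-specific classification loss (L1)
#'
#' Sum of the three per-characteristic cross-entropies J1 + J2 + J3, each the
#' cross-entropy of softmax(logits) against the true category, averaged over
#' the batch.
#'
#' @param logitsTriple list of three logit matrices (modality, organ,
#'   disease), each n x nclass; vectors are treated as single samples.
#' @param labels data.frame (or single triple) with columns/elements
#'   modality, organ, disease — 1-based true category indices.
#' @return nonnegative scalar (nats).
#' @export
classificationLoss <- function(logitsTriple, labels) {
  if (!is.data.frame(labels))
    labels <- as.data.frame(as.list(asLabelTriple(labels)))
  total <- 0
  for (k in 1:3) {
    lg <- logitsTriple[[k]]
    if (is.null(dim(lg))) lg <- matrix(lg, nrow = 1)
    y <- labels[[c("modality", "organ", "disease")[k]]]
    if (any(y < 1L | y > ncol(lg))) stop("label out of range")
    p <- softmaxRows(lg)
    total <- total + mean(-log(pmax(p[cbind(seq_len(nrow(lg)), y)], 1e-300)))
  }
  total
}

#' Continuous Hamming distance
#'
#' d = (K/2)(1 - cos(hi, hj)). On binary codes this equals the integer
#' mismatch count exactly; on relaxed codes it is the training-time distance.
#'
#' @param hi,hj equal-length numeric vectors with nonzero norm.
#' @return distance in [0, K].
#' @export
continuousHamming <- function(hi, hj) {
  stopifnot(length(hi) == length(hj))
  ni <- sqrt(sum(hi^2)); nj <- sqrt(sum(hj^2))
  if (ni == 0 || nj == 0) stop("zero-norm code")
  K <- length(hi)
  (K / 2) * (1 - sum(hi * hj) / (ni * nj))
}

#' Cauchy similarity
#'
#' Heavy-tailed map from distance to a predicted pair-similarity probability:
#' s-hat = gamma / (gamma + d).
#'
#' @param hi,hj codes (relaxed or binary).
#' @param gamma Cauchy scale > 0.
#' @return value in (0, 1]; 1 at distance 0, 0.5 at d = gamma.
#' @export
cauchySimilarity <- function(hi, hj, gamma) {
  stopifnot(gamma > 0)
  gamma / (gamma + continuousHamming(hi, hj))
}

#' Pairwise Cauchy cross-entropy loss (L2) for one pair
#'
#' Binary cross-entropy between the supervision s and the Cauchy similarity:
#' -[s log(s-hat) + (1-s) log(1 - s-hat)]. For s in \{0, 1\} this equals
#' s log(d/gamma) + log(1 + gamma/d). The distance is floored at
#' `epsilon` inside the logarithms so the loss stays finite at d = 0.
#'
#' @param hi,hj codes.
#' @param s pair similarity, 0 or 1.
#' @param gamma Cauchy scale > 0.
#' @param epsilon distance floor (default 1e-6).
#' @return nonnegative loss (nats).
#' @export
cauchyLoss <- function(hi, hj, s, gamma, epsilon = 1e-6) {
  stopifnot(s %in% c(0, 1), gamma > 0)
  d <- max(continuousHamming(hi, hj), 0)
  cauchyLossFromDistance(d, s, gamma, epsilon)
}

cauchyLossFromDistance <- function(d, s, gamma, epsilon = 1e-6) {
  de <- pmax(d, epsilon)
  s * (log(de + gamma) - log(gamma)) + (1 - s) * (log(de + gamma) - log(de))
}

#' Quantization loss (L3)
#'
#' The Euclidean norm of the gap between a relaxed code and its binarized
#' version, ||h - sign(h)||_2, averaged over rows when given a matrix. Zero
#' exactly when the code is already binary.
#'
#' @param h relaxed code vector, matrix (rows = images), or a list with a
#'   `relaxed` element as produced by [forwardAll()].
#' @return nonnegative scalar.
#' @export
quantizationLoss <- function(h) {
  if (is.list(h) && !is.null(h$relaxed)) h <- h$relaxed
  if (is.null(dim(h))) h <- matrix(h, nrow = 1)
  r <- h - binarizeCode(h)
  mean(sqrt(rowSums(r^2)))
}

#' Combine loss components
#'
#' L = L1 + L2 + alpha * L3, with components outside `lossSubset`
#' contributing 0 (the ablation protocol trains with L1 only, L1+L2, or the
#' full objective).
#'
#' @param L1,L2,L3 loss components.
#' @param config a [lossConfig()].
#' @return total loss.
#' @export
totalLoss <- function(L1, L2, L3, config) {
  act <- function(nm) as.numeric(nm %in% config$lossSubset)
  act("L1") * L1 + act("L2") * L2 + config$alpha * act("L3") * L3
}
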