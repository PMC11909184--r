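# Independent brute-force scorers, written deliberately as plain loops so
# they share no code path with the package implementations.

oracleAP <- function(rel) {
  nrel <- 0
  for (r in seq_along(rel)) nrel <- nrel + rel[r]
  if (nrel == 0) return(0)
  acc <- 0
  for (r in seq_along(rel)) {
    if (rel[r] == 1) {
      hits <- 0
      for (k in 1:r) hits <- hits + rel[k]
      acc <- acc + hits / r
    }
  }
  acc / nrel
}

oracleDCG <- function(gains) {
  acc <- 0
  for (r in seq_along(gains)) acc <- acc + (2^gains[r] - 1) / log2(r + 1)
  acc
}

oracleNDCG <- function(gains) {
  ideal <- oracleDCG(sort(gains, decreasing = TRUE))
  if (ideal == 0) return(1)
  oracleDCG(gains) / ideal
}

oracleHamming <- function(a, b) {
  n <- 0
  for (i in seq_along(a)) if (a[i] != b[i]) n <- n + 1
  n
}

# all binary vectors of length n, as rows
allBinaryVectors <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# all +/-1 codes of length n, as rows
allCodes <- function(n) {
  2 * allBinaryVectors(n) - 1
}

randomCode <- function(K) sample(c(-1, 1), K, replace = TRUE)

# one-vs-rest ridge probe on raw pixels: a pixel-level linear classifier used
# to certify the generator's separability contract
ridgeProbeAccuracy <- function(X, y, trainFrac = 0.8, lambda = 10,
                               seed = 1) {
  set.seed(seed)
  classes <- sort(unique(y))
  trainIdx <- unlist(lapply(classes, function(cl) {
    i <- which(y == cl)
    sample(i, max(1, floor(trainFrac * length(i))))
  }))
  testIdx <- setdiff(seq_along(y), trainIdx)
  Xtr <- X[trainIdx, , drop = FALSE]
  Y <- outer(y[trainIdx], classes, "==") * 1
  A <- crossprod(Xtr) + lambda * diag(ncol(X))
  W <- solve(A, crossprod(Xtr, Y))
  pred <- classes[max.col(X[testIdx, , drop = FALSE] %*% W)]
  mean(pred == y[testIdx])
}
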