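#' Training configuration
#'
#' Defaults target the tiny CPU profile; the full-scale settings are batch
#' size 256 and learning rate 1e-4 with the same plateau schedule.
#'
#' @param model a [modelConfig()].
#' @param loss a [lossConfig()]; defaults to gamma = K/4, alpha = 0.01 and
#'   all three losses active.
#' @param batchSize images per batch (>= 2 so that pairs exist).
#' @param learningRate Adam step size.
#' @param maxEpochs training epoch cap.
#' @param schedulerPatience epochs without improvement before the learning
#'   rate is multiplied by `schedulerFactor`.
#' @param schedulerFactor learning-rate decay factor on plateau.
#' @param stopPatience stop when the best epoch loss has not improved by
#'   `stopDelta` for this many epochs (loss saturation).
#' @param stopDelta minimal improvement counted as progress.
#' @param seed master seed for shuffling and weight initialisation.
#' @return list of class "TrainConfig".
#' @export
trainConfig <- function(model, loss = NULL, batchSize = 64L,
                        learningRate = 1e-3, maxEpochs = 30L,
                        schedulerPatience = 10L, schedulerFactor = 0.1,
                        stopPatience = 25L, stopDelta = 1e-4, seed = 1L) {
  stopifnot(inherits(model, "ModelConfig"), batchSize >= 2,
            learningRate > 0, maxEpochs >= 1)
  if (is.null(loss)) loss <- lossConfig(K = codeLength(model$structure))
  structure(list(model = model, loss = loss,
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate,
                 maxEpochs = as.integer(maxEpochs),
                 schedulerPatience = as.integer(schedulerPatience),
                 schedulerFactor = schedulerFactor,
                 stopPatience = as.integer(stopPatience),
                 stopDelta = stopDelta, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Enumerate all within-batch pairs with their similarity
#'
#' @param labels data.frame with integer columns modality, organ, disease
#'   for the batch (>= 2 rows).
#' @return data.frame with columns i, j (1-based, i < j) and s (0/1 from
#'   [pairSimilarity()]); B(B-1)/2 rows.
#' @export
samplePairs <- function(labels) {
  B <- nrow(labels)
  if (B < 2L) stop("a batch needs at least 2 samples to form pairs")
  ij <- utils::combn(B, 2)
  S <- pairSimilarityMatrix(labels)
  data.frame(i = ij[1, ], j = ij[2, ], s = S[t(ij)])
}

# ---- internal training engine -------------------------------------------

# forward + loss + gradients for one batch; returns breakdown and grads
batchStep <- function(cfg, params, x, labIdx, lcfg) {
  mcfg <- cfg$model
  B <- dim(x)[4]
  K <- codeLength(mcfg$structure)
  active <- c(L1 = "L1" %in% lcfg$lossSubset,
              L2 = "L2" %in% lcfg$lossSubset,
              L3 = "L3" %in% lcfg$lossSubset)
  fwd <- encForward(mcfg, params, x, keepCache = TRUE)
  f <- fwd$f
  heads <- vector("list", 3)
  for (k in 1:3) {
    P <- params[[paste0("head", k)]]
    U <- addBias(f %*% P$W1, P$b1)
    heads[[k]] <- list(U = U,
                       logits = addBias(U %*% P$Wy, P$by),
                       z = addBias(U %*% P$Wz, P$bz))
  }
  hList <- lapply(heads, function(hd) tanh(hd$z))
  h <- do.call(cbind, hList)

  # L1: mean CE per head, summed over heads
  ycols <- c("modality", "organ", "disease")
  L1 <- 0
  dlogits <- vector("list", 3)
  for (k in 1:3) {
    p <- softmaxRows(heads[[k]]$logits)
    y <- labIdx[[ycols[k]]]
    L1 <- L1 + mean(-log(pmax(p[cbind(seq_len(B), y)], 1e-300)))
    Y <- matrix(0, B, ncol(p)); Y[cbind(seq_len(B), y)] <- 1
    dlogits[[k]] <- if (active["L1"]) (p - Y) / B else matrix(0, B, ncol(p))
  }

  # L2: Cauchy cross-entropy over all unordered within-batch pairs, averaged
  eps <- 1e-6
  gamma <- lcfg$gamma
  S <- pairSimilarityMatrix(labIdx)
  hn <- sqrt(rowSums(h^2))
  hn[hn == 0] <- eps
  Cs <- tcrossprod(h) / outer(hn, hn)
  Cs <- pmin(pmax(Cs, -1), 1)
  Dm <- (K / 2) * (1 - Cs)
  De <- pmax(Dm, eps)
  up <- upper.tri(Dm)
  nPairs <- sum(up)
  Lp <- S * (log(De + gamma) - log(gamma)) +
    (1 - S) * (log(De + gamma) - log(De))
  L2 <- sum(Lp[up]) / nPairs
  dh <- matrix(0, B, K)
  if (active["L2"]) {
    gd <- 1 / (De + gamma) - (1 - S) / De
    gd[Dm < eps & S == 0] <- 0          # flat region under the floor
    diag(gd) <- 0
    gd <- gd / nPairs
    A <- gd * (K / 2) / outer(hn, hn)
    rowB <- rowSums(gd * (K / 2) * Cs) / (hn^2)
    dh <- dh + (-(A %*% h) + rowB * h)
  }

  # L3: mean row-wise norm of h - sign(h)
  bsign <- binarizeCode(h)
  r <- h - bsign
  nr <- sqrt(rowSums(r^2))
  L3 <- mean(nr)
  if (active["L3"] && lcfg$alpha > 0) {
    sc <- ifelse(nr > 0, 1 / (nr * B), 0)
    dh <- dh + lcfg$alpha * (r * sc)
  }

  # backward: dh -> dz per head (tanh), plus classification path
  grads <- list()
  df <- matrix(0, B, mcfg$featureDim)
  ranges <- list(subcodeRange(mcfg$structure, "modality"),
                 subcodeRange(mcfg$structure, "organ"),
                 subcodeRange(mcfg$structure, "disease"))
  for (k in 1:3) {
    P <- params[[paste0("head", k)]]
    hk <- hList[[k]]
    dz <- dh[, ranges[[k]], drop = FALSE] * (1 - hk^2)
    dU <- dlogits[[k]] %*% t(P$Wy) + dz %*% t(P$Wz)
    grads[[paste0("head", k)]] <- list(
      W1 = crossprod(f, dU), b1 = colSums(dU),
      Wy = crossprod(heads[[k]]$U, dlogits[[k]]), by = colSums(dlogits[[k]]),
      Wz = crossprod(heads[[k]]$U, dz), bz = colSums(dz))
    df <- df + dU %*% t(P$W1)
  }
  grads <- c(grads, encBackward(mcfg, params, fwd, df))
  L1r <- if (active["L1"]) L1 else 0
  L2r <- if (active["L2"]) L2 else 0
  L3r <- if (active["L3"]) L3 else 0
  list(grads = grads,
       loss = c(L1 = L1r, L2 = L2r, L3 = L3r,
                L = L1r + L2r + lcfg$alpha * L3r))
}

adamInit <- function(params) {
  lapply(params, function(blk) lapply(blk, function(a)
    list(m = a * 0, v = a * 0)))
}

adamUpdate <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (blk in names(params)) {
    for (nm in names(params[[blk]])) {
      g <- grads[[blk]][[nm]]
      st <- state[[blk]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      params[[blk]][[nm]] <- params[[blk]][[nm]] - lr * mh / (sqrt(vh) + eps)
      state[[blk]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train the deep hashing network
#'
#' Minimises L = L1 + L2 + alpha L3 with Adam over the train split: every
#' batch contributes the per-characteristic classification cross-entropies,
#' the Cauchy cross-entropy over all within-batch pairs, and the
#' quantization penalty. The learning rate is reduced on plateau and training
#' stops when the epoch loss saturates (or at `maxEpochs`). Fully seeded and
#' single-threaded, so runs repeat bit-for-bit.
#'
#' @param manifest manifest data.frame (or path to a manifest CSV).
#' @param dictionary a [LabelDictionary-class]; when `manifest` is a path and
#'   a `dictionary.yml` sits beside it, it is read automatically.
#' @param dir base directory for image paths (defaults to the manifest's
#'   directory when a path is given).
#' @param config a [trainConfig()].
#' @return list with `model` (trained [ModHashModel-class]) and `log`, a
#'   data.frame with per-epoch columns epoch, L1, L2, L3, L, lr.
#' @export
trainModHash <- function(manifest, dictionary = NULL, dir = ".",
                         config) {
  stopifnot(inherits(config, "TrainConfig"))
  if (is.character(manifest)) {
    path <- manifest
    dir <- dirname(path)
    manifest <- readManifest(path)
    dictPath <- file.path(dir, "dictionary.yml")
    if (is.null(dictionary) && file.exists(dictPath))
      dictionary <- readLabelDictionary(dictPath)
  }
  if (is.null(dictionary)) stop("a LabelDictionary is required")
  train <- manifest[manifest$split == "train", ]
  if (nrow(train) == 0L) stop("train split is empty")
  labIdx <- manifestLabels(train, dictionary)
  imgs <- loadImages(train, dir)
  x <- imgs$x
  if (dim(x)[1] != config$model$inputSize || dim(x)[2] != config$model$inputSize)
    stop("image size ", dim(x)[1], "x", dim(x)[2],
         " does not match model inputSize ", config$model$inputSize)
  n <- dim(x)[4]
  mcfg <- config$model
  lcfg <- config$loss
  model <- modHashModel(mcfg, seed = config$seed)
  params <- model@params
  state <- adamInit(params)
  lr <- config$learningRate
  logRows <- vector("list", config$maxEpochs)
  best <- Inf
  sinceImprove <- 0L
  sinceLr <- 0L
  t <- 0L
  withSeed(mixSeed(config$seed, 777L), {
    for (epoch in seq_len(config$maxEpochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batchSize)
      acc <- c(L1 = 0, L2 = 0, L3 = 0, L = 0)
      nb <- 0L
      for (s0 in starts) {
        sel <- perm[s0:min(s0 + config$batchSize - 1L, n)]
        if (length(sel) < 2L) next  # pairs need >= 2 samples
        xb <- x[, , , sel, drop = FALSE]
        lb <- labIdx[sel, , drop = FALSE]
        st <- batchStep(config, params, xb, lb, lcfg)
        if (!all(is.finite(st$loss)))
          stop("training diverged: non-finite loss at epoch ", epoch)
        t <- t + 1L
        upd <- adamUpdate(params, st$grads, state, lr, t)
        params <- upd$params
        state <- upd$state
        acc <- acc + st$loss
        nb <- nb + 1L
      }
      acc <- acc / nb
      logRows[[epoch]] <- data.frame(epoch = epoch, L1 = acc["L1"],
                                     L2 = acc["L2"], L3 = acc["L3"],
                                     L = acc["L"], lr = lr)
      if (acc["L"] < best - config$stopDelta) {
        best <- acc["L"]
        sinceImprove <- 0L
        sinceLr <- 0L
      } else {
        sinceImprove <- sinceImprove + 1L
        sinceLr <- sinceLr + 1L
      }
      if (sinceLr >= config$schedulerPatience) {
        lr <- lr * config$schedulerFactor
        sinceLr <- 0L
      }
      if (sinceImprove >= config$stopPatience) break
    }
  })
  model@params <- params
  log <- do.call(rbind, logRows[!vapply(logRows, is.null, logical(1))])
  rownames(log) <- NULL
  list(model = model, log = log)
}

#' Write a per-epoch loss log as TSV
#' @param log the `log` component of [trainModHash()].
#' @param path output TSV path.
#' @export
writeLossLog <- function(log, path) {
  utils::write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode a manifest split into structured binary codes
#'
#' Runs the trained model over every image of the split and binarizes the
#' relaxed codes (sign, with sign(0) = +1). Deterministic in evaluation.
#'
#' @param model a trained [ModHashModel-class].
#' @param manifest manifest data.frame.
#' @param dictionary a [LabelDictionary-class].
#' @param dir base directory for image paths.
#' @param split which split to encode ("gallery", "query" or "train").
#' @param batchSize forward batch size.
#' @return list with `codes` (a [HashCodeSet-class]) and `labels`
#'   (integer data.frame).
#' @export
encodeDataset <- function(model, manifest, dictionary, dir = ".",
                          split = "gallery", batchSize = 128L) {
  sub <- manifest[manifest$split == split, ]
  if (nrow(sub) == 0L) stop("split '", split, "' is empty")
  imgs <- loadImages(sub, dir)
  n <- dim(imgs$x)[4]
  K <- codeLength(model@config$structure)
  codes <- matrix(0, n, K)
  for (s0 in seq(1L, n, by = batchSize)) {
    sel <- s0:min(s0 + batchSize - 1L, n)
    out <- forwardAll(model, imgs$x[, , , sel, drop = FALSE])
    codes[sel, ] <- binarizeCode(out$relaxed)
  }
  list(codes = hashCodeSet(codes, model@config$structure, sub$id),
       labels = manifestLabels(sub, dictionary))
}

#' Per-characteristic classification accuracy
#'
#' Argmax accuracy of the three classification heads over a manifest split.
#'
#' @inheritParams encodeDataset
#' @return named numeric vector c(modality=, organ=, disease=).
#' @export
classificationAccuracy <- function(model, manifest, dictionary, dir = ".",
                                   split = "query", batchSize = 128L) {
  sub <- manifest[manifest$split == split, ]
  if (nrow(sub) == 0L) stop("split '", split, "' is empty")
  labIdx <- manifestLabels(sub, dictionary)
  imgs <- loadImages(sub, dir)
  n <- dim(imgs$x)[4]
  pred <- matrix(0L, n, 3)
  for (s0 in seq(1L, n, by = batchSize)) {
    sel <- s0:min(s0 + batchSize - 1L, n)
    out <- forwardAll(model, imgs$x[, , , sel, drop = FALSE])
    for (k in 1:3)
      pred[sel, k] <- max.col(out[[k]]$logits, ties.method = "first")
  }
  c(modality = mean(pred[, 1] == labIdx$modality),
    organ = mean(pred[, 2] == labIdx$organ),
    disease = mean(pred[, 3] == labIdx$disease))
}
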