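#' Model configuration
#'
#' Two encoder scales are provided. `scale = "full"` is the AlexNet-derived
#' stack: Conv(64c,11w,4s,2p)-ReLU-MaxPool(3w,2s)-Conv(192c,5w,1s,2p)-ReLU-
#' MaxPool(3w,2s)-Conv(384c,3w,1s,1p)-ReLU-Conv(256c,3w,1s,1p)-ReLU-
#' Conv(256c,3w,1s,1p)-MaxPool(3w,2s)-Flatten-Linear(1024), intended for
#' 224 x 224 inputs. `scale = "tiny"` is a reduced stack for small images and
#' CPU budgets: three Conv(3w,1s,1p)-ReLU-MaxPool(2w,2s) blocks with 8, 16
#' and 32 channels followed by Flatten-Linear(featureDim).
#'
#' Each characteristic sub-network is Linear(512) followed by two parallel
#' linear maps: one to the class logits (lambda, mu or nu wide) and one to
#' the sub-code features (K1, K2 or K3 wide). The three sub-networks share
#' the same architecture, differing only in output widths; class count and
#' sub-code length are independent knobs.
#'
#' @param lambda,mu,nu category counts for modality, organ, disease.
#' @param structure a [CodeStructure-class]; must satisfy
#'   [validateCodeStructure()].
#' @param inputSize input image side in pixels (default 32 for tiny,
#'   use 224 for the full-scale stack).
#' @param featureDim encoder output length (1024 at full scale, 128 tiny).
#' @param scale `"tiny"` or `"full"`.
#' @return config list (class "ModelConfig") with the traced encoder spec.
#' @export
modelConfig <- function(lambda, mu, nu, structure,
                        inputSize = if (scale == "full") 224L else 32L,
                        featureDim = if (scale == "full") 1024L else 128L,
                        scale = c("tiny", "full")) {
  scale <- match.arg(scale)
  ok <- validateCodeStructure(lambda, mu, nu, structure)
  if (!isTRUE(ok)) stop(paste(attr(ok, "reason"), collapse = "; "))
  if (featureDim < max(structure@K1, structure@K2, structure@K3))
    stop("featureDim must be >= the longest sub-code")
  enc <- encoderSpec(scale)
  flat <- traceEncoderShape(enc, inputSize)
  if (flat$side < 1) stop("inputSize too small for the ", scale, " encoder")
  cfg <- list(lambda = as.integer(lambda), mu = as.integer(mu),
              nu = as.integer(nu), structure = structure,
              inputSize = as.integer(inputSize),
              featureDim = as.integer(featureDim), scale = scale,
              headHidden = 512L, encoder = enc, flatDim = flat$dim)
  class(cfg) <- "ModelConfig"
  cfg
}

encoderSpec <- function(scale) {
  if (scale == "full")
    list(list(out = 64L, k = 11L, s = 4L, p = 2L, relu = TRUE, pool = c(3L, 2L)),
         list(out = 192L, k = 5L, s = 1L, p = 2L, relu = TRUE, pool = c(3L, 2L)),
         list(out = 384L, k = 3L, s = 1L, p = 1L, relu = TRUE, pool = NULL),
         list(out = 256L, k = 3L, s = 1L, p = 1L, relu = TRUE, pool = NULL),
         list(out = 256L, k = 3L, s = 1L, p = 1L, relu = FALSE, pool = c(3L, 2L)))
  else
    list(list(out = 8L, k = 3L, s = 1L, p = 1L, relu = TRUE, pool = c(2L, 2L)),
         list(out = 16L, k = 3L, s = 1L, p = 1L, relu = TRUE, pool = c(2L, 2L)),
         list(out = 32L, k = 3L, s = 1L, p = 1L, relu = TRUE, pool = c(2L, 2L)))
}

traceEncoderShape <- function(spec, side) {
  ch <- 1L
  for (L in spec) {
    side <- floor((side + 2L * L$p - L$k) / L$s) + 1L
    ch <- L$out
    if (!is.null(L$pool)) side <- floor((side - L$pool[1]) / L$pool[2]) + 1L
  }
  list(side = side, dim = as.integer(side * side * ch))
}

#' Initialise a ModHashModel
#'
#' Weights use fan-in uniform initialisation,
#' U(-1/sqrt(fan_in), 1/sqrt(fan_in)), for every linear and convolutional
#' layer (biases included). Fully seeded; the global RNG state is restored
#' afterwards.
#'
#' @param config from [modelConfig()].
#' @param seed integer initialisation seed.
#' @return a [ModHashModel-class].
#' @export
modHashModel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ModelConfig"))
  params <- withSeed(mixSeed(seed, 424243L), initParams(config))
  new("ModHashModel", config = unclass(config), params = params)
}

fanInUnif <- function(dims, fanIn) {
  b <- 1 / sqrt(fanIn)
  array(stats::runif(prod(dims), -b, b), dims)
}

initParams <- function(cfg) {
  params <- list()
  cin <- 1L
  for (li in seq_along(cfg$encoder)) {
    L <- cfg$encoder[[li]]
    fi <- L$k * L$k * cin
    params[[paste0("enc", li)]] <-
      list(W = fanInUnif(c(L$k, L$k, cin, L$out), fi),
           b = as.numeric(fanInUnif(L$out, fi)))
    cin <- L$out
  }
  params$fc <- list(W = fanInUnif(c(cfg$flatDim, cfg$featureDim), cfg$flatDim),
                    b = as.numeric(fanInUnif(cfg$featureDim, cfg$flatDim)))
  nclass <- c(cfg$lambda, cfg$mu, cfg$nu)
  klen <- c(cfg$structure@K1, cfg$structure@K2, cfg$structure@K3)
  for (k in 1:3) {
    params[[paste0("head", k)]] <- list(
      W1 = fanInUnif(c(cfg$featureDim, cfg$headHidden), cfg$featureDim),
      b1 = as.numeric(fanInUnif(cfg$headHidden, cfg$featureDim)),
      Wy = fanInUnif(c(cfg$headHidden, nclass[k]), cfg$headHidden),
      by = as.numeric(fanInUnif(nclass[k], cfg$headHidden)),
      Wz = fanInUnif(c(cfg$headHidden, klen[k]), cfg$headHidden),
      bz = as.numeric(fanInUnif(klen[k], cfg$headHidden)))
  }
  params
}

asBatchArray <- function(x, inputSize) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L, 1L))
  if (length(dim(x)) == 3L)
    x <- array(x, c(dim(x)[1], dim(x)[2], 1L, dim(x)[3]))
  if (dim(x)[1] != inputSize || dim(x)[2] != inputSize)
    stop("image size ", dim(x)[1], "x", dim(x)[2],
         " does not match model inputSize ", inputSize)
  x
}

#' Encoder forward pass
#'
#' @param model a [ModHashModel-class].
#' @param x a single image matrix, an (H, W, n) or (H, W, 1, n) array.
#' @return n x featureDim matrix of feature vectors.
#' @export
encodeFeatures <- function(model, x) {
  x <- asBatchArray(x, model@config$inputSize)
  encForward(model@config, model@params, x)$f
}

encForward <- function(cfg, params, x, keepCache = FALSE) {
  caches <- if (keepCache) vector("list", length(cfg$encoder)) else NULL
  a <- x
  for (li in seq_along(cfg$encoder)) {
    L <- cfg$encoder[[li]]
    P <- params[[paste0("enc", li)]]
    pre <- conv2dForwardC(a, dim(a), P$W, dim(P$W), P$b, L$s, L$p)
    act <- pre
    mask <- NULL
    if (L$relu) { mask <- pre > 0; act <- pre * mask }
    if (!is.null(L$pool)) {
      pr <- maxPoolForwardC(act, dim(act), L$pool[1], L$pool[2])
      if (keepCache)
        caches[[li]] <- list(x = a, mask = mask, preDim = dim(act),
                             idx = pr$idx)
      a <- pr$out
    } else {
      if (keepCache) caches[[li]] <- list(x = a, mask = mask)
      a <- act
    }
  }
  D <- prod(dim(a)[1:3]); B <- dim(a)[4]
  F0 <- t(matrix(a, nrow = D, ncol = B))
  f <- addBias(F0 %*% params$fc$W, params$fc$b)
  list(f = f, F0 = F0, caches = caches, adim = dim(a))
}

encBackward <- function(cfg, params, fwd, df) {
  grads <- list(fc = list(W = crossprod(fwd$F0, df), b = colSums(df)))
  ga <- array(t(df %*% t(params$fc$W)), dim = fwd$adim)
  for (li in rev(seq_along(cfg$encoder))) {
    L <- cfg$encoder[[li]]
    Cch <- fwd$caches[[li]]
    P <- params[[paste0("enc", li)]]
    if (!is.null(L$pool)) ga <- maxPoolBackwardC(ga, Cch$idx, Cch$preDim)
    if (L$relu) ga <- ga * Cch$mask
    bw <- conv2dBackwardC(Cch$x, dim(Cch$x), P$W, dim(P$W), ga, L$s, L$p)
    grads[[paste0("enc", li)]] <- list(W = bw$gw, b = bw$gb)
    ga <- bw$gx
  }
  grads
}

addBias <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)

#' Characteristic sub-network forward pass
#'
#' Applies one of the three identical sub-networks to encoder features:
#' Linear(512) then two parallel linear maps giving the class logits and the
#' sub-code features. There is no nonlinearity inside the sub-network, so a
#' zero feature vector yields the bias-propagated outputs.
#'
#' @param model a [ModHashModel-class].
#' @param f feature matrix (n x featureDim) or single feature vector.
#' @param head `"modality"`, `"organ"` or `"disease"`.
#' @return list with `logits` (n x nclass) and `codeFeatures` (n x Kk).
#' @export
headForward <- function(model, f, head = c("modality", "organ", "disease")) {
  head <- match.arg(head)
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  if (ncol(f) != model@config$featureDim)
    stop("feature length does not match featureDim")
  k <- match(head, c("modality", "organ", "disease"))
  P <- model@params[[paste0("head", k)]]
  U <- addBias(f %*% P$W1, P$b1)
  list(logits = addBias(U %*% P$Wy, P$by),
       codeFeatures = addBias(U %*% P$Wz, P$bz))
}

#' Full forward pass: heads and relaxed hash code
#'
#' @param model a [ModHashModel-class].
#' @param x image matrix or batch array.
#' @return list with `modality`, `organ`, `disease` (each a [headForward()]
#'   output) and `relaxed`, the n x K tanh-relaxed code in [-1, 1] laid out
#'   as (modality, organ, disease) sub-code blocks.
#' @export
forwardAll <- function(model, x) {
  f <- encodeFeatures(model, x)
  heads <- lapply(c("modality", "organ", "disease"),
                  function(h) headForward(model, f, h))
  names(heads) <- c("modality", "organ", "disease")
  relaxed <- do.call(cbind, lapply(heads, function(h) relaxCode(h$codeFeatures)))
  c(heads, list(relaxed = relaxed, features = f))
}

#' Save / load a model
#'
#' The checkpoint is R's native serialisation of the config and weight list.
#'
#' @param model a [ModHashModel-class].
#' @param path checkpoint file path (.rds).
#' @export
writeModHashModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params), path)
  invisible(path)
}

#' @rdname writeModHashModel
#' @return [readModHashModel()]: the restored [ModHashModel-class].
#' @export
readModHashModel <- function(path) {
  obj <- readRDS(path)
  new("ModHashModel", config = obj$config, params = obj$params)
}
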