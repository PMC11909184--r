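test_that("output shape contracts hold across a parameter sweep", {
  sweep <- list(list(l = 2, m = 3, n = 4, k = c(2, 3, 4)),
                list(l = 5, m = 4, n = 13, k = c(8, 8, 8)),
                list(l = 6, m = 2, n = 15, k = c(20, 20, 24)))
  for (cse in sweep) {
    cs <- codeStructure(cse$k[1], cse$k[2], cse$k[3])
    cfg <- modelConfig(cse$l, cse$m, cse$n, cs, inputSize = 32L,
                       featureDim = 64L, scale = "tiny")
    model <- modHashModel(cfg, seed = 3)
    x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
    f <- encodeFeatures(model, x)
    expect_equal(dim(f), c(2L, 64L))
    out <- forwardAll(model, x)
    expect_equal(ncol(out$modality$logits), cse$l)
    expect_equal(ncol(out$organ$logits), cse$m)
    expect_equal(ncol(out$disease$logits), cse$n)
    expect_equal(ncol(out$modality$codeFeatures), cse$k[1])
    expect_equal(ncol(out$organ$codeFeatures), cse$k[2])
    expect_equal(ncol(out$disease$codeFeatures), cse$k[3])
    expect_equal(ncol(out$relaxed), sum(cse$k))
    expect_true(all(out$relaxed >= -1 & out$relaxed <= 1))
  }
})

test_that("the full-scale encoder maps a 224x224 image to 1024 features", {
  cs <- codeStructure(18, 18, 22)
  cfg <- modelConfig(5, 4, 13, cs, scale = "full")
  expect_equal(cfg$featureDim, 1024L)
  expect_equal(cfg$inputSize, 224L)
  model <- modHashModel(cfg, seed = 1)
  x <- matrix(runif(224 * 224), 224, 224)
  f <- encodeFeatures(model, x)
  expect_equal(dim(f), c(1L, 1024L))
})

test_that("tiny encoder feature length follows the declared reduced stack", {
  # 32 -> 16 -> 8 -> 4 spatial, 32 channels at the end: flatten dim 512
  cs <- codeStructure(4, 4, 4)
  cfg <- modelConfig(3, 3, 3, cs, inputSize = 32L, featureDim = 128L,
                     scale = "tiny")
  expect_equal(cfg$flatDim, 512L)
  model <- modHashModel(cfg, seed = 2)
  f <- encodeFeatures(model, matrix(runif(32 * 32), 32, 32))
  expect_equal(length(f), 128L)
})

test_that("heads are architecturally identical and linear in the features", {
  cs <- codeStructure(8, 8, 8)
  cfg <- modelConfig(5, 4, 13, cs, inputSize = 32L, featureDim = 32L,
                     scale = "tiny")
  model <- modHashModel(cfg, seed = 5)
  # identical shapes up to output widths
  for (k in 1:3) {
    P <- model@params[[paste0("head", k)]]
    expect_equal(dim(P$W1), c(32L, 512L))
    expect_equal(nrow(P$Wy), 512L)
    expect_equal(nrow(P$Wz), 512L)
  }
  # zero feature vector: output is the bias-propagated term
  z <- rep(0, 32)
  out <- headForward(model, z, "modality")
  P <- model@params$head1
  expect_equal(as.numeric(out$logits), as.numeric(P$b1 %*% P$Wy + P$by))
  expect_equal(as.numeric(out$codeFeatures),
               as.numeric(P$b1 %*% P$Wz + P$bz))
  # linearity: f(a) + f(b) - f(0) = f(a + b)
  a <- runif(32); b <- runif(32)
  fa <- headForward(model, a, "organ")$logits
  fb <- headForward(model, b, "organ")$logits
  f0 <- headForward(model, rep(0, 32), "organ")$logits
  fab <- headForward(model, a + b, "organ")$logits
  expect_equal(fa + fb - f0, fab, tolerance = 1e-10)
})

test_that("class count and code length vary independently", {
  expect_true(validateCodeStructure(2, 2, 2, codeStructure(16, 16, 16)))
  expect_false(isTRUE(validateCodeStructure(3, 3, 3, codeStructure(2, 3, 3))))
  expect_true(validateCodeStructure(3, 3, 3, codeStructure(3, 3, 3)))
  cfg <- modelConfig(2, 2, 2, codeStructure(16, 2, 2), inputSize = 32L,
                     featureDim = 32L, scale = "tiny")
  model <- modHashModel(cfg, seed = 1)
  out <- forwardAll(model, matrix(runif(32 * 32), 32, 32))
  expect_equal(ncol(out$modality$codeFeatures), 16L)
  expect_equal(ncol(out$modality$logits), 2L)
})

test_that("forward passes are deterministic and checkpoints round-trip", {
  cs <- codeStructure(6, 6, 6)
  cfg <- modelConfig(4, 3, 5, cs, inputSize = 32L, featureDim = 32L,
                     scale = "tiny")
  model <- modHashModel(cfg, seed = 8)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  o1 <- forwardAll(model, x)
  o2 <- forwardAll(model, x)
  expect_identical(o1$relaxed, o2$relaxed)
  path <- tempfile(fileext = ".rds")
  writeModHashModel(model, path)
  back <- readModHashModel(path)
  expect_identical(forwardAll(back, x)$relaxed, o1$relaxed)
})
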