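test_that("classification loss matches closed forms and symmetries", {
  # certainty: probability ~1 on the true class for all three heads
  big <- 50
  logits <- list(c(big, 0, 0, 0, 0), c(0, big, 0, 0), c(rep(0, 12), big))
  lab <- c(modality = 1, organ = 2, disease = 13)
  expect_lt(classificationLoss(logits, lab), 1e-10)
  # uniform logits: ln(lambda) + ln(mu) + ln(nu)
  logits <- list(rep(0, 5), rep(0, 4), rep(0, 13))
  expect_equal(classificationLoss(logits, c(1, 1, 1)),
               log(5) + log(4) + log(13), tolerance = 1e-12)
  expect_equal(log(5) + log(4) + log(13), 5.560, tolerance = 1e-3)
  # joint permutation of classes and labels leaves the loss unchanged
  set.seed(2)
  lg <- lapply(c(5, 4, 13), function(n) rnorm(n))
  lab <- c(2, 3, 7)
  base <- classificationLoss(lg, lab)
  perms <- list(sample(5), sample(4), sample(13))
  lg2 <- Map(function(v, p) v[p], lg, perms)
  lab2 <- mapply(function(p, y) which(p == y), perms, lab)
  expect_equal(classificationLoss(lg2, lab2), base, tolerance = 1e-12)
  expect_error(classificationLoss(lg, c(6, 1, 1)), "label out of range")
})

test_that("continuous Hamming distance equals mismatch count on binary codes", {
  h <- randomCode(24)
  expect_equal(continuousHamming(h, h), 0)
  expect_equal(continuousHamming(h, -h), 24)
  set.seed(3)
  for (i in 1:50) {
    a <- randomCode(16); b <- randomCode(16)
    expect_equal(continuousHamming(a, b), oracleHamming(a, b),
                 tolerance = 1e-12)
  }
  expect_error(continuousHamming(rep(0, 4), rep(1, 4)), "zero-norm")
})

test_that("Cauchy similarity follows gamma / (gamma + d)", {
  a <- randomCode(24)
  expect_equal(cauchySimilarity(a, a, 6), 1)
  b <- a; b[1:6] <- -b[1:6]          # d = gamma = 6
  expect_equal(cauchySimilarity(a, b, 6), 0.5)
  b2 <- a; b2[1:18] <- -b2[1:18]     # d = 18, gamma = 6
  expect_equal(cauchySimilarity(a, b2, 6), 0.25)
  # strictly decreasing in d
  sims <- sapply(0:24, function(m) {
    b <- a; if (m > 0) b[seq_len(m)] <- -b[seq_len(m)]
    cauchySimilarity(a, b, 6)
  })
  expect_true(all(diff(sims) < 0))
})

test_that("Cauchy loss limits and monotonicity", {
  a <- randomCode(24)
  expect_lt(cauchyLoss(a, a, s = 1, gamma = 6), 1e-6)
  b <- a; b[1:6] <- -b[1:6]
  expect_equal(cauchyLoss(a, b, s = 0, gamma = 6), log(2), tolerance = 1e-12)
  # s = 0 loss vanishes as d grows; s = 1 loss grows with d
  l0 <- sapply(1:24, function(m) {
    b <- a; b[seq_len(m)] <- -b[seq_len(m)]
    cauchyLoss(a, b, s = 0, gamma = 6)
  })
  l1 <- sapply(1:24, function(m) {
    b <- a; b[seq_len(m)] <- -b[seq_len(m)]
    cauchyLoss(a, b, s = 1, gamma = 6)
  })
  expect_true(all(diff(l0) < 0))
  expect_true(all(diff(l1) > 0))
  expect_lt(l0[24], l0[1])
})

test_that("quantization loss is zero exactly on binary codes", {
  expect_equal(quantizationLoss(randomCode(24)), 0)
  expect_equal(quantizationLoss(rep(0, 24)), sqrt(24))
  h <- runif(24, -1, 1)
  expect_gt(quantizationLoss(h), 0)
  expect_equal(quantizationLoss(h), quantizationLoss(-h), tolerance = 1e-12)
  # matrix input averages over rows
  m <- rbind(randomCode(24), rep(0, 24))
  expect_equal(quantizationLoss(m), sqrt(24) / 2)
})

test_that("total loss combines components with alpha and the ablation subset", {
  cfg <- lossConfig(gamma = 6, alpha = 0.01)
  expect_equal(totalLoss(1, 2, 3, cfg), 3.03)
  expect_equal(lossConfig(K = 24)$gamma, 6)       # default gamma = K/4
  expect_equal(cfg$alpha, 0.01)
  only1 <- lossConfig(gamma = 6, lossSubset = "L1")
  expect_equal(totalLoss(1, 2, 3, only1), 1)
  expect_equal(totalLoss(1, 2, 3, lossConfig(gamma = 6,
                                             lossSubset = c("L1", "L2"))), 3)
})
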