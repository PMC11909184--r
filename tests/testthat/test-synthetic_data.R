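test_that("rendering is deterministic and factors stay visually independent", {
  a <- renderImage(2, 3, 5, size = 32, seed = 9)
  b <- renderImage(2, 3, 5, size = 32, seed = 9)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  # a different seed moves pixels but not the label content
  c2 <- renderImage(2, 3, 5, size = 32, seed = 10)
  expect_false(identical(a, c2))
  # the organ mask is untouched by the disease index
  expect_identical(organMask(3, 32), organMask(3, 32))
  m1 <- organMask(1, 32); m4 <- organMask(4, 32)
  expect_false(identical(m1, m4))
  # every lesion quadrant site lies inside every organ shape
  ax <- ((seq_len(32) - 16.5) / 32) * 2
  for (o in 1:6) {
    msk <- organMask(o, 32)
    for (cy in c(-0.33, 0.33)) for (cx in c(-0.33, 0.33)) {
      i <- which.min(abs(ax - cy)); j <- which.min(abs(ax - cx))
      expect_equal(msk[i, j], 1, label = paste("organ", o))
    }
  }
})

test_that("batch mean intensity tracks modality, not disease", {
  meansBy <- function(vals, n = 100) {
    vapply(vals, function(v) {
      mean(vapply(seq_len(n), function(s)
        mean(renderImage(v[1], v[2], v[3], 32, seed = s)), numeric(1)))
    }, numeric(1))
  }
  # sweep modality at fixed organ/disease
  byMod <- meansBy(lapply(1:5, function(m) c(m, 2, 4)))
  expect_true(all(diff(byMod) > 0.05))  # background steps dominate
  # sweep disease at fixed modality/organ: only the lesion area can move it
  byDis <- meansBy(lapply(c(1, 5, 13), function(d) c(2, 2, d)))
  expect_lt(max(byDis) - min(byDis), 0.05)
})

test_that("generated datasets have exact split arithmetic and seeded identity", {
  dict12 <- labelDictionary(
    paste0("mod", 1:3), paste0("org", 1:2), paste0("dis", 1:4),
    data.frame(modality = rep(1:3, 4), organ = rep(1:2, 6),
               disease = rep(1:4, each = 3)))
  cfg <- syntheticConfig(dict12, imageSize = 16L, nPerCombination = 30L,
                         splitFractions = c(0.6, 0.3, 0.1), seed = 5L)
  d1 <- file.path(tempdir(), "synth-a")
  d2 <- file.path(tempdir(), "synth-b")
  d3 <- file.path(tempdir(), "synth-c")
  m1 <- generateDataset(cfg, d1)
  expect_equal(nrow(m1), 360L)
  expect_equal(as.integer(table(m1$split)[c("train", "gallery", "query")]),
               c(216L, 108L, 36L))
  # same seed: byte-identical manifest and images
  generateDataset(cfg, d2)
  expect_identical(readBin(file.path(d1, "manifest.csv"), "raw", 1e6),
                   readBin(file.path(d2, "manifest.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(d1, m1$path[7]), "raw", 1e5),
                   readBin(file.path(d2, m1$path[7]), "raw", 1e5))
  # different seed: same counts, different pixels
  cfg2 <- syntheticConfig(dict12, imageSize = 16L, nPerCombination = 30L,
                          splitFractions = c(0.6, 0.3, 0.1), seed = 6L)
  m3 <- generateDataset(cfg2, d3)
  expect_equal(table(m3$split), table(m1$split))
  expect_false(identical(readBin(file.path(d1, m1$path[7]), "raw", 1e5),
                         readBin(file.path(d3, m1$path[7]), "raw", 1e5)))
  # split discipline is checked by the manifest validator
  expect_silent(validateManifest(m1, dict12, d1))
})

test_that("the default configuration matches the emulated archive", {
  cfg <- defaultSyntheticConfig()
  dict <- cfg$dictionary
  expect_equal(unname(categoryCounts(dict)), c(5L, 4L, 13L))
  cmb <- validCombinations(dict)
  expect_equal(nrow(cmb), 15L)
  lims <- categoryCounts(dict)
  expect_true(all(cmb[, 1] >= 1 & cmb[, 1] <= lims["lambda"]))
  expect_true(all(cmb[, 2] >= 1 & cmb[, 2] <= lims["mu"]))
  expect_true(all(cmb[, 3] >= 1 & cmb[, 3] <= lims["nu"]))
})

test_that("each characteristic is linearly decodable from pixels (separability contract)", {
  d <- smallDataset()
  labs <- manifestLabels(d$manifest, d$dict)
  imgs <- loadImages(d$manifest, d$dir)
  X <- t(matrix(imgs$x, nrow = 32 * 32))
  expect_gte(ridgeProbeAccuracy(X, labs$modality), 0.95)
  expect_gte(ridgeProbeAccuracy(X, labs$organ), 0.95)
  expect_gte(ridgeProbeAccuracy(X, labs$disease), 0.95)
})
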