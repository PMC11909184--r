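test_that("relevance maps respect the seven characteristic specs", {
  yq <- c(modality = 2, organ = 2, disease = 4)
  same <- yq
  disOnly <- c(modality = 1, organ = 1, disease = 4)
  modOnly <- c(modality = 2, organ = 1, disease = 5)
  expect_equal(relevanceMap(same, yq, "MOD"), 1L)
  expect_equal(relevanceMap(disOnly, yq, "D"), 1L)
  expect_equal(relevanceMap(modOnly, yq, "MO"), 0L)
  expect_equal(relevanceMap(disOnly, yq, "MOD"), 0L)
  # graded gains count matching characteristics
  expect_equal(relevanceNdcg(c(2, 2, 5), yq, "MOD"), 2L)
  expect_equal(relevanceNdcg(modOnly, yq, "MD"), 1L)
  expect_equal(relevanceNdcg(c(1, 1, 1), yq, "MOD"), 0L)
  expect_equal(relevanceNdcg(same, yq, "MOD"), 3L)
  # binary MOD relevance is equivalent to a full gain of 3
  cmb <- validCombinations(defaultLabelDictionary())
  for (i in seq_len(nrow(cmb))) for (j in seq_len(nrow(cmb))) {
    a <- cmb[i, ]; b <- cmb[j, ]
    expect_equal(relevanceMap(a, b, "MOD") == 1L,
                 relevanceNdcg(a, b, "MOD") == 3L)
  }
  expect_error(relevanceMap(same, yq, "X"), "unknown characteristic spec")
})

test_that("average precision matches hand values and its conventions", {
  expect_equal(averagePrecisionAtP(c(1, 1, 1)), 1)
  expect_equal(averagePrecisionAtP(c(0, 0, 0)), 0)
  expect_equal(averagePrecisionAtP(c(1, 0, 1)), (1 + 2 / 3) / 2)
  # prepending an irrelevant item never increases AP
  set.seed(6)
  for (i in 1:200) {
    rel <- sample(0:1, sample(1:8, 1), replace = TRUE)
    expect_lte(averagePrecisionAtP(c(0, rel)), averagePrecisionAtP(rel))
  }
})

test_that("DCG and nDCG match hand values and ordering properties", {
  expect_equal(dcgAtP(c(3, 0, 1)), 7 + 0 + 0.5)
  expect_equal(dcgAtP(c(0, 0)), 0)
  expect_equal(dcgAtP(1), 1)
  expect_equal(ndcgAtP(c(0, 3)), (7 / log2(3)) / 7)
  expect_equal(ndcgAtP(c(0, 3)), 1 / log2(3), tolerance = 1e-12)
  expect_equal(ndcgAtP(c(0, 3)), 0.630930, tolerance = 1e-5)
  expect_equal(ndcgAtP(c(3, 0, 1)), 7.5 / (7 + 1 / log2(3)))
  expect_equal(ndcgAtP(c(3, 0, 1)), 0.98284, tolerance = 1e-4)
  expect_equal(ndcgAtP(c(0, 0, 0)), 1)  # no relevant item: any order ideal
  # nDCG = 1 iff gains are non-increasing (when some gain > 0)
  set.seed(7)
  for (i in 1:200) {
    g <- sample(0:3, sample(2:6, 1), replace = TRUE)
    if (sum(g) == 0) next
    expect_equal(ndcgAtP(g) == 1, !is.unsorted(rev(g)))
    # swapping a higher-gain item earlier never decreases nDCG
    k <- which(diff(g) > 0)
    if (length(k) > 0) {
      g2 <- g
      g2[c(k[1], k[1] + 1)] <- g2[c(k[1] + 1, k[1])]
      expect_gte(ndcgAtP(g2), ndcgAtP(g))
    }
  }
})

test_that("evaluation over a toy gallery reproduces hand-computed scores", {
  cs <- codeStructure(2, 2, 2)
  # gallery of 4, distances to the all-ones query: 0, 1, 2, 3
  codes <- rbind(rep(1, 6),
                 c(-1, rep(1, 5)),
                 c(-1, -1, rep(1, 4)),
                 c(-1, -1, -1, rep(1, 3)))
  labels <- data.frame(modality = c(1L, 2L, 1L, 1L),
                       organ = c(1L, 1L, 2L, 1L),
                       disease = c(1L, 1L, 1L, 1L))
  idx <- galleryIndex(hashCodeSet(codes, cs, paste0("g", 1:4)), labels)
  qset <- hashCodeSet(matrix(rep(1, 6), 1), cs, "q")
  qlab <- data.frame(modality = 1L, organ = 1L, disease = 1L)
  rep_ <- evaluateRetrieval(qset, qlab, idx, specs = c("MOD", "M"),
                            pList = 4)
  # ranked MOD relevances: 1, 0, 0, 1 -> AP = (1 + 2/4) / 2
  expect_equal(rep_$mAP[rep_$spec == "MOD"], (1 + 0.5) / 2)
  # ranked modality relevances: 1, 0, 1, 1
  expect_equal(rep_$mAP[rep_$spec == "M"], (1 + 2 / 3 + 3 / 4) / 3)
  # ranked MOD gains: 3, 2, 2, 3
  gains <- c(3, 2, 2, 3)
  expect_equal(rep_$nDCG[rep_$spec == "MOD"], oracleNDCG(gains))
  # all-matching gallery: every metric is 1
  labAll <- data.frame(modality = rep(1L, 4), organ = rep(1L, 4),
                       disease = rep(1L, 4))
  idxAll <- galleryIndex(hashCodeSet(codes, cs, paste0("g", 1:4)), labAll)
  repAll <- evaluateRetrieval(qset, qlab, idxAll, pList = c(2, 4))
  expect_true(all(repAll$mAP == 1))
  expect_true(all(repAll$nDCG == 1))
})

test_that("evaluation agrees with a brute-force scorer over gallery permutations", {
  cs <- codeStructure(2, 2, 2)
  base <- rbind(rep(1, 6), c(-1, rep(1, 5)), c(-1, -1, rep(1, 4)),
                c(rep(-1, 3), rep(1, 3)), c(rep(-1, 4), 1, 1))
  labels <- data.frame(modality = c(1L, 2L, 1L, 2L, 1L),
                       organ = c(1L, 1L, 2L, 2L, 1L),
                       disease = c(1L, 1L, 1L, 2L, 2L))
  qlab <- data.frame(modality = 1L, organ = 1L, disease = 1L)
  qset <- hashCodeSet(matrix(rep(1, 6), 1), cs, "q")
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  for (pi in seq_len(nrow(perms))) {
    p <- perms[pi, ]
    idx <- galleryIndex(hashCodeSet(base[p, ], cs, paste0("g", 1:5)),
                        labels[p, ])
    rep_ <- evaluateRetrieval(qset, qlab, idx, specs = "MOD", pList = 5)
    # oracle: stable-rank the permuted gallery, score with the naive loops
    d <- apply(base[p, ], 1, function(g) oracleHamming(g, rep(1, 6)))
    ord <- order(d)
    lr <- labels[p, ][ord, ]
    rel <- as.integer(lr$modality == 1 & lr$organ == 1 & lr$disease == 1)
    gains <- (lr$modality == 1) + (lr$organ == 1) + (lr$disease == 1)
    expect_equal(rep_$mAP, oracleAP(rel))
    expect_equal(rep_$nDCG, oracleNDCG(gains))
  }
})
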