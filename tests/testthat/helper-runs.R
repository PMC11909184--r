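# Shared seeded artefacts, built lazily once per test session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small synthetic dataset for unit tests (300 images, 32 px)
smallDataset <- function() {
  memo("small", {
    dir <- file.path(tempdir(), "modhash-small")
    cfg <- syntheticConfig(defaultLabelDictionary(), imageSize = 32L,
                           nPerCombination = 20L, seed = 101L)
    manifest <- generateDataset(cfg, dir)
    list(dir = dir, manifest = manifest, dict = defaultLabelDictionary(),
         cfg = cfg)
  })
}

# the full-scale seeded study run: default generator conditions, 64-bit
# structured code (20+20+24), trained with the full objective and once more
# with the classification loss alone for the ablation comparison
studyRun <- function() {
  memo("study", {
    seed <- 1L
    dir <- file.path(tempdir(), "modhash-study")
    dict <- defaultLabelDictionary()
    manifest <- generateDataset(defaultSyntheticConfig(seed = seed), dir)
    cs <- codeStructure(20, 20, 24)
    mcfg <- modelConfig(5, 4, 13, cs, scale = "tiny")
    full <- trainModHash(manifest, dict, dir,
                         trainConfig(mcfg, maxEpochs = 30L, seed = seed))
    l1only <- trainModHash(manifest, dict, dir,
                           trainConfig(mcfg,
                                       loss = lossConfig(K = codeLength(cs),
                                                         lossSubset = "L1"),
                                       maxEpochs = 30L, seed = seed))
    gal <- encodeDataset(full$model, manifest, dict, dir, "gallery")
    qry <- encodeDataset(full$model, manifest, dict, dir, "query")
    galA <- encodeDataset(l1only$model, manifest, dict, dir, "gallery")
    qryA <- encodeDataset(l1only$model, manifest, dict, dir, "query")
    list(dir = dir, dict = dict, manifest = manifest, cs = cs,
         full = full, l1only = l1only,
         index = galleryIndex(gal$codes, gal$labels), query = qry,
         indexA = galleryIndex(galA$codes, galA$labels), queryA = qryA)
  })
}
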