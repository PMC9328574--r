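# Builds a trained screening stage + background on a shared fixture once;
# individual tests reuse it.
makeTransferFixture <- function(n = 500, seed = 90, link = "gaussian",
                                sf = 1) {
  ds <- signalDataset(n = n, seed = seed, link = link, sf = sf, nNull = 1)
  d <- dosages(ds@genotypes)
  y <- phenotype(ds@genotypes)
  tr <- 1:(0.8 * n); te <- (0.8 * n + 1):n
  sr <- screenGenome(
    GenotypeData(d[tr, ], phenotype = y[tr],
                 outcomeType = outcomeType(ds@genotypes)),
    fastNet(epochs = 25), K = 4, alpha = 0.05, nPerm = 20, seed = 91,
    regions = ds@regions)
  grm <- computeGRM(d[tr, ])
  bg <- fitGBLUP(grm, y[tr])
  list(ds = ds, d = d, y = y, tr = tr, te = te, sr = sr, bg = bg,
       bgTest = predictBackground(bg, d[tr, ], d[te, ]))
}

fx <- makeTransferFixture()

test_that("the transfer architecture reports the documented parameter counts", {
  # 4 gene nets of last hidden width 10 -> stack [100, 10] -> 1, + gamma0
  nets <- lapply(1:4, function(k) {
    ds <- signalDataset(n = 80, seed = 100 + k, nNull = 0)
    fitGeneNetwork(dosages(ds@genotypes)[, ds@regions[[1]]],
                   phenotype(ds@genotypes),
                   fastNet(epochs = 2, seed = k), geneId = paste0("g", k))
  })
  vi <- setNames(lapply(1:4, function(k) 1:10), paste0("g", 1:4))
  bg <- fx$bg
  m <- buildTransferNetwork(nets, bg, TransferConfig(), variantIndices = vi)
  pc <- parameterCounts(m)
  expect_identical(pc$trainable,
                   as.integer((40 * 100 + 100) + (100 * 10 + 10) + (10 * 1 + 1) + 1))
  expect_identical(pc$trainable, 5122L)
  # frozen = per-gene hidden-layer parameters
  expect_identical(pc$frozen, as.integer(4 * ((10 * 50 + 50) + (50 * 10 + 10))))
  mOpt <- buildTransferNetwork(nets, bg, TransferConfig(mode = "optimal"),
                               variantIndices = vi)
  pcOpt <- parameterCounts(mOpt)
  expect_identical(pcOpt$trainable, pc$trainable + pc$frozen)
  expect_identical(pcOpt$frozen, 0L)
  expect_gt(pcOpt$trainable, pc$trainable)  # strict economy for any p >= 1
})

test_that("transfer mode never mutates the pre-trained gene parameters", {
  sr <- fx$sr
  expect_gt(length(geneNetworks(sr)), 0)
  model <- buildTransferNetwork(
    geneNetworks(sr), fx$bg, TransferConfig(epochs = 30, seed = 5),
    variantIndices = regionIndices(fx$ds@regions)[selectedGenes(sr)])
  before <- serialize(lapply(model@geneNetworks, function(g) g@weights), NULL)
  fitted <- fitTransferModel(model, fx$d[fx$tr, ], y = fx$y[fx$tr],
                             background = fx$bg@blup)
  after <- serialize(lapply(fitted@geneNetworks, function(g) g@weights), NULL)
  expect_identical(after, before)
  expect_true(fitted@trained)
})

test_that("optimal mode retrains the gene parameters", {
  sr <- fx$sr
  model <- buildTransferNetwork(
    geneNetworks(sr), fx$bg, TransferConfig(epochs = 10, mode = "optimal",
                                            seed = 6),
    variantIndices = regionIndices(fx$ds@regions)[selectedGenes(sr)])
  before <- serialize(lapply(model@geneNetworks, function(g) g@weights), NULL)
  fitted <- fitTransferModel(model, fx$d[fx$tr, ], y = fx$y[fx$tr],
                             background = fx$bg@blup)
  after <- serialize(lapply(fitted@geneNetworks, function(g) g@weights), NULL)
  expect_false(identical(after, before))
})

test_that("predictions decompose additively into gene stack and background", {
  sr <- fx$sr
  model <- buildTransferNetwork(
    geneNetworks(sr), fx$bg, TransferConfig(epochs = 20, seed = 7),
    variantIndices = regionIndices(fx$ds@regions)[selectedGenes(sr)])
  model <- fitTransferModel(model, fx$d[fx$tr, ], y = fx$y[fx$tr],
                            background = fx$bg@blup)
  parts <- predictRisk(model, fx$d[fx$te, ], background = fx$bgTest,
                       parts = TRUE)
  expect_equal(parts$genePart + parts$backgroundPart, parts$linear,
               tolerance = 1e-10)
  expect_equal(parts$prediction, parts$linear, tolerance = 1e-10)
  # deterministic inference: a duplicated row predicts identically
  p2 <- predictRisk(model, fx$d[fx$te, ][c(1, 1, 2), ],
                    background = fx$bgTest[c(1, 1, 2)])
  expect_identical(p2[1], p2[2])
})

test_that("with no selected genes the model reduces to the weighted background", {
  model <- buildTransferNetwork(
    list(), fx$bg, TransferConfig(epochs = 20, seed = 8))
  model <- fitTransferModel(model, fx$d[fx$tr, ], y = fx$y[fx$tr],
                            background = fx$bg@blup)
  parts <- predictRisk(model, fx$d[fx$te, ], background = fx$bgTest,
                       parts = TRUE)
  # the gene part collapses to a trained constant; predictions are an
  # affine function of the background value alone
  expect_identical(length(unique(round(parts$genePart, 10))), 1L)
  expect_equal(stats::cor(parts$prediction, fx$bgTest) * sign(model@gamma0), 1,
               tolerance = 1e-8)
})

test_that("ablating the gene stack reproduces the gBLUP predictions", {
  sr <- fx$sr
  model <- buildTransferNetwork(
    geneNetworks(sr), fx$bg, TransferConfig(epochs = 20, seed = 9),
    variantIndices = regionIndices(fx$ds@regions)[selectedGenes(sr)])
  model <- fitTransferModel(model, fx$d[fx$tr, ], y = fx$y[fx$tr],
                            background = fx$bg@blup)
  abl <- predictRisk(model, fx$d[fx$te, ], background = fx$bgTest,
                     ablateStack = TRUE)
  expect_equal(abl, model@gamma0 * fx$bgTest, tolerance = 1e-12)
  yTe <- fx$y[fx$te]
  expect_lt(abs(pearsonCor(yTe, abl) -
                pearsonCor(yTe, fx$bgTest) * sign(model@gamma0)), 1e-12)
})

test_that("binary transfer models emit probabilities and train on cross-entropy", {
  fxb <- makeTransferFixture(n = 400, seed = 95, link = "logistic", sf = 2)
  sel <- selectedGenes(fxb$sr)
  model <- buildTransferNetwork(
    geneNetworks(fxb$sr), fxb$bg,
    TransferConfig(epochs = 25, seed = 10),
    variantIndices = regionIndices(fxb$ds@regions)[sel],
    outcomeType = "binary")
  model <- fitTransferModel(model, fxb$d[fxb$tr, ], y = fxb$y[fxb$tr],
                            background = fxb$bg@blup)
  p <- predictRisk(model, fxb$d[fxb$te, ], background = fxb$bgTest)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the within-genes-only scope keeps the stack block-diagonal", {
  sr <- fx$sr
  ds2 <- signalDataset(n = 300, seed = 97, sf = 1, nNull = 0)
  net2 <- fitGeneNetwork(dosages(ds2@genotypes)[, ds2@regions[[1]]],
                         phenotype(ds2@genotypes), fastNet(epochs = 5, seed = 2),
                         geneId = "sig2")
  nets <- c(geneNetworks(sr)[1], list(net2))
  vi <- list(sig = fx$ds@regions[["sig"]], sig2 = ds2@regions[[1]])
  cfgW <- TransferConfig(epochs = 10, seed = 11,
                         interactionScope = "within_genes_only")
  model <- buildTransferNetwork(nets, fx$bg, cfgW, variantIndices = vi)
  # both fixtures use 10-variant genes on the same column layout
  model <- fitTransferModel(model, fx$d[fx$tr, ], y = fx$y[fx$tr],
                            background = fx$bg@blup)
  W1 <- model@stack$W[[1]]
  mask <- model@stackMask[[1]]
  expect_true(all(W1[mask == 0] == 0))
  expect_gt(sum(W1[mask == 1] != 0), 0)
  pcW <- parameterCounts(model)
  pcB <- parameterCounts(buildTransferNetwork(nets, fx$bg,
           TransferConfig(epochs = 10), variantIndices = vi))
  expect_lt(pcW$trainable, pcB$trainable)
})

test_that("the end-to-end pipeline recovers signal and beats background alone", {
  ds <- signalDataset(n = 700, seed = 120, sf = 1.5, nNull = 2)
  out <- runPipeline(ds, fastNet(epochs = 25), TransferConfig(epochs = 40),
                     alpha = 0.05, K = 4, nPerm = 20, seed = 5)
  expect_true("sig" %in% selectedGenes(out$screen))
  expect_gt(out$metrics$pearson, 0.3)
  yTe <- phenotype(ds@genotypes)[out$testIdx]
  rBg <- pearsonCor(yTe, out$backgroundTest)
  expect_gt(out$metrics$pearson, rBg - 0.05)
})

test_that("pipeline predictions on pure noise hover near zero correlation", {
  ds <- nullDataset(n = 400, seed = 130, nGenes = 3, nk = 10)
  out <- runPipeline(ds, fastNet(epochs = 10), TransferConfig(epochs = 15),
                     alpha = 0.001, K = 3, nPerm = 10, seed = 6)
  if (!is.na(out$metrics$pearson))
    expect_lt(abs(out$metrics$pearson), 0.35)  # ~3 SE at 80 test samples
})
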