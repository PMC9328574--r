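#' @rdname TransferConfig-class
#' @param stackedHiddenSizes widths of the newly added hidden layers
#'   (default \code{c(100, 10)})
#' @param epochs training passes (default 100; no early stopping)
#' @param learningRate Adam learning rate (default 3e-3)
#' @param batchSize minibatch size (default 32); 0 = full batch
#' @param mode \code{"transfer"} (freeze per-gene parameters) or
#'   \code{"optimal"} (retrain everything)
#' @param interactionScope \code{"between_genes"} or
#'   \code{"within_genes_only"}
#' @param seed training seed; \code{NA} consumes the ambient RNG stream
#' @export
TransferConfig <- function(stackedHiddenSizes = c(100, 10), epochs = 100,
                           learningRate = 3e-3, batchSize = 32,
                           mode = "transfer",
                           interactionScope = "between_genes", seed = NA) {
  new("TransferConfig", stackedHiddenSizes = as.integer(stackedHiddenSizes),
      epochs = as.integer(epochs), learningRate = learningRate,
      batchSize = as.integer(batchSize), mode = mode,
      interactionScope = interactionScope, seed = as.integer(seed))
}

# Last-hidden width of a gene network = rows of its output weight matrix.
geneHiddenWidth <- function(net) nrow(net@weights$W[[length(net@weights$W)]])

# Block-diagonal masks realizing the per-gene private-stack wiring: each
# gene's hidden output feeds only its own share of the stacked layers; the
# final output node combines all genes. Per-gene widths are the configured
# stack widths split evenly across genes (at least one unit each).
buildStackMask <- function(geneWidths, stackSizes) {
  p <- length(geneWidths)
  perGene <- lapply(stackSizes, function(s) rep(max(1L, s %/% p), p))
  masks <- list()
  inWidths <- geneWidths
  for (l in seq_along(perGene)) {
    outWidths <- perGene[[l]]
    M <- matrix(0, sum(inWidths), sum(outWidths))
    ri <- cumsum(c(0, inWidths)); ci <- cumsum(c(0, outWidths))
    for (g in seq_len(p))
      M[(ri[g] + 1):ri[g + 1], (ci[g] + 1):ci[g + 1]] <- 1
    masks[[l]] <- M
    inWidths <- outWidths
  }
  masks[length(masks) + 1] <- list(NULL)  # output layer fully connected
  list(masks = masks, stackSizes = vapply(perGene, sum, integer(1)))
}

#' Build the transfer prediction network
#'
#' Assembles the architecture of the prediction model: the last hidden
#' layers of the pre-trained per-gene networks are the (frozen) feature
#' extractors, the newly added stacked layers model the joint effects of
#' the selected genes, and the gBLUP background node enters additively
#' through a single scalar weight. With zero gene networks the model
#' reduces to the scalar-weighted background alone.
#'
#' @param geneNets list of \linkS4class{GeneNetwork} objects for the
#'   selected genes (e.g. \code{geneNetworks(screenResult)})
#' @param background a \linkS4class{BackgroundModel}
#' @param cfg a \linkS4class{TransferConfig}
#' @param variantIndices named list mapping each gene to its dosage columns
#'   (e.g. \code{regionIndices(regions)[selectedGenes(sr)]})
#' @param outcomeType \code{"continuous"} or \code{"binary"}
#' @return an untrained \linkS4class{TransferModel}
#' @export
buildTransferNetwork <- function(geneNets, background, cfg = TransferConfig(),
                                 variantIndices = NULL,
                                 outcomeType = "continuous") {
  geneNets <- unname(as.list(geneNets))
  p <- length(geneNets)
  ids <- vapply(geneNets, function(g) g@geneId, character(1))
  if (is.null(variantIndices)) variantIndices <- stats::setNames(vector("list", p), ids)
  if (p > 0) {
    variantIndices <- variantIndices[ids]
    for (k in seq_len(p)) {
      if (!is.null(variantIndices[[k]]) &&
          length(variantIndices[[k]]) != geneNets[[k]]@nInputs)
        stop("variant columns for gene '", ids[k],
             "' do not match the network input width")
    }
  }
  widths <- vapply(geneNets, geneHiddenWidth, integer(1))
  stackMask <- list()
  stackSizes <- cfg@stackedHiddenSizes
  if (cfg@interactionScope == "within_genes_only" && p > 1) {
    bm <- buildStackMask(widths, cfg@stackedHiddenSizes)
    stackMask <- bm$masks
    stackSizes <- bm$stackSizes
  }
  cfg@stackedHiddenSizes <- as.integer(stackSizes)
  new("TransferModel",
      geneNetworks = geneNets, geneIds = ids,
      variantIndices = variantIndices,
      stack = list(), gamma0 = 1, background = background,
      config = cfg, outcomeType = outcomeType, stackMask = stackMask,
      trained = FALSE, lossHistory = numeric(0))
}

#' @rdname parameterCounts
#' @details Frozen parameters are those of the gene hidden layers feeding
#'   the stack (the screening networks' output heads are not part of the
#'   prediction architecture). Trainable parameters are the stacked-layer
#'   weights and biases (non-zero wiring only, under a sparse scope), the
#'   output head, and the scalar background weight. In optimal mode the
#'   frozen set moves into the trainable count.
#' @export
setMethod("parameterCounts", "TransferModel", function(object) {
  geneCount <- 0L
  for (net in object@geneNetworks) {
    W <- net@weights$W; b <- net@weights$b
    for (l in seq_len(length(W) - 1))  # hidden layers only
      geneCount <- geneCount + length(W[[l]]) + length(b[[l]])
  }
  inW <- if (length(object@geneNetworks) > 0)
    sum(vapply(object@geneNetworks, geneHiddenWidth, integer(1))) else 1L
  dims <- c(inW, object@config@stackedHiddenSizes, 1L)
  stackCount <- 0L
  for (l in seq_len(length(dims) - 1)) {
    wEntries <- if (l <= length(object@stackMask) &&
                    !is.null(object@stackMask[[l]]))
      sum(object@stackMask[[l]] != 0) else dims[l] * dims[l + 1]
    stackCount <- stackCount + wEntries + dims[l + 1]
  }
  trainable <- stackCount + 1L  # + gamma0
  if (object@config@mode == "optimal") {
    list(trainable = trainable + geneCount, frozen = 0L)
  } else {
    list(trainable = trainable, frozen = geneCount)
  }
})

# Fresh He-style initialisation matching the shapes of an existing weight
# set (hidden biases spread, output bias zero), drawn from the ambient RNG.
reinitWeights <- function(w) {
  L <- length(w$W)
  for (l in seq_len(L)) {
    fanIn <- nrow(w$W[[l]])
    w$W[[l]] <- matrix(stats::rnorm(length(w$W[[l]]), 0, sqrt(2 / fanIn)),
                       nrow = fanIn)
    w$b[[l]] <- if (l < L) stats::rnorm(length(w$b[[l]]), 0, 0.5)
                else rep(0, length(w$b[[l]]))
  }
  w
}

# Per-gene dosage blocks in model order, standardized with each network's
# stored training transform (the frozen feature extractors expect the same
# input scale they were trained on).
modelXlist <- function(model, genotypes) {
  d <- if (is(genotypes, "GenotypeData")) dosages(genotypes)
       else as.matrix(genotypes)
  lapply(seq_along(model@geneNetworks), function(k) {
    idx <- model@variantIndices[[k]]
    if (is.null(idx)) stop("variant columns unknown for gene '",
                           model@geneIds[k], "'")
    if (max(idx) > ncol(d))
      stop("genotype matrix lacks the columns of gene '",
           model@geneIds[k], "'")
    standardizeInputs(model@geneNetworks[[k]], d[, idx, drop = FALSE])
  })
}

#' Train the transfer prediction network
#'
#' Transfer mode updates only the background weight and the stacked layers;
#' the per-gene parameters are bitwise untouched. Optimal mode retrains the
#' gene hidden layers jointly (dropout after each gene's first hidden layer
#' stays active, matching the screening architecture). Loss is mean squared
#' error for continuous outcomes and cross-entropy for binary ones.
#'
#' @param model a \linkS4class{TransferModel} from
#'   \code{\link{buildTransferNetwork}}
#' @param genotypes training \linkS4class{GenotypeData} or dosage matrix
#' @param y training phenotype; defaults to the phenotype attached to
#'   \code{genotypes}
#' @param background per-sample background values; defaults to the training
#'   BLUPs of the model's \linkS4class{BackgroundModel}
#' @return the trained \linkS4class{TransferModel}
#' @export
fitTransferModel <- function(model, genotypes, y = NULL, background = NULL) {
  if (is.null(y) && is(genotypes, "GenotypeData")) y <- phenotype(genotypes)
  if (is.null(y)) stop("no phenotype supplied")
  if (is.null(background))
    background <- if (length(model@background@blupCV) > 0 &&
                      any(model@background@blupCV != 0))
      model@background@blupCV else model@background@blup
  n <- length(y)
  if (length(background) == 0) background <- rep(0, n)
  if (length(background) != n)
    stop("background length does not match phenotype")
  cfg <- model@config
  freeze <- cfg@mode == "transfer"
  Xlist <- modelXlist(model, genotypes)
  geneNets <- lapply(model@geneNetworks, function(g) g@weights)
  if (!freeze) {
    # optimal mode retrains the whole architecture from scratch: the gene
    # subnets start from a fresh random initialisation rather than the
    # pre-trained weights, so the comparison with transfer mode contrasts
    # training regimes, not starting points
    geneNets <- withSeed(
      if (is.na(cfg@seed)) NA else deriveSeed(cfg@seed, 91),
      lapply(geneNets, reinitWeights))
  }
  dropout <- if (length(model@geneNetworks) > 0)
    model@geneNetworks[[1]]@config@dropoutRate else 0
  if (!all(vapply(Xlist, nrow, integer(1)) == n) && length(Xlist) > 0)
    stop("genotype rows do not match phenotype length")
  mask <- if (length(model@stackMask) > 0) model@stackMask else NULL
  fit <- withSeed(cfg@seed,
    cpp_composite_fit(geneNets, Xlist, as.numeric(background),
                      as.numeric(y), cfg@stackedHiddenSizes, dropout,
                      dropout, freeze, model@outcomeType == "binary",
                      cfg@epochs, cfg@learningRate, cfg@batchSize, mask))
  if (!all(is.finite(fit$loss)))
    stop("training diverged: non-finite loss at epoch ",
         which(!is.finite(fit$loss))[1])
  if (!freeze) {
    for (k in seq_along(model@geneNetworks))
      model@geneNetworks[[k]]@weights <- fit$genes[[k]]
  }
  model@stack <- fit$stack
  model@gamma0 <- fit$gamma0
  model@trained <- TRUE
  model@lossHistory <- as.numeric(fit$loss)
  model
}

#' @rdname predictRisk
#' @param background per-sample background values for the prediction
#'   samples (from \code{\link{predictBackground}} for held-out samples, or
#'   the training BLUPs for training samples)
#' @param parts return the additive decomposition as a data.frame
#' @param ablateStack zero the gene-stack contribution (gBLUP limit)
#' @export
setMethod("predictRisk", "TransferModel",
function(object, genotypes, background = NULL, parts = FALSE,
         ablateStack = FALSE, ...) {
  if (!object@trained) stop("model is not trained")
  Xlist <- modelXlist(object, genotypes)
  n <- if (length(Xlist) > 0) nrow(Xlist[[1]])
       else if (is(genotypes, "GenotypeData")) nSamples(genotypes)
       else nrow(as.matrix(genotypes))
  if (is.null(background)) background <- rep(0, n)
  pr <- cpp_composite_predict(lapply(object@geneNetworks, function(g) g@weights),
                              object@stack, object@gamma0, Xlist,
                              as.numeric(background),
                              object@outcomeType == "binary")
  if (ablateStack) {
    z <- as.numeric(pr$bg_part)
    pred <- if (object@outcomeType == "binary") stats::plogis(z) else z
    genePart <- rep(0, n)
  } else {
    pred <- as.numeric(pr$pred)
    z <- as.numeric(pr$linear)
    genePart <- as.numeric(pr$gene_part)
  }
  if (parts)
    return(data.frame(prediction = pred, linear = z, genePart = genePart,
                      backgroundPart = as.numeric(pr$bg_part)))
  pred
})

setMethod("show", "TransferModel", function(object) {
  pc <- parameterCounts(object)
  cat("TransferModel (", object@config@mode, ", ",
      object@config@interactionScope, "): ",
      length(object@geneNetworks), " gene nets -> stack [",
      paste(object@config@stackedHiddenSizes, collapse = ", "),
      "] + background\n", sep = "")
  cat("  trainable parameters:", pc$trainable, "| frozen:", pc$frozen,
      "|", if (object@trained) "trained" else "untrained", "\n")
})

#' Run the two-stage pipeline end to end
#'
#' Splits samples into training and held-out sets, screens gene regions on
#' the training set, fits the gBLUP background on all training variants,
#' builds and trains the transfer network on the selected genes, and
#' reports held-out accuracy (Pearson correlation for continuous outcomes,
#' AUC for binary).
#'
#' @param dataset a \linkS4class{SimulatedDataset}, or a
#'   \linkS4class{GenotypeData} with phenotype (then supply \code{regions})
#' @param screenCfg \linkS4class{NetworkConfig} for the screening networks
#' @param transferCfg \linkS4class{TransferConfig} for the prediction model
#' @param alpha screening threshold (default 0.001)
#' @param K screening folds
#' @param nPerm permutations per fold
#' @param testFraction held-out fraction (default 0.2)
#' @param seed master seed (split, screening, training)
#' @param regions regions when \code{dataset} is a
#'   \linkS4class{GenotypeData}
#' @param useBackground set \code{FALSE} to omit the background node
#' @return list with \code{screen} (\linkS4class{ScreenResult}),
#'   \code{model}, \code{background}, \code{testIdx}, \code{predictions},
#'   and \code{metrics}
#' @export
runPipeline <- function(dataset, screenCfg = NetworkConfig(),
                        transferCfg = TransferConfig(), alpha = 0.001,
                        K = 20, nPerm = 100, testFraction = 0.2, seed = 1,
                        regions = NULL, useBackground = TRUE) {
  if (is(dataset, "SimulatedDataset")) {
    gd <- dataset@genotypes
    regions <- dataset@regions
  } else {
    gd <- dataset
    if (is.null(regions)) stop("supply 'regions' for GenotypeData input")
  }
  y <- phenotype(gd)
  if (is.null(y)) stop("no phenotype attached")
  ot <- outcomeType(gd)
  n <- nSamples(gd)
  testIdx <- withSeed(deriveSeed(seed, 71),
                      sort(sample.int(n, round(testFraction * n))))
  trainIdx <- setdiff(seq_len(n), testIdx)
  d <- dosages(gd)
  dTr <- d[trainIdx, , drop = FALSE]
  dTe <- d[testIdx, , drop = FALSE]
  yTr <- y[trainIdx]; yTe <- y[testIdx]

  gdTr <- GenotypeData(dTr,
                       variants = SummarizedExperiment::rowRanges(gd),
                       sampleIds = colnames(gd)[trainIdx],
                       outcomeType = ot)
  phenotype(gdTr) <- yTr
  sr <- screenGenome(gdTr, screenCfg, K = K, alpha = alpha, nPerm = nPerm,
                     seed = deriveSeed(seed, 72), regions = regions)

  if (useBackground) {
    grm <- computeGRM(dTr)
    bgModel <- fitGBLUP(grm, yTr)
    bgTrain <- bgModel@blupCV
    bgTest <- predictBackground(bgModel, dTr, dTe)
  } else {
    bgModel <- new("BackgroundModel", varG = 0, varE = 1, mu = mean(yTr),
                   blup = numeric(0), blupCV = numeric(0),
                   alpha = numeric(0),
                   wAlpha = numeric(0), freqs = numeric(0),
                   keep = integer(0), nVariants = 0L, reml = list())
    bgTrain <- rep(0, length(trainIdx))
    bgTest <- rep(0, length(testIdx))
  }

  tCfg <- transferCfg
  if (is.na(tCfg@seed)) tCfg@seed <- deriveSeed(seed, 73)
  model <- buildTransferNetwork(
    geneNetworks(sr), bgModel, tCfg,
    variantIndices = regionIndices(regions)[selectedGenes(sr)],
    outcomeType = ot)
  model <- fitTransferModel(model, dTr, y = yTr, background = bgTrain)
  predTest <- predictRisk(model, dTe, background = bgTest)

  metrics <- if (ot == "binary") {
    list(auc = if (length(unique(yTe)) == 2) rocAUC(yTe, predTest) else NA_real_)
  } else {
    list(pearson = if (stats::sd(predTest) > 0) pearsonCor(yTe, predTest)
                   else 0)
  }
  list(screen = sr, model = model, background = bgModel,
       trainIdx = trainIdx, testIdx = testIdx,
       backgroundTest = bgTest, predictions = predTest, metrics = metrics)
}
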