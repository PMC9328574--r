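#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Genotype dosage container
#'
#' Thin wrapper around \linkS4class{RangedSummarizedExperiment} holding an
#' allele-dosage matrix (variants in rows, samples in columns, values in
#' \{0, 1, 2\} with \code{NA} for missing calls), variant coordinates as the
#' \code{rowRanges}, and the phenotype in \code{colData}. All numerical code
#' in the package works with the transposed n-by-m view returned by
#' \code{\link{dosages}}.
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (!"dosage" %in% names(a))
    return("assay 'dosage' is required")
  d <- a[["dosage"]]
  ok <- is.na(d) | (d >= 0 & d <= 2)
  if (!all(ok))
    return("dosage values must lie in [0, 2] or be NA")
  TRUE
})

#' Gene regions: named groups of variant columns
#'
#' Maps each gene to the (strictly increasing) column indices of its variants
#' in the paired \linkS4class{GenotypeData}. Produced by
#' \code{\link{groupVariants}} or by the simulator.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot indices list of integer vectors, parallel to \code{geneIds}.
#' @export
setClass("GeneRegionList",
         representation(geneIds = "character", indices = "list"))

setValidity("GeneRegionList", function(object) {
  if (length(object@geneIds) != length(object@indices))
    return("geneIds and indices must have equal length")
  if (anyDuplicated(object@geneIds))
    return("gene identifiers must be unique")
  for (i in seq_along(object@indices)) {
    idx <- object@indices[[i]]
    if (length(idx) == 0)
      return(sprintf("region '%s' has no variants", object@geneIds[i]))
    if (any(idx < 1) || is.unsorted(idx, strictly = TRUE))
      return(sprintf("indices of region '%s' must be strictly increasing positive integers",
                     object@geneIds[i]))
  }
  TRUE
})

#' Architecture and training settings for a per-gene network
#'
#' Defaults follow the screening-stage reference architecture: two hidden
#' layers of 50 and 10 units, dropout (default rate 0.2) after the first
#' hidden layer, 100 training epochs with Adam at learning rate 3e-3 on
#' minibatches of 32. \code{batchSize = 0} requests full-batch training.
#'
#' @export
setClass("NetworkConfig",
         representation(hiddenSizes = "integer", dropoutRate = "numeric",
                        epochs = "integer", learningRate = "numeric",
                        batchSize = "integer", seed = "integer"))

setValidity("NetworkConfig", function(object) {
  if (any(object@hiddenSizes < 1)) return("hidden layer widths must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must be in [0, 1)")
  if (object@epochs < 1) return("epochs must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be positive")
  TRUE
})

#' A trained per-gene multi-layer perceptron
#'
#' Stores the fitted parameters, the architecture record and the outcome
#' type. Inference is deterministic (dropout is train-time only); the
#' last-hidden-layer transform used by the transfer model is exposed via
#' \code{\link{hiddenActivations}}.
#'
#' @export
setClass("GeneNetwork",
         representation(geneId = "character", weights = "list",
                        config = "NetworkConfig", outcomeType = "character",
                        nInputs = "integer", center = "numeric",
                        scale = "numeric", lossHistory = "numeric"))

#' Per-fold screening score
#' @export
setClass("FoldScore",
         representation(fold = "integer", trainIdx = "integer",
                        validIdx = "integer", delta = "numeric",
                        var = "numeric", perSubjectLoss = "numeric"))

setValidity("FoldScore", function(object) {
  if (length(intersect(object@trainIdx, object@validIdx)) > 0)
    return("train and validation indices overlap")
  if (object@var < 0) return("variance must be non-negative")
  if (abs(object@delta - sum(object@perSubjectLoss)) > 1e-8 * max(1, abs(object@delta)))
    return("delta must equal the sum of per-subject losses")
  TRUE
})

#' K-fold aggregated importance result for one gene
#'
#' Holds the group-wise feature importance score (mean of the K per-fold
#' scores), its standard error, the one-sided z statistic and lower-tail
#' normal p-value.
#'
#' @export
setClass("ImportanceResult",
         representation(geneId = "character", nVariants = "integer",
                        foldScores = "list", delta = "numeric",
                        se = "numeric", z = "numeric", p = "numeric",
                        K = "integer"))

setValidity("ImportanceResult", function(object) {
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  if (length(object@foldScores) != object@K)
    return("K must equal the number of fold scores")
  TRUE
})

#' Genome-wide screening result
#'
#' @slot table \code{DataFrame} with one row per gene (delta, se, z, p,
#'   selected flag) in input order.
#' @slot results list of \linkS4class{ImportanceResult}.
#' @slot networks list of refitted \linkS4class{GeneNetwork} objects for the
#'   selected genes.
#' @slot alpha the screening threshold applied.
#' @export
setClass("ScreenResult",
         representation(table = "DataFrame", results = "list",
                        networks = "list", alpha = "numeric"))

#' Genomic relationship matrix
#' @export
setClass("GRM",
         representation(matrix = "matrix", nVariants = "integer",
                        freqs = "numeric", keep = "integer",
                        sampleIds = "character"))

setValidity("GRM", function(object) {
  if (nrow(object@matrix) != ncol(object@matrix)) return("GRM must be square")
  if (max(abs(object@matrix - t(object@matrix))) > 1e-8)
    return("GRM must be symmetric")
  TRUE
})

#' Fitted gBLUP background model
#'
#' Variance components estimated by restricted maximum likelihood on the
#' eigendecomposition of the GRM, training-sample BLUPs (the background-node
#' inputs), and the projection data needed to predict the background value
#' for held-out samples from their cross-relationship with the training set.
#'
#' @export
setClass("BackgroundModel",
         representation(varG = "numeric", varE = "numeric", mu = "numeric",
                        blup = "numeric", blupCV = "numeric",
                        alpha = "numeric",
                        wAlpha = "numeric", freqs = "numeric",
                        keep = "integer", nVariants = "integer",
                        reml = "list"))

setValidity("BackgroundModel", function(object) {
  if (object@varG < 0 || object@varE < 0)
    return("variance components must be non-negative")
  TRUE
})

#' Settings for the transfer prediction network
#'
#' @slot mode \code{"transfer"} keeps the per-gene parameters frozen and
#'   trains only the stacked layers and the background weight;
#'   \code{"optimal"} retrains everything.
#' @slot interactionScope \code{"between_genes"} concatenates all last-hidden
#'   activations into one fully connected stack; \code{"within_genes_only"}
#'   gives each gene a private stack (block-diagonal weights) joined only at
#'   the output node.
#' @export
setClass("TransferConfig",
         representation(stackedHiddenSizes = "integer", epochs = "integer",
                        learningRate = "numeric", batchSize = "integer",
                        mode = "character", interactionScope = "character",
                        seed = "integer"))

setValidity("TransferConfig", function(object) {
  if (any(object@stackedHiddenSizes < 1)) return("stack widths must be positive")
  if (!object@mode %in% c("transfer", "optimal"))
    return("mode must be 'transfer' or 'optimal'")
  if (!object@interactionScope %in% c("between_genes", "within_genes_only"))
    return("interactionScope must be 'between_genes' or 'within_genes_only'")
  TRUE
})

#' Transfer-learning prediction model
#'
#' Frozen (or retrained, in optimal mode) per-gene networks feeding stacked
#' hidden layers, plus a scalar-weighted gBLUP background node entering
#' additively on the linear-predictor scale.
#'
#' @export
setClass("TransferModel",
         representation(geneNetworks = "list", geneIds = "character",
                        variantIndices = "list", stack = "list",
                        gamma0 = "numeric", background = "BackgroundModel",
                        config = "TransferConfig", outcomeType = "character",
                        stackMask = "list", trained = "logical",
                        lossHistory = "numeric"))

#' Simulation design
#'
#' Encodes the synthetic study conditions: sample size, the gene panel with
#' per-gene roles (linear with 90\% or 10\% causal variants, pairwise
#' interaction, cosine, or null), effect scales, the four indicator switches
#' of the disease models, the outcome link, and the genotype model
#' (minor-allele-frequency range and within-gene LD decay).
#'
#' @export
setClass("SimulationSpec",
         representation(n = "integer", genes = "data.frame",
                        causalFraction = "numeric", effectScales = "list",
                        switches = "numeric", noiseSd = "numeric",
                        link = "character", mafRange = "numeric",
                        ldDecay = "numeric", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  if (object@n < 2) return("n must be >= 2")
  if (!all(c("gene_id", "n_k", "role") %in% names(object@genes)))
    return("genes must have columns gene_id, n_k, role")
  if (any(object@genes$n_k < 1)) return("each n_k must be >= 1")
  bad <- setdiff(object@genes$role,
                 c("linear90", "linear10", "interaction", "cosine", "null"))
  if (length(bad) > 0)
    return(paste("unknown gene role(s):", paste(bad, collapse = ", ")))
  if (any(object@causalFraction <= 0) || any(object@causalFraction > 1))
    return("causal fractions must lie in (0, 1]")
  if (length(object@switches) != 4)
    return("switches must have length 4 (I1..I4)")
  if (!object@link %in% c("gaussian", "logistic"))
    return("link must be 'gaussian' or 'logistic'")
  if (object@link == "gaussian" && object@noiseSd <= 0)
    return("noiseSd must be positive for the gaussian link")
  if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    return("mafRange must be an increasing pair within (0, 0.5]")
  if (object@ldDecay < 0 || object@ldDecay >= 1)
    return("ldDecay must lie in [0, 1)")
  TRUE
})

#' Simulated dataset bundle
#'
#' Genotypes, gene regions, phenotype, the latent mean vector, and the
#' ground-truth causal structure (per-gene and per-variant flags plus the
#' realized effect sizes), all reproducible from the spec seed.
#'
#' @export
setClass("SimulatedDataset",
         representation(genotypes = "GenotypeData", regions = "GeneRegionList",
                        mu = "numeric", truth = "list",
                        spec = "SimulationSpec"))

#' Resolved run configuration
#' @export
setClass("RunConfig",
         representation(paths = "list", alpha = "numeric", kFolds = "integer",
                        nPerm = "integer", network = "NetworkConfig",
                        transfer = "TransferConfig", seed = "integer",
                        logLevel = "character"))

setValidity("RunConfig", function(object) {
  if (object@alpha <= 0 || object@alpha > 1) return("alpha must lie in (0, 1]")
  if (object@kFolds < 2) return("kFolds must be >= 2")
  if (object@nPerm < 1) return("nPerm must be >= 1")
  TRUE
})
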