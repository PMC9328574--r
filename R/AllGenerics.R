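#' @rdname GenotypeData-class
#' @param x,object a \linkS4class{GenotypeData}
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname GenotypeData-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname GenotypeData-class
#' @param value replacement value
#' @export
setGeneric("phenotype<-", function(x, value) standardGeneric("phenotype<-"))

#' @rdname GenotypeData-class
#' @export
setGeneric("outcomeType", function(x) standardGeneric("outcomeType"))

#' @rdname GenotypeData-class
#' @export
setGeneric("outcomeType<-", function(x, value) standardGeneric("outcomeType<-"))

#' Replace missing dosages by per-variant means
#' @param x a \linkS4class{GenotypeData}
#' @export
setGeneric("imputeMissing", function(x) standardGeneric("imputeMissing"))

#' @rdname GeneRegionList-class
#' @param x a \linkS4class{GeneRegionList}
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneRegionList-class
#' @export
setGeneric("regionIndices", function(x) standardGeneric("regionIndices"))

#' Importance-test accessors
#' @param x an \linkS4class{ImportanceResult} or \linkS4class{ScreenResult}
#' @name importance-accessors
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))

#' @rdname importance-accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname importance-accessors
#' @export
setGeneric("geneNetworks", function(x) standardGeneric("geneNetworks"))

#' Last-hidden-layer activations of a fitted network
#'
#' @param object a \linkS4class{GeneNetwork}
#' @param X dosage block (samples by variants) for that gene
#' @return numeric matrix, one row per sample, one column per unit of the
#'   final hidden layer
#' @export
setGeneric("hiddenActivations",
           function(object, X) standardGeneric("hiddenActivations"))

#' Trainable/frozen parameter accounting of a transfer model
#' @param object a \linkS4class{TransferModel}
#' @export
setGeneric("parameterCounts",
           function(object) standardGeneric("parameterCounts"))

#' Risk prediction from a fitted model
#'
#' @param object a fitted \linkS4class{TransferModel}
#' @param genotypes a \linkS4class{GenotypeData} (or dosage matrix) carrying
#'   the same variant columns as at training time
#' @param ... further arguments (\code{parts = TRUE} returns the additive
#'   decomposition into gene-stack and background contributions;
#'   \code{ablateStack = TRUE} zeroes the gene-stack contribution, leaving
#'   the scalar-weighted background, i.e. the gBLUP-equivalent limit)
#' @export
setGeneric("predictRisk",
           function(object, genotypes, ...) standardGeneric("predictRisk"))
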