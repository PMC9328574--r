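#' Construct a GenotypeData object
#'
#' @param dosages numeric matrix of allele dosages with samples in rows and
#'   variants in columns; values in \code{[0, 2]} or \code{NA} for missing.
#' @param variants a \code{GRanges} of variant coordinates (one per column),
#'   or \code{NULL} to place variants at consecutive positions on a dummy
#'   chromosome. Metadata columns \code{ref}/\code{alt} are kept if present.
#' @param sampleIds sample identifiers; defaults to rownames or S1..Sn.
#' @param phenotype optional numeric phenotype vector, one value per sample.
#' @param outcomeType \code{"continuous"} or \code{"binary"}.
#' @return a \linkS4class{GenotypeData}
#' @export
GenotypeData <- function(dosages, variants = NULL, sampleIds = NULL,
                         phenotype = NULL, outcomeType = "continuous") {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages); m <- ncol(dosages)
  if (n == 0L || m == 0L)
    stop("empty input: need at least one sample and one variant")
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(dosages))) rownames(dosages)
                 else paste0("S", seq_len(n))
  if (is.null(variants)) {
    variants <- GenomicRanges::GRanges("chrU",
                                       IRanges::IRanges(seq_len(m), width = 1L))
    names(variants) <- if (!is.null(colnames(dosages))) colnames(dosages)
                       else paste0("v", seq_len(m))
  }
  dimnames(dosages) <- NULL
  if (length(variants) != m)
    stop("length(variants) must equal the number of dosage columns")
  if (is.null(names(variants)))
    names(variants) <- paste0("v", seq_len(m))
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosages)),
    rowRanges = variants, colData = cd)
  gd <- new("GenotypeData", se)
  S4Vectors::metadata(gd)$outcomeType <- outcomeType
  if (!is.null(phenotype))
    phenotype(gd) <- phenotype
  gd
}

#' @rdname GenotypeData-class
#' @export
setMethod("dosages", "GenotypeData", function(x) {
  t(SummarizedExperiment::assay(x, "dosage"))
})

#' @rdname GenotypeData-class
#' @export
setMethod("nSamples", "GenotypeData", function(x) ncol(x))

#' @rdname GenotypeData-class
#' @export
setMethod("nVariants", "GenotypeData", function(x) nrow(x))

#' @rdname GenotypeData-class
#' @export
setMethod("phenotype", "GenotypeData", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"phenotype" %in% names(cd)) return(NULL)
  cd$phenotype
})

#' @rdname GenotypeData-class
#' @export
setReplaceMethod("phenotype", "GenotypeData", function(x, value) {
  if (length(value) != ncol(x))
    stop("phenotype length must match sample count")
  ot <- outcomeType(x)
  if (identical(ot, "binary") && !all(value %in% c(0, 1)))
    stop("binary phenotype values must be in {0, 1}")
  SummarizedExperiment::colData(x)$phenotype <- as.numeric(value)
  x
})

#' @rdname GenotypeData-class
#' @export
setMethod("outcomeType", "GenotypeData", function(x) {
  ot <- S4Vectors::metadata(x)$outcomeType
  if (is.null(ot)) "continuous" else ot
})

#' @rdname GenotypeData-class
#' @export
setReplaceMethod("outcomeType", "GenotypeData", function(x, value) {
  value <- match.arg(value, c("continuous", "binary"))
  S4Vectors::metadata(x)$outcomeType <- value
  x
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", ncol(object), "samples x", nrow(object), "variants\n")
  nmiss <- sum(is.na(SummarizedExperiment::assay(object, "dosage")))
  cat("  missing calls:", nmiss, "\n")
  ph <- phenotype(object)
  cat("  phenotype:", if (is.null(ph)) "absent"
      else paste0(outcomeType(object), " (n=", length(ph), ")"), "\n")
})

#' Per-variant alternate allele frequencies
#'
#' Column means of the dosage matrix divided by two, ignoring missing calls.
#'
#' @param x a \linkS4class{GenotypeData}
#' @return named numeric vector of length \code{nVariants(x)}
#' @export
alleleFreqs <- function(x) {
  d <- dosages(x)
  colMeans(d, na.rm = TRUE) / 2
}

#' @rdname imputeMissing
#' @details Missing dosages are replaced by the per-variant mean of observed
#'   dosages; observed entries are never altered. A variant with all calls
#'   missing is an error.
#' @export
setMethod("imputeMissing", "GenotypeData", function(x) {
  d <- SummarizedExperiment::assay(x, "dosage")  # variants x samples
  miss <- is.na(d)
  if (!any(miss)) return(x)
  allMiss <- rowSums(!miss) == 0L
  if (any(allMiss))
    stop("variant(s) with all entries missing: ",
         paste(rownames(d)[allMiss], collapse = ", "))
  rm <- rowMeans(d, na.rm = TRUE)
  d[miss] <- rm[row(d)[miss]]
  SummarizedExperiment::assay(x, "dosage") <- d
  x
})

#' Optional variant filters
#'
#' Drops variants with minor allele frequency below \code{maf} or missing
#' rate above \code{missingRate}. Both filters are off (\code{NULL}) by
#' default; they are intended for real genotype panels rather than synthetic
#' data.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param maf minimum minor allele frequency, e.g. \code{0.01}
#' @param missingRate maximum per-variant missing rate, e.g. \code{0.05}
#' @export
filterVariants <- function(x, maf = NULL, missingRate = NULL) {
  keep <- rep(TRUE, nVariants(x))
  d <- SummarizedExperiment::assay(x, "dosage")
  if (!is.null(missingRate))
    keep <- keep & rowMeans(is.na(d)) <= missingRate
  if (!is.null(maf)) {
    p <- rowMeans(d, na.rm = TRUE) / 2
    keep <- keep & pmin(p, 1 - p) >= maf
  }
  x[keep, ]
}
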