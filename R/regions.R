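#' @rdname GeneRegionList-class
#' @param geneIds character vector of gene names
#' @param indices list of strictly increasing integer vectors of variant
#'   columns
#' @export
GeneRegionList <- function(geneIds, indices) {
  new("GeneRegionList", geneIds = as.character(geneIds),
      indices = lapply(indices, as.integer))
}

#' @rdname GeneRegionList-class
#' @export
setMethod("geneIds", "GeneRegionList", function(x) x@geneIds)

#' @rdname GeneRegionList-class
#' @export
setMethod("regionIndices", "GeneRegionList", function(x) {
  stats::setNames(x@indices, x@geneIds)
})

#' @rdname GeneRegionList-class
#' @export
setMethod("length", "GeneRegionList", function(x) length(x@geneIds))

#' @rdname GeneRegionList-class
#' @param i index or gene name
#' @export
setMethod("[[", "GeneRegionList", function(x, i) {
  if (is.character(i)) i <- match(i, x@geneIds)
  x@indices[[i]]
})

setMethod("show", "GeneRegionList", function(object) {
  nk <- lengths(object@indices)
  cat("GeneRegionList:", length(object), "regions,",
      sum(nk), "variants assigned\n")
  if (length(object) > 0)
    cat("  sizes:", paste(utils::head(paste0(object@geneIds, "=", nk), 8),
                          collapse = " "),
        if (length(object) > 8) "...\n" else "\n")
})

#' Group variants into gene regions
#'
#' Assigns each variant of \code{genotypes} to the annotation interval
#' containing its position (1-based, closed on both ends; both interval
#' boundaries are included). A variant falling inside several regions is
#' assigned to the first region in annotation order, with a warning, so that
#' signal is never double-counted. Variants in no region and regions with no
#' assigned variants are dropped.
#'
#' @param genotypes a \linkS4class{GenotypeData}
#' @param annotation a \code{GRanges} of regions (see
#'   \code{\link{readRegions}}) or a data.frame with columns
#'   \code{gene_id, chrom, start, end}
#' @return a \linkS4class{GeneRegionList} in annotation order
#' @export
groupVariants <- function(genotypes, annotation) {
  if (is.data.frame(annotation)) {
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(annotation)))
      stop("annotation data.frame needs columns: ",
           paste(need, collapse = ", "))
    gr <- GenomicRanges::GRanges(annotation$chrom,
            IRanges::IRanges(annotation$start, annotation$end))
    names(gr) <- annotation$gene_id
    annotation <- gr
  }
  if (!is(annotation, "GRanges")) stop("annotation must be GRanges or data.frame")
  if (is.null(names(annotation)))
    names(annotation) <- paste0("region", seq_along(annotation))
  vr <- SummarizedExperiment::rowRanges(genotypes)
  hits <- GenomicRanges::findOverlaps(vr, annotation, type = "within",
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(qh)) {
    warning("variant(s) overlap multiple regions; assigned to the first region in annotation order")
    ord <- order(qh, sh)
    qh <- qh[ord]; sh <- sh[ord]
    keep <- !duplicated(qh)
    qh <- qh[keep]; sh <- sh[keep]
  }
  ids <- character(0); idx <- list()
  for (r in seq_along(annotation)) {
    v <- sort(qh[sh == r])
    if (length(v) == 0) next
    ids <- c(ids, names(annotation)[r])
    idx <- c(idx, list(v))
  }
  GeneRegionList(ids, idx)
}
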