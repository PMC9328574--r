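#' Read a genotype dosage matrix from PLINK or VCF
#'
#' PLINK input is the classic BED/BIM/FAM triple (SNP-major BED); dosages
#' count the A1 allele. VCF input (plain or bgzipped) is parsed with
#' \pkg{vcfR}; dosages count the ALT allele. Missing calls become \code{NA}.
#' Sample and variant order are preserved from file.
#'
#' @param path for \code{format = "bed"}, the file prefix or the
#'   \code{.bed} path; for \code{format = "vcf"}, the VCF path.
#' @param format \code{"bed"} or \code{"vcf"}.
#' @return a \linkS4class{GenotypeData}
#' @export
readGenotypes <- function(path, format = c("bed", "vcf")) {
  format <- match.arg(format)
  if (format == "bed") readPlink(path) else readVcfDosages(path)
}

readPlink <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("PLINK file not found: ", f)
  bimTab <- data.table::fread(bim, header = FALSE,
    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  famTab <- data.table::fread(fam, header = FALSE)
  n <- nrow(famTab); m <- nrow(bimTab)
  if (n == 0L || m == 0L) stop("empty PLINK input: zero samples or variants")
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major PLINK BED files are supported")
  bpv <- ceiling(n / 4)  # bytes per variant
  body <- raw[-(1:3)]
  if (length(body) != bpv * m)
    stop("PLINK BED payload size does not match BIM/FAM dimensions")
  # unpack 2-bit genotype codes: 00 -> 2 (hom A1), 10 -> 1 (het),
  # 11 -> 0 (hom A2), 01 -> NA (missing)
  codes <- as.integer(body)
  bits <- matrix(0L, 4L, length(codes))
  for (s in 0:3) bits[s + 1L, ] <- bitwAnd(bitwShiftR(codes, 2L * s), 3L)
  lut <- c(2, NA, 1, 0)  # indexed by code + 1
  g <- matrix(lut[as.vector(bits) + 1L], nrow = 4L * bpv)
  g <- g[seq_len(n), , drop = FALSE]  # n x m
  variants <- GenomicRanges::GRanges(
    as.character(bimTab$chrom),
    IRanges::IRanges(bimTab$pos, width = 1L),
    ref = bimTab$a2, alt = bimTab$a1)
  names(variants) <- bimTab$id
  GenotypeData(g, variants = variants, sampleIds = as.character(famTab[[2]]))
}

readVcfDosages <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) stop("empty VCF input: zero variants")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF has no sample genotypes")
  cnt <- function(x) {
    alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(alleles, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == "." | a == ""))
        return(NA_real_)
      sum(a != "0")
    }, numeric(1))
  }
  d <- apply(gt, 2, cnt)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  fix <- v@fix
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- GenomicRanges::GRanges(
    fix[, "CHROM"], IRanges::IRanges(as.integer(fix[, "POS"]), width = 1L),
    ref = fix[, "REF"], alt = fix[, "ALT"])
  names(variants) <- ids
  GenotypeData(t(d), variants = variants, sampleIds = colnames(gt))
}

#' Write a GenotypeData object as a PLINK BED/BIM/FAM triple
#'
#' Dosages are hard calls; fractional values are an error. Used by the
#' fixture generator and round-trip tests.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param prefix output path prefix
#' @return the prefix, invisibly
#' @export
writePlink <- function(x, prefix) {
  d <- dosages(x)
  if (any(!is.na(d) & d != round(d)))
    stop("writePlink requires hard-called dosages in {0, 1, 2}")
  n <- nrow(d); m <- ncol(d)
  gr <- SummarizedExperiment::rowRanges(x)
  ref <- if (!is.null(gr$ref)) gr$ref else rep("A", m)
  alt <- if (!is.null(gr$alt)) gr$alt else rep("B", m)
  bim <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    id = names(gr), cm = 0L,
                    pos = GenomicRanges::start(gr), a1 = alt, a2 = ref)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE)
  sid <- colnames(x)
  fam <- data.frame(fid = sid, iid = sid, pat = 0L, mat = 0L, sex = 0L,
                    phe = -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE)
  # pack: dosage 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, m)
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[is.na(d)] <- 1L
  bpv <- ceiling(n / 4)
  pad <- matrix(0L, 4L * bpv - n, m)
  codePad <- rbind(code, pad)
  shifts <- rep(c(0L, 2L, 4L, 6L), bpv)
  bytes <- vapply(seq_len(m), function(j) {
    v <- bitwShiftL(codePad[, j], shifts)
    as.integer(colSums(matrix(v, nrow = 4L)))
  }, integer(bpv))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Write a GenotypeData object as a minimal VCF 4.2 text file
#'
#' @param x a \linkS4class{GenotypeData} with hard-called dosages
#' @param path output path
#' @export
writeVcf <- function(x, path) {
  d <- dosages(x)
  if (any(!is.na(d) & d != round(d)))
    stop("writeVcf requires hard-called dosages in {0, 1, 2}")
  gr <- SummarizedExperiment::rowRanges(x)
  ref <- if (!is.null(gr$ref)) gr$ref else rep("A", ncol(d))
  alt <- if (!is.null(gr$alt)) gr$alt else rep("C", ncol(d))
  gtStr <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(x)), collapse = "\t"))
  rows <- vapply(seq_len(ncol(d)), function(j) {
    gt <- ifelse(is.na(d[, j]), "./.", gtStr[d[, j] + 1L])
    paste(c(as.character(GenomicRanges::seqnames(gr))[j],
            GenomicRanges::start(gr)[j], names(gr)[j], ref[j], alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Expects a tab-delimited file with header \code{sample_id<TAB>phenotype}.
#' If \code{genotypes} is supplied, values are matched to its sample order
#' and attached to the returned object.
#'
#' @param path phenotype TSV path
#' @param genotypes optional \linkS4class{GenotypeData} to attach to
#' @param outcomeType \code{"continuous"}, \code{"binary"}, or
#'   \code{"auto"} (binary iff all values are 0/1)
#' @export
readPhenotype <- function(path, genotypes = NULL, outcomeType = "auto") {
  tab <- data.table::fread(path, header = TRUE)
  if (ncol(tab) < 2) stop("phenotype file needs sample_id and phenotype columns")
  ids <- as.character(tab[[1]]); y <- as.numeric(tab[[2]])
  if (outcomeType == "auto")
    outcomeType <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  if (is.null(genotypes))
    return(list(sampleIds = ids, values = y, outcomeType = outcomeType))
  idx <- match(colnames(genotypes), ids)
  if (anyNA(idx))
    stop("phenotype file is missing sample(s): ",
         paste(head(colnames(genotypes)[is.na(idx)]), collapse = ", "))
  outcomeType(genotypes) <- outcomeType
  phenotype(genotypes) <- y[idx]
  genotypes
}

#' Read a gene/region annotation as GRanges
#'
#' BED and GFF3 are supported through \pkg{rtracklayer}, which converts BED's
#' 0-based half-open coordinates to the 1-based closed convention used
#' throughout. Region names are taken from the BED name column or the GFF3
#' \code{ID}/\code{Name}/\code{gene_id} attribute.
#'
#' @param path annotation path (.bed, .gff3/.gff)
#' @export
readRegions <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("malformed annotation '", path,
                                          "': ", conditionMessage(e)))
  nm <- NULL
  for (col in c("name", "ID", "Name", "gene_id"))
    if (col %in% names(S4Vectors::mcols(gr)) && is.null(nm)) {
      v <- as.character(S4Vectors::mcols(gr)[[col]])
      if (!all(is.na(v))) nm <- v
    }
  if (is.null(nm)) nm <- paste0("region", seq_along(gr))
  names(gr) <- nm
  gr
}

#' Write the per-gene importance table
#'
#' Tab-delimited with columns \code{gene_id, n_variants, delta, se, z, p},
#' one row per gene in input order. P-values are serialized at full
#' precision so that round-trip reads are exact.
#'
#' @param results a \linkS4class{ScreenResult}, a list of
#'   \linkS4class{ImportanceResult}, or a data.frame with the six columns
#' @param path output path
#' @export
writeImportanceTable <- function(results, path) {
  tab <- importanceAsDataFrame(results)
  if (nrow(tab) == 0) stop("no results to write")
  fmt <- function(v) sprintf("%.17g", v)
  out <- data.frame(gene_id = tab$gene_id, n_variants = tab$n_variants,
                    delta = fmt(tab$delta), se = fmt(tab$se),
                    z = fmt(tab$z), p = fmt(tab$p))
  ok <- tryCatch({
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write importance table to '", path,
                              "': ", conditionMessage(e)))
  invisible(path)
}

#' @rdname writeImportanceTable
#' @export
readImportanceTable <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           colClasses = list(character = "gene_id"))
  as.data.frame(tab)
}

importanceAsDataFrame <- function(results) {
  if (is(results, "ScreenResult"))
    return(as.data.frame(results@table[, c("gene_id", "n_variants", "delta",
                                           "se", "z", "p")]))
  if (is.data.frame(results)) return(results)
  if (is.list(results) && all(vapply(results, is, logical(1), "ImportanceResult"))) {
    if (length(results) == 0) stop("no results to write")
    return(data.frame(
      gene_id = vapply(results, function(r) r@geneId, character(1)),
      n_variants = vapply(results, function(r) r@nVariants, integer(1)),
      delta = vapply(results, function(r) r@delta, numeric(1)),
      se = vapply(results, function(r) r@se, numeric(1)),
      z = vapply(results, function(r) r@z, numeric(1)),
      p = vapply(results, function(r) r@p, numeric(1))))
  }
  stop("unsupported results object")
}

#' Import a GCTA binary GRM
#'
#' Reads the \code{.grm.bin} / \code{.grm.id} pair written by GCTA
#' (lower-triangle float32 values).
#'
#' @param prefix path prefix (without extensions)
#' @export
readGRMBin <- function(prefix) {
  ids <- data.table::fread(paste0(prefix, ".grm.id"), header = FALSE)
  n <- nrow(ids)
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", size = 4,
                  n = n * (n + 1) / 2)
  G <- matrix(0, n, n)
  G[upper.tri(G, diag = TRUE)] <- vals
  G <- G + t(G) - diag(diag(G))
  nv <- 0L
  nbin <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nbin))
    nv <- as.integer(readBin(nbin, "numeric", size = 4, n = 1))
  new("GRM", matrix = G, nVariants = nv, freqs = numeric(0),
      keep = integer(0), sampleIds = as.character(ids[[2]]))
}

#' Export BLUP values as a two-column TSV
#'
#' @param model a \linkS4class{BackgroundModel}
#' @param sampleIds identifiers for the training samples
#' @param path output path
#' @export
exportBlup <- function(model, sampleIds, path) {
  stopifnot(length(sampleIds) == length(model@blup))
  data.table::fwrite(data.frame(sample_id = sampleIds, blup = model@blup),
                     path, sep = "\t")
  invisible(path)
}
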