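#' Default gene panel for the simulation design
#'
#' Four causal genes — linear with 90\% causal variants, linear with 10\%
#' causal variants, pairwise interaction, cosine — plus \code{nNull} genes
#' carrying only noise variants.
#'
#' @param nNull number of null genes (default 6, for a ten-gene panel)
#' @param nVariantsPerGene variants per gene (default 20)
#' @export
defaultGenePanel <- function(nNull = 6, nVariantsPerGene = 20) {
  roles <- c("linear90", "linear10", "interaction", "cosine",
             rep("null", nNull))
  data.frame(gene_id = sprintf("gene%02d", seq_along(roles)),
             n_k = as.integer(nVariantsPerGene), role = roles,
             stringsAsFactors = FALSE)
}

#' Construct a simulation design
#'
#' @param n sample count.
#' @param genes data.frame with columns \code{gene_id}, \code{n_k},
#'   \code{role} (\code{linear90}, \code{linear10}, \code{interaction},
#'   \code{cosine}, or \code{null}); default \code{\link{defaultGenePanel}()}.
#' @param causalFraction named causal-variant fractions for the two linear
#'   roles.
#' @param effectScales list with \code{sigma1}, \code{sigma2} (SDs of the
#'   per-variant effect draws for the two linear genes), fixed \code{beta3},
#'   \code{beta4}, and optionally \code{signalFraction}: a named vector
#'   giving, per causal role, the target variance of that gene's (centered)
#'   contribution relative to the noise variance. When present (the
#'   default), the drawn effects are rescaled once per dataset so each
#'   active term attains its target; the rescaled coefficients are what is
#'   stored in the truth record.
#' @param switches numeric length-4 indicator vector (I1..I4) activating the
#'   linear90, linear10, interaction and cosine terms.
#' @param noiseSd residual SD for the gaussian link.
#' @param link \code{"gaussian"} or \code{"logistic"}.
#' @param mafRange range for per-variant minor allele frequencies.
#' @param ldDecay within-gene LD parameter: latent haplotype correlation
#'   between adjacent variants decays as \code{ldDecay^distance}; 0 gives
#'   independent variants.
#' @param seed master seed; all randomness in the generated dataset derives
#'   from it.
#' @return a \linkS4class{SimulationSpec}
#' @export
SimulationSpec <- function(n = 1000, genes = defaultGenePanel(),
                           causalFraction = c(linear90 = 0.9, linear10 = 0.1),
                           effectScales = list(), switches = c(1, 1, 1, 1),
                           noiseSd = 1, link = "gaussian",
                           mafRange = c(0.05, 0.5), ldDecay = 0.5,
                           seed = 1L) {
  es <- list(sigma1 = 1, sigma2 = 1, beta3 = 1, beta4 = 1,
             signalFraction = c(linear90 = 0.25, linear10 = 0.25,
                                interaction = 0.25, cosine = 0.25))
  es[names(effectScales)] <- effectScales
  new("SimulationSpec", n = as.integer(n), genes = genes,
      causalFraction = causalFraction, effectScales = es,
      switches = as.numeric(switches), noiseSd = noiseSd, link = link,
      mafRange = mafRange, ldDecay = ldDecay, seed = as.integer(seed))
}

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec: n =", object@n, "|", nrow(object@genes), "genes (",
      sum(object@genes$role != "null"), "causal ) | link =", object@link,
      "| switches =", paste(object@switches, collapse = ""), "\n")
})

#' Set the indicator switches for a named disease model
#'
#' \code{S1}: linear effects only (1,1,0,0); \code{S2}: non-linear effects
#' only (0,0,1,1); \code{S3}: both (1,1,1,1).
#'
#' @param scenario one of \code{"S1"}, \code{"S2"}, \code{"S3"}
#' @param spec a \linkS4class{SimulationSpec} to modify
#' @export
makeDiseaseModel <- function(scenario, spec = SimulationSpec()) {
  sw <- switch(scenario,
               S1 = c(1, 1, 0, 0),
               S2 = c(0, 0, 1, 1),
               S3 = c(1, 1, 1, 1),
               stop("unknown scenario label: ", scenario))
  spec@switches <- sw
  validObject(spec)
  spec
}

# One gene's dosage block: two latent Gaussian haplotypes with AR(1)
# correlation ldDecay^|i-j|, each thresholded at the per-variant MAF
# quantile, summed. Marginals are Binomial(2, maf); within-gene LD comes
# from the shared latent correlation.
simulateGeneBlock <- function(n, nk, mafRange, ldDecay) {
  maf <- stats::runif(nk, mafRange[1], mafRange[2])
  thr <- stats::qnorm(1 - maf)
  g <- matrix(0L, n, nk)
  if (ldDecay > 0 && nk > 1) {
    R <- ldDecay^abs(outer(seq_len(nk), seq_len(nk), "-"))
    L <- chol(R)
    for (h in 1:2) {
      Z <- matrix(stats::rnorm(n * nk), n, nk) %*% L
      g <- g + (Z > rep(thr, each = n))
    }
  } else {
    for (h in 1:2) {
      Z <- matrix(stats::rnorm(n * nk), n, nk)
      g <- g + (Z > rep(thr, each = n))
    }
  }
  storage.mode(g) <- "double"
  attr(g, "maf") <- maf
  g
}

# Genomic coordinates for simulated genes: gene k occupies its own 10 kb
# window on chr1, one variant per base from the window start.
simulatedVariantRanges <- function(genes, offset = 0L) {
  chrom <- "chr1"
  pos <- integer(0); ids <- character(0)
  for (k in seq_len(nrow(genes))) {
    base <- (offset + k - 1L) * 10000L
    nk <- genes$n_k[k]
    pos <- c(pos, base + seq_len(nk))
    ids <- c(ids, sprintf("%s_v%03d", genes$gene_id[k], seq_len(nk)))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = "A", alt = "C")
  names(gr) <- ids
  gr
}

#' Region annotation for a simulated gene panel
#'
#' Returns the GRanges of gene windows matching the coordinates produced by
#' \code{\link{simulateGenotypes}}, usable with \code{\link{groupVariants}}
#' and writable as BED/GFF3 fixtures.
#'
#' @param spec a \linkS4class{SimulationSpec}
#' @export
regionAnnotation <- function(spec) {
  genes <- spec@genes
  starts <- (seq_len(nrow(genes)) - 1L) * 10000L + 1L
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(starts, starts + genes$n_k - 1L))
  names(gr) <- genes$gene_id
  gr
}

#' Simulate genotypes with within-gene LD
#'
#' Gaussian-copula surrogate for a real genotype panel: dosages are drawn
#' per gene from two latent multivariate-normal haplotypes with AR(1)
#' within-gene correlation, thresholded at quantiles matching each variant's
#' MAF drawn from \code{mafRange}. Genes are mutually independent. The one
#' property the screening method relies on — within-gene correlation
#' structure preserved under row permutation — is preserved by construction.
#'
#' @param spec a \linkS4class{SimulationSpec}
#' @return list with elements \code{genotypes} (a
#'   \linkS4class{GenotypeData}) and \code{regions}
#'   (a \linkS4class{GeneRegionList})
#' @export
simulateGenotypes <- function(spec) {
  validObject(spec)
  genes <- spec@genes
  withSeed(deriveSeed(spec@seed, 1), {
    blocks <- lapply(seq_len(nrow(genes)), function(k)
      simulateGeneBlock(spec@n, genes$n_k[k], spec@mafRange, spec@ldDecay))
  })
  d <- do.call(cbind, blocks)
  gr <- simulatedVariantRanges(genes)
  gd <- GenotypeData(d, variants = gr)
  ends <- cumsum(genes$n_k)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  regions <- GeneRegionList(genes$gene_id,
                            mapply(function(s, e) seq.int(s, e),
                                   starts, ends, SIMPLIFY = FALSE))
  list(genotypes = gd, regions = regions)
}

# Raw (uncentered, unscaled) per-gene term and its causal structure.
geneTerm <- function(X, role, causalFraction, effectScales) {
  nk <- ncol(X)
  switch(role,
    linear90 = ,
    linear10 = {
      frac <- if (role == "linear90") causalFraction[["linear90"]]
              else causalFraction[["linear10"]]
      sigma <- if (role == "linear90") effectScales$sigma1
               else effectScales$sigma2
      ncausal <- max(1L, round(frac * nk))
      causal <- sort(sample.int(nk, ncausal))
      beta <- numeric(nk)
      beta[causal] <- stats::rnorm(ncausal, 0, sigma)
      list(term = as.numeric(X %*% beta), beta = beta,
           causal = seq_len(nk) %in% causal)
    },
    interaction = {
      s <- rowSums(X)
      list(term = effectScales$beta3 * s^2,
           beta = effectScales$beta3, causal = rep(TRUE, nk))
    },
    cosine = {
      s <- rowSums(X)
      list(term = effectScales$beta4 * cos(s),
           beta = effectScales$beta4, causal = rep(TRUE, nk))
    },
    stop("geneTerm called on role ", role))
}

#' Simulate a phenotype under the four-term disease model
#'
#' The latent mean is the sum of the active gene terms: a linear term over
#' the causal variants of the linear90 gene, the same for the linear10
#' gene, a squared dosage-sum (pairwise interaction) term, and a cosine of
#' the dosage sum, each gated by its indicator switch. Per-variant linear
#' effects are drawn afresh for every dataset. Each active term is centered
#' at its sample mean (so the binary link keeps prevalence near 1/2) and,
#' when \code{signalFraction} targets are set, rescaled so its variance hits
#' the target; the stored truth record carries the effective (rescaled)
#' coefficients and centering offsets, from which the latent mean can be
#' re-evaluated exactly.
#'
#' The gaussian link adds N(0, noiseSd^2) noise; the logistic link draws
#' Bernoulli outcomes with success probability \code{plogis(mu)}.
#'
#' @param genotypes a \linkS4class{GenotypeData}
#' @param regions a \linkS4class{GeneRegionList}
#' @param spec a \linkS4class{SimulationSpec}
#' @return list with \code{phenotype} (numeric), \code{mu}, and
#'   \code{truth} (per-gene causal flags, per-variant causal flags,
#'   effective coefficients, offsets)
#' @export
simulatePhenotype <- function(genotypes, regions, spec) {
  validObject(spec)
  d <- dosages(genotypes)
  genes <- spec@genes
  roleOrder <- c("linear90", "linear10", "interaction", "cosine")
  active <- roleOrder[spec@switches != 0]
  missingRoles <- setdiff(active, genes$role)
  if (length(missingRoles) > 0)
    stop("switch active for role(s) absent from the gene panel: ",
         paste(missingRoles, collapse = ", "))
  n <- nrow(d)
  mu <- numeric(n)
  sf <- spec@effectScales$signalFraction
  truth <- list(geneCausal = logical(nrow(genes)),
                variantCausal = vector("list", nrow(genes)),
                beta = vector("list", nrow(genes)),
                offset = numeric(nrow(genes)),
                scale = numeric(nrow(genes)))
  names(truth$geneCausal) <- genes$gene_id
  names(truth$variantCausal) <- names(truth$beta) <- genes$gene_id
  withSeed(deriveSeed(spec@seed, 2), {
    for (k in seq_len(nrow(genes))) {
      role <- genes$role[k]
      idx <- regions[[genes$gene_id[k]]]
      truth$variantCausal[[k]] <- rep(FALSE, length(idx))
      truth$scale[k] <- 1
      if (role == "null" || !(role %in% active)) next
      tk <- geneTerm(d[, idx, drop = FALSE], role, spec@causalFraction,
                     spec@effectScales)
      sc <- 1
      if (!is.null(sf) && role %in% names(sf)) {
        sdT <- stats::sd(tk$term)
        if (sdT > 0)
          sc <- sqrt(sf[[role]]) * spec@noiseSd / sdT
      }
      term <- sc * tk$term
      off <- mean(term)
      mu <- mu + (term - off)
      truth$geneCausal[k] <- TRUE
      truth$variantCausal[[k]] <- tk$causal
      truth$beta[[k]] <- sc * tk$beta
      truth$offset[k] <- off
      truth$scale[k] <- sc
    }
    y <- if (spec@link == "gaussian") {
      mu + stats::rnorm(n, 0, spec@noiseSd)
    } else {
      stats::rbinom(n, 1, stats::plogis(mu))
    }
  })
  list(phenotype = as.numeric(y), mu = mu, truth = truth)
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper running \code{\link{simulateGenotypes}} and
#' \code{\link{simulatePhenotype}} and packaging the result. The whole
#' dataset is a pure function of the spec (including its seed).
#'
#' @param spec a \linkS4class{SimulationSpec}
#' @return a \linkS4class{SimulatedDataset}
#' @export
simulateDataset <- function(spec) {
  g <- simulateGenotypes(spec)
  ph <- simulatePhenotype(g$genotypes, g$regions, spec)
  gd <- g$genotypes
  outcomeType(gd) <- if (spec@link == "logistic") "binary" else "continuous"
  phenotype(gd) <- ph$phenotype
  new("SimulatedDataset", genotypes = gd, regions = g$regions,
      mu = ph$mu, truth = ph$truth, spec = spec)
}

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset:", nSamples(object@genotypes), "samples,",
      length(object@regions), "genes (",
      sum(object@truth$geneCausal), "causal )\n")
  cat("  link:", object@spec@link, "| var(mu) =",
      signif(stats::var(object@mu), 3), "\n")
})

#' Append noise genes to a simulated dataset
#'
#' Adds \code{count} null genes drawn independently of the phenotype (the
#' phenotype vector is untouched), with truth flags marking them
#' non-causal. Deterministic given the dataset's spec seed and
#' \code{count}.
#'
#' @param dataset a \linkS4class{SimulatedDataset}
#' @param count number of noise genes to append (>= 0)
#' @param nVariantsPerGene variants per appended gene
#' @export
addNoiseGenes <- function(dataset, count, nVariantsPerGene = 20) {
  stopifnot(count >= 0)
  if (count == 0) return(dataset)
  spec <- dataset@spec
  nOld <- nrow(spec@genes)
  newGenes <- data.frame(
    gene_id = sprintf("noise%02d", seq_len(count) + nOld),
    n_k = as.integer(nVariantsPerGene), role = "null",
    stringsAsFactors = FALSE)
  withSeed(deriveSeed(spec@seed, 3), {
    blocks <- lapply(seq_len(count), function(k)
      simulateGeneBlock(spec@n, newGenes$n_k[k], spec@mafRange,
                        spec@ldDecay))
  })
  dNew <- do.call(cbind, blocks)
  grNew <- simulatedVariantRanges(newGenes, offset = nOld)
  dAll <- cbind(dosages(dataset@genotypes), dNew)
  grAll <- c(SummarizedExperiment::rowRanges(dataset@genotypes), grNew)
  gd <- GenotypeData(dAll, variants = grAll,
                     sampleIds = colnames(dataset@genotypes),
                     outcomeType = outcomeType(dataset@genotypes))
  phenotype(gd) <- phenotype(dataset@genotypes)
  mOld <- nVariants(dataset@genotypes)
  ends <- mOld + cumsum(newGenes$n_k)
  starts <- c(mOld + 1L, utils::head(ends, -1) + 1L)
  regions <- GeneRegionList(
    c(geneIds(dataset@regions), newGenes$gene_id),
    c(dataset@regions@indices,
      mapply(function(s, e) seq.int(s, e), starts, ends, SIMPLIFY = FALSE)))
  truth <- dataset@truth
  truth$geneCausal <- c(truth$geneCausal,
                        stats::setNames(rep(FALSE, count), newGenes$gene_id))
  truth$variantCausal <- c(truth$variantCausal,
    stats::setNames(lapply(newGenes$n_k, function(nk) rep(FALSE, nk)),
                    newGenes$gene_id))
  truth$beta <- c(truth$beta,
    stats::setNames(vector("list", count), newGenes$gene_id))
  truth$offset <- c(truth$offset, rep(0, count))
  truth$scale <- c(truth$scale, rep(1, count))
  spec@genes <- rbind(spec@genes, newGenes)
  new("SimulatedDataset", genotypes = gd, regions = regions,
      mu = dataset@mu, truth = truth, spec = spec)
}
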