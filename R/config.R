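#' Parse a YAML run configuration
#'
#' Reads a structured configuration with blocks \code{paths},
#' \code{screening} (alpha, k_folds, n_perm, network settings),
#' \code{transfer}, plus \code{seed} and \code{log_level}. Unknown keys are
#' rejected; missing keys take the package defaults (alpha 0.001, K = 20,
#' 100 permutations, the reference network architectures).
#'
#' @param file path to a YAML file, or \code{NULL} for all defaults
#' @return a \linkS4class{RunConfig}
#' @export
parseRunConfig <- function(file = NULL) {
  cfg <- if (is.null(file)) list() else yaml::read_yaml(file)
  if (is.null(cfg)) cfg <- list()
  known <- c("paths", "screening", "transfer", "seed", "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  scr <- cfg$screening %||% list()
  knownScr <- c("alpha", "k_folds", "n_perm", "hidden_sizes",
                "dropout_rate", "epochs", "learning_rate", "batch_size")
  bad <- setdiff(names(scr), knownScr)
  if (length(bad) > 0)
    stop("unknown screening key(s): ", paste(bad, collapse = ", "))
  tr <- cfg$transfer %||% list()
  knownTr <- c("stacked_hidden_sizes", "epochs", "learning_rate",
               "batch_size", "mode", "interaction_scope")
  bad <- setdiff(names(tr), knownTr)
  if (length(bad) > 0)
    stop("unknown transfer key(s): ", paste(bad, collapse = ", "))
  alpha <- scr$alpha %||% 0.001
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("invalid value for key 'alpha': must lie in (0, 1]")
  net <- NetworkConfig(
    hiddenSizes = scr$hidden_sizes %||% c(50, 10),
    dropoutRate = scr$dropout_rate %||% 0.2,
    epochs = scr$epochs %||% 100,
    learningRate = scr$learning_rate %||% 3e-3,
    batchSize = scr$batch_size %||% 32)
  trans <- TransferConfig(
    stackedHiddenSizes = tr$stacked_hidden_sizes %||% c(100, 10),
    epochs = tr$epochs %||% 100,
    learningRate = tr$learning_rate %||% 3e-3,
    batchSize = tr$batch_size %||% 32,
    mode = tr$mode %||% "transfer",
    interactionScope = tr$interaction_scope %||% "between_genes")
  new("RunConfig",
      paths = cfg$paths %||% list(),
      alpha = alpha,
      kFolds = as.integer(scr$k_folds %||% 20),
      nPerm = as.integer(scr$n_perm %||% 100),
      network = net, transfer = trans,
      seed = as.integer(cfg$seed %||% 1),
      logLevel = cfg$log_level %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a RunConfig back to YAML
#'
#' \code{parseRunConfig(writeRunConfig(cfg, f))} reproduces \code{cfg}.
#'
#' @param cfg a \linkS4class{RunConfig}
#' @param file output path
#' @export
writeRunConfig <- function(cfg, file) {
  out <- list(
    paths = cfg@paths,
    screening = list(alpha = cfg@alpha, k_folds = cfg@kFolds,
                     n_perm = cfg@nPerm,
                     hidden_sizes = as.integer(cfg@network@hiddenSizes),
                     dropout_rate = cfg@network@dropoutRate,
                     epochs = cfg@network@epochs,
                     learning_rate = cfg@network@learningRate,
                     batch_size = cfg@network@batchSize),
    transfer = list(
      stacked_hidden_sizes = as.integer(cfg@transfer@stackedHiddenSizes),
      epochs = cfg@transfer@epochs,
      learning_rate = cfg@transfer@learningRate,
      batch_size = cfg@transfer@batchSize,
      mode = cfg@transfer@mode,
      interaction_scope = cfg@transfer@interactionScope),
    seed = cfg@seed,
    log_level = cfg@logLevel)
  yaml::write_yaml(out, file)
  invisible(file)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: alpha =", object@alpha, "| K =", object@kFolds,
      "| nPerm =", object@nPerm, "| seed =", object@seed, "\n")
})

#' Write the deterministic fixture set used by the test suite
#'
#' Generates a small simulated dataset and writes it in every supported
#' on-disk format: a PLINK BED/BIM/FAM triple, a VCF, region annotations as
#' BED and GFF3, a phenotype TSV, and the simulation spec as YAML (from
#' which the phenotype can be regenerated exactly). Byte-identical for a
#' given seed.
#'
#' @param outDir writable directory
#' @param seed master seed
#' @param n samples (default 30)
#' @param missingRate fraction of dosage calls masked as missing in the VCF
#'   copy (default 0 — the PLINK/VCF copies stay identical)
#' @return named list of the written paths
#' @export
makeFixtures <- function(outDir, seed = 1, n = 30, missingRate = 0) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  spec <- SimulationSpec(n = n,
                         genes = defaultGenePanel(nNull = 2,
                                                  nVariantsPerGene = 5),
                         seed = seed)
  ds <- simulateDataset(spec)
  gd <- ds@genotypes
  paths <- list(
    plink = file.path(outDir, "fixture"),
    vcf = file.path(outDir, "fixture.vcf"),
    bed = file.path(outDir, "regions.bed"),
    gff3 = file.path(outDir, "regions.gff3"),
    pheno = file.path(outDir, "phenotype.tsv"),
    spec = file.path(outDir, "simulation.yaml"))
  writePlink(gd, paths$plink)
  gdV <- gd
  if (missingRate > 0) {
    d <- dosages(gd)
    mask <- withSeed(deriveSeed(seed, 9),
                     matrix(stats::runif(length(d)) < missingRate,
                            nrow(d), ncol(d)))
    d[mask] <- NA
    gdV <- GenotypeData(d, variants = SummarizedExperiment::rowRanges(gd),
                        sampleIds = colnames(gd))
  }
  writeVcf(gdV, paths$vcf)
  ann <- regionAnnotation(spec)
  bedTab <- data.frame(chrom = as.character(GenomicRanges::seqnames(ann)),
                       start = GenomicRanges::start(ann) - 1L,  # 0-based
                       end = GenomicRanges::end(ann),
                       name = names(ann))
  data.table::fwrite(bedTab, paths$bed, sep = "\t", col.names = FALSE)
  gffRows <- sprintf("chr1\tDeepPRS\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     GenomicRanges::start(ann), GenomicRanges::end(ann),
                     names(ann))
  writeLines(c("##gff-version 3", gffRows), paths$gff3)
  data.table::fwrite(data.frame(sample_id = colnames(gd),
                                phenotype = phenotype(gd)),
                     paths$pheno, sep = "\t")
  yaml::write_yaml(list(n = spec@n,
                        genes = spec@genes,
                        causal_fraction = as.list(spec@causalFraction),
                        effect_scales = c(
                          spec@effectScales[c("sigma1", "sigma2", "beta3",
                                              "beta4")],
                          list(signalFraction =
                                 as.list(spec@effectScales$signalFraction))),
                        switches = spec@switches,
                        noise_sd = spec@noiseSd, link = spec@link,
                        maf_range = spec@mafRange, ld_decay = spec@ldDecay,
                        seed = spec@seed),
                   paths$spec)
  paths
}

#' Rebuild a SimulationSpec from a fixture YAML
#'
#' @param file path written by \code{\link{makeFixtures}}
#' @export
readSimulationSpec <- function(file) {
  s <- yaml::read_yaml(file)
  SimulationSpec(n = s$n,
                 genes = data.frame(gene_id = vapply(s$genes$gene_id, identity, character(1)),
                                    n_k = as.integer(unlist(s$genes$n_k)),
                                    role = unlist(s$genes$role),
                                    stringsAsFactors = FALSE),
                 causalFraction = unlist(s$causal_fraction),
                 effectScales = list(
                   sigma1 = s$effect_scales$sigma1,
                   sigma2 = s$effect_scales$sigma2,
                   beta3 = s$effect_scales$beta3,
                   beta4 = s$effect_scales$beta4,
                   signalFraction = unlist(s$effect_scales$signalFraction)),
                 switches = unlist(s$switches), noiseSd = s$noise_sd,
                 link = s$link, mafRange = unlist(s$maf_range),
                 ldDecay = s$ld_decay, seed = s$seed)
}
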