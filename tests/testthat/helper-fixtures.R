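# Shared fixture builders; everything is generated in code at test time.

# Tiny hard-called genotype container with known dosages.
tinyGenotypes <- function(d = NULL, phenotype = NULL,
                          outcomeType = "continuous") {
  if (is.null(d))
    d <- matrix(c(0, 1, 2,
                  2, 1, 0,
                  1, 1, 1,
                  0, 2, 0), nrow = 4, byrow = TRUE)
  GenotypeData(d, phenotype = phenotype, outcomeType = outcomeType)
}

# A small dataset with a strong linear gene plus null genes, for screening
# and transfer tests that need real signal quickly.
signalDataset <- function(n = 600, seed = 42, link = "gaussian",
                          nNull = 2, sf = 0.5) {
  panel <- data.frame(
    gene_id = c("sig", paste0("nul", seq_len(nNull))),
    n_k = 10L,
    role = c("linear90", rep("null", nNull)),
    stringsAsFactors = FALSE)
  spec <- SimulationSpec(n = n, genes = panel, switches = c(1, 0, 0, 0),
                         link = link,
                         effectScales = list(signalFraction = c(linear90 = sf)),
                         seed = seed)
  simulateDataset(spec)
}

# Pure-noise dataset: phenotype independent of every gene.
nullDataset <- function(n = 400, seed = 7, link = "gaussian", nGenes = 1,
                        nk = 20) {
  panel <- data.frame(gene_id = paste0("g", seq_len(nGenes)),
                      n_k = as.integer(nk), role = "null",
                      stringsAsFactors = FALSE)
  spec <- SimulationSpec(n = n, genes = panel, switches = c(0, 0, 0, 0),
                         link = link, seed = seed)
  simulateDataset(spec)
}

fastNet <- function(epochs = 20, seed = 1, ...) {
  NetworkConfig(epochs = epochs, seed = seed, ...)
}
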