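test_that("the generated dataset is a pure function of the spec seed", {
  spec <- SimulationSpec(n = 60, seed = 9)
  d1 <- simulateDataset(spec)
  d2 <- simulateDataset(spec)
  expect_identical(dosages(d1@genotypes), dosages(d2@genotypes))
  expect_identical(phenotype(d1@genotypes), phenotype(d2@genotypes))
  expect_identical(d1@mu, d2@mu)
  d3 <- simulateDataset(SimulationSpec(n = 60, seed = 10))
  expect_false(identical(dosages(d1@genotypes), dosages(d3@genotypes)))
})

test_that("ld_decay = 0 gives essentially independent variants", {
  panel <- data.frame(gene_id = "g", n_k = 10L, role = "null")
  spec <- SimulationSpec(n = 5000, genes = panel, switches = rep(0, 4),
                         ldDecay = 0, seed = 3)
  g <- simulateGenotypes(spec)
  cc <- stats::cor(dosages(g$genotypes))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("ld_decay > 0 induces decaying within-gene correlation", {
  panel <- data.frame(gene_id = "g", n_k = 10L, role = "null")
  spec <- SimulationSpec(n = 5000, genes = panel, switches = rep(0, 4),
                         ldDecay = 0.7, seed = 3)
  g <- simulateGenotypes(spec)
  cc <- stats::cor(dosages(g$genotypes))
  adj <- mean(cc[cbind(1:9, 2:10)])     # lag-1
  far <- mean(cc[cbind(1:5, 6:10)])     # lag-5
  expect_gt(adj, 0.2)
  expect_gt(adj, far + 0.1)
})

test_that("empirical MAF hits its target within binomial error", {
  panel <- data.frame(gene_id = "g", n_k = 1L, role = "null")
  spec <- SimulationSpec(n = 20000, genes = panel, switches = rep(0, 4),
                         mafRange = c(0.3, 0.3), seed = 21)
  g <- simulateGenotypes(spec)
  expect_lt(abs(alleleFreqs(g$genotypes) - 0.3), 0.01)
})

test_that("all switches off gives pure noise of the stated variance", {
  spec <- SimulationSpec(n = 20000, switches = c(0, 0, 0, 0), noiseSd = 1.5,
                         seed = 4)
  ds <- simulateDataset(spec)
  y <- phenotype(ds@genotypes)
  expect_identical(ds@mu, rep(0, 20000))
  expect_lt(abs(mean(y)), 3 * 1.5 / sqrt(20000))
  # var of sample variance ~ 2 sigma^4 / n
  expect_lt(abs(stats::var(y) - 2.25), 3 * sqrt(2 * 1.5^4 / 20000))
})

test_that("logistic link with zero mean gives success probability one half", {
  spec <- SimulationSpec(n = 5000, switches = c(0, 0, 0, 0),
                         link = "logistic", seed = 5)
  ds <- simulateDataset(spec)
  expect_identical(unique(ds@mu), 0)
  expect_identical(stats::plogis(ds@mu[1]), 0.5)
  y <- phenotype(ds@genotypes)
  expect_true(all(y %in% c(0, 1)))
  expect_lt(abs(mean(y) - 0.5), 3 * 0.5 / sqrt(5000))
})

test_that("the latent mean re-evaluates term-by-term from the stored truth", {
  spec <- SimulationSpec(n = 100, seed = 12)
  ds <- simulateDataset(spec)
  d <- dosages(ds@genotypes)
  genes <- spec@genes
  mu <- numeric(100)
  for (k in seq_len(nrow(genes))) {
    if (!ds@truth$geneCausal[k]) next
    idx <- ds@regions[[genes$gene_id[k]]]
    role <- genes$role[k]
    term <- switch(role,
      linear90 = ,
      linear10 = as.numeric(d[, idx] %*% ds@truth$beta[[k]]),
      interaction = ds@truth$beta[[k]] * rowSums(d[, idx])^2,
      cosine = ds@truth$beta[[k]] * cos(rowSums(d[, idx])))
    mu <- mu + term - ds@truth$offset[k]
  }
  expect_equal(ds@mu, mu, tolerance = 1e-10)
})

test_that("disease model scenarios set the indicator switches", {
  base <- SimulationSpec(n = 10)
  expect_identical(makeDiseaseModel("S1", base)@switches, c(1, 1, 0, 0))
  expect_identical(makeDiseaseModel("S2", base)@switches, c(0, 0, 1, 1))
  expect_identical(makeDiseaseModel("S3", base)@switches, c(1, 1, 1, 1))
  expect_error(makeDiseaseModel("S4", base), "unknown scenario")
})

test_that("noise genes extend the panel without touching the phenotype", {
  spec <- SimulationSpec(n = 50, seed = 2)
  ds <- simulateDataset(spec)
  expect_identical(addNoiseGenes(ds, 0), ds)
  ds6 <- addNoiseGenes(ds, 6)
  expect_identical(length(ds6@regions), 16L)  # 10 panel genes + 6
  expect_identical(phenotype(ds6@genotypes), phenotype(ds@genotypes))
  expect_identical(sum(ds6@truth$geneCausal), sum(ds@truth$geneCausal))
  ds96 <- addNoiseGenes(ds, 96)
  expect_identical(length(ds96@regions), 106L)
  # appended genes carry valid, disjoint column indices
  idx <- unlist(regionIndices(ds96@regions))
  expect_identical(anyDuplicated(idx), 0L)
  expect_identical(max(idx), nVariants(ds96@genotypes))
})

test_that("signal fractions control the realized signal proportion", {
  panel <- data.frame(gene_id = "g", n_k = 10L, role = "linear90")
  mk <- function(sf) {
    spec <- SimulationSpec(n = 4000, genes = panel, switches = c(1, 0, 0, 0),
                           effectScales = list(signalFraction = c(linear90 = sf)),
                           seed = 77)
    ds <- simulateDataset(spec)
    stats::var(ds@mu) / stats::var(phenotype(ds@genotypes))
  }
  r1 <- mk(0.1); r2 <- mk(0.4); r3 <- mk(0.8)
  expect_true(r1 < r2 && r2 < r3)
  expect_equal(r2, 0.4 / 1.4, tolerance = 0.05)
})

test_that("a role demanded by an active switch must exist in the panel", {
  panel <- data.frame(gene_id = "g", n_k = 5L, role = "null")
  spec <- SimulationSpec(n = 30, genes = panel, switches = c(1, 0, 0, 0),
                         seed = 1)
  g <- simulateGenotypes(spec)
  expect_error(simulatePhenotype(g$genotypes, g$regions, spec),
               "absent from the gene panel")
})

test_that("invalid simulation parameters are rejected", {
  expect_error(SimulationSpec(n = 30, mafRange = c(0, 0.6)), "mafRange")
  expect_error(SimulationSpec(n = 30, noiseSd = 0), "noiseSd")
  expect_error(SimulationSpec(n = 1), "n must be")
})
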