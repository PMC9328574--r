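#' @rdname NetworkConfig-class
#' @param hiddenSizes hidden layer widths (default \code{c(50, 10)})
#' @param dropoutRate dropout fraction applied after the first hidden layer;
#'   the recommended range is 0.2 to 0.8 (default 0.2)
#' @param epochs training passes (default 100)
#' @param learningRate Adam learning rate (default 3e-3)
#' @param batchSize minibatch size (default 32); 0 = full batch
#' @param seed seed for weight initialisation, dropout and minibatch order;
#'   \code{NA} consumes the ambient RNG stream
#' @export
NetworkConfig <- function(hiddenSizes = c(50, 10), dropoutRate = 0.2,
                          epochs = 100, learningRate = 3e-3, batchSize = 32,
                          seed = NA) {
  cfg <- new("NetworkConfig", hiddenSizes = as.integer(hiddenSizes),
             dropoutRate = dropoutRate, epochs = as.integer(epochs),
             learningRate = learningRate, batchSize = as.integer(batchSize),
             seed = as.integer(seed))
  if (dropoutRate > 0 && (dropoutRate < 0.2 || dropoutRate > 0.8))
    warning("dropoutRate outside the recommended range [0.2, 0.8]")
  cfg
}

#' Fit a per-gene multi-layer perceptron
#'
#' ReLU hidden layers with dropout after the first, a linear output head
#' (logit scale for binary outcomes), Adam optimisation, mean squared error
#' for continuous outcomes and cross-entropy for binary ones. Input columns
#' are standardized to zero mean and unit variance on the training data
#' (the transform is stored on the network and applied at inference), which
#' keeps the ReLU breakpoints inside the data range regardless of allele
#' frequencies. Training is reproducible from \code{cfg@seed}; the
#' returned network is in deterministic inference mode.
#'
#' @param X dosage block for one gene, samples in rows
#' @param y phenotype vector
#' @param cfg a \linkS4class{NetworkConfig}
#' @param outcomeType \code{"continuous"} or \code{"binary"}
#' @param geneId identifier stored on the result
#' @return a \linkS4class{GeneNetwork}
#' @export
fitGeneNetwork <- function(X, y, cfg = NetworkConfig(),
                           outcomeType = "continuous", geneId = "gene") {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("empty region: gene '", geneId, "' has no variants")
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (length(y) != nrow(X)) stop("phenotype length must match rows of X")
  if (stats::sd(y) == 0)
    stop("degenerate outcome: phenotype is constant")
  binary <- outcomeType == "binary"
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  fit <- withSeed(cfg@seed,
    cpp_mlp_fit(Xs, as.numeric(y), cfg@hiddenSizes, cfg@dropoutRate,
                cfg@epochs, cfg@learningRate, cfg@batchSize, binary))
  new("GeneNetwork", geneId = geneId,
      weights = list(W = fit$W, b = fit$b), config = cfg,
      outcomeType = outcomeType, nInputs = ncol(X),
      center = ctr, scale = scl,
      lossHistory = as.numeric(fit$loss))
}

#' @describeIn fitGeneNetwork deterministic predictions (conditional mean
#'   for continuous outcomes, probability for binary)
#' @param object a \linkS4class{GeneNetwork}
#' @param newdata dosage block with \code{nInputs} columns
#' @export
setMethod("predict", "GeneNetwork", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object@nInputs)
    stop("newdata has ", ncol(newdata), " columns; network expects ",
         object@nInputs)
  fw <- cpp_mlp_forward(object@weights$W, object@weights$b,
                        standardizeInputs(object, newdata),
                        object@outcomeType == "binary")
  as.numeric(fw$pred)
})

standardizeInputs <- function(net, X) {
  sweep(sweep(X, 2, net@center, "-"), 2, net@scale, "/")
}

#' @rdname hiddenActivations
#' @export
setMethod("hiddenActivations", "GeneNetwork", function(object, X) {
  X <- as.matrix(X)
  fw <- cpp_mlp_forward(object@weights$W, object@weights$b,
                        standardizeInputs(object, X),
                        object@outcomeType == "binary")
  fw$hidden
})

setMethod("show", "GeneNetwork", function(object) {
  widths <- vapply(object@weights$W, ncol, integer(1))
  cat("GeneNetwork '", object@geneId, "': ", object@nInputs, " -> ",
      paste(widths, collapse = " -> "), " (", object@outcomeType, ")\n",
      sep = "")
})

#' Permute the subject rows of a dosage block
#'
#' Reorders rows by a uniform random permutation; columns are untouched, so
#' every column-wise statistic — allele frequencies, the within-gene LD
#' matrix — is exactly preserved.
#'
#' @param X matrix with samples in rows
#' @param seed optional seed; \code{NULL} consumes the ambient RNG stream
#' @export
permuteRows <- function(X, seed = NULL) {
  perm <- withSeed(if (is.null(seed)) NA else seed, sample.int(nrow(X)))
  X[perm, , drop = FALSE]
}

# All permutations of 1..n (n small), used by the exact mode.
allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

#' Per-subject loss differences between observed and permuted genotypes
#'
#' For each validation subject, the loss of the fitted network on the
#' observed genotype row minus the expected loss over uniform row
#' permutations of the validation block. The network is never refitted; the
#' expectation is approximated by averaging over \code{nPerm} independent
#' permutations (or computed exactly over all \code{n!} permutations when
#' \code{exact = TRUE}, feasible for small blocks). Since the network maps
#' rows independently, permuting rows then applying the network equals
#' permuting its predictions, which is what is computed.
#'
#' @param net a fitted \linkS4class{GeneNetwork} (trained on disjoint data)
#' @param X validation dosage block
#' @param y validation phenotype
#' @param nPerm number of permutations averaged (default 100)
#' @param exact enumerate all permutations instead of sampling
#' @return numeric vector of per-subject loss differences
#' @export
lossDifference <- function(net, X, y, nPerm = 100, exact = FALSE) {
  if (!exact && nPerm < 1) stop("nPerm must be >= 1")
  X <- as.matrix(X)
  nv <- nrow(X)
  pred <- predict(net, X)
  obs <- perSampleLoss(y, pred, net@outcomeType)
  if (exact) {
    if (nv > 8) stop("exact enumeration is limited to 8 subjects")
    perms <- allPermutations(nv)
    permMean <- Reduce(`+`, lapply(perms, function(p)
      perSampleLoss(y, pred[p], net@outcomeType))) / length(perms)
  } else {
    acc <- numeric(nv)
    for (j in seq_len(nPerm))
      acc <- acc + perSampleLoss(y, pred[sample.int(nv)], net@outcomeType)
    permMean <- acc / nPerm
  }
  obs - permMean
}

#' Score one cross-validation fold
#'
#' Fits the gene network on the training part, evaluates the per-subject
#' loss differences on the validation part, and returns the fold score
#' (their sum) together with its variance estimate
#' \code{|D2| * var(l_i)}.
#'
#' @param X full dosage block for the gene
#' @param y full phenotype vector
#' @param fold list with integer elements \code{train} and \code{validation}
#'   partitioning the samples
#' @param cfg a \linkS4class{NetworkConfig}
#' @param nPerm permutations per fold
#' @param outcomeType \code{"continuous"} or \code{"binary"}
#' @param foldIndex index stored on the result
#' @return a \linkS4class{FoldScore}
#' @export
foldScore <- function(X, y, fold, cfg = NetworkConfig(), nPerm = 100,
                      outcomeType = "continuous", foldIndex = 1L) {
  tr <- as.integer(fold$train); va <- as.integer(fold$validation)
  if (length(va) < 2) stop("validation fold too small (need >= 2 subjects)")
  net <- fitGeneNetwork(X[tr, , drop = FALSE], y[tr], cfg, outcomeType)
  l <- lossDifference(net, X[va, , drop = FALSE], y[va], nPerm = nPerm)
  new("FoldScore", fold = as.integer(foldIndex), trainIdx = tr,
      validIdx = va, delta = sum(l), var = length(va) * stats::var(l),
      perSubjectLoss = l)
}

# K-fold partition of n samples, shuffled.
makeFolds <- function(n, K) {
  assign <- sample(rep_len(seq_len(K), n))
  lapply(seq_len(K), function(k)
    list(train = which(assign != k), validation = which(assign == k)))
}

#' Group-wise feature importance test for one gene
#'
#' Computes the K-fold aggregated importance score
#' \eqn{\Delta_k = (1/K)\sum_i \Delta_{ik}}, its standard error
#' \eqn{\sqrt{(1/K^2)\sum_i \sigma^2_{ik}}}, and the one-sided lower-tail
#' normal p-value for the test of H0: \eqn{\Delta_k \ge 0} against
#' H1: \eqn{\Delta_k < 0}. A degenerate zero standard error (e.g. a
#' constant network) yields p = 1: no predictive evidence.
#'
#' All stochastic stages consume seeds derived from \code{seed}:
#' offset 10 for the fold partition, 100 + fold for each fold's network
#' fit and permutations.
#'
#' @param X dosage block for the gene
#' @param y phenotype vector
#' @param cfg a \linkS4class{NetworkConfig}
#' @param K number of cross-validation folds (default 20)
#' @param nPerm permutations per fold (default 100)
#' @param outcomeType \code{"continuous"} or \code{"binary"}
#' @param seed master seed for this gene's test; \code{NA} uses the ambient
#'   stream
#' @param geneId identifier stored on the result
#' @return an \linkS4class{ImportanceResult}
#' @export
groupImportance <- function(X, y, cfg = NetworkConfig(), K = 20,
                            nPerm = 100, outcomeType = "continuous",
                            seed = NA, geneId = "gene") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (K < 2) stop("K must be >= 2")
  if (n < 2 * K) stop("need at least 2K samples for K-fold screening")
  folds <- withSeed(if (is.na(seed)) NA else deriveSeed(seed, 10),
                    makeFolds(n, K))
  scores <- vector("list", K)
  for (k in seq_len(K)) {
    cfgK <- cfg
    if (!is.na(seed)) cfgK@seed <- deriveSeed(seed, 100 + k)
    scores[[k]] <- withSeed(if (is.na(seed)) NA else deriveSeed(seed, 200 + k),
      foldScore(X, y, folds[[k]], cfgK, nPerm = nPerm,
                outcomeType = outcomeType, foldIndex = k))
  }
  deltas <- vapply(scores, function(s) s@delta, numeric(1))
  vars <- vapply(scores, function(s) s@var, numeric(1))
  delta <- mean(deltas)
  se <- sqrt(sum(vars)) / K
  # degenerate-score guard: a constant model leaves only floating-point
  # residue in the per-subject losses; measured against the loss scale
  lossScale <- max(stats::var(y), 1e-8)
  if (se < 1e-9 * lossScale * sqrt(n)) se <- 0
  if (se > 0) {
    z <- delta / se
    p <- stats::pnorm(z)
  } else {
    z <- 0
    p <- 1
  }
  new("ImportanceResult", geneId = geneId, nVariants = ncol(X),
      foldScores = scores, delta = delta, se = se, z = z, p = p,
      K = as.integer(K))
}

setMethod("show", "ImportanceResult", function(object) {
  cat(sprintf("ImportanceResult '%s': delta = %.4g, se = %.4g, z = %.3f, p = %.3g (K = %d)\n",
              object@geneId, object@delta, object@se, object@z, object@p,
              object@K))
})

#' Screen all gene regions of a dataset
#'
#' Runs the group-wise importance test on every region, selects regions
#' with p below \code{alpha} (in input order), and refits one network per
#' selected gene on the full data to serve as the pre-trained model for the
#' transfer stage.
#'
#' @param dataset a \linkS4class{SimulatedDataset}, or a
#'   \linkS4class{GenotypeData} with phenotype attached (then supply
#'   \code{regions})
#' @param cfg a \linkS4class{NetworkConfig}
#' @param K folds (default 20)
#' @param alpha selection threshold on the raw one-sided p-value (default
#'   0.001, the recommended whole-exome setting)
#' @param nPerm permutations per fold
#' @param seed master seed; per-gene seeds are derived from it by gene index
#' @param regions a \linkS4class{GeneRegionList} when \code{dataset} is a
#'   \linkS4class{GenotypeData}
#' @return a \linkS4class{ScreenResult}
#' @export
screenGenome <- function(dataset, cfg = NetworkConfig(), K = 20,
                         alpha = 0.001, nPerm = 100, seed = NA,
                         regions = NULL) {
  if (is(dataset, "SimulatedDataset")) {
    gd <- dataset@genotypes
    regions <- dataset@regions
  } else {
    gd <- dataset
    if (is.null(regions)) stop("supply 'regions' for GenotypeData input")
  }
  y <- phenotype(gd)
  if (is.null(y)) stop("genotype data has no phenotype attached")
  ot <- outcomeType(gd)
  d <- dosages(gd)
  ids <- geneIds(regions)
  results <- vector("list", length(ids))
  for (g in seq_along(ids)) {
    idx <- regions[[g]]
    results[[g]] <- groupImportance(
      d[, idx, drop = FALSE], y, cfg, K = K, nPerm = nPerm,
      outcomeType = ot,
      seed = if (is.na(seed)) NA else deriveSeed(seed, 1000 + g),
      geneId = ids[g])
  }
  pvals <- vapply(results, function(r) r@p, numeric(1))
  sel <- which(pvals < alpha)
  nets <- vector("list", length(sel))
  names(nets) <- ids[sel]
  for (j in seq_along(sel)) {
    g <- sel[j]
    cfgG <- cfg
    if (!is.na(seed)) cfgG@seed <- deriveSeed(seed, 5000 + g)
    nets[[j]] <- fitGeneNetwork(d[, regions[[g]], drop = FALSE], y, cfgG,
                                outcomeType = ot, geneId = ids[g])
  }
  tab <- S4Vectors::DataFrame(
    gene_id = ids,
    n_variants = lengths(regionIndices(regions)),
    delta = vapply(results, function(r) r@delta, numeric(1)),
    se = vapply(results, function(r) r@se, numeric(1)),
    z = vapply(results, function(r) r@z, numeric(1)),
    p = pvals,
    selected = seq_along(ids) %in% sel)
  new("ScreenResult", table = tab, results = results, networks = nets,
      alpha = alpha)
}

#' @rdname importance-accessors
#' @export
setMethod("importanceTable", "ScreenResult", function(x) x@table)

#' @rdname importance-accessors
#' @export
setMethod("selectedGenes", "ScreenResult", function(x) {
  as.character(x@table$gene_id[x@table$selected])
})

#' @rdname importance-accessors
#' @export
setMethod("geneNetworks", "ScreenResult", function(x) x@networks)

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:", nrow(object@table), "genes tested, ",
      sum(object@table$selected), "selected at alpha =", object@alpha, "\n")
})
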