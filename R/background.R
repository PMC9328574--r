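#' Compute the genomic relationship matrix
#'
#' \eqn{G = W W^T / m} with standardized columns
#' \eqn{w_j = (x_j - 2 p_j) / \sqrt{2 p_j (1 - p_j)}}, where \eqn{p_j} is
#' the observed alternate allele frequency. Monomorphic variants carry no
#' relationship information and are dropped with a warning.
#'
#' @param genotypes a \linkS4class{GenotypeData} or numeric dosage matrix
#'   (samples in rows); missing dosages must be imputed first
#' @return a \linkS4class{GRM}
#' @export
computeGRM <- function(genotypes) {
  d <- if (is(genotypes, "GenotypeData")) dosages(genotypes)
       else as.matrix(genotypes)
  if (anyNA(d)) stop("impute missing dosages before computing the GRM")
  if (nrow(d) < 2) stop("need at least 2 samples")
  p <- colMeans(d) / 2
  v <- colMeans(d^2) - colMeans(d)^2
  poly <- v > 0  # a variant with no variation carries no relationship signal
  if (!any(poly)) stop("all variants are monomorphic")
  if (!all(poly))
    warning(sum(!poly), " monomorphic variant(s) dropped from the GRM")
  keep <- which(poly)
  pk <- p[keep]
  W <- sweep(d[, keep, drop = FALSE], 2, 2 * pk, "-")
  W <- sweep(W, 2, sqrt(2 * pk * (1 - pk)), "/")
  m <- length(keep)
  G <- tcrossprod(W) / m
  sid <- if (is(genotypes, "GenotypeData")) colnames(genotypes)
         else if (!is.null(rownames(d))) rownames(d)
         else paste0("S", seq_len(nrow(d)))
  new("GRM", matrix = G, nVariants = m, freqs = as.numeric(pk),
      keep = as.integer(keep), sampleIds = sid)
}

setMethod("show", "GRM", function(object) {
  cat("GRM:", nrow(object@matrix), "samples from", object@nVariants,
      "variants; mean diagonal =",
      signif(mean(diag(object@matrix)), 4), "\n")
})

# REML log-likelihood machinery on the eigendecomposition of G:
# y = 1*mu + g + e,  g ~ N(0, sigma_g^2 G),  e ~ N(0, sigma_e^2 I).
# Parametrised by h = sigma_g^2 / (sigma_g^2 + sigma_e^2); the total scale
# is profiled out. All per-evaluation work is O(n) after one eigen().
remlProfile <- function(h, D, yt, xt) {
  d <- h * D + (1 - h)
  xvx <- sum(xt^2 / d)
  beta <- sum(xt * yt / d) / xvx
  r <- yt - xt * beta
  ypy <- sum(r^2 / d)
  n <- length(yt)
  ll <- -0.5 * (sum(log(d)) + log(xvx) + (n - 1) * log(ypy))
  list(ll = ll, beta = beta, ypy = ypy, r = r, d = d)
}

#' Fit the gBLUP background model
#'
#' Estimates the genetic and residual variance components by restricted
#' maximum likelihood (profile REML over the heritability ratio on the
#' eigendecomposition of the GRM, refined by golden-section search after a
#' coarse grid pass), then computes training-sample BLUPs
#' \eqn{\hat g = \sigma_g^2 G V^{-1} (y - \hat\mu)} and stores the
#' projection needed to predict the genetic value of held-out samples from
#' their cross-relationship with the training set — held-out phenotypes are
#' never used.
#'
#' Binary outcomes are fitted on the observed 0/1 scale with the same
#' linear mixed model, the usual observed-scale GREML practice.
#'
#' @param grm a \linkS4class{GRM} computed from the training samples
#' @param y training phenotype vector
#' @param cvFolds folds for the cross-validated training background values
#'   stored in \code{blupCV} (out-of-fold predictions under the full-data
#'   variance components; the honest training-time input for a downstream
#'   model); 0 disables and leaves zeros
#' @return a \linkS4class{BackgroundModel}
#' @export
fitGBLUP <- function(grm, y, cvFolds = 5) {
  G <- grm@matrix
  n <- nrow(G)
  if (length(y) != n) stop("phenotype length does not match GRM dimension")
  eg <- eigen(G, symmetric = TRUE)
  D <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- as.numeric(crossprod(U, y))
  xt <- as.numeric(crossprod(U, rep(1, n)))
  # coarse grid guards against local optima at desk-scale n
  grid <- seq(0.01, 0.99, by = 0.02)
  llGrid <- vapply(grid, function(h) remlProfile(h, D, yt, xt)$ll, numeric(1))
  hBest <- grid[which.max(llGrid)]
  opt <- stats::optimize(function(h) remlProfile(h, D, yt, xt)$ll,
                         lower = max(1e-4, hBest - 0.05),
                         upper = min(1 - 1e-4, hBest + 0.05),
                         maximum = TRUE, tol = 1e-8)
  h <- opt$maximum
  prof <- remlProfile(h, D, yt, xt)
  sigmaP <- prof$ypy / (n - 1)
  varG <- h * sigmaP
  varE <- (1 - h) * sigmaP
  mu <- prof$beta
  # alpha = V^{-1} (y - mu); BLUP = varG * G alpha
  alpha <- as.numeric(U %*% (prof$r / (sigmaP * prof$d)))
  blup <- varG * as.numeric(G %*% alpha)
  # cross-validated background values for the training samples: each
  # sample's genetic value is predicted from the other folds under the
  # full-data variance components, so the value carries no in-sample fit.
  # Training BLUPs on a high-rank GRM can track the phenotype almost
  # perfectly in-sample while generalizing far worse, which would mislead
  # any downstream model trained on them.
  blupCV <- rep(0, n)
  if (cvFolds >= 2 && varG > 0) {
    fold <- rep_len(seq_len(cvFolds), n)
    for (f in seq_len(cvFolds)) {
      inF <- which(fold == f)
      outF <- which(fold != f)
      Vsub <- varG * G[outF, outF] + varE * diag(length(outF))
      blupCV[inF] <- varG * as.numeric(
        G[inF, outF, drop = FALSE] %*% solve(Vsub, y[outF] - mu))
    }
  }
  new("BackgroundModel", varG = varG, varE = varE, mu = mu, blup = blup,
      blupCV = blupCV, alpha = alpha, wAlpha = numeric(0),
      freqs = grm@freqs, keep = grm@keep, nVariants = grm@nVariants,
      reml = list(h = h, logLik = prof$ll, grid = grid, gridLogLik = llGrid))
}

#' Predict background genetic values for new samples
#'
#' \eqn{\hat g_{new} = \sigma_g^2 G_{new,train} V^{-1} (y - \hat\mu)}, where
#' the cross-GRM uses the training-sample allele frequencies for
#' standardization. Only training phenotypes enter the projection.
#'
#' @param model a \linkS4class{BackgroundModel}
#' @param trainGenotypes dosage matrix (or \linkS4class{GenotypeData}) of
#'   the training samples, identical to what the GRM was computed from
#' @param newGenotypes dosage matrix (or \linkS4class{GenotypeData}) of the
#'   held-out samples, same variant columns
#' @return numeric vector of predicted genetic values
#' @export
predictBackground <- function(model, trainGenotypes, newGenotypes) {
  dTr <- if (is(trainGenotypes, "GenotypeData")) dosages(trainGenotypes)
         else as.matrix(trainGenotypes)
  dNew <- if (is(newGenotypes, "GenotypeData")) dosages(newGenotypes)
          else as.matrix(newGenotypes)
  if (ncol(dNew) != ncol(dTr))
    stop("new samples must carry the same variant columns as training")
  keep <- model@keep
  pk <- model@freqs
  std <- function(d) {
    W <- sweep(d[, keep, drop = FALSE], 2, 2 * pk, "-")
    sweep(W, 2, sqrt(2 * pk * (1 - pk)), "/")
  }
  Wtr <- std(dTr)
  Wnew <- std(dNew)
  m <- length(keep)
  crossG <- tcrossprod(Wnew, Wtr) / m
  as.numeric(model@varG * crossG %*% model@alpha)
}

setMethod("show", "BackgroundModel", function(object) {
  h2 <- object@varG / (object@varG + object@varE)
  cat(sprintf("BackgroundModel (gBLUP): varG = %.4g, varE = %.4g, h2 = %.3f, n = %d\n",
              object@varG, object@varE, h2, length(object@blup)))
})
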