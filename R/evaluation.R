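#' Pearson correlation between observed and predicted values
#'
#' @param yTrue observed values (>= 3, non-constant)
#' @param yPred predicted values
#' @export
pearsonCor <- function(yTrue, yPred) {
  if (length(yTrue) < 3) stop("need at least 3 pairs")
  if (stats::sd(yTrue) == 0 || stats::sd(yPred) == 0)
    stop("correlation undefined for constant input")
  stats::cor(yTrue, yPred)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by the number of
#' case-control pairs, with ties counted half.
#'
#' @param yTrue binary labels (both classes present)
#' @param scores predicted scores
#' @export
rocAUC <- function(yTrue, scores) {
  yTrue <- as.numeric(yTrue)
  if (!all(yTrue %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(yTrue == 1); n0 <- sum(yTrue == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[yTrue == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Monte-Carlo type-I error of the screening test
#'
#' Simulates independent null datasets (one gene carrying no effect on the
#' outcome) and reports the rejection proportion of the group-wise
#' importance test at each requested significance level, with binomial
#' standard errors.
#'
#' @param spec a \linkS4class{SimulationSpec} whose panel contains at least
#'   one null gene; the first null gene is the one tested
#' @param alphas significance levels (default \code{c(0.05, 0.01)})
#' @param reps Monte-Carlo replicates
#' @param seed master seed; replicate r uses seed offsets derived from it
#' @param cfg \linkS4class{NetworkConfig} for the per-gene networks
#' @param K folds
#' @param nPerm permutations per fold
#' @return list of class \code{ExperimentReport}: scenario label, settings,
#'   p-values, and a metric table of rejection rates with standard errors
#' @export
typeIErrorExperiment <- function(spec, alphas = c(0.05, 0.01), reps = 500,
                                 seed = 1, cfg = NetworkConfig(), K = 20,
                                 nPerm = 100) {
  nullGene <- which(spec@genes$role == "null")[1]
  if (is.na(nullGene)) stop("spec contains no null gene")
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    sp <- spec
    sp@seed <- deriveSeed(seed, r)
    ds <- simulateDataset(sp)
    idx <- ds@regions[[nullGene]]
    pvals[r] <- groupImportance(
      dosages(ds@genotypes)[, idx, drop = FALSE],
      phenotype(ds@genotypes), cfg, K = K, nPerm = nPerm,
      outcomeType = outcomeType(ds@genotypes),
      seed = deriveSeed(seed, 100000 + r))@p
  }
  rate <- vapply(alphas, function(a) mean(pvals < a), numeric(1))
  tab <- data.frame(alpha = alphas, rejectionRate = rate,
                    se = sqrt(rate * (1 - rate) / reps), reps = reps)
  structure(list(scenario = "type-I error", link = spec@link, n = spec@n,
                 reps = reps, seed = seed, K = K, pvalues = pvals,
                 table = tab),
            class = "ExperimentReport")
}

#' Monte-Carlo power of the screening test per causal-gene role
#'
#' @param spec a \linkS4class{SimulationSpec} with causal genes
#' @param alphas significance levels
#' @param reps Monte-Carlo replicates
#' @param seed master seed
#' @param cfg,K,nPerm screening settings as in
#'   \code{\link{typeIErrorExperiment}}
#' @param roles causal roles to evaluate (default: all causal roles present)
#' @return \code{ExperimentReport} with per-role rejection rates and the
#'   per-replicate p-value matrix
#' @export
powerExperiment <- function(spec, alphas = 0.05, reps = 100, seed = 1,
                            cfg = NetworkConfig(), K = 20, nPerm = 100,
                            roles = NULL) {
  if (is.null(roles))
    roles <- intersect(c("linear90", "linear10", "interaction", "cosine"),
                       spec@genes$role)
  if (length(roles) == 0) stop("spec contains no causal genes")
  pmat <- matrix(NA_real_, reps, length(roles),
                 dimnames = list(NULL, roles))
  for (r in seq_len(reps)) {
    sp <- spec
    sp@seed <- deriveSeed(seed, r)
    ds <- simulateDataset(sp)
    for (role in roles) {
      g <- which(sp@genes$role == role)[1]
      idx <- ds@regions[[g]]
      pmat[r, role] <- groupImportance(
        dosages(ds@genotypes)[, idx, drop = FALSE],
        phenotype(ds@genotypes), cfg, K = K, nPerm = nPerm,
        outcomeType = outcomeType(ds@genotypes),
        seed = deriveSeed(seed, 100000 + r * 10 + which(roles == role)))@p
    }
  }
  tab <- do.call(rbind, lapply(alphas, function(a) {
    pw <- colMeans(pmat < a)
    data.frame(alpha = a, role = roles, power = pw,
               se = sqrt(pw * (1 - pw) / reps), reps = reps,
               row.names = NULL)
  }))
  structure(list(scenario = "power", link = spec@link, n = spec@n,
                 reps = reps, seed = seed, K = K, pvalues = pmat,
                 table = tab),
            class = "ExperimentReport")
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat("ExperimentReport:", x$scenario, "| link =", x$link, "| n =", x$n,
      "| reps =", x$reps, "| K =", x$K, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
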