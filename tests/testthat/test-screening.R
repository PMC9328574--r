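test_that("row permutation preserves every column-wise statistic", {
  set.seed(8)
  X <- matrix(rbinom(600, 2, 0.3), 60, 10)
  Xp <- permuteRows(X, seed = 101)
  expect_equal(colMeans(Xp), colMeans(X), tolerance = 1e-12)
  expect_equal(stats::cor(Xp), stats::cor(X), tolerance = 1e-12)
  expect_false(identical(Xp, X))
  # the permutation equals an independent draw from the stated PRNG
  set.seed(101)
  expect_identical(Xp, X[sample.int(60), ])
})

test_that("loss differences with exact enumeration match the closed form", {
  # for a uniform random permutation, pi(i) is uniform over all positions,
  # so E[L(y_i, f(x_pi(i)))] = mean_j L(y_i, f(x_j)) -- an independent
  # closed-form oracle for the enumeration average
  ds <- signalDataset(n = 100, seed = 31)
  X <- dosages(ds@genotypes)[, ds@regions[["sig"]]]
  y <- phenotype(ds@genotypes)
  net <- fitGeneNetwork(X[1:90, ], y[1:90], fastNet(epochs = 10, seed = 4))
  Xv <- X[91:93, ]; yv <- y[91:93]
  l <- lossDifference(net, Xv, yv, exact = TRUE)
  pred <- predict(net, Xv)
  oracle <- vapply(1:3, function(i)
    (yv[i] - pred[i])^2 - mean((yv[i] - pred)^2), numeric(1))
  expect_equal(l, oracle, tolerance = 1e-12)
})

test_that("a constant network yields exactly zero loss differences", {
  ds <- nullDataset(n = 50, seed = 3)
  X <- dosages(ds@genotypes)[, ds@regions[[1]]]
  y <- phenotype(ds@genotypes)
  net <- fitGeneNetwork(X, y, fastNet(epochs = 2, seed = 1))
  # force a constant predictor: zero all weights
  net@weights$W <- lapply(net@weights$W, function(w) w * 0)
  net@weights$b <- lapply(net@weights$b, function(b) b * 0)
  l <- lossDifference(net, X, y, nPerm = 5)
  expect_equal(l, rep(0, 50), tolerance = 1e-12)
})

test_that("loss differences never refit or mutate the network", {
  ds <- signalDataset(n = 120, seed = 6)
  X <- dosages(ds@genotypes)[, ds@regions[["sig"]]]
  y <- phenotype(ds@genotypes)
  net <- fitGeneNetwork(X, y, fastNet(epochs = 5, seed = 9))
  before <- serialize(net@weights, NULL)
  invisible(lossDifference(net, X, y, nPerm = 20))
  expect_identical(serialize(net@weights, NULL), before)
})

test_that("mean loss difference is negative on a well-fitted signal gene", {
  ds <- signalDataset(n = 2000, sf = 1, seed = 23)
  X <- dosages(ds@genotypes)[, ds@regions[["sig"]]]
  y <- phenotype(ds@genotypes)
  tr <- 1:1600; va <- 1601:2000
  net <- fitGeneNetwork(X[tr, ], y[tr], fastNet(epochs = 40, seed = 2))
  l <- lossDifference(net, X[va, ], y[va], nPerm = 100)
  expect_lt(mean(l), 0)
})

test_that("fold scores aggregate per-subject losses with the stated estimator", {
  ds <- signalDataset(n = 200, seed = 44)
  X <- dosages(ds@genotypes)[, ds@regions[["sig"]]]
  y <- phenotype(ds@genotypes)
  fold <- list(train = 1:150, validation = 151:200)
  fs <- withr::with_seed(5,
    foldScore(X, y, fold, fastNet(epochs = 10, seed = 3), nPerm = 30))
  expect_identical(fs@delta, sum(fs@perSubjectLoss))
  expect_equal(fs@var, 50 * stats::var(fs@perSubjectLoss), tolerance = 1e-12)
  expect_error(foldScore(X, y, list(train = 1:199, validation = 200L),
                         fastNet()), "too small")
})

test_that("the variance estimator matches hand arithmetic on l = (-1, 0, 1)", {
  fs <- new("FoldScore", fold = 1L, trainIdx = 1:3, validIdx = 4:6,
            delta = 0, var = 3 * stats::var(c(-1, 0, 1)),
            perSubjectLoss = c(-1, 0, 1))
  expect_identical(fs@delta, 0)
  expect_identical(fs@var, 3)  # |D2| * sample variance = 3 * 1
})

test_that("a constant-input gene is declared non-predictive with p = 1", {
  set.seed(2)
  X <- matrix(1, 80, 3)  # no variation: the network output is constant
  y <- rnorm(80)
  res <- groupImportance(X, y, fastNet(epochs = 5), K = 4, nPerm = 10,
                         seed = 60)
  expect_identical(res@p, 1)
  expect_equal(res@delta, 0, tolerance = 1e-10)
})

test_that("the K-fold statistic combines folds as stated and is seed-stable", {
  ds <- signalDataset(n = 240, seed = 50)
  X <- dosages(ds@genotypes)[, ds@regions[["sig"]]]
  y <- phenotype(ds@genotypes)
  r1 <- groupImportance(X, y, fastNet(epochs = 8), K = 4, nPerm = 20,
                        seed = 77)
  r2 <- groupImportance(X, y, fastNet(epochs = 8), K = 4, nPerm = 20,
                        seed = 77)
  expect_identical(r1@delta, r2@delta)
  expect_identical(r1@p, r2@p)
  deltas <- vapply(r1@foldScores, function(s) s@delta, numeric(1))
  vars <- vapply(r1@foldScores, function(s) s@var, numeric(1))
  expect_equal(r1@delta, mean(deltas), tolerance = 1e-12)
  expect_equal(r1@se, sqrt(sum(vars)) / 4, tolerance = 1e-12)
  expect_equal(r1@p, stats::pnorm(r1@delta / r1@se), tolerance = 1e-12)
  # folds partition the samples
  for (s in r1@foldScores) {
    expect_length(intersect(s@trainIdx, s@validIdx), 0)
    expect_setequal(c(s@trainIdx, s@validIdx), 1:240)
  }
})

test_that("null fold statistics center at zero and p-values look uniform", {
  reps <- 40
  stats_z <- numeric(reps)
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    ds <- nullDataset(n = 160, seed = 600 + r, nk = 8)
    X <- dosages(ds@genotypes)[, ds@regions[[1]]]
    y <- phenotype(ds@genotypes)
    res <- groupImportance(X, y, fastNet(epochs = 10), K = 2, nPerm = 30,
                           seed = 800 + r)
    stats_z[r] <- res@delta
    ps[r] <- res@p
  }
  # sign property: mean delta within 3 SE of 0 under the null
  expect_lt(abs(mean(stats_z)), 3 * stats::sd(stats_z) / sqrt(reps))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("genome screening selects by threshold and refits selected genes", {
  ds <- signalDataset(n = 500, sf = 1.5, seed = 70, nNull = 2)
  cfg <- fastNet(epochs = 25)
  sr <- screenGenome(ds, cfg, K = 4, alpha = 0.05, nPerm = 30, seed = 13)
  tab <- importanceTable(sr)
  expect_identical(nrow(tab), 3L)
  expect_identical(as.character(tab$gene_id), geneIds(ds@regions))
  expect_true("sig" %in% selectedGenes(sr))
  expect_identical(names(geneNetworks(sr)), selectedGenes(sr))
  expect_s4_class(geneNetworks(sr)[[1]], "GeneNetwork")
  # alpha = 1 selects everything, alpha = 0 selects nothing
  srAll <- screenGenome(ds, fastNet(epochs = 3), K = 2, alpha = 1,
                        nPerm = 5, seed = 14)
  expect_identical(selectedGenes(srAll), geneIds(ds@regions))
  srNone <- screenGenome(ds, fastNet(epochs = 3), K = 2, alpha = 0,
                         nPerm = 5, seed = 15)
  expect_length(selectedGenes(srNone), 0)
})

test_that("parameter contracts are enforced", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  expect_error(groupImportance(X, y, fastNet(), K = 1), "K must be")
  expect_error(groupImportance(X, y, fastNet(), K = 15), "2K samples")
  net <- fitGeneNetwork(X, y, fastNet(epochs = 2, seed = 1))
  expect_error(lossDifference(net, X, y, nPerm = 0), "nPerm")
})
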