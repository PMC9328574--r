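test_that("the GRM matches hand-computed standardization on a toy matrix", {
  d <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), nrow = 3, byrow = TRUE)
  # columns: p = (0.5, 1/3, 0.5)
  g <- computeGRM(d)
  p <- colMeans(d) / 2
  W <- sweep(d, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(g@matrix, tcrossprod(W) / 3, tolerance = 1e-12)
  expect_identical(g@nVariants, 3L)
})

test_that("identical samples have off-diagonal equal to their diagonals", {
  set.seed(4)
  d <- matrix(rbinom(40, 2, 0.4), 4, 10)
  d[2, ] <- d[1, ]
  g <- suppressWarnings(computeGRM(d))@matrix  # draw may contain a constant column
  expect_equal(g[1, 2], g[1, 1], tolerance = 1e-12)
  expect_equal(g[1, 2], g[2, 2], tolerance = 1e-12)
})

test_that("monomorphic variants are dropped with a warning", {
  d <- cbind(rep(1, 6), rbinom(6, 2, 0.5), rep(0, 6))
  d[1, 2] <- 1  # ensure polymorphic
  expect_warning(g <- computeGRM(d), "monomorphic")
  expect_identical(g@nVariants, 1L)
  expect_error(computeGRM(matrix(1, 4, 2)), "monomorphic")
})

test_that("unrelated samples give a GRM near the identity in expectation", {
  set.seed(11)
  d <- matrix(rbinom(200 * 1000, 2, runif(1000, 0.1, 0.5)[rep(1:1000, each = 200)]),
              200, 1000)
  g <- computeGRM(d)@matrix
  expect_lt(abs(mean(g[upper.tri(g)])), 0.05)
  expect_lt(abs(mean(diag(g)) - 1), 0.1)
})

test_that("BLUPs match a direct dense mixed-model solve on a small instance", {
  set.seed(21)
  n <- 5
  L <- matrix(rnorm(25), 5, 5)
  G <- tcrossprod(L) / 5
  diag(G) <- diag(G) + 0.1
  y <- rnorm(5, sd = 2)
  grm <- new("GRM", matrix = G, nVariants = 10L, freqs = numeric(0),
             keep = integer(0), sampleIds = paste0("s", 1:5))
  fit <- fitGBLUP(grm, y)
  # independent oracle: g_hat = varG * G * solve(V) * (y - mu), dense solve
  V <- fit@varG * G + fit@varE * diag(n)
  Vi <- solve(V)
  mu <- drop(solve(t(rep(1, n)) %*% Vi %*% rep(1, n)) %*%
             t(rep(1, n)) %*% Vi %*% y)
  gHat <- drop(fit@varG * G %*% Vi %*% (y - mu))
  expect_equal(fit@mu, mu, tolerance = 1e-6)
  expect_equal(fit@blup, gHat, tolerance = 1e-6)
})

test_that("BLUPs equal ridge regression on standardized genotypes", {
  set.seed(31)
  n <- 40; m <- 15
  d <- matrix(rbinom(n * m, 2, 0.3), n, m)
  keepPoly <- apply(d, 2, function(x) length(unique(x)) > 1)
  d <- d[, keepPoly]
  m <- ncol(d)
  y <- rnorm(n) + 0.3 * rowSums(scale(d))
  grm <- computeGRM(d)
  fit <- fitGBLUP(grm, y)
  p <- colMeans(d) / 2
  W <- sweep(sweep(d, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  lambda <- m * fit@varE / fit@varG
  beta <- solve(crossprod(W) + lambda * diag(m), crossprod(W, y - fit@mu))
  expect_equal(fit@blup, drop(W %*% beta), tolerance = 1e-6)
})

test_that("heritability is recovered on an additive trait", {
  set.seed(41)
  n <- 1200; m <- 400
  p <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  W <- scale(d)
  u <- rnorm(m, 0, sqrt(1 / m))
  gval <- drop(W %*% u)
  gval <- gval / stats::sd(gval) * sqrt(0.5)
  y <- gval + rnorm(n, 0, sqrt(0.5))
  fit <- fitGBLUP(computeGRM(d), y)
  h2 <- fit@varG / (fit@varG + fit@varE)
  expect_lt(abs(h2 - 0.5), 0.1)
})

test_that("null phenotypes give near-zero heritability and shrunken BLUPs", {
  set.seed(51)
  n <- 600; m <- 300
  d <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rnorm(n)
  fit <- fitGBLUP(computeGRM(d), y)
  h2 <- fit@varG / (fit@varG + fit@varE)
  expect_lt(h2, 0.15)
  expect_lt(stats::var(fit@blup) / stats::var(y), 0.15)
})

test_that("as residual noise vanishes the BLUPs approach the centered phenotype", {
  set.seed(61)
  n <- 300; m <- 600  # m > n so the genetic term can fit y exactly
  d <- matrix(rbinom(n * m, 2, 0.3), n, m)
  W <- scale(d)
  y <- drop(W %*% rnorm(m, 0, 1 / sqrt(m))) + rnorm(n, 0, 0.02)
  fit <- fitGBLUP(computeGRM(d), y)
  expect_gt(stats::cor(fit@blup, y - mean(y)), 0.98)
})

test_that("held-out background prediction uses no held-out phenotype", {
  set.seed(71)
  n <- 250; m <- 200
  p <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom((n + 50) * m, 2, rep(p, each = n + 50)), n + 50, m)
  W <- scale(d)
  y <- drop(W %*% rnorm(m, 0, sqrt(0.8 / m))) + rnorm(n + 50, 0, sqrt(0.5))
  dTr <- d[1:n, ]; dNew <- d[(n + 1):(n + 50), ]
  fit <- fitGBLUP(computeGRM(dTr), y[1:n])
  pred <- predictBackground(fit, dTr, dNew)
  # oracle: sigma_g^2 * G_cross * alpha with training-frequency standardization
  pTr <- colMeans(dTr)[fit@keep] / 2
  std <- function(x) sweep(sweep(x[, fit@keep, drop = FALSE], 2, 2 * pTr, "-"),
                           2, sqrt(2 * pTr * (1 - pTr)), "/")
  Gc <- tcrossprod(std(dNew), std(dTr)) / length(fit@keep)
  expect_equal(pred, drop(fit@varG * Gc %*% fit@alpha), tolerance = 1e-10)
  # the prediction actually carries genetic signal
  expect_gt(stats::cor(pred, y[(n + 1):(n + 50)]), 0)
})

test_that("GCTA binary GRM import reproduces a written lower triangle", {
  set.seed(81)
  n <- 6
  L <- matrix(rnorm(36), 6, 6)
  G <- tcrossprod(L) / 6
  prefix <- file.path(withr::local_tempdir(), "toy")
  ids <- data.frame(fid = paste0("f", 1:n), iid = paste0("i", 1:n))
  utils::write.table(ids, paste0(prefix, ".grm.id"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  vals <- G[upper.tri(G, diag = TRUE)]
  writeBin(as.numeric(vals), paste0(prefix, ".grm.bin"), size = 4)
  back <- readGRMBin(prefix)
  expect_equal(back@matrix, G, tolerance = 1e-6)
  expect_identical(back@sampleIds, paste0("i", 1:n))
})

test_that("cross-validated background values carry no in-sample fit", {
  set.seed(91)
  n <- 200; m <- 400  # high-rank GRM: in-sample BLUPs can track noise
  d <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rnorm(n)
  fit <- fitGBLUP(computeGRM(d), y)
  expect_length(fit@blupCV, n)
  expect_false(identical(fit@blup, fit@blupCV))
  # in-sample BLUPs fit the noise; out-of-fold values do not
  expect_gt(stats::cor(fit@blup, y), stats::cor(fit@blupCV, y) + 0.2)
  expect_lt(abs(stats::cor(fit@blupCV, y)), 0.3)
})
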