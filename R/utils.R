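#' Derive a stage seed from a master seed
#'
#' Every stochastic stage (genotype draw, effect-size draw, fold partition,
#' network initialisation, permutations) consumes its own seed derived from
#' one master seed, so individual stages can be replayed in isolation.
#' The derivation is a fixed affine map modulo 2^31 - 1.
#'
#' @param master master seed (integer)
#' @param offset stage offset (integer); conventional offsets are documented
#'   in the functions that use them
#' @return an integer seed in [1, 2^31 - 2]
#' @export
deriveSeed <- function(master, offset = 0) {
  s <- (abs(as.numeric(master)) %% 2147483647) * 48271 +
       (as.numeric(offset) + 1) * 16807
  as.integer(s %% 2147483646) + 1L
}

# Evaluate expr with the RNG seeded (when seed is not NA), without
# disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Per-sample loss: squared error for continuous outcomes, cross-entropy for
# binary (predictions are probabilities).
perSampleLoss <- function(y, pred, outcomeType) {
  if (outcomeType == "binary") {
    p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
    -(y * log(p) + (1 - y) * log(1 - p))
  } else {
    (y - pred)^2
  }
}
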