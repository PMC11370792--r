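#' Evaluate an expression under a local RNG state
#'
#' Seeds the RNG deterministically, evaluates `expr`, and restores the
#' caller's RNG state afterwards, so seeded computations never perturb
#' the surrounding random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Combines a global integer seed with a stage name through a small string
#' hash, so that every stochastic pipeline stage gets its own reproducible
#' stream and adding stages never perturbs existing ones.
#'
#' @param globalSeed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in \[0, 2^31).
#' @export
deriveSeed <- function(globalSeed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147480009
  as.integer((as.numeric(globalSeed) * 2654435 + h) %% 2147483647)
}

# Sample a zero-mean Gaussian random field over regions with covariance
# exp(-dist/scale), via Cholesky with a small ridge. Returns an
# nRegions x nFields matrix.
gaussianField <- function(dmat, scale, nFields) {
  stopifnot(scale > 0)
  K <- exp(-dmat / scale)
  L <- chol(K + diag(1e-8, nrow(K)))
  z <- matrix(rnorm(nrow(dmat) * nFields), nrow(dmat), nFields)
  crossprod(L, z)
}

# Pearson correlation of one vector against each column of a matrix.
corVec <- function(x, M) as.vector(cor(x, M))

logSpace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))
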