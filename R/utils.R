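# Internal numerical helpers shared across modules.

# Row-wise numerically stable softmax.
.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.softmaxVec <- function(v) {
  v <- v - max(v)
  e <- exp(v)
  e / sum(e)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

# log(1 + exp(x)) without overflow.
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softplusInverse <- function(y) log(expm1(y))

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Dense numeric matrix from a possibly sparse assay.
.denseMatrix <- function(m) {
  if (is(m, "sparseMatrix")) as.matrix(m) else as.matrix(m)
}

.isWholeNumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) <= tol)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
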