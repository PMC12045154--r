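# Internal engine for the five-hidden-layer residual MLP: He
# initialization, forward/backward passes with inverted dropout, Adagrad
# updates. All state lives in plain lists of matrices so that training is
# bit-reproducible given one RNG seed.

.mlpInit <- function(spec) {
  dims <- c(spec$inputDim, spec$hiddenDims, spec$outputDim)
  L <- length(dims) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(dims[l + 1L] * dims[l],
                                  sd = sqrt(2 / dims[l])),
                     dims[l + 1L], dims[l])
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# Forward pass. X: batch x inputDim. Returns probs and, when keepState,
# the intermediate activations needed for backprop.
.mlpForward <- function(X, params, spec, train = FALSE, keepState = FALSE) {
  nH <- length(spec$hiddenDims)
  src <- spec$residual[1L]
  dst <- spec$residual[2L]
  p <- spec$dropout
  B <- nrow(X)
  A <- vector("list", nH + 1L)   # A[[1]] = input, A[[l+1]] = hidden l
  Z <- vector("list", nH)
  M <- vector("list", nH)        # dropout masks
  A[[1L]] <- X
  for (l in seq_len(nH)) {
    Zl <- A[[l]] %*% t(params$W[[l]]) +
      matrix(params$b[[l]], B, length(params$b[[l]]), byrow = TRUE)
    if (l == dst) Zl <- Zl + A[[src + 1L]]
    Z[[l]] <- Zl
    Al <- .relu(Zl)
    if (train && p > 0) {
      M[[l]] <- matrix(stats::runif(length(Al)) >= p, nrow(Al), ncol(Al))
      Al <- Al * M[[l]] / (1 - p)
    }
    A[[l + 1L]] <- Al
  }
  Zo <- A[[nH + 1L]] %*% t(params$W[[nH + 1L]]) +
    matrix(params$b[[nH + 1L]], B, spec$outputDim, byrow = TRUE)
  probs <- .softmaxRows(Zo)
  if (!keepState) return(probs)
  list(probs = probs, A = A, Z = Z, M = M)
}

# Backward pass for mean cross-entropy over the batch.
.mlpBackward <- function(state, y, params, spec) {
  nH <- length(spec$hiddenDims)
  src <- spec$residual[1L]
  dst <- spec$residual[2L]
  p <- spec$dropout
  B <- nrow(state$probs)
  K <- ncol(state$probs)
  Y <- matrix(0, B, K)
  Y[cbind(seq_len(B), y)] <- 1
  gW <- vector("list", nH + 1L)
  gb <- vector("list", nH + 1L)
  dZ <- (state$probs - Y) / B
  gW[[nH + 1L]] <- t(dZ) %*% state$A[[nH + 1L]]
  gb[[nH + 1L]] <- colSums(dZ)
  dA <- dZ %*% params$W[[nH + 1L]]
  dRes <- NULL                                  # gradient entering A[src+1]
  for (l in rev(seq_len(nH))) {
    if (p > 0 && !is.null(state$M[[l]]))
      dA <- dA * state$M[[l]] / (1 - p)
    dZl <- dA
    dZl[state$Z[[l]] <= 0] <- 0
    if (l == dst) dRes <- dZl                   # skip path into A[[src+1]]
    gW[[l]] <- t(dZl) %*% state$A[[l]]
    gb[[l]] <- colSums(dZl)
    dA <- dZl %*% params$W[[l]]
    if (!is.null(dRes) && l == src + 1L) {
      dA <- dA + dRes
      dRes <- NULL
    }
  }
  list(W = gW, b = gb)
}

.adagradInit <- function(params) {
  list(W = lapply(params$W, function(w) w * 0),
       b = lapply(params$b, function(v) v * 0))
}

.adagradStep <- function(params, grads, acc, lr, eps = 1e-8) {
  for (l in seq_along(params$W)) {
    acc$W[[l]] <- acc$W[[l]] + grads$W[[l]]^2
    acc$b[[l]] <- acc$b[[l]] + grads$b[[l]]^2
    params$W[[l]] <- params$W[[l]] -
      lr * grads$W[[l]] / (sqrt(acc$W[[l]]) + eps)
    params$b[[l]] <- params$b[[l]] -
      lr * grads$b[[l]] / (sqrt(acc$b[[l]]) + eps)
  }
  list(params = params, acc = acc)
}

# Stratified index split; returns list(train, val). fraction = 0 gives an
# empty validation set.
.stratifiedSplit <- function(codes, fraction) {
  val <- integer(0)
  if (fraction > 0) {
    for (k in unique(codes)) {
      idx <- which(codes == k)
      if (length(idx) < 2L)
        .stopf("every class needs >= 2 cells for a validation split")
      nVal <- max(1L, floor(fraction * length(idx)))
      val <- c(val, sample(idx)[seq_len(nVal)])
    }
  }
  list(train = setdiff(seq_along(codes), val), val = sort(val))
}
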