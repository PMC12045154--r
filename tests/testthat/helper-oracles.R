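# Independent brute-force oracles, coded with explicit loops/sums so they
# share nothing with the package implementations they check.

oracleCos <- function(p, r) {
  s <- np <- nr <- 0
  for (i in seq_along(p)) {
    s <- s + p[i] * r[i]
    np <- np + p[i]^2
    nr <- nr + r[i]^2
  }
  if (np == 0 || nr == 0) return(0)
  s / (sqrt(np) * sqrt(nr))
}

oraclePearson <- function(p, r) {
  n <- length(p)
  mp <- sum(p) / n
  mr <- sum(r) / n
  num <- den1 <- den2 <- 0
  for (i in seq_len(n)) {
    num <- num + (p[i] - mp) * (r[i] - mr)
    den1 <- den1 + (p[i] - mp)^2
    den2 <- den2 + (r[i] - mr)^2
  }
  if (den1 == 0 || den2 == 0) return(0)
  num / sqrt(den1 * den2)
}

# Global SSIM with L = 1 after per-vector max scaling, population moments.
oracleSSIM <- function(p, r) {
  if (max(p) > 0) p <- p / max(p)
  if (max(r) > 0) r <- r / max(r)
  n <- length(p)
  mp <- sum(p) / n
  mr <- sum(r) / n
  vp <- vr <- cv <- 0
  for (i in seq_len(n)) {
    vp <- vp + (p[i] - mp)^2
    vr <- vr + (r[i] - mr)^2
    cv <- cv + (p[i] - mp) * (r[i] - mr)
  }
  vp <- vp / n; vr <- vr / n; cv <- cv / n
  c1 <- 0.01^2; c2 <- 0.03^2
  ((2 * mp * mr + c1) * (2 * cv + c2)) /
    ((mp^2 + mr^2 + c1) * (vp + vr + c2))
}

oracleKL <- function(p, r, eps = 1e-12) {
  q <- (p + eps) / sum(p + eps)
  s <- (r + eps) / sum(r + eps)
  total <- 0
  for (i in seq_along(q)) total <- total + s[i] * log(s[i] / q[i])
  total
}

oracleJS <- function(p, r, eps = 1e-12) {
  q <- (p + eps) / sum(p + eps)
  s <- (r + eps) / sum(r + eps)
  m <- (q + s) / 2
  a <- b <- 0
  for (i in seq_along(q)) {
    a <- a + q[i] * log(q[i] / m[i])
    b <- b + s[i] * log(s[i] / m[i])
  }
  (a + b) / 2
}

# Cosine of gene expression against a 0/1 type indicator, per (gene, type).
oracleLambda <- function(X, labels) {
  types <- unique(labels)
  out <- matrix(0, nrow(X), length(types),
                dimnames = list(rownames(X), types))
  for (g in seq_len(nrow(X))) {
    x <- X[g, ]
    nx <- sqrt(sum(x^2))
    for (k in seq_along(types)) {
      u <- as.numeric(labels == types[k])
      out[g, k] <- if (nx == 0) 0 else sum(x * u) / (nx * sqrt(sum(u)))
    }
  }
  out
}

# Absolute standardized mean difference per gene for a two-class labelling
# (the univariate class-separation oracle for attention sanity checks).
oracleSMD <- function(X, labels) {
  cls <- unique(labels)
  stopifnot(length(cls) == 2L)
  a <- X[, labels == cls[1L], drop = FALSE]
  b <- X[, labels == cls[2L], drop = FALSE]
  sapply(seq_len(nrow(X)), function(g) {
    sp <- sqrt((var(a[g, ]) + var(b[g, ])) / 2)
    if (sp == 0) 0 else abs(mean(a[g, ]) - mean(b[g, ])) / sp
  })
}
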