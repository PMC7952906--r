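## Internal neural-network primitives.
##
## Activations use a "tall" layout: a matrix [n*L, C] whose rows are grouped
## in position-major blocks of n clones (row (p-1)*n + i = clone i, position
## p). Convolutions are im2col + GEMM with TensorFlow-style SAME padding and
## ceil-division output lengths; rectifier nonlinearities; pad positions are
## masked to -Inf before global max pooling so padding never wins the max.

.convOutLen <- function(L, s) as.integer(ceiling(L / s))

.convPadLeft <- function(L, k, s) {
  Lo <- .convOutLen(L, s)
  tot <- max((Lo - 1L) * s + k - L, 0L)
  as.integer(floor(tot / 2))
}

.glorot <- function(fan_in, fan_out, nr = fan_in, nc = fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.im2col <- function(A, n, L, C, k, s) {
  .cpp_im2col(A, n, L, C, k, s, .convPadLeft(L, k, s), .convOutLen(L, s))
}

.col2im <- function(dX, n, L, C, k, s, Lo, pl) {
  .cpp_col2im(dX, n, L, C, k, s, pl, Lo)
}

.convForward <- function(A, n, L, W, b, k, s, relu = TRUE) {
  C <- ncol(A)
  X <- .im2col(A, n, L, C, k, s)
  Z <- .addBias(.gemm(X, W), b)
  H <- if (relu) pmax(Z, 0) else Z
  list(H = H, Z = Z, X = X, Lo = .convOutLen(L, s), pl = .convPadLeft(L, k, s),
       L = L, C = C, k = k, s = s)
}

.convBackward <- function(cache, dH, W, relu = TRUE) {
  dZ <- if (relu) dH * (cache$Z > 0) else dH
  list(dW = .gemm_tA(cache$X, dZ),
       db = colSums(dZ),
       dA = .col2im(.gemm_tB(dZ, W), nrow(dZ) / cache$Lo, cache$L, cache$C,
                    cache$k, cache$s, cache$Lo, cache$pl))
}

## Masked global max over positions. H: [n*L, C]; len: valid length per clone
## at this layer (>= 1). Returns pooled [n, C] and argmax positions [n, C].
.maxPool <- function(H, n, L, len) {
  C <- ncol(H)
  pooled <- matrix(-Inf, n, C); arg <- matrix(1L, n, C)
  for (t in seq_len(L)) {
    cur <- H[((t - 1L) * n + 1L):(t * n), , drop = FALSE]
    if (any(t > len)) cur[t > len, ] <- -Inf
    sel <- cur > pooled
    if (any(sel)) { pooled[sel] <- cur[sel]; arg[sel] <- t }
  }
  list(pooled = pooled, arg = arg)
}

.maxPoolBackward <- function(dP, arg, n, L, C) {
  dH <- matrix(0, n * L, C)
  idx <- (rep(seq_len(C), each = n) - 1L) * (n * L) +
    (as.vector(arg) - 1L) * n + rep(seq_len(n), C)
  dH[idx] <- as.vector(dP)
  dH
}

## [n*L, C] position-major -> [n, L*C] flat (position blocks of C columns)
.flatten <- function(H, n, L) {
  C <- ncol(H)
  F_ <- matrix(0, n, L * C)
  for (t in seq_len(L))
    F_[, ((t - 1L) * C + 1L):(t * C)] <- H[((t - 1L) * n + 1L):(t * n), , drop = FALSE]
  F_
}

.unflatten <- function(F_, n, L, C) {
  H <- matrix(0, n * L, C)
  for (t in seq_len(L))
    H[((t - 1L) * n + 1L):(t * n), ] <- F_[, ((t - 1L) * C + 1L):(t * C), drop = FALSE]
  H
}

## ---- Adam over a flat named list of parameter arrays ----

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

.accumGrads <- function(acc, g) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}
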