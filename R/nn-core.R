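# Internal neural-network primitives: dense/conv layers as explicit matrix
# ops with hand-derived backward passes, plus the Adam optimizer. All
# networks here are small (tens of thousands of parameters), so plain BLAS
# matrix products are the right tool; no framework is involved.

relu <- function(x) pmax(x, 0)

sigmoid_ <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -l, l), nr, nc)
}

bce_loss <- function(s, y, eps = 1e-12) {
  s <- pmin(pmax(s, eps), 1 - eps)
  -mean(y * log(s) + (1 - y) * log(1 - s))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, \(p) p * 0),
       v = lapply(params, \(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) lapply(params, \(p) p * 0)

add_grads <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

scale_grads <- function(g, k) lapply(g, \(x) x * k)

# --- im2col ----------------------------------------------------------------

pad_rows <- function(X, min_rows) {
  if (nrow(X) >= min_rows) return(X)
  rbind(X, matrix(0, min_rows - nrow(X), ncol(X)))
}

pad_matrix <- function(M, min_r, min_c) {
  if (nrow(M) < min_r) M <- rbind(M, matrix(0, min_r - nrow(M), ncol(M)))
  if (ncol(M) < min_c) M <- cbind(M, matrix(0, nrow(M), min_c - ncol(M)))
  M
}

im2col_1d <- function(X, k) {
  n_out <- nrow(X) - k + 1L
  do.call(cbind, lapply(0:(k - 1L), \(o) X[(1 + o):(n_out + o), , drop = FALSE]))
}

im2col_2d <- function(M, k) {
  oh <- nrow(M) - k + 1L
  ow <- ncol(M) - k + 1L
  cols <- vector("list", k * k)
  idx <- 1L
  for (dc in 0:(k - 1L)) {
    for (dr in 0:(k - 1L)) {
      cols[[idx]] <- as.vector(M[(1 + dr):(oh + dr), (1 + dc):(ow + dc)])
      idx <- idx + 1L
    }
  }
  list(A = do.call(cbind, cols), oh = oh, ow = ow)
}

# --- shared conv/pool blocks ----------------------------------------------

# 1-D convolution + ReLU + global max pooling over a token-embedding matrix.
conv1d_pool_fwd <- function(X, Wc, bc, k) {
  X <- pad_rows(X, k)
  A <- im2col_1d(X, k)
  Z <- sweep(A %*% Wc, 2, bc, "+")
  H <- relu(Z)
  ia <- max.col(t(H), ties.method = "first")
  p <- H[cbind(ia, seq_along(ia))]
  list(p = p, A = A, Z = Z, ia = ia)
}

conv1d_pool_bwd <- function(cache, dp) {
  nf <- length(dp)
  dZ <- cache$Z * 0
  dZ[cbind(cache$ia, seq_len(nf))] <- dp
  dZ <- dZ * (cache$Z > 0)
  list(dWc = crossprod(cache$A, dZ), dbc = colSums(dZ))
}

# 2-D convolution + ReLU + g x g dynamic max pooling over an interaction map.
conv2d_pool_fwd <- function(M, Wc, bc, k, g) {
  M <- pad_matrix(M, g + k - 1L, g + k - 1L)
  ic <- im2col_2d(M, k)
  Z <- sweep(ic$A %*% Wc, 2, bc, "+")
  H <- relu(Z)
  pos <- seq_len(ic$oh * ic$ow)
  r <- ((pos - 1L) %% ic$oh) + 1L
  cc <- ((pos - 1L) %/% ic$oh) + 1L
  cell <- (ceiling(g * cc / ic$ow) - 1L) * g + ceiling(g * r / ic$oh)
  nf <- ncol(H)
  n_cells <- g * g
  Pm <- matrix(0, n_cells, nf)
  arg <- matrix(0L, n_cells, nf)
  cell_idx <- split(pos, cell)
  for (ci in seq_len(n_cells)) {
    idx <- cell_idx[[as.character(ci)]]
    Hsub <- H[idx, , drop = FALSE]
    amax <- max.col(t(Hsub), ties.method = "first")
    arg[ci, ] <- idx[amax]
    Pm[ci, ] <- Hsub[cbind(amax, seq_len(nf))]
  }
  list(p = as.vector(Pm), A = ic$A, Z = Z, arg = arg, n_cells = n_cells)
}

conv2d_pool_bwd <- function(cache, dp) {
  nf <- ncol(cache$Z)
  dPm <- matrix(dp, cache$n_cells, nf)
  dH <- cache$Z * 0
  for (ci in seq_len(cache$n_cells)) {
    dH[cbind(cache$arg[ci, ], seq_len(nf))] <-
      dH[cbind(cache$arg[ci, ], seq_len(nf))] + dPm[ci, ]
  }
  dZ <- dH * (cache$Z > 0)
  list(dWc = crossprod(cache$A, dZ), dbc = colSums(dZ))
}

# --- dense scoring head: feature -> hidden (the relevance vector) -> score --

head_fwd <- function(f, params) {
  zh <- as.vector(f %*% params$Wh) + params$bh
  h <- relu(zh)
  zo <- sum(h * params$Wo) + params$bo
  list(score = sigmoid_(zo), h = h, zh = zh, f = f)
}

head_bwd <- function(cache, params, dzo) {
  dWo <- matrix(cache$h * dzo, ncol = 1)
  dbo <- dzo
  dh <- params$Wo[, 1] * dzo
  dzh <- dh * (cache$zh > 0)
  dWh <- outer(cache$f, dzh)
  dbh <- dzh
  df <- as.vector(params$Wh %*% dzh)
  list(grads = list(dWh = dWh, dbh = dbh, dWo = dWo, dbo = dbo), df = df)
}
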