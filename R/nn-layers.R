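# Internal neural-network primitives for the patch VAE.
#
# Activations live in "channel-matrix" (cm) layout: a dense (N * P) x C
# matrix whose rows enumerate samples fastest, then spatial positions in
# column-major image order (row index = n + (p - 1) * N, with
# p = (col - 1) * h + row).  Convolutions gather kernel neighbourhoods by
# row indexing (an im2col whose index vectors are precomputed per batch
# size), so the hot path is plain dense matrix products and block copies;
# transposed convolutions are the exact adjoint, sharing the same index
# machinery, which covers both the stride-2 upsamplers and the stride-1
# same-padded output heads.

# Geometry of a convolution over an h x w x c_in activation with a k x k
# kernel; pad = c(top, bottom, left, right) zeros.  pmap[q, j] is the input
# position feeding output position q through kernel offset j (NA = padding).
conv_geom <- function(h, w, c_in, k, stride, pad = c(0L, 0L, 0L, 0L)) {
  oh <- (h + pad[1] + pad[2] - k) %/% stride + 1L
  ow <- (w + pad[3] + pad[4] - k) %/% stride + 1L
  stopifnot(oh >= 1L, ow >= 1L)
  P <- oh * ow
  kk <- k * k
  pmap <- matrix(NA_integer_, P, kk)
  for (qc in seq_len(ow)) for (qr in seq_len(oh)) {
    q <- (qc - 1L) * oh + qr
    for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
      r <- (qr - 1L) * stride + dr + 1L - pad[1]
      cc <- (qc - 1L) * stride + dc + 1L - pad[3]
      if (r >= 1L && r <= h && cc >= 1L && cc <= w) {
        pmap[q, dc * k + dr + 1L] <- (cc - 1L) * h + r
      }
    }
  }
  list(h = h, w = w, c_in = c_in, k = k, stride = stride, oh = oh, ow = ow,
       P = P, Pin = h * w, kk = kk, K = kk * c_in, pmap = pmap,
       cache = new.env(parent = emptyenv()))
}

# Row-index vectors for batch size N: src[[j]][n + (q-1)N] is the source row
# in the (zero-row-augmented) input for output row (n, q); padding maps to
# the dummy zero row N * Pin + 1.
conv_rowmaps <- function(geom, N) {
  key <- as.character(N)
  hit <- geom$cache[[key]]
  if (!is.null(hit)) return(hit)
  dummy <- N * geom$Pin + 1L
  src <- lapply(seq_len(geom$kk), function(j) {
    idx <- rep((geom$pmap[, j] - 1L) * N, each = N) + seq_len(N)
    idx[is.na(idx)] <- dummy
    idx
  })
  geom$cache[[key]] <- src
  src
}

# im2col gather: A is cm (N*Pin) x c_in -> B is (N*P) x (kk*c_in).
conv_gather <- function(A, geom, N) {
  src <- conv_rowmaps(geom, N)
  Az <- rbind(A, 0)
  C <- geom$c_in
  B <- matrix(0, N * geom$P, geom$K)
  for (j in seq_len(geom$kk)) {
    B[, ((j - 1L) * C + 1L):(j * C)] <- Az[src[[j]], , drop = FALSE]
  }
  B
}

# Adjoint of conv_gather: scatter-add dB blocks back onto the input rows.
conv_scatter <- function(dB, geom, N) {
  src <- conv_rowmaps(geom, N)
  C <- geom$c_in
  dAz <- matrix(0, N * geom$Pin + 1L, C)
  for (j in seq_len(geom$kk)) {
    idx <- src[[j]]
    dAz[idx, ] <- dAz[idx, ] + dB[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dAz[seq_len(N * geom$Pin), , drop = FALSE]
}

conv_forward <- function(A, geom, W, b, N) {
  B <- conv_gather(A, geom, N)
  Y <- B %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(out = Y, B = B, N = N)
}

conv_backward <- function(dY, cache, geom, W) {
  list(dX = conv_scatter(dY %*% t(W), geom, cache$N),
       dW = crossprod(cache$B, dY),
       db = colSums(dY))
}

# Transposed convolution: geom describes the convolution over the OUTPUT
# image, so geom$P equals the number of input positions, geom$c_in the
# number of OUTPUT channels, and W is c_in_tconv x geom$K.
tconv_forward <- function(U, geom, W, b, N) {
  Z <- U %*% W
  V <- conv_scatter(Z, geom, N)
  V <- sweep(V, 2L, b, "+")
  list(out = V, U = U, N = N)
}

tconv_backward <- function(dV, cache, geom, W) {
  dZ <- conv_gather(dV, geom, cache$N)
  list(dX = dZ %*% t(W),
       dW = crossprod(cache$U, dZ),
       db = colSums(dV))
}

# Layout converters used at the conv/FC boundary (small matrices only).
cm_to_flat <- function(xm, N) {
  P <- nrow(xm) %/% N
  C <- ncol(xm)
  matrix(aperm(array(xm, c(N, P, C)), c(1L, 3L, 2L)), N, C * P)
}

flat_to_cm <- function(x, C) {
  N <- nrow(x)
  P <- ncol(x) %/% C
  matrix(aperm(array(x, c(N, C, P)), c(1L, 3L, 2L)), N * P, C)
}

BN_EPS <- 1e-5

# Batch normalization over channels; xm in cm layout (columns = channels).
# stats is list(mean, var) of running statistics (used in inference mode).
bn_forward <- function(xm, gamma, beta, stats, training, momentum = 0.1) {
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc * xc)
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    mu <- stats$mean
    v <- stats$var
    xc <- sweep(xm, 2L, mu)
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = y, xhat = xhat, inv = inv, stats = stats)
}

bn_backward <- function(dy, cache, gamma) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  Nn <- nrow(dy)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(
    dxhat - matrix(m1, Nn, length(m1), byrow = TRUE) -
      sweep(cache$xhat, 2L, m2, "*"),
    2L, cache$inv, "*"
  )
  list(dX = dx, dgamma = dgamma, dbeta = dbeta)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Adam optimizer step over a flat named list of parameter arrays.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(
    t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

# Single-filter stride-1 convolution head (the decoder's mean/log-variance
# outputs).  Reduces channels per kernel offset first (one matmul), then
# accumulates spatially shifted copies by column indexing on N x P images —
# much cheaper than the generic im2col for this 4x4, 16-offset kernel.
head_forward <- function(A, geom, W, b, N) {
  C <- geom$c_in
  Wm <- matrix(W, C, geom$kk)
  S <- A %*% Wm                              # (N*Pin) x kk
  Y <- matrix(b[1], N, geom$P)
  for (j in seq_len(geom$kk)) {
    idx <- geom$pmap[, j]
    valid <- which(!is.na(idx))
    Sj <- matrix(S[, j], N, geom$Pin)
    Y[, valid] <- Y[, valid] + Sj[, idx[valid], drop = FALSE]
  }
  list(out = Y, A = A, N = N)
}

head_backward <- function(dY, cache, geom, W) {
  N <- cache$N
  C <- geom$c_in
  Wm <- matrix(W, C, geom$kk)
  D <- matrix(0, N * geom$Pin, geom$kk)
  for (j in seq_len(geom$kk)) {
    idx <- geom$pmap[, j]
    valid <- which(!is.na(idx))
    Dm <- matrix(0, N, geom$Pin)
    Dm[, idx[valid]] <- dY[, valid, drop = FALSE]
    D[, j] <- Dm
  }
  dWm <- crossprod(D, cache$A)               # kk x C
  list(dX = D %*% t(Wm),
       dW = matrix(t(dWm), ncol = 1L),
       db = sum(dY))
}
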