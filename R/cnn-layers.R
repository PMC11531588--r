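# 3D layer primitives for the voxel classifiers.
#
# Convolutions are computed as im2col gathers followed by one BLAS matmul;
# the gather index matrix depends only on (input dims, kernel dims) and is
# cached per model. All layers operate on a single sample laid out as a 4D
# array (x, y, z, channel); batching is an outer loop.
#
# Activations are leaky rectifiers: non-negative envelope inputs make a
# hard relu prone to whole-network die-off at aggressive learning rates.
leaky_slope <- 0.1

im2col_index <- function(cache, dims, kernel) {
  key <- paste(c(dims, kernel), collapse = "x")
  if (!is.null(cache[[key]])) return(cache[[key]])
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]; ci <- dims[4]
  kx <- kernel[1]; ky <- kernel[2]; kz <- kernel[3]
  ox <- nx - kx + 1L; oy <- ny - ky + 1L; oz <- nz - kz + 1L
  # 0-based linear offset of each output voxel's (1,1,1) corner
  out_off <- as.vector(outer(outer((seq_len(ox) - 1L),
                                   (seq_len(oy) - 1L) * nx, `+`),
                             (seq_len(oz) - 1L) * nx * ny, `+`))
  # 0-based offsets of the kernel taps across input channels
  tap_off <- as.vector(outer(outer(outer((seq_len(kx) - 1L),
                                         (seq_len(ky) - 1L) * nx, `+`),
                             (seq_len(kz) - 1L) * nx * ny, `+`),
                             (seq_len(ci) - 1L) * nx * ny * nz, `+`))
  idx <- outer(out_off, tap_off, `+`) + 1L
  storage.mode(idx) <- "integer"
  res <- list(idx = idx, out_dim = c(ox, oy, oz))
  cache[[key]] <- res
  res
}

conv3d_forward <- function(x, W, b, cache_env) {
  dims <- dim(x)
  kd <- dim(W)                      # kx, ky, kz, Cin, Cout
  ic <- im2col_index(cache_env, dims, kd[1:3])
  co <- kd[5]
  X <- matrix(x[ic$idx], nrow = nrow(ic$idx))
  Wmat <- matrix(W, ncol = co)
  Y <- X %*% Wmat
  Y <- Y + rep(b, each = nrow(Y))
  A <- Y
  neg <- A < 0
  A[neg] <- leaky_slope * A[neg]      # leaky relu: keeps gradients alive
  out <- array(A, c(ic$out_dim, co))
  list(out = out,
       cache = list(X = X, A = A, neg = neg, in_dim = dims,
                    out_dim = ic$out_dim, idx = ic$idx))
}

conv3d_backward <- function(dout, W, cache, want_dx = TRUE) {
  co <- dim(W)[5]
  dY <- matrix(dout, ncol = co)
  dY[cache$neg] <- leaky_slope * dY[cache$neg]
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  dx <- NULL
  if (want_dx) {
    Wmat <- matrix(W, ncol = co)
    dXcol <- tcrossprod(dY, Wmat)   # M x (K*Cin)
    agg <- rowsum(as.vector(dXcol), group = as.vector(cache$idx))
    dx_vec <- numeric(prod(cache$in_dim))
    dx_vec[as.integer(rownames(agg))] <- agg
    dx <- array(dx_vec, cache$in_dim)
  }
  list(dW = array(dW, dim(W)), db = db, dx = dx)
}

maxpool3d_forward <- function(x, pool) {
  d <- dim(x)
  nb <- d[1:3] %/% pool
  if (any(nb < 1L)) stop("pooling collapses a spatial axis to zero")
  cr <- nb * pool
  xc <- x[seq_len(cr[1]), seq_len(cr[2]), seq_len(cr[3]), , drop = FALSE]
  out <- array(-Inf, c(nb, d[4]))
  arg <- array(0L, c(nb, d[4]))
  s <- 0L
  for (c3 in seq_len(pool[3])) for (c2 in seq_len(pool[2]))
    for (c1 in seq_len(pool[1])) {
      s <- s + 1L
      cand <- xc[seq(c1, cr[1], pool[1]), seq(c2, cr[2], pool[2]),
                 seq(c3, cr[3], pool[3]), , drop = FALSE]
      m <- cand > out
      out[m] <- cand[m]
      arg[m] <- s
    }
  list(out = out, cache = list(arg = arg, in_dim = d, pool = pool, nb = nb))
}

maxpool3d_backward <- function(dout, cache) {
  d <- cache$in_dim; pool <- cache$pool; nb <- cache$nb
  cr <- nb * pool
  dx <- array(0, d)
  s <- 0L
  for (c3 in seq_len(pool[3])) for (c2 in seq_len(pool[2]))
    for (c1 in seq_len(pool[1])) {
      s <- s + 1L
      m <- cache$arg == s
      if (any(m)) {
        sub <- array(0, dim(dout))
        sub[m] <- dout[m]
        dx[seq(c1, cr[1], pool[1]), seq(c2, cr[2], pool[2]),
           seq(c3, cr[3], pool[3]), ] <- sub
      }
    }
  dx
}

avgpool_z_forward <- function(x, factor) {
  d <- dim(x)
  nb <- d[3] %/% factor
  out <- array(0, c(d[1], d[2], nb, d[4]))
  for (j in seq_len(factor)) {
    out <- out + x[, , seq(j, nb * factor, by = factor), , drop = FALSE]
  }
  out <- out / factor
  list(out = out, cache = list(in_dim = d, factor = factor, nb = nb))
}

# global pooling head: per-channel mean and max concatenated. The mean
# summarizes diffuse energy; the max keys on localized blobs that occupy a
# small fraction of the voxel.
gap_forward <- function(x) {
  d <- dim(x)
  m <- prod(d[1:3])
  mat <- matrix(x, nrow = m, ncol = d[4])
  mu <- colMeans(mat)
  amax <- max.col(t(mat), ties.method = "first")
  mx <- mat[cbind(amax, seq_len(d[4]))]
  list(out = c(mu, mx),
       cache = list(in_dim = d, m = m, amax = amax))
}

gap_backward <- function(dout, cache) {
  k <- cache$in_dim[4]
  dmat <- matrix(rep(dout[seq_len(k)] / cache$m, each = cache$m),
                 cache$m, k)
  dmat[cbind(cache$amax, seq_len(k))] <-
    dmat[cbind(cache$amax, seq_len(k))] + dout[k + seq_len(k)]
  array(dmat, cache$in_dim)
}

dense_forward <- function(feat, W, b, relu = FALSE) {
  z <- drop(feat %*% W) + b
  a <- if (relu) ifelse(z < 0, leaky_slope * z, z) else z
  list(out = a, cache = list(feat = feat, z = z, relu = relu))
}

dense_backward <- function(dout, W, cache) {
  if (cache$relu) dout <- dout * ifelse(cache$z < 0, leaky_slope, 1)
  list(dW = outer(cache$feat, dout), db = dout, dx = drop(W %*% dout))
}

softmax_probs <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

# cross-entropy loss and its gradient wrt logits for one sample
xent_loss_grad <- function(logits, y) {
  p <- softmax_probs(logits)
  list(loss = -log(max(p[y], 1e-12)), probs = p,
       dlogits = p - (seq_along(p) == y))
}
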