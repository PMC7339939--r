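# Low-level neural-network layers for the U-Net, implemented as BLAS matrix
# products (im2col for 3x3 convolutions, precomputed interpolation matrices
# for bilinear upsampling). Arrays are H x W x C.

conv_patches <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  P <- matrix(0, H * W, 9 * C)
  k <- 0
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1
    block <- xp[dy + seq_len(H), dx + seq_len(W), , drop = FALSE]
    P[, ((k - 1) * C + 1):(k * C)] <- matrix(block, H * W, C)
  }
  P
}

conv_patches_bwd <- function(dP, H, W, C) {
  dxp <- array(0, c(H + 2, W + 2, C))
  k <- 0
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1
    block <- array(dP[, ((k - 1) * C + 1):(k * C)], c(H, W, C))
    dxp[dy + seq_len(H), dx + seq_len(W), ] <-
      dxp[dy + seq_len(H), dx + seq_len(W), , drop = FALSE] + block
  }
  dxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

# 3x3 same-padding convolution; Wm is (9*Cin) x Cout
conv3_fwd <- function(x, Wm, b) {
  d <- dim(x)
  P <- conv_patches(x)
  out_mat <- P %*% Wm
  out_mat <- sweep(out_mat, 2, b, "+")
  list(out = array(out_mat, c(d[1], d[2], ncol(Wm))), P = P)
}

conv3_bwd <- function(d_out, P, Wm, in_dim) {
  d_mat <- matrix(d_out, nrow(P), ncol(Wm))
  dW <- crossprod(P, d_mat)
  db <- colSums(d_mat)
  dP <- tcrossprod(d_mat, Wm)
  dx <- conv_patches_bwd(dP, in_dim[1], in_dim[2], in_dim[3])
  list(dx = dx, dW = dW, db = db)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

maxpool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  i1 <- seq(1, H, 2); i2 <- seq(2, H, 2)
  j1 <- seq(1, W, 2); j2 <- seq(2, W, 2)
  s <- list(x[i1, j1, , drop = FALSE], x[i2, j1, , drop = FALSE],
            x[i1, j2, , drop = FALSE], x[i2, j2, , drop = FALSE])
  m <- s[[1]]
  arg <- array(1L, dim(m))
  for (k in 2:4) {
    upd <- s[[k]] > m
    m[upd] <- s[[k]][upd]
    arg[upd] <- k
  }
  list(out = m, arg = arg)
}

maxpool_bwd <- function(d_out, arg, in_dim) {
  H <- in_dim[1]; W <- in_dim[2]
  i1 <- seq(1, H, 2); i2 <- seq(2, H, 2)
  j1 <- seq(1, W, 2); j2 <- seq(2, W, 2)
  rows <- list(i1, i2, i1, i2)
  cols <- list(j1, j1, j2, j2)
  dx <- array(0, in_dim)
  for (k in 1:4) {
    tmp <- d_out
    tmp[arg != k] <- 0
    dx[rows[[k]], cols[[k]], ] <- dx[rows[[k]], cols[[k]], , drop = FALSE] + tmp
  }
  dx
}

# interpolation matrix for x2 bilinear upsampling (half-pixel centers)
bilinear_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5
    i0 <- floor(src); f <- src - i0
    lo <- min(max(i0, 0), n_in - 1)
    hi <- min(max(i0 + 1, 0), n_in - 1)
    M[i, lo + 1] <- M[i, lo + 1] + (1 - f)
    M[i, hi + 1] <- M[i, hi + 1] + f
  }
  M
}

upsample_fwd <- function(x, Ur, Uc) {
  d <- dim(x)
  out <- array(0, c(nrow(Ur), nrow(Uc), d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Ur %*% x[, , c] %*% t(Uc)
  out
}

upsample_bwd <- function(d_out, Ur, Uc) {
  d <- dim(d_out)
  dx <- array(0, c(ncol(Ur), ncol(Uc), d[3]))
  for (c in seq_len(d[3])) dx[, , c] <- t(Ur) %*% d_out[, , c] %*% Uc
  dx
}

# 2x2 stride-2 transposed convolution; Wt is Cin x (4*Cout)
tconv_fwd <- function(x, Wt, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  cout <- ncol(Wt) / 4
  x_mat <- matrix(x, H * W, Cin)
  out <- array(0, c(2 * H, 2 * W, cout))
  rows <- list(seq(1, 2 * H, 2), seq(2, 2 * H, 2))
  cols <- list(seq(1, 2 * W, 2), seq(2, 2 * W, 2))
  k <- 0
  for (dx in 1:2) for (dy in 1:2) {
    k <- k + 1
    blk <- x_mat %*% Wt[, ((k - 1) * cout + 1):(k * cout), drop = FALSE]
    out[rows[[dy]], cols[[dx]], ] <- array(blk, c(H, W, cout))
  }
  sweep_b <- array(rep(b, each = 4 * H * W), c(2 * H, 2 * W, cout))
  list(out = out + sweep_b, x_mat = x_mat)
}

tconv_bwd <- function(d_out, x_mat, Wt, in_dim) {
  H <- in_dim[1]; W <- in_dim[2]; Cin <- in_dim[3]
  cout <- ncol(Wt) / 4
  rows <- list(seq(1, 2 * H, 2), seq(2, 2 * H, 2))
  cols <- list(seq(1, 2 * W, 2), seq(2, 2 * W, 2))
  dW <- matrix(0, Cin, 4 * cout)
  dx_mat <- matrix(0, H * W, Cin)
  db <- numeric(cout)
  k <- 0
  for (dx in 1:2) for (dy in 1:2) {
    k <- k + 1
    blk <- matrix(d_out[rows[[dy]], cols[[dx]], , drop = FALSE], H * W, cout)
    idx <- ((k - 1) * cout + 1):(k * cout)
    dW[, idx] <- crossprod(x_mat, blk)
    dx_mat <- dx_mat + tcrossprod(blk, Wt[, idx, drop = FALSE])
    db <- db + colSums(blk)
  }
  list(dx = array(dx_mat, in_dim), dW = dW, db = db)
}

# reflection-pad an H x W (x C) array to target spatial size
pad_reflect <- function(x, H2, W2) {
  d <- dim(x)
  is_mat <- length(d) == 2
  H <- d[1]; W <- d[2]
  if (H2 < H || W2 < W) stop("cannot pad to a smaller size")
  if (H2 - H >= H || W2 - W >= W) stop("reflection pad larger than the image")
  ri <- c(seq_len(H), H - seq_len(H2 - H))
  ci <- c(seq_len(W), W - seq_len(W2 - W))
  if (is_mat) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}
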