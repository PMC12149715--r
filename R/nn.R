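# Minimal convolutional network toolkit.
#
# No tensor/autodiff framework is available to R here, and the networks this
# package needs are deliberately small (CPU-scale, per-organ), so the layers
# are implemented directly: 3x3 and 1x1 convolutions expressed as BLAS
# matrix products over shifted views, 2x2 max pooling, nearest-neighbor
# upsampling, dense layers, and Adam. Tensors are arrays in [H, W, N, C]
# layout (column-major, so the first three dims are contiguous and channel
# matmuls need no permutation). Gradients are hand-derived and verified
# against finite differences in the test suite.

# parameters are nested lists: layer name -> list(W = array, b = vector)
nn_zeros_like <- function(p) {
  lapply(p, function(layer) lapply(layer, function(x) {
    if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  }))
}

init_conv <- function(kh, kw, cin, cout) {
  list(W = array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_dense <- function(fin, fout) {
  list(W = matrix(rnorm(fin * fout, 0, sqrt(2 / fin)), fin, fout),
       b = numeric(fout))
}

conv_fwd <- function(X, W, b) {
  dw <- dim(W); kh <- dw[1]; cin <- dw[3]; cout <- dw[4]
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]
  if (kh == 1L) {
    out <- matrix(X, ncol = cin) %*% matrix(W, cin, cout)
  } else {
    Xp <- array(0, c(H + 2L, Wd + 2L, N, cin))
    Xp[2:(H + 1L), 2:(Wd + 1L), , ] <- X
    out <- matrix(0, H * Wd * N, cout)
    for (di in 0:2) for (dj in 0:2) {
      Xs <- Xp[(1L + di):(H + di), (1L + dj):(Wd + dj), , , drop = FALSE]
      out <- out + matrix(Xs, ncol = cin) %*% matrix(W[di + 1L, dj + 1L, , ], cin, cout)
    }
  }
  out <- out + rep(b, each = H * Wd * N)
  array(out, c(H, Wd, N, cout))
}

conv_bwd <- function(X, W, dOut) {
  dw <- dim(W); kh <- dw[1]; cin <- dw[3]; cout <- dw[4]
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]
  dOm <- matrix(dOut, ncol = cout)
  db <- colSums(dOm)
  if (kh == 1L) {
    dW <- array(crossprod(matrix(X, ncol = cin), dOm), dim(W))
    dX <- array(dOm %*% t(matrix(W, cin, cout)), dim(X))
    return(list(dX = dX, dW = dW, db = db))
  }
  Xp <- array(0, c(H + 2L, Wd + 2L, N, cin))
  Xp[2:(H + 1L), 2:(Wd + 1L), , ] <- X
  dXp <- array(0, dim(Xp))
  dW <- array(0, dim(W))
  for (di in 0:2) for (dj in 0:2) {
    ri <- (1L + di):(H + di); rj <- (1L + dj):(Wd + dj)
    Xs <- Xp[ri, rj, , , drop = FALSE]
    dW[di + 1L, dj + 1L, , ] <- crossprod(matrix(Xs, ncol = cin), dOm)
    dXs <- array(dOm %*% t(matrix(W[di + 1L, dj + 1L, , ], cin, cout)),
                 c(H, Wd, N, cin))
    dXp[ri, rj, , ] <- dXp[ri, rj, , , drop = FALSE] + dXs
  }
  list(dX = dXp[2:(H + 1L), 2:(Wd + 1L), , , drop = FALSE], dW = dW, db = db)
}

relu_fwd <- function(X) { X[X < 0] <- 0; X }
relu_bwd <- function(dOut, out) { dOut[out <= 0] <- 0; dOut }

sigmoid <- function(x) 1 / (1 + exp(-x))

pool_slabs <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]
  list(X[seq(1, H, 2), seq(1, W, 2), , , drop = FALSE],
       X[seq(2, H, 2), seq(1, W, 2), , , drop = FALSE],
       X[seq(1, H, 2), seq(2, W, 2), , , drop = FALSE],
       X[seq(2, H, 2), seq(2, W, 2), , , drop = FALSE])
}

maxpool_fwd <- function(X) {
  s <- pool_slabs(X)
  pmax(s[[1]], s[[2]], s[[3]], s[[4]])
}

maxpool_bwd <- function(X, out, dOut) {
  d <- dim(X); H <- d[1]; W <- d[2]
  s <- pool_slabs(X)
  dX <- array(0, d)
  used <- array(FALSE, dim(out))
  sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    m <- (s[[k]] == out) & !used
    used <- used | m
    ri <- seq(sel[[k]][1], H, 2); rj <- seq(sel[[k]][2], W, 2)
    dX[ri, rj, , ] <- dOut * m
  }
  dX
}

upsample_fwd <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

upsample_bwd <- function(dOut) {
  d <- dim(dOut); H <- d[1]; W <- d[2]
  dOut[seq(1, H, 2), seq(1, W, 2), , , drop = FALSE] +
    dOut[seq(2, H, 2), seq(1, W, 2), , , drop = FALSE] +
    dOut[seq(1, H, 2), seq(2, W, 2), , , drop = FALSE] +
    dOut[seq(2, H, 2), seq(2, W, 2), , , drop = FALSE]
}

concat_ch <- function(A, B) {
  da <- dim(A); db <- dim(B)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- A
  out[, , , da[4] + seq_len(db[4])] <- B
  out
}

# [H,W,N,C] -> [N, H*W*C] feature matrix (per-sample rows)
flatten_fwd <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(3, 1, 2, 4)), nrow = d[3])
}

flatten_bwd <- function(dMat, xdim) {
  aperm(array(dMat, c(xdim[3], xdim[1], xdim[2], xdim[4])), c(2, 3, 1, 4))
}

dense_fwd <- function(Xm, W, b) sweep(Xm %*% W, 2, b, "+")

dense_bwd <- function(Xm, W, dOut) {
  list(dX = dOut %*% t(W), dW = crossprod(Xm, dOut), db = colSums(dOut))
}

adam_init <- function(params) {
  list(m = nn_zeros_like(params), v = nn_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (k in names(params[[nm]])) {
      g <- grads[[nm]][[k]]
      state$m[[nm]][[k]] <- beta1 * state$m[[nm]][[k]] + (1 - beta1) * g
      state$v[[nm]][[k]] <- beta2 * state$v[[nm]][[k]] + (1 - beta2) * g * g
      params[[nm]][[k]] <- params[[nm]][[k]] -
        lr * (state$m[[nm]][[k]] / bc1) / (sqrt(state$v[[nm]][[k]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# combined soft-Dice + binary cross-entropy on probabilities, with the
# gradient taken directly at the logits (numerically stable)
seg_loss <- function(probs, target, smooth = 1) {
  n <- length(probs)
  p <- pmin(1 - 1e-7, pmax(1e-7, probs))
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  S <- sum(probs * target); D <- sum(probs) + sum(target)
  dice <- 1 - (2 * S + smooth) / (D + smooth)
  d_bce <- (probs - target) / n
  d_dice_dp <- -(2 * target * (D + smooth) - (2 * S + smooth)) / (D + smooth)^2
  d_logits <- d_bce + d_dice_dp * probs * (1 - probs)
  list(loss = bce + dice, d_logits = array(d_logits, dim(probs)))
}
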