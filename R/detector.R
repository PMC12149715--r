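# Trainable single-box detector. The localization design is detector
# agnostic: anything honoring the predict_box() contract can be plugged in.
# The built-in reference detector is a small convolutional regressor
# (coordinate channels -> three conv/pool stages -> dense head) predicting
# a normalized center/size box plus a presence confidence; it is sized for
# single-organ DRRs and CPU training.

#' Detector training configuration
#'
#' @param seed RNG seed.
#' @param epochs training epochs (maximum 600 by default).
#' @param batch_size images per optimization step (default 32).
#' @param lr Adam learning rate.
#' @param input_size square side the DRR is resized to (nearest neighbor).
#' @param width base channel width.
#' @param min_confidence presence threshold below which prediction reports
#'   "not found".
#' @param presence_weight weight of the presence term in the loss.
#' @param max_shift translation-augmentation amplitude in resized pixels;
#'   each training sample is shifted jointly with its box target (0
#'   disables).
#' @return a `detector_config` list.
#' @export
detector_config <- function(seed = 1L, epochs = 600L, batch_size = 32L,
                            lr = 2e-3, input_size = 64L, width = 8L,
                            min_confidence = 0.5, presence_weight = 0.1,
                            max_shift = input_size %/% 8L) {
  structure(list(seed = as.integer(seed), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 input_size = as.integer(input_size), width = as.integer(width),
                 min_confidence = min_confidence,
                 presence_weight = presence_weight,
                 max_shift = as.integer(max_shift)),
            class = "detector_config")
}

# integer-shift a [S,S] matrix with zero fill
shift2d <- function(m, dr, dc) {
  S1 <- nrow(m); S2 <- ncol(m)
  out <- matrix(0, S1, S2)
  sr <- max(1, 1 - dr):min(S1, S1 - dr)
  sc <- max(1, 1 - dc):min(S2, S2 - dc)
  out[sr + dr, sc + dc] <- m[sr, sc]
  out
}

# nearest-neighbor resize of a [H,W] matrix (or [H,W,C] array) to S x S
resize_nearest_2d <- function(px, S) {
  d <- dim(px)
  mi <- pmin(d[1], floor((seq_len(S) - 0.5) * d[1] / S) + 1L)
  mj <- pmin(d[2], floor((seq_len(S) - 0.5) * d[2] / S) + 1L)
  if (length(d) == 2L) px[mi, mj, drop = FALSE] else px[mi, mj, , drop = FALSE]
}

# DRR -> network input [S,S,1,C+2]: intensity channels in [0,1] plus
# normalized row/column coordinate channels (the regression head needs an
# explicit notion of position)
detector_input <- function(drr, S) {
  px <- drr$pixels
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  small <- resize_nearest_2d(px, S) / 255
  C <- dim(small)[3]
  out <- array(0, c(S, S, 1L, C + 2L))
  out[, , 1, seq_len(C)] <- small
  out[, , 1, C + 1L] <- matrix(rep((seq_len(S) - 0.5) / S, S), S, S)
  out[, , 1, C + 2L] <- matrix(rep((seq_len(S) - 0.5) / S, each = S), S, S)
  out
}

# box -> normalized (cu, cv, h, w) targets relative to the DRR shape
box_targets <- function(box, shape) {
  H <- shape[1]; W <- shape[2]
  c((box$u[1] + box$u[2]) / 2 / H, (box$v[1] + box$v[2]) / 2 / W,
    iv_len(box$u) / H, iv_len(box$v) / W)
}

detector_forward <- function(params, X) {
  c1 <- conv_fwd(X, params$c1$W, params$c1$b); a1 <- relu_fwd(c1)
  p1 <- maxpool_fwd(a1)
  c2 <- conv_fwd(p1, params$c2$W, params$c2$b); a2 <- relu_fwd(c2)
  p2 <- maxpool_fwd(a2)
  c3 <- conv_fwd(p2, params$c3$W, params$c3$b); a3 <- relu_fwd(c3)
  p3 <- maxpool_fwd(a3)
  f <- flatten_fwd(p3)
  d1 <- dense_fwd(f, params$d1$W, params$d1$b); r1 <- pmax(d1, 0)
  out <- dense_fwd(r1, params$d2$W, params$d2$b)
  list(out = out, X = X, a1 = a1, p1 = p1, a2 = a2, p2 = p2, a3 = a3,
       p3 = p3, f = f, r1 = r1)
}

detector_backward <- function(params, fw, dOut) {
  g <- list()
  gd2 <- dense_bwd(fw$r1, params$d2$W, dOut)
  g$d2 <- list(W = gd2$dW, b = gd2$db)
  dR1 <- gd2$dX; dR1[fw$r1 <= 0] <- 0
  gd1 <- dense_bwd(fw$f, params$d1$W, dR1)
  g$d1 <- list(W = gd1$dW, b = gd1$db)
  dP3 <- flatten_bwd(gd1$dX, dim(fw$p3))
  dA3 <- maxpool_bwd(fw$a3, fw$p3, dP3)
  dA3 <- relu_bwd(dA3, fw$a3)
  gc3 <- conv_bwd(fw$p2, params$c3$W, dA3)
  g$c3 <- list(W = gc3$dW, b = gc3$db)
  dA2 <- maxpool_bwd(fw$a2, fw$p2, gc3$dX)
  dA2 <- relu_bwd(dA2, fw$a2)
  gc2 <- conv_bwd(fw$p1, params$c2$W, dA2)
  g$c2 <- list(W = gc2$dW, b = gc2$db)
  dA1 <- maxpool_bwd(fw$a1, fw$p1, gc2$dX)
  dA1 <- relu_bwd(dA1, fw$a1)
  gc1 <- conv_bwd(fw$X, params$c1$W, dA1)
  g$c1 <- list(W = gc1$dW, b = gc1$db)
  g
}

#' Train a single-class bounding-box detector
#'
#' Fits the built-in convolutional box regressor to (DRR, reference box)
#' pairs for one organ and plane. Deterministic for a fixed `config$seed`.
#'
#' @param images list of [drr_image()]s (3-channel).
#' @param boxes list of reference [box2d()]s, one per image.
#' @param config a [detector_config()].
#' @return a detector of class `cnn_detector` honoring [predict_box()].
#' @export
train_detector <- function(images, boxes, config = detector_config()) {
  if (!length(images)) abort("empty detector training set.")
  if (length(images) != length(boxes)) abort("images and boxes differ in length.")
  S <- config$input_size
  plane <- images[[1]]$plane
  Xs <- lapply(images, detector_input, S = S)
  Cin <- dim(Xs[[1]])[4]
  X <- do.call(abind_n, Xs)
  TT <- t(vapply(seq_along(boxes), function(i) {
    box_targets(boxes[[i]], dim(images[[i]]$pixels))
  }, numeric(4)))
  n <- dim(X)[3]
  w <- config$width
  fdim <- (S %/% 8L)^2L * 2L * w
  params <- with_seed(config$seed, list(
    c1 = init_conv(3, 3, Cin, w),
    c2 = init_conv(3, 3, w, 2L * w),
    c3 = init_conv(3, 3, 2L * w, 2L * w),
    d1 = init_dense(fdim, 64L),
    d2 = init_dense(64L, 5L)
  ))
  with_seed(config$seed + 1L, {
    st <- adam_init(params)
    trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- perm[start:min(n, start + config$batch_size - 1L)]
        Xb <- X[, , idx, , drop = FALSE]
        tt <- TT[idx, , drop = FALSE]
        if (config$max_shift > 0L) {
          nch <- Cin - 2L      # intensity channels; coords stay absolute
          for (k in seq_along(idx)) {
            dr <- sample(-config$max_shift:config$max_shift, 1)
            dc <- sample(-config$max_shift:config$max_shift, 1)
            for (ch in seq_len(nch)) {
              Xb[, , k, ch] <- shift2d(Xb[, , k, ch], dr, dc)
            }
            tt[k, 1] <- tt[k, 1] + dr / S
            tt[k, 2] <- tt[k, 2] + dc / S
          }
        }
        fw <- detector_forward(params, Xb)
        nb <- length(idx)
        ph <- sigmoid(fw$out[, 1:4, drop = FALSE])
        conf <- sigmoid(fw$out[, 5])
        loss <- mean((ph - tt)^2) - config$presence_weight * mean(log(pmax(conf, 1e-7)))
        dOut <- matrix(0, nb, 5)
        dOut[, 1:4] <- 2 * (ph - tt) / (4 * nb) * ph * (1 - ph)
        dOut[, 5] <- -config$presence_weight * (1 - conf) / nb
        g <- detector_backward(params, fw, dOut)
        upd <- adam_step(params, g, st, lr = config$lr)
        params <- upd$params; st <- upd$state
        losses <- c(losses, loss)
      }
      trace[ep] <- mean(losses)
    }
    structure(list(params = params, config = config, plane = plane,
                   loss_trace = trace),
              class = c("cnn_detector", "oar_detector"))
  })
}

#' @export
predict_box.cnn_detector <- function(detector, drr) {
  S <- detector$config$input_size
  X <- detector_input(drr, S)
  fw <- detector_forward(detector$params, X)
  conf <- sigmoid(fw$out[1, 5])
  if (conf < detector$config$min_confidence) return(NULL)
  ph <- sigmoid(fw$out[1, 1:4])
  H <- nrow(drr$pixels); W <- ncol(drr$pixels)
  u1 <- round((ph[1] - ph[3] / 2) * H); u2 <- round((ph[1] + ph[3] / 2) * H)
  v1 <- round((ph[2] - ph[4] / 2) * W); v2 <- round((ph[2] + ph[4] / 2) * W)
  u1 <- max(0, min(u1, H - 1)); u2 <- max(u1 + 1, min(u2, H))
  v1 <- max(0, min(v1, W - 1)); v2 <- max(v1 + 1, min(v2, W))
  box2d(drr$plane, c(u1, u2), c(v1, v2), confidence = conf)
}

#' @export
tidy.cnn_detector <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' Intersection-over-union of two boxes
#'
#' @param a,b [box2d()]s on the same plane.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  iu <- max(0, min(a$u[2], b$u[2]) - max(a$u[1], b$u[1]))
  ivl <- max(0, min(a$v[2], b$v[2]) - max(a$v[1], b$v[1]))
  inter <- iu * ivl
  union <- iv_len(a$u) * iv_len(a$v) + iv_len(b$u) * iv_len(b$v) - inter
  inter / union
}
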