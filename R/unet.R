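# U-Net variants for organ-specific segmentation of mini-CT axial slices:
# a basic encoder-decoder with skip connections, an attention-gated variant,
# and a 2.5D variant (the basic 2D network fed a 3-channel slice sandwich).
# Depth and width are configuration; defaults are sized for CPU training on
# cropped mini-CT scans.

#' Training configuration for segmentation models
#'
#' Augmentation follows the in-plane scheme: with probability
#' `augment_prob`, a rotation uniform in +/- `rot_limit` degrees and an
#' isotropic scaling uniform in 1 +/- `scale_limit` are applied jointly to
#' image and mask. Binary masks are produced at `threshold` on the sigmoid
#' output.
#'
#' @param seed RNG seed controlling initialization, shuffling and
#'   augmentation.
#' @param epochs training epochs.
#' @param batch_size slices per optimization step.
#' @param lr Adam learning rate.
#' @param rot_limit rotation limit, degrees.
#' @param scale_limit relative isotropic scale limit.
#' @param augment_prob probability a training slice is augmented.
#' @param threshold probability threshold for binarization.
#' @return a `train_config` list.
#' @export
train_config <- function(seed = 1L, epochs = 25L, batch_size = 8L, lr = 1e-3,
                         rot_limit = 15, scale_limit = 0.15,
                         augment_prob = 0.5, threshold = 0.5) {
  if (augment_prob < 0 || augment_prob > 1) abort("augment_prob must be in [0,1].")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0,1).")
  structure(list(seed = as.integer(seed), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 rot_limit = rot_limit, scale_limit = scale_limit,
                 augment_prob = augment_prob, threshold = threshold),
            class = "train_config")
}

#' Build an untrained segmentation model
#'
#' @param variant `"basic_unet"`, `"attention_unet"` or `"unet_2p5d"`. The
#'   attention variant gates each skip connection with an additive attention
#'   block; the 2.5D variant is the basic 2D network with a 3-channel input
#'   (superior / target / inferior slice).
#' @param width base channel width (doubled at each level).
#' @param levels number of pooling levels.
#' @param seed RNG seed for weight initialization.
#' @return object of class `unet_model` (untrained).
#' @export
build_model <- function(variant = c("basic_unet", "attention_unet", "unet_2p5d"),
                        width = 8L, levels = 2L, seed = 1L) {
  variant <- match.arg(variant)
  in_ch <- if (variant == "unet_2p5d") 3L else 1L
  L <- as.integer(levels); w <- as.integer(width)
  params <- with_seed(as.integer(seed), {
    p <- list()
    cin <- in_ch
    for (i in seq_len(L)) {
      cw <- w * 2L^(i - 1L)
      p[[paste0("enc", i, "a")]] <- init_conv(3, 3, cin, cw)
      p[[paste0("enc", i, "b")]] <- init_conv(3, 3, cw, cw)
      cin <- cw
    }
    cb <- w * 2L^L
    p$bott_a <- init_conv(3, 3, cin, cb)
    p$bott_b <- init_conv(3, 3, cb, cb)
    for (i in rev(seq_len(L))) {
      cs <- w * 2L^(i - 1L)          # skip width at level i
      cu <- w * 2L^i                 # upsampled width arriving from below
      if (variant == "attention_unet") {
        fi <- max(4L, cs %/% 2L)
        p[[paste0("att", i, "_x")]] <- init_conv(1, 1, cs, fi)
        p[[paste0("att", i, "_g")]] <- init_conv(1, 1, cu, fi)
        p[[paste0("att", i, "_psi")]] <- init_conv(1, 1, fi, 1L)
      }
      p[[paste0("dec", i, "a")]] <- init_conv(3, 3, cu + cs, cs)
      p[[paste0("dec", i, "b")]] <- init_conv(3, 3, cs, cs)
    }
    p$out <- init_conv(1, 1, w, 1L)
    p
  })
  structure(list(variant = variant, in_channels = in_ch, width = w,
                 levels = L, params = params, loss_trace = numeric(0),
                 trained = FALSE),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(l) length(l$W) + length(l$b), numeric(1)))
  cat(sprintf("<unet_model %s  width %d  levels %d  %d parameters  %s>\n",
              x$variant, x$width, x$levels, np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `unet_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(l) length(l$W) + length(l$b), numeric(1)))
}

conv_block_fwd <- function(X, pa, pb) {
  h1 <- conv_fwd(X, pa$W, pa$b); a1 <- relu_fwd(h1)
  h2 <- conv_fwd(a1, pb$W, pb$b); a2 <- relu_fwd(h2)
  list(out = a2, X = X, a1 = a1)
}

conv_block_bwd <- function(cache, pa, pb, dOut) {
  dOut <- relu_bwd(dOut, cache$out)
  g2 <- conv_bwd(cache$a1, pb$W, dOut)
  dA1 <- relu_bwd(g2$dX, cache$a1)
  g1 <- conv_bwd(cache$X, pa$W, dA1)
  list(dX = g1$dX,
       grads = list(a = list(W = g1$dW, b = g1$db),
                    b = list(W = g2$dW, b = g2$db)))
}

unet_forward <- function(model, X) {
  p <- model$params; L <- model$levels
  if (dim(X)[4] != model$in_channels) {
    abort(sprintf("model expects %d input channel(s), got %d.",
                  model$in_channels, dim(X)[4]))
  }
  if (any(dim(X)[1:2] %% 2L^L != 0L)) {
    abort(sprintf("input height/width must be divisible by %d.", 2L^L))
  }
  cache <- list(enc = vector("list", L), pooled = vector("list", L),
                att = vector("list", L), dec = vector("list", L),
                up = vector("list", L), cat = vector("list", L))
  cur <- X
  for (i in seq_len(L)) {
    blk <- conv_block_fwd(cur, p[[paste0("enc", i, "a")]], p[[paste0("enc", i, "b")]])
    cache$enc[[i]] <- blk
    cache$pooled[[i]] <- maxpool_fwd(blk$out)
    cur <- cache$pooled[[i]]
  }
  blk <- conv_block_fwd(cur, p$bott_a, p$bott_b)
  cache$bott <- blk
  cur <- blk$out
  for (i in rev(seq_len(L))) {
    up <- upsample_fwd(cur)
    cache$up[[i]] <- up
    skip <- cache$enc[[i]]$out
    if (model$variant == "attention_unet") {
      ax <- conv_fwd(skip, p[[paste0("att", i, "_x")]]$W, p[[paste0("att", i, "_x")]]$b)
      ag <- conv_fwd(up, p[[paste0("att", i, "_g")]]$W, p[[paste0("att", i, "_g")]]$b)
      inter <- relu_fwd(ax + ag)
      psi <- conv_fwd(inter, p[[paste0("att", i, "_psi")]]$W, p[[paste0("att", i, "_psi")]]$b)
      a <- sigmoid(psi)
      cache$att[[i]] <- list(skip = skip, up = up, inter = inter, a = a)
      skip <- skip * c(a)
    }
    cat_in <- concat_ch(up, skip)
    cache$cat[[i]] <- cat_in
    blk <- conv_block_fwd(cat_in, p[[paste0("dec", i, "a")]], p[[paste0("dec", i, "b")]])
    cache$dec[[i]] <- blk
    cur <- blk$out
  }
  logits <- conv_fwd(cur, p$out$W, p$out$b)
  list(probs = sigmoid(logits), logits = logits, last = cur, cache = cache)
}

# Backward pass mirrors the forward graph: dec1 .. decL, bottleneck, then
# encL .. enc1 with skip gradients merged at each level.
unet_backward <- function(model, fwd, d_logits) {
  p <- model$params; L <- model$levels
  grads <- list()
  g_out <- conv_bwd(fwd$last, p$out$W, d_logits)
  grads$out <- list(W = g_out$dW, b = g_out$db)
  dCur <- g_out$dX                      # gradient at dec1 output
  dSkipStore <- vector("list", L)
  for (i in seq_len(L)) {
    bb <- conv_block_bwd(fwd$cache$dec[[i]], p[[paste0("dec", i, "a")]],
                         p[[paste0("dec", i, "b")]], dCur)
    grads[[paste0("dec", i, "a")]] <- bb$grads$a
    grads[[paste0("dec", i, "b")]] <- bb$grads$b
    dCat <- bb$dX
    cu <- dim(fwd$cache$up[[i]])[4]
    dUp <- dCat[, , , seq_len(cu), drop = FALSE]
    dSkipOut <- dCat[, , , -seq_len(cu), drop = FALSE]
    if (model$variant == "attention_unet") {
      at <- fwd$cache$att[[i]]
      dSkip <- dSkipOut * c(at$a)
      da <- array(rowSums(matrix(dSkipOut * at$skip, ncol = dim(at$skip)[4])),
                  dim(at$a))
      dPsi <- da * at$a * (1 - at$a)
      g_psi <- conv_bwd(at$inter, p[[paste0("att", i, "_psi")]]$W, dPsi)
      grads[[paste0("att", i, "_psi")]] <- list(W = g_psi$dW, b = g_psi$db)
      dInter <- relu_bwd(g_psi$dX, at$inter)
      g_ax <- conv_bwd(at$skip, p[[paste0("att", i, "_x")]]$W, dInter)
      g_ag <- conv_bwd(at$up, p[[paste0("att", i, "_g")]]$W, dInter)
      grads[[paste0("att", i, "_x")]] <- list(W = g_ax$dW, b = g_ax$db)
      grads[[paste0("att", i, "_g")]] <- list(W = g_ag$dW, b = g_ag$db)
      dSkip <- dSkip + g_ax$dX
      dUp <- dUp + g_ag$dX
    } else {
      dSkip <- dSkipOut
    }
    dSkipStore[[i]] <- dSkip
    dCur <- upsample_bwd(dUp)           # gradient at the next-deeper output
  }
  bb <- conv_block_bwd(fwd$cache$bott, p$bott_a, p$bott_b, dCur)
  grads$bott_a <- bb$grads$a
  grads$bott_b <- bb$grads$b
  dPool <- bb$dX                        # gradient at pooled[L]
  for (i in rev(seq_len(L))) {
    enc_out <- fwd$cache$enc[[i]]$out
    dEncOut <- maxpool_bwd(enc_out, fwd$cache$pooled[[i]], dPool) + dSkipStore[[i]]
    bb <- conv_block_bwd(fwd$cache$enc[[i]], p[[paste0("enc", i, "a")]],
                         p[[paste0("enc", i, "b")]], dEncOut)
    grads[[paste0("enc", i, "a")]] <- bb$grads$a
    grads[[paste0("enc", i, "b")]] <- bb$grads$b
    dPool <- bb$dX
  }
  grads
}
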