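# Organ-specific segmentation stage: mini-CT extraction with percentile HU
# clipping, augmentation, training of the U-Net variants on axial slices,
# and post-processing of predictions back into whole-body masks.

#' HU clipping range for mini-CT normalization
#'
#' Body organs use the percentile rule: `lo` is the smaller of the 10th
#' percentile inside the reference mask and within a 2 mm rim around it;
#' `hi` is the larger of the two 90th percentiles. Head structures use a
#' fixed 0-250 HU window.
#'
#' @param lo,hi HU bounds, `lo < hi`.
#' @param organ organ name.
#' @param source one of `"percentile_rule"`, `"head_fixed"`, `"config"`.
#' @return object of class `clip_range`.
#' @export
clip_range <- function(lo, hi, organ = NA_character_,
                       source = c("percentile_rule", "head_fixed", "config")) {
  source <- match.arg(source)
  if (lo >= hi) abort("clip range must satisfy lo < hi.")
  structure(list(lo = lo, hi = hi, organ = organ, source = source),
            class = "clip_range")
}

#' Fixed clipping range for small head structures
#' @param organ organ name.
#' @return a `clip_range(0, 250)` with source `"head_fixed"`.
#' @export
head_clip_range <- function(organ = NA_character_) {
  clip_range(0, 250, organ, "head_fixed")
}

shift3 <- function(arr, dz, dy, dx) {
  d <- dim(arr)
  out <- array(FALSE, d)
  src_z <- max(1, 1 - dz):min(d[1], d[1] - dz)
  src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
  src_x <- max(1, 1 - dx):min(d[3], d[3] - dx)
  out[src_z + dz, src_y + dy, src_x + dx] <- arr[src_z, src_y, src_x]
  out
}

# morphological dilation by all voxel offsets within `mm` physical distance
dilate_mm <- function(mask, spacing, mm) {
  r <- pmax(1L, as.integer(ceiling(mm / spacing)))
  offs <- as.matrix(expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3]))
  dist <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
                 (offs[, 3] * spacing[3])^2)
  offs <- offs[dist <= mm + 1e-9, , drop = FALSE]
  m <- mask != 0
  out <- m
  for (k in seq_len(nrow(offs))) {
    if (all(offs[k, ] == 0)) next
    out <- out | shift3(m, offs[k, 1], offs[k, 2], offs[k, 3])
  }
  out
}

#' Compute the percentile clipping range for a body organ
#'
#' `lo = min(P10 inside the mask, P10 in the rim)` and
#' `hi = max(P90 inside, P90 in the rim)`, where the rim is a morphological
#' dilation of the mask by `rim_mm` (converted to voxels per axis, rounding
#' up) minus the mask itself. A degenerate constant range is widened by one
#' HU on each side.
#'
#' @param vol a [ct_volume()].
#' @param mask nonempty reference mask.
#' @param rim_mm rim thickness in mm (default 2).
#' @param organ organ name recorded in the result.
#' @return a `clip_range` with source `"percentile_rule"`.
#' @export
compute_clip_range <- function(vol, mask, rim_mm = 2, organ = NA_character_) {
  if (!any(mask != 0)) abort("reference mask is empty.")
  inside <- vol$voxels[mask != 0]
  rim_mask <- dilate_mm(mask, vol$spacing, rim_mm) & !(mask != 0)
  rim <- vol$voxels[rim_mask]
  q <- function(x, p) unname(quantile(x, p, names = FALSE))
  if (length(rim)) {
    lo <- min(q(inside, 0.10), q(rim, 0.10))
    hi <- max(q(inside, 0.90), q(rim, 0.90))
  } else {
    lo <- q(inside, 0.10); hi <- q(inside, 0.90)
  }
  if (hi <= lo) { lo <- lo - 1; hi <- hi + 1 }
  clip_range(lo, hi, organ, "percentile_rule")
}

#' Aggregate per-case clipping ranges into one organ-level range
#'
#' Inference-time volumes have no reference mask, so the percentile rule
#' cannot be evaluated; the organ's range is frozen as the medians of the
#' training-case `lo` and `hi` values.
#'
#' @param per_case list of `clip_range`s from training cases.
#' @return a `clip_range` with source `"config"`.
#' @export
aggregate_clip_range <- function(per_case) {
  if (!length(per_case)) abort("need at least one training-case clip range.")
  lo <- median(vapply(per_case, function(r) r$lo, numeric(1)))
  hi <- median(vapply(per_case, function(r) r$hi, numeric(1)))
  if (hi <= lo) { lo <- lo - 1; hi <- hi + 1 }
  clip_range(lo, hi, per_case[[1]]$organ, "config")
}

#' Extract a normalized, padded mini-CT around an ROI
#'
#' Crop, clamp to the clip range, map `[lo, hi]` linearly onto `[0, 1]`,
#' then zero-pad symmetrically to the organ's uniform size. Normalization
#' precedes padding so that pad value 0 coincides with the clip minimum and
#' the network sees a constant background.
#'
#' @param vol a [ct_volume()].
#' @param roi a [roi3d()] inside the volume.
#' @param organ organ name.
#' @param uniform_size `(Z, Y, X)` target size, each `>=` the ROI size.
#' @param clip a `clip_range`.
#' @return object of class `mini_ct`: `voxels` (normalized, padded), `roi`,
#'   `organ`, `pad_before`, `crop_shape`, `clip`.
#' @export
extract_mini_ct <- function(vol, roi, organ, uniform_size, clip) {
  d <- dim(vol$voxels)
  if (roi$z[2] > d[1] || roi$y[2] > d[2] || roi$x[2] > d[3] ||
      roi$z[1] < 0 || roi$y[1] < 0 || roi$x[1] < 0) {
    abort("ROI extends outside the volume.")
  }
  us <- as.integer(uniform_size)
  cs <- roi_shape(roi)
  if (any(cs > us)) abort("ROI larger than the uniform size; clip the ROI first.")
  crop <- roi_crop(vol$voxels, roi)
  crop <- (pmin(pmax(crop, clip$lo), clip$hi) - clip$lo) / (clip$hi - clip$lo)
  pad_before <- (us - cs) %/% 2L
  out <- array(0, us)
  out[pad_before[1] + seq_len(cs[1]),
      pad_before[2] + seq_len(cs[2]),
      pad_before[3] + seq_len(cs[3])] <- crop
  structure(list(voxels = out, roi = roi, organ = organ,
                 pad_before = pad_before, crop_shape = cs, clip = clip),
            class = "mini_ct")
}

# crop a parent-shaped mask to a mini-CT's padded frame (training targets)
mask_to_mini <- function(mask, mini) {
  us <- dim(mini$voxels)
  out <- array(0L, us)
  crop <- roi_crop(mask, mini$roi)
  out[mini$pad_before[1] + seq_len(mini$crop_shape[1]),
      mini$pad_before[2] + seq_len(mini$crop_shape[2]),
      mini$pad_before[3] + seq_len(mini$crop_shape[3])] <- crop
  out
}

#' Place a mini-CT prediction back into the whole-body frame
#'
#' Strips the symmetric padding and writes the mask at its ROI in a zero
#' background of the parent shape. Predictions for different organs are
#' always written to separate outputs, never merged.
#'
#' @param mini_mask binary array in the mini-CT's padded frame.
#' @param roi the mini-CT's [roi3d()].
#' @param parent_shape `(Z, Y, X)` of the whole-body volume.
#' @param pad_before per-axis padding that was applied before the crop
#'   (from the `mini_ct`).
#' @return binary array of shape `parent_shape`.
#' @export
paste_back <- function(mini_mask, roi, parent_shape, pad_before = c(0L, 0L, 0L)) {
  d <- as.integer(parent_shape)
  if (roi$z[2] > d[1] || roi$y[2] > d[2] || roi$x[2] > d[3]) {
    abort("ROI lies outside the parent volume.")
  }
  cs <- roi_shape(roi)
  core <- mini_mask[pad_before[1] + seq_len(cs[1]),
                    pad_before[2] + seq_len(cs[2]),
                    pad_before[3] + seq_len(cs[3]), drop = FALSE]
  out <- array(0L, d)
  out[iv_seq(roi$z), iv_seq(roi$y), iv_seq(roi$x)] <- as.integer(core != 0)
  out
}

# --- augmentation ----------------------------------------------------------

# in-plane warp: rotation by `theta` degrees and isotropic scaling about the
# slice center; inverse mapping with bilinear or nearest sampling
warp2d <- function(img, theta, scale, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  ci <- (H - 1) / 2; cj <- (W - 1) / 2
  th <- theta * pi / 180
  di <- matrix(rep(seq_len(H) - 1 - ci, W), H, W)
  dj <- matrix(rep(seq_len(W) - 1 - cj, each = H), H, W)
  si <- ci + (cos(th) * di + sin(th) * dj) / scale
  sj <- cj + (-sin(th) * di + cos(th) * dj) / scale
  if (interp == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 0 & ri <= H - 1 & rj >= 0 & rj <= W - 1
    out <- matrix(fill, H, W)
    out[ok] <- img[cbind(ri[ok] + 1, rj[ok] + 1)]
    return(out)
  }
  out <- matrix(fill, H, W)
  ok <- si >= 0 & si <= H - 1 & sj >= 0 & sj <= W - 1
  i0 <- pmin(floor(si), H - 2); j0 <- pmin(floor(sj), W - 2)
  fi <- si - i0; fj <- sj - j0
  idx <- function(a, b) img[cbind(a[ok] + 1, b[ok] + 1)]
  out[ok] <- idx(i0, j0) * (1 - fi[ok]) * (1 - fj[ok]) +
    idx(i0 + 1, j0) * fi[ok] * (1 - fj[ok]) +
    idx(i0, j0 + 1) * (1 - fi[ok]) * fj[ok] +
    idx(i0 + 1, j0 + 1) * fi[ok] * fj[ok]
  out
}

#' Jointly augment an image/mask pair
#'
#' With probability `cfg$augment_prob` an in-axial-plane rotation uniform in
#' +/- `rot_limit` degrees and an isotropic scaling uniform in
#' `1 +/- scale_limit` are applied about each slice center: bilinear
#' resampling for the image, nearest-neighbor for the mask, the identical
#' transform for both. Otherwise the pair is returned unchanged. Draws come
#' from the current RNG stream; seed the stream for reproducibility.
#'
#' @param image 3D array `(Z, Y, X)`.
#' @param mask 3D binary array, same shape.
#' @param cfg a [train_config()].
#' @return list with `image` and `mask`.
#' @export
augment_pair <- function(image, mask, cfg) {
  stopifnot(identical(dim(image), dim(mask)))
  if (runif(1) >= cfg$augment_prob) return(list(image = image, mask = mask))
  theta <- runif(1, -cfg$rot_limit, cfg$rot_limit)
  sc <- runif(1, 1 - cfg$scale_limit, 1 + cfg$scale_limit)
  for (z in seq_len(dim(image)[1])) {
    image[z, , ] <- warp2d(image[z, , ], theta, sc, "bilinear")
    mask[z, , ] <- warp2d(mask[z, , ], theta, sc, "nearest")
  }
  list(image = image, mask = as_binary_array(mask))
}

#' 3-channel slice sandwiches for the 2.5D variant
#'
#' One input per axial slice with channels (superior neighbor, target
#' slice, inferior neighbor); at the volume ends the missing neighbor is
#' replaced by edge replication. The model's output is the mask of the
#' middle channel only.
#'
#' @param mini a `mini_ct` or a 3D `(Z, Y, X)` array.
#' @return array `(Y, X, Z, 3)`: slice sandwiches stacked along the third
#'   (sample) dimension.
#' @export
make_2p5d_stacks <- function(mini) {
  v <- if (inherits(mini, "mini_ct")) mini$voxels else mini
  Z <- dim(v)[1]
  sup <- pmax(1L, seq_len(Z) - 1L)
  inf <- pmin(Z, seq_len(Z) + 1L)
  out <- array(0, c(dim(v)[2], dim(v)[3], Z, 3L))
  out[, , , 1] <- aperm(v[sup, , , drop = FALSE], c(2, 3, 1))
  out[, , , 2] <- aperm(v, c(2, 3, 1))
  out[, , , 3] <- aperm(v[inf, , , drop = FALSE], c(2, 3, 1))
  out
}

# single-channel slice stack [Y, X, Z, 1]
make_2d_stacks <- function(v) {
  out <- array(0, c(dim(v)[2], dim(v)[3], dim(v)[1], 1L))
  out[, , , 1] <- aperm(v, c(2, 3, 1))
  out
}

model_inputs <- function(model, v) {
  if (model$variant == "unet_2p5d") make_2p5d_stacks(v) else make_2d_stacks(v)
}

#' Train a segmentation model on mini-CT / mask pairs
#'
#' Training is slice-wise in the axial plane (2D for the basic and
#' attention variants, 3-channel sandwiches for 2.5D) with the combined
#' soft-Dice + binary cross-entropy loss and Adam. Deterministic for a
#' fixed `cfg$seed`.
#'
#' @param model an untrained [build_model()] output.
#' @param dataset list of `list(image = , mask = )` pairs: normalized
#'   mini-CT arrays `(Z, Y, X)` and binary masks of the same shape.
#' @param cfg a [train_config()].
#' @return the trained `unet_model`, with `loss_trace` holding the mean
#'   epoch losses.
#' @export
train_segmenter <- function(model, dataset, cfg = train_config()) {
  if (!length(dataset)) abort("training dataset is empty.")
  X <- do.call(abind_n, lapply(dataset, function(d) model_inputs(model, d$image)))
  Y <- do.call(abind_n, lapply(dataset, function(d) make_2d_stacks(d$mask)))
  n <- dim(X)[3]
  with_seed(cfg$seed, {
    st <- adam_init(model$params)
    trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[start:min(n, start + cfg$batch_size - 1L)]
        Xb <- X[, , idx, , drop = FALSE]
        Yb <- Y[, , idx, , drop = FALSE]
        for (k in seq_along(idx)) {
          if (runif(1) < cfg$augment_prob) {
            theta <- runif(1, -cfg$rot_limit, cfg$rot_limit)
            sc <- runif(1, 1 - cfg$scale_limit, 1 + cfg$scale_limit)
            for (ch in seq_len(dim(Xb)[4])) {
              Xb[, , k, ch] <- warp2d(Xb[, , k, ch], theta, sc, "bilinear")
            }
            Yb[, , k, 1] <- warp2d(Yb[, , k, 1], theta, sc, "nearest")
          }
        }
        fwd <- unet_forward(model, Xb)
        ls <- seg_loss(fwd$probs, Yb)
        grads <- unet_backward(model, fwd, ls$d_logits)
        upd <- adam_step(model$params, grads, st, lr = cfg$lr)
        model$params <- upd$params
        st <- upd$state
        losses <- c(losses, ls$loss)
      }
      trace[ep] <- mean(losses)
    }
    model$loss_trace <- c(model$loss_trace, trace)
  })
  model$trained <- TRUE
  model
}

# concatenate [H,W,N,C] arrays along the sample dimension
abind_n <- function(...) {
  parts <- list(...)
  d1 <- dim(parts[[1]])
  ns <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(ns), d1[4]))
  at <- 0L
  for (p in parts) {
    out[, , at + seq_len(dim(p)[3]), ] <- p
    at <- at + dim(p)[3]
  }
  out
}

#' Predict a binary mask for a mini-CT
#'
#' Slice-wise sigmoid probability maps, binarized at the threshold (voxels
#' with probability strictly above it are foreground) and stacked back to
#' 3D.
#'
#' @param model a trained `unet_model`.
#' @param mini a `mini_ct` (or normalized 3D array).
#' @param threshold probability threshold, default 0.5.
#' @return binary array in the mini-CT frame `(Z, Y, X)`.
#' @export
predict_mask <- function(model, mini, threshold = 0.5) {
  v <- if (inherits(mini, "mini_ct")) mini$voxels else mini
  X <- model_inputs(model, v)
  probs <- unet_forward(model, X)$probs
  mask <- aperm(array(probs[, , , 1] > threshold, dim(probs)[1:3]), c(3, 1, 2))
  array(as.integer(mask), dim(v))
}

#' @export
tidy.unet_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @export
glance.unet_model <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, width = x$width, levels = x$levels,
    parameters = n_parameters(x),
    epochs = length(x$loss_trace),
    final_loss = if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)] else NA_real_
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
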