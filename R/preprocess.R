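# Shared preprocessing: body masking, canvas centering, label exclusivity
# and nearest-neighbor resampling. Applied identically before either
# localization or segmentation.

#' Derive a body support mask from HU values
#'
#' A stand-in for a clinical body contour: voxels above `threshold` HU,
#' reduced to the largest 26-connected component, with holes (lungs, bowel
#' gas, trachea) filled slice-by-slice in the axial plane.
#'
#' @param vol a [ct_volume()].
#' @param threshold HU threshold separating body from air; default -300.
#' @return object of class `body_mask`: list with `mask` (binary array) and
#'   `source = "derived"`.
#' @export
derive_body_mask <- function(vol, threshold = -300) {
  raw <- vol$voxels > threshold
  if (!any(raw)) abort("no body found above the HU threshold.")
  m <- largest_component(raw, connectivity = 26)
  for (z in seq_len(dim(m)[1])) {
    m[z, , ] <- as.integer(EBImage::fillHull(m[z, , ]))
  }
  structure(list(mask = m, source = "derived"), class = "body_mask")
}

#' Wrap an externally provided body mask
#'
#' @param mask 3D binary array.
#' @return a `body_mask` with `source = "provided"`.
#' @export
body_mask <- function(mask) {
  if (!any(mask != 0)) abort("body mask must be nonempty.")
  structure(list(mask = as_binary_array(mask), source = "provided"),
            class = "body_mask")
}

#' Set voxels outside the body to -1000 HU
#'
#' @param vol a [ct_volume()].
#' @param body a `body_mask` (from [derive_body_mask()] or [body_mask()]).
#' @return the masked [ct_volume()].
#' @export
mask_outside_body <- function(vol, body) {
  m <- if (inherits(body, "body_mask")) body$mask else body
  if (!identical(dim(m), dim(vol$voxels))) abort("body mask shape mismatch.")
  v <- vol$voxels
  v[m == 0] <- -1000
  ct_volume(v, vol$spacing, vol$id)
}

#' Center the patient on a fixed axial canvas
#'
#' Axial slices are placed on a `W_x` by `H_y` canvas (default 512 x 256,
#' lateral by anterior-posterior) such that the body-mask centroid maps to
#' the canvas center (both rounded down). The volume is padded with
#' -1000 HU, masks with 0; labels undergo the identical integer shift.
#'
#' @param vol a [ct_volume()].
#' @param labels optional [label_set()] transformed identically.
#' @param canvas integer `(W_x, H_y)` canvas size in pixels.
#' @param body optional `body_mask`; derived from `vol` when missing.
#' @return list with `volume` and (if supplied) `labels`.
#' @export
center_on_canvas <- function(vol, labels = NULL, canvas = c(512L, 256L),
                             body = NULL) {
  d <- dim(vol$voxels)
  W <- as.integer(canvas[1]); H <- as.integer(canvas[2])
  if (is.null(body)) body <- derive_body_mask(vol)
  bm <- body$mask
  idx <- which(bm != 0, arr.ind = TRUE)
  bb_y <- range(idx[, 2]) - 1L; bb_x <- range(idx[, 3]) - 1L
  if (diff(bb_y) + 1L > H || diff(bb_x) + 1L > W) {
    abort("body larger than the canvas; resample to coarser spacing first.")
  }
  cx <- floor(mean(idx[, 3]) - 1)
  cy <- floor(mean(idx[, 2]) - 1)
  shift_x <- W %/% 2L - cx
  shift_y <- H %/% 2L - cy
  if (bb_x[1] + shift_x < 0L || bb_x[2] + shift_x >= W ||
      bb_y[1] + shift_y < 0L || bb_y[2] + shift_y >= H) {
    abort("body does not fit the canvas at the centered position; resample first.")
  }
  place <- function(arr, fill) {
    out <- array(fill, c(d[1], H, W))
    src_y <- max(0L, -shift_y):(min(d[2], H - shift_y) - 1L)
    src_x <- max(0L, -shift_x):(min(d[3], W - shift_x) - 1L)
    out[, src_y + shift_y + 1L, src_x + shift_x + 1L] <-
      arr[, src_y + 1L, src_x + 1L, drop = FALSE]
    out
  }
  out_vol <- ct_volume(place(vol$voxels, -1000), vol$spacing, vol$id)
  res <- list(volume = out_vol,
              shift = c(y = shift_y, x = shift_x),
              body = body_mask(place(bm, 0L)))
  if (!is.null(labels)) {
    res$labels <- label_set(lapply(labels$masks, place, fill = 0L))
  }
  res
}

#' Resample a volume (and masks) to a target spacing, nearest neighbor
#'
#' Both image and masks use nearest-neighbor interpolation so that masks
#' stay strictly binary. Output shape is `round(shape * spacing /
#' target_spacing)` per axis.
#'
#' @param vol a [ct_volume()].
#' @param labels optional [label_set()].
#' @param target_spacing numeric `(dz, dy, dx)` mm.
#' @return list with `volume` and (if supplied) `labels`.
#' @export
resample_nearest <- function(vol, labels = NULL, target_spacing) {
  tsp <- as.numeric(target_spacing)
  if (length(tsp) != 3L || any(tsp <= 0)) abort("target spacing must be positive.")
  d <- dim(vol$voxels)
  out_d <- as.integer(round(d * vol$spacing / tsp))
  if (any(out_d < 1L)) abort("degenerate output shape at this target spacing.")
  maps <- lapply(1:3, function(a) {
    pmin(d[a] - 1L, as.integer(floor((seq_len(out_d[a]) - 0.5) * d[a] / out_d[a]))) + 1L
  })
  res <- list(volume = ct_volume(vol$voxels[maps[[1]], maps[[2]], maps[[3]], drop = FALSE],
                                 tsp, vol$id))
  if (!is.null(labels)) {
    res$labels <- label_set(lapply(labels$masks, function(m) {
      m[maps[[1]], maps[[2]], maps[[3]], drop = FALSE]
    }))
  }
  res
}

#' Make overlapping labels mutually exclusive
#'
#' For each ordered pair `(small, large)` the small structure is cropped out
#' of the larger one it overlaps with (`large := large AND NOT small`); the
#' small structure is left untouched. Applying the same pairs twice is a
#' no-op.
#'
#' @param labels a [label_set()].
#' @param containment list of character pairs `c(small, large)`.
#' @return the exclusive [label_set()].
#' @export
make_labels_exclusive <- function(labels, containment) {
  masks <- labels$masks
  for (pair in containment) {
    small <- pair[1]; large <- pair[2]
    for (nm in c(small, large)) {
      if (!nm %in% names(masks)) abort(sprintf("unknown organ name '%s'.", nm))
    }
    masks[[large]] <- array(as.integer(masks[[large]] & !masks[[small]]),
                            dim(masks[[large]]))
  }
  label_set(masks)
}

#' Default containment pairs for the phantom organ set
#'
#' Smaller structures that sit inside larger ones and must be cropped out of
#' them: lenses from eyes, the spinal canal from the vertebral column, and
#' brainstem/chiasm/optic nerves from the brain.
#'
#' @return list of `c(small, large)` character pairs.
#' @export
default_containment <- function() {
  list(
    c("lens_l", "eye_l"),
    c("lens_r", "eye_r"),
    c("spinal_canal", "vertebral_column"),
    c("brainstem", "brain"),
    c("chiasm", "brain"),
    c("optic_nerve_l", "brain"),
    c("optic_nerve_r", "brain")
  )
}
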