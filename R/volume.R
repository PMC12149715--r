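#' @importFrom rlang %||% abort warn
#' @importFrom stats median quantile rnorm runif sd setNames
NULL

#' CT volume container
#'
#' A `ct_volume` holds a 3D grid of Hounsfield-unit (HU) values in the
#' package-wide canonical axis order `(z, y, x)`:
#' * `z` — superior to inferior (index increasing toward the feet),
#' * `y` — anterior to posterior,
#' * `x` — patient-left to patient-right as stored.
#'
#' All downstream operations (projection, localization, cropping) assume this
#' order; on-disk orientations are converted once at load time by
#' [load_volume()].
#'
#' @param voxels 3D numeric array of HU values, dimension `(Z, Y, X)`.
#' @param spacing numeric length-3, voxel spacing `(dz, dy, dx)` in mm.
#' @param id patient identifier string.
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `id`.
#' @export
ct_volume <- function(voxels, spacing, id = "anon") {
  if (length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array in (z, y, x) order.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive values (dz, dy, dx).")
  }
  if (any(!is.finite(voxels))) {
    abort("HU values must be finite.")
  }
  structure(
    list(voxels = voxels, spacing = spacing, id = as.character(id)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume '%s'  %d x %d x %d (z,y,x)  spacing %.2f x %.2f x %.2f mm  HU [%d, %d]>\n",
    x$id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    round(min(x$voxels)), round(max(x$voxels))
  ))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Named set of binary organ masks
#'
#' A `label_set` maps organ names to binary (0/1) arrays congruent with the
#' parent [ct_volume()].
#'
#' @param masks named list of 3D arrays with values in `{0, 1}`.
#' @param shape expected dimension, usually `dim(vol)`; checked against every
#'   mask.
#' @return An object of class `label_set`.
#' @export
label_set <- function(masks, shape = NULL) {
  if (length(masks) && is.null(names(masks))) {
    abort("`masks` must be a named list (organ name -> binary array).")
  }
  masks <- lapply(masks, function(m) {
    m <- as_binary_array(m)
    if (!is.null(shape) && !identical(dim(m), as.integer(shape))) {
      abort("every mask must have the same shape as the parent volume.")
    }
    m
  })
  structure(list(masks = masks), class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  counts <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<label_set  %d organs>\n", length(x$masks)))
  for (nm in names(x$masks)) cat(sprintf("  %-18s %d voxels\n", nm, counts[[nm]]))
  invisible(x)
}

#' @export
names.label_set <- function(x) names(x$masks)

# Coerce to an integer {0,1} array, validating binarity.
as_binary_array <- function(m) {
  if (is.logical(m)) {
    storage.mode(m) <- "integer"
  }
  u <- unique(as.vector(m))
  if (!all(u %in% c(0L, 1L, 0, 1))) abort("mask values must be in {0, 1}.")
  a <- array(as.integer(m), dim = dim(m))
  a
}

#' Extract one organ's mask from a label set
#'
#' @param labels a [label_set()].
#' @param organ organ name; unknown names are an error.
#' @return the binary 3D mask array.
#' @export
mask_of <- function(labels, organ) {
  if (!organ %in% names(labels$masks)) {
    abort(sprintf("unknown organ name '%s'.", organ))
  }
  labels$masks[[organ]]
}

# --- half-open integer intervals ------------------------------------------

# Intervals are 0-based, half-open [lo, hi): the localization currency.
iv <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (hi <= lo) abort("interval must be nonempty (hi > lo).")
  c(lo, hi)
}

iv_len <- function(r) r[2] - r[1]

# 1-based R index sequence for a 0-based half-open interval.
iv_seq <- function(r) (r[1] + 1L):r[2]

iv_clamp <- function(r, n) {
  lo <- max(0L, r[1]); hi <- min(as.integer(n), r[2])
  if (hi <= lo) abort("interval empty after clamping to bounds.")
  c(lo, hi)
}

# --- 3D ROI ---------------------------------------------------------------

#' Axis-aligned 3D region of interest
#'
#' Half-open, 0-based voxel intervals along each canonical axis.
#'
#' @param z_range,y_range,x_range length-2 integer vectors `c(lo, hi)`,
#'   half-open and 0-based.
#' @return An object of class `roi3d`.
#' @export
roi3d <- function(z_range, y_range, x_range) {
  structure(
    list(z = iv(z_range[1], z_range[2]),
         y = iv(y_range[1], y_range[2]),
         x = iv(x_range[1], x_range[2])),
    class = "roi3d"
  )
}

#' @export
print.roi3d <- function(x, ...) {
  cat(sprintf("<roi3d  z [%d,%d)  y [%d,%d)  x [%d,%d)>\n",
              x$z[1], x$z[2], x$y[1], x$y[2], x$x[1], x$x[2]))
  invisible(x)
}

roi_shape <- function(roi) c(iv_len(roi$z), iv_len(roi$y), iv_len(roi$x))

roi_crop <- function(arr, roi) {
  arr[iv_seq(roi$z), iv_seq(roi$y), iv_seq(roi$x), drop = FALSE]
}

# Tight 0-based half-open bounding intervals of a nonempty binary array.
mask_bbox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("mask is empty.")
  list(
    z = c(min(idx[, 1]) - 1L, max(idx[, 1])),
    y = c(min(idx[, 2]) - 1L, max(idx[, 2])),
    x = c(min(idx[, 3]) - 1L, max(idx[, 3]))
  )
}

# run `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
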