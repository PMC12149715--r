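# Digitally reconstructed radiographs: HU-clipped parallel projections of a
# CT volume along a canonical axis, min-max normalized to 0-255.

#' Contrast window
#'
#' HU clamping ranges that enhance one tissue class before projection:
#' lung `[-1500, 0]`, soft tissue `[0, 50]`, bone `[250, 3000]`. The
#' `composite` window has no range of its own; it denotes the 3-channel
#' concatenation of the three scalar windows.
#'
#' @param name one of `"lung"`, `"soft_tissue"`, `"bone"`, `"composite"`.
#' @param lo,hi optional HU bounds overriding the defaults for scalar
#'   windows.
#' @return object of class `contrast_window`.
#' @export
contrast_window <- function(name = c("lung", "soft_tissue", "bone", "composite"),
                            lo = NULL, hi = NULL) {
  name <- match.arg(name)
  defaults <- list(lung = c(-1500, 0), soft_tissue = c(0, 50), bone = c(250, 3000))
  if (name == "composite") {
    if (!is.null(lo) || !is.null(hi)) abort("the composite window has no lo/hi of its own.")
    return(structure(list(name = name, lo = NA_real_, hi = NA_real_),
                     class = "contrast_window"))
  }
  rng <- defaults[[name]]
  lo <- lo %||% rng[1]; hi <- hi %||% rng[2]
  if (lo >= hi) abort("window must satisfy lo < hi.")
  structure(list(name = name, lo = lo, hi = hi), class = "contrast_window")
}

#' Clip a volume to a contrast window
#'
#' @param vol a [ct_volume()].
#' @param w a scalar [contrast_window()] (not `composite`).
#' @return the clipped [ct_volume()].
#' @export
clip_to_window <- function(vol, w) {
  stopifnot(inherits(w, "contrast_window"))
  if (w$name == "composite") {
    abort("cannot clip to the composite window; clip to its three scalar windows.")
  }
  ct_volume(pmin(pmax(vol$voxels, w$lo), w$hi), vol$spacing, vol$id)
}

drr_image <- function(pixels, plane, summed_range, window, origin = 0L) {
  structure(
    list(pixels = pixels, plane = plane,
         summed_range = c(as.integer(summed_range[1]), as.integer(summed_range[2])),
         window = window, origin = as.integer(origin)),
    class = "drr_image"
  )
}

#' @export
print.drr_image <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3) d[3] else 1L
  cat(sprintf("<drr_image  %s  %d x %d  %d channel(s)  window %s  summed [%d,%d)>\n",
              x$plane, d[1], d[2], ch, x$window$name,
              x$summed_range[1], x$summed_range[2]))
  invisible(x)
}

drr_nchannel <- function(d) if (length(dim(d$pixels)) == 3L) dim(d$pixels)[3] else 1L

# Axis summed over for each projection plane under the (z, y, x) convention.
plane_axis <- function(plane) {
  switch(plane, coronal = 2L, sagittal = 3L, axial = 1L,
         abort(sprintf("unknown plane '%s'.", plane)))
}

#' Project a volume into a DRR
#'
#' Clips the volume to the window, sums along the projection axis restricted
#' to `summed_range`, then maps the result affinely so min -> 0 and
#' max -> 255 with round-half-to-even. An all-constant projection maps to an
#' all-zero image, so empty crops remain representable.
#'
#' Under the canonical axis order, `coronal` sums over y (rows z, cols x),
#' `sagittal` sums over x (rows z, cols y), and `axial` sums over z
#' (rows y, cols x).
#'
#' @param vol a [ct_volume()].
#' @param plane `"coronal"`, `"sagittal"` or `"axial"`.
#' @param summed_range half-open 0-based interval along the projection axis;
#'   defaults to the full extent.
#' @param w a scalar [contrast_window()].
#' @param origin 0-based offset of the DRR's row axis within the parent
#'   volume (nonzero for projections of z-cropped subvolumes).
#' @return a [drr_image()] with integer pixels in `[0, 255]`.
#' @export
project <- function(vol, plane, summed_range = NULL, w = contrast_window("soft_tissue"),
                    origin = 0L) {
  ax <- plane_axis(plane)
  d <- dim(vol$voxels)
  summed_range <- summed_range %||% c(0L, d[ax])
  if (summed_range[2] <= summed_range[1]) abort("summed_range is empty.")
  summed_range <- iv_clamp(iv(summed_range[1], summed_range[2]), d[ax])
  clipped <- clip_to_window(vol, w)$voxels
  sel <- iv_seq(summed_range)
  d <- dim(clipped)
  # sum along the projection axis via colSums on a reshaped view (the
  # summed axis moved first); much faster than apply() on large volumes
  raw <- switch(plane,
    coronal = {
      m <- aperm(clipped[, sel, , drop = FALSE], c(2, 1, 3))
      matrix(colSums(matrix(m, nrow = length(sel))), d[1], d[3])
    },
    sagittal = {
      m <- aperm(clipped[, , sel, drop = FALSE], c(3, 1, 2))
      matrix(colSums(matrix(m, nrow = length(sel))), d[1], d[2])
    },
    axial = {
      m <- clipped[sel, , , drop = FALSE]
      matrix(colSums(matrix(m, nrow = length(sel))), d[2], d[3])
    }
  )
  rng <- range(raw)
  pix <- if (rng[2] > rng[1]) {
    round((raw - rng[1]) / (rng[2] - rng[1]) * 255)
  } else {
    array(0, dim(raw))
  }
  storage.mode(pix) <- "integer"
  drr_image(pix, plane, summed_range, w, origin = origin)
}

#' Compose lung/soft-tissue/bone DRRs into one 3-channel image
#'
#' Channel order is (lung, soft_tissue, bone); the result carries the
#' `composite` window.
#'
#' @param lung,soft,bone single-channel [drr_image()]s with identical shape,
#'   plane and summed range.
#' @return 3-channel [drr_image()].
#' @export
compose_channels <- function(lung, soft, bone) {
  imgs <- list(lung, soft, bone)
  for (im in imgs) {
    if (drr_nchannel(im) != 1L) abort("compose_channels expects single-channel inputs.")
  }
  same <- function(f) length(unique(vapply(imgs, function(i) paste(f(i), collapse = ","), ""))) == 1L
  if (!same(function(i) dim(i$pixels)) || !same(function(i) i$plane) ||
      !same(function(i) i$summed_range) || !same(function(i) i$origin)) {
    abort("inputs differ in shape, plane or summed range.")
  }
  px <- array(0L, c(dim(lung$pixels), 3L))
  px[, , 1] <- lung$pixels; px[, , 2] <- soft$pixels; px[, , 3] <- bone$pixels
  drr_image(px, lung$plane, lung$summed_range, contrast_window("composite"),
            origin = lung$origin)
}

#' Replicate a single-channel DRR into 3 identical channels
#'
#' Detectors consume 3-channel inputs; a scalar-window DRR is duplicated
#' across channels.
#'
#' @param d a single-channel [drr_image()].
#' @return 3-channel [drr_image()].
#' @export
replicate_channels <- function(d) {
  if (drr_nchannel(d) != 1L) abort("input already has 3 channels.")
  px <- array(d$pixels, c(dim(d$pixels), 3L))
  drr_image(px, d$plane, d$summed_range, d$window, origin = d$origin)
}

# 3-channel DRR of `vol` in the organ's optimal window: composite windows
# are built from the three scalar projections, scalar windows are
# channel-replicated.
project_multichannel <- function(vol, plane, summed_range = NULL, window_name,
                                 origin = 0L) {
  if (window_name == "composite") {
    parts <- lapply(c("lung", "soft_tissue", "bone"), function(nm) {
      project(vol, plane, summed_range, contrast_window(nm), origin = origin)
    })
    compose_channels(parts[[1]], parts[[2]], parts[[3]])
  } else {
    replicate_channels(project(vol, plane, summed_range, contrast_window(window_name),
                               origin = origin))
  }
}

#' Plot a DRR
#'
#' @param object a [drr_image()].
#' @param ... ignored.
#' @return a ggplot object (raster heat map; multi-channel images show the
#'   mean across channels).
#' @method autoplot drr_image
#' @export
autoplot.drr_image <- function(object, ...) {
  px <- object$pixels
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  df <- tidyr::expand_grid(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$value <- as.vector(t(px))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "pixel",
                  title = sprintf("%s DRR (%s window)", object$plane, object$window$name)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Write a DRR to a PNG file for visual inspection
#'
#' @param d a [drr_image()].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_drr_png <- function(d, path) {
  png::writePNG(d$pixels / 255, path)
  invisible(path)
}
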