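# Organ localization: orthogonal 2D bounding boxes on DRRs are fused into
# 3D ROIs. Body structures use a coronal -> restricted-sagittal two-step;
# small head structures use a sagittal -> axial two-step on bone-window DRRs
# of the head region, with reference boxes scaled by two for context.

#' 2D bounding box on a DRR
#'
#' Half-open, 0-based pixel intervals; `u` indexes the DRR's row axis and
#' `v` its column axis.
#'
#' @param plane the DRR plane the box lives on.
#' @param u_range,v_range half-open `c(lo, hi)` pixel intervals.
#' @param confidence detection confidence in `[0, 1]`.
#' @return object of class `box2d`.
#' @export
box2d <- function(plane, u_range, v_range, confidence = 1) {
  structure(
    list(plane = plane, u = iv(u_range[1], u_range[2]),
         v = iv(v_range[1], v_range[2]), confidence = confidence),
    class = "box2d"
  )
}

#' @export
print.box2d <- function(x, ...) {
  cat(sprintf("<box2d %s  u [%d,%d)  v [%d,%d)  conf %.2f>\n",
              x$plane, x$u[1], x$u[2], x$v[1], x$v[2], x$confidence))
  invisible(x)
}

#' Per-organ localization and cropping configuration
#'
#' Axial margins follow the body-structure inference rule: +20 pixels for
#' the lungs, +15 for the spinal canal target, vertebral bodies, kidneys and
#' esophagus, +10 for brain and brainstem; small head structures use
#' reference boxes scaled by two instead of margins.
#'
#' @param name organ name.
#' @param group `"body"` or `"head"` (which localization procedure to use).
#' @param window optimal contrast window name for detection.
#' @param axial_margin pixels added around the ROI in the axial plane.
#' @param max_crop_size optional `(Z, Y, X)` cap on the ROI size.
#' @param laterality `"left"`, `"right"` or `"none"`; selects the half
#'   sagittal DRR for head structures.
#' @param box_scale reference-box scale factor (1 body, 2 head).
#' @return object of class `organ_spec`.
#' @export
organ_spec <- function(name, group = c("body", "head"), window = "composite",
                       axial_margin = 0L, max_crop_size = NULL,
                       laterality = c("none", "left", "right"),
                       box_scale = if (match.arg(group) == "head") 2 else 1) {
  group <- match.arg(group); laterality <- match.arg(laterality)
  if (axial_margin < 0) abort("axial_margin must be >= 0.")
  if (!is.null(max_crop_size) && any(max_crop_size < 1)) {
    abort("max_crop_size must be positive.")
  }
  structure(
    list(name = name, group = group, window = window,
         axial_margin = as.integer(axial_margin),
         max_crop_size = if (is.null(max_crop_size)) NULL else as.integer(max_crop_size),
         laterality = laterality, box_scale = box_scale),
    class = "organ_spec"
  )
}

#' Default organ specifications for the phantom organ set
#'
#' @return named list of [organ_spec()]s.
#' @export
default_organ_specs <- function() {
  sp <- list(
    lung_l = organ_spec("lung_l", "body", "lung", 20, laterality = "left"),
    lung_r = organ_spec("lung_r", "body", "lung", 20, laterality = "right"),
    vertebral_column = organ_spec("vertebral_column", "body", "bone", 15),
    spinal_canal = organ_spec("spinal_canal", "body", "bone", 15),
    esophagus = organ_spec("esophagus", "body", "composite", 15),
    kidney_l = organ_spec("kidney_l", "body", "composite", 15, laterality = "left"),
    kidney_r = organ_spec("kidney_r", "body", "composite", 15, laterality = "right"),
    brain = organ_spec("brain", "body", "composite", 10),
    brainstem = organ_spec("brainstem", "body", "composite", 10)
  )
  head_organs <- list(
    eye_l = "left", eye_r = "right", lens_l = "left", lens_r = "right",
    cochlea_l = "left", cochlea_r = "right",
    optic_nerve_l = "left", optic_nerve_r = "right", chiasm = "none"
  )
  for (nm in names(head_organs)) {
    sp[[nm]] <- organ_spec(nm, "head", "bone", 0, laterality = head_organs[[nm]])
  }
  sp
}

# Project a 3D mask onto a plane; rows/cols follow the DRR convention.
mask_projection <- function(mask, plane) {
  d <- dim(mask)
  switch(plane,
    coronal = {
      m <- aperm(mask != 0, c(2, 1, 3))
      matrix(as.integer(colSums(matrix(m, nrow = d[2])) > 0), d[1], d[3])
    },
    sagittal = {
      m <- aperm(mask != 0, c(3, 1, 2))
      matrix(as.integer(colSums(matrix(m, nrow = d[3])) > 0), d[1], d[2])
    },
    axial = {
      matrix(as.integer(colSums(matrix(mask != 0, nrow = d[1])) > 0), d[2], d[3])
    },
    abort(sprintf("unknown plane '%s'.", plane))
  )
}

#' Reference bounding box of a mask's planar projection
#'
#' The tight box of the projected mask, then center-preserving scaling of
#' height and width by `scale` (2 for head structures), clamped to the image
#' bounds.
#'
#' @param mask 3D binary array.
#' @param plane projection plane.
#' @param scale box scale factor (>= 1).
#' @return a [box2d()] with confidence 1.
#' @export
reference_box_from_mask <- function(mask, plane, scale = 1) {
  if (!any(mask != 0)) abort("mask is empty.")
  proj <- mask_projection(mask, plane)
  rows <- which(rowSums(proj) > 0); cols <- which(colSums(proj) > 0)
  scale_iv <- function(lo, hi, n) {
    ctr <- (lo + hi) / 2; half <- (hi - lo) / 2 * scale
    iv_clamp(iv(floor(ctr - half), ceiling(ctr + half)), n)
  }
  box2d(plane,
        scale_iv(min(rows) - 1L, max(rows), nrow(proj)),
        scale_iv(min(cols) - 1L, max(cols), ncol(proj)),
        confidence = 1)
}

#' Sagittal DRR restricted to a lateral extent
#'
#' Sums only the sagittal slices within `x_range` (the lateral extent of the
#' coronal detection), suppressing irrelevant lateral information.
#'
#' @param vol a [ct_volume()].
#' @param x_range half-open 0-based lateral interval.
#' @param w a scalar [contrast_window()].
#' @return a sagittal [drr_image()].
#' @export
restricted_sagittal_drr <- function(vol, x_range, w) {
  project(vol, "sagittal", summed_range = x_range, w = w)
}

#' Fuse orthogonal body boxes into a 3D ROI
#'
#' Lateral (x) extent from the coronal box columns; anterior-posterior (y)
#' from the sagittal box columns; superior-inferior (z) from the sagittal
#' box rows. Pure coordinate bookkeeping, exactly invertible.
#'
#' @param coronal a coronal [box2d()] (rows z, cols x).
#' @param sagittal a sagittal [box2d()] (rows z, cols y).
#' @param coronal_origin,sagittal_origin 0-based z offsets of the DRRs' row
#'   axes within the parent volume (nonzero for z-cropped DRRs).
#' @return a [roi3d()].
#' @export
fuse_body_boxes <- function(coronal, sagittal, coronal_origin = 0L,
                            sagittal_origin = 0L) {
  if (coronal$plane != "coronal" || sagittal$plane != "sagittal") {
    abort("fuse_body_boxes expects a coronal and a sagittal box, in that order.")
  }
  roi3d(z_range = sagittal$u + sagittal_origin,
        y_range = sagittal$v,
        x_range = coronal$v)
}

#' Grow an ROI in the axial plane
#'
#' Adds `margin` pixels on every side of the y and x ranges (clamped to the
#' volume bounds); the superior-inferior extent is untouched.
#'
#' @param roi a [roi3d()].
#' @param margin pixels (>= 0).
#' @param bounds volume shape `(Z, Y, X)`.
#' @return the expanded [roi3d()].
#' @export
expand_axial <- function(roi, margin, bounds) {
  if (margin < 0) abort("margin must be >= 0.")
  m <- as.integer(margin)
  roi3d(roi$z,
        iv_clamp(c(roi$y[1] - m, roi$y[2] + m), bounds[2]),
        iv_clamp(c(roi$x[1] - m, roi$x[2] + m), bounds[3]))
}

# Shrink an ROI symmetrically about its center so no axis exceeds
# `max_size`; keeps the ROI inside `bounds`.
clip_roi_to_max <- function(roi, max_size, bounds) {
  if (is.null(max_size)) return(roi)
  shrink <- function(r, mx, n) {
    mx <- as.integer(mx)
    if (iv_len(r) <= mx) return(r)
    ctr <- (r[1] + r[2]) / 2
    lo <- as.integer(round(ctr - mx / 2))
    lo <- max(0L, min(lo, as.integer(n) - mx))
    c(lo, lo + mx)
  }
  roi3d(shrink(roi$z, max_size[1], bounds[1]),
        shrink(roi$y, max_size[2], bounds[2]),
        shrink(roi$x, max_size[3], bounds[3]))
}

# --- detector contract -----------------------------------------------------

#' Predict a single bounding box on a DRR
#'
#' The detector contract: returns the highest-confidence [box2d()] or `NULL`
#' when the structure is not found.
#'
#' @param detector a detector object ([oracle_detector()] or
#'   [train_detector()] output).
#' @param drr a [drr_image()].
#' @return a [box2d()] or `NULL`.
#' @export
predict_box <- function(detector, drr) UseMethod("predict_box")

#' Ground-truth-backed detector
#'
#' Predicts the reference box of the organ's mask with confidence 1; used to
#' exercise the localization geometry independently of any trained model.
#'
#' @param labels a [label_set()] holding the reference masks.
#' @param organ organ name; if absent or empty the detector reports "not
#'   found".
#' @param plane DRR plane the detector answers for.
#' @param scale reference-box scale factor.
#' @return a detector honoring the [predict_box()] contract.
#' @export
oracle_detector <- function(labels, organ, plane, scale = 1) {
  structure(list(labels = labels, organ = organ, plane = plane, scale = scale),
            class = c("oracle_detector", "oar_detector"))
}

#' @export
predict_box.oracle_detector <- function(detector, drr) {
  if (!detector$organ %in% names(detector$labels$masks)) return(NULL)
  m <- detector$labels$masks[[detector$organ]]
  if (!any(m != 0)) return(NULL)
  if (drr$plane != detector$plane) {
    abort(sprintf("oracle detector for plane '%s' got a '%s' DRR.",
                  detector$plane, drr$plane))
  }
  box <- reference_box_from_mask(m, detector$plane, detector$scale)
  nr <- nrow(drr$pixels); nc <- ncol(drr$pixels)
  u <- c(box$u[1] - drr$origin, box$u[2] - drr$origin)
  u[1] <- max(0L, u[1]); u[2] <- min(nr, u[2])
  if (u[2] <= u[1]) return(NULL)
  v <- c(max(0L, box$v[1]), min(nc, box$v[2]))
  if (v[2] <= v[1]) return(NULL)
  box2d(detector$plane, u, v, confidence = 1)
}

localization_result <- function(organ, status, roi = NULL, confidence = NA_real_) {
  structure(list(organ = organ, status = status, roi = roi,
                 confidence = confidence),
            class = "localization_result")
}

#' Localize a body organ via the coronal -> sagittal two-step
#'
#' The coronal detector runs on the organ's optimal-window coronal DRR; a
#' sagittal DRR restricted to the detected lateral extent is then built and
#' passed to the sagittal detector. The two boxes are fused into a 3D ROI,
#' the axial margin is added, and the ROI is clipped to the organ's maximum
#' crop size by symmetric shrinking.
#'
#' @param vol a preprocessed [ct_volume()].
#' @param spec the organ's [organ_spec()].
#' @param det_coronal,det_sagittal detectors honoring [predict_box()].
#' @return a `localization_result` with `status` `"ok"` or `"not_found"`.
#' @export
localize_body_organ <- function(vol, spec, det_coronal, det_sagittal) {
  drr_c <- project_multichannel(vol, "coronal", NULL, spec$window)
  b_c <- predict_box(det_coronal, drr_c)
  if (is.null(b_c)) return(localization_result(spec$name, "not_found"))
  drr_s <- project_multichannel(vol, "sagittal", b_c$v, spec$window)
  b_s <- predict_box(det_sagittal, drr_s)
  if (is.null(b_s)) return(localization_result(spec$name, "not_found"))
  roi <- fuse_body_boxes(b_c, b_s)
  roi <- expand_axial(roi, spec$axial_margin, dim(vol$voxels))
  roi <- clip_roi_to_max(roi, spec$max_crop_size, dim(vol$voxels))
  localization_result(spec$name, "ok", roi,
                      confidence = min(b_c$confidence, b_s$confidence))
}

#' Superior-inferior extent of the head region
#'
#' The head area runs from the volume top to the inferior border of the
#' brainstem, supplied either as a reference mask (training) or as a
#' localized ROI (inference).
#'
#' @param vol a [ct_volume()].
#' @param brainstem 3D binary mask or a [roi3d()] from brainstem
#'   localization.
#' @return half-open z interval `c(0, z_inferior)`.
#' @export
head_region <- function(vol, brainstem) {
  if (inherits(brainstem, "roi3d")) {
    z_hi <- brainstem$z[2]
  } else if (is.array(brainstem)) {
    if (!any(brainstem != 0)) abort("brainstem mask is empty.")
    z_hi <- max(which(apply(brainstem != 0, 1, any)))
  } else {
    abort("brainstem must be a mask array or an roi3d.")
  }
  iv(0, min(z_hi, dim(vol$voxels)[1]))
}

#' Left/right half sagittal DRRs of the head
#'
#' Two bone-window sagittal DRRs of the head region: one summing the
#' sagittal slices from the patient-left edge to the midline, one from the
#' midline to the right. The midline is the body-mask lateral centroid
#' column within the head region.
#'
#' @param vol a [ct_volume()].
#' @param head_z half-open z interval from [head_region()].
#' @param w the bone [contrast_window()]; head structures use the bone
#'   window only.
#' @param body optional `body_mask`; derived when missing.
#' @return list with `left` and `right` [drr_image()]s (each carries the
#'   head-region z offset in `origin`).
#' @export
split_sagittal_drrs <- function(vol, head_z, w = contrast_window("bone"),
                                body = NULL) {
  if (w$name != "bone") abort("head structures are projected in the bone window only.")
  if (head_z[2] <= head_z[1]) abort("head z interval is empty.")
  if (is.null(body)) body <- derive_body_mask(vol)
  bm <- body$mask[iv_seq(head_z), , , drop = FALSE]
  idx <- which(bm != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("no body voxels inside the head region.")
  mid <- as.integer(round(mean(idx[, 3]) - 1))
  X <- dim(vol$voxels)[3]
  if (mid <= 0L || mid >= X) abort("one head half is empty at this midline.")
  sub <- ct_volume(vol$voxels[iv_seq(head_z), , , drop = FALSE], vol$spacing, vol$id)
  list(
    left = project(sub, "sagittal", c(0L, mid), w, origin = head_z[1]),
    right = project(sub, "sagittal", c(mid, X), w, origin = head_z[1]),
    midline = mid
  )
}

#' Localize a small head structure via the sagittal -> axial two-step
#'
#' The sagittal detector runs on the organ's laterality-matched half
#' sagittal DRR of the head; an axial bone-window DRR summed over the
#' detected superior-inferior extent is then passed to the axial detector.
#' The ROI takes z from the sagittal box and y/x from the axial box.
#'
#' @param vol a preprocessed [ct_volume()].
#' @param spec the organ's [organ_spec()] (`group = "head"`).
#' @param det_sagittal,det_axial detectors honoring [predict_box()].
#' @param head_z half-open z interval from [head_region()].
#' @param body optional `body_mask`.
#' @return a `localization_result`.
#' @export
localize_head_organ <- function(vol, spec, det_sagittal, det_axial, head_z,
                                body = NULL) {
  halves <- split_sagittal_drrs(vol, head_z, contrast_window("bone"), body)
  sag <- if (spec$laterality == "right") halves$right else halves$left
  b_s <- predict_box(det_sagittal, replicate_channels(sag))
  if (is.null(b_s)) return(localization_result(spec$name, "not_found"))
  z_range <- b_s$u + sag$origin
  drr_a <- project_multichannel(vol, "axial", z_range, "bone")
  b_a <- predict_box(det_axial, drr_a)
  if (is.null(b_a)) return(localization_result(spec$name, "not_found"))
  roi <- roi3d(z_range, b_a$u, b_a$v)
  roi <- expand_axial(roi, spec$axial_margin, dim(vol$voxels))
  roi <- clip_roi_to_max(roi, spec$max_crop_size, dim(vol$voxels))
  localization_result(spec$name, "ok", roi,
                      confidence = min(b_s$confidence, b_a$confidence))
}

#' Does an ROI fully contain a mask?
#'
#' @param roi a [roi3d()].
#' @param mask 3D binary array.
#' @return logical.
#' @export
roi_contains_mask <- function(roi, mask) {
  bb <- mask_bbox(mask)
  bb$z[1] >= roi$z[1] && bb$z[2] <= roi$z[2] &&
    bb$y[1] >= roi$y[1] && bb$y[2] <= roi$y[2] &&
    bb$x[1] >= roi$x[1] && bb$x[2] <= roi$x[2]
}
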