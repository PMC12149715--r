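# NIfTI reading/writing. On disk, volumes may be stored in any axis
# orientation; everything in memory uses the canonical (z, y, x) order
# documented in ct_volume(). The conversion happens exactly once, here.

# RAS-ordered array (i: L->R, j: P->A, k: I->S) -> canonical (z, y, x)
ras_to_canonical <- function(arr) {
  a <- aperm(arr, c(3, 2, 1))
  a[dim(a)[1]:1, dim(a)[2]:1, , drop = FALSE]
}

canonical_to_ras <- function(vox) {
  a <- vox[dim(vox)[1]:1, dim(vox)[2]:1, , drop = FALSE]
  aperm(a, c(3, 2, 1))
}

#' Load a CT volume (or mask) from a NIfTI file
#'
#' The on-disk orientation (from the qform/sform) is normalized so that the
#' returned voxel array is always in canonical `(z, y, x)` order with
#' z superior-to-inferior, y anterior-to-posterior, x patient-left-to-right.
#' Spacing is read from the header.
#'
#' @param path path to a `.nii` / `.nii.gz` file containing a 3D image.
#' @param id patient identifier; defaults to the file name stem.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path, id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    abort(sprintf("expected a 3D image, got %d dimension(s).", length(dim(img))))
  }
  RNifti::orientation(img) <- "RAS"
  sp_ras <- RNifti::pixdim(img)
  vox <- ras_to_canonical(array(as.numeric(img), dim(img)))
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(vox, spacing = rev(sp_ras[1:3]), id = id)
}

#' Write a CT volume to NIfTI
#'
#' Data are written in RAS orientation with the spacing encoded in the
#' affine, so that [load_volume()] round-trips voxels and spacing exactly.
#'
#' @param vol a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  arr <- canonical_to_ras(vol$voxels)
  sp <- rev(vol$spacing)                       # (dx, dy, dz) for (i, j, k)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  aff <- diag(c(sp, 1))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a set of per-organ mask files
#'
#' @param paths named character vector, organ name -> NIfTI mask path.
#' @param vol the parent [ct_volume()]; mask shapes are validated against
#'   it.
#' @return A [label_set()].
#' @export
load_label_set <- function(paths, vol) {
  masks <- lapply(paths, function(p) {
    m <- load_volume(p)
    round(m$voxels)
  })
  label_set(masks, shape = dim(vol$voxels))
}

#' Write a label set as one NIfTI file per organ
#'
#' Files are named `<patient>_<organ>.nii.gz`.
#'
#' @param labels a [label_set()].
#' @param vol parent [ct_volume()] supplying spacing and patient id.
#' @param dir output directory (created if missing).
#' @return named vector of written paths, invisibly.
#' @export
save_label_set <- function(labels, vol, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(labels$masks), function(nm) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", vol$id, nm))
    save_volume(ct_volume(labels$masks[[nm]] + 0, vol$spacing, vol$id), p)
    p
  }, character(1))
  invisible(paths)
}
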