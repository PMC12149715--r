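test_that("reference boxes are the tight projected bounds, with scaling", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      m <- array(0L, c(12, 14, 16))
      blob <- which(random_mask(c(4, 5, 6), 0.4) == 1, arr.ind = TRUE)
      if (nrow(blob) == 0) next
      m[cbind(blob[, 1] + 4, blob[, 2] + 5, blob[, 3] + 6)] <- 1L
      for (plane in c("coronal", "sagittal", "axial")) {
        box <- reference_box_from_mask(m, plane, scale = 1)
        idx <- which(m == 1, arr.ind = TRUE)
        axes <- switch(plane, coronal = c(1, 3), sagittal = c(1, 2), axial = c(2, 3))
        expect_equal(box$u, c(min(idx[, axes[1]]) - 1L, max(idx[, axes[1]])))
        expect_equal(box$v, c(min(idx[, axes[2]]) - 1L, max(idx[, axes[2]])))
      }
    }
  })
  # single voxel, scale 1 -> 1 x 1 box at its projection
  m <- array(0L, c(8, 8, 8)); m[3, 4, 5] <- 1L
  box <- reference_box_from_mask(m, "axial", 1)
  expect_equal(box$u, c(3L, 4L)); expect_equal(box$v, c(4L, 5L))
  # head-structure scaling doubles height and width about the center
  m2 <- array(0L, c(20, 20, 20)); m2[8:11, 8:11, 9:12] <- 1L
  b1 <- reference_box_from_mask(m2, "coronal", 1)
  b2 <- reference_box_from_mask(m2, "coronal", 2)
  expect_equal(diff(b2$u), 2L * diff(b1$u))
  expect_equal(diff(b2$v), 2L * diff(b1$v))
  expect_equal(mean(b2$u), mean(b1$u))
  expect_error(reference_box_from_mask(array(0L, c(4, 4, 4)), "coronal"), "empty")
})

test_that("restricted sagittal DRRs exclude out-of-range material", {
  ph <- tiny_phantom()
  vol <- ph$volume
  X <- dim(vol$voxels)[3]
  w <- contrast_window("soft_tissue")
  full <- restricted_sagittal_drr(vol, c(0, X), w)
  expect_identical(full$pixels, project(vol, "sagittal", w = w)$pixels)

  # width-1 restriction equals the normalized single sagittal slice
  one <- restricted_sagittal_drr(vol, c(10, 11), w)
  slice <- pmin(pmax(vol$voxels[, , 11], w$lo), w$hi)
  rng <- range(slice)
  expect_identical(one$pixels,
                   array(as.integer(round((slice - rng[1]) / diff(rng) * 255)),
                         dim(slice)))

  # structure outside the lateral range contributes nothing pre-normalization
  vox <- array(0, c(6, 6, 10))
  vox[3, 3, 8] <- 50
  v2 <- ct_volume(vox, c(1, 1, 1))
  left <- project(v2, "sagittal", c(0, 5), w)
  presum <- apply(pmin(pmax(vox[, , 1:5], w$lo), w$hi), c(1, 2), sum)
  expect_true(all(presum == 0))
  expect_true(all(left$pixels == 0))
  expect_error(restricted_sagittal_drr(vol, c(5, 5), w), "empty|nonempty")
})

test_that("fuse_body_boxes is exact coordinate bookkeeping", {
  cor <- box2d("coronal", c(5, 80), c(10, 50))
  sag <- box2d("sagittal", c(7, 78), c(20, 60))
  roi <- fuse_body_boxes(cor, sag)
  expect_equal(roi$x, c(10L, 50L))
  expect_equal(roi$y, c(20L, 60L))
  expect_equal(roi$z, c(7L, 78L))
  expect_error(fuse_body_boxes(sag, cor), "coronal")
  # randomized round-trip: re-projecting the ROI reproduces the box ranges
  withr::with_seed(31, {
    for (rep in 1:20) {
      z <- sort(sample(0:99, 2)); y <- sort(sample(0:99, 2)); x <- sort(sample(0:99, 2))
      if (z[1] == z[2]) z[2] <- z[2] + 1
      if (y[1] == y[2]) y[2] <- y[2] + 1
      if (x[1] == x[2]) x[2] <- x[2] + 1
      r <- fuse_body_boxes(box2d("coronal", z, x), box2d("sagittal", z, y))
      expect_identical(list(r$z, r$y, r$x),
                       list(as.integer(z), as.integer(y), as.integer(x)))
    }
  })
})

test_that("axial expansion grows y/x only, clamps, and composes additively", {
  bounds <- c(100, 100, 100)
  roi <- roi3d(c(10, 20), c(30, 40), c(50, 60))
  ex <- expand_axial(roi, 15, bounds)
  expect_equal(ex$z, roi$z)
  expect_equal(ex$y, c(15L, 55L))
  expect_equal(ex$x, c(35L, 75L))
  expect_identical(expand_axial(roi, 0, bounds), roi)
  corner <- roi3d(c(0, 5), c(0, 10), c(95, 100))
  exc <- expand_axial(corner, 15, bounds)
  expect_equal(exc$y, c(0L, 25L))
  expect_equal(exc$x, c(80L, 100L))
  a <- expand_axial(expand_axial(roi, 4, bounds), 6, bounds)
  b <- expand_axial(roi, 10, bounds)
  expect_identical(a, b)
  expect_error(expand_axial(roi, -1, bounds), ">= 0")
})

test_that("default organ specs carry the published margins and scales", {
  sp <- default_organ_specs()
  expect_equal(sp$lung_l$axial_margin, 20L)
  expect_equal(sp$vertebral_column$axial_margin, 15L)
  expect_equal(sp$spinal_canal$axial_margin, 15L)
  expect_equal(sp$kidney_r$axial_margin, 15L)
  expect_equal(sp$esophagus$axial_margin, 15L)
  expect_equal(sp$brain$axial_margin, 10L)
  expect_equal(sp$brainstem$axial_margin, 10L)
  for (nm in c("eye_l", "lens_r", "chiasm", "cochlea_l", "optic_nerve_r")) {
    expect_equal(sp[[nm]]$box_scale, 2)
    expect_equal(sp[[nm]]$group, "head")
  }
  expect_equal(sp$kidney_l$box_scale, 1)
})

test_that("oracle detectors reproduce reference boxes and report misses", {
  ph <- tiny_phantom()
  det <- oracle_detector(ph$labels, "kidney_l", "coronal", 1)
  drr <- project_multichannel(ph$volume, "coronal", NULL, "composite")
  box <- predict_box(det, drr)
  ref <- reference_box_from_mask(ph$labels$masks$kidney_l, "coronal", 1)
  expect_identical(box$u, ref$u); expect_identical(box$v, ref$v)
  expect_equal(box$confidence, 1)
  missing <- oracle_detector(ph$labels, "no_such_organ", "coronal", 1)
  expect_null(predict_box(missing, drr))
})

test_that("head region runs from the top to the brainstem's inferior border", {
  bs <- array(0L, c(50, 10, 10)); bs[12:40, 4:6, 4:6] <- 1L
  vol <- ct_volume(array(0, c(50, 10, 10)), c(1, 1, 1))
  expect_equal(head_region(vol, bs), c(0L, 40L))
  expect_error(head_region(vol, array(0L, c(50, 10, 10))), "empty")
  ph <- tiny_case()
  hz <- head_region(ph$volume, mask_of(ph$labels, "brainstem"))
  for (org in c("eye_l", "eye_r", "lens_l", "chiasm", "cochlea_r")) {
    bb <- csiseg:::mask_bbox(mask_of(ph$labels, org))
    expect_lte(bb$z[2], hz[2])
  }
})

test_that("the head sagittal split is bone-window-only and respects sides", {
  case <- tiny_case()
  hz <- head_region(case$volume, mask_of(case$labels, "brainstem"))
  expect_error(split_sagittal_drrs(case$volume, hz, contrast_window("lung")),
               "bone")
  halves <- split_sagittal_drrs(case$volume, hz, body = case$body)
  expect_equal(halves$left$origin, 0L)
  # a noise-free symmetric phantom yields identical halves
  sym <- generate_phantom(phantom_spec(age = 10, canvas = c(96, 64, 64),
                                       noise_sd = 0, seed = 3))
  symc <- preprocess_case(sym$volume, sym$labels, body = body_mask(sym$body))
  hz2 <- head_region(symc$volume, mask_of(symc$labels, "brainstem"))
  h2 <- split_sagittal_drrs(symc$volume, hz2, body = symc$body)
  expect_identical(h2$left$pixels, h2$right$pixels)
  # a left-only structure contributes only to the left half
  lens <- mask_of(symc$labels, "cochlea_l")
  xs <- range(which(apply(lens == 1, 3, any)))
  expect_lt(xs[2], h2$midline + 1)
})

test_that("oracle-driven localization contains the organ and caps the crop", {
  case <- tiny_case()
  specs <- default_organ_specs()
  for (org in c("kidney_l", "lung_r", "esophagus", "brainstem")) {
    loc <- csiseg:::reference_localization(case, org, specs[[org]])
    expect_equal(loc$status, "ok")
    expect_true(roi_contains_mask(loc$roi, mask_of(case$labels, org)))
  }
  for (org in c("eye_r", "lens_l", "chiasm")) {
    loc <- csiseg:::reference_localization(case, org, specs[[org]])
    expect_equal(loc$status, "ok")
    expect_true(roi_contains_mask(loc$roi, mask_of(case$labels, org)))
  }
  # an organ absent from the label set produces a failure record
  spec <- specs$kidney_l
  labels2 <- label_set(case$labels$masks[setdiff(names(case$labels), "kidney_l")])
  miss <- localize_body_organ(
    case$volume, spec,
    oracle_detector(labels2, "kidney_l", "coronal", 1),
    oracle_detector(labels2, "kidney_l", "sagittal", 1)
  )
  expect_equal(miss$status, "not_found")
  expect_null(miss$roi)
  # max_crop_size is enforced by symmetric shrinking
  spec_small <- spec; spec_small$max_crop_size <- c(5L, 6L, 7L)
  loc2 <- csiseg:::reference_localization(case, "kidney_l", spec_small)
  expect_true(all(csiseg:::roi_shape(loc2$roi) <= c(5, 6, 7)))
})
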