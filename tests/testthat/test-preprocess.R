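test_that("derived body mask recovers the phantom body support", {
  ph <- tiny_phantom()
  bm <- derive_body_mask(ph$volume)
  expect_s3_class(bm, "body_mask")
  expect_equal(bm$source, "derived")
  ref <- ph$body
  # exact up to boundary voxels pushed across the threshold by noise
  agree <- mean(bm$mask == ref)
  expect_gt(agree, 0.995)
  expect_gt(dsc(bm$mask, ref), 0.995)
})

test_that("body mask keeps only the largest component and errors when empty", {
  vox <- array(-1000, c(20, 20, 20))
  vox[3:12, 3:12, 3:12] <- 40         # 1000-voxel body
  vox[16:17, 16:17, 16:17] <- 40      # small floater, 8 voxels
  bm <- derive_body_mask(ct_volume(vox, c(1, 1, 1)))
  expect_equal(sum(bm$mask[16:17, 16:17, 16:17]), 0)
  expect_equal(sum(bm$mask), 1000)
  expect_error(derive_body_mask(ct_volume(array(-1000, c(5, 5, 5)), c(1, 1, 1))),
               "no body")
})

test_that("masking outside the body sets exactly the outside to -1000", {
  vox <- array(rnorm(8^3, 100, 10), c(8, 8, 8))
  vol <- ct_volume(vox, c(1, 1, 1))
  full <- array(1L, c(8, 8, 8))
  expect_identical(mask_outside_body(vol, body_mask(full))$voxels, vox)
  half <- array(0L, c(8, 8, 8)); half[, , 1:4] <- 1L
  out <- mask_outside_body(vol, structure(list(mask = half), class = "body_mask"))
  expect_identical(out$voxels[, , 1:4], vox[, , 1:4])
  expect_true(all(out$voxels[, , 5:8] == -1000))
  none <- structure(list(mask = array(0L, c(8, 8, 8))), class = "body_mask")
  expect_true(all(mask_outside_body(vol, none)$voxels == -1000))
  expect_error(mask_outside_body(vol, body_mask(array(1L, c(4, 4, 4)))), "mismatch")
})

test_that("centering places the body centroid at the canvas center", {
  vox <- array(-1000, c(10, 40, 60))
  vox[3:8, 5:14, 9:20] <- 50          # off-center blob
  vol <- ct_volume(vox, c(1, 1, 1))
  res <- center_on_canvas(vol, canvas = c(128, 64))
  expect_equal(dim(res$volume$voxels), c(10, 64, 128))
  idx <- which(res$volume$voxels > -500, arr.ind = TRUE)
  expect_lt(abs(mean(idx[, 3]) - 1 - 64), 1)
  expect_lt(abs(mean(idx[, 2]) - 1 - 32), 1)
  # cropping the body back out reproduces the original body voxels exactly
  orig <- which(vox > -500, arr.ind = TRUE)
  shifted <- cbind(orig[, 1], orig[, 2] + res$shift["y"], orig[, 3] + res$shift["x"])
  expect_identical(res$volume$voxels[shifted], vox[orig])
})

test_that("default canvas yields 256 x 512 axial slices in (y, x) order", {
  vox <- array(-1000, c(4, 40, 60))
  vox[, 10:30, 20:40] <- 30
  res <- center_on_canvas(ct_volume(vox, c(1, 1, 1)))
  expect_equal(dim(res$volume$voxels)[2:3], c(256L, 512L))
})

test_that("centering an already-centered canvas-size volume is the identity", {
  vox <- array(-1000, c(6, 32, 48))
  vox[, 14:21, 22:29] <- 30
  vol <- ct_volume(vox, c(1, 1, 1))
  res <- center_on_canvas(vol, canvas = c(48, 32))
  expect_identical(res$volume$voxels, vox)
  big <- array(10, c(4, 50, 50))
  expect_error(center_on_canvas(ct_volume(big, c(1, 1, 1)), canvas = c(32, 32)),
               "resample")
})

test_that("labels are transformed identically to the volume when centering", {
  ph <- tiny_phantom()
  res <- center_on_canvas(ph$volume, ph$labels, canvas = c(80, 80),
                          body = body_mask(ph$body))
  kl <- res$labels$masks$kidney_l
  expect_equal(sum(kl), sum(ph$labels$masks$kidney_l))
  # mask voxels still sit on kidney-valued HU
  expect_gt(mean(abs(res$volume$voxels[kl == 1] - 35) < 40), 0.99)
})

test_that("nearest-neighbor resampling maps indices as expected", {
  ph <- tiny_phantom()
  idres <- resample_nearest(ph$volume, ph$labels, ph$volume$spacing)
  expect_identical(idres$volume$voxels, ph$volume$voxels)
  expect_identical(idres$labels$masks, ph$labels$masks)

  # checkerboard mask stays strictly binary under 2x downsampling
  cb <- array(as.integer((outer(1:8, 1:8, "+") %% 2) == 0), c(8, 8, 8))
  for (z in 1:8) cb[z, , ] <- (cb[z, , ] + z) %% 2
  vol <- ct_volume(array(rnorm(8^3), c(8, 8, 8)), c(1, 1, 1))
  down <- resample_nearest(vol, label_set(list(cb = cb)), c(2, 2, 2))
  expect_true(all(down$labels$masks$cb %in% c(0L, 1L)))
  expect_equal(dim(down$labels$masks$cb), c(4L, 4L, 4L))

  # upsampling z from 3 mm to 1.5 mm duplicates every slice
  vz <- ct_volume(array(rnorm(5 * 4 * 4), c(5, 4, 4)), c(3, 1, 1))
  up <- resample_nearest(vz, target_spacing = c(1.5, 1, 1))
  expect_equal(dim(up$volume$voxels)[1], 10L)
  for (k in 1:5) {
    expect_identical(up$volume$voxels[2 * k - 1, , ], vz$voxels[k, , ])
    expect_identical(up$volume$voxels[2 * k, , ], vz$voxels[k, , ])
  }
  expect_error(resample_nearest(vz, target_spacing = c(0, 1, 1)), "positive")
  expect_error(resample_nearest(vz, target_spacing = c(1e6, 1e6, 1e6)), "degenerate")
})

test_that("label exclusivity crops small structures out of large ones", {
  eye <- array(0L, c(10, 10, 10)); eye[3:8, 3:8, 3:8] <- 1L
  lens <- array(0L, c(10, 10, 10)); lens[5:6, 5:6, 5:6] <- 1L
  ls <- label_set(list(eye = eye, lens = lens))
  out <- make_labels_exclusive(ls, list(c("lens", "eye")))
  expect_identical(out$masks$lens, lens)
  expect_equal(sum(out$masks$eye & lens), 0)
  expect_equal(sum(out$masks$eye), sum(eye) - sum(lens))
  # disjoint organs: identity
  a <- array(0L, c(6, 6, 6)); a[1:2, , ] <- 1L
  b <- array(0L, c(6, 6, 6)); b[5:6, , ] <- 1L
  ls2 <- label_set(list(a = a, b = b))
  expect_identical(make_labels_exclusive(ls2, list(c("a", "b")))$masks, ls2$masks)
  expect_error(make_labels_exclusive(ls2, list(c("a", "nope"))), "unknown organ")
})

test_that("exclusivity is idempotent and yields pairwise-disjoint nesting", {
  d <- c(12, 12, 12)
  inner <- array(0L, d); inner[6:7, 6:7, 6:7] <- 1L
  mid <- array(0L, d); mid[4:9, 4:9, 4:9] <- 1L
  outer_m <- array(0L, d); outer_m[2:11, 2:11, 2:11] <- 1L
  ls <- label_set(list(inner = inner, mid = mid, outer = outer_m))
  pairs <- list(c("inner", "mid"), c("inner", "outer"), c("mid", "outer"))
  once <- make_labels_exclusive(ls, pairs)
  twice <- make_labels_exclusive(once, pairs)
  expect_identical(once$masks, twice$masks)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sum(once$masks[[i]] & once$masks[[j]]), 0)
  }
  # set algebra: outer lost exactly the mid voxels (inner is inside mid)
  expect_equal(sum(once$masks$outer), sum(outer_m) - sum(mid))
  expect_equal(sum(once$masks$mid), sum(mid) - sum(inner))
})
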