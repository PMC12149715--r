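test_that("percentile clip range matches a sort-based oracle", {
  # inside values span 0..99, rim values 50..149
  vox <- array(-1000, c(10, 10, 10))
  mask <- array(0L, c(10, 10, 10))
  mask[4:7, 4:7, 4:7] <- 1L                 # 64 voxels inside
  inside_vals <- seq(0, 99, length.out = 64)
  vox[mask == 1] <- inside_vals
  rim <- csiseg:::dilate_mm(mask, c(1, 1, 1), 1) & mask == 0
  rim_vals <- seq(50, 149, length.out = sum(rim))
  vox[rim] <- rim_vals
  cr <- compute_clip_range(ct_volume(vox, c(1, 1, 1)), mask, rim_mm = 1)
  expect_equal(cr$lo, min(oracle_percentile(inside_vals, 0.10),
                          oracle_percentile(rim_vals, 0.10)))
  expect_equal(cr$hi, max(oracle_percentile(inside_vals, 0.90),
                          oracle_percentile(rim_vals, 0.90)))
  expect_equal(cr$source, "percentile_rule")
})

test_that("degenerate and head clip ranges are handled", {
  vox <- array(40, c(6, 6, 6))
  mask <- array(0L, c(6, 6, 6)); mask[3:4, 3:4, 3:4] <- 1L
  cr <- compute_clip_range(ct_volume(vox, c(1, 1, 1)), mask)
  expect_equal(c(cr$lo, cr$hi), c(39, 41))
  # mask filling the whole volume: rim is empty, inside-only values used
  full <- array(1L, c(6, 6, 6))
  vox2 <- array(seq(0, 99, length.out = 216), c(6, 6, 6))
  cr2 <- compute_clip_range(ct_volume(vox2, c(1, 1, 1)), full)
  expect_equal(cr2$lo, oracle_percentile(as.vector(vox2), 0.10))
  hc <- head_clip_range("eye_l")
  expect_equal(c(hc$lo, hc$hi), c(0, 250))
  expect_equal(hc$source, "head_fixed")
  expect_error(compute_clip_range(ct_volume(vox, c(1, 1, 1)),
                                  array(0L, c(6, 6, 6))), "empty")
})

test_that("aggregation takes medians of the per-case bounds", {
  mk <- function(lo, hi) clip_range(lo, hi, "kidney_l")
  agg <- aggregate_clip_range(list(mk(10, 100), mk(20, 110), mk(30, 120)))
  expect_equal(c(agg$lo, agg$hi), c(20, 110))
  one <- aggregate_clip_range(list(mk(5, 50)))
  expect_equal(c(one$lo, one$hi), c(5, 50))
  same <- aggregate_clip_range(list(mk(1, 2), mk(1, 2)))
  expect_equal(c(same$lo, same$hi), c(1, 2))
  expect_error(aggregate_clip_range(list()), "at least one")
})

test_that("mini-CT extraction normalizes, pads, and round-trips", {
  withr::with_seed(8, {
    vox <- array(rnorm(20^3, 50, 30), c(20, 20, 20))
    vol <- ct_volume(vox, c(1, 1, 1))
    roi <- roi3d(c(4, 12), c(5, 11), c(6, 14))
    clip <- clip_range(0, 100, "t", "config")
    mini <- extract_mini_ct(vol, roi, "t", c(10, 8, 8), clip)
    expect_equal(dim(mini$voxels), c(10L, 8L, 8L))
    expect_true(all(mini$voxels >= 0 & mini$voxels <= 1))
    # normalization is monotone on the cropped voxels
    crop <- csiseg:::roi_crop(vox, roi)
    inside <- crop > 0 & crop < 100
    expect_equal(mini$voxels[mini$pad_before[1] + seq_len(8),
                             mini$pad_before[2] + seq_len(6),
                             mini$pad_before[3] + seq_len(8)][inside],
                 crop[inside] / 100)
    # an ROI exactly the uniform size needs no padding
    exact <- extract_mini_ct(vol, roi, "t", c(8, 6, 8), clip)
    expect_equal(exact$pad_before, c(0L, 0L, 0L))
    # all-lo crop maps to all zeros
    lo_vol <- ct_volume(array(-5, c(8, 8, 8)), c(1, 1, 1))
    z <- extract_mini_ct(lo_vol, roi3d(c(0, 4), c(0, 4), c(0, 4)), "t",
                         c(6, 6, 6), clip)
    expect_true(all(z$voxels == 0))
    expect_error(extract_mini_ct(vol, roi, "t", c(4, 4, 4), clip), "uniform")
    expect_error(extract_mini_ct(vol, roi3d(c(10, 30), c(0, 4), c(0, 4)), "t",
                                 c(30, 6, 6), clip), "outside")
    # paste_back under an identity model reproduces placement exactly
    mask <- array(as.integer(runif(prod(dim(mini$voxels))) < 0.3),
                  dim(mini$voxels))
    full <- paste_back(mask, mini$roi, dim(vox), mini$pad_before)
    expect_equal(sum(full), sum(mask[mini$pad_before[1] + seq_len(8),
                                     mini$pad_before[2] + seq_len(6),
                                     mini$pad_before[3] + seq_len(8)]))
    back <- csiseg:::roi_crop(full, roi)
    expect_identical(back, array(as.integer(
      mask[mini$pad_before[1] + seq_len(8), mini$pad_before[2] + seq_len(6),
           mini$pad_before[3] + seq_len(8)] != 0), c(8L, 6L, 8L)))
    empty <- paste_back(array(0L, dim(mini$voxels)), mini$roi, dim(vox),
                        mini$pad_before)
    expect_equal(sum(empty), 0)
    expect_error(paste_back(mask, roi3d(c(15, 25), c(0, 6), c(0, 8)), dim(vox),
                            mini$pad_before), "outside")
  })
})

test_that("augmentation is a seeded identity/transform pair", {
  withr::with_seed(14, {
    img <- array(rnorm(6 * 16 * 16), c(6, 16, 16))
    msk <- array(as.integer(runif(6 * 16 * 16) < 0.3), c(6, 16, 16))
    off_cfg <- train_config(augment_prob = 0)
    out <- augment_pair(img, msk, off_cfg)
    expect_identical(out$image, img)
    expect_identical(out$mask, msk)
    # zero rotation and unit scale reproduce the input up to interpolation
    w <- csiseg:::warp2d(img[1, , ], 0, 1, "bilinear")
    expect_equal(w, img[1, , ], tolerance = 1e-10)
    wn <- csiseg:::warp2d(msk[1, , ], 0, 1, "nearest")
    expect_identical(wn, msk[1, , ] + 0)
    on_cfg <- train_config(augment_prob = 1)
    a1 <- withr::with_seed(77, augment_pair(img, msk, on_cfg))
    a2 <- withr::with_seed(77, augment_pair(img, msk, on_cfg))
    expect_identical(a1, a2)
    expect_true(all(a1$mask %in% c(0L, 1L)))
    expect_false(identical(a1$image, img))
  })
})

test_that("2.5D stacks sandwich each slice with edge replication", {
  v <- array(seq_len(4 * 6 * 6), c(4, 6, 6))
  st <- make_2p5d_stacks(v)
  expect_equal(dim(st), c(6L, 6L, 4L, 3L))
  for (k in 2:3) {
    expect_equal(st[, , k, 1], v[k - 1, , ])
    expect_equal(st[, , k, 2], v[k, , ])
    expect_equal(st[, , k, 3], v[k + 1, , ])
  }
  expect_equal(st[, , 1, 1], v[1, , ])   # superior edge replicated
  expect_equal(st[, , 4, 3], v[4, , ])   # inferior edge replicated
  one <- make_2p5d_stacks(array(rnorm(36), c(1, 6, 6)))
  expect_equal(one[, , 1, 1], one[, , 1, 2])
  expect_equal(one[, , 1, 2], one[, , 1, 3])
})

test_that("prediction thresholds the probability map at 0.5", {
  m <- build_model("basic_unet", width = 4, levels = 1, seed = 3)
  # force the output bias so probabilities are uniformly just below/above 0.5
  m$params <- lapply(m$params, function(l) lapply(l, function(x) x * 0))
  m$params$out$b <- qlogis(0.49)
  v <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  expect_equal(sum(predict_mask(m, v)), 0)
  m$params$out$b <- qlogis(0.51)
  expect_equal(sum(predict_mask(m, v)), 2 * 8 * 8)
  # mixed map agrees with an elementwise comparison oracle
  withr::with_seed(5, {
    mm <- build_model("basic_unet", width = 4, levels = 1, seed = 9)
    probs <- csiseg:::unet_forward(mm, csiseg:::make_2d_stacks(v))$probs
    got <- predict_mask(mm, v)
    want <- aperm(array(as.integer(probs[, , , 1] > 0.5), dim(probs)[1:3]),
                  c(3, 1, 2))
    expect_identical(got, want)
  })
})

test_that("largest_component keeps corner-connected voxels together", {
  m <- array(0L, c(5, 5, 5))
  m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L      # touch only at a corner
  out <- largest_component(m)
  expect_identical(out, m)                 # one 26-connected component
  # size 10 vs size 3
  m2 <- array(0L, c(10, 10, 10))
  m2[1:10, 1, 1] <- 1L
  m2[5:7, 8, 8] <- 1L
  out2 <- largest_component(m2)
  expect_equal(sum(out2), 10)
  expect_equal(sum(out2[, 8, 8]), 0)
  expect_identical(largest_component(array(0L, c(4, 4, 4))),
                   array(0L, c(4, 4, 4)))
  # idempotent, never grows
  withr::with_seed(6, {
    r <- random_mask(c(12, 12, 12), 0.25)
    l1 <- largest_component(r)
    expect_identical(largest_component(l1), l1)
    expect_lte(sum(l1), sum(r))
  })
})

test_that("training smoke: loss is finite and decreasing on an easy task", {
  withr::with_seed(99, {
    ds <- lapply(1:4, function(i) {
      msk <- array(0L, c(4, 16, 16))
      ctr <- sample(6:10, 2)
      for (z in 1:4) {
        msk[z, (ctr[1] - 3):(ctr[1] + 3), (ctr[2] - 3):(ctr[2] + 3)] <- 1L
      }
      img <- array(rnorm(4 * 16 * 16, 0.2, 0.05), c(4, 16, 16))
      img[msk == 1] <- img[msk == 1] + 0.6
      list(image = img, mask = msk)
    })
    m <- build_model("basic_unet", width = 4, levels = 2, seed = 2)
    m <- train_segmenter(m, ds, train_config(seed = 2, epochs = 8, augment_prob = 0))
    expect_true(all(is.finite(m$loss_trace)))
    expect_lt(mean(tail(m$loss_trace, 2)), mean(head(m$loss_trace, 2)))
    expect_error(train_segmenter(build_model("basic_unet"), list(),
                                 train_config()), "empty")
    # broom-style accessors
    td <- tidy(m)
    expect_equal(nrow(td), 8)
    gl <- glance(m)
    expect_equal(gl$variant, "basic_unet")
    expect_equal(gl$parameters, n_parameters(m))
  })
})
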