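# End-to-end glue: shared preprocessing, reference-label generation,
# detector and segmenter training for one organ, inference back to
# whole-body masks, and the scaled phantom study used for validation.

#' Shared preprocessing for one case
#'
#' Derives (or accepts) the body mask, blanks everything outside the body
#' to -1000 HU, and makes overlapping labels mutually exclusive.
#'
#' @param vol a [ct_volume()].
#' @param labels a [label_set()].
#' @param containment containment pairs for [make_labels_exclusive()].
#' @param body optional precomputed `body_mask`.
#' @return list with `volume`, `labels`, `body`.
#' @export
preprocess_case <- function(vol, labels, containment = default_containment(),
                            body = NULL) {
  if (is.null(body)) body <- derive_body_mask(vol)
  vol <- mask_outside_body(vol, body)
  containment <- Filter(function(p) all(p %in% names(labels$masks)), containment)
  labels <- make_labels_exclusive(labels, containment)
  list(volume = vol, labels = labels, body = body)
}

# reference (oracle-detector) localization for a training case
reference_localization <- function(case, organ, spec) {
  labels <- case$labels
  if (spec$group == "body") {
    localize_body_organ(
      case$volume, spec,
      oracle_detector(labels, organ, "coronal", spec$box_scale),
      oracle_detector(labels, organ, "sagittal", spec$box_scale)
    )
  } else {
    head_z <- head_region(case$volume, mask_of(labels, "brainstem"))
    localize_head_organ(
      case$volume, spec,
      oracle_detector(labels, organ, "sagittal", spec$box_scale),
      oracle_detector(labels, organ, "axial", spec$box_scale),
      head_z, body = case$body
    )
  }
}

# detector training sets mirror the inference-time inputs: the coronal DRR
# plus the reference-restricted sagittal DRR for body organs; the half
# sagittal and z-restricted axial bone DRRs for head organs
body_detector_data <- function(cases, organ, spec) {
  cor_im <- list(); cor_bx <- list(); sag_im <- list(); sag_bx <- list()
  for (case in cases) {
    mask <- mask_of(case$labels, organ)
    drr_c <- project_multichannel(case$volume, "coronal", NULL, spec$window)
    b_c <- reference_box_from_mask(mask, "coronal", spec$box_scale)
    drr_s <- project_multichannel(case$volume, "sagittal", b_c$v, spec$window)
    b_s <- reference_box_from_mask(mask, "sagittal", spec$box_scale)
    cor_im <- c(cor_im, list(drr_c)); cor_bx <- c(cor_bx, list(b_c))
    sag_im <- c(sag_im, list(drr_s)); sag_bx <- c(sag_bx, list(b_s))
  }
  list(coronal = list(images = cor_im, boxes = cor_bx),
       sagittal = list(images = sag_im, boxes = sag_bx))
}

head_detector_data <- function(cases, organ, spec) {
  sag_im <- list(); sag_bx <- list(); ax_im <- list(); ax_bx <- list()
  for (case in cases) {
    labels <- case$labels
    mask <- mask_of(labels, organ)
    head_z <- head_region(case$volume, mask_of(labels, "brainstem"))
    halves <- split_sagittal_drrs(case$volume, head_z, body = case$body)
    sag <- if (spec$laterality == "right") halves$right else halves$left
    sag3 <- replicate_channels(sag)
    b_s <- predict_box(oracle_detector(labels, organ, "sagittal", spec$box_scale), sag3)
    z_range <- b_s$u + sag$origin
    drr_a <- project_multichannel(case$volume, "axial", z_range, "bone")
    b_a <- predict_box(oracle_detector(labels, organ, "axial", spec$box_scale), drr_a)
    sag_im <- c(sag_im, list(sag3)); sag_bx <- c(sag_bx, list(b_s))
    ax_im <- c(ax_im, list(drr_a)); ax_bx <- c(ax_bx, list(b_a))
  }
  list(sagittal = list(images = sag_im, boxes = sag_bx),
       axial = list(images = ax_im, boxes = ax_bx))
}

round_up <- function(x, to) as.integer(ceiling(x / to) * to)

#' Fit the full two-stage pipeline for one organ
#'
#' Trains the plane-specific detectors on reference boxes (plus brainstem
#' detectors for head organs, needed to find the head region at inference),
#' derives the organ's uniform crop size and frozen clipping range from the
#' training cohort, and trains the segmentation model on reference-localized
#' mini-CTs.
#'
#' @param cases list of preprocessed training cases ([preprocess_case()]).
#' @param organ organ name.
#' @param variant segmentation variant, see [build_model()].
#' @param det_cfg a [detector_config()].
#' @param seg_cfg a [train_config()].
#' @param specs organ specification list.
#' @param width,levels segmentation network size.
#' @return an `oar_pipeline` object.
#' @export
fit_oar_pipeline <- function(cases, organ, variant = "basic_unet",
                             det_cfg = detector_config(),
                             seg_cfg = train_config(),
                             specs = default_organ_specs(),
                             width = 8L, levels = 2L) {
  spec <- specs[[organ]]
  if (is.null(spec)) abort(sprintf("no organ_spec for '%s'.", organ))

  detectors <- list()
  if (spec$group == "body") {
    dat <- body_detector_data(cases, organ, spec)
    detectors$coronal <- train_detector(dat$coronal$images, dat$coronal$boxes, det_cfg)
    detectors$sagittal <- train_detector(dat$sagittal$images, dat$sagittal$boxes, det_cfg)
  } else {
    bs_spec <- specs$brainstem
    bs_dat <- body_detector_data(cases, "brainstem", bs_spec)
    detectors$bs_coronal <- train_detector(bs_dat$coronal$images, bs_dat$coronal$boxes, det_cfg)
    detectors$bs_sagittal <- train_detector(bs_dat$sagittal$images, bs_dat$sagittal$boxes, det_cfg)
    dat <- head_detector_data(cases, organ, spec)
    detectors$sagittal <- train_detector(dat$sagittal$images, dat$sagittal$boxes, det_cfg)
    detectors$axial <- train_detector(dat$axial$images, dat$axial$boxes, det_cfg)
  }

  # reference ROIs on the training cohort fix the uniform mini-CT size
  # (per-axis maxima, y/x rounded up for the pooling levels) and, absent an
  # external table, the maximum crop size
  rois <- lapply(cases, function(case) reference_localization(case, organ, spec)$roi)
  sizes <- do.call(rbind, lapply(rois, roi_shape))
  uniform <- c(max(sizes[, 1]),
               round_up(max(sizes[, 2]), 2^levels),
               round_up(max(sizes[, 3]), 2^levels))
  spec$max_crop_size <- spec$max_crop_size %||% uniform

  if (spec$group == "head") {
    clip <- head_clip_range(organ)
  } else {
    clip <- aggregate_clip_range(lapply(cases, function(case) {
      compute_clip_range(case$volume, mask_of(case$labels, organ), organ = organ)
    }))
  }

  dataset <- purrr::map2(cases, rois, function(case, roi) {
    mini <- extract_mini_ct(case$volume, roi, organ, uniform, clip)
    list(image = mini$voxels, mask = mask_to_mini(mask_of(case$labels, organ), mini))
  })
  model <- build_model(variant, width = width, levels = levels, seed = seg_cfg$seed)
  model <- train_segmenter(model, dataset, seg_cfg)

  structure(list(organ = organ, spec = spec, detectors = detectors,
                 clip = clip, uniform_size = uniform, model = model,
                 threshold = seg_cfg$threshold),
            class = "oar_pipeline")
}

#' @export
print.oar_pipeline <- function(x, ...) {
  cat(sprintf("<oar_pipeline %s  (%s, %s)  crop %s  clip [%.0f, %.0f]>\n",
              x$organ, x$spec$group, x$model$variant,
              paste(x$uniform_size, collapse = "x"), x$clip$lo, x$clip$hi))
  invisible(x)
}

#' Run the trained pipeline on a new case
#'
#' Detector-driven localization, mini-CT extraction with the frozen clip
#' range, slice-wise prediction, thresholding, largest-component filtering,
#' and paste-back into the whole-body frame. Detector misses are reported
#' as a `"not_found"` status, not an error.
#'
#' @param pipeline an [fit_oar_pipeline()] result.
#' @param vol preprocessed [ct_volume()].
#' @param body optional `body_mask` (derived if missing; used for the head
#'   midline split).
#' @return list with `status`, `mask` (whole-body binary array or NULL),
#'   `roi`.
#' @export
predict_oar <- function(pipeline, vol, body = NULL) {
  spec <- pipeline$spec
  det <- pipeline$detectors
  if (spec$group == "body") {
    loc <- localize_body_organ(vol, spec, det$coronal, det$sagittal)
  } else {
    bs_spec <- default_organ_specs()$brainstem
    bs <- localize_body_organ(vol, bs_spec, det$bs_coronal, det$bs_sagittal)
    if (bs$status != "ok") return(list(status = "not_found", mask = NULL, roi = NULL))
    head_z <- head_region(vol, bs$roi)
    loc <- localize_head_organ(vol, spec, det$sagittal, det$axial, head_z, body = body)
  }
  if (loc$status != "ok") return(list(status = "not_found", mask = NULL, roi = NULL))
  mini <- extract_mini_ct(vol, loc$roi, pipeline$organ, pipeline$uniform_size,
                          pipeline$clip)
  pred <- predict_mask(pipeline$model, mini, pipeline$threshold)
  pred <- largest_component(pred, connectivity = 26)
  full <- paste_back(pred, mini$roi, dim(vol$voxels), mini$pad_before)
  list(status = "ok", mask = full, roi = loc$roi)
}

#' Evaluate trained pipelines on test cases
#'
#' @param pipelines named list of `oar_pipeline`s (name = organ).
#' @param cases list of preprocessed test cases.
#' @param meta tibble with `id`, `age` (and optionally `cohort`) per case.
#' @return tibble of DSC records; localization failures score a DSC of 0.
#' @export
evaluate_pipelines <- function(pipelines, cases, meta) {
  rows <- list()
  for (i in seq_along(cases)) {
    case <- cases[[i]]
    for (organ in names(pipelines)) {
      pl <- pipelines[[organ]]
      res <- predict_oar(pl, case$volume, body = case$body)
      ref <- mask_of(case$labels, organ)
      d <- if (res$status == "ok") dsc(ref, res$mask) else 0
      rows[[length(rows) + 1L]] <- dsc_record(
        meta$id[i], organ, pl$model$variant, d, age = meta$age[i],
        cohort = meta$cohort[i] %||% NA_character_
      )
    }
  }
  dplyr::bind_rows(rows)
}

# generate + preprocess a seeded study cohort with a train/test split;
# each raw phantom is preprocessed and released before the next one is
# generated, so only the preprocessed cases are ever held in memory
study_cases <- function(n, n_test, seed, canvas = c(160L, 96L, 96L),
                        spacing = c(2, 2, 2), noise_sd = 8,
                        age_range = c(3, 18)) {
  draws <- with_seed(as.integer(seed), list(
    ages = runif(n, age_range[1], age_range[2]),
    seeds = sample.int(.Machine$integer.max %/% 2L, n)
  ))
  ids <- sprintf("P%03d", seq_len(n))
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(phantom_spec(age = draws$ages[i], canvas = canvas,
                                        spacing = spacing, noise_sd = noise_sd,
                                        seed = draws$seeds[i], id = ids[i]))
    cases[[i]] <- preprocess_case(ph$volume, ph$labels, body = body_mask(ph$body))
    rm(ph)
  }
  meta <- tibble::tibble(id = ids, age = draws$ages, cohort = NA_character_)
  idx_test <- seq_len(n_test)
  meta$cohort <- ifelse(seq_len(n) %in% idx_test, "test", "train")
  list(cases = cases, meta = meta, idx_test = idx_test,
       idx_train = setdiff(seq_len(n), idx_test))
}

#' Scaled end-to-end phantom study
#'
#' Generates a seeded phantom cohort, preprocesses it, trains the two-stage
#' pipeline for the requested organs and variants on the training split,
#' and evaluates DSC on the held-out split. This is the package's
#' self-contained stand-in for a clinical validation study.
#'
#' @param n cohort size; `n_test` phantoms are held out.
#' @param n_test held-out phantoms.
#' @param seed master seed; all derived seeds are deterministic functions
#'   of it.
#' @param organs organs to train (one pipeline per organ x variant).
#' @param variants segmentation variants.
#' @param det_epochs detector training epochs.
#' @param seg_epochs_body,seg_epochs_head segmenter epochs by organ group
#'   (head minis are tiny, so their longer schedule is cheap).
#' @param width_body,width_head segmenter base widths by organ group.
#' @param canvas,spacing,noise_sd,age_range phantom study conditions.
#' @param .prep prebuilt cohort (internal; the output of `study_cases()`
#'   with matching `n`, `n_test` and `seed`), to avoid regenerating
#'   phantoms when the caller already holds them.
#' @return list with `records` (DSC tibble), `pipelines`, `train_meta`,
#'   `test_meta`.
#' @export
run_phantom_study <- function(n = 16, n_test = 4, seed = 1L,
                              organs = c("kidney_l", "eye_l"),
                              variants = "basic_unet",
                              det_epochs = 150L,
                              seg_epochs_body = 10L, seg_epochs_head = 40L,
                              width_body = 8L, width_head = 16L,
                              canvas = c(160L, 96L, 96L), spacing = c(2, 2, 2),
                              noise_sd = 8, age_range = c(3, 18),
                              .prep = NULL) {
  seed <- as.integer(seed)
  prep <- .prep %||% study_cases(n, n_test, seed, canvas = canvas,
                                 spacing = spacing, noise_sd = noise_sd,
                                 age_range = age_range)
  cases <- prep$cases
  meta <- prep$meta
  idx_test <- prep$idx_test
  idx_train <- prep$idx_train

  specs <- default_organ_specs()
  pipelines <- list()
  for (organ in organs) {
    is_head <- specs[[organ]]$group == "head"
    for (variant in variants) {
      key <- if (length(variants) > 1) paste(organ, variant, sep = ".") else organ
      pipelines[[key]] <- fit_oar_pipeline(
        cases[idx_train], organ, variant = variant,
        det_cfg = detector_config(seed = seed + 11L, epochs = det_epochs,
                                  batch_size = 6L),
        seg_cfg = train_config(seed = seed + 23L,
                               epochs = if (is_head) seg_epochs_head else seg_epochs_body,
                               batch_size = if (is_head) 8L else 12L),
        width = if (is_head) width_head else width_body
      )
    }
  }
  # evaluate each pipeline against its own organ
  names(pipelines) <- vapply(pipelines, function(p) p$organ, character(1)) |>
    make.unique()
  records <- list()
  for (key in names(pipelines)) {
    pl <- pipelines[[key]]
    rec <- evaluate_pipelines(stats::setNames(list(pl), pl$organ),
                              cases[idx_test], meta[idx_test, ])
    records[[key]] <- rec
  }
  list(records = dplyr::bind_rows(records), pipelines = pipelines,
       train_meta = meta[idx_train, ], test_meta = meta[idx_test, ])
}
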