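# Synthetic whole-body CT phantoms with exact ground-truth organ masks.
#
# The phantom emulates the gross HU structure of a pediatric whole-body
# planning CT: a soft-tissue body in -1000 HU air, low-HU lung analogs, a
# high-HU vertebral column with an embedded spinal-canal analog, kidney
# analogs with an age-dependent perirenal fat rim, an esophagus-like tube
# adjacent to an air-filled trachea analog, and a head with skull shell,
# brain, brainstem, paired eyes/lenses/optic nerves, chiasm, and cochlear
# bone points. All structure sizes scale monotonically with a synthetic age
# covariate (linear in the cube root of target volume). Ground-truth masks
# are exact, computed from the same geometry before noise is added.

#' Phantom specification
#'
#' @param age synthetic patient age in years (> 0; sizes scale with
#'   `(age/12)^(1/3)`, i.e. linearly in the cube root of volume).
#' @param canvas integer length-3 `(Z, Y, X)` canvas in voxels.
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @param noise_sd additive Gaussian noise, HU.
#' @param seed integer RNG seed; a fixed seed makes the phantom
#'   deterministic.
#' @param id patient identifier.
#' @param hu named list overriding default tissue HU means (names: `body`,
#'   `lung`, `trachea`, `esophagus`, `bone`, `canal`, `kidney`, `fat`,
#'   `orbital_fat`, `brain`, `brainstem`, `eye`, `lens`, `cochlea`, `nerve`,
#'   `chiasm`).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(age = 10, canvas = c(160L, 96L, 96L),
                         spacing = c(2, 2, 2), noise_sd = 8,
                         seed = 1L, id = "P01", hu = list()) {
  if (age <= 0) abort("`age` must be positive.")
  hu_def <- list(
    body = 30, lung = -800, trachea = -900, esophagus = 30,
    bone = 700, canal = 20, kidney = 35, fat = -100, orbital_fat = -80,
    brain = 35, brainstem = 38, eye = 20, lens = 60, cochlea = 500,
    nerve = 30, chiasm = 30
  )
  hu_def[names(hu)] <- hu
  structure(
    list(age = age, canvas = as.integer(canvas), spacing = as.numeric(spacing),
         noise_sd = noise_sd, seed = as.integer(seed), id = as.character(id),
         hu = hu_def),
    class = "phantom_spec"
  )
}

# size multiplier: linear in the cube root of target volume, 1 at age 12
organ_scale <- function(age) (age / 12)^(1 / 3)

# Logical ellipsoid; `center` and `radii` in 0-based voxel coordinates.
# Computed only inside the bounding window for speed. Guaranteed nonempty
# (falls back to the voxel nearest the center).
ellipsoid_mask <- function(dims, center, radii, z_range = NULL) {
  m <- array(FALSE, dims)
  r_eff <- radii
  if (is.infinite(r_eff[1])) {
    zr <- if (is.null(z_range)) c(0, dims[1]) else z_range
    zlo <- max(1, floor(zr[1]) + 1); zhi <- min(dims[1], ceiling(zr[2]))
  } else {
    zlo <- max(1, floor(center[1] - r_eff[1]) + 1)
    zhi <- min(dims[1], ceiling(center[1] + r_eff[1]) + 1)
  }
  ylo <- max(1, floor(center[2] - r_eff[2]) + 1)
  yhi <- min(dims[2], ceiling(center[2] + r_eff[2]) + 1)
  xlo <- max(1, floor(center[3] - r_eff[3]) + 1)
  xhi <- min(dims[3], ceiling(center[3] + r_eff[3]) + 1)
  if (zhi >= zlo && yhi >= ylo && xhi >= xlo) {
    iz <- (zlo:zhi) - 1; iy <- (ylo:yhi) - 1; ix <- (xlo:xhi) - 1
    tz <- if (is.infinite(radii[1])) rep(0, length(iz)) else ((iz - center[1]) / radii[1])^2
    ty <- ((iy - center[2]) / radii[2])^2
    tx <- ((ix - center[3]) / radii[3])^2
    w <- outer(outer(tz, ty, "+"), tx, "+") <= 1
    if (!is.null(z_range) && !is.infinite(radii[1])) {
      keep <- iz >= z_range[1] & iz < z_range[2]
      w[!keep, , ] <- FALSE
    }
    if (!is.null(z_range) && is.infinite(radii[1])) {
      keep <- iz >= z_range[1] & iz < z_range[2]
      w[!keep, , ] <- FALSE
    }
    m[zlo:zhi, ylo:yhi, xlo:xhi] <- w
  }
  if (!any(m)) {
    nv <- pmin(dims, pmax(1, round(center) + 1))
    m[nv[1], nv[2], nv[3]] <- TRUE
  }
  m
}

# Union of spheres sampled along a segment: optic-nerve style tube.
# Painted inside the segment's bounding window only.
tube_mask <- function(dims, from, to, radius, n_steps = 24) {
  lo <- pmax(0, floor(pmin(from, to) - radius - 1))
  hi <- pmin(dims - 1, ceiling(pmax(from, to) + radius + 1))
  sub_dims <- as.integer(hi - lo + 1)
  sub <- array(FALSE, sub_dims)
  for (t in seq(0, 1, length.out = n_steps)) {
    p <- from + t * (to - from) - lo
    sub <- sub | ellipsoid_mask(sub_dims, p, rep(radius, 3))
  }
  m <- array(FALSE, dims)
  m[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1] <- sub
  m
}

#' Generate a whole-body CT phantom with ground-truth masks
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [ct_volume()]), `labels` (a
#'   [label_set()] of 18 organ-analog masks), `body` (the exact body support
#'   mask), and `meta` (one-row tibble: id, age, cohort).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$canvas
  Z <- d[1]; Y <- d[2]; X <- d[3]
  s <- organ_scale(spec$age)
  hu <- spec$hu
  yc <- (Y - 1) / 2; xc <- (X - 1) / 2

  vox <- array(-1000, d)
  paint <- function(mask, value) vox[mask] <<- value

  # ---- body: head ellipsoid + neck + torso --------------------------------
  rh <- 0.10 * Z * s                       # head radius (z units, isotropic)
  zc_head <- 0.03 * Z + rh
  head_body <- ellipsoid_mask(d, c(zc_head, yc, xc), c(rh, 1.38 * rh, rh))
  neck <- ellipsoid_mask(d, c(0, yc, xc), c(Inf, 0.14 * Y * s, 0.12 * X * s),
                         z_range = c(zc_head, 0.30 * Z))
  torso <- ellipsoid_mask(d, c(0, yc, xc), c(Inf, 0.30 * Y * s, 0.38 * X * s),
                          z_range = c(0.25 * Z, 0.97 * Z))
  body <- head_body | neck | torso
  paint(body, hu$body)

  masks <- list()

  # ---- lungs --------------------------------------------------------------
  for (side in c("l", "r")) {
    sgn <- if (side == "l") -1 else 1
    m <- ellipsoid_mask(d, c(0.36 * Z, yc - 0.03 * Y, xc + sgn * 0.15 * X),
                        c(0.095 * Z, 0.16 * Y, 0.10 * X) * s)
    masks[[paste0("lung_", side)]] <- m
    paint(m, hu$lung)
  }

  # ---- trachea analog (context only, no mask) + esophagus -----------------
  r_tr <- max(1.6, 0.024 * Y * s)
  r_es <- max(1.2, 0.018 * Y * s)
  trachea <- ellipsoid_mask(d, c(0, yc - 0.10 * Y * s, xc), c(Inf, r_tr, r_tr),
                            z_range = c(0.20 * Z, 0.42 * Z))
  paint(trachea, hu$trachea)
  eso <- ellipsoid_mask(d, c(0, yc - 0.10 * Y * s + r_tr + r_es, xc),
                        c(Inf, r_es, r_es), z_range = c(0.20 * Z, 0.58 * Z))
  masks$esophagus <- eso
  paint(eso, hu$esophagus)

  # ---- vertebral column + spinal canal ------------------------------------
  y_vert <- yc + 0.155 * Y * s
  rv <- max(2.2, 0.035 * Y * s)
  vert <- ellipsoid_mask(d, c(0, y_vert, xc), c(Inf, rv, rv),
                         z_range = c(0.24 * Z, 0.94 * Z))
  canal <- ellipsoid_mask(d, c(0, y_vert, xc),
                          c(Inf, max(1.0, 0.016 * Y * s), max(1.0, 0.016 * Y * s)),
                          z_range = c(0.25 * Z, 0.93 * Z))
  masks$vertebral_column <- vert
  masks$spinal_canal <- canal
  paint(vert, hu$bone)
  paint(canal, hu$canal)

  # ---- kidneys with age-dependent perirenal fat rim -----------------------
  t_fat <- 1 + 2.2 * (spec$age / 18)
  for (side in c("l", "r")) {
    sgn <- if (side == "l") -1 else 1
    ctr <- c(0.62 * Z, yc + 0.08 * Y * s, xc + sgn * 0.15 * X * s)
    radii <- c(0.065 * Z, 0.07 * Y, 0.055 * X) * s
    kid <- ellipsoid_mask(d, ctr, radii)
    rim <- ellipsoid_mask(d, ctr, radii + t_fat) & !kid
    paint(rim, hu$fat)
    paint(kid, hu$kidney)
    masks[[paste0("kidney_", side)]] <- kid
  }

  # ---- head: skull, brain, brainstem, eyes, lenses, nerves, chiasm,
  # cochleae ---------------------------------------------------------------
  t_sk <- max(1.5, 0.09 * rh)
  skull_outer <- ellipsoid_mask(d, c(zc_head, yc, xc), rep(rh, 3))
  skull_inner <- ellipsoid_mask(d, c(zc_head, yc, xc), rep(rh - t_sk, 3))
  skull <- skull_outer & !skull_inner

  re <- 0.24 * rh
  eye_ctr <- list(
    l = c(zc_head + 0.15 * rh, yc - 1.0 * rh, xc - 0.42 * rh),
    r = c(zc_head + 0.15 * rh, yc - 1.0 * rh, xc + 0.42 * rh)
  )
  orbit <- array(FALSE, d)
  eyes <- list(); lenses <- list()
  for (side in c("l", "r")) {
    ec <- eye_ctr[[side]]
    orbit <- orbit | ellipsoid_mask(d, ec, rep(re * 1.5, 3))
    eyes[[side]] <- ellipsoid_mask(d, ec, rep(re, 3))
    lenses[[side]] <- ellipsoid_mask(d, ec + c(0, -0.62 * re, 0), rep(max(0.7, 0.42 * re), 3))
  }
  skull <- skull & !orbit
  paint(skull, hu$bone)

  brain <- ellipsoid_mask(d, c(zc_head, yc, xc), rep(rh - t_sk - 0.5, 3))
  brainstem <- ellipsoid_mask(d, c(0, yc + 0.12 * rh, xc),
                              c(Inf, max(1.2, 0.16 * rh), max(1.2, 0.16 * rh)),
                              z_range = c(zc_head, zc_head + rh + 0.05 * Z))
  chiasm_ctr <- c(zc_head + 0.18 * rh, yc - 0.15 * rh, xc)
  chiasm <- ellipsoid_mask(d, chiasm_ctr, rep(max(1.0, 0.16 * rh), 3))
  nerves <- list()
  for (side in c("l", "r")) {
    ec <- eye_ctr[[side]]
    nerves[[side]] <- tube_mask(d, ec + c(0, 0.8 * re, 0), chiasm_ctr,
                                max(0.8, 0.10 * rh))
  }
  cochleae <- list()
  for (side in c("l", "r")) {
    sgn <- if (side == "l") -1 else 1
    cochleae[[side]] <- ellipsoid_mask(
      d, c(zc_head + 0.35 * rh, yc + 0.18 * rh, xc + sgn * 0.62 * rh),
      rep(max(0.8, 0.11 * rh), 3)
    )
  }

  # brain ground truth never overlaps orbit contents or cochlear bone
  brain <- brain & !orbit & !cochleae$l & !cochleae$r
  paint(brain, hu$brain)
  paint(brainstem & body, hu$brainstem)
  paint(orbit & !eyes$l & !eyes$r, hu$orbital_fat)
  for (side in c("l", "r")) paint(eyes[[side]], hu$eye)
  for (side in c("l", "r")) paint(lenses[[side]], hu$lens)
  for (side in c("l", "r")) paint(nerves[[side]] & !eyes$l & !eyes$r, hu$nerve)
  paint(chiasm, hu$chiasm)
  for (side in c("l", "r")) paint(cochleae[[side]], hu$cochlea)

  masks$brain <- brain
  masks$brainstem <- brainstem & body
  masks$eye_l <- eyes$l; masks$eye_r <- eyes$r
  masks$lens_l <- lenses$l; masks$lens_r <- lenses$r
  masks$optic_nerve_l <- nerves$l & !eyes$l & !eyes$r & !chiasm
  masks$optic_nerve_r <- nerves$r & !eyes$l & !eyes$r & !chiasm
  masks$chiasm <- chiasm
  masks$cochlea_l <- cochleae$l
  masks$cochlea_r <- cochleae$r

  # ---- sanity: organs inside the canvas, none empty -----------------------
  for (nm in names(masks)) {
    if (!any(masks[[nm]])) abort(sprintf("organ '%s' is out of canvas (empty mask).", nm))
  }
  edge_touch <- any(body[c(1, Z), , ]) || any(body[, c(1, Y), ]) || any(body[, , c(1, X)])
  if (edge_touch) abort("phantom body exceeds the canvas; enlarge the canvas or lower the age.")

  vox <- vox + array(rnorm(length(vox), 0, spec$noise_sd), d)

  list(
    volume = ct_volume(vox, spec$spacing, id = spec$id),
    labels = label_set(masks, shape = d),
    body = array(as.integer(body), d),
    meta = tibble::tibble(id = spec$id, age = spec$age, cohort = NA_character_)
  )
}

#' Generate a cohort of phantoms
#'
#' Ages are drawn uniformly in `age_range` from the seeded generator;
#' per-phantom seeds are derived deterministically from the cohort seed.
#'
#' @param n number of phantoms (>= 1).
#' @param age_range length-2 numeric, years.
#' @param seed cohort seed.
#' @param ... passed to [phantom_spec()] (`canvas`, `spacing`, `noise_sd`,
#'   `hu`).
#' @return list with `phantoms` (list of [generate_phantom()] results) and
#'   `meta` (tibble of id, age, cohort).
#' @export
generate_cohort <- function(n, age_range = c(3, 18), seed = 1L, ...) {
  if (n < 1) abort("`n` must be >= 1.")
  if (length(age_range) != 2 || age_range[1] <= 0 || age_range[2] <= age_range[1]) {
    abort("`age_range` must be an increasing pair of positive ages.")
  }
  draws <- with_seed(as.integer(seed), list(
    ages = runif(n, age_range[1], age_range[2]),
    seeds = sample.int(.Machine$integer.max %/% 2L, n)
  ))
  ids <- sprintf("P%03d", seq_len(n))
  phantoms <- purrr::pmap(
    list(draws$ages, draws$seeds, ids),
    function(age, sd_i, id) {
      generate_phantom(phantom_spec(age = age, seed = sd_i, id = id, ...))
    }
  )
  meta <- dplyr::bind_rows(purrr::map(phantoms, "meta"))
  list(phantoms = phantoms, meta = meta)
}

#' Plant an age-related trend into a DSC table
#'
#' Adds an age-proportional shift plus Gaussian noise to the named organ's
#' DSC values and clips to `[0, 1]`; a test fixture for the trend-analysis
#' machinery.
#'
#' @param records tibble of DSC records with columns `organ`, `age`, `dsc`.
#' @param organ organ whose records are shifted.
#' @param slope DSC change per year of age (0 leaves the distribution as a
#'   pure noise null).
#' @param seed RNG seed.
#' @param noise_sd standard deviation of the added noise (DSC units).
#' @return the records tibble with modified `dsc`.
#' @export
plant_dsc_trend <- function(records, organ, slope, seed = 1L, noise_sd = 0.03) {
  if (!organ %in% records$organ) abort(sprintf("unknown organ '%s' in records.", organ))
  sel <- records$organ == organ
  shift <- with_seed(as.integer(seed), {
    slope * (records$age[sel] - mean(records$age[sel])) +
      rnorm(sum(sel), 0, noise_sd)
  })
  records$dsc[sel] <- pmin(1, pmax(0, records$dsc[sel] + shift))
  records
}
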