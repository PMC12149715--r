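# Independent oracle implementations used to cross-check the package.
# These deliberately use different algorithms from the implementations they
# verify.

# --- connected components: iterative dilation flood fill -------------------

oracle_shift <- function(arr, dz, dy, dx) {
  d <- dim(arr)
  out <- array(FALSE, d)
  sz <- max(1, 1 - dz):min(d[1], d[1] - dz)
  sy <- max(1, 1 - dy):min(d[2], d[2] - dy)
  sx <- max(1, 1 - dx):min(d[3], d[3] - dx)
  out[sz + dz, sy + dy, sx + dx] <- arr[sz, sy, sx]
  out
}

oracle_dilate26 <- function(arr) {
  out <- arr
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    out <- out | oracle_shift(arr, dz, dy, dx)
  }
  out
}

# label all 26-connected components by repeated dilation until fixpoint
oracle_components26 <- function(mask) {
  fg <- mask != 0
  lab <- array(0L, dim(mask))
  k <- 0L
  while (any(fg & lab == 0L)) {
    k <- k + 1L
    seed <- which(fg & lab == 0L)[1]
    comp <- array(FALSE, dim(mask))
    comp[seed] <- TRUE
    repeat {
      grown <- oracle_dilate26(comp) & fg
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    lab[comp] <- k
  }
  lab
}

# the component the tie rule should pick: largest, ties by the smallest
# (z, y, x) coordinate tuple among the component's voxels
oracle_largest26 <- function(mask) {
  lab <- oracle_components26(mask)
  k <- max(lab)
  if (k == 0L) return(array(0L, dim(mask)))
  sizes <- tabulate(lab[lab > 0], nbins = k)
  cand <- which(sizes == max(sizes))
  best <- NULL; best_key <- NULL
  for (l in cand) {
    idx <- which(lab == l, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
    key <- idx[1, ]
    if (is.null(best_key) ||
        key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] && key[3] < best_key[3])) {
      best <- l; best_key <- key
    }
  }
  array(as.integer(lab == best), dim(mask))
}

# --- DSC by explicit voxel-index set counting ------------------------------

oracle_dsc <- function(A, B, eps = 1e-7) {
  ia <- which(A != 0); ib <- which(B != 0)
  (2 * length(intersect(ia, ib)) + eps) / (length(ia) + length(ib) + eps)
}

# --- Mann-Kendall tau by O(n^2) pair counting ------------------------------

oracle_tau <- function(x) {
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[j] > x[i]) conc <- conc + 1
    if (x[j] < x[i]) disc <- disc + 1
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# --- Holm-Bonferroni step-down by hand -------------------------------------

oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- percentile via explicit sort + linear interpolation -------------------

oracle_percentile <- function(x, prob) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# random binary mask helper
random_mask <- function(dims, p = 0.3) {
  array(as.integer(runif(prod(dims)) < p), dims)
}
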