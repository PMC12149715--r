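# 3D connected-component labeling by vectorized breadth-first search on a
# zero-padded flat index space (no per-voxel R loop).

neighbor_offsets <- function(connectivity = 26) {
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else if (connectivity != 26) abort("connectivity must be 6 or 26.")
  offs
}

#' Label 3D connected components
#'
#' @param mask 3D binary array.
#' @param connectivity 26 (faces, edges and corners) or 6 (faces only).
#' @return integer array of the same shape: 0 for background, 1..k component
#'   labels in discovery order.
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) != 3L) abort("`mask` must be a 3D array.")
  dp <- d + 2L
  core_z <- 2:(d[1] + 1L); core_y <- 2:(d[2] + 1L); core_x <- 2:(d[3] + 1L)
  fg <- array(FALSE, dp)
  fg[core_z, core_y, core_x] <- mask != 0
  remaining <- as.vector(fg)
  lab <- integer(length(remaining))
  offs <- neighbor_offsets(connectivity)
  delta <- offs[, 1] + dp[1] * (offs[, 2] + dp[2] * offs[, 3])
  cur <- 0L
  repeat {
    seed <- which.max(remaining)
    if (!remaining[seed]) break
    cur <- cur + 1L
    remaining[seed] <- FALSE
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier)) {
      nb <- rep(frontier, each = length(delta)) + delta
      nb <- nb[remaining[nb]]
      if (length(nb)) {
        nb <- unique(nb)
        remaining[nb] <- FALSE
        lab[nb] <- cur
      }
      frontier <- nb
    }
  }
  array(lab, dp)[core_z, core_y, core_x]
}

#' Keep only the largest connected component
#'
#' The single post-processing step applied to predicted masks: retain the
#' largest 26-connected component. An empty mask is returned unchanged.
#' Equal-size ties are broken deterministically in favor of the component
#' containing the lexicographically smallest `(z, y, x)` voxel.
#'
#' @param mask 3D binary array.
#' @param connectivity voxel adjacency, default 26.
#' @return binary integer array with only the winning component set.
#' @export
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  k <- max(lab)
  if (k == 0L) return(array(0L, dim(mask)))
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    keys <- lapply(cand, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      idx[order(idx[, 1], idx[, 2], idx[, 3])[1], ]
    })
    ord <- do.call(order, as.data.frame(do.call(rbind, keys)))
    winner <- cand[ord[1]]
  } else {
    winner <- cand
  }
  array(as.integer(lab == winner), dim(mask))
}
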