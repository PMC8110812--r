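#' Create a lesion mask on a voxel grid
#'
#' @param mask logical or 0/1 array (3D).
#' @param voxel_size_mm edge length of a voxel in mm.
#' @return object of class `lesion_mask` with fields `mask` (logical array)
#'   and `voxel_size_mm`.
#' @export
lesion_mask <- function(mask, voxel_size_mm) {
  vals <- unique(as.vector(mask))
  assert_that(all(vals %in% c(0, 1, TRUE, FALSE)),
              "lesion mask must be binary", class = "chacomed_nonbinary")
  structure(list(mask = array(as.logical(mask), dim = dim(mask)),
                 voxel_size_mm = voxel_size_mm),
            class = "lesion_mask")
}

#' Lesion volume in millilitres
#'
#' Voxel count times voxel volume; 1 ml = 1000 mm^3.
#'
#' @param mask a [lesion_mask()].
#' @return volume in ml.
#' @export
lesion_volume <- function(mask) {
  assert_that(inherits(mask, "lesion_mask"), "expected a lesion_mask")
  sum(mask$mask) * mask$voxel_size_mm^3 / 1000
}

# 6-connected neighbours of voxels given as an n x 3 integer matrix,
# clipped to the grid.
neighbours6 <- function(vox, dims) {
  offs <- rbind(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  out <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
    sweep(vox, 2L, offs[i, ], "+")
  }))
  keep <- out[, 1L] >= 1L & out[, 1L] <= dims[1L] &
    out[, 2L] >= 1L & out[, 2L] <= dims[2L] &
    out[, 3L] >= 1L & out[, 3L] <= dims[3L]
  out[keep, , drop = FALSE]
}

# Eden-type growth: starting from `current` (logical array, possibly a
# single seed voxel), repeatedly add a uniformly chosen 6-connected
# boundary voxel inside `allowed` until `target` voxels are set. Produces
# connected clusters with exact volume control. Consumes RNG draws.
grow_region <- function(current, allowed, target, dims) {
  n_now <- sum(current)
  if (n_now >= target) return(current)
  frontier_arr <- array(FALSE, dim = dims)
  vox <- which(current, arr.ind = TRUE)
  nb <- neighbours6(vox, dims)
  lin <- voxel_linear(nb, dims)
  ok <- allowed[lin] & !current[lin] & !frontier_arr[lin]
  frontier <- unique(lin[ok])
  frontier_arr[frontier] <- TRUE
  while (n_now < target && length(frontier) > 0L) {
    pick_i <- if (length(frontier) == 1L) 1L else
      sample.int(length(frontier), 1L)
    pick <- frontier[pick_i]
    frontier <- frontier[-pick_i]
    frontier_arr[pick] <- FALSE
    current[pick] <- TRUE
    n_now <- n_now + 1L
    pv <- arrayInd(pick, dims)
    nb <- neighbours6(matrix(as.integer(pv), 1L, 3L), dims)
    lin <- voxel_linear(nb, dims)
    new <- lin[allowed[lin] & !current[lin] & !frontier_arr[lin]]
    if (length(new)) {
      frontier <- c(frontier, new)
      frontier_arr[new] <- TRUE
    }
  }
  current
}

# Random boundary erosion down to `target` voxels (used for shrinking
# lesions, emulating DWI reversal). Removal order is random over current
# boundary voxels; the remainder may in principle fragment, which is
# acceptable for a partially reversed lesion.
shrink_region <- function(current, target, dims) {
  n_now <- sum(current)
  while (n_now > target) {
    vox <- which(current, arr.ind = TRUE)
    # boundary voxel: fewer than 6 in-grid lesion neighbours
    lin_all <- voxel_linear(vox, dims)
    is_boundary <- vapply(seq_len(nrow(vox)), function(i) {
      nbi <- neighbours6(vox[i, , drop = FALSE], dims)
      sum(current[voxel_linear(nbi, dims)]) < 6L
    }, logical(1))
    cand <- lin_all[is_boundary]
    if (!length(cand)) cand <- lin_all
    n_rm <- min(length(cand), n_now - target)
    rm_idx <- if (length(cand) == 1L) cand else
      sample(cand, n_rm)
    current[rm_idx] <- FALSE
    n_now <- n_now - n_rm
  }
  current
}
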