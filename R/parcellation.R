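#' Construct a synthetic grey-matter parcellation
#'
#' Partitions a voxel grid into two disjoint hemispheres (split along the
#' first axis) and divides each hemisphere into `n_regions_per_hemisphere`
#' contiguous slabs. This is a generic stand-in for an anatomical atlas
#' such as Desikan-Killiany or AAL: every labelled voxel belongs to exactly
#' one region, regions carry hemisphere and lobe metadata, and label 0 is
#' background. Real atlas volumes can be supplied through the NIfTI path
#' instead ([read_parcellation_nifti()]).
#'
#' The construction is deterministic given `params`; no random numbers are
#' consumed.
#'
#' @param params a [cohort_params()] list; uses `grid_shape`,
#'   `voxel_size_mm` and `n_regions_per_hemisphere`.
#' @return an object of class `parcellation`: a list with `labels` (3D
#'   integer array, 0 = background), `regions` (data.frame with `id`,
#'   `name`, `hemisphere`, `lobe`), `voxel_size_mm`, and `hemi_of_voxel`
#'   (3D character array mapping every voxel to "L" or "R").
#' @export
make_parcellation <- function(params) {
  dims <- as.integer(params$grid_shape)
  nreg <- as.integer(params$n_regions_per_hemisphere)
  assert_that(length(dims) == 3 && all(dims >= 1),
              "grid_shape must be three positive integers")
  assert_that(nreg >= 1, "n_regions_per_hemisphere must be >= 1")
  nx <- dims[1L]
  half <- nx %/% 2L
  if (half < 1L || prod(half, dims[2L], dims[3L]) < nreg)
    stop_chacomed("grid too small for ", nreg, " regions per hemisphere",
                  class = "chacomed_sizing")

  labels <- array(0L, dim = dims)
  hemi_of_voxel <- array("R", dim = dims)
  hemi_of_voxel[seq_len(half), , ] <- "L"

  lobes <- c("frontal", "parietal", "temporal", "occipital", "limbic",
             "subcortical")
  regions <- data.frame(
    id = seq_len(2L * nreg),
    name = c(sprintf("L%02d", seq_len(nreg)), sprintf("R%02d", seq_len(nreg))),
    hemisphere = rep(c("L", "R"), each = nreg),
    lobe = rep(lobes[((seq_len(nreg) - 1L) %% length(lobes)) + 1L], 2L),
    stringsAsFactors = FALSE
  )

  # slice each hemisphere into near-equal contiguous chunks in (y, z, x) order
  for (h in c("L", "R")) {
    xs <- if (h == "L") seq_len(half) else (half + 1L):nx
    vox <- as.matrix(expand.grid(x = xs, y = seq_len(dims[2L]),
                                 z = seq_len(dims[3L])))
    ord <- order(vox[, "z"], vox[, "y"], vox[, "x"])
    vox <- vox[ord, , drop = FALSE]
    cut_id <- ceiling(seq_along(ord) / (nrow(vox) / nreg))
    cut_id <- pmin(cut_id, nreg)
    offset <- if (h == "L") 0L else nreg
    labels[vox] <- as.integer(cut_id) + offset
  }

  structure(
    list(labels = labels, regions = regions,
         voxel_size_mm = params$voxel_size_mm,
         hemi_of_voxel = hemi_of_voxel),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation> ", paste(dim(x$labels), collapse = "x"),
      " grid, ", nrow(x$regions), " regions (",
      sum(x$regions$hemisphere == "L"), " L / ",
      sum(x$regions$hemisphere == "R"), " R), voxel ",
      x$voxel_size_mm, " mm\n", sep = "")
  invisible(x)
}

# region ids for one hemisphere, in within-hemisphere order
hemisphere_regions <- function(parcellation, hemisphere) {
  parcellation$regions$id[parcellation$regions$hemisphere == hemisphere]
}

# hemisphere ("L"/"R") of a lesion; errors on bilateral lesions
lesion_hemisphere <- function(lesion, parcellation) {
  idx <- which(lesion$mask)
  assert_that(length(idx) > 0, "empty lesion has no hemisphere")
  hemis <- unique(parcellation$hemi_of_voxel[idx])
  if (length(hemis) > 1L)
    stop_chacomed("bilateral lesion: voxels in both hemispheres",
                  class = "chacomed_bilateral")
  hemis
}
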