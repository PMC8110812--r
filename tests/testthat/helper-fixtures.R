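# Shared fixtures: hand-built toy parcellations/tractograms and an
# independent brute-force ChaCo enumerator used as oracle.

# parcellation built directly from a label array (bypasses the generator,
# so generator and scorer can be tested against each other)
manual_parcellation <- function(labels, hemispheres, voxel_size_mm = 1) {
  ids <- sort(unique(labels[labels > 0]))
  dims <- dim(labels)
  hemi_of_voxel <- array(hemispheres[1], dim = dims)
  if (length(hemispheres) > 1) {
    half <- dims[1] %/% 2
    hemi_of_voxel[seq_len(half), , ] <- "L"
    hemi_of_voxel[(half + 1):dims[1], , ] <- "R"
  }
  structure(list(
    labels = labels,
    regions = data.frame(id = ids, name = paste0("reg", ids),
                         hemisphere = vapply(ids, function(r) {
                           v <- which(labels == r)
                           hemi_of_voxel[v[1]]
                         }, ""),
                         lobe = "frontal", stringsAsFactors = FALSE),
    voxel_size_mm = voxel_size_mm,
    hemi_of_voxel = hemi_of_voxel), class = "parcellation")
}

# the worked 3-streamline toy: regions A=1, B=2 on a 4x1x1 grid;
# s1 (A-B) through voxels 1,2; s2 (A-B) at voxel 3; s3 (B-B) at voxel 4
toy_tractogram_abc <- function() {
  labels <- array(c(1L, 1L, 2L, 2L), dim = c(4L, 1L, 1L))
  parc <- manual_parcellation(labels, "L")
  sl <- list(rbind(c(1L, 1L, 1L), c(3L, 1L, 1L)),   # s1: A-B, voxels 1,3
             rbind(c(2L, 1L, 1L), c(4L, 1L, 1L)),   # s2: A-B, voxels 2,4
             rbind(c(3L, 1L, 1L), c(4L, 1L, 1L)))   # s3: B-B, voxels 3,4
  tg <- assign_endpoints(tractogram("toy", sl), parc)
  list(parc = parc, tg = tg)
}

toy_lesion <- function(parc, voxels) {
  m <- array(FALSE, dim = dim(parc$labels))
  for (i in seq_len(nrow(voxels))) m[matrix(voxels[i, ], 1)] <- TRUE
  lesion_mask(m, parc$voxel_size_mm)
}

# Independent brute-force ChaCo enumerator: plain loops over streamlines
# and voxels, no shared code with the implementation's vectorized path.
chaco_brute <- function(tg, parc, lesion) {
  ids <- parc$regions$id
  lesion_vox <- which(lesion$mask, arr.ind = TRUE)
  hit_one <- function(s) {
    for (i in seq_len(nrow(s))) {
      for (j in seq_len(nrow(lesion_vox))) {
        if (all(s[i, ] == lesion_vox[j, ])) return(TRUE)
      }
    }
    FALSE
  }
  out <- setNames(numeric(length(ids)), as.character(ids))
  for (r in ids) {
    total <- 0L
    hits <- 0L
    for (k in seq_along(tg$streamlines)) {
      ep <- tg$endpoints[k, ]
      if (r %in% ep) {
        total <- total + 1L
        if (nrow(lesion_vox) > 0 && hit_one(tg$streamlines[[k]]))
          hits <- hits + 1L
      }
    }
    out[as.character(r)] <- if (total == 0L) NA_real_ else hits / total
  }
  out
}

# random toy instance: a parcellation with <= 8 regions on a small grid,
# one tractogram with <= max_streamlines random paths, one random lesion
random_toy <- function(max_streamlines = 50, max_regions = 8) {
  dims <- c(sample(4:8, 1), sample(2:5, 1), sample(2:5, 1))
  nreg <- sample(2:max_regions, 1)
  labels <- array(sample.int(nreg, prod(dims), replace = TRUE), dim = dims)
  parc <- manual_parcellation(labels, c("L", "R"))
  n_sl <- sample.int(max_streamlines, 1)
  sl <- lapply(seq_len(n_sl), function(i) {
    len <- sample(2:6, 1)
    cbind(sample.int(dims[1], len, replace = TRUE),
          sample.int(dims[2], len, replace = TRUE),
          sample.int(dims[3], len, replace = TRUE))
  })
  tg <- assign_endpoints(tractogram("rand", sl), parc)
  lesion <- lesion_mask(array(runif(prod(dims)) < 0.15, dim = dims), 1)
  list(parc = parc, tg = tg, lesion = lesion)
}

# small fast generator params for module tests (overridable defaults)
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(12L, 8L, 8L), voxel_size_mm = 3,
         n_regions_per_hemisphere = 4L, n_reference_subjects = 3L,
         streamlines_per_region_pair = 3L, eloquent_regions = c(2L, 3L)),
    list(...))
  do.call(cohort_params, args)
}
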