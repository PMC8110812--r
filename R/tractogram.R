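# Synthetic reference tractograms: streamlines as voxelized paths between
# region pairs, with per-subject geometric jitter so reference subjects
# differ while sharing the same gross anatomy.

#' Generate a set of synthetic reference tractograms
#'
#' For every within-hemisphere region pair (self-pairs included with
#' probability `self_pair_rate`) each reference subject receives
#' `streamlines_per_region_pair` streamlines. A streamline is an ordered
#' voxel path whose two endpoints lie in the pair's regions. Endpoints and
#' the base path shape are drawn from a pair-specific stream shared by all
#' subjects; each subject bends the path interior by a random perpendicular
#' offset with standard deviation `path_jitter` (in voxels), so
#' `path_jitter = 0` makes all subjects identical.
#'
#' @param parcellation a [make_parcellation()] result.
#' @param params a [cohort_params()] list; uses `n_reference_subjects`,
#'   `streamlines_per_region_pair`, `self_pair_rate`, `path_jitter`, `seed`.
#' @param n_subjects optional override of `params$n_reference_subjects`.
#' @return object of class `reference_set`: list of `tractogram` objects
#'   (fields `subject_id`, `streamlines` (list of n x 3 integer voxel
#'   matrices), `endpoints`, `totals`, `n_dropped`), all with endpoint
#'   regions assigned against `parcellation`.
#' @export
make_reference_tractograms <- function(parcellation, params,
                                       n_subjects = NULL) {
  n_subjects <- as.integer(n_subjects %||% params$n_reference_subjects)
  assert_that(n_subjects >= 1, "need at least one reference subject")
  dims <- dim(parcellation$labels)
  nspp <- as.integer(params$streamlines_per_region_pair)
  regions <- parcellation$regions

  region_vox <- lapply(regions$id, function(r)
    which(parcellation$labels == r, arr.ind = TRUE))

  pairs <- list()
  for (h in c("L", "R")) {
    ids <- hemisphere_regions(parcellation, h)
    for (i in seq_along(ids)) for (j in i:length(ids)) {
      a <- ids[i]; b <- ids[j]
      if (a == b) {
        keep <- with_seed(derive_seed(params$seed, "selfpair", a),
                          runif(1) < params$self_pair_rate)
        if (!keep) next
      }
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }

  # pair-level base geometry, shared across subjects
  base <- lapply(seq_along(pairs), function(pi) {
    pr <- pairs[[pi]]
    with_seed(derive_seed(params$seed, "pairbase", pr[1], pr[2]), {
      lapply(seq_len(nspp), function(k) {
        va <- region_vox[[pr[1]]]
        vb <- region_vox[[pr[2]]]
        p0 <- va[sample.int(nrow(va), 1L), ]
        p1 <- vb[sample.int(nrow(vb), 1L), ]
        list(from = as.integer(p0), to = as.integer(p1),
             bend_dir = rnorm(3))
      })
    })
  })

  subjects <- lapply(seq_len(n_subjects), function(s) {
    sl <- list()
    with_seed(derive_seed(params$seed, "subject", s), {
      for (pi in seq_along(pairs)) {
        for (k in seq_len(nspp)) {
          g <- base[[pi]][[k]]
          off <- rnorm(3, sd = params$path_jitter)
          sl[[length(sl) + 1L]] <- voxel_path(g$from, g$to,
                                              g$bend_dir * sqrt(sum(off^2)),
                                              dims)
        }
      }
    })
    tg <- tractogram(sprintf("ref%03d", s), sl)
    assign_endpoints(tg, parcellation)
  })

  for (s in subjects) {
    zero <- names(s$totals)[s$totals == 0]
    if (length(zero))
      stop_chacomed("region(s) with zero streamlines in subject ",
                    s$subject_id, ": ", paste(zero, collapse = ", "),
                    class = "chacomed_generation")
  }
  structure(subjects, class = "reference_set")
}

# Quadratic-bezier voxel path from `from` to `to` with a mid-path control
# offset `bend` (numeric length-3); densely sampled, rounded to the grid,
# clipped, consecutive duplicates removed. Endpoints are preserved exactly.
voxel_path <- function(from, to, bend, dims) {
  n_steps <- max(2L, 2L * sum(abs(to - from)) + 4L)
  t <- seq(0, 1, length.out = n_steps)
  mid <- (from + to) / 2 + bend
  path <- outer((1 - t)^2, from) + outer(2 * t * (1 - t), mid) +
    outer(t^2, to)
  path <- round(path)
  path[, 1] <- pmin(pmax(path[, 1], 1), dims[1])
  path[, 2] <- pmin(pmax(path[, 2], 1), dims[2])
  path[, 3] <- pmin(pmax(path[, 3], 1), dims[3])
  path[1, ] <- from
  path[nrow(path), ] <- to
  keep <- c(TRUE, rowSums(abs(diff(path))) > 0)
  storage.mode(path) <- "integer"
  path[keep, , drop = FALSE]
}

#' Construct a tractogram from a list of streamline voxel paths
#'
#' @param subject_id identifier.
#' @param streamlines list of n x 3 integer matrices (ordered voxel paths,
#'   each with at least 2 rows... a single-voxel path is accepted and
#'   treated as a degenerate streamline whose two endpoints coincide).
#' @return object of class `tractogram`; endpoint regions and per-region
#'   totals are unset until [assign_endpoints()] is called.
#' @export
tractogram <- function(subject_id, streamlines) {
  assert_that(length(streamlines) > 0, "empty tractogram",
              class = "chacomed_empty")
  structure(list(subject_id = subject_id, streamlines = streamlines,
                 endpoints = NULL, totals = NULL, n_dropped = 0L),
            class = "tractogram")
}

#' Assign endpoint regions and per-region connectivity totals
#'
#' Each streamline's first and last voxel are looked up in the parcellation
#' label volume. Streamlines with an unlabelled (background) endpoint are
#' dropped and counted in `n_dropped`. The total connectivity of region r
#' is the number of streamlines with r among their endpoint regions; a
#' streamline connecting a region to itself counts once, so per-region
#' disconnection proportions are bounded by one.
#'
#' @param tg a [tractogram()].
#' @param parcellation a parcellation on the same grid.
#' @return the tractogram with `endpoints` (n x 2 integer matrix), `totals`
#'   (named integer vector over all regions) and `n_dropped` filled in.
#' @export
assign_endpoints <- function(tg, parcellation) {
  assert_that(inherits(tg, "tractogram"), "expected a tractogram")
  assert_that(length(tg$streamlines) > 0, "empty tractogram",
              class = "chacomed_empty")
  dims <- dim(parcellation$labels)
  ep <- t(vapply(tg$streamlines, function(s) {
    c(parcellation$labels[matrix(s[1L, ], 1L)],
      parcellation$labels[matrix(s[nrow(s), ], 1L)])
  }, integer(2)))
  ok <- ep[, 1L] > 0L & ep[, 2L] > 0L
  tg$n_dropped <- sum(!ok)
  tg$streamlines <- tg$streamlines[ok]
  tg$endpoints <- ep[ok, , drop = FALSE]
  ids <- parcellation$regions$id
  totals <- integer(length(ids))
  names(totals) <- as.character(ids)
  for (r in seq_along(ids)) {
    totals[r] <- sum(tg$endpoints[, 1L] == ids[r] |
                       tg$endpoints[, 2L] == ids[r])
  }
  tg$totals <- totals
  tg
}

#' @export
print.tractogram <- function(x, ...) {
  cat("<tractogram> ", x$subject_id, ": ", length(x$streamlines),
      " streamlines", if (x$n_dropped) paste0(" (", x$n_dropped, " dropped)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> ", length(x), " subjects, ",
      length(x[[1]]$streamlines), " streamlines each\n", sep = "")
  invisible(x)
}
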