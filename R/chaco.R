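# Change-of-Connectivity (ChaCo) scoring: per-region disconnection
# obtained by intersecting a binary lesion mask with reference
# tractograms. For a region r and one reference subject, the score is the
# number of streamlines that (a) have r among their endpoint regions and
# (b) pass through at least one lesion voxel, divided by the total
# connectivity of r. The ChaCo score is the mean of these proportions
# across reference subjects: 0 = intact, 1 = complete disconnection.

#' Streamlines passing through a lesion
#'
#' A streamline is hit iff any of its path voxels (endpoints included) is a
#' lesion voxel.
#'
#' @param tg a [tractogram()] (endpoint assignment not required).
#' @param lesion a [lesion_mask()] on the same grid.
#' @return integer vector of streamline indices.
#' @export
lesion_hits <- function(tg, lesion) {
  assert_that(inherits(lesion, "lesion_mask"), "expected a lesion_mask")
  dims <- dim(lesion$mask)
  first <- tg$streamlines[[1]]
  if (any(first > rep(dims, each = nrow(first))))
    stop_chacomed("streamline voxels outside lesion grid",
                  class = "chacomed_grid_mismatch")
  if (!any(lesion$mask)) return(integer(0))
  which(vapply(tg$streamlines, function(s) {
    any(lesion$mask[voxel_linear(s, dims)])
  }, logical(1)))
}

#' Per-region disconnection proportions for one reference subject
#'
#' @param tg a tractogram with endpoints assigned ([assign_endpoints()]).
#' @param parcellation the shared parcellation.
#' @param lesion a [lesion_mask()].
#' @return named numeric vector over all regions; regions with zero total
#'   connectivity are `NA` (undefined, not silently 0) and listed in the
#'   `undefined` attribute.
#' @export
chaco_single <- function(tg, parcellation, lesion) {
  assert_that(!is.null(tg$totals),
              "endpoints/totals not assigned; call assign_endpoints() first")
  hits <- lesion_hits(tg, lesion)
  ids <- parcellation$regions$id
  score <- setNames(numeric(length(ids)), as.character(ids))
  if (length(hits)) {
    ep <- tg$endpoints[hits, , drop = FALSE]
    for (r in seq_along(ids)) {
      score[r] <- sum(ep[, 1L] == ids[r] | ep[, 2L] == ids[r])
    }
  }
  undef <- tg$totals == 0L
  score <- score / ifelse(undef, NA_real_, tg$totals)
  attr(score, "undefined") <- names(score)[undef]
  score
}

#' ChaCo profile: mean disconnection over a reference set
#'
#' @param refs a [make_reference_tractograms()] result (or list of
#'   endpoint-assigned tractograms).
#' @param parcellation the shared parcellation.
#' @param lesion a [lesion_mask()].
#' @param time time-point label, e.g. `"T1"`.
#' @param subject_id id of the lesioned patient.
#' @param strict if `TRUE`, a region undefined (zero total connectivity) in
#'   any reference subject is an error; otherwise that subject is excluded
#'   from the region's mean and recorded in the diagnostics.
#' @return object of class `chaco_profile`: list with `scores` (named
#'   vector over regions), `raw` (regions x subjects matrix of per-subject
#'   proportions), `time`, `subject_id`, `undefined` (region ids undefined
#'   in at least one subject).
#' @export
chaco_score <- function(refs, parcellation, lesion, time = "T1",
                        subject_id = NA_character_, strict = FALSE) {
  assert_that(length(refs) >= 1, "need at least one reference subject")
  raw <- vapply(refs, function(tg) chaco_single(tg, parcellation, lesion),
                numeric(nrow(parcellation$regions)))
  raw <- matrix(raw, nrow = nrow(parcellation$regions),
                dimnames = list(as.character(parcellation$regions$id),
                                vapply(refs, function(t) t$subject_id, "")))
  undef <- rownames(raw)[apply(raw, 1L, function(x) any(is.na(x)))]
  if (strict && length(undef))
    stop_chacomed("region(s) undefined in some reference subject: ",
                  paste(undef, collapse = ", "),
                  class = "chacomed_undefined_region")
  scores <- rowMeans(raw, na.rm = TRUE)
  scores[is.nan(scores)] <- NA_real_
  structure(list(scores = scores, raw = raw, time = time,
                 subject_id = subject_id, undefined = undef),
            class = "chaco_profile")
}

#' Restrict a ChaCo profile to the stroke hemisphere
#'
#' Disconnection is analysed for regions of the lesioned hemisphere only;
#' patients with bilateral lesions are excluded (error). Streamlines
#' crossing from the other hemisphere still contributed to totals and hits
#' when the profile was computed; restriction only drops contralateral
#' *regions* from the output.
#'
#' @param profile a [chaco_score()] result.
#' @param lesion the lesion the profile was computed for.
#' @param parcellation the shared parcellation.
#' @return the profile restricted to stroke-hemisphere regions, with a
#'   `hemisphere` field added.
#' @export
restrict_to_stroke_hemisphere <- function(profile, lesion, parcellation) {
  hemi <- lesion_hemisphere(lesion, parcellation)
  keep <- as.character(hemisphere_regions(parcellation, hemi))
  profile$scores <- profile$scores[keep]
  profile$raw <- profile$raw[keep, , drop = FALSE]
  profile$undefined <- intersect(profile$undefined, keep)
  profile$hemisphere <- hemi
  profile
}

#' Within-subject change of disconnection between two time points
#'
#' `delta_r = score_T2_r - score_T1_r`. Because both profiles are computed
#' against the same reference tractograms, the difference is interpreted as
#' the absolute within-subject loss of connectivity; negative values are
#' allowed (lesion shrinkage).
#'
#' @param profile_T1,profile_T2 [chaco_score()] results for the same
#'   subject on the same region set.
#' @return named numeric vector of per-region deltas.
#' @export
chaco_change <- function(profile_T1, profile_T2) {
  assert_that(identical(names(profile_T1$scores), names(profile_T2$scores)),
              "profiles cover different region sets",
              class = "chacomed_region_mismatch")
  profile_T2$scores - profile_T1$scores
}

#' @export
print.chaco_profile <- function(x, ...) {
  cat("<chaco_profile> subject ", x$subject_id, " time ", x$time, ": ",
      length(x$scores), " regions, mean score ",
      signif(mean(x$scores, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Long-format ChaCo table for a cohort
#'
#' One row per subject x region x time with treatment arm and
#' log-transformed lesion volume, the layout consumed by [fit_mixture()]
#' and written by the pipeline.
#'
#' @param cohort an imaging-mode [generate_cohort()] result.
#' @return data.frame with columns `subject`, `region`, `hemisphere`,
#'   `time`, `treatment`, `chaco`, `volume`.
#' @export
cohort_chaco_long <- function(cohort) {
  assert_that(cohort$mode == "imaging",
              "ChaCo long table requires an imaging-mode cohort")
  rows <- lapply(cohort$patients, function(p) {
    do.call(rbind, lapply(c("T1", "T2"), function(tp) {
      pr <- p$chaco[[tp]]
      data.frame(subject = p$id, region = names(pr$scores),
                 hemisphere = pr$hemisphere, time = tp, treatment = p$arm,
                 chaco = unname(pr$scores),
                 volume = if (tp == "T1") p$vol_T1 else p$vol_T2,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
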