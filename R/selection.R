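# Data-driven selection of mediator regions: rank regions by
# alteplase-responsiveness (association of dChaCo with treatment) and
# clinical eloquence (association of dChaCo with favorable outcome),
# qualify candidates whose 95% CIs both exclude the null, and enumerate
# the distinct mediation models generated by sweeping the two inclusion
# thresholds.

dchaco_columns <- function(tab) grep("^dchaco_", names(tab), value = TRUE)

# analysis subsample and standardized design shared by both scans: rows
# with non-missing outcome, dChaCo standardized on that subsample
scan_data <- function(cohort) {
  tab <- if (inherits(cohort, "cohort")) cohort$table else cohort
  tab <- tab[!is.na(tab$favorable), ]
  tab$armA <- as.integer(tab$arm == "A")
  tab$log_vol_T1 <- log(pmax(tab$vol_T1, 5e-4))
  tab
}

#' Alteplase-responsiveness scan
#'
#' Per region, linear regression of the standardized change in ChaCo on
#' treatment allocation, adjusted for age, baseline NIHSS and log baseline
#' volume; reports the standardized coefficient (Beta) of treatment with
#' Wald 95% CI and p. Computed on the subsample with non-missing outcome
#' so both scans share one design. Zero-variance regions are skipped with
#' a diagnostic.
#'
#' @param cohort a [generate_cohort()] result or cohort table with
#'   `dchaco_*` columns.
#' @return data.frame: `region`, `beta`, `lo`, `hi`, `p`, `skipped`.
#' @export
responsiveness_scan <- function(cohort) {
  tab <- scan_data(cohort)
  cols <- dchaco_columns(tab)
  assert_that(length(cols) > 0, "no dchaco_* columns found")
  rows <- lapply(cols, function(cl) {
    y <- tab[[cl]]
    if (sd(y) == 0 || anyNA(y))
      return(data.frame(region = cl, beta = NA_real_, lo = NA_real_,
                        hi = NA_real_, p = NA_real_, skipped = TRUE))
    z <- as.numeric(scale(y))
    fit <- stats::lm(z ~ armA + age + nihss + log_vol_T1, data = tab)
    sm <- summary(fit)$coefficients["armA", ]
    data.frame(region = cl, beta = sm[1], lo = sm[1] - 1.96 * sm[2],
               hi = sm[1] + 1.96 * sm[2], p = sm[4], skipped = FALSE,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Clinical-eloquence scan
#'
#' Per region, logistic regression of favorable outcome on the
#' standardized change in ChaCo, adjusted for age, baseline NIHSS and log
#' baseline volume; reports the standardized odds ratio (per SD of
#' dChaCo) with Wald 95% CI and p. Rescaling dChaCo leaves the OR
#' unchanged. Separation is flagged; the region is retained with its
#' (unreliable) Wald summary rather than dropped.
#'
#' @inheritParams responsiveness_scan
#' @return data.frame: `region`, `or`, `lo`, `hi`, `p`, `separation`.
#' @export
eloquence_scan <- function(cohort) {
  tab <- scan_data(cohort)
  cols <- dchaco_columns(tab)
  rows <- lapply(cols, function(cl) {
    y <- tab[[cl]]
    if (sd(y) == 0 || anyNA(y))
      return(data.frame(region = cl, or = NA_real_, lo = NA_real_,
                        hi = NA_real_, p = NA_real_, separation = NA))
    tab$z <- as.numeric(scale(y))
    fit <- suppressWarnings(glm(favorable ~ z + age + nihss + log_vol_T1,
                                data = tab, family = binomial()))
    sep <- !fit$converged || abs(coef(fit)["z"]) > 15
    sm <- summary(fit)$coefficients["z", ]
    data.frame(region = cl, or = exp(sm[1]), lo = exp(sm[1] - 1.96 * sm[2]),
               hi = exp(sm[1] + 1.96 * sm[2]), p = sm[4], separation = sep,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

# deterministic "strength of evidence" ordering: ascending p, ties broken
# by descending absolute standardized effect, then region id
rank_regions <- function(scan, effect_col, null_value) {
  eff <- abs(if (null_value == 1) log(scan[[effect_col]])
             else scan[[effect_col]])
  ord <- order(scan$p, -eff, scan$region, na.last = TRUE)
  scan$region[ord]
}

#' Qualify mediator candidates and rank regions
#'
#' Regions are ordered by statistical evidence (ascending p) within each
#' criterion; a region qualifies as a potential mediator iff its
#' responsiveness CI excludes 0 *and* its eloquence CI excludes 1. The
#' Spearman correlation between the two rank orderings is reported.
#'
#' @param resp a [responsiveness_scan()] result.
#' @param eloq an [eloquence_scan()] result.
#' @return list of class `region_ranking`: `table` (region, both effects,
#'   both ranks, `qualified`), `resp_order`, `eloq_order`, `qualified`,
#'   `spearman_rho`.
#' @export
qualify_and_rank <- function(resp, eloq) {
  assert_that(identical(resp$region, eloq$region),
              "scans cover different regions")
  resp_order <- rank_regions(resp, "beta", 0)
  eloq_order <- rank_regions(eloq, "or", 1)
  qualified <- resp$region[
    !is.na(resp$lo) & (resp$lo > 0 | resp$hi < 0) &
      !is.na(eloq$lo) & (eloq$lo > 1 | eloq$hi < 1)]
  if (!length(qualified))
    warning("no region qualifies; downstream mediation is growth-only",
            call. = FALSE)
  tabl <- data.frame(
    region = resp$region, beta = resp$beta, beta_lo = resp$lo,
    beta_hi = resp$hi, beta_p = resp$p,
    rank_resp = match(resp$region, resp_order),
    or = eloq$or, or_lo = eloq$lo, or_hi = eloq$hi, or_p = eloq$p,
    rank_eloq = match(resp$region, eloq_order),
    qualified = resp$region %in% qualified, stringsAsFactors = FALSE)
  rho <- suppressWarnings(cor(tabl$rank_resp, tabl$rank_eloq,
                              method = "spearman"))
  structure(list(table = tabl, resp_order = resp_order,
                 eloq_order = eloq_order, qualified = qualified,
                 spearman_rho = rho),
            class = "region_ranking")
}

#' Enumerate distinct mediation models from threshold sweeps
#'
#' For every pair of inclusion thresholds `(i <= i_max, j <= j_max)` the
#' mediator set is the intersection of the `i` most responsive regions,
#' the `j` most eloquent regions, and the qualified set. Distinct
#' non-empty sets become mediation model specifications (infarct growth is
#' always included as a co-mediator); each spec records every generating
#' `(i, j)` pair. If no set is non-empty, the growth-only spec is returned
#' with a warning.
#'
#' @param ranking a [qualify_and_rank()] result.
#' @param i_max,j_max largest thresholds swept (defaults 9 and 15).
#' @return list of `mediation_spec` objects (see [mediation_spec()]); the
#'   growth-only spec is always first.
#' @export
enumerate_models <- function(ranking, i_max = 9, j_max = 15) {
  specs <- list(mediation_spec(character(0), label = "growth_only"))
  seen <- list()
  prov <- list()
  for (i in seq_len(min(i_max, length(ranking$resp_order)))) {
    for (j in seq_len(min(j_max, length(ranking$eloq_order)))) {
      set <- intersect(intersect(head(ranking$resp_order, i),
                                 head(ranking$eloq_order, j)),
                       ranking$qualified)
      if (!length(set)) next
      key <- paste(sort(set), collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- length(specs) + 1L
        specs[[length(specs) + 1L]] <-
          mediation_spec(sort(set),
                         label = sprintf("model_%02d", length(specs)))
      }
      k <- seen[[key]]
      specs[[k]]$provenance <- rbind(specs[[k]]$provenance,
                                     data.frame(i = i, j = j))
    }
  }
  if (length(specs) == 1L)
    warning("threshold sweep produced no region set; growth-only model",
            call. = FALSE)
  specs
}
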