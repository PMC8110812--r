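# Counterfactual multiple-mediator mediation via inverse-probability
# weighting (ratio-of-mediator-probability weighting):
#   NDE = odds(P_{T,M|P}) / odds(P_{P,M|P})
#   NIE = odds(P_{T,M|T}) / odds(P_{T,M|P})
#   TE  = NIE * NDE                 (identity, by construction)
#   proportion mediated = log(NIE) / log(TE)
# The mediator set always contains infarct growth; a connectivity-only
# indirect effect is not statistically identified and is deliberately not
# offered by this API.

#' Specify a mediation model
#'
#' A mediator set is a (possibly empty) collection of dChaCo region
#' columns; infarct growth (`log2_growth`) is always included as a
#' co-mediator, so the empty set is the growth-only model.
#'
#' @param regions character vector of `dchaco_*` column names (or integer
#'   within-hemisphere region indices).
#' @param label model label.
#' @return object of class `mediation_spec` with `regions`, `label`,
#'   `provenance` (filled by [enumerate_models()]).
#' @export
mediation_spec <- function(regions = character(0), label = NULL) {
  if (is.numeric(regions)) regions <- paste0("dchaco_", regions)
  label <- label %||%
    if (length(regions)) paste(regions, collapse = "+") else "growth_only"
  structure(list(regions = regions, label = label, provenance = NULL),
            class = "mediation_spec")
}

#' @export
print.mediation_spec <- function(x, ...) {
  cat("<mediation_spec> ", x$label, ": growth",
      if (length(x$regions)) paste0(" + ", paste(x$regions, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

# fast logistic fit returning fitted probabilities; falls back to glm.fit
# when the compiled IRLS does not converge
fit_logistic_prob <- function(X, y) {
  f <- logistic_irls_cpp(X, y)
  if (!f$converged || anyNA(f$coef)) {
    g <- suppressWarnings(glm.fit(X, y, family = binomial()))
    return(as.numeric(g$fitted.values))
  }
  as.numeric(f$fitted)
}

truncate_weights <- function(w, probs) {
  if (is.null(probs)) return(list(w = w, n_truncated = 0L))
  q <- quantile(w, probs, names = FALSE)
  list(w = pmin(pmax(w, q[1]), q[2]),
       n_truncated = sum(w < q[1] | w > q[2]))
}

# analysis design shared by point estimation and bootstrap
med_design <- function(cohort, covariates = c("age", "nihss", "log_vol_T1")) {
  tab <- if (inherits(cohort, "cohort")) cohort$table else cohort
  if (is.null(tab$log_vol_T1)) tab$log_vol_T1 <- log(pmax(tab$vol_T1, 5e-4))
  tab <- tab[!is.na(tab$favorable), ]
  list(A = as.numeric(tab$arm == "A"),
       Y = as.numeric(tab$favorable),
       C = as.matrix(tab[, covariates, drop = FALSE]),
       M_all = as.matrix(tab[, c("log2_growth", dchaco_columns(tab)),
                             drop = FALSE]),
       n = nrow(tab))
}

mediator_matrix <- function(design, spec) {
  cols <- c("log2_growth", spec$regions)
  design$M_all[, cols, drop = FALSE]
}

# core IPW estimator on raw vectors/matrices (hot path: no data.frame).
# pT_C may be supplied to share the exposure-given-covariates fit across
# several mediator sets on the same data (joint bootstrap).
ipw_probs <- function(A, Y, C, M, truncate = c(0.01, 0.99),
                      overlap_floor = 1e-6, pT_C = NULL) {
  X_MC <- cbind(1, M, C)
  if (is.null(pT_C)) pT_C <- fit_logistic_prob(cbind(1, C), A)
  pT_MC <- fit_logistic_prob(X_MC, A)
  bad <- pmin(pT_C, 1 - pT_C, pT_MC, 1 - pT_MC) < overlap_floor
  if (any(bad))
    stop_chacomed("non-overlap: fitted exposure probability below floor ",
                  "for subject(s) ", paste(which(bad), collapse = ", "),
                  class = "chacomed_nonoverlap")
  tr <- A == 1
  n_trunc <- 0L

  wTT <- 1 / pT_C[tr]
  tw <- truncate_weights(wTT, truncate); wTT <- tw$w
  n_trunc <- n_trunc + tw$n_truncated
  P_T_M_T <- sum(wTT * Y[tr]) / sum(wTT)

  wPP <- 1 / (1 - pT_C[!tr])
  tw <- truncate_weights(wPP, truncate); wPP <- tw$w
  n_trunc <- n_trunc + tw$n_truncated
  P_P_M_P <- sum(wPP * Y[!tr]) / sum(wPP)

  wTP <- ((1 - pT_MC[tr]) / pT_MC[tr]) / (1 - pT_C[tr])
  tw <- truncate_weights(wTP, truncate); wTP <- tw$w
  n_trunc <- n_trunc + tw$n_truncated
  P_T_M_P <- sum(wTP * Y[tr]) / sum(wTP)

  list(P_T_M_T = P_T_M_T, P_T_M_P = P_T_M_P, P_P_M_P = P_P_M_P,
       n_truncated = n_trunc, n = length(A))
}

#' Counterfactual outcome probabilities by inverse-probability weighting
#'
#' Estimates the three counterfactual probabilities of favorable outcome
#' from a randomized (or confounded) cohort. `P_{T,M|T}` and `P_{P,M|P}`
#' are covariate-weighted outcome means in the respective arms (weights
#' `1/P(A = a | C)`); the cross-world term `P_{T,M|P}` reweights treated
#' subjects by the ratio of fitted exposure odds given mediators and
#' covariates, `[P(A=P|M,C)/P(A=T|M,C)] / P(A=P|C)`. Both exposure models
#' are simple logistic regressions with linear mediator and covariate
#' terms. All weights are normalized within arm (Hajek estimator);
#' extreme weights are truncated at configurable quantiles.
#'
#' @param cohort a [generate_cohort()] result or cohort table; subjects
#'   with missing outcome are excluded.
#' @param spec a [mediation_spec()] naming the dChaCo mediators (growth is
#'   always included).
#' @param covariates covariate column names entering both exposure models.
#' @param truncate weight truncation quantiles (`NULL` to disable).
#' @param overlap_floor smallest tolerated fitted exposure probability;
#'   below it an error lists the offending subjects.
#' @return object of class `counterfactual_probs`: `P_T_M_T`, `P_T_M_P`,
#'   `P_P_M_P`, `n_truncated`, `n`.
#' @export
counterfactual_probabilities <- function(cohort, spec = mediation_spec(),
                                         covariates = c("age", "nihss",
                                                        "log_vol_T1"),
                                         truncate = c(0.01, 0.99),
                                         overlap_floor = 1e-6) {
  d <- med_design(cohort, covariates)
  p <- ipw_probs(d$A, d$Y, d$C, mediator_matrix(d, spec), truncate,
                 overlap_floor)
  structure(p, class = "counterfactual_probs")
}

#' Natural effects on the odds-ratio scale
#'
#' @param probs list with `P_T_M_T`, `P_T_M_P`, `P_P_M_P`, all in (0, 1)
#'   (e.g. a [counterfactual_probabilities()] result).
#' @return object of class `natural_effects`: `nde`, `nie`, `te`
#'   (`te = nie * nde` exactly), `pm` (`log(nie)/log(te)`; `NA` and
#'   flagged when `te = 1`), and the input `probs`.
#' @export
natural_effects <- function(probs) {
  p <- unlist(probs[c("P_T_M_T", "P_T_M_P", "P_P_M_P")])
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1))
    stop_chacomed("counterfactual probabilities must lie strictly in (0,1)",
                  class = "chacomed_degenerate")
  odds <- function(q) q / (1 - q)
  nde <- odds(probs$P_T_M_P) / odds(probs$P_P_M_P)
  nie <- odds(probs$P_T_M_T) / odds(probs$P_T_M_P)
  te <- nie * nde
  pm_defined <- abs(log(te)) > .Machine$double.eps^0.5
  pm <- if (pm_defined) log(nie) / log(te) else NA_real_
  structure(list(nde = nde, nie = nie, te = te, pm = pm,
                 pm_defined = pm_defined,
                 probs = probs[c("P_T_M_T", "P_T_M_P", "P_P_M_P")]),
            class = "natural_effects")
}

#' @export
print.natural_effects <- function(x, ...) {
  cat(sprintf("<natural_effects> NDE %.3f  NIE %.3f  TE %.3f  PM %s\n",
              x$nde, x$nie, x$te,
              if (x$pm_defined) sprintf("%.1f%%", 100 * x$pm)
              else "undefined (TE = 1)"))
  invisible(x)
}

#' Estimate natural effects for one mediation model
#'
#' Convenience wrapper: [counterfactual_probabilities()] followed by
#' [natural_effects()].
#'
#' @inheritParams counterfactual_probabilities
#' @return a `natural_effects` object.
#' @export
estimate_mediation <- function(cohort, spec = mediation_spec(),
                               covariates = c("age", "nihss", "log_vol_T1"),
                               truncate = c(0.01, 0.99)) {
  natural_effects(counterfactual_probabilities(cohort, spec, covariates,
                                               truncate))
}

#' Joint bootstrap of natural effects across mediation models
#'
#' Subject-level resampling with replacement; within each replicate every
#' model spec (including growth-only) is estimated on the *same* resample,
#' preserving the joint distribution of effects across models. Replicates
#' on which estimation degenerates (single arm drawn, non-overlap,
#' boundary probabilities) are redrawn and counted.
#'
#' @param cohort cohort or table (missing outcomes excluded).
#' @param specs list of [mediation_spec()]s.
#' @param k number of bootstrap resamples (>= 100 recommended).
#' @param seed integer seed.
#' @param covariates covariate columns.
#' @param truncate weight truncation quantiles.
#' @return object of class `bootstrap_replicates`: matrices `nie`, `nde`,
#'   `te`, `pm` of dimension k x n_models (columns named by spec labels),
#'   `seed`, `n_redrawn`.
#' @export
bootstrap_effects <- function(cohort, specs, k = 10000, seed = 1L,
                              covariates = c("age", "nihss", "log_vol_T1"),
                              truncate = c(0.01, 0.99)) {
  if (inherits(specs, "mediation_spec")) specs <- list(specs)
  d <- med_design(cohort, covariates)
  labels <- vapply(specs, function(s) s$label, "")
  Ms <- lapply(specs, function(s) mediator_matrix(d, s))
  nie <- nde <- te <- pm <- matrix(NA_real_, k, length(specs),
                                   dimnames = list(NULL, labels))
  n_redrawn <- 0L
  with_seed(derive_seed(seed, "bootstrap"), {
    for (b in seq_len(k)) {
      res <- NULL
      for (try in seq_len(200L)) {
        idx <- sample.int(d$n, d$n, replace = TRUE)
        A <- d$A[idx]
        if (sum(A) < 2 || sum(1 - A) < 2) {
          n_redrawn <- n_redrawn + 1L
          next
        }
        Y <- d$Y[idx]
        C <- d$C[idx, , drop = FALSE]
        res <- tryCatch({
          pT_C <- fit_logistic_prob(cbind(1, C), A)
          lapply(Ms, function(M)
            natural_effects(ipw_probs(A, Y, C, M[idx, , drop = FALSE],
                                      truncate, pT_C = pT_C)))
        }, chacomed_error = function(e) NULL)
        if (!is.null(res)) break
        n_redrawn <- n_redrawn + 1L
      }
      if (is.null(res))
        stop_chacomed("bootstrap replicate failed repeatedly",
                      class = "chacomed_bootstrap")
      nie[b, ] <- vapply(res, function(x) x$nie, 0)
      nde[b, ] <- vapply(res, function(x) x$nde, 0)
      te[b, ] <- vapply(res, function(x) x$te, 0)
      pm[b, ] <- vapply(res, function(x) x$pm, 0)
    }
  })
  structure(list(nie = nie, nde = nde, te = te, pm = pm,
                 seed = as.integer(seed), n_redrawn = n_redrawn),
            class = "bootstrap_replicates")
}

#' Bias-corrected percentile bootstrap interval
#'
#' BC (no acceleration): `z0 = qnorm(mean(replicates < estimate))`;
#' interval endpoints at percentiles `pnorm(2 z0 +- z_{(1+level)/2})`. The
#' bias fraction is clamped to `[1/(B+1), B/(B+1)]` (flagged) so `z0`
#' stays finite when the estimate falls outside the replicate range.
#'
#' @param replicates numeric vector of bootstrap replicates (>= 100).
#' @param estimate full-data point estimate.
#' @param level confidence level.
#' @return named vector `c(lo, hi)`; attributes `z0`, `degenerate`
#'   (all replicates identical), `clamped`.
#' @export
bc_interval <- function(replicates, estimate, level = 0.95) {
  replicates <- replicates[is.finite(replicates)]
  assert_that(length(replicates) >= 100,
              "need at least 100 finite replicates")
  degenerate <- length(unique(replicates)) == 1L
  b <- length(replicates)
  frac <- mean(replicates < estimate)
  clamped <- frac <= 0 || frac >= 1
  frac <- min(max(frac, 1 / (b + 1)), b / (b + 1))
  z0 <- qnorm(frac)
  za <- qnorm((1 + level) / 2)
  lo_p <- pnorm(2 * z0 - za)
  hi_p <- pnorm(2 * z0 + za)
  out <- quantile(replicates, c(lo_p, hi_p), names = FALSE)
  names(out) <- c("lo", "hi")
  attr(out, "z0") <- z0
  attr(out, "degenerate") <- degenerate
  attr(out, "clamped") <- clamped
  if (degenerate)
    warning("all bootstrap replicates identical; degenerate interval",
            call. = FALSE)
  out
}

#' Excess mediation: ratio of joint to growth-only indirect effects
#'
#' Replicate-wise `NIE_joint / NIE_growth` from a joint bootstrap, with
#' the full-data point estimate and a BC interval. A "significant excess"
#' of connectivity-mediated effect is declared iff the CI excludes 1.
#'
#' @param boot a [bootstrap_effects()] result containing both models.
#' @param estimates named vector (or list) of full-data NIE point
#'   estimates, named by spec label.
#' @param joint,growth spec labels of the joint and growth-only models.
#' @param level CI level.
#' @return list: `ratio`, `lo`, `hi`, `significant`.
#' @export
nie_ratio <- function(boot, estimates, joint, growth = "growth_only",
                      level = 0.95) {
  assert_that(all(c(joint, growth) %in% colnames(boot$nie)),
              "spec missing from bootstrap replicates",
              class = "chacomed_missing_spec")
  est <- unlist(estimates)
  ratio <- est[[joint]] / est[[growth]]
  reps <- boot$nie[, joint] / boot$nie[, growth]
  ci <- bc_interval(reps, ratio, level)
  list(ratio = ratio, lo = ci[["lo"]], hi = ci[["hi"]],
       significant = ci[["lo"]] > 1 || ci[["hi"]] < 1)
}

# thresholds on the log-NIE scale for one set of centered joint draws
stepdown_thresholds <- function(Z, order_idx, q) {
  M <- ncol(Z)
  k <- nrow(Z)
  vapply(seq_len(M), function(s) {
    rem <- order_idx[s:M]
    pooled <- sort(as.vector(Z[, rem, drop = FALSE]), decreasing = TRUE)
    r <- floor(q * s * k) + 1L
    if (r > length(pooled)) -Inf else pooled[r]
  }, 0)
}

#' Step-down FDR control over correlated mediation models
#'
#' Models are ordered by decreasing empirical NIE. Centered joint
#' bootstrap draws (`log NIE* - log NIE-hat`, per model) stand in for the
#' joint null distribution. At step s (s-1 models already rejected) the
#' rejection threshold is the smallest c such that the expected number of
#' null exceedances among the remaining models, estimated from the
#' centered draws, is at most `q * s`; the s-th model is rejected iff its
#' log NIE exceeds the threshold, and rejection stops at the first
#' non-exceedance. This estimated-FDP construction keeps the false
#' discovery proportion among rejected models at or below `q` (validated
#' by simulation; see the acceptance suite). Threshold uncertainty is
#' assessed by resampling the replicate set (`n_outer` outer draws).
#'
#' @param estimates named vector of full-data NIE estimates (one per
#'   model).
#' @param boot a [bootstrap_effects()] result covering the same models.
#' @param q target false discovery rate.
#' @param n_outer outer resamples for the threshold-curve CI (0 disables).
#' @param seed seed for the outer resampling (default: derived from the
#'   replicate object's seed).
#' @return list of class `stepdown_fdr`: `order` (labels, decreasing
#'   NIE), `nie` (ordered estimates), `thresholds` (NIE scale),
#'   `rejected` (logical, ordered), `threshold_ci` (matrix lo/med/hi x
#'   steps, when `n_outer > 0`).
#' @export
stepdown_fdr <- function(estimates, boot, q = 0.05, n_outer = 100,
                         seed = NULL) {
  est <- unlist(estimates)
  labs <- colnames(boot$nie)
  assert_that(all(names(est) %in% labs), "estimates and replicates disagree")
  est <- est[labs]
  logT <- log(est)
  Z <- sweep(log(boot$nie), 2L, logT)  # centered joint draws
  ord <- order(logT, decreasing = TRUE)
  thr <- stepdown_thresholds(Z, ord, q)
  M <- length(ord)
  rejected <- logical(M)
  for (s in seq_len(M)) {
    if (logT[ord[s]] > thr[s]) rejected[s] <- TRUE else break
  }
  thr_ci <- NULL
  if (n_outer > 0) {
    k <- nrow(Z)
    outer_thr <- with_seed(
      derive_seed(seed %||% boot$seed %||% 1L, "stepdown_outer"),
      vapply(seq_len(n_outer), function(b) {
        rows <- sample.int(k, k, replace = TRUE)
        stepdown_thresholds(Z[rows, , drop = FALSE], ord, q)
      }, numeric(M)))
    thr_ci <- apply(matrix(outer_thr, nrow = M), 1L, quantile,
                    probs = c(0.025, 0.5, 0.975))
    rownames(thr_ci) <- c("lo", "med", "hi")
    thr_ci <- exp(thr_ci + rep(logT[ord], each = 3))
  }
  structure(list(order = labs[ord], nie = est[ord],
                 thresholds = exp(thr + logT[ord]), rejected = rejected,
                 threshold_ci = thr_ci, q = q),
            class = "stepdown_fdr")
}

#' Null distribution of joint NIEs over random region subsets
#'
#' Samples `k` mediator sets uniformly from the region pool (set sizes
#' from `size_law`, default uniform on 1..4), estimates the joint
#' (growth + set) NIE for each, and returns the null distribution together
#' with the growth-only NIE and a percentile function for observed models.
#' Draws on which estimation fails are redrawn and logged.
#'
#' @param cohort cohort or table.
#' @param region_pool character vector of `dchaco_*` columns (default: all
#'   present).
#' @param k number of subset draws.
#' @param size_law function(n) returning n set sizes.
#' @param seed integer seed.
#' @param covariates covariate columns.
#' @return list of class `subset_null`: `nie` (length k), `sets`,
#'   `growth_only_nie`, `n_redrawn`, `percentile(x)`.
#' @export
random_subset_null <- function(cohort, region_pool = NULL, k = 10000,
                               size_law = function(n)
                                 sample.int(4L, n, replace = TRUE),
                               seed = 1L,
                               covariates = c("age", "nihss", "log_vol_T1")) {
  d <- med_design(cohort, covariates)
  pool <- region_pool %||% colnames(d$M_all)[-1L]
  growth_nie <- natural_effects(
    ipw_probs(d$A, d$Y, d$C, d$M_all[, "log2_growth", drop = FALSE]))$nie
  nies <- numeric(k)
  sets <- vector("list", k)
  n_redrawn <- 0L
  with_seed(derive_seed(seed, "subset_null"), {
    sizes <- pmin(size_law(k), length(pool))
    for (i in seq_len(k)) {
      repeat {
        set <- sample(pool, sizes[i])
        M <- d$M_all[, c("log2_growth", set), drop = FALSE]
        ne <- tryCatch(natural_effects(ipw_probs(d$A, d$Y, d$C, M)),
                       chacomed_error = function(e) NULL)
        if (!is.null(ne)) break
        n_redrawn <- n_redrawn + 1L
      }
      nies[i] <- ne$nie
      sets[[i]] <- set
    }
  })
  structure(list(nie = nies, sets = sets, growth_only_nie = growth_nie,
                 n_redrawn = n_redrawn,
                 percentile = function(x) ecdf(nies)(x)),
            class = "subset_null")
}
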