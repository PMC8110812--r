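# Synthetic trial cohorts from a fully specified causal model:
# randomized arm -> lesion growth -> regional disconnection -> binary
# favorable outcome (mRS 0-1), with pre-treatment covariates. Two
# generation modes share one outcome law:
#  * "imaging": voxel lesions grown on a grid, ChaCo profiles computed
#    mechanically against reference tractograms (slow, small n);
#  * "tabular": the reduced-form mediator law below (fast, large n), used
#    by the estimator-validation suites and matched exactly by the
#    Monte-Carlo oracle.
# Reduced-form mediator law, for stroke-hemisphere region r:
#   g              ~ Normal(mu_arm, sigma_g)        [log2 growth ratio]
#   dChaCo_r       = delta0 + delta_g * g + delta_A_r * 1[arm = A] + eps_r,
#   eps_r          ~ Normal(0, mediator_sd), independent across regions.

#' Parameters of the synthetic cohort generator
#'
#' Defaults encode the stated world of an alteplase-vs-placebo trial in
#' anterior-circulation stroke: ~270 patients randomized 1:1, small
#' baseline lesions (median 3 ml) that grow between baseline (T1) and
#' 22-36 h follow-up (T2) with treatment-attenuated growth, about a
#' quarter of patients shrinking (DWI reversal), and a favorable-outcome
#' law in which growth and disconnection of designated "eloquent" regions
#' are harmful while thrombolysis also has a direct beneficial effect.
#' See the methods vignette for the calibration rationale of every value.
#'
#' @param grid_shape voxel grid dimensions (3 ints).
#' @param voxel_size_mm voxel edge length in mm.
#' @param n_regions_per_hemisphere regions per hemisphere.
#' @param n_reference_subjects reference tractogram subjects (73 mirrors a
#'   typical normative-connectome bank; reduce for speed).
#' @param streamlines_per_region_pair streamlines per within-hemisphere
#'   region pair, per reference subject.
#' @param self_pair_rate probability a region receives self-connecting
#'   streamlines.
#' @param path_jitter per-subject streamline bend SD, in voxels.
#' @param arm_growth_log2_mean named pair `c(P=, A=)`: mean log2 growth
#'   ratio per arm; `A <= P` encodes treatment-attenuated growth.
#' @param growth_log2_sd SD of log2 growth ratio.
#' @param baseline_volume_lognormal `c(meanlog=, sdlog=)` of baseline
#'   volume in ml.
#' @param age_mean,age_sd age distribution (years).
#' @param nihss_shape,nihss_scale Gamma parameters of the (rounded) NIHSS.
#' @param outcome_coefs list of logistic outcome coefficients: `b0`
#'   intercept, `bA` direct treatment effect, `bG` per log2 growth unit,
#'   `br` per-region effects per unit change in ChaCo (length
#'   `n_regions_per_hemisphere`, indexed within the stroke hemisphere),
#'   `bage`, `bN`, `bV` (per log ml baseline volume).
#' @param eloquent_regions within-hemisphere indices of clinically
#'   eloquent regions (receive `eloquent_br` and `eloquent_delta_A`).
#' @param eloquent_br outcome coefficient of eloquent-region dChaCo.
#' @param delta0,delta_g,mediator_sd reduced-form mediator law (above).
#' @param eloquent_delta_A direct treatment effect on eloquent-region
#'   dChaCo (negative: alteplase attenuates disconnection growth).
#' @param missing_outcome_fraction fraction of patients with missing
#'   90-day outcome.
#' @param confounded_exposure if `TRUE`, exposure depends on covariates
#'   (tests IPW under confounding); default is trial randomization.
#' @param seed integer seed stored with the parameters.
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(grid_shape = c(24L, 16L, 16L),
                          voxel_size_mm = 3,
                          n_regions_per_hemisphere = 8L,
                          n_reference_subjects = 73L,
                          streamlines_per_region_pair = 3L,
                          self_pair_rate = 0.5,
                          path_jitter = 1,
                          arm_growth_log2_mean = c(P = 0.8, A = 0.4),
                          growth_log2_sd = 0.8,
                          baseline_volume_lognormal = c(meanlog = log(3),
                                                        sdlog = 1.3),
                          age_mean = 65.5, age_sd = 11,
                          nihss_shape = 3.5, nihss_scale = 2,
                          outcome_coefs = NULL,
                          eloquent_regions = c(2L, 3L, 5L, 7L),
                          eloquent_br = -2,
                          delta0 = 0.02, delta_g = 0.05,
                          mediator_sd = 0.03,
                          eloquent_delta_A = -0.02,
                          missing_outcome_fraction = 6 / 269,
                          confounded_exposure = FALSE,
                          seed = 1L) {
  nreg <- as.integer(n_regions_per_hemisphere)
  eloquent_regions <- eloquent_regions[eloquent_regions <= nreg]
  if (is.null(outcome_coefs)) {
    br <- numeric(nreg)
    br[eloquent_regions] <- eloquent_br
    outcome_coefs <- list(b0 = 3.4, bA = log(1.5), bG = log(0.77), br = br,
                          bage = -0.03, bN = -0.1, bV = -0.2)
  }
  delta_A <- numeric(nreg)
  delta_A[eloquent_regions] <- eloquent_delta_A
  p <- list(grid_shape = as.integer(grid_shape),
            voxel_size_mm = voxel_size_mm,
            n_regions_per_hemisphere = nreg,
            n_reference_subjects = as.integer(n_reference_subjects),
            streamlines_per_region_pair =
              as.integer(streamlines_per_region_pair),
            self_pair_rate = self_pair_rate,
            path_jitter = path_jitter,
            arm_growth_log2_mean = arm_growth_log2_mean,
            growth_log2_sd = growth_log2_sd,
            baseline_volume_lognormal = baseline_volume_lognormal,
            age_mean = age_mean, age_sd = age_sd,
            nihss_shape = nihss_shape, nihss_scale = nihss_scale,
            outcome_coefs = outcome_coefs,
            eloquent_regions = as.integer(eloquent_regions),
            delta0 = delta0, delta_g = delta_g,
            mediator_sd = mediator_sd, delta_A = delta_A,
            missing_outcome_fraction = missing_outcome_fraction,
            confounded_exposure = confounded_exposure,
            seed = as.integer(seed))
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  assert_that(p$arm_growth_log2_mean[["A"]] <= p$arm_growth_log2_mean[["P"]],
              "treatment-attenuated growth requires mu_A <= mu_P")
  assert_that(p$growth_log2_sd > 0 && p$age_sd > 0 && p$mediator_sd > 0 &&
                p$baseline_volume_lognormal[["sdlog"]] > 0,
              "all standard deviations must be > 0")
  assert_that(length(p$outcome_coefs$br) == p$n_regions_per_hemisphere,
              "outcome_coefs$br must have one entry per hemisphere region")
  invisible(p)
}

# draw covariates for n patients (consumes RNG)
draw_covariates <- function(n, params) {
  data.frame(
    age = rnorm(n, params$age_mean, params$age_sd),
    nihss = pmin(42, pmax(0, round(rgamma(n, shape = params$nihss_shape,
                                          scale = params$nihss_scale))))
  )
}

#' Simulate one lesioned patient (imaging mode, without outcome)
#'
#' Baseline lesion: a connected voxel cluster grown by random boundary
#' accretion from a random seed voxel of one hemisphere to a target volume
#' drawn from the baseline log-normal. Follow-up lesion: the baseline
#' cluster grown (or eroded, for negative draws) to a volume with
#' `log2(vol_T2/vol_T1) ~ Normal(mu_arm, sigma)`. Lesions never cross the
#' midline; targets exceeding hemisphere capacity are clipped with a
#' warning record on the patient.
#'
#' @param parcellation a [make_parcellation()] result.
#' @param arm `"P"` or `"A"`.
#' @param params a [cohort_params()].
#' @param id patient identifier.
#' @return a `patient_record` list (no outcome yet): `id`, `arm`, `age`,
#'   `nihss`, `lesion_T1`, `lesion_T2`, `vol_T1`, `vol_T2`, `warnings`.
#' @export
simulate_patient <- function(parcellation, arm, params, id = "p001") {
  assert_that(arm %in% c("P", "A"), "arm must be 'P' or 'A'")
  dims <- dim(parcellation$labels)
  vox_ml <- params$voxel_size_mm^3 / 1000
  covs <- draw_covariates(1L, params)
  hemi <- sample(c("L", "R"), 1L)
  allowed <- parcellation$hemi_of_voxel == hemi
  capacity <- sum(allowed)
  warnings <- character(0)

  v1_ml <- rlnorm(1, params$baseline_volume_lognormal[["meanlog"]],
                  params$baseline_volume_lognormal[["sdlog"]])
  target1 <- max(1L, round(v1_ml / vox_ml))
  if (target1 > capacity) {
    warnings <- c(warnings, "baseline volume clipped to hemisphere capacity")
    target1 <- capacity
  }
  seed_lin <- sample(which(allowed), 1L)
  seed_arr <- array(FALSE, dims)
  seed_arr[seed_lin] <- TRUE
  m1 <- grow_region(seed_arr, allowed, target1, dims)

  g <- rnorm(1, params$arm_growth_log2_mean[[arm]], params$growth_log2_sd)
  target2 <- max(1L, round(target1 * 2^g))
  if (target2 > capacity) {
    warnings <- c(warnings, "follow-up volume clipped to hemisphere capacity")
    target2 <- capacity
  }
  m2 <- if (target2 >= target1) grow_region(m1, allowed, target2, dims)
  else shrink_region(m1, target2, dims)

  list(id = id, arm = arm, age = covs$age, nihss = covs$nihss,
       lesion_T1 = lesion_mask(m1, params$voxel_size_mm),
       lesion_T2 = lesion_mask(m2, params$voxel_size_mm),
       vol_T1 = sum(m1) * vox_ml, vol_T2 = sum(m2) * vox_ml,
       hemisphere = hemi, favorable = NA_integer_, warnings = warnings)
}

# shared linear predictor of the favorable-outcome law
outcome_lp <- function(coefs, arm_is_A, log2_growth, dchaco, age, nihss,
                       log_vol_T1) {
  coefs$b0 + coefs$bA * arm_is_A + coefs$bG * log2_growth +
    as.vector(dchaco %*% coefs$br) +
    coefs$bage * age + coefs$bN * nihss + coefs$bV * log_vol_T1
}

#' Simulate the binary favorable outcome (mRS 0-1) for one patient
#'
#' `favorable ~ Bernoulli(expit(b0 + bA 1[A] + bG log2(volT2/volT1) +
#' sum_r br dChaCo_r + bage age + bN NIHSS + bV log(volT1)))`.
#'
#' @param patient a [simulate_patient()] record (or any list with `arm`,
#'   `age`, `nihss`, `vol_T1`, `vol_T2`).
#' @param chaco_change_profile named or plain numeric vector of per-region
#'   change in ChaCo for the stroke hemisphere, in within-hemisphere
#'   region order.
#' @param params a [cohort_params()].
#' @return 0/1 outcome.
#' @export
simulate_outcome <- function(patient, chaco_change_profile, params) {
  br <- params$outcome_coefs$br
  if (length(chaco_change_profile) < length(br) &&
      any(br[seq(length(chaco_change_profile) + 1L, length(br))] != 0))
    stop_chacomed("dChaCo missing for a region with nonzero outcome effect",
                  class = "chacomed_specification")
  dch <- matrix(chaco_change_profile[seq_along(br)], nrow = 1L)
  if (any(is.na(dch) & br != 0))
    stop_chacomed("dChaCo missing for a region with nonzero outcome effect",
                  class = "chacomed_specification")
  dch[is.na(dch)] <- 0
  lp <- outcome_lp(params$outcome_coefs, as.numeric(patient$arm == "A"),
                   log2(patient$vol_T2 / patient$vol_T1), dch,
                   patient$age, patient$nihss, log(patient$vol_T1))
  rbinom(1L, 1L, expit(lp))
}

#' Generate a synthetic trial cohort
#'
#' @param params a [cohort_params()].
#' @param n number of patients (>= 2).
#' @param seed integer seed; the cohort is fully reproducible from
#'   `(params, n, seed)`.
#' @param mode `"tabular"` (reduced-form mediators; fast, default) or
#'   `"imaging"` (voxel lesions + mechanical ChaCo against reference
#'   tractograms).
#' @param parcellation,refs optional pre-built parcellation and reference
#'   set for imaging mode (built from `params` if omitted).
#' @param balance if `TRUE` (default), exact 1:1 randomization.
#' @return object of class `cohort`: list with `table` (one row per
#'   patient: `id`, `arm`, `age`, `nihss`, `vol_T1`, `vol_T2`,
#'   `log2_growth`, `favorable`, `log_vol_T1`, and `dchaco_1` ...
#'   `dchaco_R` in within-hemisphere region order), `patients` (imaging
#'   mode only: full records incl. masks and ChaCo profiles), `mode`,
#'   `params`, `seed`, `parcellation_id`, `provenance`.
#' @export
generate_cohort <- function(params, n, seed, mode = c("tabular", "imaging"),
                            parcellation = NULL, refs = NULL,
                            balance = TRUE) {
  mode <- match.arg(mode)
  assert_that(n >= 2, "need n >= 2")
  assert_that(!(params$confounded_exposure && mode == "imaging"),
              "confounded exposure is only supported in tabular mode")
  nreg <- params$n_regions_per_hemisphere

  if (mode == "tabular")
    return(generate_cohort_tabular(params, n, seed, balance))

  arms <- with_seed(derive_seed(seed, "arms"), {
    if (balance) sample(rep(c("P", "A"), length.out = n))
    else sample(c("P", "A"), n, replace = TRUE)
  })

  if (is.null(parcellation)) parcellation <- make_parcellation(params)
  if (is.null(refs)) refs <- make_reference_tractograms(parcellation, params)

  patients <- vector("list", n)
  tab_rows <- vector("list", n)
  for (i in seq_len(n)) {
    pseed <- derive_seed(seed, "patient", i)
    id <- sprintf("s%04d", i)
    p <- with_seed(pseed, {
      pt <- simulate_patient(parcellation, arms[i], params, id = id)
      pr1 <- restrict_to_stroke_hemisphere(
        chaco_score(refs, parcellation, pt$lesion_T1, "T1", id),
        pt$lesion_T1, parcellation)
      pr2 <- restrict_to_stroke_hemisphere(
        chaco_score(refs, parcellation, pt$lesion_T2, "T2", id),
        pt$lesion_T2, parcellation)
      pt$chaco <- list(T1 = pr1, T2 = pr2)
      pt$dchaco <- chaco_change(pr1, pr2)
      pt$favorable <- simulate_outcome(pt, pt$dchaco, params)
      pt
    })
    patients[[i]] <- p
    dch <- as.numeric(p$dchaco)[seq_len(nreg)]
    tab_rows[[i]] <- data.frame(
      id = p$id, arm = p$arm, age = p$age, nihss = p$nihss,
      vol_T1 = p$vol_T1, vol_T2 = p$vol_T2,
      log2_growth = log2(p$vol_T2 / p$vol_T1),
      favorable = p$favorable,
      as.list(setNames(dch, paste0("dchaco_", seq_len(nreg)))),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tab_rows)
  tab$log_vol_T1 <- log(tab$vol_T1)

  n_miss <- round(params$missing_outcome_fraction * n)
  if (n_miss > 0) {
    miss_idx <- with_seed(derive_seed(seed, "missing"),
                          sample.int(n, n_miss))
    tab$favorable[miss_idx] <- NA_integer_
  }

  structure(list(table = tab, patients = patients,
                 mode = mode, params = params, seed = as.integer(seed),
                 parcellation_id = "synthetic",
                 provenance = list(seed = as.integer(seed),
                                   params_hash = rlang::hash(params))),
            class = "cohort")
}

# vectorized reduced-form generator (one substream for the whole cohort)
generate_cohort_tabular <- function(params, n, seed, balance = TRUE) {
  nreg <- params$n_regions_per_hemisphere
  co <- params$outcome_coefs
  tab <- with_seed(derive_seed(seed, "tabular"), {
    covs <- draw_covariates(n, params)
    arm <- if (params$confounded_exposure) {
      p_treat <- expit(0.4 * (covs$age - params$age_mean) / params$age_sd +
                         0.3 * (covs$nihss - 7) / 4)
      ifelse(runif(n) < p_treat, "A", "P")
    } else if (balance) {
      sample(rep(c("P", "A"), length.out = n))
    } else {
      sample(c("P", "A"), n, replace = TRUE)
    }
    is_A <- as.numeric(arm == "A")
    v1 <- rlnorm(n, params$baseline_volume_lognormal[["meanlog"]],
                 params$baseline_volume_lognormal[["sdlog"]])
    mu_g <- ifelse(arm == "A", params$arm_growth_log2_mean[["A"]],
                   params$arm_growth_log2_mean[["P"]])
    g <- rnorm(n, mu_g, params$growth_log2_sd)
    dch <- params$delta0 + params$delta_g * g +
      outer(is_A, params$delta_A) +
      matrix(rnorm(n * nreg, 0, params$mediator_sd), n, nreg)
    lp <- outcome_lp(co, is_A, g, dch, covs$age, covs$nihss, log(v1))
    fav <- rbinom(n, 1L, expit(lp))
    colnames(dch) <- paste0("dchaco_", seq_len(nreg))
    data.frame(id = sprintf("s%04d", seq_len(n)), arm = arm,
               age = covs$age, nihss = covs$nihss, vol_T1 = v1,
               vol_T2 = v1 * 2^g, log2_growth = g, favorable = fav,
               dch, stringsAsFactors = FALSE)
  })
  tab$log_vol_T1 <- log(tab$vol_T1)
  n_miss <- round(params$missing_outcome_fraction * n)
  if (n_miss > 0) {
    miss_idx <- with_seed(derive_seed(seed, "missing"),
                          sample.int(n, n_miss))
    tab$favorable[miss_idx] <- NA_integer_
  }
  structure(list(table = tab, patients = NULL, mode = "tabular",
                 params = params, seed = as.integer(seed),
                 parcellation_id = NA,
                 provenance = list(seed = as.integer(seed),
                                   params_hash = rlang::hash(params))),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> n = ", nrow(x$table), " (", sum(x$table$arm == "P"), " P / ",
      sum(x$table$arm == "A"), " A), mode ", x$mode, ", ",
      sum(!is.na(x$table$favorable)), " with outcome\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) x$table

#' Monte-Carlo oracle for the true natural effects of the generator
#'
#' Brute-force counterfactual simulation under the reduced-form
#' (tabular-mode) generative law: for each Monte-Carlo subject, covariates
#' are drawn once, the full mediator vector (log2 growth plus all regional
#' dChaCo) is drawn under both arms, and the three counterfactual
#' favorable-outcome probabilities are averaged over subjects:
#' `P_{T,M|T}` (treated, treated mediators), `P_{T,M|P}` (treated, placebo
#' mediators) and `P_{P,M|P}`. Natural effects follow on the odds-ratio
#' scale via [natural_effects()]. The mediator set of the oracle is the
#' *full* vector; it coincides with any subset that contains growth and
#' every region with a nonzero outcome coefficient.
#'
#' @param params a [cohort_params()].
#' @param n_mc number of Monte-Carlo subjects (>= 10000 recommended).
#' @param seed integer seed.
#' @return a `natural_effects` object (see [natural_effects()]) with the
#'   counterfactual probabilities in `$probs`.
#' @export
oracle_natural_effects <- function(params, n_mc = 1e5, seed = 1L) {
  nreg <- params$n_regions_per_hemisphere
  with_seed(derive_seed(seed, "oracle"), {
    covs <- draw_covariates(n_mc, params)
    v1 <- rlnorm(n_mc, params$baseline_volume_lognormal[["meanlog"]],
                 params$baseline_volume_lognormal[["sdlog"]])
    gP <- rnorm(n_mc, params$arm_growth_log2_mean[["P"]],
                params$growth_log2_sd)
    gA <- rnorm(n_mc, params$arm_growth_log2_mean[["A"]],
                params$growth_log2_sd)
    eps <- matrix(rnorm(n_mc * nreg, 0, params$mediator_sd), n_mc, nreg)
    dchP <- params$delta0 + params$delta_g * gP +
      matrix(0, n_mc, nreg, byrow = TRUE) + eps
    eps2 <- matrix(rnorm(n_mc * nreg, 0, params$mediator_sd), n_mc, nreg)
    dchA <- params$delta0 + params$delta_g * gA +
      matrix(params$delta_A, n_mc, nreg, byrow = TRUE) + eps2
    co <- params$outcome_coefs
    lp <- function(armA, g, dch) {
      co$b0 + co$bA * armA + co$bG * g + as.vector(dch %*% co$br) +
        co$bage * covs$age + co$bN * covs$nihss + co$bV * log(v1)
    }
    probs <- list(P_T_M_T = mean(expit(lp(1, gA, dchA))),
                  P_T_M_P = mean(expit(lp(1, gP, dchP))),
                  P_P_M_P = mean(expit(lp(0, gP, dchP))))
    natural_effects(probs)
  })
}
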