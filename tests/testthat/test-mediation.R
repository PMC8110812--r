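null_mediation_params <- function(...) {
  # no mediated path: growth and disconnection do not affect outcome
  cohort_params(outcome_coefs = list(b0 = 0.2, bA = 0.6, bG = 0,
                                     br = numeric(8), bage = -0.02,
                                     bN = -0.05, bV = -0.1), ...)
}

test_that("natural_effects reproduces the worked example exactly", {
  ne <- natural_effects(list(P_T_M_T = 0.6, P_T_M_P = 0.5, P_P_M_P = 0.4))
  expect_equal(ne$nde, 1.5, tolerance = 1e-12)
  expect_equal(ne$nie, 1.5, tolerance = 1e-12)
  expect_equal(ne$te, 2.25, tolerance = 1e-12)
  expect_equal(ne$pm, 0.5, tolerance = 1e-12)
  # degenerate: all equal probabilities -> unit effects, PM flagged
  ne0 <- natural_effects(list(P_T_M_T = 0.5, P_T_M_P = 0.5, P_P_M_P = 0.5))
  expect_equal(c(ne0$nde, ne0$nie, ne0$te), c(1, 1, 1))
  expect_false(ne0$pm_defined)
  # swapping arms inverts the odds ratios
  ne_sw <- natural_effects(list(P_T_M_T = 0.4, P_T_M_P = 0.5, P_P_M_P = 0.6))
  expect_equal(ne_sw$nde, 1 / 1.5, tolerance = 1e-12)
  expect_equal(ne_sw$nie, 1 / 1.5, tolerance = 1e-12)
  expect_error(natural_effects(list(P_T_M_T = 1, P_T_M_P = 0.5,
                                    P_P_M_P = 0.5)),
               class = "chacomed_degenerate")
})

test_that("randomized exposure with no mediator-exposure link gives NIE 1", {
  # mediators unrelated to exposure: P(A|M,C) = P(A|C) -> weights constant
  withr::local_seed(50)
  n <- 600
  tab <- data.frame(id = as.character(1:n),
                    arm = rep(c("P", "A"), n / 2),
                    age = rnorm(n, 65, 10), nihss = rpois(n, 6),
                    vol_T1 = exp(rnorm(n)), vol_T2 = exp(rnorm(n)),
                    log2_growth = rnorm(n),  # independent of arm
                    favorable = rbinom(n, 1, 0.5))
  tab$dchaco_1 <- rnorm(n)
  probs <- counterfactual_probabilities(tab, mediation_spec(1),
                                        truncate = NULL)
  expect_equal(probs$P_T_M_P, probs$P_T_M_T, tolerance = 0.02)
  ne <- natural_effects(probs)
  expect_equal(ne$nie, 1, tolerance = 0.1)
})

test_that("IPW estimates approach the oracle on a large cohort", {
  p <- cohort_params(missing_outcome_fraction = 0)
  co <- generate_cohort(p, 20000, seed = 51)
  est <- estimate_mediation(co, mediation_spec(c(2, 3, 5, 7)),
                            truncate = NULL)
  orc <- oracle_natural_effects(p, 3e5, seed = 52)
  expect_equal(est$nie, orc$nie, tolerance = 0.12)
  expect_equal(est$nde, orc$nde, tolerance = 0.12)
  expect_equal(est$te, orc$te, tolerance = 0.15)
  # TE identity to machine precision
  expect_equal(est$te, est$nie * est$nde, tolerance = 1e-12)
})

test_that("IPW remains consistent under confounded exposure", {
  p <- cohort_params(missing_outcome_fraction = 0,
                     confounded_exposure = TRUE)
  co <- generate_cohort(p, 20000, seed = 53)
  # exposure depends on age and NIHSS; unweighted arm contrast is biased,
  # the IPW estimate still tracks the oracle
  est <- estimate_mediation(co, mediation_spec(c(2, 3, 5, 7)),
                            truncate = NULL)
  orc <- oracle_natural_effects(p, 3e5, seed = 54)
  expect_equal(est$te, orc$te, tolerance = 0.2)
  expect_equal(est$nie, orc$nie, tolerance = 0.15)
})

test_that("estimator consistency: error shrinks with n", {
  p <- cohort_params(missing_outcome_fraction = 0)
  orc <- oracle_natural_effects(p, 3e5, seed = 55)
  reps <- c(12, 12, 4)
  ns <- c(500, 2000, 20000)
  err <- vapply(seq_along(ns), function(i) {
    e <- vapply(seq_len(reps[i]), function(r) {
      co <- generate_cohort(p, ns[i], seed = 100 * ns[i] + r)
      estimate_mediation(co, mediation_spec(c(2, 3, 5, 7)),
                         truncate = NULL)$nie
    }, 0)
    median(abs(e - orc$nie))
  }, 0)
  expect_true(err[3] < err[2] && err[2] < err[1])
})

test_that("missing outcomes are excluded, non-overlap raises", {
  p <- cohort_params()
  co <- generate_cohort(p, 400, seed = 56)
  pr <- counterfactual_probabilities(co, mediation_spec())
  expect_equal(pr$n, sum(!is.na(co$table$favorable)))
  # degenerate exposure probabilities -> non-overlap error
  tab <- co$table[!is.na(co$table$favorable), ]
  tab$age <- ifelse(tab$arm == "A", 100, 20)  # perfect separation in A ~ C
  expect_error(counterfactual_probabilities(tab, mediation_spec(),
                                            overlap_floor = 1e-3),
               class = "chacomed_nonoverlap")
})

test_that("bootstrap replicates are deterministic and respect Eq-1", {
  co <- generate_cohort(cohort_params(), 300, seed = 57)
  specs <- list(mediation_spec(), mediation_spec(c(2, 3)))
  b1 <- bootstrap_effects(co, specs, k = 120, seed = 5)
  b2 <- bootstrap_effects(co, specs, k = 120, seed = 5)
  expect_identical(b1$nie, b2$nie)
  expect_equal(b1$te, b1$nie * b1$nde, tolerance = 1e-12)
  expect_equal(colnames(b1$nie), c("growth_only", "dchaco_2+dchaco_3"))
  # overlapping region sets -> strongly correlated replicate NIEs
  b3 <- bootstrap_effects(co, list(mediation_spec(c(2, 3)),
                                   mediation_spec(c(2, 3, 5))),
                          k = 150, seed = 5)
  expect_gt(cor(log(b3$nie[, 1]), log(b3$nie[, 2])), 0.5)
})

test_that("bc_interval: symmetric replicates reduce to percentiles", {
  withr::local_seed(58)
  reps <- rnorm(2000, 1.5, 0.2)
  ci <- bc_interval(reps, median(reps))
  plain <- quantile(reps, c(0.025, 0.975), names = FALSE)
  expect_equal(as.numeric(ci), plain, tolerance = 0.02)
  # estimate below all replicates: clamped, flagged
  ci2 <- bc_interval(reps, min(reps) - 1)
  expect_true(attr(ci2, "clamped"))
  expect_true(all(is.finite(ci2)))
  expect_warning(bc_interval(rep(1, 200), 1), "degenerate")
})

test_that("nie_ratio detects excess mediation when region effects exist", {
  # strong region effects so the excess is reliably detectable
  p <- cohort_params(missing_outcome_fraction = 0, eloquent_br = -4)
  co <- generate_cohort(p, 4000, seed = 59)
  specs <- list(mediation_spec(), mediation_spec(c(2, 3, 5, 7)))
  est <- lapply(specs, function(s) estimate_mediation(co, s))
  nies <- setNames(vapply(est, function(e) e$nie, 0),
                   vapply(specs, function(s) s$label, ""))
  boot <- bootstrap_effects(co, specs, k = 400, seed = 6)
  nr <- nie_ratio(boot, nies, joint = "dchaco_2+dchaco_3+dchaco_5+dchaco_7")
  expect_gt(nr$ratio, 1)
  expect_true(nr$significant)
  # identical specs: ratio identically one
  boot2 <- bootstrap_effects(co, list(mediation_spec(), mediation_spec()),
                             k = 120, seed = 7)
  expect_true(all(abs(boot2$nie[, 1] / boot2$nie[, 2] - 1) < 1e-12))
  expect_error(nie_ratio(boot, nies, joint = "nope"),
               class = "chacomed_missing_spec")
})

test_that("null generator: NIE ratio centred at one", {
  co <- generate_cohort(null_mediation_params(missing_outcome_fraction = 0),
                        4000, seed = 60)
  specs <- list(mediation_spec(), mediation_spec(c(2, 3, 5, 7)))
  est <- lapply(specs, function(s)
    estimate_mediation(co, s, truncate = NULL))
  ratio <- est[[2]]$nie / est[[1]]$nie
  expect_equal(ratio, 1, tolerance = 0.08)
})

test_that("step-down FDR: joint rejection behaviour", {
  co <- generate_cohort(cohort_params(missing_outcome_fraction = 0),
                        2000, seed = 61)
  specs <- list(mediation_spec(c(2, 3)), mediation_spec(c(2, 3, 5)),
                mediation_spec(c(2, 3, 5, 7)))
  est <- setNames(lapply(specs, function(s) estimate_mediation(co, s)),
                  vapply(specs, function(s) s$label, ""))
  nies <- vapply(est, function(e) e$nie, 0)
  boot <- bootstrap_effects(co, specs, k = 300, seed = 8)
  sd_res <- stepdown_fdr(nies, boot, q = 0.05, n_outer = 40)
  # real effects in all three models: everything rejected, thresholds finite
  expect_true(all(sd_res$rejected))
  expect_equal(sd_res$order, names(sort(nies, decreasing = TRUE)))
  expect_true(all(is.finite(sd_res$thresholds)))
  expect_equal(dim(sd_res$threshold_ci), c(3L, 3L))
})

test_that("random_subset_null centres on growth-only NIE without effects", {
  co <- generate_cohort(null_mediation_params(missing_outcome_fraction = 0),
                        1500, seed = 62)
  sn <- random_subset_null(co, k = 150, seed = 9)
  expect_length(sn$nie, 150)
  expect_equal(median(sn$nie), sn$growth_only_nie, tolerance = 0.05)
  expect_true(all(vapply(sn$sets, length, 0L) <= 4))
  p50 <- sn$percentile(median(sn$nie))
  expect_gt(p50, 0.4); expect_lt(p50, 0.6)
  # k = 1: single draw, degenerate percentile
  sn1 <- random_subset_null(co, k = 1, seed = 10)
  expect_length(sn1$nie, 1)
})
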