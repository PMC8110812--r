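test_that("parcellation partitions the grid with hemisphere metadata", {
  p <- cohort_params(grid_shape = c(8L, 4L, 4L),
                     n_regions_per_hemisphere = 2L)
  parc <- make_parcellation(p)
  expect_equal(nrow(parc$regions), 4L)
  expect_true(all(parc$labels %in% 0:4))
  # every labelled voxel in exactly one region; L and R blocks disjoint
  for (r in 1:4) {
    vox <- which(parc$labels == r)
    expect_gt(length(vox), 0)
    expect_equal(unique(parc$hemi_of_voxel[vox]),
                 parc$regions$hemisphere[r])
  }
  p1 <- cohort_params(grid_shape = c(8L, 4L, 4L),
                      n_regions_per_hemisphere = 1L)
  expect_equal(nrow(make_parcellation(p1)$regions), 2L)
  # determinism
  expect_identical(make_parcellation(p)$labels, parc$labels)
  expect_error(make_parcellation(cohort_params(grid_shape = c(2L, 1L, 1L),
                                               n_regions_per_hemisphere = 4L)),
               class = "chacomed_sizing")
})

test_that("reference tractograms honour pair structure, jitter and seed", {
  p <- tiny_params(n_reference_subjects = 2L, seed = 9)
  parc <- make_parcellation(p)
  refs <- make_reference_tractograms(parc, p)
  expect_length(refs, 2L)
  for (s in refs) expect_true(all(s$totals >= p$streamlines_per_region_pair))
  # fixed seed reproduces identical voxel paths
  refs2 <- make_reference_tractograms(parc, p)
  expect_identical(refs[[1]]$streamlines, refs2[[1]]$streamlines)
  # zero jitter: all subjects identical
  p0 <- tiny_params(n_reference_subjects = 3L, path_jitter = 0, seed = 9)
  refs0 <- make_reference_tractograms(parc, p0)
  expect_identical(refs0[[1]]$streamlines, refs0[[3]]$streamlines)
  # with jitter, subjects differ
  expect_false(identical(refs[[1]]$streamlines, refs[[2]]$streamlines))
})

test_that("lesion growth hits its volume targets and stays unilateral", {
  p <- tiny_params(seed = 3)
  parc <- make_parcellation(p)
  # forced doubling: mu_P = 1, sigma -> 0
  pf <- tiny_params(arm_growth_log2_mean = c(P = 1, A = 1),
                    growth_log2_sd = 1e-9,
                    baseline_volume_lognormal = c(meanlog = log(1),
                                                  sdlog = 1e-9))
  withr::local_seed(31)
  vox_ml <- pf$voxel_size_mm^3 / 1000
  for (i in 1:5) {
    pt <- simulate_patient(parc, "P", pf)
    expect_equal(pt$vol_T1, 1, tolerance = vox_ml * 1.5)
    expect_equal(pt$vol_T2, 2 * pt$vol_T1, tolerance = vox_ml * 1.5)
    # monotone growth, unilateral, connected start
    expect_true(all(pt$lesion_T2$mask[pt$lesion_T1$mask]))
    expect_length(unique(parc$hemi_of_voxel[pt$lesion_T2$mask]), 1L)
  }
})

test_that("log2 growth follows the stated normal law", {
  # 1000 placebo draws, mu_P = 1, sigma = 0.5 (reduced-form generator)
  p <- cohort_params(arm_growth_log2_mean = c(P = 1, A = 0.4),
                     growth_log2_sd = 0.5, missing_outcome_fraction = 0)
  co <- generate_cohort(p, 2000, seed = 77, balance = TRUE)
  g <- co$table$log2_growth[co$table$arm == "P"]
  se <- 0.5 / sqrt(length(g))
  expect_lt(abs(mean(g) - 1), 3 * se)
  expect_equal(sd(g), 0.5, tolerance = 0.06)
})

test_that("simulate_outcome follows the logistic law", {
  p <- tiny_params()
  pt <- list(arm = "P", age = 0, nihss = 0, vol_T1 = 1, vol_T2 = 2)
  # all coefficients zero -> P = 0.5
  p0 <- tiny_params(outcome_coefs = list(b0 = 0, bA = 0, bG = 0,
                                         br = numeric(4), bage = 0, bN = 0,
                                         bV = 0))
  withr::local_seed(5)
  ys <- replicate(4000, simulate_outcome(pt, numeric(4), p0))
  expect_equal(mean(ys), 0.5, tolerance = 0.03)
  # bG = -1, log2 growth = 1, others 0 -> P = expit(-1)
  p1 <- tiny_params(outcome_coefs = list(b0 = 0, bA = 0, bG = -1,
                                         br = numeric(4), bage = 0, bN = 0,
                                         bV = 0))
  ys <- replicate(4000, simulate_outcome(pt, numeric(4), p1))
  expect_equal(mean(ys), exp(-1) / (1 + exp(-1)), tolerance = 0.03)
  # huge direct effect: all treated favorable
  pA <- tiny_params(outcome_coefs = list(b0 = 0, bA = 50, bG = 0,
                                         br = numeric(4), bage = 0, bN = 0,
                                         bV = 0))
  ptA <- pt; ptA$arm <- "A"
  expect_true(all(replicate(50, simulate_outcome(ptA, numeric(4), pA)) == 1))
  # missing dChaCo for a region with nonzero effect
  expect_error(simulate_outcome(pt, numeric(1), tiny_params()),
               class = "chacomed_specification")
})

test_that("generate_cohort: balance, missingness, determinism", {
  p <- cohort_params()
  co <- generate_cohort(p, 269, seed = 12)
  expect_equal(sum(is.na(co$table$favorable)), 6L)  # 6/269 missing
  expect_equal(sum(!is.na(co$table$favorable)), 263L)
  expect_equal(abs(sum(co$table$arm == "P") - sum(co$table$arm == "A")) <= 1,
               TRUE)
  expect_false(any(duplicated(co$table$id)))
  co2 <- generate_cohort(p, 269, seed = 12)
  expect_identical(co$table, co2$table)
  # n = 2 under forced balance: one per arm
  co_min <- generate_cohort(p, 2, seed = 1)
  expect_setequal(co_min$table$arm, c("P", "A"))
})

test_that("about a quarter of patients shrink under default growth law", {
  co <- generate_cohort(cohort_params(missing_outcome_fraction = 0), 4000,
                        seed = 8)
  shrink <- mean(co$table$vol_T2 < co$table$vol_T1)
  expect_equal(shrink, 0.25, tolerance = 0.04)
})

test_that("oracle causal identities hold", {
  nreg <- 8L
  # no mediated path: NIE = 1
  p_null <- cohort_params(outcome_coefs = list(
    b0 = 0.2, bA = 0.5, bG = 0, br = numeric(nreg), bage = -0.03,
    bN = -0.1, bV = -0.2))
  orc <- oracle_natural_effects(p_null, 5e4, seed = 2)
  expect_equal(orc$nie, 1, tolerance = 1e-9)
  expect_gt(orc$nde, 1)
  # no direct effect: NDE = 1
  p_nde <- cohort_params(outcome_coefs = list(
    b0 = 0.2, bA = 0, bG = log(0.77), br = c(-2, numeric(nreg - 1)),
    bage = -0.03, bN = -0.1, bV = -0.2))
  orc2 <- oracle_natural_effects(p_nde, 5e4, seed = 2)
  expect_equal(orc2$nde, 1, tolerance = 1e-9)
  expect_gt(orc2$nie, 1)
  # TE = NIE x NDE for arbitrary params
  orc3 <- oracle_natural_effects(cohort_params(), 2e4, seed = 3)
  expect_equal(orc3$te, orc3$nie * orc3$nde, tolerance = 1e-12)
  # determinism
  orc4 <- oracle_natural_effects(cohort_params(), 2e4, seed = 3)
  expect_identical(orc3$probs, orc4$probs)
})

test_that("growth law recovery per arm at n = 1000", {
  p <- cohort_params(missing_outcome_fraction = 0)
  co <- generate_cohort(p, 2000, seed = 21)
  for (a in c("P", "A")) {
    g <- co$table$log2_growth[co$table$arm == a]
    mu <- p$arm_growth_log2_mean[[a]]
    se <- p$growth_log2_sd / sqrt(length(g))
    expect_lt(abs(mean(g) - mu), 3 * se)
    expect_equal(sd(g), p$growth_log2_sd, tolerance = 0.1)
  }
})
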