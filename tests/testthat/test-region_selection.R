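make_scan_cohort <- function(n = 1500, seed = 30, ...) {
  generate_cohort(cohort_params(missing_outcome_fraction = 0, ...), n, seed)
}

test_that("scans localize the generator's eloquent regions", {
  co <- make_scan_cohort()
  resp <- responsiveness_scan(co)
  eloq <- eloquence_scan(co)
  # treatment attenuates disconnection growth in eloquent regions
  elo_cols <- paste0("dchaco_", c(2, 3, 5, 7))
  expect_true(all(resp$beta[resp$region %in% elo_cols] < 0))
  expect_true(all(resp$p[resp$region %in% elo_cols] < 0.01))
  # all regions respond through growth, but eloquent ones respond more
  expect_lt(max(resp$p[resp$region %in% elo_cols]),
            min(resp$p[!resp$region %in% elo_cols]))
  # only eloquent regions predict outcome strongly (OR < 1)
  expect_true(all(eloq$or[eloq$region %in% elo_cols] < 1))
  expect_true(all(eloq$p[eloq$region %in% elo_cols] < 0.01))
})

test_that("null generator gives near-zero betas and unit ORs", {
  co <- make_scan_cohort(
    n = 1200, seed = 31,
    arm_growth_log2_mean = c(P = 0.6, A = 0.6), eloquent_delta_A = 0,
    outcome_coefs = list(b0 = 0, bA = 0.4, bG = 0, br = numeric(8),
                         bage = 0, bN = 0, bV = 0))
  resp <- responsiveness_scan(co)
  eloq <- eloquence_scan(co)
  expect_lt(mean(abs(resp$beta)), 0.08)
  expect_true(all(eloq$or > 0.8 & eloq$or < 1.25))
})

test_that("standardization makes scans scale invariant", {
  co <- make_scan_cohort(n = 400, seed = 32)
  co2 <- co
  for (cl in paste0("dchaco_", 1:8)) co2$table[[cl]] <- 2 * co2$table[[cl]]
  expect_equal(responsiveness_scan(co)$beta, responsiveness_scan(co2)$beta,
               tolerance = 1e-10)
  expect_equal(eloquence_scan(co)$or, eloquence_scan(co2)$or,
               tolerance = 1e-10)
})

test_that("qualification, ranking and Spearman correlation", {
  co <- make_scan_cohort()
  resp <- responsiveness_scan(co)
  eloq <- eloquence_scan(co)
  rk <- qualify_and_rank(resp, eloq)
  elo_cols <- paste0("dchaco_", c(2, 3, 5, 7))
  expect_true(all(elo_cols %in% rk$qualified))
  expect_equal(rk$table$region[order(rk$table$rank_resp)], rk$resp_order)
  expect_true(rk$spearman_rho >= -1 && rk$spearman_rho <= 1)
  # identical rankings -> rho = 1
  rk2 <- qualify_and_rank(resp, transform(
    resp, or = exp(beta), lo = exp(lo), hi = exp(hi), separation = FALSE))
  expect_equal(rk2$spearman_rho, 1)
})

test_that("empty qualified set degrades to growth-only with a warning", {
  resp <- data.frame(region = paste0("dchaco_", 1:3), beta = c(0.1, 0, -0.1),
                     lo = c(-0.2, -0.1, -0.3), hi = c(0.4, 0.1, 0.1),
                     p = c(0.5, 0.9, 0.4), skipped = FALSE)
  eloq <- data.frame(region = paste0("dchaco_", 1:3), or = c(1.1, 0.9, 1),
                     lo = c(0.8, 0.7, 0.9), hi = c(1.5, 1.2, 1.2),
                     p = c(0.6, 0.5, 0.9), separation = FALSE)
  expect_warning(rk <- qualify_and_rank(resp, eloq), "no region qualifies")
  expect_length(rk$qualified, 0)
  expect_warning(specs <- enumerate_models(rk), "growth-only")
  expect_length(specs, 1L)
  expect_equal(specs[[1]]$label, "growth_only")
})

test_that("model enumeration dedupes, is monotone, records provenance", {
  # hand-built ranking: nested orders, qualified = 4 regions
  rk <- structure(list(
    resp_order = paste0("dchaco_", c(1, 2, 3, 4, 5, 6)),
    eloq_order = paste0("dchaco_", c(2, 1, 4, 3, 6, 5)),
    qualified = paste0("dchaco_", 1:4)), class = "region_ranking")
  specs <- enumerate_models(rk, i_max = 6, j_max = 6)
  labels <- vapply(specs, function(s) s$label, "")
  sets <- lapply(specs, function(s) s$regions)
  expect_equal(labels[1], "growth_only")
  # all sets are subsets of the qualified regions, no duplicates
  expect_true(all(vapply(sets[-1], function(s)
    all(s %in% rk$qualified), TRUE)))
  keys <- vapply(sets, paste, "", collapse = ",")
  expect_false(any(duplicated(keys)))
  # monotone: growing (i, j) never removes regions at fixed thresholds
  for (sp in specs[-1]) {
    expect_gt(nrow(sp$provenance), 0)
    ij <- sp$provenance[1, ]
    later <- intersect(intersect(head(rk$resp_order, ij$i + 1),
                                 head(rk$eloq_order, ij$j + 1)),
                       rk$qualified)
    expect_true(all(sp$regions %in% later))
  }
  # single qualified region: exactly one region model
  rk1 <- structure(list(resp_order = rk$resp_order,
                        eloq_order = rk$eloq_order,
                        qualified = "dchaco_1"), class = "region_ranking")
  specs1 <- enumerate_models(rk1)
  expect_length(specs1, 2L)
  expect_equal(specs1[[2]]$regions, "dchaco_1")
})
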