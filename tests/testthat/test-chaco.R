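test_that("endpoint assignment counts self-pairs once and drops background", {
  labels <- array(c(1L, 1L, 0L, 2L), dim = c(4L, 1L, 1L))
  parc <- manual_parcellation(labels, "L")
  sl <- list(rbind(c(1L, 1L, 1L), c(4L, 1L, 1L)),  # A-B
             rbind(c(1L, 1L, 1L), c(2L, 1L, 1L)),  # A-A (self)
             rbind(c(2L, 1L, 1L), c(3L, 1L, 1L)))  # endpoint in background
  tg <- assign_endpoints(tractogram("t", sl), parc)
  expect_equal(tg$n_dropped, 1L)
  expect_equal(length(tg$streamlines), 2L)
  expect_equal(unname(tg$totals), c(2L, 1L))  # self-pair counts once for A
  expect_error(assign_endpoints(tractogram("t", sl[0]), parc),
               class = "chacomed_error")
})

test_that("lesion_hits matches brute force on the worked toy", {
  toy <- toy_tractogram_abc()
  lesion <- toy_lesion(toy$parc, rbind(c(1L, 1L, 1L)))
  expect_equal(lesion_hits(toy$tg, lesion), 1L)  # exactly s1
  empty <- toy_lesion(toy$parc, matrix(integer(0), 0, 3))
  expect_equal(lesion_hits(toy$tg, empty), integer(0))
  full <- lesion_mask(array(TRUE, dim(toy$parc$labels)), 1)
  expect_equal(lesion_hits(toy$tg, full), 1:3)
})

test_that("chaco_single reproduces the worked toy proportions", {
  toy <- toy_tractogram_abc()
  lesion <- toy_lesion(toy$parc, rbind(c(1L, 1L, 1L)))
  sc <- chaco_single(toy$tg, toy$parc, lesion)
  expect_equal(as.vector(sc), c(1 / 2, 1 / 3))
  # empty lesion -> all zero; full coverage -> all one
  empty <- toy_lesion(toy$parc, matrix(integer(0), 0, 3))
  expect_equal(as.vector(chaco_single(toy$tg, toy$parc, empty)), c(0, 0))
  full <- lesion_mask(array(TRUE, dim(toy$parc$labels)), 1)
  expect_equal(as.vector(chaco_single(toy$tg, toy$parc, full)), c(1, 1))
})

test_that("zero-total regions are undefined, not zero", {
  labels <- array(c(1L, 1L, 2L, 3L), dim = c(4L, 1L, 1L))
  parc <- manual_parcellation(labels, "L")
  sl <- list(rbind(c(1L, 1L, 1L), c(3L, 1L, 1L)))  # connects 1 and 2 only
  tg <- assign_endpoints(tractogram("t", sl), parc)
  sc <- chaco_single(tg, parc, toy_lesion(parc, rbind(c(1L, 1L, 1L))))
  expect_true(is.na(sc[["3"]]))
  expect_equal(attr(sc, "undefined"), "3")
  expect_error(
    chaco_score(list(tg), parc, toy_lesion(parc, rbind(c(1L, 1L, 1L))),
                strict = TRUE),
    class = "chacomed_undefined_region")
})

test_that("chaco_score averages per-subject proportions", {
  labels <- array(c(1L, 1L, 2L, 2L), dim = c(4L, 1L, 1L))
  parc <- manual_parcellation(labels, "L")
  # ref1: A total 2, 1 hit (A = 0.5); ref2: A total 4, 1 hit (A = 0.25)
  ref1 <- assign_endpoints(tractogram("r1", list(
    rbind(c(1L, 1L, 1L), c(3L, 1L, 1L)),
    rbind(c(2L, 1L, 1L), c(3L, 1L, 1L)))), parc)
  ref2 <- assign_endpoints(tractogram("r2", list(
    rbind(c(1L, 1L, 1L), c(3L, 1L, 1L)),
    rbind(c(2L, 1L, 1L), c(3L, 1L, 1L)),
    rbind(c(2L, 1L, 1L), c(4L, 1L, 1L)),
    rbind(c(2L, 1L, 1L), c(4L, 1L, 1L)))), parc)
  lesion <- toy_lesion(parc, rbind(c(1L, 1L, 1L)))
  pr <- chaco_score(list(ref1, ref2), parc, lesion)
  expect_equal(pr$scores[["1"]], mean(c(0.5, 0.25)))
  expect_equal(dim(pr$raw), c(2L, 2L))
  # identical subjects: mean equals the single-subject score
  pr2 <- chaco_score(list(ref1, ref1), parc, lesion)
  expect_equal(pr2$scores, chaco_score(list(ref1), parc, lesion)$scores)
})

test_that("implementation matches the brute-force enumerator exactly", {
  withr::local_seed(401)
  for (i in 1:40) {
    toy <- random_toy()
    got <- chaco_single(toy$tg, toy$parc, toy$lesion)
    want <- chaco_brute(toy$tg, toy$parc, toy$lesion)
    expect_equal(as.vector(got), as.vector(want))
  }
})

test_that("monotonicity: nested lesions give pointwise nondecreasing scores", {
  withr::local_seed(402)
  for (i in 1:20) {
    toy <- random_toy()
    m2 <- toy$lesion$mask
    m1 <- m2 & (array(runif(length(m2)), dim = dim(m2)) < 0.5)
    s1 <- chaco_single(toy$tg, toy$parc, lesion_mask(m1, 1))
    s2 <- chaco_single(toy$tg, toy$parc, lesion_mask(m2, 1))
    ok <- !is.na(s1) & !is.na(s2)
    expect_true(all(s1[ok] <= s2[ok] + 1e-12))
    expect_true(all(s1[ok] >= 0 & s2[ok] <= 1))
  }
})

test_that("hemisphere restriction keeps contralateral contributions", {
  labels <- array(0L, dim = c(4L, 2L, 1L))
  labels[1, 1, 1] <- 1L  # L region
  labels[4, 1, 1] <- 2L  # R region
  labels[4, 2, 1] <- 3L  # R region
  parc <- manual_parcellation(labels, c("L", "R"))
  # cross-hemisphere streamline L->R plus an R-only streamline
  sl <- list(rbind(c(1L, 1L, 1L), c(2L, 1L, 1L), c(3L, 1L, 1L), c(4L, 1L, 1L)),
             rbind(c(4L, 1L, 1L), c(4L, 2L, 1L)))
  tg <- assign_endpoints(tractogram("t", sl), parc)
  lesion_r <- toy_lesion(parc, rbind(c(4L, 1L, 1L)))  # right-sided lesion
  pr <- restrict_to_stroke_hemisphere(chaco_score(list(tg), parc, lesion_r),
                                      lesion_r, parc)
  expect_equal(pr$hemisphere, "R")
  expect_setequal(names(pr$scores), c("2", "3"))
  # the cross-hemisphere streamline is hit and counted for region 2
  expect_equal(pr$scores[["2"]], 1)
  # bilateral lesion is rejected
  bil <- toy_lesion(parc, rbind(c(1L, 1L, 1L), c(4L, 1L, 1L)))
  expect_error(restrict_to_stroke_hemisphere(
    chaco_score(list(tg), parc, bil), bil, parc),
    class = "chacomed_bilateral")
})

test_that("chaco_change signs and region checks", {
  toy <- toy_tractogram_abc()
  l1 <- toy_lesion(toy$parc, rbind(c(1L, 1L, 1L)))
  l2 <- toy_lesion(toy$parc, rbind(c(1L, 1L, 1L), c(2L, 1L, 1L)))
  p1 <- chaco_score(list(toy$tg), toy$parc, l1, "T1")
  p2 <- chaco_score(list(toy$tg), toy$parc, l2, "T2")
  d <- chaco_change(p1, p2)
  expect_true(all(d >= 0))          # growing lesion
  expect_equal(unname(chaco_change(p1, p1)), c(0, 0))
  d_shrink <- chaco_change(p2, p1)  # shrinking lesion: negatives allowed
  expect_true(any(d_shrink < 0))
  p_bad <- p2
  names(p_bad$scores) <- c("9", "10")
  expect_error(chaco_change(p1, p_bad), class = "chacomed_region_mismatch")
})

test_that("chaco_score equals the mean of chaco_single across subjects", {
  withr::local_seed(403)
  toy <- random_toy()
  # second subject: every other streamline of the first
  keep <- seq(1, length(toy$tg$streamlines), by = 2)
  tg2 <- assign_endpoints(tractogram("rand2", toy$tg$streamlines[keep]),
                          toy$parc)
  refs <- list(toy$tg, tg2)
  pr <- chaco_score(refs, toy$parc, toy$lesion)
  manual <- rowMeans(cbind(chaco_single(toy$tg, toy$parc, toy$lesion),
                           chaco_single(tg2, toy$parc, toy$lesion)),
                     na.rm = TRUE)
  expect_equal(unname(pr$scores), unname(manual))
})
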