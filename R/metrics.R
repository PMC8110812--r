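# Rank-based lesion and disconnection metrics: growth ratios, Wilcoxon /
# Mann-Whitney tests, probability-of-superiority effect sizes and
# surprisal (S-value) reporting.

#' Growth ratio of lesion volumes
#'
#' The mediator variable of all downstream models is the log2 of
#' `vol_T2 / vol_T1` ("per doubling" scale). Zero volumes are replaced by
#' a configurable floor before forming the ratio so the log stays finite.
#'
#' @param vol_T1,vol_T2 volumes in ml (>= 0).
#' @param floor replacement for zero volumes; default half of one 1 mm
#'   voxel (5e-4 ml).
#' @return list of class `growth_record`: `vol_T1`, `vol_T2`, `ratio`,
#'   `log2_ratio`.
#' @export
growth_ratio <- function(vol_T1, vol_T2, floor = 5e-4) {
  assert_that(all(vol_T1 >= 0) && all(vol_T2 >= 0),
              "volumes must be non-negative")
  v1 <- pmax(vol_T1, floor)
  v2 <- pmax(vol_T2, floor)
  structure(list(vol_T1 = vol_T1, vol_T2 = vol_T2, ratio = v2 / v1,
                 log2_ratio = log2(v2 / v1)),
            class = "growth_record")
}

#' Probability of superiority (common-language effect size)
#'
#' Paired version: `(#\{d > 0\} + 0.5 #\{d = 0\}) / n` for within-pair
#' differences `d = x - y`. Unpaired: the normalized Mann-Whitney U
#' statistic `(#\{x_i > y_j\} + 0.5 ties) / (n_x n_y)`. Ties are credited
#' one half, consistent with the U statistic.
#'
#' @param x,y numeric samples; equal length if `paired`.
#' @param paired logical.
#' @return estimate in `[0, 1]`.
#' @export
prob_superiority <- function(x, y, paired = FALSE) {
  assert_that(length(x) > 0 && length(y) > 0, "empty input")
  if (paired) {
    assert_that(length(x) == length(y), "paired samples of unequal length")
    d <- x - y
    (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
  } else {
    cmp <- outer(x, y, ">")
    tie <- outer(x, y, "==")
    (sum(cmp) + 0.5 * sum(tie)) / (length(x) * length(y))
  }
}

#' Surprisal of a p-value, in bits
#'
#' `s = -log2(p)`: the information against the tested hypothesis. Base 2
#' is used so that p = 0.5 carries exactly one bit.
#'
#' @param p p-value(s) in (0, 1].
#' @return surprisal in bits.
#' @export
surprisal <- function(p) {
  assert_that(all(p > 0) && all(p <= 1), "p must be in (0, 1]")
  -log2(p)
}

rank_summary <- function(estimate, p, n) {
  flagged <- is.na(p)
  structure(list(estimate = estimate, p_value = p,
                 surprisal = if (flagged) NA_real_ else surprisal(p),
                 n = n, flagged = flagged),
            class = "effect_summary")
}

#' Paired Wilcoxon signed-rank test with probability-of-superiority
#'
#' Two-sided signed-rank test of `x_T2` vs `x_T1` (exact for small
#' tie-free samples, normal approximation otherwise, as in
#' [stats::wilcox.test()]); the effect size is `P(T2 > T1)` with ties
#' credited one half. All-tied data leave the p-value undefined
#' (`flagged`).
#'
#' @param x_T1,x_T2 paired samples.
#' @return an `effect_summary` list: `estimate`, `p_value`, `surprisal`
#'   (bits), `n`, `flagged`.
#' @export
paired_rank_test <- function(x_T1, x_T2) {
  assert_that(length(x_T1) == length(x_T2), "paired samples differ in length")
  assert_that(length(x_T1) >= 2, "need n >= 2")
  est <- prob_superiority(x_T2, x_T1, paired = TRUE)
  d <- x_T2 - x_T1
  p <- if (all(d == 0)) NA_real_ else
    suppressWarnings(wilcox.test(x_T2, x_T1, paired = TRUE)$p.value)
  rank_summary(est, p, length(x_T1))
}

#' Two-sample Mann-Whitney U test with probability-of-superiority
#'
#' @param x_P,x_A samples for the two groups (e.g. placebo, alteplase).
#' @return an `effect_summary` with `estimate = P(x_P > x_A)`.
#' @export
two_sample_rank_test <- function(x_P, x_A) {
  assert_that(length(x_P) >= 2 && length(x_A) >= 2, "need n >= 2 per group")
  est <- prob_superiority(x_P, x_A)
  all_tied <- length(unique(c(x_P, x_A))) == 1L
  p <- if (all_tied) NA_real_ else
    suppressWarnings(wilcox.test(x_P, x_A)$p.value)
  rank_summary(est, p, c(length(x_P), length(x_A)))
}

#' Mass-univariate per-region scan of disconnection effects
#'
#' For every region of a long ChaCo table, computes the three rank-based
#' contrasts: effect of time `P(T2 > T1)` (paired signed-rank), effect of
#' treatment `P(P > A)` at each time point (Mann-Whitney), and the
#' time-by-treatment interaction `P(dP > dA)` on within-subject changes
#' (Mann-Whitney). P-values are reported without multiplicity adjustment,
#' with surprisal in bits alongside.
#'
#' @param chaco_long a [cohort_chaco_long()] table.
#' @return data.frame: `region`, `contrast`, `estimate`, `p`, `surprisal`,
#'   `n`.
#' @export
region_scan <- function(chaco_long) {
  out <- list()
  for (r in unique(chaco_long$region)) {
    d <- chaco_long[chaco_long$region == r, ]
    w1 <- d[d$time == "T1", ]
    w2 <- d[d$time == "T2", ]
    common <- intersect(w1$subject, w2$subject)
    w1 <- w1[match(common, w1$subject), ]
    w2 <- w2[match(common, w2$subject), ]
    res <- list(
      time = paired_rank_test(w1$chaco, w2$chaco),
      treatment_T1 = two_sample_rank_test(w1$chaco[w1$treatment == "P"],
                                          w1$chaco[w1$treatment == "A"]),
      treatment_T2 = two_sample_rank_test(w2$chaco[w2$treatment == "P"],
                                          w2$chaco[w2$treatment == "A"]),
      interaction = {
        delta <- w2$chaco - w1$chaco
        two_sample_rank_test(delta[w1$treatment == "P"],
                             delta[w1$treatment == "A"])
      })
    for (ct in names(res)) {
      out[[length(out) + 1L]] <- data.frame(
        region = r, contrast = ct, estimate = res[[ct]]$estimate,
        p = res[[ct]]$p_value, surprisal = res[[ct]]$surprisal,
        n = length(common), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
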