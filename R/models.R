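# Parametric models of disconnection progression and outcome.
#
# ChaCo scores are semicontinuous: a point mass at zero (region untouched
# by the lesion) and a heavy-tailed positive part. They are modelled as a
# two-component mixture: a logistic model for P(ChaCo > 0) and, on the
# positive rows only, a Gaussian linear mixed model of log(ChaCo) with a
# per-subject random intercept:
#   log(ChaCo+) ~ time * treatment + region * (time + log(volume)) + (1 | subject)

#' Simulate a long ChaCo table from the mixture law
#'
#' Direct simulator of the semicontinuous model above, used to study the
#' fitting machinery at known parameter values (type-I calibration, power,
#' ratio recovery) without the cost of voxel-level lesion simulation.
#'
#' @param n_per_arm subjects per arm.
#' @param n_regions regions.
#' @param time_ratio_P,time_ratio_A multiplicative T2/T1 change of the
#'   positive ChaCo part per arm (1 = no change).
#' @param zero_prob probability of a structural zero per subject x region
#'   x time.
#' @param subject_sd SD of the per-subject random intercept (log scale).
#' @param resid_sd residual SD (log scale).
#' @param base_log mean log ChaCo at T1.
#' @param vol_meanlog,vol_sdlog baseline volume law (ml, log scale);
#'   volumes double on average at T2.
#' @param seed integer seed.
#' @return data.frame with `subject`, `region`, `time`, `treatment`,
#'   `chaco`, `volume`.
#' @export
simulate_chaco_table <- function(n_per_arm = 50, n_regions = 6,
                                 time_ratio_P = 1.7, time_ratio_A = 1.15,
                                 zero_prob = 0.2, subject_sd = 0.8,
                                 resid_sd = 0.6, base_log = -4,
                                 vol_meanlog = log(3), vol_sdlog = 1,
                                 seed = 1L) {
  with_seed(derive_seed(seed, "chaco_table"), {
    n <- 2L * n_per_arm
    subj <- sprintf("s%03d", seq_len(n))
    arm <- rep(c("P", "A"), each = n_per_arm)
    b_subj <- rnorm(n, 0, subject_sd)
    v1 <- rlnorm(n, vol_meanlog, vol_sdlog)
    v2 <- v1 * 2^rnorm(n, 1, 0.3)
    region_eff <- rnorm(n_regions, 0, 0.5)
    grid <- expand.grid(i = seq_len(n), region = seq_len(n_regions),
                        time = c("T1", "T2"), stringsAsFactors = FALSE)
    tr <- ifelse(grid$time == "T2",
                 ifelse(arm[grid$i] == "P", log(time_ratio_P),
                        log(time_ratio_A)), 0)
    vol <- ifelse(grid$time == "T2", v2[grid$i], v1[grid$i])
    mu <- base_log + b_subj[grid$i] + region_eff[grid$region] +
      0.5 * log(vol) + tr
    y <- exp(rnorm(nrow(grid), mu, resid_sd))
    y[runif(nrow(grid)) < zero_prob] <- 0
    data.frame(subject = subj[grid$i], region = paste0("r", grid$region),
               time = grid$time, treatment = arm[grid$i], chaco = y,
               volume = vol, stringsAsFactors = FALSE)
  })
}

fixed_rhs <- function(n_regions) {
  if (n_regions > 1)
    "time * treatment + region * (time + log_vol)"
  else "time * treatment + log_vol"
}

#' Fit the two-component mixture model of ChaCo progression
#'
#' Positive part: Gaussian linear mixed model of `log(chaco)` on the
#' positive rows, fixed effects `time * treatment + region * (time +
#' log(volume))`, random intercept per subject, fitted by maximum
#' likelihood. Zero part (optional): logistic mixed model of
#' `1[chaco > 0]` with the same fixed-effect structure; if it fails to
#' converge the `region:log_vol` term is dropped and the fallback is
#' recorded. An analysis-of-deviance table with one chi-square per term is
#' computed by model comparison respecting marginality (type-II: a term is
#' tested against the model containing all terms that do not include it).
#'
#' @param table a long ChaCo table ([cohort_chaco_long()] or
#'   [simulate_chaco_table()]).
#' @param zero_part fit the zero component (default `TRUE`).
#' @param anova_table compute the per-term type-II table (several ML
#'   refits; default `TRUE`).
#' @return object of class `mixture_fit`: `positive` (the lmer fit),
#'   `zero` (glmer fit or `NULL`), `zero_fallback`, `wald`
#'   (data.frame term / chisq / df / p), `interaction` (1-df Wald test of
#'   time:treatment), `data` (the positive-part model frame inputs).
#' @export
fit_mixture <- function(table, zero_part = TRUE, anova_table = TRUE) {
  assert_that(all(c("subject", "region", "time", "treatment", "chaco",
                    "volume") %in% names(table)),
              "long ChaCo table is missing required columns")
  assert_that(length(unique(table$time)) == 2, "need both time points")
  for (a in c("P", "A"))
    assert_that(length(unique(table$subject[table$treatment == a])) >= 2,
                "need >= 2 subjects per arm")
  tab <- table
  tab$log_vol <- log(pmax(tab$volume, 5e-4))
  tab$time <- factor(tab$time, levels = c("T1", "T2"))
  tab$treatment <- factor(tab$treatment, levels = c("P", "A"))
  tab$region <- factor(tab$region)
  nreg <- nlevels(tab$region)

  pos <- tab[tab$chaco > 0, ]
  pos$log_chaco <- log(pos$chaco)
  rhs <- fixed_rhs(nreg)
  form <- as.formula(paste("log_chaco ~", rhs, "+ (1 | subject)"))
  fit <- lme4::lmer(form, data = pos, REML = FALSE)
  if (lme4::isSingular(fit))
    warning("positive-part fit is singular; diagnostics: ",
            paste(names(lme4::getME(fit, "theta")), collapse = ", "),
            call. = FALSE)

  wald <- if (anova_table) type2_table(form, pos) else NULL

  # 1-df Wald z test of the time:treatment interaction from the full fit
  fe <- lme4::fixef(fit)
  vc <- as.matrix(vcov(fit))
  ix <- grep("^timeT2:treatmentA$", names(fe))
  inter <- if (length(ix) == 1) {
    z <- fe[ix] / sqrt(vc[ix, ix])
    list(estimate = unname(fe[ix]), z = unname(z),
         chisq = unname(z^2), p = unname(2 * pnorm(-abs(z))))
  } else NULL

  zero_fit <- NULL
  zero_fallback <- FALSE
  if (zero_part) {
    tab$nonzero <- as.integer(tab$chaco > 0)
    zf <- as.formula(paste("nonzero ~", rhs, "+ (1 | subject)"))
    zero_fit <- tryCatch(
      suppressWarnings(lme4::glmer(zf, data = tab, family = binomial(),
                                   nAGQ = 0L)),
      error = function(e) NULL)
    if (is.null(zero_fit) && nreg > 1) {
      zero_fallback <- TRUE
      zf <- nonzero ~ time * treatment + region * time + log_vol +
        (1 | subject)
      zero_fit <- tryCatch(
        suppressWarnings(lme4::glmer(zf, data = tab, family = binomial(),
                                     nAGQ = 0L)),
        error = function(e) NULL)
    }
  }

  structure(list(positive = fit, zero = zero_fit,
                 zero_fallback = zero_fallback, wald = wald,
                 interaction = inter, data = pos),
            class = "mixture_fit")
}

# Type-II analysis of deviance by model comparison respecting marginality:
# term T is tested by comparing the ML fit containing every fixed term
# that does not include T against the same model plus T.
type2_table <- function(full_formula, data) {
  rhs_terms <- attr(stats::terms(lme4::nobars(full_formula)), "term.labels")
  re_part <- "(1 | subject)"
  rows <- lapply(rhs_terms, function(tt) {
    contains <- vapply(rhs_terms, function(o) {
      pt <- strsplit(tt, ":", fixed = TRUE)[[1]]
      po <- strsplit(o, ":", fixed = TRUE)[[1]]
      all(pt %in% po)
    }, logical(1))
    base_terms <- rhs_terms[!contains]
    with_terms <- c(base_terms, tt)
    f0 <- as.formula(paste("log_chaco ~",
                           if (length(base_terms))
                             paste(base_terms, collapse = " + ") else "1",
                           "+", re_part))
    f1 <- as.formula(paste("log_chaco ~",
                           paste(with_terms, collapse = " + "), "+", re_part))
    m0 <- lme4::lmer(f0, data = data, REML = FALSE)
    m1 <- lme4::lmer(f1, data = data, REML = FALSE)
    chisq <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
    df <- attr(logLik(m1), "df") - attr(logLik(m0), "df")
    data.frame(term = tt, chisq = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-arm geometric T2/T1 ratios of positive ChaCo
#'
#' Exponentiated marginal time contrasts on the log scale, averaged over
#' regions (balanced grid) at the mean log-volume, with Wald 95% CIs from
#' the fixed-effect covariance. The ratio of the two arm ratios equals the
#' exponentiated time:treatment coefficient.
#'
#' @param fit a [fit_mixture()] result.
#' @return data.frame: `arm`, `ratio`, `lo`, `hi`.
#' @export
arm_time_ratios <- function(fit) {
  mod <- fit$positive
  fe <- lme4::fixef(mod)
  vc <- as.matrix(vcov(mod))
  dat <- fit$data
  regions <- levels(dat$region)
  mlv <- mean(dat$log_vol)
  tt <- stats::delete.response(stats::terms(lme4::nobars(stats::formula(mod))))
  grid <- expand.grid(time = factor(c("T1", "T2"), levels = c("T1", "T2")),
                      treatment = factor(c("P", "A"), levels = c("P", "A")),
                      region = factor(regions, levels = regions))
  grid$log_vol <- mlv
  X <- model.matrix(tt, grid)
  out <- lapply(c("P", "A"), function(a) {
    c2 <- colMeans(X[grid$treatment == a & grid$time == "T2", , drop = FALSE])
    c1 <- colMeans(X[grid$treatment == a & grid$time == "T1", , drop = FALSE])
    cv <- c2 - c1
    est <- sum(cv * fe)
    se <- sqrt(as.numeric(t(cv) %*% vc %*% cv))
    data.frame(arm = a, ratio = exp(est), lo = exp(est - 1.96 * se),
               hi = exp(est + 1.96 * se), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Adjusted logistic regressions of favorable outcome
#'
#' Fits `favorable ~ <exposure> + age + nihss + log(vol_T1)` on subjects
#' with non-missing outcome, where the exposure is treatment allocation
#' (`"arm"`) or the log2 growth ratio (`"growth"`; the OR is then "per
#' doubling" of the volume ratio, additionally adjusted for treatment).
#' Profile-likelihood CIs, Wald p-values. Complete separation is flagged.
#'
#' @param cohort a [generate_cohort()] result or its `table`.
#' @param exposure `"arm"` or `"growth"`.
#' @param level CI level.
#' @return data.frame: `term`, `or`, `lo`, `hi`, `p`, `separation`.
#' @export
outcome_logistic <- function(cohort, exposure = c("arm", "growth"),
                             level = 0.95) {
  exposure <- match.arg(exposure)
  tab <- if (inherits(cohort, "cohort")) cohort$table else cohort
  tab <- tab[!is.na(tab$favorable), ]
  tab$armA <- as.integer(tab$arm == "A")
  tab$log_vol_T1 <- log(pmax(tab$vol_T1, 5e-4))
  form <- if (exposure == "arm")
    favorable ~ armA + age + nihss + log_vol_T1
  else favorable ~ log2_growth + armA + age + nihss + log_vol_T1
  fit <- glm(form, data = tab, family = binomial())
  sep <- !fit$converged || any(abs(coef(fit)) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (sep) warning("possible complete separation in outcome model",
                   call. = FALSE)
  ci <- suppressMessages(tryCatch(confint(fit, level = level),
                                  error = function(e) {
                                    se <- sqrt(diag(vcov(fit)))
                                    cbind(coef(fit) - 1.96 * se,
                                          coef(fit) + 1.96 * se)
                                  }))
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), or = exp(sm[, 1]), lo = exp(ci[, 1]),
             hi = exp(ci[, 2]), p = sm[, 4], separation = sep,
             row.names = NULL, stringsAsFactors = FALSE)
}
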