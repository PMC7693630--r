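# Multilevel model, likelihood-ratio tests, area binning, per-patient
# effects, two-scan reproducibility.

simNull <- function(seed, n_per = 30, sd_slope = 0, sd_eps = 0.1) {
  set.seed(seed)
  pats <- sprintf("P%02d", 1:8); cls <- c(250, 300, 350, 600)
  d <- expand.grid(patient = pats, cycle_length = cls,
                   rep = seq_len(n_per), KEEP.OUT.ATTRS = FALSE)
  u <- rnorm(8, 0, 0.05); names(u) <- pats
  v <- rnorm(4, 0, 0.02); names(v) <- as.character(cls)
  b2 <- rnorm(8, 0, sd_slope); names(b2) <- pats
  d$intensity <- rnorm(nrow(d), 1.5, 1)
  d$cv <- 1 + u[d$patient] + v[as.character(d$cycle_length)] +
    (-0.104 + b2[d$patient]) * d$intensity + rnorm(nrow(d), 0, sd_eps)
  d
}

test_that("degenerate inputs take the documented paths", {
  # data exactly on a line: exact-fit flag, exact coefficients, infinite lik
  d <- simNull(1, sd_eps = 0)
  d$cv <- 0.9 - 0.2 * d$intensity
  fit <- fitMultilevel(d)
  expect_true(fit@exact_fit)
  expect_identical(fit@loglik, Inf)
  expect_equal(unname(fixedEffects(fit)), c(0.9, -0.2), tolerance = 1e-10)

  dconst <- simNull(2); dconst$intensity <- 1
  expect_error(fitMultilevel(dconst), "constant")
  done <- simNull(3); done <- done[done$patient == "P01", ]
  expect_error(fitMultilevel(done), "2 patients")
})

test_that("without random effects the fit reproduces OLS exactly", {
  d <- simNull(4)
  fit <- fitMultilevel(d, random_slopes = FALSE, random_intercepts = FALSE)
  ols <- lm(cv ~ intensity, data = d)
  expect_equal(fit@beta0, unname(coef(ols)[1]), tolerance = 1e-8)
  expect_equal(fit@beta1, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(fit@loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("fixed effects are invariant to relabeling patients and CLs", {
  d <- simNull(5, sd_slope = 0.02)
  fit1 <- fitMultilevel(d)
  d2 <- d
  d2$patient <- factor(d$patient,
                       labels = rev(sprintf("Q%02d", 1:8)))
  d2$cycle_length <- factor(d$cycle_length, labels = c("d", "c", "b", "a"))
  fit2 <- fitMultilevel(d2)
  expect_equal(fit1@beta1, fit2@beta1, tolerance = 1e-6)
  expect_equal(fit1@beta0, fit2@beta0, tolerance = 1e-6)
  expect_equal(fit1@loglik, fit2@loglik, tolerance = 1e-6)
})

test_that("likelihood-ratio test matches a brute-force refit", {
  d <- simNull(6, sd_slope = 0.03)
  full <- fitMultilevel(d, random_slopes = TRUE)
  red <- fitMultilevel(d, random_slopes = FALSE)
  lrt <- likelihoodRatioTest(full, red)
  expect_equal(lrt$statistic, 2 * (full@loglik - red@loglik),
               tolerance = 1e-10)
  expect_identical(lrt$df, full@df - red@df)
  expect_gte(lrt$statistic, 0)
  # identical models: statistic 0, p = 1
  self <- likelihoodRatioTest(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  expect_error(likelihoodRatioTest(red, full), "fewer parameters")
})

test_that("LRT for the random slope holds its size under the null", {
  # variance-on-the-boundary null: the chi-squared reference is conservative,
  # so the rejection rate at alpha = 0.05 must not exceed the nominal level
  # by more than Monte-Carlo noise
  n_sim <- 60
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    d <- simNull(100 + i, n_per = 15, sd_slope = 0)
    full <- fitMultilevel(d, random_slopes = TRUE)
    red <- fitMultilevel(d, random_slopes = FALSE)
    rej[i] <- likelihoodRatioTest(full, red)$p_value < 0.05
  }
  expect_lte(mean(rej), 0.10)
})

test_that("area-binned slopes use half-open bins and skip sparse bins", {
  d <- simNull(7)
  d$area_mm2 <- runif(nrow(d), 0, 30)
  d$area_mm2[1] <- 10.0  # boundary triad
  bins <- areaBinnedSlopes(d, bin_width_mm2 = 10, range_mm2 = c(0, 40))
  expect_identical(nrow(bins), 4L)
  # the 10.0 mm^2 triad counts in [10, 20), not [0, 10)
  n_manual <- sum(d$area_mm2 >= 10 & d$area_mm2 < 20)
  expect_identical(bins$n_triads[2], n_manual)
  expect_true(bins$skipped[4])  # empty bin
  expect_match(bins$reason[4], "insufficient data")
  # area-independent generative slope: flat beta1 across bins, truth in CIs
  ok <- !bins$skipped
  expect_true(all(bins$ci_lo[ok] <= -0.104 & -0.104 <= bins$ci_hi[ok]))
})

test_that("per-patient effects recover injected deviations and centre at zero", {
  d <- simNull(8, sd_slope = 0.02)
  # inject a +0.05 slope offset for one patient
  sel <- d$patient == "P03"
  d$cv[sel] <- d$cv[sel] + 0.05 * d$intensity[sel]
  fit <- fitMultilevel(d)
  eff <- perPatientEffects(fit)
  i3 <- which(eff$patient == "P03")
  expect_gt(eff$slope_dev[i3], 0.02)
  expect_true(eff$slope_lo[i3] <= eff$slope_dev[i3] + 0.05 ||
              eff$slope_p[i3] < 0.05)
  # shrinkage centring: deviations sum to approximately zero
  expect_lt(abs(sum(eff$slope_dev)), 0.02)
  expect_lt(abs(sum(eff$intercept_dev)), 0.05)
  # zero variance components: all deviations zero (exact-fit path)
  d0 <- simNull(9, sd_eps = 0)
  d0$cv <- 1 - 0.104 * d0$intensity
  eff0 <- perPatientEffects(fitMultilevel(d0))
  expect_true(all(eff0$slope_dev == 0) && all(eff0$intercept_dev == 0))
})

test_that("identical scans compare as identical; mismatched labels error", {
  d <- simNull(10, sd_slope = 0.02)
  fit1 <- fitMultilevel(d)
  cmp <- reproducibilityCompare(fit1, fit1)
  expect_identical(cmp$overall$slope_diff, 0)
  expect_identical(cmp$overall$slope_p, 1)
  expect_false(cmp$different)
  d2 <- d; d2$patient <- factor(sub("P0", "X0", d2$patient))
  expect_error(reproducibilityCompare(fit1, fitMultilevel(d2)),
               "patient labels")
})
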