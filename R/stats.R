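# Multilevel association model between conduction velocity and wall
# intensity, likelihood-ratio comparison, per-patient effects, triad-area
# binning and two-scan reproducibility.

.as_obs <- function(data) {
  req <- c("cv", "intensity", "patient", "cycle_length")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("observation table lacks column(s): ", paste(miss, collapse = ", "))
  data$patient <- factor(data$patient)
  data$cycle_length <- factor(data$cycle_length)
  data
}

#' Fit the multilevel CV-intensity model
#'
#' Maximum-likelihood fit (not REML, since model comparison uses
#' likelihood-ratio tests) of
#' \deqn{V_{ijk} = (\beta_0 + u_j + v_k) + (\beta_1 + \beta_{2j}) I_{ijk}
#'   + \epsilon_{ijk}}
#' with crossed random intercepts for patient (`u_j`) and pacing cycle
#' length (`v_k`) and, optionally, per-patient random slope deviations
#' (`beta_{2j}`) independent of the intercepts (the model has no
#' intercept-slope covariance term).
#'
#' Degenerate inputs are handled explicitly: data lying exactly on one line
#' (all variance components zero) would send the likelihood to infinity, so
#' such fits return the exact OLS line with the `exact_fit` flag and
#' `loglik = Inf`; a singular fit (some variance component collapsing to
#' zero) is flagged, not fatal. With `random_intercepts = FALSE` and
#' `random_slopes = FALSE` the model reduces to ordinary least squares.
#'
#' @param data data.frame of triad observations with columns `cv` (m/s),
#'   `intensity`, `patient`, `cycle_length` (and optionally `area_mm2`,
#'   `scan`).
#' @param metric `"ni"` or `"iir"` (recorded in the result).
#' @param random_slopes include per-patient random slopes (default TRUE).
#' @param random_intercepts include the crossed patient/CL random
#'   intercepts (default TRUE).
#' @return a [MixedModelFit-class].
#' @export
fitMultilevel <- function(data, metric = c("ni", "iir"),
                          random_slopes = TRUE, random_intercepts = TRUE) {
  metric <- match.arg(metric)
  data <- .as_obs(data)
  data <- data[is.finite(data$cv) & is.finite(data$intensity), ]
  if (var(data$intensity) == 0)
    stop("intensity is constant; slope not identifiable")
  if (random_intercepts &&
      (nlevels(droplevels(data$patient)) < 2 ||
       nlevels(droplevels(data$cycle_length)) < 2))
    stop("need at least 2 patients and 2 cycle lengths for crossed random intercepts")
  npat <- nlevels(droplevels(data$patient))
  ncl <- nlevels(droplevels(data$cycle_length))

  ols <- lm(cv ~ intensity, data = data)
  sse <- sum(ols$residuals^2)
  if (sse < 1e-16 * max(1, sum(data$cv^2))) {
    co <- coef(ols)
    return(new("MixedModelFit",
               beta0 = unname(co[1]), beta1 = unname(co[2]),
               se_beta0 = 0, se_beta1 = 0,
               u = setNames(rep(0, npat), levels(droplevels(data$patient))),
               v = setNames(rep(0, ncl), levels(droplevels(data$cycle_length))),
               beta2 = setNames(rep(0, npat), levels(droplevels(data$patient))),
               var_u = 0, var_v = 0, var_slope = 0, var_eps = 0,
               loglik = Inf, df = 2L, n_obs = nrow(data), metric = metric,
               singular = FALSE, exact_fit = TRUE, model = NULL))
  }

  if (!random_intercepts && !random_slopes) {
    smry <- summary(ols)$coefficients
    n <- nrow(data)
    ll <- as.numeric(logLik(ols))
    return(new("MixedModelFit",
               beta0 = unname(coef(ols)[1]), beta1 = unname(coef(ols)[2]),
               se_beta0 = smry[1, 2], se_beta1 = smry[2, 2],
               u = setNames(rep(0, npat), levels(droplevels(data$patient))),
               v = setNames(rep(0, ncl), levels(droplevels(data$cycle_length))),
               beta2 = setNames(rep(0, npat), levels(droplevels(data$patient))),
               var_u = 0, var_v = 0, var_slope = 0,
               var_eps = sse / n, loglik = ll, df = 3L,
               n_obs = as.integer(n), metric = metric,
               singular = FALSE, exact_fit = FALSE, model = ols))
  }

  terms <- c("intensity")
  if (random_intercepts)
    terms <- c(terms, "(1 | patient)", "(1 | cycle_length)")
  if (random_slopes)
    terms <- c(terms, "(0 + intensity | patient)")
  form <- stats::as.formula(paste("cv ~", paste(terms, collapse = " + ")))
  fit <- suppressMessages(
    lme4::lmer(form, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(grp, nm) {
    i <- which(vc$grp == grp & vc$var1 == nm)
    if (length(i)) vc$vcov[i] else 0
  }
  re <- lme4::ranef(fit)
  fx <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  pull_re <- function(grp, col) {
    if (!is.null(re[[grp]]) && col %in% names(re[[grp]]))
      setNames(re[[grp]][[col]], rownames(re[[grp]]))
    else setNames(numeric(0), character(0))
  }
  # with random slopes, lme4 lists 'patient' twice; collect by column name
  u_hat <- setNames(rep(0, npat), levels(droplevels(data$patient)))
  b2_hat <- u_hat
  v_hat <- setNames(rep(0, ncl), levels(droplevels(data$cycle_length)))
  for (g in seq_along(re)) {
    grp <- names(re)[g]
    fr <- re[[g]]
    if (grp == "patient" && "(Intercept)" %in% names(fr))
      u_hat[rownames(fr)] <- fr[["(Intercept)"]]
    if (grp == "patient" && "intensity" %in% names(fr))
      b2_hat[rownames(fr)] <- fr[["intensity"]]
    if (grp == "cycle_length" && "(Intercept)" %in% names(fr))
      v_hat[rownames(fr)] <- fr[["(Intercept)"]]
  }
  var_u <- if (random_intercepts) getvar("patient", "(Intercept)") else 0
  var_v <- if (random_intercepts) getvar("cycle_length", "(Intercept)") else 0
  var_s <- if (random_slopes) {
    i <- which(vc$grp %in% c("patient", "patient.1") & vc$var1 == "intensity")
    if (length(i)) vc$vcov[i[1]] else 0
  } else 0
  new("MixedModelFit",
      beta0 = unname(fx["(Intercept)"]), beta1 = unname(fx["intensity"]),
      se_beta0 = unname(se[1]), se_beta1 = unname(se[2]),
      u = u_hat, v = v_hat, beta2 = b2_hat,
      var_u = var_u, var_v = var_v, var_slope = var_s,
      var_eps = stats::sigma(fit)^2,
      loglik = as.numeric(logLik(fit)),
      df = as.integer(attr(logLik(fit), "df")),
      n_obs = nrow(data), metric = metric,
      singular = lme4::isSingular(fit), exact_fit = FALSE, model = fit)
}

#' Likelihood-ratio test between nested maximum-likelihood fits
#'
#' `statistic = 2 (logLik_full - logLik_reduced)`, referred to a chi-squared
#' distribution with df equal to the parameter-count difference. Both fits
#' must be ML fits of nested fixed/random structures on identical data.
#'
#' @param full,reduced [MixedModelFit-class] objects.
#' @param tol tolerance for a slightly negative statistic attributable to
#'   optimizer noise (variance components at the boundary routinely leave
#'   the full model a fraction of a log-likelihood unit short).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihoodRatioTest <- function(full, reduced, tol = 1e-3) {
  if (full@n_obs != reduced@n_obs)
    stop("invalid comparison: fits use different data")
  if (full@df < reduced@df)
    stop("invalid comparison: 'full' has fewer parameters than 'reduced'")
  stat <- 2 * (full@loglik - reduced@loglik)
  if (is.nan(stat)) stat <- 0  # both exact fits
  if (stat < -tol)
    stop("fit-quality error: reduced model has higher likelihood than full")
  stat <- max(stat, 0)
  df <- full@df - reduced@df
  p <- if (df == 0) as.numeric(stat <= tol) else
    pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Slope of the CV-intensity association by triad-area bin
#'
#' Bins triads into half-open `[lo, hi)` area intervals of `bin_width_mm2`
#' over `range_mm2` and fits the multilevel model within each bin. Bins with
#' insufficient data to support the model (fewer than `min_triads`
#' observations or fewer than 2 patients) are skipped with a logged reason.
#'
#' @param data triad observation data.frame (needs an `area_mm2` column).
#' @param bin_width_mm2 bin width (default 10 mm^2).
#' @param range_mm2 length-2 interval (default c(0, 160)).
#' @param metric `"ni"` or `"iir"`.
#' @param min_triads minimum observations per bin (default 50).
#' @param random_slopes passed to [fitMultilevel()].
#' @param conf_level confidence level of the Wald interval.
#' @return data.frame with bin_lo, bin_hi, beta1, se, ci_lo, ci_hi,
#'   n_triads, n_patients, skipped, reason.
#' @export
areaBinnedSlopes <- function(data, bin_width_mm2 = 10, range_mm2 = c(0, 160),
                             metric = c("ni", "iir"), min_triads = 50,
                             random_slopes = TRUE, conf_level = 0.95) {
  metric <- match.arg(metric)
  if (!"area_mm2" %in% names(data)) stop("data needs an 'area_mm2' column")
  lo <- seq(range_mm2[1], range_mm2[2] - bin_width_mm2, by = bin_width_mm2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(lo, function(l) {
    h <- l + bin_width_mm2
    sub <- data[data$area_mm2 >= l & data$area_mm2 < h, , drop = FALSE]
    npat <- length(unique(sub$patient))
    ncl <- length(unique(sub$cycle_length))
    base <- data.frame(bin_lo = l, bin_hi = h, beta1 = NA_real_,
                       se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                       n_triads = nrow(sub), n_patients = npat,
                       skipped = TRUE, reason = "", stringsAsFactors = FALSE)
    if (nrow(sub) < min_triads || npat < 2 || ncl < 2) {
      base$reason <- "insufficient data to generate reliable statistical models"
      return(base)
    }
    fit <- tryCatch(fitMultilevel(sub, metric = metric,
                                  random_slopes = random_slopes),
                    error = function(e) NULL)
    if (is.null(fit)) {
      base$reason <- "model fit failed"
      return(base)
    }
    base$beta1 <- fit@beta1; base$se <- fit@se_beta1
    base$ci_lo <- fit@beta1 - z * fit@se_beta1
    base$ci_hi <- fit@beta1 + z * fit@se_beta1
    base$skipped <- FALSE
    base
  })
  do.call(rbind, rows)
}

#' Per-patient intercept and slope deviations
#'
#' Empirical best linear unbiased predictions of the patient random effects
#' with approximate (conditional-variance) standard errors, Wald tests of
#' each deviation against 0 and Wald confidence intervals. Mirrors the
#' per-patient forest display of patient-specific associations.
#'
#' @param fit a [MixedModelFit-class] with an underlying lme4 model.
#' @param conf_level confidence level.
#' @return data.frame with one row per patient: intercept_dev, slope_dev,
#'   their SEs, CIs, z and p values.
#' @export
perPatientEffects <- function(fit, conf_level = 0.95) {
  pats <- names(fit@u)
  z <- qnorm(1 - (1 - conf_level) / 2)
  int_se <- slope_se <- setNames(rep(0, length(pats)), pats)
  if (!is.null(fit@model) && inherits(fit@model, "merMod")) {
    re <- lme4::ranef(fit@model, condVar = TRUE)
    for (g in seq_along(re)) {
      if (names(re)[g] != "patient") next
      fr <- re[[g]]
      pv <- attr(fr, "postVar")
      assign_se <- function(nm, sds) {
        if (nm == "(Intercept)") int_se[rownames(fr)] <<- sds
        if (nm == "intensity") slope_se[rownames(fr)] <<- sds
      }
      if (is.list(pv)) {
        # uncorrelated term blocks on the same grouping factor: one
        # conditional-variance array per block, named by its column
        for (nm in names(pv)) assign_se(nm, sqrt(pv[[nm]][1, 1, ]))
      } else {
        cols <- names(fr)
        for (ci in seq_along(cols)) assign_se(cols[ci], sqrt(pv[ci, ci, ]))
      }
    }
  }
  idev <- fit@u[pats]; sdev <- fit@beta2[pats]
  zi <- ifelse(int_se > 0, idev / int_se, 0)
  zs <- ifelse(slope_se > 0, sdev / slope_se, 0)
  data.frame(patient = pats,
             intercept_dev = unname(idev), intercept_se = unname(int_se),
             intercept_lo = unname(idev - z * int_se),
             intercept_hi = unname(idev + z * int_se),
             intercept_p = unname(2 * pnorm(-abs(zi))),
             slope_dev = unname(sdev), slope_se = unname(slope_se),
             slope_lo = unname(sdev - z * slope_se),
             slope_hi = unname(sdev + z * slope_se),
             slope_p = unname(2 * pnorm(-abs(zs))),
             stringsAsFactors = FALSE)
}

#' Compare the association between two scans of the same patients
#'
#' Wald tests on the differences of the overall and patient-specific slopes
#' and intercepts between two fits that share the electroanatomic data but
#' use intensity maps from two different scans. A reproducible normalization
#' should yield non-significant differences.
#'
#' @param fit_scan1,fit_scan2 [MixedModelFit-class] objects over the same
#'   patients.
#' @param alpha significance level (default 0.05).
#' @return list with `overall` (slope/intercept differences, SEs and p
#'   values), `per_patient` (data.frame of patient-specific slope and
#'   intercept differences) and `different` (logical: any significant
#'   difference).
#' @export
reproducibilityCompare <- function(fit_scan1, fit_scan2, alpha = 0.05) {
  if (!identical(sort(names(fit_scan1@u)), sort(names(fit_scan2@u))))
    stop("invalid comparison: patient labels differ between fits")
  slope_diff <- fit_scan1@beta1 - fit_scan2@beta1
  slope_se <- sqrt(fit_scan1@se_beta1^2 + fit_scan2@se_beta1^2)
  int_diff <- fit_scan1@beta0 - fit_scan2@beta0
  int_se <- sqrt(fit_scan1@se_beta0^2 + fit_scan2@se_beta0^2)
  zp <- function(d, s) if (d == 0) 1 else if (s == 0) 0 else
    2 * pnorm(-abs(d / s))
  eff1 <- perPatientEffects(fit_scan1)
  eff2 <- perPatientEffects(fit_scan2)
  eff2 <- eff2[match(eff1$patient, eff2$patient), ]
  ps_diff <- (fit_scan1@beta1 + eff1$slope_dev) -
    (fit_scan2@beta1 + eff2$slope_dev)
  ps_se <- sqrt(fit_scan1@se_beta1^2 + eff1$slope_se^2 +
                  fit_scan2@se_beta1^2 + eff2$slope_se^2)
  pi_diff <- (fit_scan1@beta0 + eff1$intercept_dev) -
    (fit_scan2@beta0 + eff2$intercept_dev)
  pi_se <- sqrt(fit_scan1@se_beta0^2 + eff1$intercept_se^2 +
                  fit_scan2@se_beta0^2 + eff2$intercept_se^2)
  pp <- data.frame(patient = eff1$patient,
                   slope_diff = ps_diff, slope_se = ps_se,
                   slope_p = mapply(zp, ps_diff, ps_se),
                   intercept_diff = pi_diff, intercept_se = pi_se,
                   intercept_p = mapply(zp, pi_diff, pi_se),
                   stringsAsFactors = FALSE)
  overall <- list(slope_diff = slope_diff, slope_se = slope_se,
                  slope_p = zp(slope_diff, slope_se),
                  intercept_diff = int_diff, intercept_se = int_se,
                  intercept_p = zp(int_diff, int_se))
  different <- overall$slope_p < alpha || overall$intercept_p < alpha ||
    any(pp$slope_p < alpha) || any(pp$intercept_p < alpha)
  list(overall = overall, per_patient = pp, different = different)
}
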