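# Per-study generalized least-squares dose-response trends.
#
# Stage one of the two-stage meta-analysis: regress each study's correlated
# log RRs on dose (linear) or on a restricted-cubic-spline basis (3 knots,
# two coefficients), through the origin of the reference category, using the
# reconstructed within-study covariance. Stage two (pooling) lives in
# meta_pooling.R.

#' Place spline knots at weighted quantiles of the pooled dose distribution
#'
#' Knots sit at the requested percentiles of the pooled vector of assigned
#' category doses across all studies, weighted by category totals
#' (participants or person-time), using linear interpolation on the
#' cumulative-weight scale (equal weights reproduce the standard type-7
#' sample quantile).
#'
#' @param studies list of dose-assigned [study_record] objects.
#' @param percentiles three increasing fractions in (0, 1); default
#'   `c(0.25, 0.50, 0.75)`.
#' @return object of class `spline_spec` with element `knots` (length 3).
#' @export
place_knots <- function(studies, percentiles = c(0.25, 0.50, 0.75)) {
  stopifnot(length(percentiles) == 3L, all(diff(percentiles) > 0),
            all(percentiles > 0), all(percentiles < 1))
  doses <- unlist(lapply(studies, function(s) s$categories$dose_assigned))
  w <- unlist(lapply(studies, function(s) s$categories$total))
  if (any(is.na(doses))) stop("all doses must be assigned before knot placement",
                              call. = FALSE)
  w[is.na(w)] <- 1
  knots <- weighted_quantile(doses, w, percentiles)
  if (any(diff(knots) <= 0)) {
    stop("degenerate knots: dose distribution too concentrated for 3 distinct knots",
         call. = FALSE)
  }
  structure(list(knots = knots), class = "spline_spec")
}

#' Restricted cubic spline basis (3 knots, 2 terms)
#'
#' Harrell-style basis: `s1 = dose` and
#' `s2 = [(d-k1)+^3 - (d-k2)+^3 (k3-k1)/(k3-k2) + (d-k3)+^3 (k2-k1)/(k3-k2)] / (k3-k1)^2`.
#' `s2` is zero below the first knot and exactly linear beyond the last, so
#' the fitted curve is linear in the tails.
#'
#' @param dose numeric vector of doses (U/L).
#' @param spec a `spline_spec` from [place_knots()], or a numeric vector of 3
#'   increasing knots.
#' @return matrix with columns `s1`, `s2`, one row per dose.
#' @export
rcs_basis <- function(dose, spec) {
  k <- if (inherits(spec, "spline_spec")) spec$knots else spec
  stopifnot(length(k) == 3L, all(diff(k) > 0))
  cube <- function(x) pmax(x, 0)^3
  s2 <- (cube(dose - k[1]) -
           cube(dose - k[2]) * (k[3] - k[1]) / (k[3] - k[2]) +
           cube(dose - k[3]) * (k[2] - k[1]) / (k[3] - k[2])) / (k[3] - k[1])^2
  cbind(s1 = dose, s2 = s2)
}

#' Construct a per-study trend fit
#'
#' Normally produced by [gls_fit()]; exposed so externally computed
#' study-level coefficients (e.g. from publications reporting trends
#' directly) can enter the pooling stage.
#'
#' @param study_id,stratum_id identifiers.
#' @param model `"linear"` or `"spline"`.
#' @param beta coefficient vector (log RR per U/L scale).
#' @param cov_beta coefficient covariance matrix.
#' @param reference_dose anchor dose in U/L.
#' @return object of class `trend_fit`.
#' @export
trend_fit <- function(study_id, stratum_id = "all", model = "linear",
                      beta = numeric(), cov_beta = matrix(numeric(), 0, 0),
                      reference_dose = NA_real_) {
  cov_beta <- (cov_beta + t(cov_beta)) / 2
  structure(list(study_id = study_id, stratum_id = stratum_id, model = model,
                 beta = beta, cov_beta = cov_beta,
                 reference_dose = reference_dose),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s/%s %s: beta = %s\n", x$study_id, x$stratum_id,
              x$model, paste(signif(x$beta, 4), collapse = ", ")))
  invisible(x)
}

#' Generalized least-squares trend fit for one study
#'
#' Regresses the non-reference log RRs on the dose contrast with the
#' reference category, through the origin, with the full within-study
#' covariance: `beta = (X' C^-1 X)^-1 X' C^-1 L` and
#' `cov(beta) = (X' C^-1 X)^-1`. The design matrix is `dose_i - dose_ref`
#' (linear) or the spline-basis contrast (spline; requires at least 3
#' non-reference categories).
#'
#' @param study dose-assigned [study_record].
#' @param lrr list with `L` and `ref` as from [log_rr_vector()].
#' @param C within-study covariance of `L` (from [covariance_matrix()], or a
#'   diagonal matrix of the reported variances).
#' @param model `"linear"` or `"spline"`.
#' @param spec `spline_spec`, required for the spline model.
#' @return a `trend_fit` (per-U/L log-RR scale).
#' @export
gls_fit <- function(study, lrr, C, model = c("linear", "spline"), spec = NULL) {
  model <- match.arg(model)
  cats <- study$categories
  ref <- lrr$ref
  nonref <- setdiff(seq_len(nrow(cats)), ref)
  d <- cats$dose_assigned
  if (any(is.na(d))) stop("doses must be assigned before fitting", call. = FALSE)
  if (model == "linear") {
    X <- matrix(d[nonref] - d[ref], ncol = 1,
                dimnames = list(NULL, "dose"))
  } else {
    if (is.null(spec)) stop("spline model needs a spline_spec", call. = FALSE)
    if (length(nonref) < 3L) {
      stop("spline model needs at least 3 non-reference categories",
           call. = FALSE)
    }
    B <- rcs_basis(d, spec)
    X <- B[nonref, , drop = FALSE] -
      matrix(B[ref, ], length(nonref), 2, byrow = TRUE)
  }
  L <- lrr$L
  Cinv_X <- spd_solve(C, X, what = "within-study covariance")
  Cinv_L <- spd_solve(C, L, what = "within-study covariance")
  XtCiX <- crossprod(X, Cinv_X)
  cov_beta <- spd_inverse(XtCiX, what = "GLS information matrix")
  beta <- drop(cov_beta %*% crossprod(X, Cinv_L))
  trend_fit(study$study_id, study$stratum_id, model, beta, cov_beta, d[ref])
}

#' Combine stratum fits within one study (fixed effect)
#'
#' Sex or subgroup strata of the same cohort are combined by
#' (multivariate) inverse-variance fixed-effect analysis before cross-study
#' pooling: `cov = (sum_j cov_j^-1)^-1`,
#' `beta = cov %*% sum_j cov_j^-1 beta_j`.
#'
#' @param fits list of `trend_fit` objects sharing `study_id`, same model.
#' @return a single `trend_fit` with `stratum_id = "combined"`.
#' @export
combine_strata <- function(fits) {
  stopifnot(length(fits) >= 1L)
  if (length(fits) == 1L) return(fits[[1L]])
  models <- vapply(fits, function(f) f$model, character(1))
  ids <- vapply(fits, function(f) f$study_id, character(1))
  if (length(unique(models)) != 1L) {
    stop("cannot combine strata fitted with different models", call. = FALSE)
  }
  if (length(unique(ids)) != 1L) {
    stop("combine_strata expects fits from a single study", call. = FALSE)
  }
  p <- length(fits[[1L]]$beta)
  Wsum <- matrix(0, p, p)
  Wb <- numeric(p)
  for (f in fits) {
    W <- spd_inverse(f$cov_beta, what = "stratum covariance")
    Wsum <- Wsum + W
    Wb <- Wb + drop(W %*% f$beta)
  }
  cov <- spd_inverse(Wsum, what = "combined precision")
  trend_fit(ids[1L], "combined", models[1L], drop(cov %*% Wb), cov,
            fits[[1L]]$reference_dose)
}

#' Predict the pooled dose-response curve
#'
#' Evaluates the pooled trend as RR relative to a reference dose over a dose
#' grid: `log RR(d) = (x(d) - x(ref))' beta`, with pointwise delta-method
#' confidence bands `var = x' cov x`. The curve is anchored at RR = 1 at the
#' reference dose.
#'
#' @param beta,cov_beta pooled coefficients and covariance (length 1 linear,
#'   2 spline).
#' @param reference_dose anchor dose in U/L.
#' @param grid doses at which to evaluate.
#' @param spec `spline_spec` when `beta` has 2 elements.
#' @param ci_level coverage of the pointwise band.
#' @return data frame `(dose, rr, ci_low, ci_high)`.
#' @export
predict_curve <- function(beta, cov_beta, reference_dose, grid,
                          spec = NULL, ci_level = 0.95) {
  p <- length(beta)
  cov_beta <- matrix(cov_beta, p, p)
  if (p == 2L) {
    if (is.null(spec)) stop("spline curve needs a spline_spec", call. = FALSE)
    X <- rcs_basis(grid, spec) -
      matrix(rcs_basis(reference_dose, spec), length(grid), 2, byrow = TRUE)
  } else {
    X <- matrix(grid - reference_dose, ncol = 1)
  }
  lp <- drop(X %*% beta)
  se <- sqrt(pmax(0, rowSums((X %*% cov_beta) * X)))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  data.frame(dose = grid, rr = exp(lp),
             ci_low = exp(lp - z * se), ci_high = exp(lp + z * se))
}

#' Rescale a linear trend to an increment of interest
#'
#' Turns a per-U/L slope into the RR for a stated increment (5 U/L by
#' default): `RR = exp(inc * beta)` with
#' `CI = exp(inc * (beta +/- z * se))`.
#'
#' @param beta linear slope (log RR per U/L).
#' @param var variance of `beta`.
#' @param increment dose increment in U/L.
#' @param ci_level CI coverage.
#' @return named numeric vector `(rr, ci_low, ci_high)`.
#' @export
per_increment <- function(beta, var, increment = 5, ci_level = 0.95) {
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  se <- sqrt(var)
  c(rr = exp(increment * beta),
    ci_low = exp(increment * (beta - z * se)),
    ci_high = exp(increment * (beta + z * se)))
}
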