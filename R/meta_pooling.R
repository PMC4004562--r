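# Stage two: combining per-study trend coefficients across studies.
#
# Fixed-effect pooling is (multivariate) inverse-variance weighting. Random
# effects use the DerSimonian-Laird moment estimator; for the bivariate
# spline model a single scalar tau2 is added to each coefficient's variance,
# moment-matched on the multivariate Q (five studies cannot support an
# unstructured between-study covariance).

pooled_result <- function(model, beta, cov, tau2, Q, df, k, method) {
  cov <- matrix(cov, length(beta), length(beta))
  p_Q <- stats::pchisq(Q, df, lower.tail = FALSE)
  I2 <- max(0, 100 * (Q - df) / Q)
  structure(list(model = model, beta = beta, cov = cov, tau2 = tau2,
                 Q = Q, df = df, p_Q = p_Q, I2 = I2, k = k, method = method),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("<pooled_result> %s (%s effects), k = %d\n  beta = %s\n  tau2 = %.4g, Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
              x$model, x$method, x$k,
              paste(signif(x$beta, 4), collapse = ", "),
              x$tau2, x$Q, x$df, x$p_Q, x$I2))
  invisible(x)
}

pool_core <- function(fits) {
  k <- length(fits)
  p <- length(fits[[1L]]$beta)
  betas <- do.call(rbind, lapply(fits, function(f) f$beta))
  Ws <- lapply(fits, function(f) spd_inverse(f$cov_beta,
                                             what = "study covariance"))
  Wsum <- Reduce(`+`, Ws)
  cov_fe <- spd_inverse(Wsum, what = "pooled precision")
  beta_fe <- drop(cov_fe %*% Reduce(`+`, Map(function(W, i)
    W %*% betas[i, ], Ws, seq_len(k))))
  Q <- sum(vapply(seq_len(k), function(i) {
    r <- betas[i, ] - beta_fe
    drop(t(r) %*% Ws[[i]] %*% r)
  }, numeric(1)))
  list(k = k, p = p, betas = betas, Ws = Ws, Wsum = Wsum,
       beta_fe = beta_fe, cov_fe = cov_fe, Q = Q, df = p * (k - 1L))
}

check_poolable <- function(fits) {
  if (length(fits) < 2L) stop("pooling needs at least 2 studies", call. = FALSE)
  models <- vapply(fits, function(f) f$model, character(1))
  if (length(unique(models)) != 1L) {
    stop("all fits must use the same model", call. = FALSE)
  }
  models[1L]
}

#' Fixed-effect pooling of per-study trends
#'
#' @param fits list of `trend_fit` objects (same model, one per study).
#' @return a `pooled_result` with Cochran's Q (df = p(k-1)) and I-squared.
#' @export
pool_fixed <- function(fits) {
  model <- check_poolable(fits)
  pc <- pool_core(fits)
  pooled_result(model, pc$beta_fe, pc$cov_fe, tau2 = 0, Q = pc$Q, df = pc$df,
                k = pc$k, method = "fixed")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Univariate: `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` with
#' fixed-effect weights `w_i = 1 / var_i`, then weights
#' `1 / (var_i + tau2)`. Multivariate (spline): the same moment construction
#' with a common scalar `tau2` added to each coefficient's variance,
#' `tau2 = max(0, (Q - df) / (sum_i tr(W_i) - tr(Wsum^-1 sum_i W_i^2)))`.
#' With `tau2 = 0` the result equals [pool_fixed()] exactly.
#'
#' @inheritParams pool_fixed
#' @return a `pooled_result`; `Q`, `df` and `I2` are the fixed-effect
#'   heterogeneity statistics on which `tau2` is based.
#' @export
pool_random <- function(fits) {
  model <- check_poolable(fits)
  pc <- pool_core(fits)
  trace <- function(M) sum(diag(as.matrix(M)))
  denom <- sum(vapply(pc$Ws, trace, numeric(1))) -
    trace(spd_inverse(pc$Wsum, what = "pooled precision") %*%
            Reduce(`+`, lapply(pc$Ws, function(W) W %*% W)))
  tau2 <- max(0, (pc$Q - pc$df) / denom)
  p <- pc$p
  Ws_re <- lapply(fits, function(f)
    spd_inverse(f$cov_beta + tau2 * diag(p), what = "study covariance"))
  Wsum_re <- Reduce(`+`, Ws_re)
  cov_re <- spd_inverse(Wsum_re, what = "pooled precision")
  beta_re <- drop(cov_re %*% Reduce(`+`, Map(function(W, i)
    W %*% pc$betas[i, ], Ws_re, seq_len(pc$k))))
  pooled_result(model, beta_re, cov_re, tau2 = tau2, Q = pc$Q, df = pc$df,
                k = pc$k, method = "random")
}

#' Test-based confidence interval for I-squared
#'
#' Higgins-Thompson test-based interval: `H = sqrt(Q / (k - 1))`, truncated at
#' 1; `se(ln H) = (ln Q - ln(k-1)) / (2 (sqrt(2Q) - sqrt(2k-3)))` when
#' `Q > k`, else `sqrt(1/(2(k-2)) * (1 - 1/(3(k-2)^2)))`. The CI is formed on
#' the ln H scale and mapped through `I2 = 100 (H^2 - 1) / H^2`, truncating
#' the final interval to \[0, 100\].
#'
#' @param Q Cochran's Q.
#' @param k number of studies.
#' @param ci_level coverage (default 0.95).
#' @return list `I2`, `ci_low`, `ci_high` (percent); the bounds are `NA` with
#'   a warning when `k = 2` and `Q <= k` (se formula undefined).
#' @export
heterogeneity_ci <- function(Q, k, ci_level = 0.95) {
  stopifnot(k >= 2)
  df <- k - 1
  H <- max(1, sqrt(Q / df))
  I2 <- 100 * (H^2 - 1) / H^2
  if (Q > k) {
    se_lnH <- 0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * k - 3))
  } else if (k > 2) {
    se_lnH <- sqrt(1 / (2 * (k - 2)) * (1 - 1 / (3 * (k - 2)^2)))
  } else {
    warning("I2 confidence interval undefined for k = 2 with Q <= k",
            call. = FALSE)
    return(list(I2 = I2, ci_low = NA_real_, ci_high = NA_real_))
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  H_lo <- exp(log(H) - z * se_lnH)
  H_hi <- exp(log(H) + z * se_lnH)
  i2_of <- function(h) 100 * (h^2 - 1) / h^2
  list(I2 = I2,
       ci_low = min(100, max(0, i2_of(H_lo))),
       ci_high = min(100, max(0, i2_of(H_hi))))
}

#' Wald test for nonlinearity of the pooled spline trend
#'
#' Tests the null that the second (nonlinear) spline coefficient is zero:
#' `z = beta2 / se(beta2)`, two-sided standard-normal p-value. Under the
#' null the restricted model is the linear trend, so rejection indicates
#' departure from log-linearity.
#'
#' @param pooled a spline `pooled_result` (2 coefficients).
#' @return two-sided p-value.
#' @export
nonlinearity_test <- function(pooled) {
  if (length(pooled$beta) != 2L) {
    stop("nonlinearity test needs a pooled spline fit (2 coefficients)",
         call. = FALSE)
  }
  v <- pooled$cov[2, 2]
  if (!is.finite(v) || v <= 0) {
    stop("degenerate variance for the second spline coefficient", call. = FALSE)
  }
  z <- pooled$beta[2] / sqrt(v)
  2 * stats::pnorm(-abs(z))
}
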