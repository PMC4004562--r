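# Publication-bias diagnostics and leave-one-out sensitivity analysis,
# operating on the per-study linear trend fits.

fit_effects <- function(fits) {
  data.frame(
    study_id = vapply(fits, function(f) f$study_id, character(1)),
    effect = vapply(fits, function(f) f$beta[1L], numeric(1)),
    se = vapply(fits, function(f) sqrt(f$cov_beta[1L, 1L]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Classical (unweighted) form: ordinary least squares of the standardized
#' effect `beta_i / se_i` on the precision `1 / se_i`; a nonzero intercept
#' indicates small-study asymmetry. Two-sided t-test on the intercept with
#' k - 2 degrees of freedom.
#'
#' @param fits list of linear `trend_fit` objects, k >= 3.
#' @return list `intercept`, `se`, `p`, `k`.
#' @export
egger_test <- function(fits) {
  eff <- fit_effects(fits)
  k <- nrow(eff)
  if (k < 3L) stop("Egger's test needs at least 3 studies", call. = FALSE)
  snd <- eff$effect / eff$se
  prec <- 1 / eff$se
  if (stats::sd(prec) == 0) {
    stop("all precisions equal: Egger regression is singular", call. = FALSE)
  }
  xbar <- mean(prec); ybar <- mean(snd)
  sxx <- sum((prec - xbar)^2)
  slope <- sum((prec - xbar) * (snd - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- snd - intercept - slope * prec
  s2 <- sum(resid^2) / (k - 2)
  se_int <- sqrt(s2 * (1 / k + xbar^2 / sxx))
  tval <- intercept / se_int
  list(intercept = intercept, se = se_int,
       p = 2 * stats::pt(-abs(tval), df = k - 2), k = k)
}

#' Begg rank-correlation test for publication bias
#'
#' Kendall's tau between the variance-stabilized effect deviations
#' `(beta_i - beta_FE) / sqrt(var_i - var_FE)` and the variances `var_i`,
#' with the tie-adjusted score variance and a continuity correction
#' (subtract 1 from |score|) in the normal approximation.
#'
#' @param fits list of linear `trend_fit` objects, k >= 3.
#' @return list `tau`, `p`, `score`, `k`.
#' @export
begg_test <- function(fits) {
  eff <- fit_effects(fits)
  k <- nrow(eff)
  if (k < 3L) stop("Begg's test needs at least 3 studies", call. = FALSE)
  v <- eff$se^2
  w <- 1 / v
  beta_fe <- sum(w * eff$effect) / sum(w)
  var_fe <- 1 / sum(w)
  vstar <- v - var_fe
  floor_idx <- vstar <= 0
  if (any(floor_idx)) {
    message(sprintf("begg_test: %d stud%s with var_i <= var_FE; tolerance floor applied",
                    sum(floor_idx), if (sum(floor_idx) == 1) "y" else "ies"))
    vstar[floor_idx] <- .Machine$double.eps * v[floor_idx]
  }
  dev <- (eff$effect - beta_fe) / sqrt(vstar)
  kendall_score(dev, v, k)
}

# Kendall S with tie-adjusted variance and continuity correction.
kendall_score <- function(x, y, k) {
  S <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  n_pairs <- k * (k - 1) / 2
  tie_term <- function(z) {
    t <- table(z)
    sum(t * (t - 1) * (2 * t + 5))
  }
  var_S <- (k * (k - 1) * (2 * k + 5) - tie_term(x) - tie_term(y)) / 18
  z <- if (var_S > 0) max(0, abs(S) - 1) / sqrt(var_S) else 0
  list(tau = S / n_pairs, p = 2 * stats::pnorm(-abs(z)), score = S, k = k)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the remaining studies after omitting each study in turn
#' (random effects), expressing each pooled linear trend as an RR per
#' increment.
#'
#' @param fits list of linear `trend_fit` objects, k >= 3.
#' @param increment dose increment for reporting (U/L).
#' @param ci_level CI coverage.
#' @return data frame `(omitted, rr, ci_low, ci_high)`, one row per study,
#'   plus the full-data pooling as attribute `"full"`.
#' @export
leave_one_out <- function(fits, increment = 5, ci_level = 0.95) {
  k <- length(fits)
  if (k < 3L) stop("leave-one-out needs at least 3 studies", call. = FALSE)
  rows <- lapply(seq_len(k), function(i) {
    pr <- pool_random(fits[-i])
    est <- per_increment(pr$beta[1L], pr$cov[1L, 1L], increment, ci_level)
    data.frame(omitted = fits[[i]]$study_id, rr = est[["rr"]],
               ci_low = est[["ci_low"]], ci_high = est[["ci_high"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  full <- pool_random(fits)
  attr(out, "full") <- per_increment(full$beta[1L], full$cov[1L, 1L],
                                     increment, ci_level)
  out
}

#' Funnel-plot table
#'
#' Per-study effect and standard error for external funnel plotting.
#' @param fits list of linear `trend_fit` objects.
#' @return data frame `(study_id, effect, se)`.
#' @export
funnel_table <- function(fits) fit_effects(fits)
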