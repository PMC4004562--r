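`%||%` <- function(x, y) if (is.null(x)) y else x

is_absent <- function(x) is.null(x) || length(x) == 0L || all(is.na(x))

#' Weighted empirical quantiles with linear interpolation
#'
#' Quantiles of a weighted sample, linearly interpolated on the
#' cumulative-weight scale. Duplicated values are aggregated first. With equal
#' weights the result coincides with [stats::quantile()] type 7. Positions are
#' `u_k = (C_k - w_k) / (W - w_k)` for the k-th distinct sorted value, where
#' `C_k` is the cumulative weight and `W` the total; this is invariant to
#' rescaling all weights and monotone in k.
#'
#' @param x numeric values.
#' @param w nonnegative weights, same length as `x`.
#' @param probs probabilities in (0, 1).
#' @return numeric vector of quantiles, one per element of `probs`.
#' @keywords internal
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0,
            all(probs > 0), all(probs < 1))
  agg <- tapply(w, x, sum)
  xs <- as.numeric(names(agg))
  ws <- as.numeric(agg)
  o <- order(xs)
  xs <- xs[o]; ws <- ws[o]
  if (length(xs) == 1L) return(rep(xs, length(probs)))
  W <- sum(ws)
  ck <- cumsum(ws)
  u <- (ck - ws) / (W - ws)
  vapply(probs, function(p) stats::approx(u, xs, xout = p, rule = 2)$y,
         numeric(1))
}

# Solve S x = b for symmetric positive-definite S via Cholesky, with a
# reciprocal-condition-number guard.
spd_solve <- function(S, b, rcond_min = 1e-12, what = "matrix") {
  S <- (S + t(S)) / 2
  if (rcond(S) < rcond_min) {
    stop(sprintf("%s is numerically singular (rcond < %g)", what, rcond_min),
         call. = FALSE)
  }
  R <- tryCatch(chol(S), error = function(e) {
    stop(sprintf("%s is not positive definite: %s", what, conditionMessage(e)),
         call. = FALSE)
  })
  backsolve(R, forwardsolve(t(R), b))
}

spd_inverse <- function(S, rcond_min = 1e-12, what = "matrix") {
  spd_solve(S, diag(nrow(S)), rcond_min = rcond_min, what = what)
}

check_positive_definite <- function(S, what = "covariance matrix") {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop(sprintf("%s is not positive definite (min eigenvalue %.3g); review the input data",
                 what, min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}
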