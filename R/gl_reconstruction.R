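# Greenland-Longnecker reconstruction of the within-study covariance of
# correlated log relative risks.
#
# All non-reference RRs in a study share the same reference group, so their
# log RRs are positively correlated. Given the category margins (cases and
# participants or person-time) we fit pseudo-counts a_i such that the crude
# category-specific RRs computed from (a_i, total_i) reproduce the reported
# adjusted RRs exactly while conserving the total-case margin. The fitted
# reference cell a_0 then yields the shared covariance term between any two
# log RRs. Reported variances (from the published CIs) are kept on the
# diagonal; only the off-diagonals come from the pseudo-counts.

#' Log relative risks and their reported variances
#'
#' For the non-reference categories of a study, computes
#' `L_i = ln(rr_i)` and the variance implied by the published CI,
#' `V_i = ((ln ci_high - ln ci_low) / (2 z))^2` with `z` the standard-normal
#' quantile for the coverage level.
#'
#' @param study a [study_record].
#' @param ci_level CI coverage of the published intervals (default 0.95).
#' @return list with elements `L`, `V` (length = #categories - 1), `labels`,
#'   and `ref` (row index of the reference category).
#' @export
log_rr_vector <- function(study, ci_level = 0.95) {
  cats <- study$categories
  ref <- which(cats$is_reference)
  if (length(ref) != 1L) stop("study must have exactly one reference category",
                              call. = FALSE)
  nonref <- setdiff(seq_len(nrow(cats)), ref)
  bad <- nonref[cats$ci_high[nonref] <= cats$ci_low[nonref]]
  if (length(bad)) {
    stop(sprintf("invalid CI (ci_high <= ci_low) in category %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(
    L = log(cats$rr[nonref]),
    V = ((log(cats$ci_high[nonref]) - log(cats$ci_low[nonref])) / (2 * z))^2,
    labels = cats$label[nonref],
    ref = ref
  )
}

#' Fit Greenland-Longnecker pseudo-counts
#'
#' Finds fitted pseudo-cases `a_i` (one per category) such that the design's
#' crude RR formula applied to `(a_i, total_i)` reproduces each adjusted log
#' RR `L_i` exactly, while the fitted cases sum to the study's reported total
#' cases. Every `a_i` is an explicit function of the reference cell `a_0`, so
#' the margin equation is solved by bisection on `a_0`.
#'
#' Crude formulas by design: cumulative incidence and incidence rate use
#' `(a_i / n_i) / (a_0 / n_0)` (participant counts or person-time);
#' case-control uses the odds ratio `(a_i b_0) / (a_0 b_i)` with
#' `b_i = n_i - a_i`.
#'
#' @param study a [study_record] with `cases` and `total` for every category.
#' @param L log-RR vector for the non-reference categories (in category
#'   order), e.g. from [log_rr_vector()].
#' @param tol absolute tolerance on the case-margin residual.
#' @param max_iter bisection iteration cap.
#' @return list of class `pseudo_table`: `a` (fitted pseudo-cases, all
#'   categories in order), `b` (non-cases for cumulative-incidence /
#'   case-control, person-time for incidence-rate), `ref`, `design`,
#'   `residual`.
#' @export
fit_pseudo_counts <- function(study, L, tol = 1e-10, max_iter = 200L) {
  cats <- study$categories
  ref <- which(cats$is_reference)
  nonref <- setdiff(seq_len(nrow(cats)), ref)
  if (length(L) != length(nonref)) {
    stop("length(L) must equal the number of non-reference categories",
         call. = FALSE)
  }
  if (any(is.na(cats$cases)) || any(is.na(cats$total))) {
    stop("cases and totals are required for every category", call. = FALSE)
  }
  if (any(!is.finite(L))) stop("L must be finite", call. = FALSE)
  cases <- cats$cases
  if (any(cases == 0)) {
    warning("zero observed cases in a category; adding 0.5 before fitting",
            call. = FALSE)
    cases[cases == 0] <- 0.5
  }
  n <- cats$total
  A <- sum(cases)
  rr <- exp(L)
  design <- study$design

  # fitted cells as a function of the reference cell
  a_of <- function(a0) {
    a <- numeric(length(n))
    a[ref] <- a0
    if (design %in% c("cumulative_incidence", "incidence_rate")) {
      a[nonref] <- rr * n[nonref] * a0 / n[ref]
    } else {                                  # case_control odds ratios
      r <- rr * a0 / (n[ref] - a0)
      a[nonref] <- n[nonref] * r / (1 + r)
    }
    a
  }
  margin <- function(a0) sum(a_of(a0)) - A

  upper <- if (design == "incidence_rate") A else min(A, n[ref])
  lo <- 1e-9 * A
  hi <- upper - 1e-9 * A
  if (margin(lo) > 0 || margin(hi) < 0) {
    stop("infeasible margins: no reference cell in (0, total cases) reproduces the reported RRs",
         call. = FALSE)
  }
  iter <- 0L
  repeat {
    mid <- (lo + hi) / 2
    res <- margin(mid)
    if (abs(res) <= tol) break
    if (res > 0) hi <- mid else lo <- mid
    iter <- iter + 1L
    if (iter >= max_iter) {
      # margin() is monotone and smooth; the bracket midpoint is accurate to
      # (hi - lo) / 2 even when the residual tolerance is not yet met
      if (abs(res) > 1e-6 * max(1, A)) {
        stop(sprintf("pseudo-count fit did not converge (residual %.3g after %d iterations)",
                     res, iter), call. = FALSE)
      }
      break
    }
  }
  a <- a_of(mid)
  if (design == "cumulative_incidence" && any(a > n + 1e-8)) {
    stop("infeasible margins: fitted pseudo-cases exceed category totals",
         call. = FALSE)
  }
  b <- if (design == "incidence_rate") n else n - a
  structure(list(a = a, b = b, ref = ref, design = design,
                 residual = margin(mid)),
            class = "pseudo_table")
}

#' Within-study covariance matrix of the log relative risks
#'
#' Diagonal entries are the reported variances `V`; off-diagonals come from
#' the fitted reference cell: `1/a_0 - 1/n_0` (cumulative incidence),
#' `1/a_0` (incidence rate), `1/a_0 + 1/b_0` (case-control).
#'
#' @param pseudo a `pseudo_table` from [fit_pseudo_counts()].
#' @param V reported variances of the non-reference log RRs, in order.
#' @return symmetric positive-definite covariance matrix, dimension
#'   `length(V)`.
#' @export
covariance_matrix <- function(pseudo, V) {
  a0 <- pseudo$a[pseudo$ref]
  off <- switch(pseudo$design,
    cumulative_incidence = 1 / a0 - 1 / (pseudo$a[pseudo$ref] + pseudo$b[pseudo$ref]),
    incidence_rate = 1 / a0,
    case_control = 1 / a0 + 1 / pseudo$b[pseudo$ref]
  )
  m <- length(V)
  C <- matrix(off, m, m)
  diag(C) <- V
  check_positive_definite(C, "log-RR covariance matrix")
  C
}
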