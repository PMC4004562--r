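# Builders for small in-memory studies and fits used across the suite.

make_categories <- function(rr, ci_low, ci_high, cases, total,
                            dose = NULL, dose_low = NA, dose_high = NA) {
  k <- length(rr)
  data.frame(
    label = paste0("cat", seq_len(k)),
    dose_low = rep_len(dose_low, k), dose_high = rep_len(dose_high, k),
    dose_assigned = if (is.null(dose)) NA_real_ else dose,
    rr = rr, ci_low = ci_low, ci_high = ci_high,
    cases = cases, total = total,
    is_reference = seq_len(k) == 1L,
    stringsAsFactors = FALSE
  )
}

# Well-formed cumulative-incidence study; RRs/CIs consistent on the log scale.
make_study <- function(rr = c(1, 1.5, 2), dose = c(0, 5, 10),
                       cases = c(20, 20, 20), total = c(200, 100, 100),
                       se = 0.2, design = "cumulative_incidence",
                       study_id = "s1", stratum_id = "all") {
  z <- qnorm(0.975)
  ci_low <- ifelse(seq_along(rr) == 1, 1, exp(log(rr) - z * se))
  ci_high <- ifelse(seq_along(rr) == 1, 1, exp(log(rr) + z * se))
  study_record(study_id, stratum_id, design,
               make_categories(rr, ci_low, ci_high, cases, total, dose))
}

make_fit <- function(id, beta, var, model = "linear", ref = 6) {
  p <- length(beta)
  trend_fit(id, "all", model, beta, matrix(var, p, p), ref)
}

# k univariate linear fits from effect/variance vectors
make_fits <- function(yi, vi, ids = paste0("s", seq_along(yi))) {
  Map(function(y, v, id) trend_fit(id, "all", "linear", y, matrix(v, 1, 1), 6),
      yi, vi, ids)
}

write_temp_table <- function(records) {
  path <- tempfile(fileext = ".csv")
  write_study_table(records, path)
  path
}

# Grid-search oracle for the pseudo-count reference cell: minimises the
# absolute margin residual over a fine grid of a0 values.
grid_search_a0 <- function(study, L, step = 1e-4) {
  cats <- study$categories
  ref <- which(cats$is_reference)
  nonref <- setdiff(seq_len(nrow(cats)), ref)
  n <- cats$total
  A <- sum(cats$cases)
  rr <- exp(L)
  a_of <- function(a0) {
    a <- numeric(length(n)); a[ref] <- a0
    if (study$design %in% c("cumulative_incidence", "incidence_rate")) {
      a[nonref] <- rr * n[nonref] * a0 / n[ref]
    } else {
      r <- rr * a0 / (n[ref] - a0)
      a[nonref] <- n[nonref] * r / (1 + r)
    }
    a
  }
  upper <- if (study$design == "incidence_rate") A else min(A, n[ref])
  grid <- seq(step, upper - step, by = step)
  # vectorised margin over the grid
  if (study$design %in% c("cumulative_incidence", "incidence_rate")) {
    margins <- grid * (1 + sum(rr * n[nonref]) / n[ref])
  } else {
    r <- outer(grid / (n[ref] - grid), rr)              # grid x categories
    margins <- grid + rowSums(sweep(r / (1 + r), 2, n[nonref], `*`))
  }
  a_of(grid[which.min(abs(margins - A))])
}
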