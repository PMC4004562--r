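# Synthetic category-level cohort studies with a known true dose-response.
#
# The generator emulates a five-cohort meta-analysis of baseline ALT (U/L)
# and incident metabolic-syndrome risk: each synthetic cohort reports 3-5
# ordered ALT categories, participant counts, binomially sampled event
# counts, and crude category RRs with log-scale Wald CIs against the lowest
# (reference) category. Default sizes match the published five-cohort
# setting (participants 3545/1097/21535/2957/681, expected events calibrated
# to 309/226/802/608/180). Participants are spread over the dose range
# according to a right-skewed lognormal ALT distribution, so the reference
# category is the most populous, as in real cohorts.

#' Define a true dose-risk curve
#'
#' @param form `"linear"` (log RR proportional to dose), `"threshold"`
#'   (flat up to `threshold`, then linear), or `"spline"` (user function).
#' @param slope log RR per U/L (for `"linear"`/`"threshold"`).
#' @param threshold dose (U/L) where risk starts rising (`"threshold"` only).
#' @param logrr_fun function(dose) -> log RR, for `form = "spline"`.
#' @param baseline_risk optional reference-category risk; when `NULL` the
#'   generator calibrates it to a study's target case count.
#' @return object of class `true_curve`.
#' @export
true_curve <- function(form = c("linear", "threshold", "spline"),
                       slope = log(1.14) / 5, threshold = 20,
                       logrr_fun = NULL, baseline_risk = NULL) {
  form <- match.arg(form)
  if (form == "spline" && !is.function(logrr_fun)) {
    stop("form = 'spline' needs logrr_fun", call. = FALSE)
  }
  structure(list(form = form, slope = slope, threshold = threshold,
                 logrr_fun = logrr_fun, baseline_risk = baseline_risk),
            class = "true_curve")
}

curve_logrr <- function(curve, dose, slope = curve$slope) {
  switch(curve$form,
    linear = slope * dose,
    threshold = slope * pmax(0, dose - curve$threshold),
    spline = curve$logrr_fun(dose)
  )
}

#' Simulation specification for a synthetic meta-dataset
#'
#' Defaults emulate the five published cohorts: their participant totals,
#' expected case counts, 3-5 ALT categories spanning 6-40 U/L, no
#' between-study heterogeneity (the observed I2 was 0%), and a lognormal
#' ALT distribution (meanlog log(18), sdlog 0.5) governing how participants
#' fall into dose categories.
#'
#' @param n_studies number of cohorts.
#' @param totals participants per cohort.
#' @param target_cases expected events per cohort (calibrates baseline risk).
#' @param n_categories exposure categories per cohort (3-5 each).
#' @param dose_range observed dose span in U/L.
#' @param tau2 between-study variance of the per-U/L slope.
#' @param break_jitter_sd sd (U/L) of the jitter on interior category
#'   boundaries, making category layouts differ across cohorts.
#' @param alt_meanlog,alt_sdlog lognormal ALT distribution parameters.
#' @param design study design for all cohorts.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(n_studies = 5L,
                     totals = c(3545L, 1097L, 21535L, 2957L, 681L),
                     target_cases = c(309L, 226L, 802L, 608L, 180L),
                     n_categories = c(4L, 4L, 5L, 4L, 4L),
                     dose_range = c(6, 40),
                     tau2 = 0,
                     break_jitter_sd = 1,
                     alt_meanlog = log(18), alt_sdlog = 0.5,
                     design = "cumulative_incidence") {
  stopifnot(length(totals) == n_studies, length(target_cases) == n_studies,
            length(n_categories) == n_studies,
            all(n_categories >= 3L), all(n_categories <= 5L),
            all(totals > 0), all(target_cases > 0), tau2 >= 0,
            dose_range[1] < dose_range[2])
  structure(list(n_studies = as.integer(n_studies), totals = totals,
                 target_cases = target_cases,
                 n_categories = as.integer(n_categories),
                 dose_range = dose_range, tau2 = tau2,
                 break_jitter_sd = break_jitter_sd,
                 alt_meanlog = alt_meanlog, alt_sdlog = alt_sdlog,
                 design = design),
            class = "sim_spec")
}

# Share of a truncated lognormal falling in each [breaks[i], breaks[i+1])
lognormal_shares <- function(breaks, meanlog, sdlog) {
  p <- stats::plnorm(breaks, meanlog, sdlog)
  diff(p) / (p[length(p)] - p[1])
}

# Integer allocation of `total` by `shares`, largest-remainder rounding
allocate <- function(total, shares) {
  raw <- total * shares
  n <- floor(raw)
  short <- total - sum(n)
  if (short > 0) {
    o <- order(raw - n, decreasing = TRUE)
    n[o[seq_len(short)]] <- n[o[seq_len(short)]] + 1
  }
  as.integer(n)
}

#' Generate one synthetic cohort study
#'
#' Category boundaries are jittered around an even split of the dose range;
#' participants are allocated by the lognormal ALT distribution; events are
#' drawn binomially with risk `baseline * exp(logRR(dose) - logRR(ref dose))`
#' at the category midpoint; crude RRs with log-scale Wald CIs (0.5
#' continuity correction if any zero cell) are reported against the lowest
#' category. Consumes the current R random stream.
#'
#' @param spec a [sim_spec()].
#' @param curve a [true_curve()].
#' @param study_index which cohort of the spec to generate.
#' @param slope per-U/L slope for this cohort (defaults to the curve's; used
#'   to inject between-study heterogeneity).
#' @return a [study_record]; attribute `"truth"` records the generating
#'   parameters.
#' @export
generate_study <- function(spec, curve, study_index = 1L,
                           slope = curve$slope) {
  ncat <- spec$n_categories[study_index]
  total <- spec$totals[study_index]
  breaks <- seq(spec$dose_range[1], spec$dose_range[2], length.out = ncat + 1)
  if (ncat > 1 && spec$break_jitter_sd > 0) {
    gap <- diff(spec$dose_range) / ncat
    jit <- stats::rnorm(ncat - 1, 0, spec$break_jitter_sd)
    jit <- pmax(pmin(jit, gap / 3), -gap / 3)   # keep boundaries ordered
    breaks[2:ncat] <- breaks[2:ncat] + jit
  }
  doses <- (breaks[-1] + breaks[-(ncat + 1)]) / 2
  shares <- lognormal_shares(breaks, spec$alt_meanlog, spec$alt_sdlog)
  n <- allocate(total, shares)
  if (any(n == 0)) stop("category with zero participants; adjust sim_spec",
                        call. = FALSE)
  lrr <- curve_logrr(curve, doses, slope) - curve_logrr(curve, doses[1], slope)
  base <- curve$baseline_risk %||%
    (spec$target_cases[study_index] / sum(n * exp(lrr)))
  risk <- base * exp(lrr)
  if (any(risk >= 1)) {
    stop(sprintf("true risk >= 1 at dose %.1f U/L; lower the slope or baseline",
                 doses[which(risk >= 1)[1]]), call. = FALSE)
  }
  cases <- stats::rbinom(ncat, n, risk)
  a <- cases; nn <- n
  if (any(cases == 0)) { a <- cases + 0.5 }   # continuity for the Wald CI
  rr <- (a / nn) / (a[1] / nn[1])
  se <- sqrt(1 / a + 1 / a[1] - 1 / nn - 1 / nn[1])
  z <- stats::qnorm(0.975)
  cats <- data.frame(
    label = sprintf("[%.1f,%.1f)", breaks[-(ncat + 1)], breaks[-1]),
    dose_low = breaks[-(ncat + 1)], dose_high = breaks[-1],
    dose_assigned = NA_real_,
    rr = ifelse(seq_len(ncat) == 1L, 1, rr),
    ci_low = ifelse(seq_len(ncat) == 1L, 1, exp(log(rr) - z * se)),
    ci_high = ifelse(seq_len(ncat) == 1L, 1, exp(log(rr) + z * se)),
    cases = cases, total = n,
    is_reference = seq_len(ncat) == 1L,
    stringsAsFactors = FALSE
  )
  rec <- study_record(sprintf("synthetic_%02d", study_index),
                      design = spec$design, categories = cats)
  attr(rec, "truth") <- list(slope = slope, baseline_risk = base,
                             doses = doses, risk = risk)
  rec
}

#' Generate a synthetic meta-dataset
#'
#' Draws study-specific slopes from `Normal(true slope, tau2)` and generates
#' each cohort with [generate_study()].
#'
#' @param spec a [sim_spec()].
#' @param curve a [true_curve()].
#' @param seed optional integer; when given, seeds the R random stream.
#' @return list of [study_record]s; attribute `"truth"` holds the generating
#'   slope vector and curve.
#' @export
generate_meta_dataset <- function(spec, curve = true_curve(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slopes <- stats::rnorm(spec$n_studies, curve$slope, sqrt(spec$tau2))
  studies <- lapply(seq_len(spec$n_studies), function(i)
    generate_study(spec, curve, i, slope = slopes[i]))
  attr(studies, "truth") <- list(curve = curve, slopes = slopes, spec = spec)
  studies
}

#' Study-level metadata of the five source cohorts
#'
#' Loads the packaged fixture of published study characteristics (five
#' prospective cohorts: identifiers, location, design metadata, follow-up,
#' participants, events). Category-level results were not published, so the
#' fixture carries study-level metadata only.
#'
#' @return data frame with one row per cohort, columns including
#'   `study_id`, `followup_years`, `total`, `cases`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_studies.csv", package = "dosetrend",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
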