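# End-to-end orchestration: dose assignment -> covariance reconstruction ->
# per-study GLS -> within-study stratum combination -> cross-study pooling ->
# heterogeneity, nonlinearity, bias and sensitivity diagnostics -> curve.

#' Run configuration
#'
#' @param increment dose increment for trend reporting, U/L (default 5).
#' @param ci_level CI coverage (default 0.95).
#' @param knot_percentiles three increasing fractions for spline knots.
#' @param pooling_model `"random"` or `"fixed"` for the headline estimates.
#' @param reference_dose curve anchor in U/L; `NULL` = lowest assigned dose.
#' @param grid_n number of curve grid points over the observed dose range.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters for simulated inputs).
#' @param tol,max_iter pseudo-count fit controls.
#' @return object of class `run_config`.
#' @export
run_config <- function(increment = 5, ci_level = 0.95,
                       knot_percentiles = c(0.25, 0.50, 0.75),
                       pooling_model = c("random", "fixed"),
                       reference_dose = NULL, grid_n = 100L,
                       seed = 1L, tol = 1e-10, max_iter = 200L) {
  pooling_model <- match.arg(pooling_model)
  stopifnot(ci_level > 0, ci_level < 1,
            length(knot_percentiles) == 3L,
            all(knot_percentiles > 0), all(knot_percentiles < 1),
            all(diff(knot_percentiles) > 0))
  structure(list(increment = increment, ci_level = ci_level,
                 knot_percentiles = knot_percentiles,
                 pooling_model = pooling_model,
                 reference_dose = reference_dose, grid_n = as.integer(grid_n),
                 seed = as.integer(seed), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "run_config")
}

# Stage one for a single (study, stratum): covariance reconstruction + GLS.
fit_study <- function(study, config, spec) {
  lrr <- log_rr_vector(study, config$ci_level)
  cats <- study$categories
  C <- if (any(is.na(cats$cases)) || any(is.na(cats$total))) {
    warning(sprintf("%s/%s: cases/totals missing; falling back to a diagonal (independence) covariance",
                    study$study_id, study$stratum_id), call. = FALSE)
    diag(lrr$V, nrow = length(lrr$V))
  } else {
    pseudo <- fit_pseudo_counts(study, lrr$L, tol = config$tol,
                                max_iter = config$max_iter)
    covariance_matrix(pseudo, lrr$V)
  }
  linear <- gls_fit(study, lrr, C, "linear")
  spline <- if (length(lrr$L) >= 3L) gls_fit(study, lrr, C, "spline", spec)
  list(linear = linear, spline = spline)
}

#' Run the full dose-response meta-analysis pipeline
#'
#' Executes, in order: dose assignment, spline-knot placement,
#' per-(study, stratum) covariance reconstruction and GLS trend fits
#' (linear always; spline where the study has at least 4 categories),
#' fixed-effect combination of strata within studies, fixed- and
#' random-effects cross-study pooling, heterogeneity statistics with the
#' Higgins I-squared CI, the Wald nonlinearity test, Egger / Begg
#' publication-bias tests, leave-one-out sensitivity analysis, and the
#' pooled dose-response curve anchored at the reference dose.
#'
#' @param input path to a study-table CSV, or a list of [study_record]s.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, the summary JSON,
#'   curve / per-study / funnel tables and a run manifest are written.
#' @return list with elements `summary` (all statistics), `fits`, `curve`,
#'   `per_study`, `funnel`, `loo`, and `manifest`.
#' @export
run_pipeline <- function(input, config = run_config(), out_dir = NULL) {
  t0 <- Sys.time()
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  result <- withCallingHandlers(
    run_pipeline_impl(input, config),
    warning = note
  )
  digest <- if (is.character(input)) unname(tools::md5sum(input)) else NA_character_
  manifest <- list(
    package_version = as.character(utils::packageVersion("dosetrend")),
    config = unclass(config),
    input_digest = digest,
    n_studies = result$summary$pooling$k,
    warnings = as.list(unique(warnings_seen)),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = character(0)
  )
  if (!is.null(out_dir)) {
    files <- write_results(result$summary, result$curve, result$per_study,
                           out_dir, funnel = result$funnel)
    manifest$files <- files
    mf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    manifest$files <- c(files, mf)
  }
  result$manifest <- manifest
  result
}

run_pipeline_impl <- function(input, config) {
  studies <- if (is.character(input)) read_study_table(input) else input
  if (length(studies) == 0L) stop("no studies in input", call. = FALSE)
  studies <- lapply(studies, assign_all)
  spec <- tryCatch(place_knots(studies, config$knot_percentiles),
                   error = function(e) {
                     warning("knot placement failed (", conditionMessage(e),
                             "); spline stage skipped", call. = FALSE)
                     NULL
                   })

  stage1 <- lapply(studies, fit_study, config = config, spec = spec)
  sid <- vapply(studies, function(s) s$study_id, character(1))
  by_study <- split(stage1, factor(sid, levels = unique(sid)))
  linear_fits <- lapply(by_study, function(fs)
    combine_strata(lapply(fs, `[[`, "linear")))
  spline_fits <- lapply(by_study, function(fs) {
    sf <- Filter(Negate(is.null), lapply(fs, `[[`, "spline"))
    if (length(sf) == length(fs)) combine_strata(sf) else NULL
  })
  spline_fits <- Filter(Negate(is.null), spline_fits)
  names(linear_fits) <- NULL

  lin_fixed <- pool_fixed(linear_fits)
  lin_random <- pool_random(linear_fits)
  headline <- if (config$pooling_model == "random") lin_random else lin_fixed
  het <- heterogeneity_ci(lin_fixed$Q, lin_fixed$k, config$ci_level)

  spl <- NULL
  if (!is.null(spec) && length(spline_fits) >= 2L) {
    spl_fixed <- pool_fixed(spline_fits)
    spl_random <- pool_random(spline_fits)
    spl <- list(fixed = spl_fixed, random = spl_random,
                p_nonlinearity_fixed = nonlinearity_test(spl_fixed),
                p_nonlinearity_random = nonlinearity_test(spl_random))
  }

  egger <- egger_test(linear_fits)
  begg <- begg_test(linear_fits)
  loo <- leave_one_out(linear_fits, config$increment, config$ci_level)
  funnel <- funnel_table(linear_fits)

  doses <- unlist(lapply(studies, function(s) s$categories$dose_assigned))
  ref_dose <- config$reference_dose %||% min(doses)
  grid <- seq(min(ref_dose, min(doses)), max(ref_dose, max(doses)),
              length.out = config$grid_n)
  curve_pool <- if (!is.null(spl)) {
    if (config$pooling_model == "random") spl$random else spl$fixed
  } else headline
  curve <- predict_curve(curve_pool$beta, curve_pool$cov, ref_dose, grid,
                         spec = if (length(curve_pool$beta) == 2L) spec,
                         ci_level = config$ci_level)

  per5 <- per_increment(headline$beta[1L], headline$cov[1L, 1L],
                        config$increment, config$ci_level)
  per_study <- do.call(rbind, lapply(linear_fits, function(f) {
    est <- per_increment(f$beta[1L], f$cov_beta[1L, 1L], config$increment,
                         config$ci_level)
    data.frame(study_id = f$study_id, slope = f$beta[1L],
               se = sqrt(f$cov_beta[1L, 1L]), rr = est[["rr"]],
               ci_low = est[["ci_low"]], ci_high = est[["ci_high"]],
               stringsAsFactors = FALSE)
  }))

  summary <- list(
    increment = config$increment,
    reference_dose = ref_dose,
    dose_range = c(min(doses), max(doses)),
    knots = if (!is.null(spec)) spec$knots,
    pooling = list(
      model = config$pooling_model,
      k = lin_fixed$k,
      rr_per_increment = per5[["rr"]],
      rr_ci_low = per5[["ci_low"]],
      rr_ci_high = per5[["ci_high"]],
      slope = headline$beta[1L],
      slope_se = sqrt(headline$cov[1L, 1L]),
      tau2 = lin_random$tau2,
      Q = signif(lin_fixed$Q, 6),
      df = lin_fixed$df,
      p_Q = signif(lin_fixed$p_Q, 4),
      I2 = het$I2,
      I2_ci_low = het$ci_low,
      I2_ci_high = het$ci_high
    ),
    nonlinearity = if (!is.null(spl)) list(
      p_fixed = signif(spl$p_nonlinearity_fixed, 4),
      p_random = signif(spl$p_nonlinearity_random, 4),
      beta_spline_fixed = spl$fixed$beta,
      beta_spline_random = spl$random$beta
    ),
    bias = list(
      egger = list(intercept = egger$intercept, se = egger$se,
                   p = signif(egger$p, 4), k = egger$k),
      begg = list(tau = begg$tau, p = signif(begg$p, 4), k = begg$k)
    ),
    sensitivity = list(
      leave_one_out = loo,
      rr_min = min(loo$rr), rr_max = max(loo$rr)
    )
  )
  list(summary = summary, fits = list(linear = linear_fits,
                                      spline = spline_fits,
                                      pooled_linear = list(fixed = lin_fixed,
                                                           random = lin_random),
                                      pooled_spline = spl),
       curve = curve, per_study = per_study, funnel = funnel, loo = loo)
}

#' Validate a study table file
#'
#' @param path study-table CSV.
#' @return list with `status` (0 = clean, 1 = validation findings,
#'   2 = unreadable) and `findings` (data frame, possibly empty).
#' @export
validate_table <- function(path) {
  records <- tryCatch(
    suppressWarnings(read_study_table(path, strict = FALSE)),
    error = function(e) e
  )
  if (inherits(records, "error")) {
    return(list(status = 2L,
                findings = data.frame(message = conditionMessage(records))))
  }
  findings <- attr(records, "findings")
  if (is.null(findings) || nrow(findings) == 0L) {
    list(status = 0L, findings = data.frame())
  } else {
    list(status = 1L, findings = findings)
  }
}
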