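# Scoring exposure categories with a single scalar dose.
#
# Published categories come as intervals, sometimes open-ended, sometimes with
# a reported median. The trend regression needs one dose per category; the
# rules here are the conventional ones in dose-response meta-analysis:
# reported median first, then interval midpoint, then (for open intervals)
# the closed bound plus/minus half the width of the adjacent closed category,
# floored at 0 U/L.

#' Assign a scalar dose to one exposure category
#'
#' @param dose_low,dose_high interval bounds in U/L (`NA` = open).
#' @param dose_assigned reported median/midpoint in U/L, if any; always wins.
#' @param width_below width of the adjacent closed category below (used for
#'   top-open categories).
#' @param width_above width of the adjacent closed category above (used for
#'   bottom-open categories).
#' @return assigned dose in U/L.
#' @export
assign_dose <- function(dose_low = NA, dose_high = NA, dose_assigned = NA,
                        width_below = NA, width_above = NA) {
  if (!is.na(dose_assigned)) return(dose_assigned)
  if (!is.na(dose_low) && !is.na(dose_high)) return((dose_low + dose_high) / 2)
  if (!is.na(dose_low)) {           # top-open: >= dose_low
    if (is.na(width_below)) {
      stop("cannot assign dose to open-top category without an adjacent closed category",
           call. = FALSE)
    }
    return(dose_low + width_below / 2)
  }
  if (!is.na(dose_high)) {          # bottom-open: < dose_high
    if (is.na(width_above)) {
      stop("cannot assign dose to open-bottom category without an adjacent closed category",
           call. = FALSE)
    }
    return(max(0, dose_high - width_above / 2))
  }
  stop("category has neither bounds nor an assigned dose", call. = FALSE)
}

#' Assign doses to every category of a study
#'
#' Categories are sorted by dose first, so the result is invariant to the
#' input order. Reported medians override interval arithmetic; open-ended
#' intervals use half the adjacent closed category's width. The resulting
#' doses must be strictly increasing.
#'
#' @param study a [study_record].
#' @return the study with `dose_assigned` filled for every category.
#' @export
assign_all <- function(study) {
  cats <- study$categories
  k <- nrow(cats)
  widths <- cats$dose_high - cats$dose_low  # NA when open
  doses <- numeric(k)
  for (i in seq_len(k)) {
    wb <- if (i > 1L) widths[i - 1L] else NA_real_
    wa <- if (i < k) widths[i + 1L] else NA_real_
    doses[i] <- assign_dose(cats$dose_low[i], cats$dose_high[i],
                            cats$dose_assigned[i], wb, wa)
  }
  if (k >= 2L && any(diff(doses) <= 0)) {
    bad <- which(diff(doses) <= 0)
    stop(sprintf("assigned doses not strictly increasing between categories %s",
                 paste(sprintf("%d-%d", bad, bad + 1L), collapse = ", ")),
         call. = FALSE)
  }
  study$categories$dose_assigned <- doses
  study
}
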