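#' dosetrend: dose-response meta-analysis of category-level cohort data
#'
#' A *study record* is the package's unit of analysis: one cohort (or one
#' sex/subgroup stratum of a cohort) reporting adjusted relative risks for
#' three or more ordered exposure categories against a designated reference
#' category. Categories carry the dose information (interval bounds and/or a
#' reported median), the adjusted RR with its 95% CI, and the category margins
#' (events and participants or person-time) needed to reconstruct the
#' within-study covariance of the log RRs.
#' @keywords internal
"_PACKAGE"

STUDY_DESIGNS <- c("cumulative_incidence", "incidence_rate", "case_control")

CATEGORY_COLUMNS <- c("label", "dose_low", "dose_high", "dose_assigned",
                      "rr", "ci_low", "ci_high", "cases", "total",
                      "is_reference")

TABLE_COLUMNS <- c("study_id", "stratum_id", "design", CATEGORY_COLUMNS,
                   "followup_years")

#' Construct a study record
#'
#' @param study_id,stratum_id identifiers; `stratum_id` defaults to `"all"`.
#' @param design one of `"cumulative_incidence"`, `"incidence_rate"`,
#'   `"case_control"`.
#' @param categories data frame with columns `label`, `dose_low`, `dose_high`,
#'   `dose_assigned`, `rr`, `ci_low`, `ci_high`, `cases`, `total`,
#'   `is_reference` (one row per exposure category; `NA` = not reported).
#' @param followup_years,covariates_note optional metadata.
#' @return object of class `study_record`.
#' @export
study_record <- function(study_id, stratum_id = "all", design, categories,
                         followup_years = NA_real_, covariates_note = "") {
  stopifnot(is.character(study_id), length(study_id) == 1L,
            is.data.frame(categories))
  design <- match.arg(design, STUDY_DESIGNS)
  missing_cols <- setdiff(CATEGORY_COLUMNS, names(categories))
  if (length(missing_cols)) {
    stop("categories is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  categories <- categories[, CATEGORY_COLUMNS]
  categories <- categories[order(category_sort_key(categories)), , drop = FALSE]
  rownames(categories) <- NULL
  structure(
    list(study_id = study_id, stratum_id = stratum_id, design = design,
         categories = categories, followup_years = followup_years,
         covariates_note = covariates_note),
    class = "study_record"
  )
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record> %s / %s (%s), %d categories\n",
              x$study_id, x$stratum_id, x$design, nrow(x$categories)))
  print(x$categories, ...)
  invisible(x)
}

# Sorting key used before doses are finalised: reported median, else interval
# midpoint, else the single available bound.
category_sort_key <- function(cats) {
  key <- cats$dose_assigned
  mid <- (cats$dose_low + cats$dose_high) / 2
  key <- ifelse(is.na(key), mid, key)
  key <- ifelse(is.na(key), cats$dose_low, key)
  key <- ifelse(is.na(key), cats$dose_high, key)
  key
}

#' Read a long-format study table
#'
#' One row per exposure category; studies are keyed by
#' (`study_id`, `stratum_id`). Empty fields are treated as absent. Columns:
#' `study_id, stratum_id, design, label, dose_low, dose_high, dose_assigned,
#' rr, ci_low, ci_high, cases, total, is_reference, followup_years`.
#'
#' @param path CSV file (UTF-8, comma separated, header row).
#' @param strict if `TRUE` (default), validation findings abort the read;
#'   otherwise findings are attached as attribute `"findings"` with a warning.
#' @return list of [study_record] objects, categories ordered by dose.
#' @export
read_study_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  missing_cols <- setdiff(TABLE_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("dose_low", "dose_high", "dose_assigned", "rr", "ci_low",
                "ci_high", "cases", "total", "followup_years")
  for (col in num_cols) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("column '%s': unparseable number '%s' at line %d",
                   col, vals[bad[1]], bad[1] + 1L), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  raw$is_reference <- parse_flag(raw$is_reference)
  raw$stratum_id[is.na(raw$stratum_id)] <- "all"
  if (nrow(raw) == 0L) return(list())

  key <- paste(raw$study_id, raw$stratum_id, sep = "\r")
  records <- lapply(split(raw, factor(key, levels = unique(key))), function(df) {
    study_record(
      study_id = df$study_id[1], stratum_id = df$stratum_id[1],
      design = df$design[1], categories = df[, CATEGORY_COLUMNS],
      followup_years = df$followup_years[1]
    )
  })
  names(records) <- NULL
  findings <- do.call(rbind, lapply(records, validate_study))
  if (!is.null(findings) && nrow(findings)) {
    msg <- paste(sprintf("%s/%s [%s]: %s", findings$study_id,
                         findings$stratum_id, findings$field, findings$message),
                 collapse = "\n  ")
    if (strict) stop("study table failed validation:\n  ", msg, call. = FALSE)
    warning("study table has validation findings:\n  ", msg, call. = FALSE)
    attr(records, "findings") <- findings
  }
  records
}

parse_flag <- function(x) {
  out <- tolower(trimws(ifelse(is.na(x), "false", x))) %in%
    c("true", "t", "1", "yes")
  out
}

finding <- function(record, field, rule, message) {
  data.frame(study_id = record$study_id, stratum_id = record$stratum_id,
             field = field, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a study record
#'
#' Checks every structural invariant of the data model. Validation is total:
#' findings are returned as data, never thrown.
#'
#' @param record a [study_record].
#' @return data frame with columns `study_id, stratum_id, field, rule,
#'   message`; zero rows when the record is well formed.
#' @export
validate_study <- function(record) {
  out <- list()
  add <- function(f) out[[length(out) + 1L]] <<- f
  cats <- record$categories
  k <- nrow(cats)

  if (!record$design %in% STUDY_DESIGNS) {
    add(finding(record, "design", "design_known",
                sprintf("unknown design '%s'", record$design)))
  }
  if (k < 3L) {
    add(finding(record, "categories", "min_categories",
                sprintf("fewer than 3 categories (%d)", k)))
  }
  nref <- sum(cats$is_reference, na.rm = TRUE)
  if (nref != 1L) {
    add(finding(record, "is_reference", "single_reference",
                sprintf("expected exactly one reference category, found %d", nref)))
  }
  for (i in seq_len(k)) {
    ci <- cats[i, ]
    where <- sprintf("category %d (%s)", i, ci$label %||% "")
    if (isTRUE(ci$is_reference)) {
      if (!is.na(ci$rr) && abs(ci$rr - 1) > 1e-6) {
        add(finding(record, "rr", "reference_rr_one",
                    paste0(where, ": reference rr must equal 1")))
      }
      degenerate <- (is.na(ci$ci_low) || ci$ci_low == 1) &&
        (is.na(ci$ci_high) || ci$ci_high == 1)
      if (!degenerate) {
        add(finding(record, "ci_low", "reference_ci_degenerate",
                    paste0(where, ": reference CI must be degenerate")))
      }
    } else {
      if (is.na(ci$rr) || ci$rr <= 0) {
        add(finding(record, "rr", "rr_positive",
                    paste0(where, ": rr must be a positive number")))
      }
      if (any(is.na(c(ci$ci_low, ci$ci_high))) ||
          isTRUE(ci$ci_low <= 0) ||
          !isTRUE(ci$ci_low <= ci$rr && ci$rr <= ci$ci_high)) {
        add(finding(record, "ci_low", "ci_brackets_rr",
                    paste0(where, ": need 0 < ci_low <= rr <= ci_high")))
      }
    }
    if (!is.na(ci$cases) && (ci$cases < 0 || ci$cases != round(ci$cases))) {
      add(finding(record, "cases", "cases_nonnegative_integer",
                  paste0(where, ": cases must be a nonnegative integer")))
    }
    if (!is.na(ci$total) && ci$total <= 0) {
      add(finding(record, "total", "total_positive",
                  paste0(where, ": total must be positive")))
    }
    if (record$design == "cumulative_incidence" && !is.na(ci$total)) {
      if (ci$total != round(ci$total)) {
        add(finding(record, "total", "participants_integer",
                    paste0(where, ": participant totals must be integers")))
      }
      if (!is.na(ci$cases) && ci$cases > ci$total) {
        add(finding(record, "cases", "cases_exceed_total",
                    paste0(where, ": cases exceed total")))
      }
    }
    if (!is.na(ci$dose_low) && !is.na(ci$dose_high) &&
        !(ci$dose_low < ci$dose_high)) {
      add(finding(record, "dose_low", "dose_bounds_ordered",
                  paste0(where, ": dose_low must be < dose_high")))
    }
  }
  key <- category_sort_key(cats)
  if (k >= 2L && !any(is.na(key)) && any(diff(key) <= 0)) {
    add(finding(record, "dose_assigned", "doses_increasing",
                "category doses are not strictly increasing"))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(study_id = character(0), stratum_id = character(0),
               field = character(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Write a study table
#'
#' Inverse of [read_study_table()]: serialises records to the long CSV format.
#' @param records list of [study_record] objects.
#' @param path output CSV path.
#' @export
write_study_table <- function(records, path) {
  rows <- lapply(records, function(r) {
    df <- r$categories
    cbind(data.frame(study_id = r$study_id, stratum_id = r$stratum_id,
                     design = r$design, stringsAsFactors = FALSE),
          df, data.frame(followup_years = r$followup_years))
  })
  tab <- do.call(rbind, rows)
  tab$is_reference <- ifelse(tab$is_reference, "true", "false")
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write pipeline result artifacts
#'
#' Writes the machine-readable summary (JSON), the dose-response curve table
#' and the per-study trend table, and returns a manifest of files written.
#'
#' @param summary named list, serialised to `summary.json`.
#' @param curve data frame `(dose, rr, ci_low, ci_high)` written as TSV.
#' @param per_study data frame of per-study trend estimates written as TSV.
#' @param out_dir output directory (created if needed).
#' @param funnel optional data frame `(study_id, effect, se)` written as TSV.
#' @return character vector of file paths written.
#' @export
write_results <- function(summary, curve, per_study, out_dir, funnel = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, p)
  write_tsv <- function(df, name) {
    fp <- file.path(out_dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 12))
    utils::write.table(df, fp, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, fp)
  }
  write_tsv(curve, "curve.tsv")
  write_tsv(per_study, "per_study.tsv")
  if (!is.null(funnel)) write_tsv(funnel, "funnel.tsv")
  paths
}
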