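#!/usr/bin/env Rscript

# Stage one: per-study dose-response trends. For each cohort in the study
# table: assign scalar doses to the exposure categories, reconstruct the
# within-study covariance of the correlated log RRs from the category
# margins (Greenland-Longnecker pseudo-counts), and fit the linear trend by
# generalized least squares. Writes the per-study slopes and per-5 U/L RRs.

suppressMessages(library(dosetrend))

studies <- read_study_table("results/synthetic_studies.csv")
studies <- lapply(studies, assign_all)

rows <- lapply(studies, function(st) {
  lrr <- log_rr_vector(st)
  pseudo <- fit_pseudo_counts(st, lrr$L)
  C <- covariance_matrix(pseudo, lrr$V)
  fit <- gls_fit(st, lrr, C, "linear")
  est <- per_increment(fit$beta, fit$cov_beta[1, 1], increment = 5)
  data.frame(study_id = st$study_id,
             slope = fit$beta, se = sqrt(fit$cov_beta[1, 1]),
             rr_per5 = est[["rr"]], ci_low = est[["ci_low"]],
             ci_high = est[["ci_high"]],
             a0 = pseudo$a[pseudo$ref],
             margin_residual = pseudo$residual)
})
trends <- do.call(rbind, rows)
write.table(format(trends, digits = 6), "results/per_study_trends.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("Per-study GLS linear trends -> results/per_study_trends.tsv\n")
for (i in seq_len(nrow(trends))) {
  cat(sprintf("  %s: RR per 5 U/L = %.3f (%.3f-%.3f)\n",
              trends$study_id[i], trends$rr_per5[i], trends$ci_low[i],
              trends$ci_high[i]))
}
cat(sprintf("  all case margins conserved to %.1e\n",
            max(abs(trends$margin_residual))))
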