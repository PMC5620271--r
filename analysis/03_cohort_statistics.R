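#!/usr/bin/env Rscript
# Cohort-level staging statistics on the fitted per-subject table:
# Shapiro-Wilk normality, pooled Student's t-tests between stage groups,
# ROC analysis with Youden cut-offs and likelihood ratios, DeLong
# comparison of Ktrans against the IVIM perfusion parameters, stepwise
# logistic regression, and Spearman correlations (Bonferroni-corrected)
# between the IVIM perfusion-related and DCE parameters.
#
# Reads:  results/cohort_table.csv (from 02_fit_parameter_maps.R)
# Writes: results/report.json, results/roc_curves.csv,
#         results/correlations.csv

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE))), "00_common.R"))

tab_path <- file.path("results", "cohort_table.csv")
if (!file.exists(tab_path))
  stop("run analysis/02_fit_parameter_maps.R first (missing ", tab_path, ")")
tab <- read_cohort_table(tab_path)

report <- analyze_cohort(tab)
print(report)

jsonlite::write_json(ivimdce:::report_to_list_(report),
                     file.path(results_dir(), "report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
roc_long <- do.call(rbind, lapply(names(report$roc), function(p)
  cbind(parameter = p, report$roc[[p]]$curve)))
write.csv(roc_long, file.path(results_dir(), "roc_curves.csv"),
          row.names = FALSE)
write.csv(report$correlations, file.path(results_dir(), "correlations.csv"),
          row.names = FALSE)

cat("\nDeLong paired AUC comparisons:\n")
print(report$auc_comparisons, row.names = FALSE)
cat("\nDirection pattern vs the reference cohort (high minus low):\n")
for (i in seq_len(nrow(report$t_tests))) {
  r <- report$t_tests[i, ]
  expected <- if (r$parameter == "ve") "higher" else "lower"
  observed <- if (r$mean_high < r$mean_low) "lower" else "higher"
  cat(sprintf("  %-7s expected %-6s observed %-6s %s\n", r$parameter,
              expected, observed,
              if (expected == observed) "(agrees)" else "(DISAGREES)"))
}
cat("\nWrote results/report.json, results/roc_curves.csv, results/correlations.csv.\n")
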