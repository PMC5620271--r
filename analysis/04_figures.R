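#!/usr/bin/env Rscript
# Figures for the cohort analysis: ROC curves per parameter and the
# IVIM-vs-DCE correlation scatter plots.
#
# Reads:  results/cohort_table.csv, results/roc_curves.csv
# Writes: results/figures/roc_curves.pdf, results/figures/correlations.pdf

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(),
  value = TRUE))), "00_common.R"))
suppressMessages(library(ggplot2))

tab <- read_cohort_table(file.path("results", "cohort_table.csv"))
roc <- read.csv(file.path("results", "roc_curves.csv"))
fig_dir <- results_dir("figures")

roc_plot <- ggplot(roc, aes(1 - spec, sens, colour = parameter)) +
  geom_step(linewidth = 0.6) +
  geom_abline(slope = 1, linetype = 3, colour = "grey50") +
  coord_equal() +
  labs(x = "1 - specificity", y = "Sensitivity",
       title = "Stage-group discrimination by ROI-mean parameter") +
  theme_minimal()
ggsave(file.path(fig_dir, "roc_curves.pdf"), roc_plot, width = 6, height = 5)

long <- do.call(rbind, lapply(c("mean_Ktrans", "mean_kep", "mean_ve",
                                "mean_vp"), function(dc)
  data.frame(f = tab$mean_f, dce_value = tab[[dc]], dce_parameter = dc,
             stage = tab$stage_group)))
sc <- ggplot(long, aes(f, dce_value, colour = stage)) +
  geom_point(size = 1, alpha = 0.8) +
  facet_wrap(~dce_parameter, scales = "free_y") +
  labs(x = "IVIM perfusion fraction f (ROI mean)", y = "DCE parameter",
       title = "IVIM perfusion fraction vs DCE parameters") +
  theme_minimal()
ggsave(file.path(fig_dir, "correlations.pdf"), sc, width = 7, height = 5)

cat("Wrote", file.path(fig_dir, "roc_curves.pdf"), "and",
    file.path(fig_dir, "correlations.pdf"), "\n")
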