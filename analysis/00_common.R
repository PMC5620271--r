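# Shared study definition for the analysis scripts.
#
# One cohort, fixed seed: 29 low-stage + 46 high-stage subjects whose
# ROI-mean parameters follow the reference group distributions, with a
# rank correlation of 0.5 induced among the perfusion-related parameters
# (f, D*, Ktrans, ve, vp), acquired at b=0 SNR 50 on reduced-resolution
# 8 x 8 x 4 grids (~32 tumor voxels per subject).

library(ivimdce)

STUDY_SEED <- 42L

study_spec <- function() {
  cohort_spec(n_low = 29L, n_high = 46L, cross_correlation = 0.5,
              noise_sigma = 20, shape = c(8L, 8L, 4L),
              voxel_size = c(1.8, 1.8, 3.3), cv_within = 0.1,
              seed = STUDY_SEED)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
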