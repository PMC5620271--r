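#' ROI mean of a parameter map
#'
#' Arithmetic mean over voxels in the ROI that also pass the validity
#' mask; the per-subject summary statistic reported for every parameter.
#'
#' @param param_map Numeric array.
#' @param roi_mask Logical array, same geometry.
#' @param valid_mask Optional logical array of fit validity; NULL keeps
#'   every ROI voxel with a finite value.
#' @return List: `mean`, `n` (contributing voxels).
#' @export
roi_mean <- function(param_map, roi_mask, valid_mask = NULL) {
  if (!identical(dim(param_map), dim(roi_mask)))
    stop("param_map and roi_mask must share geometry")
  keep <- roi_mask
  if (!is.null(valid_mask)) {
    if (!identical(dim(valid_mask), dim(roi_mask)))
      stop("valid_mask must share geometry with roi_mask")
    keep <- keep & valid_mask
  }
  vals <- param_map[keep]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L)
    stop("undefined mean: no valid voxels inside the ROI")
  list(mean = mean(vals), n = length(vals))
}

#' Tumor volume from an ROI mask
#'
#' Voxel-counting (segmentation) volume: count of ROI voxels times the
#' voxel volume. Subjects whose tumor falls below the 30 mm^3 exclusion
#' floor are expected to be dropped by the caller.
#'
#' @param roi_mask Logical array.
#' @param voxel_size Numeric length 3, mm per axis (positive).
#' @return Volume in mm^3 (0 for an empty mask).
#' @export
tumor_volume <- function(roi_mask, voxel_size) {
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  sum(roi_mask) * prod(voxel_size)
}

#' Cohen's kappa agreement between two observers
#'
#' Chance-corrected categorical agreement. Continuous measurements are
#' first binned; the default dichotomizes at the pooled median of both
#' observers' values (the binning rule for continuous parameter means is
#' an interpretation choice and is exposed via `binning`/`breaks`).
#'
#' @param obs1,obs2 Paired measurements (numeric, or factors/characters
#'   treated as ready-made categories).
#' @param binning "median" (pooled-median dichotomization) or "none"
#'   (inputs already categorical).
#' @param breaks Optional explicit cut points for numeric inputs
#'   (overrides `binning`).
#' @return List: `kappa`, `po` (observed agreement), `pe` (chance
#'   agreement), `table`.
#' @export
agreement_kappa <- function(obs1, obs2, binning = c("median", "none"),
                            breaks = NULL) {
  if (length(obs1) != length(obs2)) stop("observers must be paired")
  if (length(obs1) < 2L) stop("need at least 2 paired measurements")
  binning <- match.arg(binning)
  if (is.numeric(obs1) && is.numeric(obs2)) {
    if (!is.null(breaks)) {
      brk <- c(-Inf, breaks, Inf)
      obs1 <- cut(obs1, brk); obs2 <- cut(obs2, brk)
    } else if (binning == "median") {
      med <- stats::median(c(obs1, obs2))
      obs1 <- factor(obs1 > med, c(FALSE, TRUE), c("low", "high"))
      obs2 <- factor(obs2 > med, c(FALSE, TRUE), c("low", "high"))
    }
  }
  lev <- union(levels(factor(obs1)), levels(factor(obs2)))
  o1 <- factor(obs1, lev); o2 <- factor(obs2, lev)
  if (length(unique(o1)) == 1L && length(unique(o2)) == 1L)
    stop("kappa undefined: both observers produced a single category")
  tab <- table(o1, o2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, table = tab)
}

#' Summarize one subject's fitted maps into a record
#'
#' Produces the per-subject row used by the cohort statistics: ROI means
#' of the fitted IVIM and Tofts parameters over valid voxels, the tumor
#' volume, and the stage labels.
#'
#' @param subject_id Identifier.
#' @param stage_group "low" or "high".
#' @param ajcc_stage "I".."IV" (must be consistent with `stage_group`).
#' @param ivim An `ivim_maps` from [fit_ivim_map()].
#' @param tofts A `tofts_maps` from [fit_dce_map()].
#' @param roi_mask Logical array.
#' @param voxel_size mm per axis.
#' @return One-row data.frame with columns subject_id, stage_group,
#'   ajcc_stage, tumor_volume, mean_D, mean_f, mean_Dstar, mean_Ktrans,
#'   mean_kep, mean_ve, mean_vp, n_valid_ivim, n_valid_dce.
#' @export
subject_record <- function(subject_id, stage_group, ajcc_stage, ivim,
                           tofts, roi_mask, voxel_size) {
  stage_group <- match.arg(stage_group, c("low", "high"))
  ajcc_stage <- match.arg(ajcc_stage, c("I", "II", "III", "IV"))
  expected <- if (ajcc_stage %in% c("I", "II")) "low" else "high"
  if (stage_group != expected)
    stop(sprintf("stage_group '%s' inconsistent with AJCC stage %s",
                 stage_group, ajcc_stage))
  mi <- function(map) roi_mean(map, roi_mask, ivim$valid_mask)
  md <- function(map) roi_mean(map, roi_mask, tofts$valid_mask)
  data.frame(
    subject_id = subject_id, stage_group = stage_group,
    ajcc_stage = ajcc_stage,
    tumor_volume = tumor_volume(roi_mask, voxel_size),
    mean_D = mi(ivim$D_map)$mean,
    mean_f = mi(ivim$f_map)$mean,
    mean_Dstar = mi(ivim$Dstar_map)$mean,
    mean_Ktrans = md(tofts$Ktrans_map)$mean,
    mean_kep = md(tofts$kep_map)$mean,
    mean_ve = md(tofts$ve_map)$mean,
    mean_vp = md(tofts$vp_map)$mean,
    n_valid_ivim = sum(ivim$valid_mask & roi_mask),
    n_valid_dce = sum(tofts$valid_mask & roi_mask),
    stringsAsFactors = FALSE)
}

#' Fit both models for every cohort subject and build the cohort table
#'
#' Runs the voxel-wise IVIM and extended-Tofts pipelines per subject,
#' summarizes each into a [subject_record()], and reports the total
#' voxel exclusion counts per filter stage.
#'
#' @param cohort A `cohort` from [simulate_cohort()] with images.
#' @param snr_k SNR threshold multiple for the IVIM filter.
#' @param b_threshold High-b cut for the diffusion stage.
#' @param min_volume Tumor volume exclusion floor, mm^3 (default 30).
#' @param verbose Print per-stage exclusion summaries.
#' @return List: `table` (one row per retained subject), `excluded`
#'   (subject ids dropped by the volume floor), `exclusions`
#'   (summed voxel filter counts).
#' @export
fit_cohort <- function(cohort, snr_k = 5, b_threshold = 200,
                       min_volume = 30, verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$subjects))
    stop("cohort was simulated without images")
  rows <- list(); dropped <- character()
  excl_ivim <- NULL; excl_dce <- NULL
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    roi <- sub$truth$roi_mask
    vol <- tumor_volume(roi, sub$truth$voxel_size)
    if (vol < min_volume) { dropped <- c(dropped, sub$subject_id); next }
    iv <- fit_ivim_map(sub$dwi, roi, noise_sigma = cohort$spec$noise_sigma,
                       snr_k = snr_k, b_threshold = b_threshold)
    tf <- fit_dce_map(sub$dce, roi)
    excl_ivim <- if (is.null(excl_ivim)) iv$exclusions
                 else excl_ivim + iv$exclusions
    excl_dce <- if (is.null(excl_dce)) tf$exclusions
                else excl_dce + tf$exclusions
    rows[[length(rows) + 1L]] <- subject_record(
      sub$subject_id, cohort$truth$stage_group[i],
      cohort$truth$ajcc_stage[i], iv, tf, roi, sub$truth$voxel_size)
    if (verbose && i %% 10 == 0)
      message(sprintf("  fitted %d/%d subjects", i, length(cohort$subjects)))
  }
  if (verbose) {
    message("IVIM voxel exclusions: ",
            paste(names(excl_ivim), excl_ivim, sep = "=", collapse = ", "))
    message("DCE voxel exclusions: ",
            paste(names(excl_dce), excl_dce, sep = "=", collapse = ", "))
  }
  list(table = do.call(rbind, rows), excluded = dropped,
       exclusions = list(ivim = excl_ivim, dce = excl_dce))
}
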