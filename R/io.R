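#' Write a simulated subject to disk as NIfTI + JSON sidecars
#'
#' Emits `dwi_4d.nii.gz` (x,y,z,b), `dce_4d.nii.gz` (x,y,z,t),
#' `precontrast.nii.gz`, `roi_mask.nii.gz`, `dwi_scheme.json`,
#' `dce_scheme.json` and `aif.csv` (two columns: time_s, cp_mM) into
#' `dir`. Grids are stored in voxel space with the voxel size in pixdim
#' (no oblique affine).
#'
#' @param subject One element of `simulate_cohort(...)$subjects`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- subject$truth$voxel_size
  wr <- function(arr, file, dims = 3L) {
    img <- RNifti::asNifti(arr * 1)
    RNifti::pixdim(img) <- if (dims == 4L) c(vs, 1) else vs
    RNifti::writeNifti(img, file.path(dir, file))
  }
  wr(subject$dwi$data, "dwi_4d.nii.gz", 4L)
  wr(subject$dce$data, "dce_4d.nii.gz", 4L)
  wr(subject$dce$pre, "precontrast.nii.gz")
  wr(subject$truth$roi_mask, "roi_mask.nii.gz")
  jsonlite::write_json(unclass(subject$dwi$scheme),
                       file.path(dir, "dwi_scheme.json"), auto_unbox = TRUE)
  jsonlite::write_json(unclass(subject$dce$scheme),
                       file.path(dir, "dce_scheme.json"), auto_unbox = TRUE)
  utils::write.csv(data.frame(time_s = subject$dce$aif$time,
                              cp_mM = subject$dce$aif$cp),
                   file.path(dir, "aif.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a DWI series written by [write_subject()]
#'
#' @param dwi_path Path to the 4D NIfTI.
#' @param scheme_path Path to the scheme JSON.
#' @return A `dwi_series`.
#' @export
read_dwi_series <- function(dwi_path, scheme_path) {
  img <- RNifti::readNifti(dwi_path)
  sc <- jsonlite::read_json(scheme_path, simplifyVector = TRUE)
  scheme <- dwi_scheme(sc$b_values, sc$n_averages)
  structure(list(data = unclass(img)[, , , , drop = FALSE],
                 scheme = scheme,
                 voxel_size = RNifti::pixdim(img)[1:3],
                 noise_sigma = NA_real_),
            class = "dwi_series")
}

#' Read a DCE series written by [write_subject()]
#'
#' @param dce_path,pre_path Paths to the dynamic 4D and pre-contrast 3D
#'   NIfTI volumes.
#' @param scheme_path Path to the scheme JSON.
#' @param aif_path Path to the AIF CSV (time_s, cp_mM).
#' @return A `dce_series`.
#' @export
read_dce_series <- function(dce_path, pre_path, scheme_path, aif_path) {
  img <- RNifti::readNifti(dce_path)
  pre <- RNifti::readNifti(pre_path)
  sc <- jsonlite::read_json(scheme_path, simplifyVector = TRUE)
  scheme <- dce_scheme(sc$n_dynamics, sc$dt, sc$injection_index, sc$TR,
                       sc$flip_pre, sc$flip_dyn, sc$r1, sc$dose, sc$hct)
  av <- utils::read.csv(aif_path)
  structure(list(data = unclass(img)[, , , , drop = FALSE],
                 pre = unclass(pre)[, , , drop = FALSE][, , ],
                 scheme = scheme, aif = aif(av$time_s, av$cp_mM),
                 voxel_size = RNifti::pixdim(img)[1:3],
                 noise_sigma = NA_real_),
            class = "dce_series")
}

#' Read an ROI mask NIfTI as a logical array
#'
#' @param path NIfTI path.
#' @return Logical array.
#' @export
read_roi_mask <- function(path) {
  arr <- unclass(RNifti::readNifti(path))
  array(arr > 0.5, dim(arr))
}

#' Write fitted parameter maps as NIfTI volumes
#'
#' One file per map (`<prefix><name>.nii.gz`) plus the validity mask.
#'
#' @param maps An `ivim_maps` or `tofts_maps` object.
#' @param dir Output directory.
#' @param voxel_size mm per axis for the pixdim.
#' @param prefix Optional file-name prefix.
#' @return Paths written, invisibly.
#' @export
write_parameter_maps <- function(maps, dir, voxel_size = c(1, 1, 1),
                                 prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- grep("_map$|valid_mask", names(maps), value = TRUE)
  paths <- character()
  for (m in nm) {
    f <- file.path(dir, paste0(prefix, sub("_map$", "", m), ".nii.gz"))
    img <- RNifti::asNifti(maps[[m]] * 1)
    RNifti::pixdim(img) <- voxel_size
    RNifti::writeNifti(img, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Write / read the cohort table CSV
#'
#' @param table Cohort table (one row per subject).
#' @param path CSV path.
#' @return The path (write) or the table (read).
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
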