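#' Default pipeline configuration
#'
#' Plain-list configuration covering the whole pipeline: cohort
#' generation (counts, group distributions, correlation, noise,
#' geometry), acquisition schemes, fitting options and the global seed.
#' All defaults are the reference acquisition constants (13-b-value DWI;
#' 65-dynamic DCE with injection at the 8th dynamic, TR 4.8 ms, flips
#' 5/15 deg) and the reference cohort structure (29 low + 46 high).
#'
#' @param seed Global seed.
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_low = 29L, n_high = 46L, cross_correlation = 0.5,
                  noise_sigma = 20, shape = c(8L, 8L, 4L),
                  voxel_size = c(1.8, 1.8, 3.3), cv_within = 0.1),
    dwi = list(b_values = c(0, 10, 20, 30, 40, 60, 100, 120, 160, 200,
                            300, 500, 1000),
               n_averages = 3L),
    dce = list(n_dynamics = 65L, dt = 9.2, injection_index = 8L, TR = 4.8,
               flip_pre = 5, flip_dyn = 15, r1 = 3.5, dose = 0.1,
               hct = 0.42),
    fitting = list(b_threshold = 200, snr_k = 5, min_volume = 30,
                   criterion = "youden", alpha = 0.05)),
    class = "pipeline_config")
}

# internal: recursively overlay user values onto defaults, rejecting
# unknown keys; returns the merged list
merge_config_ <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config_(defaults[[k]], as.list(user[[k]]),
                                     paste0(path, k, "$"))
    } else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load a pipeline configuration from JSON or YAML
#'
#' Missing keys are filled from [default_config()]; unknown keys are
#' rejected with a message listing them. The resulting schemes are
#' validated immediately, so invariant violations (e.g. an injection
#' index outside the dynamic range) fail at load time.
#'
#' @param path File path ending in .json, .yaml or .yml. An empty file
#'   yields the all-defaults configuration.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (file.size(path) == 0 ||
              !nzchar(paste(readLines(path, warn = FALSE), collapse = ""))) {
    NULL
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop("config must be JSON or YAML")
  cfg <- merge_config_(unclass(default_config()), user)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Save a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @param path Output path (.json, .yaml or .yml).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(unclass(config), path)
  } else stop("config must be JSON or YAML")
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Builds every scheme/spec object the config describes, so all type
#' invariants are enforced; returns them for use by [run_pipeline()].
#'
#' @param config A `pipeline_config`.
#' @return List: `spec` (a [cohort_spec()]), `fitting`.
#' @export
validate_config <- function(config) {
  dwi <- dwi_scheme(config$dwi$b_values, config$dwi$n_averages)
  dce <- do.call(dce_scheme, config$dce)
  spec <- cohort_spec(
    n_low = config$cohort$n_low, n_high = config$cohort$n_high,
    cross_correlation = config$cohort$cross_correlation,
    noise_sigma = config$cohort$noise_sigma,
    shape = config$cohort$shape, voxel_size = config$cohort$voxel_size,
    cv_within = config$cohort$cv_within, dwi = dwi, dce = dce,
    seed = config$seed)
  ft <- config$fitting
  if (!ft$criterion %in% c("youden", "accuracy"))
    stop("fitting$criterion must be 'youden' or 'accuracy'")
  if (ft$alpha <= 0 || ft$alpha >= 1) stop("fitting$alpha must lie in (0,1)")
  invisible(list(spec = spec, fitting = ft))
}

# internal: md5 of an in-memory object via a temp file
checksum_ <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full pipeline: simulate, fit, summarize, analyze
#'
#' Simulates the cohort, fits IVIM and extended-Tofts maps per subject,
#' builds the per-subject table, runs the cohort statistics, and returns
#' a manifest (seed, counts, per-stage checksums) that makes reruns
#' verifiable: the same config yields bit-identical results.
#'
#' @param config A `pipeline_config` (see [default_config()],
#'   [load_config()]).
#' @param out_dir Optional directory; when given, the cohort table CSV,
#'   the report JSON, ROC curve CSVs and the manifest are written there.
#' @param verbose Print stage progress and voxel-exclusion counts.
#' @return List of class `pipeline_result`: `table`, `report`,
#'   `exclusions`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         verbose = TRUE) {
  parts <- validate_config(config)
  say <- function(...) if (verbose) message(...)
  say("stage 1/3: simulating cohort (",
      parts$spec$n_low, " low + ", parts$spec$n_high, " high)")
  cohort <- tryCatch(simulate_cohort(parts$spec),
                     error = function(e)
                       stop("stage simulate_cohort failed: ",
                            conditionMessage(e)))
  say("stage 2/3: voxel-wise IVIM + extended-Tofts fitting")
  fits <- tryCatch(
    fit_cohort(cohort, snr_k = parts$fitting$snr_k,
               b_threshold = parts$fitting$b_threshold,
               min_volume = parts$fitting$min_volume, verbose = verbose),
    error = function(e) stop("stage fit_cohort failed: ",
                             conditionMessage(e)))
  say("stage 3/3: cohort statistics")
  report <- tryCatch(
    analyze_cohort(fits$table, criterion = parts$fitting$criterion,
                   alpha = parts$fitting$alpha),
    error = function(e) stop("stage analyze_cohort failed: ",
                             conditionMessage(e)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ivimdce")),
    seed = config$seed,
    n_subjects = nrow(fits$table),
    excluded_subjects = fits$excluded,
    checksums = list(truth = checksum_(cohort$truth),
                     table = checksum_(fits$table),
                     report = checksum_(report)))
  res <- structure(list(table = fits$table, report = report,
                        exclusions = fits$exclusions, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_table(fits$table, file.path(out_dir, "cohort_table.csv"))
    jsonlite::write_json(report_to_list_(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    roc_long <- do.call(rbind, lapply(names(report$roc), function(p)
      cbind(parameter = p, report$roc[[p]]$curve)))
    utils::write.csv(roc_long, file.path(out_dir, "roc_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(report$correlations,
                     file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

# internal: flatten a cohort_report into JSON-friendly lists
report_to_list_ <- function(report) {
  list(
    counts = as.list(report$counts),
    t_tests = report$t_tests,
    roc = lapply(report$roc, function(r)
      r[c("auc", "optimal_cutoff", "sens", "spec", "sens_ci", "spec_ci",
          "lr_pos", "lr_neg", "lr_pos_ci", "lr_neg_ci", "direction")]),
    auc_comparisons = report$auc_comparisons,
    stepwise = report$stepwise[c("selected", "order", "coefficients",
                                 "wald_p", "deviance", "separation")],
    correlations = report$correlations)
}
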