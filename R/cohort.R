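#' Reference two-group cohort parameter distributions
#'
#' Per-stage-group means and standard deviations of the subject-level
#' (ROI-mean) parameters, matching published low-stage (AJCC I+II) versus
#' high-stage (III+IV) nasopharyngeal carcinoma values: D, f, D* lower in
#' the high-stage group, Ktrans and vp lower, ve higher. Units: D and D*
#' in mm^2/s, Ktrans and kep in 1/min, f/ve/vp dimensionless. The kep
#' entries are informational only: subject-level kep is always derived as
#' Ktrans/ve, never drawn.
#'
#' @return Nested named list `list(low = ..., high = ...)`, each entry a
#'   list of `c(mean, sd)` pairs for D, f, Dstar, Ktrans, kep, ve, vp.
#' @export
npc_group_params <- function() {
  list(
    low = list(D = c(mean = 0.803e-3, sd = 0.188e-3),
               f = c(mean = 0.157, sd = 0.096),
               Dstar = c(mean = 109.853e-3, sd = 63.651e-3),
               Ktrans = c(mean = 0.645, sd = 0.102),
               kep = c(mean = 0.885, sd = 0.213),
               ve = c(mean = 0.555, sd = 0.311),
               vp = c(mean = 0.088, sd = 0.077)),
    high = list(D = c(mean = 0.700e-3, sd = 0.193e-3),
                f = c(mean = 0.130, sd = 0.114),
                Dstar = c(mean = 98.686e-3, sd = 64.372e-3),
                Ktrans = c(mean = 0.511, sd = 0.137),
                kep = c(mean = 0.748, sd = 0.227),
                ve = c(mean = 0.869, sd = 0.631),
                vp = c(mean = 0.065, sd = 0.069)))
}

#' Cohort simulation specification
#'
#' Defines a two-stage-group cohort: subject counts, per-group parameter
#' distributions, the rank correlation induced between the perfusion-
#' related parameters (f, D*, Ktrans, ve, vp) via a Gaussian copula,
#' acquisition noise, phantom geometry and the global seed.
#'
#' @param n_low,n_high Subjects per stage group (defaults 29 and 46).
#' @param group_params As returned by [npc_group_params()].
#' @param cross_correlation Target Spearman correlation among the
#'   perfusion parameters (|rho| < 1; must keep the equicorrelation
#'   matrix positive definite, i.e. > -0.25 for 5 variables).
#' @param noise_sigma Per-acquisition DWI Rician noise scale (signal
#'   units). Default 20 against the default S0 of 1000, i.e. b = 0
#'   SNR 50.
#' @param dce_noise_sigma Gaussian noise scale for the DCE dynamics.
#'   NULL (default) matches the DCE baseline SNR to the DWI b = 0 SNR:
#'   the spoiled-gradient-echo baseline signal is only a few percent of
#'   the equilibrium signal, so reusing the DWI sigma verbatim would put
#'   the dynamics below the noise floor.
#' @param shape,voxel_size Per-subject phantom geometry. The default
#'   8 x 8 x 4 grid keeps a reduced-resolution cohort tractable while
#'   leaving ~60 ROI voxels per subject.
#' @param cv_within Within-tumor heterogeneity (log-normal CV).
#' @param dwi,dce Acquisition schemes.
#' @param seed Global integer seed; all cohort randomness derives from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_low = 29L, n_high = 46L,
                        group_params = npc_group_params(),
                        cross_correlation = 0, noise_sigma = 20,
                        dce_noise_sigma = NULL,
                        shape = c(8L, 8L, 4L), voxel_size = c(1.8, 1.8, 3.3),
                        cv_within = 0.1, dwi = dwi_scheme(),
                        dce = dce_scheme(), seed = 1L) {
  if (n_low < 1L || n_high < 1L) stop("group counts must be positive")
  if (abs(cross_correlation) >= 1) stop("|cross_correlation| must be < 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(dce_noise_sigma) && dce_noise_sigma < 0)
    stop("dce_noise_sigma must be >= 0")
  for (g in c("low", "high")) {
    gp <- group_params[[g]]
    need <- c("D", "f", "Dstar", "Ktrans", "ve", "vp")
    miss <- setdiff(need, names(gp))
    if (length(miss))
      stop("group_params$", g, " missing: ", paste(miss, collapse = ", "))
    if (gp$D[["mean"]] <= 0) stop("group mean D must be > 0")
    if (gp$Dstar[["mean"]] <= gp$D[["mean"]])
      stop("group mean Dstar must exceed mean D")
    if (gp$f[["mean"]] < 0 || gp$f[["mean"]] >= 1)
      stop("group mean f must lie in [0, 1)")
    if (gp$ve[["mean"]] <= 0) stop("group mean ve must be > 0")
    if (gp$vp[["mean"]] < 0) stop("group mean vp must be >= 0")
    if (gp$Ktrans[["mean"]] < 0) stop("group mean Ktrans must be >= 0")
  }
  structure(list(n_low = as.integer(n_low), n_high = as.integer(n_high),
                 group_params = group_params,
                 cross_correlation = cross_correlation,
                 noise_sigma = noise_sigma,
                 dce_noise_sigma = dce_noise_sigma,
                 shape = as.integer(shape),
                 voxel_size = voxel_size, cv_within = cv_within,
                 dwi = dwi, dce = dce, seed = as.integer(seed)),
            class = "cohort_spec")
}

# internal: truncate drawn subject-level parameters to physical ranges
truncate_params_ <- function(p) {
  p$D <- pmin(pmax(p$D, 0.05e-3), 3e-3)
  p$f <- pmin(pmax(p$f, 0.04), 0.6)
  p$Dstar <- pmin(pmax(p$Dstar, 10 * p$D), 0.4)
  p$Ktrans <- pmin(pmax(p$Ktrans, 0.01), 3)
  p$ve <- pmin(pmax(p$ve, 0.2), 0.95)
  p$vp <- pmin(pmax(p$vp, 0.002), 0.3)
  over <- p$ve + p$vp > 0.97
  p$vp[over] <- 0.97 - p$ve[over]
  p
}

# internal: draw n subjects' true ROI-mean parameters for one group.
# Gaussian copula with equicorrelation r = 2 sin(pi * rho_s / 6) among
# {f, Dstar, Ktrans, ve, vp} so the induced Spearman correlation equals
# the requested cross_correlation; D stays independent.
sample_group_params_ <- function(n, gp, cross_correlation) {
  vars <- c("D", "f", "Dstar", "Ktrans", "ve", "vp")
  r <- 2 * sin(pi * cross_correlation / 6)
  corr_vars <- c("f", "Dstar", "Ktrans", "ve", "vp")
  Sigma <- diag(length(vars))
  dimnames(Sigma) <- list(vars, vars)
  for (a in corr_vars) for (b in corr_vars) if (a != b) Sigma[a, b] <- r
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L))
    stop(sprintf(
      "infeasible correlation matrix: cross_correlation = %.3f between pair (%s, %s)",
      cross_correlation, corr_vars[1], corr_vars[2]))
  Z <- matrix(stats::rnorm(n * length(vars)), n) %*% L
  colnames(Z) <- vars
  out <- lapply(vars, function(v)
    gp[[v]][["mean"]] + gp[[v]][["sd"]] * Z[, v])
  names(out) <- vars
  truncate_params_(as.data.frame(out))
}

#' Simulate a two-stage-group cohort
#'
#' Draws per-subject true ROI-mean parameters from the group
#' distributions (Gaussian copula with the requested cross-parameter
#' rank correlation, then truncation to valid ranges), assigns AJCC
#' stages within each group, and optionally simulates the full per-
#' subject acquisitions (phantom + DWI + DCE + ROI mask). Deterministic
#' given `spec$seed`; every stage uses a derived sub-seed.
#'
#' @param spec A [cohort_spec()].
#' @param simulate_images If FALSE, only the ground-truth subject table
#'   is produced (fast path for statistical simulations).
#' @return List of class `cohort`: `truth` (data.frame with subject_id,
#'   stage_group, ajcc_stage and true_* parameter columns, kep derived
#'   as Ktrans/ve) and `subjects` (list of per-subject `truth`
#'   phantom, `dwi`, `dce`; NULL when `simulate_images = FALSE`),
#'   plus the `spec`.
#' @export
simulate_cohort <- function(spec, simulate_images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_low + spec$n_high
  truth <- with_seed_(spec$seed, {
    low <- sample_group_params_(spec$n_low, spec$group_params$low,
                                spec$cross_correlation)
    high <- sample_group_params_(spec$n_high, spec$group_params$high,
                                 spec$cross_correlation)
    # stage assignment within groups follows the reference cohort mix
    st_low <- sample(c("I", "II"), spec$n_low, replace = TRUE,
                     prob = c(7, 22))
    st_high <- sample(c("III", "IV"), spec$n_high, replace = TRUE,
                      prob = c(29, 17))
    df <- rbind(cbind(stage_group = "low", ajcc_stage = st_low, low),
                cbind(stage_group = "high", ajcc_stage = st_high, high))
    df
  })
  truth$kep <- truth$Ktrans / truth$ve
  truth <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), truth,
                      stringsAsFactors = FALSE)
  names(truth)[names(truth) %in%
                 c("D", "f", "Dstar", "Ktrans", "ve", "vp", "kep")] <-
    paste0("true_", c("D", "f", "Dstar", "Ktrans", "ve", "vp", "kep"))

  subjects <- NULL
  if (simulate_images) {
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      sseed <- derive_seed_(spec$seed, i)
      roi_par <- list(D = truth$true_D[i], f = truth$true_f[i],
                      Dstar = truth$true_Dstar[i],
                      Ktrans = truth$true_Ktrans[i],
                      ve = truth$true_ve[i], vp = truth$true_vp[i],
                      T10 = 1000, S0 = 1000)
      ph <- generate_phantom(roi_par, shape = spec$shape,
                             voxel_size = spec$voxel_size,
                             cv = spec$cv_within, seed = sseed)
      dwi <- simulate_dwi(ph, spec$dwi, spec$noise_sigma,
                          seed = derive_seed_(sseed, 1L))
      dce_sigma <- spec$dce_noise_sigma
      if (is.null(dce_sigma)) {
        # match baseline dynamic SNR to the DWI b=0 SNR (S0 / noise_sigma)
        base_sig <- spgr_signal(1000, 1000, spec$dce$TR, spec$dce$flip_dyn)
        dce_sigma <- if (spec$noise_sigma > 0)
          base_sig / (1000 / spec$noise_sigma) else 0
      }
      dce <- simulate_dce(ph, spec$dce, noise_sigma = dce_sigma,
                          seed = derive_seed_(sseed, 2L))
      subjects[[i]] <- list(subject_id = truth$subject_id[i],
                            truth = ph, dwi = dwi, dce = dce)
    }
  }
  structure(list(truth = truth, subjects = subjects, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d low-stage + %d high-stage subjects (images: %s)\n",
              x$spec$n_low, x$spec$n_high,
              if (is.null(x$subjects)) "no" else "yes"))
  invisible(x)
}
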