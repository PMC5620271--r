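#' Spoiled-gradient-echo steady-state signal
#'
#' S = M0 sin(a) (1 - E1) / (1 - E1 cos(a)) with E1 = exp(-TR/T1); the
#' steady-state magnitude of an ideally spoiled gradient-echo (fast
#' field-echo) acquisition.
#'
#' @param M0 Equilibrium magnetization (arbitrary units, > 0). Vectorized.
#' @param T1 Longitudinal relaxation time, ms (> 0). Vectorized.
#' @param TR Repetition time, ms (> 0).
#' @param flip_deg Flip angle in degrees, in (0, 90).
#' @return Signal, same shape as the broadcast of M0 and T1.
#' @export
spgr_signal <- function(M0, T1, TR, flip_deg) {
  if (any(M0 <= 0)) stop("M0 must be > 0")
  if (any(T1 <= 0)) stop("T1 must be > 0")
  if (TR <= 0) stop("TR must be > 0")
  if (flip_deg <= 0 || flip_deg >= 90) stop("flip angle must lie in (0, 90)")
  a <- flip_deg * pi / 180
  E1 <- exp(-TR / T1)
  M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

#' Two-point variable-flip-angle T1 estimation
#'
#' Solves the spoiled-gradient-echo equation from two signals acquired at
#' different flip angles (the pre-contrast low-flip scan and the dynamic
#' baseline). Linearizing S/sin(a) = E1 * S/tan(a) + M0 (1 - E1), the
#' slope between the two points gives E1, hence T10 = -TR/log(E1), and
#' the intercept gives M0. Vectorized over voxels.
#'
#' @param S_pre Signal at `flip_pre` (> 0).
#' @param S_dyn_baseline Baseline dynamic signal at `flip_dyn` (> 0).
#' @param TR Repetition time, ms.
#' @param flip_pre,flip_dyn Flip angles in degrees.
#' @return List of class `t1_fit`: `T10` (ms), `M0`, and `valid` (FALSE
#'   where the implied E1 falls outside (0, 1), i.e. no physical T1).
#' @export
vfa_t1 <- function(S_pre, S_dyn_baseline, TR, flip_pre, flip_dyn) {
  if (flip_pre == flip_dyn) stop("flip angles must differ")
  a1 <- flip_pre * pi / 180; a2 <- flip_dyn * pi / 180
  bad_in <- !(S_pre > 0) | !(S_dyn_baseline > 0)
  x1 <- S_pre / tan(a1); y1 <- S_pre / sin(a1)
  x2 <- S_dyn_baseline / tan(a2); y2 <- S_dyn_baseline / sin(a2)
  E1 <- (y2 - y1) / (x2 - x1)
  valid <- !bad_in & is.finite(E1) & E1 > 0 & E1 < 1
  T10 <- ifelse(valid, -TR / log(E1), NA_real_)
  M0 <- ifelse(valid, (y1 - E1 * x1) / (1 - E1), NA_real_)
  valid <- valid & is.finite(M0) & M0 > 0
  T10[!valid] <- NA_real_; M0[!valid] <- NA_real_
  structure(list(T10 = T10, M0 = M0, valid = valid), class = "t1_fit")
}

#' Convert a dynamic signal series to contrast concentration
#'
#' Inverts the spoiled-gradient-echo equation per time point (reusing the
#' pre-contrast M0) to the instantaneous T1(t), then applies the linear
#' relation between concentration and relaxation rate:
#' Ct(t) = (1/T1(t) - 1/T10) / r1 (relaxation rates in 1/s). With T10
#' estimated from the baseline mean signal, the baseline concentration is
#' zero by construction.
#'
#' @param dyn Numeric vector, dynamic signal of one voxel over time.
#' @param t1fit A single-voxel [vfa_t1()] result (scalar T10/M0).
#' @param TR Repetition time, ms.
#' @param flip_deg Dynamic flip angle, degrees.
#' @param r1 Relaxivity, 1/(mM s).
#' @param baseline_dynamics Number of pre-injection dynamics (default 7,
#'   injection at the 8th).
#' @return List: `ct` (mM, NA at invalid time points), `valid` (voxel
#'   validity: T1 fit valid and <= 20% invalid time points),
#'   `frac_invalid`.
#' @export
signal_to_concentration <- function(dyn, t1fit, TR, flip_deg, r1,
                                    baseline_dynamics = 7L) {
  if (r1 <= 0) stop("r1 must be > 0")
  if (!isTRUE(t1fit$valid[1]) || !is.finite(t1fit$T10[1]))
    return(list(ct = rep(NA_real_, length(dyn)), valid = FALSE,
                frac_invalid = 1))
  a <- flip_deg * pi / 180
  M0 <- t1fit$M0[1]; T10 <- t1fit$T10[1]
  # S = M0 sin a (1-E1)/(1-E1 cos a)  =>  E1 = (M0 sin a - S)/(M0 sin a - S cos a)
  E1 <- (M0 * sin(a) - dyn) / (M0 * sin(a) - dyn * cos(a))
  ok <- is.finite(E1) & E1 > 0 & E1 < 1
  T1t <- rep(NA_real_, length(dyn))
  T1t[ok] <- -TR / log(E1[ok])
  ct <- (1000 / T1t - 1000 / T10) / r1  # rates ms^-1 -> s^-1
  frac_invalid <- mean(!ok)
  list(ct = ct, valid = frac_invalid <= 0.2, frac_invalid = frac_invalid)
}

# internal: precompute the upsampled convolution grid for an AIF.
# Requires a (near-)uniform acquisition grid; the fine grid subdivides each
# dt into `upsample` steps and carries linearly interpolated Cp.
tofts_grid_ <- function(aif, upsample = 10L) {
  times <- aif$time
  n <- length(times)
  if (n < 2L) stop("AIF needs at least 2 time points")
  if (any(diff(times) <= 0)) stop("times must be monotone increasing")
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("extended-Tofts convolution requires a uniform time grid")
  up <- as.integer(upsample)
  h <- dt[1] / up
  fine_t <- times[1] + h * (0:((n - 1) * up))
  cp_fine <- stats::approx(times, aif$cp, xout = fine_t, rule = 2)$y
  list(h = h, cp_fine = cp_fine, coarse_idx = 1L + (0:(n - 1)) * up,
       times = times)
}

# internal: trapezoidal convolution of cp_fine with exp(-kep_s * t) on the
# uniform fine grid via the exact recursion I_i = E I_{i-1} + h/2 (cp_i + E cp_{i-1})
exp_conv_ <- function(grid, kep_s) {
  E <- exp(-kep_s * grid$h)
  cp <- grid$cp_fine
  n <- length(cp)
  z <- c(0, grid$h / 2 * (cp[-1] + E * cp[-n]))
  as.numeric(stats::filter(z, E, method = "recursive"))
}

#' Extended-Tofts forward model
#'
#' Tissue concentration Ct(t) = vp Cp(t) +
#' Ktrans integral_0^t Cp(tau) exp(-kep (t - tau)) dtau, with
#' kep = Ktrans/ve. Rate constants are given in 1/min (the reporting
#' unit) and converted internally to 1/s to match the time grid in
#' seconds. The convolution uses trapezoidal quadrature on a 10x
#' upsampled uniform grid.
#'
#' @param Ktrans Volume transfer constant, 1/min (>= 0).
#' @param ve Extravascular-extracellular volume fraction in (0, 1\].
#' @param vp Plasma volume fraction in \[0, 1).
#' @param aif An [aif()] object (time s, cp mM) on a uniform grid.
#' @param upsample Internal upsampling factor for the convolution.
#' @param grid Optional precomputed grid (internal use, for repeated fits
#'   against the same AIF).
#' @return Ct in mM on the AIF time grid.
#' @export
extended_tofts_forward <- function(Ktrans, ve, vp, aif = NULL,
                                   upsample = 10L, grid = NULL) {
  if (Ktrans < 0) stop("Ktrans must be >= 0")
  if (ve <= 0 || ve > 1) stop("ve must lie in (0, 1]")
  if (vp < 0 || vp >= 1) stop("vp must lie in [0, 1)")
  if (is.null(grid)) grid <- tofts_grid_(aif, upsample)
  cp_coarse <- grid$cp_fine[grid$coarse_idx]
  if (Ktrans == 0) return(vp * cp_coarse)
  kep_s <- (Ktrans / ve) / 60
  conv <- exp_conv_(grid, kep_s)[grid$coarse_idx]
  vp * cp_coarse + (Ktrans / 60) * conv
}

#' Fit the extended-Tofts model to a concentration curve
#'
#' Bounded Levenberg-Marquardt least squares for (Ktrans, ve, vp);
#' kep is reported as Ktrans/ve. Curves with no enhancement (all-zero
#' concentration) are excluded as unphysiological rather than fitted.
#'
#' @param ct Tissue concentration over time, mM (NAs at invalid time
#'   points are dropped from the residual).
#' @param aif An [aif()] on the same uniform time grid.
#' @param lower,upper Bounds for (Ktrans \[1/min\], ve, vp).
#' @param init Start values for (Ktrans, ve, vp).
#' @param upsample Convolution upsampling factor.
#' @param grid Optional precomputed [tofts_grid_] (internal).
#' @return List of class `tofts_params`: Ktrans, kep, ve, vp, rss,
#'   converged, valid.
#' @export
fit_extended_tofts <- function(ct, aif = NULL,
                               lower = c(0, 1e-3, 0),
                               upper = c(5, 1, 0.5),
                               init = c(0.3, 0.3, 0.05),
                               upsample = 10L, grid = NULL) {
  if (is.null(grid)) grid <- tofts_grid_(aif, upsample)
  use <- is.finite(ct)
  invalid <- structure(list(Ktrans = NA_real_, kep = NA_real_, ve = NA_real_,
                            vp = NA_real_, rss = NA_real_, converged = FALSE,
                            valid = FALSE), class = "tofts_params")
  if (sum(use) < 10L) return(invalid)
  if (max(abs(ct[use])) < 1e-12) return(invalid)  # unphysiological: zero curve
  resid_fn <- function(p) {
    pred <- extended_tofts_forward(p[1], p[2], p[3], grid = grid)
    (ct - pred)[use]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-12, ptol = 1e-12, maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(invalid)
  p <- fit$par
  conv <- fit$info %in% 1:4
  nonzero <- p[1] > 1e-8 || p[3] > 1e-8
  structure(list(Ktrans = p[1], kep = p[1] / p[2], ve = p[2], vp = p[3],
                 rss = sum(fit$fvec^2), converged = conv,
                 valid = conv && nonzero),
            class = "tofts_params")
}

#' Voxel-wise DCE pharmacokinetic mapping
#'
#' Per ROI voxel: two-point VFA T1 fit from the pre-contrast volume and
#' the dynamic baseline, signal-to-concentration conversion, then the
#' extended-Tofts fit. The validity mask records every exclusion (invalid
#' T1, too many invalid concentration points, non-convergence, zero
#' enhancement).
#'
#' @param dce A `dce_series` from [simulate_dce()] (holds the dynamic 4D
#'   array, the pre-contrast volume, its scheme and its AIF).
#' @param roi_mask Logical array; NULL fits every voxel.
#' @param aif Optional [aif()] overriding the one attached to the series.
#' @param upsample Convolution upsampling factor.
#' @param lower,upper,init Passed to [fit_extended_tofts()].
#' @return List of class `tofts_maps`: Ktrans_map, kep_map, ve_map,
#'   vp_map, T10_map, valid_mask, `exclusions` (named counts).
#' @export
fit_dce_map <- function(dce, roi_mask = NULL, aif = NULL, upsample = 10L,
                        lower = c(0, 1e-3, 0), upper = c(5, 1, 0.5),
                        init = c(0.3, 0.3, 0.05)) {
  stopifnot(inherits(dce, "dce_series"))
  scheme <- dce$scheme
  if (is.null(aif)) aif <- dce$aif
  if (is.null(aif)) stop("no AIF attached to the series or supplied")
  shape <- dim(dce$data)[1:3]
  if (dim(dce$data)[4] != scheme$n_dynamics)
    stop("series does not match its scheme")
  if (is.null(roi_mask)) roi_mask <- array(TRUE, shape)
  if (!identical(as.integer(dim(roi_mask)), as.integer(shape)))
    stop("roi_mask does not match series geometry")
  if (!any(roi_mask)) stop("ROI is empty")

  nbase <- scheme$injection_index - 1L
  if (nbase < 1L) stop("need at least one pre-injection dynamic")
  grid <- tofts_grid_(aif, upsample)
  nvox <- prod(shape)
  dyn_mat <- matrix(dce$data, nrow = nvox)
  base_mean <- rowMeans(dyn_mat[, seq_len(nbase), drop = FALSE])
  t1 <- vfa_t1(as.numeric(dce$pre), base_mean, scheme$TR,
               scheme$flip_pre, scheme$flip_dyn)

  mk <- function() array(NA_real_, shape)
  Kt <- mk(); kep <- mk(); ve <- mk(); vp <- mk(); T10 <- mk()
  valid <- array(FALSE, shape)
  excl <- c(t1_invalid = 0L, conc_invalid = 0L, nonconverged = 0L,
            zero_enhancement = 0L)

  for (v in which(roi_mask)) {
    if (!t1$valid[v]) { excl["t1_invalid"] <- excl["t1_invalid"] + 1L; next }
    voxfit <- list(T10 = t1$T10[v], M0 = t1$M0[v], valid = TRUE)
    conc <- signal_to_concentration(dyn_mat[v, ], voxfit, scheme$TR,
                                    scheme$flip_dyn, scheme$r1, nbase)
    if (!conc$valid) { excl["conc_invalid"] <- excl["conc_invalid"] + 1L; next }
    fin <- conc$ct[is.finite(conc$ct)]
    if (length(fin) < 10L || max(abs(fin)) < 1e-12) {
      excl["zero_enhancement"] <- excl["zero_enhancement"] + 1L; next
    }
    ft <- fit_extended_tofts(conc$ct, lower = lower, upper = upper,
                             init = init, grid = grid)
    if (!isTRUE(ft$converged)) {
      excl["nonconverged"] <- excl["nonconverged"] + 1L; next
    }
    if (!isTRUE(ft$valid)) {
      excl["zero_enhancement"] <- excl["zero_enhancement"] + 1L; next
    }
    Kt[v] <- ft$Ktrans; kep[v] <- ft$kep; ve[v] <- ft$ve; vp[v] <- ft$vp
    T10[v] <- t1$T10[v]; valid[v] <- TRUE
  }
  structure(list(Ktrans_map = Kt, kep_map = kep, ve_map = ve, vp_map = vp,
                 T10_map = T10, valid_mask = valid, exclusions = excl),
            class = "tofts_maps")
}
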