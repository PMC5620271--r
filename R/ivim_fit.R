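#' IVIM bi-exponential forward signal model
#'
#' S(b) = S0 * \[(1 - f) exp(-b D) + f exp(-b (D + D*))\]: true molecular
#' diffusion at rate D plus a pseudodiffusion compartment of fraction f
#' decaying at D + D*. Strictly decreasing in b for D, D* > 0 and
#' 0 < f < 1.
#'
#' @param b Diffusion weightings, s/mm^2, non-negative.
#' @param D True diffusion coefficient, mm^2/s (> 0).
#' @param f Perfusion fraction in \[0, 1\].
#' @param Dstar Pseudodiffusion coefficient, mm^2/s (>= 0).
#' @param S0 Signal at b = 0.
#' @return Signal vector, same length as `b`.
#' @export
ivim_forward <- function(b, D, f, Dstar, S0 = 1) {
  if (any(b < 0)) stop("b values must be non-negative")
  if (D <= 0) stop("D must be > 0")
  if (f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (Dstar < 0) stop("Dstar must be >= 0")
  S0 * ((1 - f) * exp(-b * D) + f * exp(-b * (D + Dstar)))
}

#' Mono-exponential diffusion fit on high b-values
#'
#' Estimates D by ordinary least squares of log S(b) on b, restricted to
#' b strictly greater than `b_threshold` where the pseudodiffusion
#' compartment has fully decayed (with the default 13-b-value scheme this
#' uses b = 300, 500, 1000 s/mm^2).
#'
#' @param signals Signal vector matched to `b_values`.
#' @param b_values Diffusion weightings, s/mm^2.
#' @param b_threshold Only b > b_threshold enter the fit (strict).
#' @return List with `D` (= minus the slope), `log_intercept` (fitted
#'   log-signal at b = 0) and `valid` (FALSE when a used signal is
#'   non-positive, making the log undefined).
#' @export
fit_high_b_mono <- function(signals, b_values, b_threshold = 200) {
  if (length(signals) != length(b_values))
    stop("signals and b_values must have equal length")
  use <- b_values > b_threshold
  if (sum(use) < 2L)
    stop("need at least 2 b-values strictly above b_threshold")
  s <- signals[use]; b <- b_values[use]
  if (any(!is.finite(s)) || any(s <= 0))
    return(list(D = NA_real_, log_intercept = NA_real_, valid = FALSE))
  y <- log(s)
  bm <- mean(b); ym <- mean(y)
  slope <- sum((b - bm) * (y - ym)) / sum((b - bm)^2)
  list(D = -slope, log_intercept = ym - slope * bm, valid = TRUE)
}

#' Perfusion-stage fit of the segmented IVIM model
#'
#' Levenberg-Marquardt least squares over all b-values for (f, D*, S0)
#' with D held fixed at the high-b estimate (classic segmented fit).
#' Bounds: f in \[0, 1\], D* in \[D, Dstar_max\]. Warm start: f0 from the
#' high-b intercept relative to the measured b = 0 signal, clipped to
#' \[0.01, 0.5\]; D*0 = 10 D.
#'
#' @param signals Signal vector over all b-values.
#' @param b_values Diffusion weightings.
#' @param D_fixed Diffusion coefficient from [fit_high_b_mono()] (> 0).
#' @param log_intercept Optional high-b log-intercept used for the f warm
#'   start.
#' @param Dstar_max Upper bound for D*, mm^2/s.
#' @param refine_D If TRUE, D is refined jointly with (f, D*, S0) in the
#'   nonlinear stage instead of staying fixed.
#' @return List of class `ivim_params`: D, f, Dstar, S0, rss, converged.
#' @export
fit_perfusion <- function(signals, b_values, D_fixed, log_intercept = NULL,
                          Dstar_max = 1.0, refine_D = FALSE) {
  if (D_fixed <= 0) stop("D_fixed must be > 0")
  if (any(!is.finite(signals))) stop("signals must be finite")
  s0_obs <- signals[which.min(b_values)]
  f0 <- if (!is.null(log_intercept) && is.finite(log_intercept) && s0_obs > 0)
    1 - exp(log_intercept) / s0_obs else 0.1
  f0 <- min(max(f0, 0.01), 0.5)
  d0 <- min(max(10 * D_fixed, D_fixed * 1.5), Dstar_max)
  start_s0 <- if (s0_obs > 0) s0_obs else max(signals, 1)

  if (refine_D) {
    resid_fn <- function(p)
      signals - ivim_forward(b_values, p[4], p[1], p[2], p[3])
    lower <- c(0, 1e-6, 0, 1e-6)
    upper <- c(1, Dstar_max, Inf, 0.01)
    start <- c(f0, d0, start_s0, D_fixed)
  } else {
    resid_fn <- function(p)
      signals - ivim_forward(b_values, D_fixed, p[1], p[2], p[3])
    lower <- c(0, D_fixed, 0)
    upper <- c(1, Dstar_max, Inf)
    start <- c(f0, max(d0, D_fixed), start_s0)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-12, ptol = 1e-12, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(D = D_fixed, f = NA_real_, Dstar = NA_real_,
                          S0 = NA_real_, rss = NA_real_, converged = FALSE),
                     class = "ivim_params"))
  }
  p <- fit$par
  conv <- fit$info %in% 1:4
  # convergence onto the D* or f upper bound means the perfusion
  # compartment is not identifiable in this voxel: clip and flag
  bound_hit <- p[2] >= Dstar_max * (1 - 1e-6) || p[1] >= 1 - 1e-6
  out <- if (refine_D)
    list(D = p[4], f = p[1], Dstar = p[2], S0 = p[3])
  else
    list(D = D_fixed, f = p[1], Dstar = p[2], S0 = p[3])
  structure(c(out, list(rss = sum(fit$fvec^2),
                        converged = conv && !bound_hit,
                        bound_hit = bound_hit)),
            class = "ivim_params")
}

#' SNR-based voxel validity mask
#'
#' A voxel is kept only when its b = 0 signal sits safely above the
#' background noise floor: S(b=0) >= k * noise_sigma.
#'
#' @param series A `dwi_series` (or a 3D array of b = 0 signal).
#' @param noise_sigma Gaussian noise scale of the underlying complex
#'   channels (> 0), estimated from a signal-free region or supplied.
#' @param k Threshold multiple (default 5).
#' @return Logical array.
#' @export
snr_valid_mask <- function(series, noise_sigma, k = 5) {
  if (noise_sigma <= 0) stop("noise_sigma must be > 0")
  b0 <- if (inherits(series, "dwi_series")) {
    nd <- length(dim(series$data))
    if (nd == 4L) series$data[, , , 1, drop = FALSE][, , , 1] else series$data
  } else series
  b0 >= k * noise_sigma
}

#' Voxel-wise segmented IVIM fitting over an ROI
#'
#' Applies the SNR filter, then the two-stage segmented fit per voxel:
#' log-linear D on high b, then Levenberg-Marquardt (f, D*) over all b.
#' The validity mask is the conjunction of SNR pass, positive usable
#' signals, D > 0, and convergence.
#'
#' @param series A `dwi_series` from [simulate_dwi()] or [read_dwi_series()].
#' @param roi_mask Logical array; NULL fits every voxel.
#' @param noise_sigma Noise scale for the SNR filter; 0 disables it
#'   (noiseless data).
#' @param snr_k SNR threshold multiple.
#' @param b_threshold High-b cut for the mono-exponential stage (strict >).
#' @param Dstar_max Upper bound for D*.
#' @param refine_D Passed to [fit_perfusion()].
#' @return List of class `ivim_maps`: D_map, f_map, Dstar_map, S0_map,
#'   valid_mask, and `exclusions` (named counts per filter stage).
#' @export
fit_ivim_map <- function(series, roi_mask = NULL, noise_sigma = 0,
                         snr_k = 5, b_threshold = 200, Dstar_max = 1.0,
                         refine_D = FALSE) {
  stopifnot(inherits(series, "dwi_series"))
  dat <- series$data
  shape <- dim(dat)[1:3]
  b_values <- series$scheme$b_values
  if (dim(dat)[4] != length(b_values))
    stop("series does not match its b-value scheme")
  if (is.null(roi_mask)) roi_mask <- array(TRUE, shape)
  if (!identical(as.integer(dim(roi_mask)), as.integer(shape)))
    stop("roi_mask does not match series geometry")
  if (!any(roi_mask)) stop("ROI is empty")

  snr_pass <- if (noise_sigma > 0)
    snr_valid_mask(series, noise_sigma, snr_k) else array(TRUE, shape)
  cand <- which(roi_mask & snr_pass)
  excl <- c(snr = sum(roi_mask) - length(cand), log_invalid = 0L,
            nonpositive_D = 0L, nonconverged = 0L)

  mk <- function() array(NA_real_, shape)
  D_map <- mk(); f_map <- mk(); Ds_map <- mk(); S0_map <- mk()
  valid <- array(FALSE, shape)
  sig_mat <- matrix(dat, nrow = prod(shape))

  for (v in cand) {
    sig <- sig_mat[v, ]
    hb <- fit_high_b_mono(sig, b_values, b_threshold)
    if (!hb$valid) { excl["log_invalid"] <- excl["log_invalid"] + 1L; next }
    if (!is.finite(hb$D) || hb$D <= 0) {
      excl["nonpositive_D"] <- excl["nonpositive_D"] + 1L; next
    }
    pf <- fit_perfusion(sig, b_values, hb$D, hb$log_intercept,
                        Dstar_max = Dstar_max, refine_D = refine_D)
    if (!isTRUE(pf$converged)) {
      excl["nonconverged"] <- excl["nonconverged"] + 1L; next
    }
    D_map[v] <- pf$D; f_map[v] <- pf$f; Ds_map[v] <- pf$Dstar
    S0_map[v] <- pf$S0; valid[v] <- TRUE
  }
  structure(list(D_map = D_map, f_map = f_map, Dstar_map = Ds_map,
                 S0_map = S0_map, valid_mask = valid, exclusions = excl),
            class = "ivim_maps")
}
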