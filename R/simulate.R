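#' Add Rician noise to a magnitude image
#'
#' Magnitude MRI noise model: the noiseless signal is perturbed in two
#' quadrature channels by independent Gaussian noise of scale `sigma` and
#' the magnitude taken, sqrt((S + n1)^2 + n2^2). In background (S = 0)
#' this yields a Rayleigh floor with mean sigma * sqrt(pi/2).
#'
#' @param S Noiseless signal (any shape).
#' @param sigma Noise scale (>= 0); 0 returns `S` unchanged.
#' @return Noisy magnitude, same shape as `S`.
#' @export
add_rician_noise <- function(S, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(S)
  n <- length(S)
  out <- sqrt((S + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(S))) dim(out) <- dim(S)
  out
}

#' Simulate a multi-b-value DWI acquisition from a phantom
#'
#' Per voxel, the signal at each b-value follows the IVIM bi-exponential
#' forward model ([ivim_forward()]), corrupted by Rician noise of scale
#' `noise_sigma` (the magnitude noise model standard for diffusion MRI).
#' The protocol acquires `scheme$n_averages` magnitude images per b-value
#' (the three orthogonal diffusion directions, isotropic here) and
#' averages them, so the emitted series carries an effective noise scale
#' of roughly `noise_sigma / sqrt(n_averages)` while `noise_sigma` is the
#' per-acquisition scale quoted for SNR. `noise_sigma = 0` returns the
#' exact forward model. Deterministic given `seed`.
#'
#' @param truth A [phantom_truth()].
#' @param scheme A [dwi_scheme()].
#' @param noise_sigma Per-acquisition Rician noise scale in signal units
#'   (>= 0).
#' @param seed Integer seed.
#' @return Object of class `dwi_series`: `data` (4D array x,y,z,b),
#'   `scheme`, `voxel_size`, `noise_sigma`.
#' @export
simulate_dwi <- function(truth, scheme = dwi_scheme(), noise_sigma = 0,
                         seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(scheme, "dwi_scheme"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  b <- scheme$b_values
  shape <- truth$shape
  nvox <- prod(shape)
  D <- as.numeric(truth$D_map); f <- as.numeric(truth$f_map)
  Ds <- as.numeric(truth$Dstar_map); S0 <- as.numeric(truth$S0_map)
  sig <- matrix(0, nvox, length(b))
  for (i in seq_along(b))
    sig[, i] <- S0 * ((1 - f) * exp(-b[i] * D) + f * exp(-b[i] * (D + Ds)))
  dat <- array(sig, c(shape, length(b)))
  if (noise_sigma > 0) {
    dat <- with_seed_(seed, {
      acc <- add_rician_noise(dat, noise_sigma)
      if (scheme$n_averages > 1L)
        for (r in seq_len(scheme$n_averages - 1L))
          acc <- acc + add_rician_noise(dat, noise_sigma)
      acc / scheme$n_averages
    })
  }
  structure(list(data = dat, scheme = scheme, voxel_size = truth$voxel_size,
                 noise_sigma = noise_sigma),
            class = "dwi_series")
}

#' Simulate a DCE acquisition plus pre-contrast volume from a phantom
#'
#' Per voxel: tissue concentration from the extended-Tofts forward model
#' driven by the AIF; instantaneous relaxation rate
#' 1/T1(t) = 1/T10 + r1 Ct(t); dynamic signal from the spoiled-gradient-
#' echo equation at `flip_dyn`; and a separate pre-contrast volume at
#' `flip_pre`. Gaussian noise of scale `noise_sigma` is added to both
#' (enhanced DCE signals are high-SNR, where the Gaussian approximation
#' to magnitude noise is accurate and keeps the inversion unbiased);
#' `noise_sigma = 0` is exact.
#'
#' @param truth A [phantom_truth()].
#' @param scheme A [dce_scheme()].
#' @param aif An [aif()]; defaults to [population_aif()] of the scheme.
#' @param noise_sigma Gaussian noise scale in signal units (>= 0).
#' @param seed Integer seed.
#' @return Object of class `dce_series`: `data` (4D x,y,z,t), `pre`
#'   (3D volume at `flip_pre`), `scheme`, `aif`, `voxel_size`,
#'   `noise_sigma`.
#' @export
simulate_dce <- function(truth, scheme = dce_scheme(), aif = NULL,
                         noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(scheme, "dce_scheme"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(aif)) aif <- population_aif(scheme)
  if (nrow(aif) != scheme$n_dynamics)
    stop("AIF grid does not match the scheme's dynamics")
  if (any(truth$T10_map <= 0)) stop("nonphysical T10 in phantom")
  shape <- truth$shape
  nvox <- prod(shape)
  grid <- tofts_grid_(aif)
  Kt <- as.numeric(truth$Ktrans_map); ve <- as.numeric(truth$ve_map)
  vp <- as.numeric(truth$vp_map); T10 <- as.numeric(truth$T10_map)
  M0 <- as.numeric(truth$S0_map)
  a <- scheme$flip_dyn * pi / 180
  dyn <- matrix(0, nvox, scheme$n_dynamics)
  for (v in seq_len(nvox)) {
    ct <- extended_tofts_forward(Kt[v], max(ve[v], 1e-3), vp[v], grid = grid)
    R1t <- 1000 / T10[v] + scheme$r1 * ct      # 1/s
    E1 <- exp(-scheme$TR / (1000 / R1t))       # TR ms, T1(t) ms
    dyn[v, ] <- M0[v] * sin(a) * (1 - E1) / (1 - E1 * cos(a))
  }
  pre <- spgr_signal(M0, T10, scheme$TR, scheme$flip_pre)
  if (noise_sigma > 0) {
    with_seed_(seed, {
      dyn <- dyn + stats::rnorm(length(dyn), 0, noise_sigma)
      pre <- pre + stats::rnorm(length(pre), 0, noise_sigma)
    })
  }
  structure(list(data = array(dyn, c(shape, scheme$n_dynamics)),
                 pre = array(pre, shape), scheme = scheme, aif = aif,
                 voxel_size = truth$voxel_size, noise_sigma = noise_sigma),
            class = "dce_series")
}
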