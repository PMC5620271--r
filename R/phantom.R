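#' Ground-truth phantom container
#'
#' Holds per-voxel ground-truth maps for a digital phantom: the IVIM
#' triplet (D, f, D*), the extended-Tofts triplet (Ktrans, ve, vp), the
#' pre-contrast relaxation time T10 and the equilibrium signal S0, plus an
#' ROI ("tumor") mask and the voxel geometry. The reflux constant kep is
#' never stored; it is derived as Ktrans/ve wherever needed.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_size Numeric length 3, mm per axis.
#' @param D_map True diffusion coefficient, mm^2/s (> 0).
#' @param f_map Perfusion fraction, dimensionless in \[0, 1).
#' @param Dstar_map Pseudodiffusion coefficient, mm^2/s (> D).
#' @param Ktrans_map Volume transfer constant, 1/min (>= 0).
#' @param ve_map Extravascular-extracellular volume fraction in \[0, 1\].
#' @param vp_map Plasma volume fraction in \[0, 1\]; ve + vp <= 1.
#' @param T10_map Pre-contrast T1, ms (> 0).
#' @param S0_map Equilibrium signal, arbitrary units (> 0).
#' @param roi_mask Logical array marking the tumor ROI.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(shape, voxel_size, D_map, f_map, Dstar_map,
                          Ktrans_map, ve_map, vp_map, T10_map, S0_map,
                          roi_mask) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers")
  maps <- list(D_map = D_map, f_map = f_map, Dstar_map = Dstar_map,
               Ktrans_map = Ktrans_map, ve_map = ve_map, vp_map = vp_map,
               T10_map = T10_map, S0_map = S0_map, roi_mask = roi_mask)
  for (nm in names(maps)) {
    if (!identical(dim(maps[[nm]]), shape) &&
        !identical(as.integer(dim(maps[[nm]])), shape))
      stop(sprintf("map '%s' does not share shape with the phantom", nm))
  }
  chk <- function(cond, field, what) {
    if (!all(cond)) stop(sprintf("invalid %s: %s", field, what))
  }
  chk(D_map > 0, "D_map", "D must be > 0")
  chk(f_map >= 0 & f_map < 1, "f_map", "f must lie in [0, 1)")
  chk(Dstar_map > D_map, "Dstar_map", "D* must exceed D")
  chk(Ktrans_map >= 0, "Ktrans_map", "Ktrans must be >= 0")
  chk(ve_map >= 0 & ve_map <= 1, "ve_map", "ve must lie in [0, 1]")
  chk(vp_map >= 0 & vp_map <= 1, "vp_map", "vp must lie in [0, 1]")
  chk(ve_map + vp_map <= 1 + 1e-9, "ve_map/vp_map", "ve + vp must be <= 1")
  chk(T10_map > 0, "T10_map", "T10 must be > 0")
  chk(S0_map > 0, "S0_map", "S0 must be > 0")
  if (!is.logical(roi_mask)) stop("invalid roi_mask: must be logical")
  structure(c(list(shape = shape, voxel_size = as.numeric(voxel_size)),
              maps),
            class = "phantom_truth")
}

#' Default tissue parameter sets
#'
#' `npc_tumor_params()` returns nasopharyngeal-carcinoma-like voxel
#' parameters (low-stage group means of the reference cohort);
#' `background_tissue_params()` returns head-and-neck background tissue
#' with low perfusion and weak enhancement.
#'
#' @return Named list with elements D, f, Dstar, Ktrans, ve, vp, T10, S0.
#' @export
npc_tumor_params <- function() {
  list(D = 0.803e-3, f = 0.157, Dstar = 109.853e-3,
       Ktrans = 0.645, ve = 0.555, vp = 0.088,
       T10 = 1000, S0 = 1000)
}

#' @rdname npc_tumor_params
#' @export
background_tissue_params <- function() {
  list(D = 1.3e-3, f = 0.05, Dstar = 25e-3,
       Ktrans = 0.05, ve = 0.12, vp = 0.02,
       T10 = 900, S0 = 800)
}

# internal: ellipsoidal mask centred in the grid with semi-axes frac*shape/2
ellipsoid_mask_ <- function(shape, frac = 0.6) {
  ctr <- (shape + 1) / 2
  semi <- pmax(frac * shape / 2, 0.5)
  ii <- slice.index(array(0, shape), 1)
  jj <- slice.index(array(0, shape), 2)
  kk <- slice.index(array(0, shape), 3)
  ((ii - ctr[1]) / semi[1])^2 + ((jj - ctr[2]) / semi[2])^2 +
    ((kk - ctr[3]) / semi[3])^2 <= 1
}

# internal: lognormal field with given mean and coefficient of variation
lognormal_field_ <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a digital phantom with an ellipsoidal tumor ROI
#'
#' Embeds an ellipsoidal "tumor" in background tissue. Voxel values inside
#' each compartment are drawn log-normally around the compartment means
#' with coefficient of variation `cv` (within-tumor heterogeneity), then
#' truncated so the `phantom_truth` invariants hold. `cv = 0` gives exact
#' homogeneous compartments. Deterministic given `seed`.
#'
#' @param roi_params,bg_params Named lists as returned by
#'   [npc_tumor_params()] / [background_tissue_params()].
#' @param shape Grid size, voxels per axis.
#' @param voxel_size Voxel edge lengths in mm.
#' @param cv Within-compartment coefficient of variation (default 10%).
#' @param roi_frac ROI ellipsoid semi-axes as a fraction of the half-grid.
#' @param seed Integer seed.
#' @return A [phantom_truth()] object.
#' @export
generate_phantom <- function(roi_params = npc_tumor_params(),
                             bg_params = background_tissue_params(),
                             shape = c(16L, 16L, 8L),
                             voxel_size = c(1.8, 1.8, 3.3),
                             cv = 0.1, roi_frac = 0.6, seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("shape must be positive")
  req <- c("D", "f", "Dstar", "Ktrans", "ve", "vp", "T10", "S0")
  for (p in list(roi_params, bg_params)) {
    miss <- setdiff(req, names(p))
    if (length(miss))
      stop("parameter set is missing field(s): ", paste(miss, collapse = ", "))
    if (p$D <= 0) stop("invalid D: must be > 0")
    if (p$f < 0 || p$f >= 1) stop("invalid f: must lie in [0, 1)")
    if (p$Dstar <= p$D) stop("invalid Dstar: must exceed D")
    if (p$Ktrans < 0) stop("invalid Ktrans: must be >= 0")
    if (p$ve < 0 || p$ve > 1) stop("invalid ve: must lie in [0, 1]")
    if (p$vp < 0 || p$vp > 1) stop("invalid vp: must lie in [0, 1]")
    if (p$ve + p$vp > 1) stop("invalid ve/vp: ve + vp must be <= 1")
    if (p$T10 <= 0) stop("invalid T10: must be > 0")
    if (p$S0 <= 0) stop("invalid S0: must be > 0")
  }
  roi <- ellipsoid_mask_(shape, roi_frac)
  n <- prod(shape)
  with_seed_(seed, {
    draw <- function(field) {
      v <- numeric(n)
      v[!roi] <- lognormal_field_(sum(!roi), bg_params[[field]], cv)
      v[roi] <- lognormal_field_(sum(roi), roi_params[[field]], cv)
      array(v, shape)
    }
    D <- pmax(draw("D"), 1e-5)
    f <- pmin(pmax(draw("f"), 0), 0.95)
    Dstar <- pmax(draw("Dstar"), 1.5 * D)
    Ktrans <- pmax(draw("Ktrans"), 0)
    ve <- pmin(pmax(draw("ve"), 1e-3), 0.95)
    vp <- pmin(pmax(draw("vp"), 0), 0.4)
    over <- ve + vp > 0.99
    vp[over] <- 0.99 - ve[over]
    T10 <- pmax(draw("T10"), 50)
    S0 <- pmax(draw("S0"), 1e-3)
    phantom_truth(shape, voxel_size, D, f, Dstar, Ktrans, ve, vp,
                  T10, S0, roi)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s voxels (%s mm), %d ROI voxels\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              sum(x$roi_mask)))
  invisible(x)
}
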