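#' Diffusion-weighted acquisition scheme
#'
#' Describes a multi-b-value DWI acquisition. The default is the 13-b-value
#' protocol used for nasopharyngeal carcinoma IVIM imaging at 3 T:
#' b = 0, 10, 20, 30, 40, 60, 100, 120, 160, 200, 300, 500, 1000 s/mm^2,
#' with three orthogonal diffusion directions averaged into one series.
#'
#' @param b_values Numeric vector of diffusion weightings in s/mm^2;
#'   must be strictly increasing and start at 0.
#' @param n_averages Number of signal averages (informational; the simulator
#'   produces the direction-averaged magnitude series directly).
#' @return An object of class `dwi_scheme`.
#' @export
dwi_scheme <- function(b_values = c(0, 10, 20, 30, 40, 60, 100, 120, 160,
                                    200, 300, 500, 1000),
                       n_averages = 3L) {
  if (!is.numeric(b_values) || length(b_values) < 2L)
    stop("b_values must be a numeric vector of length >= 2")
  if (any(!is.finite(b_values)) || any(b_values < 0))
    stop("b_values must be finite and non-negative")
  if (b_values[1L] != 0)
    stop("b_values must start at 0")
  if (any(diff(b_values) <= 0))
    stop("b_values must be strictly increasing")
  if (n_averages < 1L) stop("n_averages must be >= 1")
  structure(list(b_values = as.numeric(b_values),
                 n_averages = as.integer(n_averages)),
            class = "dwi_scheme")
}

#' Dynamic contrast-enhanced acquisition scheme
#'
#' Describes a spoiled-gradient-echo DCE acquisition with a low-flip-angle
#' pre-contrast scan for two-point variable-flip-angle T1 mapping. Defaults
#' follow a 3 T head-and-neck protocol: 65 dynamics, contrast arriving at
#' the 8th dynamic, TR = 4.8 ms, flip angles 5 deg (pre-contrast) and
#' 15 deg (dynamic), ~10 min total scan so dt = 9.2 s per dynamic.
#'
#' @param n_dynamics Number of dynamic acquisitions.
#' @param dt Inter-dynamic interval in seconds.
#' @param injection_index 1-based dynamic at which contrast arrives.
#' @param TR Repetition time in ms.
#' @param flip_pre,flip_dyn Flip angles in degrees; must differ.
#' @param r1 Contrast agent relaxivity in 1/(mM s); default 3.5 for
#'   Gd-DOTA at 3 T.
#' @param dose Contrast dose in mmol/kg.
#' @param hct Hematocrit, used only when converting a measured arterial
#'   blood signal to plasma concentration (the synthetic input function is
#'   generated directly as plasma concentration).
#' @return An object of class `dce_scheme`.
#' @export
dce_scheme <- function(n_dynamics = 65L, dt = 9.2, injection_index = 8L,
                       TR = 4.8, flip_pre = 5, flip_dyn = 15,
                       r1 = 3.5, dose = 0.1, hct = 0.42) {
  n_dynamics <- as.integer(n_dynamics)
  injection_index <- as.integer(injection_index)
  if (n_dynamics < 2L) stop("n_dynamics must be >= 2")
  if (dt <= 0) stop("dt must be positive")
  if (injection_index < 1L || injection_index > n_dynamics)
    stop("injection_index must lie within [1, n_dynamics]")
  if (TR <= 0) stop("TR must be positive")
  if (flip_pre <= 0 || flip_pre >= 90 || flip_dyn <= 0 || flip_dyn >= 90)
    stop("flip angles must lie in (0, 90) degrees")
  if (flip_pre == flip_dyn)
    stop("flip_pre and flip_dyn must differ (two-point T1 mapping)")
  if (r1 <= 0) stop("r1 must be positive")
  if (dose <= 0) stop("dose must be positive")
  if (hct <= 0 || hct >= 1) stop("hct must lie in (0, 1)")
  structure(list(n_dynamics = n_dynamics, dt = dt,
                 injection_index = injection_index, TR = TR,
                 flip_pre = flip_pre, flip_dyn = flip_dyn,
                 r1 = r1, dose = dose, hct = hct),
            class = "dce_scheme")
}

#' Dynamic time grid of a DCE scheme
#'
#' @param scheme A `dce_scheme`.
#' @return Numeric vector of acquisition times in seconds, starting at 0.
#' @export
dce_times <- function(scheme) {
  stopifnot(inherits(scheme, "dce_scheme"))
  (seq_len(scheme$n_dynamics) - 1) * scheme$dt
}

#' @export
print.dwi_scheme <- function(x, ...) {
  cat("DWI scheme:", length(x$b_values), "b-values [",
      paste(x$b_values, collapse = ", "), "] s/mm^2,",
      x$n_averages, "averages\n")
  invisible(x)
}

#' @export
print.dce_scheme <- function(x, ...) {
  cat(sprintf(
    "DCE scheme: %d dynamics, dt = %.2f s, injection at dynamic %d,\n  TR = %.2f ms, flips %g/%g deg, r1 = %.2f /(mM s), dose = %.2f mmol/kg\n",
    x$n_dynamics, x$dt, x$injection_index, x$TR, x$flip_pre, x$flip_dyn,
    x$r1, x$dose))
  invisible(x)
}

# internal: run expr with a temporary RNG state, restoring the caller's
with_seed_ <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# internal: derive a bounded child seed from a parent seed and a stream index
derive_seed_ <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %%
               2147483629)
}
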