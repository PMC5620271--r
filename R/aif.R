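#' Population arterial input function on a dynamic time grid
#'
#' Synthesizes a plasma contrast concentration curve Cp(t) using a
#' Parker-style population bolus: a sum of two Gaussians (first pass and
#' recirculation) plus a sigmoid-modulated exponential washout. The curve
#' is shifted so the bolus arrives at the scheme's `injection_index`
#' dynamic and is exactly zero before it; amplitude scales linearly with
#' dose. Generated directly as plasma concentration (no hematocrit step).
#'
#' @param scheme A [dce_scheme()].
#' @param times Optional time grid in seconds; defaults to the scheme's
#'   dynamic grid.
#' @return An object of class `aif`: data.frame with columns `time` (s)
#'   and `cp` (mM).
#' @export
population_aif <- function(scheme, times = NULL) {
  stopifnot(inherits(scheme, "dce_scheme"))
  if (is.null(times)) times <- dce_times(scheme)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  t_inj <- (scheme$injection_index - 1) * scheme$dt
  tm <- (times - t_inj) / 60  # minutes since bolus arrival
  cp <- parker_cp_(tm) * (scheme$dose / 0.1)
  cp[times < t_inj] <- 0
  cp <- pmax(cp, 0)
  structure(data.frame(time = times, cp = cp), class = c("aif", "data.frame"))
}

# internal: Parker population AIF evaluated at t in minutes (plasma, mM,
# for a 0.1 mmol/kg dose); ~0 for t <= 0
parker_cp_ <- function(tm) {
  A <- c(0.809, 0.330); T0 <- c(0.17046, 0.365); sig <- c(0.0563, 0.132)
  alpha <- 1.050; beta <- 0.1685; s <- 38.078; tau <- 0.483
  g <- A[1] / (sig[1] * sqrt(2 * pi)) * exp(-(tm - T0[1])^2 / (2 * sig[1]^2)) +
       A[2] / (sig[2] * sqrt(2 * pi)) * exp(-(tm - T0[2])^2 / (2 * sig[2]^2))
  wash <- alpha * exp(-beta * tm) / (1 + exp(-s * (tm - tau)))
  out <- g + wash
  out[tm <= 0] <- 0
  out
}

#' Construct an AIF from explicit samples
#'
#' @param time Times in seconds, strictly increasing.
#' @param cp Plasma concentration in mM, non-negative and finite.
#' @return An object of class `aif`.
#' @export
aif <- function(time, cp) {
  if (length(time) != length(cp)) stop("time and cp must have equal length")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(cp)) || any(cp < 0))
    stop("cp must be finite and non-negative")
  structure(data.frame(time = as.numeric(time), cp = as.numeric(cp)),
            class = c("aif", "data.frame"))
}
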