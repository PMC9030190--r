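#' Overhauser enhancement parameters
#'
#' Scalar efficiencies of the Overhauser enhancement relation
#' `E = 1 - xi f s |gammaS/gammaI|`.
#'
#' @param xi coupling factor, in `[-1, 0.5]` (`-1` pure scalar coupling,
#'   `+0.5` pure dipolar; proton-nitroxide systems in solution are almost
#'   entirely dipolar).
#' @param f leakage factor, in `[0, 1]`.
#' @param s electron saturation factor, in `[0, 1]`.
#' @param gamma_ratio magnitude of the electron/nuclear gyromagnetic ratio,
#'   default 658.21 (free electron / proton).
#' @export
enhancement_params <- function(xi, f = 1, s = 1, gamma_ratio = 658.21) {
  if (xi < -1 || xi > 0.5) {
    stop("coupling factor xi must lie in [-1, 0.5]", call. = FALSE)
  }
  if (f < 0 || f > 1) stop("leakage factor f must lie in [0, 1]",
                           call. = FALSE)
  if (s < 0 || s > 1) stop("saturation factor s must lie in [0, 1]",
                           call. = FALSE)
  if (gamma_ratio <= 0) stop("gamma_ratio must be > 0", call. = FALSE)
  structure(list(xi = xi, f = f, s = s, gamma_ratio = gamma_ratio),
            class = "enhancement_params")
}

#' Overhauser enhancement
#'
#' `E = 1 - xi f s |gammaS/gammaI|`, signed so that dipolar coupling
#' (`xi > 0`) gives the large negative proton enhancements characteristic of
#' ODNP (maximum magnitude ~330 for full leakage and saturation), while the
#' pure scalar limit (`xi = -1`) gives a large positive enhancement.
#'
#' @param p an [enhancement_params()].
#' @return the signed, dimensionless enhancement `E`.
#' @export
enhancement <- function(p) {
  stopifnot(inherits(p, "enhancement_params"))
  1 - p$xi * p$f * p$s * p$gamma_ratio
}

#' Time-saving factor of a signal enhancement
#'
#' Averaging time to reach a fixed signal-to-noise ratio scales with the
#' inverse square of the signal, so an enhancement `E` saves a factor `E^2`
#' (even in the sign of `E`: a moderate `E = -30` already saves a factor
#' of 900).
#'
#' @param E signed enhancement (non-zero).
#' @return `E^2`.
#' @export
time_saving <- function(E) {
  if (any(E == 0)) stop("E must be non-zero", call. = FALSE)
  E^2
}

#' Boltzmann penalty of polarize-low / detect-high shuttling
#'
#' Polarizing at a low field and detecting at a higher one forfeits the
#' detection-field Boltzmann polarization by the frequency ratio
#' `f_detect / f_polarize` (e.g. > 5 when polarizing at 15 MHz and
#' detecting at 80 MHz).
#'
#' @param f_polarize_MHz proton frequency at the polarizing field (> 0).
#' @param f_detect_MHz proton frequency at the detection field (> 0).
#' @return the penalty factor.
#' @export
boltzmann_penalty <- function(f_polarize_MHz, f_detect_MHz) {
  if (f_polarize_MHz <= 0 || f_detect_MHz <= 0) {
    stop("frequencies must be > 0", call. = FALSE)
  }
  f_detect_MHz / f_polarize_MHz
}

#' Scalar Hz <-> ppm conversion
#'
#' `ppm = Hz / f0` and `Hz = ppm * f0` at transmitter frequency `f0` MHz
#' (so 2.3 Hz at 14.7945 MHz is 0.16 ppm).
#'
#' @param value numeric value(s) to convert.
#' @param f0_MHz transmitter frequency in MHz (> 0).
#' @param direction `"hz_to_ppm"` or `"ppm_to_hz"`.
#' @return the converted value(s).
#' @export
hz_ppm <- function(value, f0_MHz, direction = c("hz_to_ppm", "ppm_to_hz")) {
  direction <- match.arg(direction)
  if (f0_MHz <= 0) stop("f0_MHz must be > 0", call. = FALSE)
  if (direction == "hz_to_ppm") value / f0_MHz else value * f0_MHz
}
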