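#' Track field drift across interleaved 1D reference scans
#'
#' Each reference FID is processed (apodization, zero-filling, Fourier
#' transform, magnitude) and the sub-bin position of the global maximum peak
#' is followed. The tracked shift is expressed in ppm relative to the first
#' reference; the tracked phase is the argument of the complex spectrum at
#' the peak after frequency registration (the FID is demodulated by the
#' measured shift, dead time included, before the phase is read), relative
#' to the first scan and unwrapped over time.
#'
#' @param references time-domain [nmr_dataset()] with dims
#'   `c("t2", "transient")`; the transient axis carries the wall-clock time
#'   of each reference scan.
#' @param processing a [window_spec()] applied before transformation.
#' @param zf_factor zero-filling factor for the reference spectra.
#' @param snr_warn minimum peak signal-to-noise ratio; scans below it are
#'   flagged in the track's `warnings`.
#' @return an object of class `reference_track`: `times_s`, `delta_ppm`
#'   (first element 0), `phase_rad` (first element 0, unwrapped),
#'   `peak_hz`, plus fit fields once [fit_drift()] has been applied.
#' @export
track_references <- function(references,
                             processing = window_spec("lorentz", lb_hz = 1),
                             zf_factor = 2, snr_warn = 5) {
  stopifnot(inherits(references, "nmr_dataset"))
  if (!identical(references$dims, c("t2", "transient"))) {
    stop("expected reference dims c('t2', 'transient')", call. = FALSE)
  }
  times <- references$coords[["transient"]]
  n_ref <- length(times)
  if (n_ref < 2L) stop("need >= 2 reference scans", call. = FALSE)
  t2 <- references$coords[["t2"]]
  f0 <- references$attrs$f0_MHz
  dead <- references$attrs$dead_time_s %||% 0
  dwell <- t2[2] - t2[1]
  env <- window_values(processing, t2)
  n_fft <- as.integer(round(zf_factor * length(t2)))
  faxis <- fft_freq_axis(n_fft, dwell)
  ord <- fftshift_order(n_fft)

  spec_of <- function(fid) {
    x <- c(fid * env, complex(n_fft - length(fid)))
    x[1] <- x[1] / 2
    (stats::fft(x) * dwell)[ord]
  }

  pos_hz <- numeric(n_ref)
  phase <- numeric(n_ref)
  warns <- character(0)
  first_peak_bin <- NA_integer_
  for (j in seq_len(n_ref)) {
    fid <- references$values[, j]
    sp <- spec_of(fid)
    mg <- Mod(sp)
    i <- which.max(mg)
    d <- 0
    if (i > 1 && i < n_fft) {
      den <- mg[i - 1] - 2 * mg[i] + mg[i + 1]
      if (den < 0) d <- 0.5 * (mg[i - 1] - mg[i + 1]) / den
    }
    pos_hz[j] <- faxis[i] + d * (faxis[2] - faxis[1])
    noise <- stats::sd(mg[seq_len(max(8L, n_fft %/% 20))])
    if (is.finite(noise) && noise > 0 && mg[i] / noise < snr_warn) {
      warns <- c(warns, sprintf("reference %d: peak SNR %.1f below %g",
                                j, mg[i] / noise, snr_warn))
    }
    if (j == 1L) first_peak_bin <- i
    # frequency registration before reading the phase
    dhz <- pos_hz[j] - pos_hz[1]
    reg <- spec_of(fid * exp(-2i * pi * dhz * (t2 + dead)))
    phase[j] <- Arg(reg[first_peak_bin])
  }
  phase <- unwrap_phase(phase - phase[1])
  structure(list(times_s = times,
                 delta_ppm = (pos_hz - pos_hz[1]) / f0,
                 phase_rad = phase,
                 peak_hz = pos_hz,
                 f0_MHz = f0,
                 dead_time_s = dead,
                 warnings = warns,
                 order = NULL, fit_coeffs = NULL, fit_domain = NULL,
                 residual_ppm = NULL, residual_max_ppm = NULL,
                 residual_rms_ppm = NULL),
            class = "reference_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-dimensional phase unwrapping (jumps folded into (-pi, pi]).
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Construct a reference track directly from known values
#'
#' Mainly for tests and for importing drift records measured elsewhere.
#'
#' @param times_s wall-clock times, seconds.
#' @param delta_ppm drift relative to the first scan, ppm (first element 0).
#' @param phase_rad per-scan phase relative to the first scan, radians.
#' @param f0_MHz transmitter frequency, MHz.
#' @param dead_time_s receiver dead time, seconds.
#' @export
reference_track <- function(times_s, delta_ppm, phase_rad = NULL,
                            f0_MHz = 14.7945, dead_time_s = 0) {
  stopifnot(length(times_s) == length(delta_ppm))
  if (is.null(phase_rad)) phase_rad <- numeric(length(times_s))
  structure(list(times_s = times_s, delta_ppm = delta_ppm,
                 phase_rad = phase_rad, peak_hz = delta_ppm * f0_MHz,
                 f0_MHz = f0_MHz, dead_time_s = dead_time_s,
                 warnings = character(0),
                 order = NULL, fit_coeffs = NULL, fit_domain = NULL,
                 residual_ppm = NULL, residual_max_ppm = NULL,
                 residual_rms_ppm = NULL),
            class = "reference_track")
}

#' Fit a polynomial drift model to a reference track
#'
#' Least-squares polynomial in wall-clock time, fitted on a domain rescaled
#' to `[-1, 1]` for numerical conditioning. Order 4 is the default; the
#' residual report lets users justify other orders for non-monotonic drifts.
#'
#' @param track a `reference_track`.
#' @param order polynomial order (default 4).
#' @param warn_residual_ppm optional residual level above which a warning is
#'   issued (e.g. a fraction of the linewidth in ppm).
#' @return the track with `fit_coeffs` (ascending powers of the rescaled
#'   time), `fit_domain`, `residual_ppm`, `residual_max_ppm`,
#'   `residual_rms_ppm` populated.
#' @export
fit_drift <- function(track, order = 4, warn_residual_ppm = NULL) {
  stopifnot(inherits(track, "reference_track"))
  n <- length(track$times_s)
  if (n < order + 1) {
    stop("underdetermined fit: ", n, " points for order ", order,
         call. = FALSE)
  }
  dom <- range(track$times_s)
  x <- rescale_time(track$times_s, dom)
  X <- outer(x, 0:order, `^`)
  coefs <- qr.solve(X, track$delta_ppm)
  fitted <- as.vector(X %*% coefs)
  res <- track$delta_ppm - fitted
  track$order <- order
  track$fit_coeffs <- coefs
  track$fit_domain <- dom
  track$residual_ppm <- res
  track$residual_max_ppm <- max(abs(res))
  track$residual_rms_ppm <- sqrt(mean(res^2))
  if (!is.null(warn_residual_ppm) &&
      track$residual_max_ppm > warn_residual_ppm) {
    warning(sprintf("drift-fit residual %.3g ppm exceeds %.3g ppm",
                    track$residual_max_ppm, warn_residual_ppm),
            call. = FALSE)
  }
  track
}

rescale_time <- function(tau, dom) {
  if (dom[2] == dom[1]) return(rep(0, length(tau)))
  2 * (tau - dom[1]) / (dom[2] - dom[1]) - 1
}

#' Evaluate a fitted drift polynomial
#'
#' @param track a fitted `reference_track`.
#' @param tau_s wall-clock times, seconds.
#' @return fitted drift in ppm.
#' @export
predict_drift <- function(track, tau_s) {
  if (is.null(track$fit_coeffs)) stop("track is not fitted", call. = FALSE)
  x <- rescale_time(tau_s, track$fit_domain)
  as.vector(outer(x, seq_along(track$fit_coeffs) - 1, `^`) %*%
              track$fit_coeffs)
}

#' Correct stored transients for field and phase drift
#'
#' For each transient at wall-clock time `tau`, the fitted drift polynomial
#' gives `df = delta(tau) f0` in Hz, and the FID is demodulated by
#' `exp(-2i pi df (t + dead_time))` (the time-domain inverse of the drift,
#' sub-bin exact, commuting with later apodization). A zeroth-order phase
#' correction, linearly interpolated between reference scans, is applied on
#' top for instabilities not captured by the frequency term.
#'
#' @param transients time-domain [nmr_dataset()] with dims
#'   `c("t2", "transient")` carrying timestamps on the transient axis.
#' @param track a fitted `reference_track`.
#' @param grid the [acquisition_grid()] of the transients (supplies
#'   `f0_MHz` and `dead_time_s`).
#' @return the corrected dataset.
#' @export
correct_transients <- function(transients, track, grid) {
  stopifnot(inherits(transients, "nmr_dataset"),
            inherits(track, "reference_track"),
            inherits(grid, "acquisition_grid"))
  if (is.null(track$fit_coeffs)) {
    stop("track is not fitted; call fit_drift() first", call. = FALSE)
  }
  if (!identical(transients$dims, c("t2", "transient"))) {
    stop("expected dims c('t2', 'transient')", call. = FALSE)
  }
  tau <- transients$coords[["transient"]]
  if (any(tau < min(track$times_s) - 1e-9) ||
      any(tau > max(track$times_s) + 1e-9)) {
    warning("transient timestamps outside the reference window; ",
            "drift polynomial extrapolated", call. = FALSE)
  }
  t2 <- transients$coords[["t2"]]
  df_hz <- predict_drift(track, tau) * grid$f0_MHz
  phi <- stats::approx(track$times_s, track$phase_rad, xout = tau,
                       rule = 2)$y
  mod <- exp(-1i * (2 * pi * outer(t2 + grid$dead_time_s, df_hz) +
                      matrix(phi, nrow = length(t2), ncol = length(tau),
                             byrow = TRUE)))
  transients$values <- transients$values * mod
  nd_log(transients, "correct_transients",
         list(order = track$order,
              residual_max_ppm = track$residual_max_ppm))
}

#' Combine phase-cycled transients
#'
#' Receiver-sign-weighted sum within each consecutive block of
#' `cycle$n_steps` transients; the transient dimension collapses to one FID
#' per cycle (per t1 increment for a JRES run).
#'
#' @param transients time-domain [nmr_dataset()] with dims
#'   `c("t2", "transient")`, transient count divisible by the cycle length.
#' @param cycle a [phase_cycle()].
#' @return [nmr_dataset()] with dims `c("t2", "t1")`; the t1 axis is taken
#'   from the dataset's `t1_values_s` attribute when present, else the cycle
#'   index.
#' @export
combine_phase_cycle <- function(transients, cycle) {
  stopifnot(inherits(transients, "nmr_dataset"),
            inherits(cycle, "phase_cycle"))
  if (!identical(transients$dims, c("t2", "transient"))) {
    stop("expected dims c('t2', 'transient')", call. = FALSE)
  }
  n_tr <- dim(transients$values)[2]
  ns <- cycle$n_steps
  if (n_tr %% ns != 0L) {
    stop("transient count ", n_tr, " not divisible by cycle length ", ns,
         call. = FALSE)
  }
  n_grp <- n_tr %/% ns
  signs <- rep(cycle$receiver_sign, n_grp)
  weighted <- transients$values *
    matrix(signs, nrow = dim(transients$values)[1], ncol = n_tr, byrow = TRUE)
  grp <- rep(seq_len(n_grp), each = ns)
  out <- vapply(seq_len(n_grp),
                function(g) rowSums(weighted[, grp == g, drop = FALSE]),
                complex(dim(transients$values)[1]))
  t1 <- transients$attrs$t1_values_s %||% seq_len(n_grp)
  t1_units <- if (is.null(transients$attrs$t1_values_s)) "s" else "s"
  ds <- nmr_dataset(out, c("t2", "t1"),
                    coords = list(t2 = transients$coords[["t2"]], t1 = t1),
                    attrs = list(f0_MHz = transients$attrs$f0_MHz,
                                 carrier_ppm = transients$attrs$carrier_ppm,
                                 dead_time_s = transients$attrs$dead_time_s,
                                 units = c(t2 = "s", t1 = t1_units),
                                 provenance = transients$attrs$provenance))
  nd_log(ds, "combine_phase_cycle", list(n_steps = ns))
}
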