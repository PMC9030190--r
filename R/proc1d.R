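#' Apodization window specification
#'
#' Window kinds, as multiplicative time-domain envelopes:
#' \describe{
#'   \item{lorentz}{`exp(-pi lb t)` — adds `lb` Hz of Lorentzian width.}
#'   \item{gauss}{`exp(-(pi gb t)^2 / (4 log 2))` — Gaussian of spectral
#'     FWHM `gb` Hz.}
#'   \item{lorentz_gauss}{`exp(+pi lb t - (pi gb t)^2 / (4 log 2))` —
#'     removes `lb` Hz of Lorentzian width and substitutes a `gb` Hz
#'     Gaussian (resolution enhancement).}
#'   \item{traficante}{`E / (E^2 + F^2)` with `E = exp(-t/T2*)`,
#'     `F = exp(-(T_aq - t)/T2*)` — amplifies late FID points while keeping
#'     the noise amplification bounded.}
#' }
#'
#' @param kind window kind.
#' @param lb_hz Lorentzian broadening in Hz (the width removed when
#'   `kind = "lorentz_gauss"`).
#' @param gb_hz Gaussian FWHM added, Hz (>= 0).
#' @param t2_star_s Traficante effective decay time, seconds (> 0).
#' @export
window_spec <- function(kind = c("lorentz", "gauss", "lorentz_gauss",
                                 "traficante"),
                        lb_hz = 0, gb_hz = 0, t2_star_s = NULL) {
  kind <- match.arg(kind)
  if (gb_hz < 0) stop("gb_hz must be >= 0", call. = FALSE)
  if (kind == "traficante" && (is.null(t2_star_s) || t2_star_s <= 0)) {
    stop("traficante window requires t2_star_s > 0", call. = FALSE)
  }
  structure(list(kind = kind, lb_hz = lb_hz, gb_hz = gb_hz,
                 t2_star_s = t2_star_s),
            class = "window_spec")
}

# Window envelope evaluated on a time axis; t_aq is the last axis point.
window_values <- function(w, t) {
  t_aq <- t[length(t)]
  switch(w$kind,
    lorentz = exp(-pi * w$lb_hz * t),
    gauss = exp(-(pi * w$gb_hz * t)^2 / (4 * log(2))),
    lorentz_gauss = exp(pi * w$lb_hz * t - (pi * w$gb_hz * t)^2 / (4 * log(2))),
    traficante = {
      e <- exp(-t / w$t2_star_s)
      f <- exp(-(t_aq - t) / w$t2_star_s)
      e / (e^2 + f^2)
    },
    stop("unknown window kind '", w$kind, "'", call. = FALSE)
  )
}

#' Apodize a time-domain dimension
#'
#' @param ds an [nmr_dataset()].
#' @param w a [window_spec()].
#' @param dim dimension name (default: first time-domain dimension).
#' @return the apodized dataset.
#' @export
apodize <- function(ds, w, dim = NULL) {
  stopifnot(inherits(ds, "nmr_dataset"), inherits(w, "window_spec"))
  dim <- default_time_dim(ds, dim)
  env <- window_values(w, ds$coords[[dim]])
  i <- dim_index(ds, dim)
  ds$values <- apply_along(ds$values, i, function(x) x * env)
  nd_log(ds, "apodize", list(dim = dim, kind = w$kind, lb_hz = w$lb_hz,
                             gb_hz = w$gb_hz, t2_star_s = w$t2_star_s))
}

default_time_dim <- function(ds, dim) {
  if (is.null(dim)) {
    td <- ds$dims[ds$attrs$domain[ds$dims] == "time" & ds$dims != "transient"]
    if (length(td) == 0L) stop("no time-domain dimension", call. = FALSE)
    dim <- td[1]
  }
  if (!identical(ds$attrs$domain[[dim]], "time")) {
    stop("dimension '", dim, "' is not time-domain", call. = FALSE)
  }
  dim
}

#' Zero-fill a time-domain dimension
#'
#' Appends zeros up to `factor` times the original length; the axis is
#' extended on the same sampling grid.
#'
#' @param ds an [nmr_dataset()].
#' @param dim dimension name (default: first time-domain dimension).
#' @param factor extension factor (>= 1); the default doubles the length.
#' @return the zero-filled dataset.
#' @export
zero_fill <- function(ds, dim = NULL, factor = 2) {
  stopifnot(inherits(ds, "nmr_dataset"))
  if (factor < 1) stop("zero-fill factor must be >= 1", call. = FALSE)
  dim <- default_time_dim(ds, dim)
  i <- dim_index(ds, dim)
  ax <- ds$coords[[dim]]
  n <- length(ax)
  n_new <- as.integer(round(factor * n))
  if (n_new == n) return(nd_log(ds, "zero_fill", list(dim = dim, factor = 1)))
  dt <- ax[2] - ax[1]
  ds$coords[[dim]] <- ax[1] + (seq_len(n_new) - 1) * dt
  ds$values <- apply_along(ds$values, i, function(x) c(x, complex(n_new - n)))
  nd_log(ds, "zero_fill", list(dim = dim, factor = factor))
}

fftshift_order <- function(n) c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2))

#' Fourier transform a time-domain dimension
#'
#' Complex FFT with the first time point halved (the standard convention
#' suppressing the discrete-sum baseline offset), scaled by the dwell time so
#' the result approximates the continuous-time transform, and reordered onto
#' a zero-centred ascending frequency axis. The dimension's domain tag flips
#' to `"frequency"`.
#'
#' @param ds an [nmr_dataset()].
#' @param dim dimension name (default: first time-domain dimension).
#' @return the transformed dataset, with the dimension renamed `t*` -> `f*`.
#' @export
fourier_transform <- function(ds, dim = NULL) {
  stopifnot(inherits(ds, "nmr_dataset"))
  if (is.null(dim)) {
    dim <- default_time_dim(ds, NULL)
  } else if (!identical(ds$attrs$domain[[dim]], "time")) {
    stop("dimension '", dim, "' is already frequency-domain", call. = FALSE)
  }
  i <- dim_index(ds, dim)
  ax <- ds$coords[[dim]]
  n <- length(ax)
  dwell <- ax[2] - ax[1]
  ord <- fftshift_order(n)
  ds$values <- apply_along(ds$values, i, function(x) {
    x[1] <- x[1] / 2
    (stats::fft(x) * dwell)[ord]
  })
  new_name <- sub("^t", "f", dim)
  if (new_name == dim) new_name <- paste0("f_", dim)
  ds$dims[i] <- new_name
  ds$coords[[dim]] <- NULL
  ds$coords[[new_name]] <- fft_freq_axis(n, dwell)
  ds$attrs$domain <- ds$attrs$domain[names(ds$attrs$domain) != dim]
  ds$attrs$domain[new_name] <- "frequency"
  ds$attrs$units <- ds$attrs$units[names(ds$attrs$units) != dim]
  ds$attrs$units[new_name] <- "Hz"
  nd_log(ds, "fourier_transform", list(dim = dim))
}

#' Zeroth/first-order phase correction
#'
#' Multiplies a frequency-domain dimension by
#' `exp(i (phi0 + phi1 (f - pivot) / SW))` with the angles in degrees.
#'
#' @param ds frequency-domain [nmr_dataset()].
#' @param phi0_deg zeroth-order phase, degrees.
#' @param phi1_deg first-order phase across the full spectral width, degrees.
#' @param pivot_hz pivot frequency for the first-order term.
#' @param dim dimension name (default: first frequency-domain dimension).
#' @return the phased dataset.
#' @export
phase_correct <- function(ds, phi0_deg, phi1_deg = 0, pivot_hz = 0,
                          dim = NULL) {
  stopifnot(inherits(ds, "nmr_dataset"))
  dim <- default_freq_dim(ds, dim)
  f <- ds$coords[[dim]]
  sw <- length(f) * (f[2] - f[1])
  ph <- exp(1i * pi / 180 * (phi0_deg + phi1_deg * (f - pivot_hz) / sw))
  i <- dim_index(ds, dim)
  ds$values <- apply_along(ds$values, i, function(x) x * ph)
  nd_log(ds, "phase_correct", list(phi0_deg = phi0_deg, phi1_deg = phi1_deg,
                                   pivot_hz = pivot_hz))
}

default_freq_dim <- function(ds, dim) {
  if (is.null(dim)) {
    fd <- ds$dims[ds$attrs$domain[ds$dims] == "frequency"]
    if (length(fd) == 0L) stop("no frequency-domain dimension", call. = FALSE)
    dim <- fd[1]
  }
  if (!identical(ds$attrs$domain[[dim]], "frequency")) {
    stop("dimension '", dim, "' is not frequency-domain", call. = FALSE)
  }
  dim
}

# Cyclic shift of a vector by s bins (y_j = x_{j+s}), sub-bin via the FFT
# shift theorem with symmetric frequency indexing. Unit-modulus phases, so
# the L2 norm is preserved exactly.
cyclic_shift_subbin <- function(x, s) {
  n <- length(x)
  if (s == 0) return(x)
  k <- seq_len(n) - 1
  kk <- ((k + floor(n / 2)) %% n) - floor(n / 2)
  xh <- stats::fft(x)
  stats::fft(xh * exp(2i * pi * kk * s / n), inverse = TRUE) / n
}

#' Align a spectrum to a reference by FT cross-correlation
#'
#' Computes the circular cross-correlation of the two magnitude spectra via
#' `IFFT(FFT(|a|) * Conj(FFT(|b|)))`, takes the arg-max as the lag of the
#' target relative to the reference, and returns the target cyclically
#' shifted back into register. Magnitude makes the estimate robust to phase
#' differences between transients.
#'
#' @param target,reference numeric/complex vectors or 1D frequency-domain
#'   [nmr_dataset()]s of equal length.
#' @param sub_bin refine the lag by 3-point parabolic interpolation of the
#'   correlation peak and apply a fractional-bin shift.
#' @return list with `lag_bins` (signed; positive = target sits at higher
#'   bins than the reference) and `aligned` (the shifted target, same type
#'   as the input).
#' @export
align_ft_xcorr <- function(target, reference, sub_bin = FALSE) {
  tv <- if (inherits(target, "nmr_dataset")) as.vector(target$values) else target
  rv <- if (inherits(reference, "nmr_dataset")) as.vector(reference$values) else reference
  if (length(tv) != length(rv)) {
    stop("target and reference lengths differ (", length(tv), " vs ",
         length(rv), ")", call. = FALSE)
  }
  n <- length(tv)
  ma <- Mod(tv)
  mb <- Mod(rv)
  cc <- Re(stats::fft(stats::fft(ma) * Conj(stats::fft(mb)),
                      inverse = TRUE)) / n
  m <- which.max(cc) - 1L
  lag <- if (m > n / 2) m - n else m
  if (sub_bin && n >= 3) {
    ym1 <- cc[((m - 1) %% n) + 1]
    y0 <- cc[m + 1]
    yp1 <- cc[((m + 1) %% n) + 1]
    den <- ym1 - 2 * y0 + yp1
    if (den < 0) lag <- lag + 0.5 * (ym1 - yp1) / den
  }
  shifted <- cyclic_shift_subbin(tv, lag)
  if (is.numeric(tv)) shifted <- Re(shifted)
  if (inherits(target, "nmr_dataset")) {
    target$values <- array(shifted, dim = dim(target$values))
    target <- nd_log(target, "align_ft_xcorr", list(lag_bins = lag))
    return(list(lag_bins = lag, aligned = target))
  }
  list(lag_bins = lag, aligned = shifted)
}

#' Pick peaks in a 1D spectrum
#'
#' Local maxima above `threshold_frac` of the global maximum, with sub-bin
#' position and height from 3-point parabolic interpolation and FWHM from
#' linear interpolation of the half-height crossings.
#'
#' @param spectrum 1D frequency-domain [nmr_dataset()], or a numeric vector
#'   (then supply `axis`).
#' @param threshold_frac detection threshold as a fraction of the global
#'   maximum.
#' @param axis frequency axis (Hz) when `spectrum` is a bare vector.
#' @param mode `"magnitude"` (default) or `"real"`.
#' @return data.frame with columns `pos_hz`, `pos_ppm` (NA without a known
#'   `f0_MHz`), `height`, `fwhm_hz`, `offset_bins`; zero rows for a flat or
#'   all-subthreshold spectrum.
#' @export
pick_peaks <- function(spectrum, threshold_frac = 0.05, axis = NULL,
                       mode = c("magnitude", "real")) {
  mode <- match.arg(mode)
  f0 <- NA_real_
  ref_off <- 0
  if (inherits(spectrum, "nmr_dataset")) {
    axis <- spectrum$coords[[spectrum$dims[1]]]
    if (!is.null(spectrum$attrs$f0_MHz)) f0 <- spectrum$attrs$f0_MHz
    if (!is.null(spectrum$attrs$ref_ppm_offset)) {
      ref_off <- spectrum$attrs$ref_ppm_offset
    }
    y <- as.vector(spectrum$values)
  } else {
    y <- spectrum
  }
  y <- if (mode == "magnitude") Mod(y) else Re(y)
  if (is.null(axis)) axis <- seq_along(y)
  empty <- data.frame(pos_hz = numeric(0), pos_ppm = numeric(0),
                      height = numeric(0), fwhm_hz = numeric(0),
                      offset_bins = numeric(0))
  n <- length(y)
  ymax <- max(y)
  if (n < 3 || ymax <= min(y)) return(empty)
  thr <- threshold_frac * ymax
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
                 y[2:(n - 1)] > thr) + 1L
  if (length(idx) == 0L) return(empty)
  dax <- axis[2] - axis[1]
  rows <- lapply(idx, function(i) {
    ym1 <- y[i - 1]; y0 <- y[i]; yp1 <- y[i + 1]
    den <- ym1 - 2 * y0 + yp1
    d <- if (den < 0) 0.5 * (ym1 - yp1) / den else 0
    h <- y0 - 0.25 * (ym1 - yp1) * d
    data.frame(pos_hz = axis[i] + d * dax,
               height = h,
               fwhm_hz = half_height_width(y, axis, i, h),
               offset_bins = d)
  })
  out <- do.call(rbind, rows)
  out$pos_ppm <- if (is.na(f0)) NA_real_ else out$pos_hz / f0 + ref_off
  out[, c("pos_hz", "pos_ppm", "height", "fwhm_hz", "offset_bins")]
}

# FWHM by walking out to the half-height crossings and interpolating.
half_height_width <- function(y, axis, i, h) {
  half <- h / 2
  l <- i
  while (l > 1 && y[l] > half) l <- l - 1
  r <- i
  n <- length(y)
  while (r < n && y[r] > half) r <- r + 1
  if (y[l] > half || y[r] > half) return(NA_real_)
  xl <- axis[l] + (axis[l + 1] - axis[l]) * (half - y[l]) / (y[l + 1] - y[l])
  xr <- axis[r - 1] + (axis[r] - axis[r - 1]) * (y[r - 1] - half) /
    (y[r - 1] - y[r])
  xr - xl
}

#' Combine per-transient spectra into one 1D spectrum
#'
#' Optionally aligns every transient to the first by FT cross-correlation
#' (integer-bin lags), then sums over the transient dimension.
#'
#' @param ds frequency-domain [nmr_dataset()] with dims
#'   `c(<freq dim>, "transient")`.
#' @param align align each transient to the first before summing.
#' @return 1D [nmr_dataset()] (the summed spectrum).
#' @export
average_transients <- function(ds, align = TRUE) {
  stopifnot(inherits(ds, "nmr_dataset"))
  if (!"transient" %in% ds$dims || length(ds$dims) != 2L) {
    stop("expected dims c(<freq>, 'transient')", call. = FALSE)
  }
  fdim <- setdiff(ds$dims, "transient")
  it <- dim_index(ds, "transient")
  m <- if (it == 2L) ds$values else t(ds$values)
  if (align && ncol(m) > 1L) {
    ref <- m[, 1]
    for (j in 2:ncol(m)) {
      lag <- align_ft_xcorr(m[, j], ref)$lag_bins
      if (lag != 0) m[, j] <- cyclic_shift_subbin(m[, j], lag)
    }
  }
  summed <- rowSums(m)
  out <- nmr_dataset(summed, fdim,
                     coords = ds$coords[fdim],
                     attrs = c(ds$attrs[setdiff(names(ds$attrs),
                                                c("units", "domain"))],
                               list(units = ds$attrs$units[fdim],
                                    domain = ds$attrs$domain[fdim])))
  nd_log(out, "average_transients", list(align = align, n = ncol(m)))
}
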