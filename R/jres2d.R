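#' Processed 2D J-resolved spectrum
#'
#' Container produced by [process_jres()] and refined by [shear()],
#' [symmetrize_geometric()] and [reference_ppm()]. Holds the magnitude
#' spectrum on `f2` (direct, Hz) x `f1` (indirect/J, Hz) axes, the complex
#' spectrum while it is still available (needed for sub-bin shearing), and
#' the ppm referencing offset.
#'
#' @name jres_result
NULL

new_jres_result <- function(magnitude, cplx, f2_hz, f1_hz, f0_MHz,
                            carrier_ppm = NA_real_, ref_ppm_offset = NULL,
                            sheared = FALSE, symmetrized = FALSE,
                            log = list()) {
  structure(list(magnitude = magnitude, cplx = cplx,
                 f2_hz = f2_hz, f1_hz = f1_hz, f0_MHz = f0_MHz,
                 carrier_ppm = carrier_ppm, ref_ppm_offset = ref_ppm_offset,
                 sheared = sheared, symmetrized = symmetrized, log = log),
            class = "jres_result")
}

#' @export
print.jres_result <- function(x, ...) {
  cat(sprintf("<jres_result> %d (f2) x %d (f1)%s%s\n",
              nrow(x$magnitude), ncol(x$magnitude),
              if (x$sheared) ", sheared" else "",
              if (x$symmetrized) ", symmetrized" else ""))
  cat(sprintf("  f2: [%.1f, %.1f] Hz   f1: [%.2f, %.2f] Hz   f0 %g MHz\n",
              min(x$f2_hz), max(x$f2_hz), min(x$f1_hz), max(x$f1_hz),
              x$f0_MHz))
  invisible(x)
}

#' ppm axis of a `jres_result`
#' @param result a [jres_result].
#' @return the `f2` axis in ppm (transmitter-relative plus the referencing
#'   offset; [reference_ppm()] sets the offset from a known peak).
#' @export
f2_ppm_axis <- function(result) {
  off <- result$ref_ppm_offset %||% (result$carrier_ppm %||% 0)
  hz_axis_to_ppm(result$f2_hz, result$f0_MHz, off)
}

#' Process per-t1 FIDs into a 2D JRES magnitude spectrum
#'
#' Apodizes both time dimensions, zero-fills both to `zf` times the original
#' length, Fourier transforms `t2` then `t1`, and takes the magnitude
#' (phase-twist lineshapes make phased 2D JRES impractical; the
#' Lorentz-Gauss window doubles as the anti-tail measure). The complex
#' spectrum is retained for exact sub-bin shearing.
#'
#' @param fids time-domain [nmr_dataset()] with dims `c("t2", "t1")` (e.g.
#'   from [combine_phase_cycle()]).
#' @param window_t2,window_t1 [window_spec()]s for the direct and indirect
#'   dimensions; default Lorentz-Gauss with 4 Hz Lorentzian removal and
#'   4 Hz Gaussian substitution on both.
#' @param zf zero-filling factor applied to both dimensions.
#' @return an unsheared [jres_result].
#' @export
process_jres <- function(fids,
                         window_t2 = window_spec("lorentz_gauss",
                                                 lb_hz = 4, gb_hz = 4),
                         window_t1 = window_spec("lorentz_gauss",
                                                 lb_hz = 4, gb_hz = 4),
                         zf = 2) {
  stopifnot(inherits(fids, "nmr_dataset"))
  if (!identical(fids$dims, c("t2", "t1"))) {
    stop("expected a 2D dataset with dims c('t2', 't1')", call. = FALSE)
  }
  ds <- apodize(fids, window_t2, dim = "t2")
  ds <- apodize(ds, window_t1, dim = "t1")
  ds <- zero_fill(ds, dim = "t2", factor = zf)
  ds <- zero_fill(ds, dim = "t1", factor = zf)
  ds <- fourier_transform(ds, dim = "t2")
  ds <- fourier_transform(ds, dim = "t1")
  cplx <- ds$values
  new_jres_result(magnitude = Mod(cplx), cplx = cplx,
                  f2_hz = ds$coords[["f2"]], f1_hz = ds$coords[["f1"]],
                  f0_MHz = fids$attrs$f0_MHz,
                  carrier_ppm = fids$attrs$carrier_ppm %||% NA_real_,
                  log = list(list(op = "process_jres",
                                  params = list(zf = zf))))
}

#' Shear (tilt) a JRES spectrum
#'
#' Shifts each indirect-frequency row along `f2` by `-f1` Hz (direction
#' `"to_shift"`), so multiplet components at `f2 = delta + m J`,
#' `f1 = m J` line up at the chemical shift `delta`. The shift is sub-bin
#' exact: each complex row is inverse transformed, multiplied by the phase
#' ramp `exp(-2i pi f1 t2)`, and transformed back; magnitude rows are
#' shifted the same way when the complex spectrum is no longer available.
#'
#' @param result a [jres_result].
#' @param direction `"to_shift"` (default, shift by `-f1`) or `"opposite"`
#'   for data acquired with the other tilt convention.
#' @return the sheared [jres_result].
#' @export
shear <- function(result, direction = c("to_shift", "opposite")) {
  direction <- match.arg(direction)
  stopifnot(inherits(result, "jres_result"))
  df2 <- result$f2_hz[2] - result$f2_hz[1]
  sw2 <- length(result$f2_hz) * df2
  if (max(abs(result$f1_hz)) >= sw2) {
    stop("shear shift exceeds the direct spectral width", call. = FALSE)
  }
  sgn <- if (direction == "to_shift") 1 else -1
  shift_bins <- sgn * result$f1_hz / df2
  if (!is.null(result$cplx)) {
    for (j in seq_along(result$f1_hz)) {
      if (shift_bins[j] != 0) {
        result$cplx[, j] <- cyclic_shift_subbin(result$cplx[, j],
                                                shift_bins[j])
      }
    }
    result$magnitude <- Mod(result$cplx)
  } else {
    for (j in seq_along(result$f1_hz)) {
      if (shift_bins[j] != 0) {
        result$magnitude[, j] <-
          Mod(cyclic_shift_subbin(result$magnitude[, j], shift_bins[j]))
      }
    }
  }
  result$sheared <- TRUE
  result$log <- c(result$log,
                  list(list(op = "shear",
                            params = list(direction = direction))))
  result
}

#' Symmetrize a sheared JRES spectrum by the geometric average
#'
#' Replaces `S(f1, f2)` and `S(-f1, f2)` by `sqrt(S(f1,f2) S(-f1,f2))`,
#' suppressing artifacts that are not mirror-symmetric about `f1 = 0` (a
#' genuine J multiplet is). The `f1 = 0` row is unchanged; the unpaired
#' Nyquist row is dropped, leaving an exactly symmetric `f1` axis. The
#' complex spectrum is discarded (magnitude only from here on).
#'
#' @param result a sheared [jres_result].
#' @return the symmetrized [jres_result].
#' @export
symmetrize_geometric <- function(result) {
  stopifnot(inherits(result, "jres_result"))
  f1 <- result$f1_hz
  df1 <- f1[2] - f1[1]
  tol <- 1e-9 * max(abs(f1), df1)
  partner <- vapply(f1, function(v) {
    i <- which(abs(f1 + v) < tol)
    if (length(i) == 1L) i else NA_integer_
  }, integer(1))
  unpaired <- which(is.na(partner))
  if (length(unpaired) > 1L) {
    stop("f1 axis cannot be paired for symmetrization", call. = FALSE)
  }
  keep <- which(!is.na(partner))
  sym <- sqrt(result$magnitude[, keep, drop = FALSE] *
                result$magnitude[, partner[keep], drop = FALSE])
  result$magnitude <- sym
  result$f1_hz <- f1[keep]
  result$cplx <- NULL
  result$symmetrized <- TRUE
  result$log <- c(result$log, list(list(op = "symmetrize_geometric",
                                        params = list())))
  result
}

#' Skyline projection (pure-shift spectrum)
#'
#' Maximum signal intensity along the indirect (J) dimension for each direct
#' frequency, collapsing each multiplet to a single line at its chemical
#' shift. Skyline heights are not quantitative; use [integrate_indirect()]
#' for site amplitudes.
#'
#' @param result a (normally sheared and symmetrized) [jres_result].
#' @return 1D frequency-domain [nmr_dataset()] over `f2`.
#' @export
skyline_projection <- function(result) {
  stopifnot(inherits(result, "jres_result"))
  sky <- apply(result$magnitude, 1, max)
  ds <- nmr_dataset(sky, "f2", coords = list(f2 = result$f2_hz),
                    attrs = list(f0_MHz = result$f0_MHz,
                                 ref_ppm_offset = result$ref_ppm_offset %||%
                                   (result$carrier_ppm %||% 0),
                                 units = c(f2 = "Hz"),
                                 domain = c(f2 = "frequency")))
  nd_log(ds, "skyline_projection", list())
}

#' Integrate along the indirect dimension over direct-dimension windows
#'
#' For each window, sums `S df1` over the indirect axis and then over the
#' window's direct-axis bins times `df2` — the quantitative counterpart of
#' the skyline projection.
#'
#' @param result a [jres_result].
#' @param windows named list of `c(lo, hi)` ranges.
#' @param units `"ppm"` (default; interpreted on the referenced ppm axis)
#'   or `"hz"`.
#' @return named numeric vector of integrals.
#' @export
integrate_indirect <- function(result, windows, units = c("ppm", "hz")) {
  units <- match.arg(units)
  stopifnot(inherits(result, "jres_result"))
  ax <- if (units == "ppm") f2_ppm_axis(result) else result$f2_hz
  df1 <- abs(result$f1_hz[2] - result$f1_hz[1])
  df2 <- abs(result$f2_hz[2] - result$f2_hz[1])
  col_int <- rowSums(result$magnitude) * df1
  out <- vapply(windows, function(w) {
    sel <- ax >= min(w) & ax <= max(w)
    if (!any(sel)) stop("empty integration window", call. = FALSE)
    sum(col_int[sel]) * df2
  }, numeric(1))
  out
}

#' Extract an indirect-dimension slice at a chemical shift
#'
#' The `f1` column at the direct-axis bin nearest `shift_ppm`, or the mean
#' over a small ppm window around it.
#'
#' @param result a [jres_result].
#' @param shift_ppm chemical shift of the slice, on the referenced ppm axis.
#' @param window_ppm half-width of the averaging window (0 = single bin).
#' @return 1D [nmr_dataset()] over `f1` (the J axis).
#' @export
slice_at_shift <- function(result, shift_ppm, window_ppm = 0) {
  stopifnot(inherits(result, "jres_result"))
  ax <- f2_ppm_axis(result)
  if (shift_ppm < min(ax) || shift_ppm > max(ax)) {
    stop("shift ", shift_ppm, " ppm outside the f2 axis [",
         round(min(ax), 2), ", ", round(max(ax), 2), "]", call. = FALSE)
  }
  if (window_ppm > 0) {
    sel <- which(abs(ax - shift_ppm) <= window_ppm)
  } else {
    sel <- which.min(abs(ax - shift_ppm))
  }
  trace <- if (length(sel) > 1L) {
    colMeans(result$magnitude[sel, , drop = FALSE])
  } else {
    result$magnitude[sel, ]
  }
  ds <- nmr_dataset(trace, "f1", coords = list(f1 = result$f1_hz),
                    attrs = list(f0_MHz = result$f0_MHz,
                                 units = c(f1 = "Hz"),
                                 domain = c(f1 = "frequency")))
  nd_log(ds, "slice_at_shift", list(shift_ppm = shift_ppm))
}

#' Measure a J coupling from an indirect-dimension slice
#'
#' Peak-picks the J trace and reports the mean spacing between adjacent
#' multiplet maxima, sub-bin interpolated, with the axis resolution as the
#' quoted uncertainty.
#'
#' @param slice 1D [nmr_dataset()] over `f1` (from [slice_at_shift()]).
#' @param multiplicity expected number of multiplet components (2 doublet,
#'   3 triplet, 4 quartet); the strongest `multiplicity` peaks are used.
#' @param threshold_frac peak-picking threshold (fraction of slice maximum).
#' @return list with `j_hz` (mean adjacent spacing), `spacings_hz`,
#'   `uncertainty_hz` (one axis bin), and the picked `peaks`.
#' @export
measure_j <- function(slice, multiplicity, threshold_frac = 0.2) {
  stopifnot(inherits(slice, "nmr_dataset"), multiplicity >= 2)
  pk <- pick_peaks(slice, threshold_frac = threshold_frac)
  if (nrow(pk) < 2L) {
    stop("cannot measure J: found ", nrow(pk), " peak(s) at ",
         paste(sprintf("%.2f Hz", pk$pos_hz), collapse = ", "),
         "; need at least 2", call. = FALSE)
  }
  if (nrow(pk) > multiplicity) {
    pk <- pk[order(pk$height, decreasing = TRUE)[seq_len(multiplicity)], ]
  }
  pk <- pk[order(pk$pos_hz), ]
  spac <- diff(pk$pos_hz)
  ax <- slice$coords[["f1"]]
  list(j_hz = mean(spac), spacings_hz = spac,
       uncertainty_hz = ax[2] - ax[1], peaks = pk)
}

#' Reference the ppm axis from a known peak
#'
#' Picks the skyline peaks and sets the ppm offset so the chosen peak lands
#' on `ref_ppm`. The default rule follows common practice for ethyl
#' crotonate: the most upfield resolved resonance is the ester methyl at
#' 1.28 ppm.
#'
#' @param result a [jres_result] (sheared/symmetrized preferably).
#' @param ref_ppm literature shift assigned to the reference peak.
#' @param rule `"most_upfield"` (lowest-frequency skyline peak) or
#'   `"tallest"`.
#' @param threshold_frac skyline peak-picking threshold.
#' @return the result with `ref_ppm_offset` set (pure axis relabelling; the
#'   data are untouched).
#' @export
reference_ppm <- function(result, ref_ppm = 1.28,
                          rule = c("most_upfield", "tallest"),
                          threshold_frac = 0.1) {
  rule <- match.arg(rule)
  stopifnot(inherits(result, "jres_result"))
  sky <- skyline_projection(result)
  pk <- pick_peaks(sky, threshold_frac = threshold_frac)
  if (nrow(pk) == 0L) stop("no skyline peaks to reference on", call. = FALSE)
  hz <- switch(rule,
               most_upfield = min(pk$pos_hz),
               tallest = pk$pos_hz[which.max(pk$height)])
  result$ref_ppm_offset <- ref_ppm - hz / result$f0_MHz
  result$log <- c(result$log,
                  list(list(op = "reference_ppm",
                            params = list(ref_ppm = ref_ppm, rule = rule))))
  result
}
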