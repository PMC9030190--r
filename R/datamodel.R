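#' n-dimensional complex NMR dataset
#'
#' The common currency of every processing stage: a complex array with named
#' dimensions, one coordinate axis per dimension, and a metadata map. The
#' metadata map carries the spectrometer frequency, a domain tag per dimension
#' (`"time"` or `"frequency"`), a units tag per axis (`"s"`, `"Hz"` or
#' `"ppm"`), the ppm referencing offset, and an append-only provenance log of
#' applied operations.
#'
#' @param values complex (or numeric, promoted to complex) array or vector.
#' @param dims character vector of dimension names, one per array dimension
#'   (e.g. `c("t2", "t1")`). A bare vector is treated as one-dimensional.
#' @param coords named list of numeric axes, one per entry of `dims`; each
#'   axis must be strictly monotonic and match the corresponding extent.
#' @param attrs named list of metadata. Recognised keys: `f0_MHz`, `domain`
#'   (named character, one tag per dimension), `units` (named character, one
#'   tag per axis), `ref_ppm_offset`, `provenance` (list). Missing keys are
#'   filled with defaults (`domain` inferred from `units`, empty provenance).
#' @return an object of class `nmr_dataset`.
#' @examples
#' grid <- acquisition_grid(dwell_s = 2e-4, n_points = 256)
#' t <- make_time_axis(grid)
#' ds <- nmr_dataset(exp(-t) * exp(2i * pi * 50 * t), "t2",
#'                   coords = list(t2 = t),
#'                   attrs = list(f0_MHz = grid$f0_MHz))
#' @export
nmr_dataset <- function(values, dims, coords, attrs = list()) {
  if (is.null(dim(values))) {
    values <- array(as.complex(values), dim = length(values))
  } else {
    values <- array(as.complex(values), dim = dim(values))
  }
  if (length(values) == 0L) {
    stop("nmr_dataset: empty values array", call. = FALSE)
  }
  dims <- as.character(dims)
  attrs <- fill_default_attrs(dims, coords, attrs)
  ds <- structure(
    list(values = values, dims = dims, coords = coords, attrs = attrs),
    class = "nmr_dataset"
  )
  validate_nmr_dataset(ds)
  ds
}

fill_default_attrs <- function(dims, coords, attrs) {
  if (is.null(attrs$units)) {
    attrs$units <- stats::setNames(rep("s", length(dims)), dims)
  }
  if (is.null(attrs$domain)) {
    attrs$domain <- stats::setNames(
      ifelse(attrs$units[dims] %in% c("Hz", "ppm"), "frequency", "time"), dims
    )
  }
  if (is.null(attrs$ref_ppm_offset)) attrs$ref_ppm_offset <- 0
  if (is.null(attrs$provenance)) attrs$provenance <- list()
  attrs
}

#' Validate an `nmr_dataset` against its structural invariants
#'
#' Checks dimension/axis bookkeeping: one named, strictly monotonic axis per
#' array extent, matching lengths, and domain tags consistent with axis units
#' (seconds for time dimensions, Hz or ppm for frequency dimensions).
#'
#' @param ds an `nmr_dataset`.
#' @return `ds`, invisibly; errors describe the first violated invariant.
#' @export
validate_nmr_dataset <- function(ds) {
  stopifnot(inherits(ds, "nmr_dataset"))
  extents <- dim(ds$values)
  if (length(extents) != length(ds$dims)) {
    stop("dims length (", length(ds$dims), ") != array rank (",
         length(extents), ")", call. = FALSE)
  }
  if (!setequal(names(ds$coords), ds$dims)) {
    stop("coords must carry exactly one axis per dimension", call. = FALSE)
  }
  for (i in seq_along(ds$dims)) {
    d <- ds$dims[i]
    ax <- ds$coords[[d]]
    if (length(ax) != extents[i]) {
      stop("axis '", d, "' length ", length(ax),
           " != extent ", extents[i], call. = FALSE)
    }
    if (length(ax) > 1L) {
      dax <- diff(ax)
      if (!(all(dax > 0) || all(dax < 0))) {
        stop("axis '", d, "' is not strictly monotonic", call. = FALSE)
      }
    }
    dom <- ds$attrs$domain[[d]]
    un <- ds$attrs$units[[d]]
    if (!is.null(dom) && !is.null(un)) {
      ok <- (dom == "time" && un == "s") ||
        (dom == "frequency" && un %in% c("Hz", "ppm"))
      if (!ok) {
        stop("axis '", d, "': domain tag '", dom,
             "' inconsistent with units '", un, "'", call. = FALSE)
      }
    }
  }
  invisible(ds)
}

#' @export
print.nmr_dataset <- function(x, ...) {
  cat("<nmr_dataset> ", paste0(x$dims, "[", dim(x$values), "]",
                               collapse = " x "), "\n", sep = "")
  for (d in x$dims) {
    ax <- x$coords[[d]]
    cat(sprintf("  %s: %s, %s, [%g, %g]\n", d,
                x$attrs$domain[[d]], x$attrs$units[[d]], min(ax), max(ax)))
  }
  if (!is.null(x$attrs$f0_MHz)) {
    cat(sprintf("  f0 = %g MHz\n", x$attrs$f0_MHz))
  }
  n_ops <- length(x$attrs$provenance)
  if (n_ops > 0L) {
    ops <- vapply(x$attrs$provenance, function(e) e$op, character(1))
    cat("  provenance:", paste(ops, collapse = " -> "), "\n")
  }
  invisible(x)
}

# Append an operation record to the provenance log (append-only by
# construction: existing entries are never touched).
nd_log <- function(ds, op, params = list()) {
  ds$attrs$provenance <- c(ds$attrs$provenance,
                           list(list(op = op, params = params)))
  ds
}

dim_index <- function(ds, dim) {
  i <- match(dim, ds$dims)
  if (is.na(i)) stop("no dimension named '", dim, "'", call. = FALSE)
  i
}

# Apply a function along one dimension of the values array. f maps a vector
# of length n to a vector (possibly of different length n_out).
apply_along <- function(values, i, f) {
  nd <- length(dim(values))
  if (nd == 1L) {
    out <- f(as.vector(values))
    return(array(out, dim = length(out)))
  }
  perm <- c(i, seq_len(nd)[-i])
  v <- aperm(values, perm)
  d <- dim(v)
  m <- matrix(v, nrow = d[1])
  cols <- lapply(seq_len(ncol(m)), function(j) f(m[, j]))
  m2 <- matrix(unlist(cols), ncol = ncol(m))
  d2 <- d
  d2[1] <- nrow(m2)
  v2 <- array(m2, dim = d2)
  aperm(v2, order(perm))
}

#' Acquisition grid for the direct dimension
#'
#' Bundles the sampling parameters of one acquisition: dwell time, number of
#' complex points, receiver dead time, transmitter frequency, carrier
#' position, and repetition time.
#'
#' @param dwell_s dwell time in seconds (> 0).
#' @param n_points number of complex points (>= 2).
#' @param dead_time_s receiver dead time in seconds (delay between excitation
#'   and the first acquired point); converts field drift into a
#'   frequency-domain linear phase roll.
#' @param f0_MHz proton transmitter frequency in MHz.
#' @param carrier_ppm chemical shift of the transmitter (axis centre), ppm.
#' @param rep_time_s repetition time per scan in seconds.
#' @param timestamps_s optional wall-clock time of each transient (strictly
#'   increasing).
#' @return an object of class `acquisition_grid`.
#' @export
acquisition_grid <- function(dwell_s, n_points, dead_time_s = 0,
                             f0_MHz = 14.7945, carrier_ppm = 4.0,
                             rep_time_s = 2.5, timestamps_s = NULL) {
  if (!is.numeric(dwell_s) || dwell_s <= 0) {
    stop("invalid grid: dwell_s must be > 0", call. = FALSE)
  }
  if (n_points < 2) stop("invalid grid: n_points must be >= 2", call. = FALSE)
  if (f0_MHz <= 0) stop("invalid grid: f0_MHz must be > 0", call. = FALSE)
  if (!is.null(timestamps_s) && any(diff(timestamps_s) <= 0)) {
    stop("invalid grid: timestamps must be strictly increasing", call. = FALSE)
  }
  structure(list(dwell_s = dwell_s, n_points = as.integer(n_points),
                 dead_time_s = dead_time_s, f0_MHz = f0_MHz,
                 carrier_ppm = carrier_ppm, rep_time_s = rep_time_s,
                 timestamps_s = timestamps_s),
            class = "acquisition_grid")
}

#' Time axis of an acquisition grid
#'
#' @param grid an [acquisition_grid()].
#' @return numeric vector `(0, dwell, 2 dwell, ..., (n-1) dwell)` seconds.
#' @export
make_time_axis <- function(grid) {
  stopifnot(inherits(grid, "acquisition_grid"))
  (seq_len(grid$n_points) - 1) * grid$dwell_s
}

#' Zero-centred frequency axis for an FFT of given length
#'
#' Spectral width is `1/dwell`; spacing is `1/(n_fft * dwell)`. The axis is
#' ascending and centred on 0 Hz (the transmitter), running from `-SW/2` to
#' `SW/2 - df` for even `n_fft`.
#'
#' @param grid an [acquisition_grid()].
#' @param n_fft transform length (>= `n_points`); defaults to `n_points`.
#' @return numeric frequency axis in Hz.
#' @export
make_frequency_axis <- function(grid, n_fft = grid$n_points) {
  stopifnot(inherits(grid, "acquisition_grid"))
  if (n_fft < grid$n_points) {
    stop("n_fft (", n_fft, ") < n_points (", grid$n_points, ")",
         call. = FALSE)
  }
  fft_freq_axis(n_fft, grid$dwell_s)
}

# Zero-centred ascending axis for an n-point FFT sampled at interval dwell.
fft_freq_axis <- function(n, dwell) {
  df <- 1 / (n * dwell)
  (seq_len(n) - 1 - floor(n / 2)) * df
}

#' Convert a Hz axis to ppm
#'
#' Pure affine relabelling `ppm = Hz / f0 + offset`; the data are never
#' shifted, so referencing stays exactly reversible. The offset is normally
#' chosen so a designated peak lands on its literature shift (for ethyl
#' crotonate, the methyl protons at 1.28 ppm).
#'
#' @param axis_Hz numeric axis in Hz (zero = transmitter).
#' @param f0_MHz transmitter frequency in MHz (> 0).
#' @param ref_ppm_offset additive ppm offset (default 0).
#' @return numeric axis in ppm.
#' @seealso [ppm_axis_to_hz()] for the exact inverse.
#' @export
hz_axis_to_ppm <- function(axis_Hz, f0_MHz, ref_ppm_offset = 0) {
  if (f0_MHz <= 0) stop("f0_MHz must be > 0", call. = FALSE)
  axis_Hz / f0_MHz + ref_ppm_offset
}

#' Inverse of [hz_axis_to_ppm()]
#' @inheritParams hz_axis_to_ppm
#' @param axis_ppm numeric axis in ppm.
#' @return numeric axis in Hz.
#' @export
ppm_axis_to_hz <- function(axis_ppm, f0_MHz, ref_ppm_offset = 0) {
  if (f0_MHz <= 0) stop("f0_MHz must be > 0", call. = FALSE)
  (axis_ppm - ref_ppm_offset) * f0_MHz
}
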