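#' Weak-coupling spin system
#'
#' A list of proton sites, each with a chemical shift, an equivalent-proton
#' count, a homogeneous linewidth, and first-order scalar couplings to other
#' sites. Couplings must be declared symmetrically (if A lists B at J Hz,
#' B must list A at the same J).
#'
#' @param sites list of [site()] objects.
#' @return an object of class `spin_system`.
#' @export
spin_system <- function(sites) {
  labels <- vapply(sites, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("site labels must be unique", call. = FALSE)
  names(sites) <- labels
  for (s in sites) {
    for (cp in s$couplings) {
      if (cp$J_hz < 0) stop("J_hz must be >= 0", call. = FALSE)
      p <- sites[[cp$partner]]
      if (is.null(p)) {
        stop("site '", s$label, "' couples to unknown partner '",
             cp$partner, "'", call. = FALSE)
      }
      back <- Filter(function(b) b$partner == s$label, p$couplings)
      if (length(back) == 0L || abs(back[[1]]$J_hz - cp$J_hz) > 1e-12) {
        stop("asymmetric coupling between '", s$label, "' and '",
             cp$partner, "'", call. = FALSE)
      }
    }
  }
  structure(list(sites = sites), class = "spin_system")
}

#' Proton site of a [spin_system()]
#'
#' @param label unique site label (e.g. `"A"`).
#' @param shift_ppm chemical shift in ppm.
#' @param n_equiv number of magnetically equivalent protons (>= 1).
#' @param r2_hz homogeneous linewidth as the full width at half maximum of
#'   the corresponding Lorentzian line, in Hz (decay `exp(-pi * r2 * t)`).
#'   Includes any paramagnetic broadening from the polarizing agent.
#' @param couplings list of [coupling()] entries.
#' @export
site <- function(label, shift_ppm, n_equiv = 1L, r2_hz = 1,
                 couplings = list()) {
  stopifnot(n_equiv >= 1, r2_hz >= 0)
  list(label = label, shift_ppm = shift_ppm, n_equiv = as.integer(n_equiv),
       r2_hz = r2_hz, couplings = couplings)
}

#' Scalar coupling of a [site()] to a partner group
#'
#' @param partner label of the coupled site.
#' @param J_hz coupling constant in Hz (>= 0).
#' @param n_partner number of equivalent protons in the partner group; the
#'   coupling contributes `cos(pi J t)^n_partner` to the FID envelope,
#'   generating the binomial multiplet (doublet, triplet, quartet, ...).
#' @export
coupling <- function(partner, J_hz, n_partner = 1L) {
  list(partner = partner, J_hz = J_hz, n_partner = as.integer(n_partner))
}

#' Field drift model
#'
#' Describes the magnet's chemical-shift drift as a function of wall-clock
#' time, `delta_ppm(tau)` with `delta_ppm(0) = 0`. The permanent-magnet
#' fixture emulated here settles exponentially once the temperature
#' regulation is switched off for acquisition.
#'
#' @param kind one of `"none"`, `"linear"`, `"exponential"`, `"polynomial"`,
#'   `"table"`.
#' @param rate_ppm_per_s linear drift rate (kind `"linear"`).
#' @param span_ppm total drift accumulated over `t_span_s` (kind
#'   `"exponential"`): `delta(tau) = span (1 - exp(-tau/tau_s)) /
#'   (1 - exp(-t_span/tau_s))`.
#' @param tau_s exponential time constant in seconds.
#' @param t_span_s window over which `span_ppm` is accumulated, seconds.
#' @param coeffs polynomial coefficients `c(c1, c2, ...)` of
#'   `c1 tau + c2 tau^2 + ...` (no constant term, so `delta(0) = 0`).
#' @param times_s,values_ppm lookup table (kind `"table"`), linearly
#'   interpolated; `values_ppm[1]` must be 0.
#' @return an object of class `drift_model`.
#' @export
drift_model <- function(kind = c("none", "linear", "exponential",
                                 "polynomial", "table"),
                        rate_ppm_per_s = NULL, span_ppm = NULL, tau_s = NULL,
                        t_span_s = NULL, coeffs = NULL, times_s = NULL,
                        values_ppm = NULL) {
  kind <- match.arg(kind)
  m <- list(kind = kind)
  if (kind == "linear") {
    stopifnot(!is.null(rate_ppm_per_s))
    m$rate_ppm_per_s <- rate_ppm_per_s
  } else if (kind == "exponential") {
    stopifnot(!is.null(span_ppm), !is.null(tau_s), !is.null(t_span_s),
              tau_s > 0, t_span_s > 0)
    m$span_ppm <- span_ppm
    m$tau_s <- tau_s
    m$t_span_s <- t_span_s
  } else if (kind == "polynomial") {
    stopifnot(!is.null(coeffs))
    m$coeffs <- coeffs
  } else if (kind == "table") {
    stopifnot(!is.null(times_s), !is.null(values_ppm),
              length(times_s) == length(values_ppm))
    if (abs(values_ppm[1]) > 0) {
      stop("table drift must start at 0 ppm", call. = FALSE)
    }
    m$times_s <- times_s
    m$values_ppm <- values_ppm
  }
  structure(m, class = "drift_model")
}

#' Evaluate a [drift_model()] at wall-clock times
#'
#' @param model a `drift_model`.
#' @param tau_s numeric vector of times in seconds.
#' @return drift in ppm, with `drift_ppm(model, 0) == 0`.
#' @export
drift_ppm <- function(model, tau_s) {
  stopifnot(inherits(model, "drift_model"))
  switch(model$kind,
    none = rep(0, length(tau_s)),
    linear = model$rate_ppm_per_s * tau_s,
    exponential = model$span_ppm * (1 - exp(-tau_s / model$tau_s)) /
      (1 - exp(-model$t_span_s / model$tau_s)),
    polynomial = {
      out <- rep(0, length(tau_s))
      for (k in seq_along(model$coeffs)) {
        out <- out + model$coeffs[k] * tau_s^k
      }
      out
    },
    table = stats::approx(model$times_s, model$values_ppm, xout = tau_s,
                          rule = 2)$y
  )
}

#' Phase cycle of the spin-echo refocusing pulse
#'
#' Default is the four-step EXORCYCLE: refocusing-pulse phases 0/90/180/270
#' degrees with receiver signs +,-,+,-. An ideal echo acquires phase `2 phi`
#' from a refocusing pulse of phase `phi`, so the signed sum retains the echo
#' while cancelling non-refocused artifacts.
#'
#' @param pulse_phases_deg refocusing-pulse phase per step, degrees.
#' @param receiver_sign receiver sign per step (+1/-1); artifact-cancelling
#'   cycles have signs summing to zero.
#' @export
phase_cycle <- function(pulse_phases_deg = c(0, 90, 180, 270),
                        receiver_sign = c(1, -1, 1, -1)) {
  stopifnot(length(pulse_phases_deg) == length(receiver_sign),
            all(receiver_sign %in% c(-1, 1)))
  structure(list(n_steps = length(pulse_phases_deg),
                 pulse_phases_deg = pulse_phases_deg,
                 receiver_sign = receiver_sign),
            class = "phase_cycle")
}

#' Indirect-dimension schedule of a JRES acquisition
#'
#' The indirect evolution time is the full echo time: `t1_i = 2 tau0 + i dt1`
#' for `i = 0, ..., n_t1 - 1`, giving an indirect spectral width of `1/dt1`.
#'
#' @param n_t1 number of indirect points (>= 2).
#' @param dt1_s increment of the indirect delay, seconds.
#' @param tau0_s initial inter-pulse delay (half the initial echo time),
#'   seconds.
#' @param n_dummy dummy scans before each t1 step (equilibrate, not stored).
#' @param interleave_reference acquire a 1D reference scan after each
#'   completed phase cycle (interleaved spectral referencing).
#' @export
jres_schedule <- function(n_t1 = 128L, dt1_s = 8e-3, tau0_s = 3e-3,
                          n_dummy = 2L, interleave_reference = TRUE) {
  stopifnot(n_t1 >= 2, dt1_s > 0, tau0_s >= 0, n_dummy >= 0)
  structure(list(n_t1 = as.integer(n_t1), dt1_s = dt1_s, tau0_s = tau0_s,
                 n_dummy = as.integer(n_dummy),
                 interleave_reference = isTRUE(interleave_reference)),
            class = "jres_schedule")
}

#' t1 axis of a [jres_schedule()]
#' @param schedule a `jres_schedule`.
#' @return echo times `2 tau0 + i dt1`, seconds.
#' @export
t1_axis <- function(schedule) {
  2 * schedule$tau0_s + (seq_len(schedule$n_t1) - 1) * schedule$dt1_s
}

# Complex FID of one site evaluated on direct-time axis t2, with the
# J-modulation and decay clocks offset by t_extra (0 for a plain FID,
# t1_i for a spin echo where shift evolution is refocused but J and
# relaxation evolve over the whole echo).
site_fid <- function(s, f_hz, t2, t_extra = 0) {
  tc <- t2 + t_extra
  env <- exp(-pi * s$r2_hz * tc)
  for (cp in s$couplings) {
    env <- env * cos(pi * cp$J_hz * tc)^cp$n_partner
  }
  s$n_equiv * env * exp(2i * pi * f_hz * t2)
}

site_offsets_hz <- function(spins, grid) {
  vapply(spins$sites,
         function(s) (s$shift_ppm - grid$carrier_ppm) * grid$f0_MHz,
         numeric(1))
}

check_aliasing <- function(spins, grid) {
  f <- site_offsets_hz(spins, grid)
  sw <- 1 / grid$dwell_s
  bad <- abs(f) > sw / 2
  if (any(bad)) {
    warning("site(s) ", paste(names(f)[bad], collapse = ", "),
            " fall outside the spectral width (", sw, " Hz) and will alias",
            call. = FALSE)
  }
}

#' Synthesise a 1D FID from a weak-coupling spin system
#'
#' Each site contributes
#' `A n_equiv exp(2i pi f t) prod_c cos(pi J_c t)^{n_c} exp(-pi r2 t)` with
#' `f = (shift - carrier) f0`. The cosine product generates the binomial
#' multiplets (1:1 doublet, 1:2:1 triplet, 1:3:3:1 quartet) without
#' enumerating individual transitions.
#'
#' @param spins a [spin_system()].
#' @param grid an [acquisition_grid()].
#' @param amp_scale overall amplitude factor `A`; a signed Overhauser
#'   enhancement may be folded in here.
#' @return a time-domain [nmr_dataset()] with dimension `"t2"`.
#' @export
synth_fid_1d <- function(spins, grid, amp_scale = 1) {
  stopifnot(inherits(spins, "spin_system"))
  check_aliasing(spins, grid)
  t2 <- make_time_axis(grid)
  f <- site_offsets_hz(spins, grid)
  sig <- complex(length(t2))
  for (i in seq_along(spins$sites)) {
    sig <- sig + site_fid(spins$sites[[i]], f[i], t2)
  }
  ds <- nmr_dataset(amp_scale * sig, "t2", coords = list(t2 = t2),
                    attrs = list(f0_MHz = grid$f0_MHz,
                                 carrier_ppm = grid$carrier_ppm,
                                 dead_time_s = grid$dead_time_s,
                                 units = c(t2 = "s")))
  nd_log(ds, "synth_fid_1d", list(amp_scale = amp_scale))
}

#' Synthesise a noiseless JRES echo set
#'
#' For each indirect time `t1_i = 2 tau0 + i dt1`, the echo refocuses
#' chemical-shift evolution (shift evolves only during `t2`) while scalar
#' couplings and relaxation evolve over the whole echo (`t1_i + t2`):
#' `s(t1_i, t2) = sum_sites A n exp(2i pi f t2)
#'   prod_c cos(pi J (t1_i + t2))^{n_c} exp(-pi r2 (t1_i + t2))`.
#'
#' @inheritParams synth_fid_1d
#' @param schedule a [jres_schedule()].
#' @param pulse_phase_deg refocusing-pulse phase; the ideal echo acquires
#'   `exp(2i phi)`.
#' @return a time-domain [nmr_dataset()] with dimensions `c("t2", "t1")`.
#' @export
synth_jres_echo <- function(spins, grid, schedule, amp_scale = 1,
                            pulse_phase_deg = 0) {
  stopifnot(inherits(spins, "spin_system"), inherits(schedule, "jres_schedule"))
  check_aliasing(spins, grid)
  t2 <- make_time_axis(grid)
  t1 <- t1_axis(schedule)
  f <- site_offsets_hz(spins, grid)
  ph <- exp(2i * pulse_phase_deg * pi / 180)
  vals <- matrix(0i, nrow = length(t2), ncol = length(t1))
  for (j in seq_along(t1)) {
    sig <- complex(length(t2))
    for (i in seq_along(spins$sites)) {
      sig <- sig + site_fid(spins$sites[[i]], f[i], t2, t_extra = t1[j])
    }
    vals[, j] <- amp_scale * ph * sig
  }
  ds <- nmr_dataset(vals, c("t2", "t1"),
                    coords = list(t2 = t2, t1 = t1),
                    attrs = list(f0_MHz = grid$f0_MHz,
                                 carrier_ppm = grid$carrier_ppm,
                                 dead_time_s = grid$dead_time_s,
                                 units = c(t2 = "s", t1 = "s")))
  nd_log(ds, "synth_jres_echo", list(n_t1 = schedule$n_t1))
}

#' Impose field drift on stored transients
#'
#' Transient `j`, acquired at wall-clock time `tau_j` (the `"transient"`
#' coordinate axis), is multiplied by
#' `exp(2i pi df_j (t + dead_time))` with `df_j = delta(tau_j) f0` in Hz.
#' The `dead_time` term is what turns field drift into the frequency-domain
#' linear phase roll seen on drifting permanent magnets.
#'
#' @param ds time-domain [nmr_dataset()] whose first dimension is the direct
#'   time axis and which carries a `"transient"` dimension whose coordinate
#'   axis is the wall-clock timestamp of each transient.
#' @param grid the [acquisition_grid()] (supplies `f0_MHz`, `dead_time_s`).
#' @param model a [drift_model()].
#' @return the drifted dataset.
#' @export
apply_drift <- function(ds, grid, model) {
  stopifnot(inherits(ds, "nmr_dataset"), inherits(model, "drift_model"))
  if (model$kind == "none") {
    return(nd_log(ds, "apply_drift", list(kind = "none")))
  }
  if (!"transient" %in% ds$dims) {
    stop("apply_drift: dataset has no 'transient' dimension with timestamps",
         call. = FALSE)
  }
  if (!identical(ds$dims, c("t2", "transient"))) {
    stop("apply_drift expects dims c('t2', 'transient')", call. = FALSE)
  }
  tau <- ds$coords[["transient"]]
  t2 <- ds$coords[["t2"]]
  df_hz <- drift_ppm(model, tau) * grid$f0_MHz
  # outer(t2 + dead, df) gives the per-point modulation phase per transient
  phase <- 2 * pi * outer(t2 + grid$dead_time_s, df_hz)
  ds$values <- ds$values * exp(1i * phase)
  nd_log(ds, "apply_drift", list(kind = model$kind))
}

#' Add complex Gaussian noise
#'
#' Independent Gaussian noise of standard deviation `sigma` per quadrature,
#' reproducible under a fixed seed.
#'
#' @param ds an [nmr_dataset()].
#' @param sigma noise standard deviation per quadrature (>= 0).
#' @param seed integer seed.
#' @return the noisy dataset.
#' @export
add_noise <- function(ds, sigma, seed = 1L) {
  stopifnot(inherits(ds, "nmr_dataset"))
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(nd_log(ds, "add_noise", list(sigma = 0)))
  n <- length(ds$values)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  nz <- complex(real = stats::rnorm(n, sd = sigma),
                imaginary = stats::rnorm(n, sd = sigma))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  ds$values <- ds$values + array(nz, dim = dim(ds$values))
  nd_log(ds, "add_noise", list(sigma = sigma, seed = seed))
}

#' Simulate a full interleaved JRES experiment
#'
#' Emits every phase-cycle transient separately (so that drift correction can
#' be applied before phase-cycle combination), advances the wall clock by the
#' repetition time for every scan including dummy scans, and appends one 1D
#' reference scan after each completed phase cycle when the schedule asks for
#' interleaved referencing. With the default four-step cycle, the references
#' add 1/5 = 20 % acquisition overhead.
#'
#' @inheritParams synth_jres_echo
#' @param cycle a [phase_cycle()].
#' @param drift a [drift_model()].
#' @param noise_sigma Gaussian noise per quadrature (0 = noiseless).
#' @param seed integer seed for the noise streams.
#' @param ref_grid [acquisition_grid()] used for the 1D reference scans;
#'   defaults to the JRES grid with 8192 points and a 2 s repetition time.
#' @return a list with elements
#'   `transients` (dims `c("t2","transient")`, transient axis = timestamps;
#'   per-transient `t1_index`, `cycle_step`, `receiver_sign` and
#'   `t1_values_s` in `attrs`), `references` (dims `c("t2","transient")`),
#'   and `truth` (injected drift at every stored timestamp, site offsets,
#'   spin/schedule/cycle parameters) for recovery tests.
#' @export
run_experiment <- function(spins, grid, schedule, cycle = phase_cycle(),
                           drift = drift_model("none"), noise_sigma = 0,
                           seed = 1L, ref_grid = NULL) {
  stopifnot(inherits(spins, "spin_system"), inherits(grid, "acquisition_grid"),
            inherits(schedule, "jres_schedule"), inherits(cycle, "phase_cycle"))
  if (is.null(ref_grid)) {
    ref_grid <- acquisition_grid(dwell_s = grid$dwell_s, n_points = 8192L,
                                 dead_time_s = grid$dead_time_s,
                                 f0_MHz = grid$f0_MHz,
                                 carrier_ppm = grid$carrier_ppm,
                                 rep_time_s = 2.0)
  }
  t2 <- make_time_axis(grid)
  t1 <- t1_axis(schedule)
  f <- site_offsets_hz(spins, grid)

  n_steps <- cycle$n_steps
  n_tr <- schedule$n_t1 * n_steps
  trans <- matrix(0i, nrow = length(t2), ncol = n_tr)
  tr_time <- numeric(n_tr)
  tr_t1 <- integer(n_tr)
  tr_step <- integer(n_tr)

  n_ref <- if (schedule$interleave_reference) schedule$n_t1 else 0L
  t2r <- make_time_axis(ref_grid)
  refs <- if (n_ref > 0) matrix(0i, nrow = length(t2r), ncol = n_ref)
  ref_time <- numeric(n_ref)
  base_ref <- {
    sig <- complex(length(t2r))
    fr <- site_offsets_hz(spins, ref_grid)
    for (i in seq_along(spins$sites)) {
      sig <- sig + site_fid(spins$sites[[i]], fr[i], t2r)
    }
    sig
  }

  clock <- 0
  k <- 0L
  for (j in seq_len(schedule$n_t1)) {
    clock <- clock + schedule$n_dummy * grid$rep_time_s
    # base echo at this t1, phase-cycle factor applied per step
    sig0 <- complex(length(t2))
    for (i in seq_along(spins$sites)) {
      sig0 <- sig0 + site_fid(spins$sites[[i]], f[i], t2, t_extra = t1[j])
    }
    for (st in seq_len(n_steps)) {
      k <- k + 1L
      ph <- exp(2i * cycle$pulse_phases_deg[st] * pi / 180)
      df <- drift_ppm(drift, clock) * grid$f0_MHz
      trans[, k] <- sig0 * ph *
        exp(2i * pi * df * (t2 + grid$dead_time_s))
      tr_time[k] <- clock
      tr_t1[k] <- j
      tr_step[k] <- st
      clock <- clock + grid$rep_time_s
    }
    if (schedule$interleave_reference) {
      dfr <- drift_ppm(drift, clock) * ref_grid$f0_MHz
      refs[, j] <- base_ref * exp(2i * pi * dfr * (t2r + ref_grid$dead_time_s))
      ref_time[j] <- clock
      clock <- clock + ref_grid$rep_time_s
    }
  }

  transients <- nmr_dataset(
    trans, c("t2", "transient"),
    coords = list(t2 = t2, transient = tr_time),
    attrs = list(f0_MHz = grid$f0_MHz, carrier_ppm = grid$carrier_ppm,
                 dead_time_s = grid$dead_time_s,
                 t1_index = tr_t1, cycle_step = tr_step,
                 receiver_sign = cycle$receiver_sign[tr_step],
                 t1_values_s = t1,
                 units = c(t2 = "s", transient = "s")))
  transients <- nd_log(transients, "run_experiment",
                       list(n_t1 = schedule$n_t1, n_steps = n_steps,
                            drift = drift$kind))
  references <- NULL
  if (n_ref > 0) {
    references <- nmr_dataset(
      refs, c("t2", "transient"),
      coords = list(t2 = t2r, transient = ref_time),
      attrs = list(f0_MHz = ref_grid$f0_MHz,
                   carrier_ppm = ref_grid$carrier_ppm,
                   dead_time_s = ref_grid$dead_time_s,
                   units = c(t2 = "s", transient = "s")))
    references <- nd_log(references, "run_experiment_reference", list())
  }
  if (noise_sigma > 0) {
    transients <- add_noise(transients, noise_sigma, seed = seed)
    if (!is.null(references)) {
      references <- add_noise(references, noise_sigma, seed = seed + 1L)
    }
  }
  list(transients = transients,
       references = references,
       truth = list(drift_ppm_transients = drift_ppm(drift, tr_time),
                    drift_ppm_references = drift_ppm(drift, ref_time),
                    site_offsets_hz = f,
                    spins = spins, schedule = schedule, cycle = cycle,
                    grid = grid, ref_grid = ref_grid, drift = drift))
}
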