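# Independent oracles and small shared fixtures for the test suite.

# Brute-force transition enumeration for one site: average the phase factors
# over every combination of partner spin states (each partner proton +/-1/2)
# instead of using the cosine-product identity. Used to cross-check the
# simulator's closed-form FID.
enum_site_fid <- function(s, f_hz, t2, t_extra = 0) {
  offsets <- 0
  for (cp in s$couplings) {
    for (k in seq_len(cp$n_partner)) {
      offsets <- as.vector(outer(offsets, c(cp$J_hz / 2, -cp$J_hz / 2), `+`))
    }
  }
  tc <- t2 + t_extra
  mod <- rowMeans(vapply(offsets,
                         function(o) exp(2i * pi * o * tc),
                         complex(length(tc))))
  s$n_equiv * mod * exp(-pi * s$r2_hz * tc) * exp(2i * pi * f_hz * t2)
}

# Single decaying complex exponential: a Lorentzian line of FWHM r2_hz at
# offset f_hz, the workhorse synthetic input for linewidth checks.
lorentzian_fid <- function(grid, f_hz, r2_hz, amp = 1) {
  t <- make_time_axis(grid)
  nmr_dataset(amp * exp(2i * pi * f_hz * t) * exp(-pi * r2_hz * t), "t2",
              coords = list(t2 = t),
              attrs = list(f0_MHz = grid$f0_MHz, units = c(t2 = "s")))
}

# Magnitude spectrum + axis of a 1D dataset through the standard chain.
quick_spectrum <- function(ds, zf = 2) {
  sp <- fourier_transform(zero_fill(ds, factor = zf))
  list(axis = sp$coords[[sp$dims[1]]], mag = Mod(as.vector(sp$values)),
       ds = sp)
}

small_grid <- function(n = 512, dwell = 2e-4, dead = 0) {
  acquisition_grid(dwell_s = dwell, n_points = n, dead_time_s = dead)
}

# Scaled-down but complete interleaved JRES study used by several deep
# tests; same physics as the full acquisition, quarter-size grids.
small_study <- function(correct_drift = TRUE, drift = fixture_drift(),
                        n_points = 1024, n_t1 = 64) {
  spins <- ethyl_crotonate_fixture()
  grid <- acquisition_grid(2e-4, n_points, dead_time_s = 1e-3)
  sched <- jres_schedule(n_t1 = n_t1)
  ref_grid <- acquisition_grid(2e-4, 2 * n_points, dead_time_s = 1e-3,
                               rep_time_s = 2)
  # pure Gaussian on t2: the short scaled-down acquisition would truncate
  # under the growing Lorentz-Gauss envelope used at full length
  suppressWarnings(
    jres_pipeline(spins, grid, sched, drift = drift, ref_grid = ref_grid,
                  correct_drift = correct_drift,
                  window_t2 = window_spec("gauss", gb_hz = 4))
  )
}

fixture_drift <- function() {
  drift_model("exponential", span_ppm = 60, tau_s = 1200, t_span_s = 1800)
}
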