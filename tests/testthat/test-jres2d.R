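# Short acquisitions truncate under a growing Lorentz-Gauss envelope, so
# these scaled-down structural tests apodize t2 with a plain Gaussian.
make_echo_result <- function(spins, n_points = 512, n_t1 = 64,
                             window_t1 = window_spec("gauss", gb_hz = 2)) {
  g <- small_grid(n_points)
  sched <- jres_schedule(n_t1 = n_t1)
  ds <- synth_jres_echo(spins, g, sched)
  process_jres(ds, window_t2 = window_spec("gauss", gb_hz = 3),
               window_t1 = window_t1)
}

# Longer acquisition + matched Lorentz-Gauss: negligible truncation ripple,
# clean lineshapes for position/integral assertions.
make_clean_result <- function(spins, n_t1 = 64) {
  g <- small_grid(2048)
  ds <- synth_jres_echo(spins, g, jres_schedule(n_t1 = n_t1))
  res <- process_jres(ds,
                      window_t2 = window_spec("lorentz_gauss",
                                              lb_hz = 3.1, gb_hz = 3),
                      window_t1 = window_spec("lorentz_gauss",
                                              lb_hz = 3.1, gb_hz = 2))
  symmetrize_geometric(shear(res))
}

make_singlet_result <- function() {
  res <- symmetrize_geometric(shear(make_echo_result(water_fixture())))
  res$ref_ppm_offset <- 4.7 - res$f2_hz[which.max(
    apply(res$magnitude, 1, max))] / res$f0_MHz
  res
}

test_that("2D processing doubles both dimensions and keeps zeros zero", {
  g <- small_grid(256)
  sched <- jres_schedule(n_t1 = 16)
  ds <- synth_jres_echo(water_fixture(), g, sched)
  res <- process_jres(ds)
  expect_equal(dim(res$magnitude), c(512, 32))
  expect_error(process_jres(synth_fid_1d(water_fixture(), g)), "t2")

  z <- nmr_dataset(matrix(0i, 64, 8) + 0i, c("t2", "t1"),
                   coords = list(t2 = (0:63) * 2e-4, t1 = (0:7) * 8e-3),
                   attrs = list(units = c(t2 = "s", t1 = "s")))
  z$values[] <- 0i
  expect_true(all(process_jres(z)$magnitude == 0))

  # uncoupled singlet: one 2D peak at (f1 = 0, f2 = site offset)
  res1 <- make_echo_result(water_fixture())
  hit <- which(res1$magnitude == max(res1$magnitude), arr.ind = TRUE)
  expect_equal(res1$f1_hz[hit[2]], 0)
  expect_equal(res1$f2_hz[hit[1]], (4.7 - 4.0) * 14.7945,
               tolerance = 1 / (512 * 2 * 2e-4))
})

test_that("shearing aligns multiplet components at the chemical shift", {
  spins <- spin_system(list(
    site("D", 5.84, 1, r2_hz = 3,
         couplings = list(coupling("E", 16, 1))),
    site("E", 6.96, 1, r2_hz = 3,
         couplings = list(coupling("D", 16, 1)))
  ))
  res <- make_echo_result(spins)
  pre <- res$magnitude
  sheared <- shear(res)
  f_d <- (5.84 - 4.0) * 14.7945

  # f1 = 0 row unchanged
  i0 <- which(res$f1_hz == 0)
  expect_equal(sheared$magnitude[, i0], pre[, i0], tolerance = 1e-12)

  # doublet components share one f2 column after shearing (search near
  # site D; site E contributes to the same +-8 Hz rows further downfield)
  near_d <- abs(res$f2_hz - f_d) < 12
  cols <- vapply(c(-8, 8), function(v) {
    j <- which.min(abs(res$f1_hz - v))
    res$f2_hz[near_d][which.max(sheared$magnitude[near_d, j])]
  }, numeric(1))
  expect_lt(abs(diff(cols)), 0.2)
  expect_equal(mean(cols), f_d, tolerance = 0.5)

  # per-row L2 norm preserved by the sub-bin shift
  pre_norm <- sqrt(colSums(pre^2))
  post_norm <- sqrt(colSums(sheared$magnitude^2))
  expect_equal(post_norm, pre_norm, tolerance = 1e-9)
})

test_that("geometric symmetrization is idempotent and AM-GM bounded", {
  res <- shear(make_echo_result(ethanol_fixture()))
  sym <- symmetrize_geometric(res)
  expect_true(all(sym$f1_hz + rev(sym$f1_hz) == 0))  # symmetric axis

  # never exceeds the max of the paired inputs
  for (j in seq_along(sym$f1_hz)) {
    jp <- which(sym$f1_hz == -sym$f1_hz[j])
    pair_max <- pmax(res$magnitude[, match(sym$f1_hz[j], res$f1_hz)],
                     res$magnitude[, match(sym$f1_hz[jp], res$f1_hz)])
    expect_true(all(sym$magnitude[, j] <= pair_max + 1e-12))
  }

  sym2 <- symmetrize_geometric(sym)
  expect_equal(sym2$magnitude, sym$magnitude, tolerance = 1e-12)

  # an artifact present only at +f1 is crushed to sqrt(S * noise floor)
  eps <- 1e-8
  toy <- ndnmr:::new_jres_result(
    magnitude = cbind(rep(eps, 4), c(1, 1, 1, 1), c(5, eps, eps, eps)),
    cplx = NULL, f2_hz = 0:3, f1_hz = c(-1, 0, 1), f0_MHz = 14.7945)
  tsym <- symmetrize_geometric(toy)
  expect_equal(tsym$magnitude[1, match(1, tsym$f1_hz)], sqrt(5 * eps))

  # symmetric input is unchanged
  symm_in <- toy
  symm_in$magnitude[, 1] <- symm_in$magnitude[, 3]
  expect_equal(symmetrize_geometric(symm_in)$magnitude[, c(1, 3)],
               symm_in$magnitude[, c(1, 3)])
})

test_that("skyline projection collapses multiplets to their shifts", {
  res <- reference_ppm(make_clean_result(ethyl_crotonate_fixture()),
                       ref_ppm = 1.28)
  sky <- skyline_projection(res)
  pk <- pick_peaks(sky, threshold_frac = 0.1)
  # quartet collapses to a single line at 4.2 ppm
  expect_true(any(abs(pk$pos_ppm - 4.2) < 0.02))
  # the two methyls (overlapping multiplets in 1D) resolve into two lines
  expect_true(any(abs(pk$pos_ppm - 1.28) < 0.02))
  expect_true(any(abs(pk$pos_ppm - 1.95) < 0.03))

  zero <- res
  zero$magnitude[] <- 0
  expect_true(all(skyline_projection(zero)$values == 0))
})

test_that("indirect integrals are quantitative where the skyline is not", {
  # isolated A-C coupled pair: amplitude ratio 3:2 by proton count; the
  # full five-site system is too crowded at 14.8 MHz for clean windows
  ac <- spin_system(list(
    site("A", 1.28, 3, 3.0, couplings = list(coupling("C", 7, 2))),
    site("C", 4.2, 2, 3.2, couplings = list(coupling("A", 7, 3)))))
  res <- reference_ppm(make_clean_result(ac), ref_ppm = 1.28)
  wins <- list(A = c(0.98, 1.58), C = c(3.9, 4.5))
  ints <- integrate_indirect(res, wins)
  expect_equal(unname(ints["A"] / ints["C"]), 1.5, tolerance = 0.1)

  doubled <- res
  doubled$magnitude <- 2 * doubled$magnitude
  ints2 <- integrate_indirect(doubled, wins)
  expect_equal(unname(ints2), 2 * unname(ints), tolerance = 1e-12)
  expect_error(integrate_indirect(res, list(bad = c(300, 301))), "empty")

  # magnitude-mode dispersive tails leave a small far-off-resonance
  # baseline; a truly zero spectrum integrates to exactly zero
  baseline <- integrate_indirect(res, list(q = c(8.2, 8.8)))
  expect_lt(unname(baseline), 0.05 * unname(ints["A"]))
  zero <- res
  zero$magnitude[] <- 0
  expect_equal(unname(integrate_indirect(zero, list(q = c(8.2, 8.8)))), 0)
})

test_that("slices expose each site's multiplet and J is measurable", {
  res <- reference_ppm(make_clean_result(ethyl_crotonate_fixture()),
                       ref_ppm = 1.28)

  d_slice <- slice_at_shift(res, 5.84)
  jd <- measure_j(d_slice, multiplicity = 2)
  expect_equal(jd$j_hz, 16, tolerance = 1)
  expect_length(jd$spacings_hz, 1)

  c_slice <- slice_at_shift(res, 4.2)
  jc <- measure_j(c_slice, multiplicity = 4, threshold_frac = 0.1)
  expect_equal(jc$j_hz, 7, tolerance = 1)
  expect_length(jc$spacings_hz, 3)

  sing <- slice_at_shift(make_singlet_result(), 4.7)
  expect_error(measure_j(sing, multiplicity = 2), "peak")
  expect_error(slice_at_shift(res, 420), "outside")
})

test_that("uncorrected drift measurably broadens the 2D result", {
  corrected <- small_study(correct_drift = TRUE, n_points = 512, n_t1 = 16)
  raw <- small_study(correct_drift = FALSE, n_points = 512, n_t1 = 16)
  sky_c <- pick_peaks(corrected$skyline, threshold_frac = 0.5)
  sky_r <- Mod(as.vector(raw$skyline$values))
  # drift smears intensity: the corrected skyline's tallest peak towers over
  # anything in the uncorrected one, and its width collapses
  expect_gt(max(sky_c$height), 2 * max(sky_r))
  axis_r <- raw$skyline$coords$f2
  width_r <- pick_peaks(sky_r, 0.5, axis_r)
  if (nrow(width_r) > 0) {
    expect_gt(min(width_r$fwhm_hz, na.rm = TRUE),
              max(sky_c$fwhm_hz, na.rm = TRUE))
  }
})

test_that("drift-corrected recovery matches the drift-free pipeline", {
  free <- small_study(correct_drift = FALSE, drift = drift_model("none"))
  corr <- small_study(correct_drift = TRUE)
  sites <- data.frame(label = c("A", "C", "D"),
                      shift_ppm = c(1.28, 4.2, 5.84),
                      multiplicity = c(3, 4, 2))
  m_free <- measure_multiplets(free$result, sites)
  m_corr <- measure_multiplets(corr$result, sites)
  expect_equal(m_corr$j_hz, m_free$j_hz, tolerance = 0.2)
  expect_equal(m_corr$skyline_ppm, m_free$skyline_ppm, tolerance = 0.02)
})
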