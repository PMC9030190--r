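test_that("window envelopes follow their closed forms", {
  g <- small_grid(1024, dwell = 1e-3)  # T_aq ~ 1 s
  t <- make_time_axis(g)
  expect_equal(ndnmr:::window_values(window_spec("lorentz", lb_hz = 3), t),
               exp(-pi * 3 * t))
  expect_equal(ndnmr:::window_values(window_spec("gauss", gb_hz = 4), t),
               exp(-(pi * 4 * t)^2 / (4 * log(2))))
  expect_equal(ndnmr:::window_values(window_spec("lorentz_gauss",
                                         lb_hz = 4, gb_hz = 4), t),
               exp(pi * 4 * t - (pi * 4 * t)^2 / (4 * log(2))))
  # Traficante at t = 0 with T_aq >> T2*: within exp(-2 T_aq / T2*) of 1
  w <- ndnmr:::window_values(window_spec("traficante", t2_star_s = 0.2), t)
  expect_lt(abs(w[1] - 1), exp(-2 * max(t) / 0.2) * 2)
  expect_error(window_spec("traficante", t2_star_s = 0), "t2_star")
  expect_error(window_spec("gauss", gb_hz = -1), "gb_hz")
})

test_that("Lorentzian broadening adds to the linewidth additively", {
  g <- small_grid(8192, dwell = 1e-3)
  ds <- lorentzian_fid(g, f_hz = 30, r2_hz = 5)
  sp <- quick_spectrum(apodize(ds, window_spec("lorentz", lb_hz = 10)))
  pk <- pick_peaks(sp$ds, 0.5, mode = "real")  # 1D widths on the real part
  df <- sp$axis[2] - sp$axis[1]
  expect_equal(pk$fwhm_hz, 15, tolerance = max(2 * df, 0.2))
})

test_that("Lorentz-Gauss substitutes a Gaussian of the requested width", {
  # lb equal to the natural width leaves a pure Gaussian of FWHM gb
  g <- small_grid(16384, dwell = 1e-3)
  ds <- lorentzian_fid(g, f_hz = 0, r2_hz = 6.3)
  sp <- quick_spectrum(apodize(ds, window_spec("lorentz_gauss",
                                               lb_hz = 6.3, gb_hz = 4)))
  pk <- pick_peaks(sp$ds, 0.5, mode = "real")
  expect_equal(pk$fwhm_hz, 4, tolerance = 0.2)

  # partial removal (the printed 4/4 Hz setting on a 6.3 Hz line) leaves a
  # Voigt profile of 2.3 Hz Lorentzian + 4 Hz Gaussian; numeric oracle:
  # fwhm ~ 0.5346 fL + sqrt(0.2166 fL^2 + fG^2)
  sp2 <- quick_spectrum(apodize(ds, window_spec("lorentz_gauss",
                                                lb_hz = 4, gb_hz = 4)))
  pk2 <- pick_peaks(sp2$ds, 0.5, mode = "real")
  voigt <- 0.5346 * 2.3 + sqrt(0.2166 * 2.3^2 + 4^2)
  expect_equal(pk2$fwhm_hz, voigt, tolerance = 0.3)
})

test_that("zero-filling extends the grid without moving peaks", {
  g <- small_grid(4096)
  ds <- lorentzian_fid(g, f_hz = 100, r2_hz = 5)
  zf <- zero_fill(ds, factor = 2)
  expect_length(zf$coords$t2, 8192)
  expect_equal(diff(zf$coords$t2[1:2]), g$dwell_s)
  expect_identical(zero_fill(ds, factor = 1)$values, ds$values)
  expect_error(zero_fill(ds, factor = 0.5), "factor")

  p1 <- pick_peaks(quick_spectrum(ds, zf = 1)$mag, 0.5,
                   quick_spectrum(ds, zf = 1)$axis)
  p2 <- pick_peaks(quick_spectrum(ds, zf = 2)$mag, 0.5,
                   quick_spectrum(ds, zf = 2)$axis)
  expect_equal(p1$pos_hz, p2$pos_hz, tolerance = 0.2)
})

test_that("Fourier transform obeys position, linearity and Parseval", {
  g <- small_grid(1024)
  t <- make_time_axis(g)
  ds <- nmr_dataset(exp(2i * pi * 100 * t), "t2", coords = list(t2 = t))
  sp <- fourier_transform(ds)
  expect_equal(sp$coords$f2[which.max(Mod(sp$values))], 100,
               tolerance = 1 / (1024 * 2e-4))
  expect_identical(sp$attrs$domain[["f2"]], "frequency")
  expect_error(fourier_transform(sp, dim = "f2"), "frequency")

  z <- nmr_dataset(rep(0i, 64) + 0i, "t2", coords = list(t2 = t[1:64]))
  z$values[1] <- 0i
  expect_true(all(Mod(fourier_transform(z)$values) == 0))

  # Parseval with the halved first point accounted for
  fid <- exp(2i * pi * 37 * t) * exp(-pi * 3 * t)
  halved <- fid
  halved[1] <- halved[1] / 2
  S <- fourier_transform(nmr_dataset(fid, "t2", coords = list(t2 = t)))
  df <- S$coords$f2[2] - S$coords$f2[1]
  lhs <- sum(Mod(S$values)^2) * df
  rhs <- sum(Mod(halved)^2) * g$dwell_s
  expect_equal(lhs, rhs, tolerance = 1e-9 * rhs)

  # linearity
  a <- nmr_dataset(fid, "t2", coords = list(t2 = t))
  b <- nmr_dataset(rev(fid), "t2", coords = list(t2 = t))
  lin <- fourier_transform(nmr_dataset(2 * fid + 3 * rev(fid), "t2",
                                       coords = list(t2 = t)))
  expect_equal(lin$values,
               2 * fourier_transform(a)$values +
                 3 * fourier_transform(b)$values,
               tolerance = 1e-12)
})

test_that("phase correction rotates the spectrum as specified", {
  g <- small_grid(2048)
  t <- make_time_axis(g)
  # 90 degree-shifted FID gives a dispersive line; phi0 = -90 restores it
  f_on_bin <- 16 / (2048 * 2e-4)  # peak centred on an axis bin
  fid <- 1i * exp(2i * pi * f_on_bin * t) * exp(-pi * 4 * t)
  sp <- fourier_transform(nmr_dataset(fid, "t2", coords = list(t2 = t)))
  expect_identical(phase_correct(sp, 0, 0)$values, sp$values)
  expect_equal(phase_correct(sp, 180)$values, -sp$values, tolerance = 1e-12)
  fixed <- phase_correct(sp, -90)
  i <- which.max(Mod(fixed$values))
  expect_gt(Re(fixed$values[i]) / Mod(fixed$values[i]), 0.999)
})

test_that("FT cross-correlation alignment inverts cyclic shifts", {
  g <- small_grid(512)
  sp <- quick_spectrum(lorentzian_fid(g, f_hz = 200, r2_hz = 8), zf = 1)
  y <- sp$mag
  expect_equal(align_ft_xcorr(y, y)$lag_bins, 0)
  for (s in c(-7L, 5L, 12L)) {
    shifted <- Re(ndnmr:::cyclic_shift_subbin(y, -s))  # place at +s bins
    out <- align_ft_xcorr(shifted, y)
    expect_equal(out$lag_bins, s)
    expect_equal(out$aligned, y, tolerance = 1e-9)
  }
  expect_error(align_ft_xcorr(y, y[-1]), "length")
})

test_that("alignment recovers a 3-bin shift in nearly all noisy trials", {
  # a realistic multi-line spectrum: sharp features make the correlation
  # peak well defined, as for the averaged transients this op serves
  g <- small_grid(1024)
  fx <- ethyl_crotonate_fixture(r2_hz = c(A = 1, B = 1, C = 1, D = 1, E = 1))
  clean <- Mod(as.vector(fourier_transform(synth_fid_1d(fx, g))$values))
  shifted <- Re(ndnmr:::cyclic_shift_subbin(clean, -3))
  sigma <- max(clean) / 10  # SNR 10
  set.seed(42)
  hits <- 0L
  for (i in 1:100) {
    a <- shifted + rnorm(length(clean), sd = sigma)
    b <- clean + rnorm(length(clean), sd = sigma)
    if (align_ft_xcorr(a, b)$lag_bins == 3) hits <- hits + 1L
  }
  expect_gte(hits, 99)
})

test_that("peak picking measures positions, widths and spacings", {
  g <- small_grid(16384, dwell = 1e-3)
  ds <- lorentzian_fid(g, f_hz = 25, r2_hz = 7.3)
  sp <- quick_spectrum(ds)
  pk <- pick_peaks(sp$ds, 0.5, mode = "real")
  expect_equal(nrow(pk), 1)
  expect_equal(pk$fwhm_hz, 7.3, tolerance = 0.1)
  expect_equal(pk$pos_hz, 25, tolerance = 0.05)

  t <- make_time_axis(g)
  doublet <- nmr_dataset(cos(pi * 16 * t) * exp(2i * pi * 30 * t) *
                           exp(-pi * 3 * t), "t2", coords = list(t2 = t))
  spd <- quick_spectrum(doublet)
  pkd <- pick_peaks(spd$mag, 0.3, spd$axis)
  expect_equal(nrow(pkd), 2)
  expect_equal(diff(pkd$pos_hz), 16, tolerance = 0.2)

  expect_equal(nrow(pick_peaks(sp$mag, 1.01, sp$axis)), 0)
  expect_equal(nrow(pick_peaks(rep(1, 100), 0.5)), 0)
})

test_that("aligned averaging preserves the linewidth that jitter destroys", {
  g <- small_grid(1024)
  sp <- quick_spectrum(lorentzian_fid(g, f_hz = 150, r2_hz = 6), zf = 1)
  n_tr <- 24
  set.seed(11)
  jit <- sample(-3:3, n_tr, replace = TRUE)
  jit[1] <- 0
  m <- vapply(jit, function(s) ndnmr:::cyclic_shift_subbin(sp$mag + 0i, -s),
              complex(length(sp$mag)))
  ds <- nmr_dataset(m, c("f2", "transient"),
                    coords = list(f2 = sp$axis, transient = seq_len(n_tr)),
                    attrs = list(units = c(f2 = "Hz", transient = "s"),
                                 domain = c(f2 = "frequency",
                                            transient = "time")))
  ideal_fwhm <- pick_peaks(sp$mag * n_tr, 0.5, sp$axis)$fwhm_hz
  aligned <- average_transients(ds, align = TRUE)
  fa <- pick_peaks(Mod(as.vector(aligned$values)), 0.5, sp$axis)$fwhm_hz
  expect_equal(fa, ideal_fwhm, tolerance = 0.05 * ideal_fwhm)
  blurred <- average_transients(ds, align = FALSE)
  fb <- pick_peaks(Mod(as.vector(blurred$values)), 0.5, sp$axis)$fwhm_hz
  expect_gt(fb, fa)

  ident <- nmr_dataset(matrix(rep(sp$mag, 4), ncol = 4) + 0i,
                       c("f2", "transient"),
                       coords = list(f2 = sp$axis, transient = 1:4),
                       attrs = list(units = c(f2 = "Hz", transient = "s"),
                                    domain = c(f2 = "frequency",
                                               transient = "time")))
  summed <- average_transients(ident, align = TRUE)
  expect_equal(as.vector(Re(summed$values)), 4 * sp$mag, tolerance = 1e-9)
})
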