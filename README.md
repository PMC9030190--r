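# ndnmr

Processing tools for **Overhauser dynamic nuclear polarization (ODNP)
enhanced proton NMR at low magnetic field** (0.35 T, 14.7945 MHz), where
permanent-magnet spectrometers drift by tens of ppm during a 2D acquisition
and J-multiplets crowd a chemical-shift range of barely 100 Hz. The package
is aimed at spectroscopists running (or simulating) benchtop ODNP
experiments: it implements the complete acquisition-to-analysis chain for
2D J-resolved (JRES) spectroscopy with **interleaved spectral referencing**
— the lock-free drift correction scheme in which a 1D reference spectrum is
recorded after every completed phase cycle, the reference-peak trajectory
is fit with a polynomial, and every stored transient is corrected in
software before the phase cycle is combined.

## What it computes

**Overhauser enhancement arithmetic.** The enhancement of nuclear
polarization under microwave saturation of the electron transition is

```
E = 1 − ξ f s |γS/γI|
```

with coupling factor ξ ∈ [−1, +0.5], leakage factor f, saturation factor s,
and |γS/γI| = 658.21 for electron/proton. Pure dipolar coupling (ξ = 0.5)
at full leakage and saturation gives E ≈ −330; averaging time to fixed SNR
scales as 1/E², so even E = −30 saves a factor of 900.

**Drift correction.** Each 1D reference spectrum is processed and the
sub-bin position and phase of its strongest peak are tracked relative to
the first reference. The shift trajectory Δδ(τ) is fit with a polynomial
(order 4 by default) in wall-clock time; each stored transient at time τ is
then demodulated by `exp(−2πi Δδ(τ) f0 (t + t_dead))` — the dead-time term
removes the drift-induced linear phase roll — plus an interpolated
zeroth-order phase correction.

**2D JRES processing.** Per-t1 FIDs are apodized (Lorentz–Gauss by
default), zero-filled ×2 in both dimensions, double Fourier transformed,
magnitude-computed, sheared so multiplet components align at their chemical
shift, symmetrized by the geometric mean of the ±f1 rows, and reduced to a
skyline (pure-shift) projection, indirect-dimension integrals, per-site
slices, and J-coupling measurements.

**Simulation.** A weak-coupling simulator generates 1D FIDs and full
interleaved JRES echo sets — binomial multiplets from cosine-product
J modulation, spin-echo shift refocusing, configurable field drift,
dead-time phase roll, four-step EXORCYCLE phase cycling, per-scan
timestamps, and complex Gaussian noise — so the whole chain is testable
without instrument data.

## Worked example

Simulate the ethyl crotonate fixture (five proton sites A–E, J(A,C) = 7 Hz,
J(B,E) = 7 Hz, J(D,E) = 16 Hz) on the full acquisition grid with a
60 ppm / 30 min exponential field drift, correct it via the interleaved
references, and measure the couplings:

```r
library(ndnmr)

grid  <- acquisition_grid(dwell_s = 2e-4, n_points = 4096, dead_time_s = 1e-3)
sched <- jres_schedule(n_t1 = 128, dt1_s = 8e-3, tau0_s = 3e-3, n_dummy = 2)
drift <- drift_model("exponential", span_ppm = 60, tau_s = 1200, t_span_s = 1800)

pl <- jres_pipeline(ethyl_crotonate_fixture(), grid, sched, drift = drift)

pl$track$residual_max_ppm
#> [1] 0.01999093

sites <- data.frame(label = c("A", "B", "C", "D"),
                    shift_ppm = c(1.28, 1.95, 4.2, 5.84),
                    multiplicity = c(3, 2, 4, 2))
measure_multiplets(pl$result, sites)
#>   label      j_hz skyline_ppm
#> 1     A  7.182142    1.280000
#> 2     B  7.116045    1.933765
#> 3     C  6.961269    4.210428
#> 4     D 16.080466    5.840993
```

The fourth-order drift fit leaves a residual of 0.02 ppm against the
60 ppm excursion; all three couplings come back within 0.2 Hz of the
simulated 7 / 7 / 16 Hz, and the methylene quartet (site C) collapses to a
single skyline line at 4.21 ppm on an axis referenced via the methyl
resonance at 1.28 ppm.

A thin command-line front end (`inst/cli/ndnmr`) exposes the same chain as
`simulate`, `proc1d`, `driftfit`, `jres` and `enhance` subcommands over the
package's versioned on-disk dataset format (`header.json` + little-endian
binary payload, tag `ndnmr/1`).

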