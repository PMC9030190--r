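---
title: "Low-field ODNP JRES processing: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-field ODNP JRES processing: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ndnmr)
```

# The problem

Overhauser DNP transfers electron polarization to nuclei in solution and is
most efficient at low magnetic field, which makes 0.35 T (14.7945 MHz for
protons) an attractive operating point: X-band EPR hardware drives the
electron transition, and enhancements of tens to hundreds offset the small
Boltzmann polarization. The price is twofold. First, chemical-shift
dispersion shrinks to ~100 Hz across the proton spectrum, so J-multiplets
overlap; 2D J-resolved (JRES) spectroscopy separates the couplings into an
indirect dimension and recovers a pure-shift spectrum by projection.
Second, permanent magnets drift: with temperature regulation disabled
during acquisition the field can move by tens of ppm over the ~30 min of a
2D experiment — far more than a linewidth — which destroys both frequency
and phase coherence between transients.

This package implements the software side of that experiment: a simulator
that generates the data the instrument would produce, the drift-correction
scheme (interleaved spectral referencing), and the 2D JRES processing
chain.

# Signal model

The simulator is first-order (weak coupling). A site with chemical shift
δ (ppm), `n_equiv` equivalent protons, homogeneous linewidth `r2_hz`
(Lorentzian FWHM, including paramagnetic broadening from the nitroxide
polarizing agent), and couplings `J_c` to groups of `n_c` equivalent
partners contributes to the 1D FID

```
s(t) = A n_equiv exp(2πi f t) Π_c cos(π J_c t)^{n_c} exp(−π r2 t),
f = (δ − δ_carrier) f0.
```

The cosine product is exactly the average of `exp(2πi m J t)` over all
partner spin states m = ±1/2, so it reproduces binomial multiplets (1:1,
1:2:1, 1:3:3:1, ...) without enumerating transitions; the test suite
verifies this identity against a brute-force enumeration oracle to 1e−10.

For the spin echo of the JRES experiment, chemical shift is refocused at
the echo centre while J coupling and relaxation evolve through the whole
echo:

```
s(t1, t2) = Σ_sites A n exp(2πi f t2) Π_c cos(π J_c (t1 + t2))^{n_c}
            exp(−π r2 (t1 + t2)).
```

An ideal refocusing pulse of phase φ multiplies the echo by `exp(2iφ)`.

**What the generator does not model.** Strong coupling (second-order
mixing) is deliberately excluded: real low-field spectra of systems such
as ethyl crotonate show strong-coupling artifacts (extra JRES ridges near
3 ppm and between 6–7 ppm) that the weak-coupling model cannot produce, so
passing tests say nothing about recognising or removing them. Also absent:
relaxation during pulses, radiation damping, B1 inhomogeneity, lineshape
asymmetry, and temperature dependence of the enhancement. Enhancement
enters only as a signed amplitude scale.

# Acquisition model and defaults

The defaults reproduce a benchtop interleaved JRES acquisition:

| parameter | default | meaning |
|---|---|---|
| `dwell_s` | 200 µs | direct dwell time (5 kHz spectral width) |
| `n_points` | 4096 (echo), 8192 (1D reference) | complex points |
| `dt1_s` | 8 ms | indirect increment (SW1 = 125 Hz) |
| `tau0_s` | 3 ms | initial inter-pulse delay |
| `n_t1` | 128 | indirect points |
| `n_dummy` | 2 | dummy scans per t1 step |
| `rep_time_s` | 2.5 s (echo), 2 s (reference) | repetition time |
| `dead_time_s` | 0 (1 ms in the drift studies) | receiver dead time |
| `f0_MHz` | 14.7945 | proton transmitter frequency |
| `carrier_ppm` | 4.0 | transmitter position |

The indirect evolution variable is taken as the **full echo time**,
`t1_i = 2 τ0 + i Δt1`: the printed 8 ms increment then gives SW1 = 125 Hz,
enough to host ±62.5 Hz of J structure (a 16 Hz doublet sits at ±8 Hz).
The alternative reading (t1 = τ) would halve the J axis; `tau0_s` and
`dt1_s` are plain parameters, so either convention is reachable.

The four-step phase cycle defaults to EXORCYCLE — refocusing-pulse phases
0°/90°/180°/270° with receiver signs +,−,+,− — the standard echo cycle;
the exact phases are rarely printed in experimental reports and are
configurable. Wall-clock timestamps advance by the repetition time for
*every* scan, dummy scans and reference scans included, which is what makes
the simulated experiment last ~37 min and the drift model meaningful.

One 1D reference scan follows each completed phase cycle, so with a
four-step cycle interleaved referencing adds exactly 25 % more scans,
i.e. references are 1/5 = 20 % of all scans.

The drift fixture is an exponential settling curve spanning 60 ppm over a
30 min window with a 20 min time constant — the signature of a permanent
magnet equilibrating after its heater is disabled — normalised so
Δδ(0) = 0 and Δδ(30 min) = 60 ppm exactly. Linear, polynomial and tabulated
drifts are available for sensitivity studies.

# Drift correction

`track_references()` processes each reference FID (1 Hz Lorentzian
apodization, ×2 zero-fill, FT, magnitude) and follows the **global maximum
peak** with three-point parabolic interpolation; shifts are expressed in
ppm relative to the first reference. The phase track is read from the
complex spectrum at the peak *after* demodulating the measured shift (dead
time included), then unwrapped. Because the frequency term with dead time
already accounts for the drift-induced linear phase roll, the residual
phase track captures only instabilities not explained by drift — in the
simulator, essentially zero; on real data, ambient and instrumental phase
wander.

`fit_drift()` fits the shift track with a least-squares polynomial in
wall-clock time on a domain rescaled to [−1, 1] (Vandermonde conditioning:
raw times up to ~2000 s at order 4 would span 13 orders of magnitude).
Order 4 is the default: for the exponential fixture sampled at 32
reference times the maximum residual is ~0.007 ppm — two orders below the
60 ppm excursion and well under the ~0.2 ppm linewidth. The residual
report (`residual_max_ppm`, `residual_rms_ppm`, per-point residuals) is
the instrument for justifying other orders when drifts oscillate. The fit
is against **time**, not scan index: dummy and reference scans make the
index non-uniform in time, and time is the physically meaningful abscissa.

`correct_transients()` demodulates each stored transient by the fitted
drift at its own timestamp — a time-domain multiplication, which is
sub-bin exact and commutes with any later apodization, rather than a
spectral bin shift — and applies the tracked phase, linearly interpolated
between the two bracketing references (the simplest interpolant consistent
with tracking only at cycle boundaries). Transients acquired before the
first reference (the first cycle) use the polynomial's extrapolation and
are flagged with a warning.

Correction happens **before** phase-cycle combination: that is the point
of storing every cycle step separately. Combining first would average
scans whose frequencies differ by many linewidths.

# 2D processing conventions

* **First-point halving** before every FFT (the standard discrete-transform
  convention suppressing the baseline offset), and scaling by the dwell
  time so spectra approximate the continuous-time transform; Parseval then
  holds as `Σ|S|² df = Σ|s'|² dt`.
* **Frequency axes** are zero-centred on the transmitter, ascending; ppm
  referencing is a pure axis relabelling (`ppm = Hz/f0 + offset`), never a
  data shift, so it is exactly invertible. The offset is set by assigning
  a known peak — for ethyl crotonate, the most upfield skyline resonance,
  the ester methyl, to 1.28 ppm.
* **Magnitude mode** for the 2D spectrum: phase-twist lineshapes make
  phased JRES impractical, and both the shearing convention and the
  geometric-average symmetrization presuppose non-negative data. 1D
  linewidths are measured on the phased real part (a magnitude Lorentzian
  is √3 wider); 2D widths on magnitude.
* **Apodization**: Lorentz–Gauss `exp(+π lb t − (π gb t)²/(4 ln 2))`
  (removes `lb` Hz of Lorentzian width, substitutes a `gb` Hz Gaussian)
  with lb = gb = 4 Hz on **both** dimensions as the 2D default — the
  resolution enhancement that makes 7 Hz multiplets measurable at 14.8 MHz.
  A Traficante window `E/(E² + F²)`, `E = exp(−t/T2*)`,
  `F = exp(−(T_aq−t)/T2*)` (the canonical published form; reports using it
  typically cite T2* ≈ 0.2 s without printing the kernel) narrows lines
  further at some noise cost. Note that a Lorentz–Gauss window whose `lb`
  exceeds the decay actually present *grows* toward the end of a short
  FID: on truncated records (e.g. 0.2 s test acquisitions) this produces
  severe ripple, which is why the scaled-down tests use matched or pure
  Gaussian windows. This is a property of the window, not a software
  limitation.
* **Shearing** before symmetrization, by row-wise inverse FT, phase ramp
  `exp(−2πi f1 t2)`, forward FT on the complex rows — sub-bin exact and
  norm-preserving; components at `f2 = δ + m J`, `f1 = m J` land at δ. A
  `direction` flag covers the opposite tilt convention.
* **Symmetrization** replaces S(f1) and S(−f1) by their geometric mean:
  idempotent, never exceeds either input (AM–GM), crushes artifacts
  present on one side only to `sqrt(S · floor)`. The unpaired Nyquist row
  of the even-length f1 axis is dropped, leaving an exactly symmetric
  axis. The f1 = 0 row passes through unchanged.
* **Peak picking** takes local maxima above a threshold fraction of the
  global maximum, three-point parabolic sub-bin interpolation for position
  and height, and linear interpolation of the half-height crossings for
  FWHM. J couplings are the mean adjacent-maximum spacing of a slice along
  f1, quoted with the axis spacing as uncertainty.

# What the validation shows — and its limits

The test suite runs the entire chain on the ethyl crotonate fixture
(A–E: methyl triplet at 1.28 ppm, allylic methyl doublet near 1.95 ppm,
methylene quartet at 4.2 ppm, vinyl doublet near 5.84 ppm, vinyl
doublet-of-quartets near 6.96 ppm; J = 7, 7, 16 Hz) with the 60 ppm drift
and 1 ms dead time injected, and recovers J(D,E), J(A,C) and J(B,E) within
±1 Hz and the collapsed methylene skyline line within ±0.02 ppm of
4.2 ppm. Skipping the correction on the same data collapses the skyline
amplitude and smears every line — the monotone-harm control.

Quantitation by indirect-dimension integration reproduces a 3:2 proton
ratio to ~10 % **for well-separated sites**: magnitude-mode lineshapes
carry slow 1/Δf dispersive tails, and overlapping multiplet components
interfere inside the magnitude, so integrals over crowded regions (A next
to B at 14.8 MHz) are biased. Skyline heights are not quantitative at all;
that is why the integration operation exists.

Reference tracking follows the *strongest* peak; in a noiseless simulation
two exactly equal peaks could alternate as the maximum between scans, so
the fixture gives its sites slightly different linewidths (3.0–3.6 Hz,
within the observed ~3 Hz homogeneous width) — real spectra never tie
exactly. On real data the tracked peak should dominate its spectrum, as a
solvent or methyl resonance does.

Problem sizes: deep structural tests run at 512–2048 direct points and
16–64 increments; the end-to-end recovery test and the acceptance script
run the full 4096 × 128 acquisition with ×2 zero-fill (8192 × 256
spectra). The suite completes in well under a minute on one CPU.

# Enhancement arithmetic conventions

The transfer relation is implemented as `E = 1 − ξ f s |γS/γI|`. Printed
forms of this equation sometimes carry the γ ratio's sign implicitly and
state ε = 1 − E instead; with the magnitude convention used here, dipolar
coupling (ξ > 0) yields the familiar large *negative* proton enhancements
(−328.105 at the dipolar limit, "−330" at two significant figures) and the
pure scalar limit ξ = −1 gives +659.21. ODNP-enhanced spectra with
negative E are conventionally phased positive; the simulator treats E as a
signed amplitude scale. The γ ratio defaults to the free-electron/proton
value 658.21 and is configurable (e.g. for ¹⁹F work). `time_saving(E) = E²`
and `boltzmann_penalty(f_pol, f_det) = f_det/f_pol` (polarizing at 15 MHz
and detecting at 80 MHz forfeits a factor >5) complete the bookkeeping.

# Known limitations

* Weak coupling only — no strong-coupling artifact simulation or removal.
* No vendor-format importers: one versioned container
  (`header.json` + little-endian 64-bit payload, tag `ndnmr/1`).
* No automatic phase optimization, baseline correction, or solvent
  suppression.
* Zeroth-order phase interpolation between references is linear; fast
  intra-cycle phase jumps would alias.
* Magnitude-mode quantitation degrades for overlapping multiplets (above).
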