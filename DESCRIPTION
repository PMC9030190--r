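Package: ndnmr
Title: Processing of Low-Field ODNP-Enhanced NMR Spectra with Interleaved
    Drift Referencing and 2D J-Resolved Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Overhauser dynamic nuclear polarization (ODNP) enhanced
    proton NMR at low magnetic field on drifting permanent magnets. Provides an
    n-dimensional complex spectral container with a versioned on-disk format; a
    weak-coupling spin-echo simulator producing 1D free induction decays and 2D
    J-resolved (JRES) echo sets with configurable field drift, dead-time phase
    roll, phase cycling and interleaved 1D reference scans; one-dimensional
    processing (Lorentz, Gauss, Lorentz-Gauss and Traficante apodization,
    zero-filling, Fourier transform, phasing, FT cross-correlation alignment,
    peak picking); magnetic-field-drift correction by polynomial fitting of
    interleaved reference spectra; full 2D JRES processing (shearing, geometric
    symmetrization, skyline projection, indirect-dimension integration,
    J-coupling measurement); and Overhauser enhancement arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
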