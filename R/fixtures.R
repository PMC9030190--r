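#' Ethyl crotonate spin-system fixture
#'
#' Five proton groups of ethyl crotonate (trans CH3-CH=CH-CO-O-CH2-CH3),
#' labelled A-E: A is the ester methyl (3H triplet at 1.28 ppm, J = 7 Hz to
#' C), C the methylene (2H quartet at 4.2 ppm), B the allylic methyl (3H
#' doublet, J = 7 Hz to E), D and E the vinyl protons (J = 16 Hz trans
#' coupling; E additionally couples to B). The A and C shifts are the
#' literature values used for referencing; B, D and E default to values in
#' their literature ranges and are configurable.
#'
#' Linewidths default to the ~3 Hz homogeneous width typical of a shimmed
#' permanent magnet with 10 mM nitroxide, made slightly site-dependent so
#' that no two peaks tie exactly in height in noiseless simulations.
#'
#' @param shift_B,shift_D,shift_E chemical shifts (ppm) of the configurable
#'   sites.
#' @param r2_hz per-site homogeneous linewidths (FWHM, Hz), named A-E.
#' @return a [spin_system()] with sites A-E.
#' @export
ethyl_crotonate_fixture <- function(shift_B = 1.95, shift_D = 5.84,
                                    shift_E = 6.96,
                                    r2_hz = c(A = 3.0, B = 3.5, C = 3.2,
                                              D = 3.4, E = 3.6)) {
  spin_system(list(
    site("A", 1.28, n_equiv = 3, r2_hz = r2_hz[["A"]],
         couplings = list(coupling("C", 7, n_partner = 2))),
    site("B", shift_B, n_equiv = 3, r2_hz = r2_hz[["B"]],
         couplings = list(coupling("E", 7, n_partner = 1))),
    site("C", 4.2, n_equiv = 2, r2_hz = r2_hz[["C"]],
         couplings = list(coupling("A", 7, n_partner = 3))),
    site("D", shift_D, n_equiv = 1, r2_hz = r2_hz[["D"]],
         couplings = list(coupling("E", 16, n_partner = 1))),
    site("E", shift_E, n_equiv = 1, r2_hz = r2_hz[["E"]],
         couplings = list(coupling("D", 16, n_partner = 1),
                          coupling("B", 7, n_partner = 3)))
  ))
}

#' Ethanol spin-system fixture
#'
#' Methyl triplet / methylene quartet pair (J = 7 Hz) plus the hydroxyl
#' singlet, at standard literature shifts.
#'
#' @return a [spin_system()].
#' @export
ethanol_fixture <- function() {
  spin_system(list(
    site("CH3", 1.19, n_equiv = 3, r2_hz = 3.0,
         couplings = list(coupling("CH2", 7, n_partner = 2))),
    site("CH2", 3.65, n_equiv = 2, r2_hz = 3.2,
         couplings = list(coupling("CH3", 7, n_partner = 3))),
    site("OH", 2.61, n_equiv = 1, r2_hz = 4.0)
  ))
}

#' Water singlet fixture
#' @return a [spin_system()] with a single 2H site at 4.7 ppm.
#' @export
water_fixture <- function() {
  spin_system(list(site("H2O", 4.7, n_equiv = 2, r2_hz = 3.0)))
}
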