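# Atomic constants pinned to the NIST Atomic Weights and Isotopic
# Compositions tables (2018 release) so every mass in the package is
# bit-reproducible.  Masses are those of the most abundant isotope of
# each element (monoisotopic convention).

#' Monoisotopic atomic masses
#'
#' Named numeric vector of monoisotopic masses (Da) for the elements the
#' formula parser accepts: the mass of the most abundant isotope of each
#' element, from the NIST isotopic-composition tables.
#'
#' @format Named numeric vector, names are element symbols.
#' @export
MONOISOTOPIC_MASS <- c(
  H  = 1.00782503224,
  C  = 12.0,
  N  = 14.00307400446,
  O  = 15.99491461960,
  P  = 30.97376199857,
  S  = 31.97207117443,
  Na = 22.98976928199,
  K  = 38.96370648661,
  Cl = 34.96885269,
  F  = 18.99840316273,
  Br = 78.91833760,
  I  = 126.90447190,
  Si = 27.97692653465,
  B  = 11.00930536,
  Li = 7.01600343659,
  Mg = 23.98504169700,
  Al = 26.98153853,
  Ca = 39.96259086300,
  Mn = 54.93804391,
  Fe = 55.93493633,
  Co = 58.93319429,
  Ni = 57.93534241,
  Cu = 62.92959772,
  Zn = 63.92914201,
  As = 74.92159457,
  Se = 79.91652180,
  Mo = 97.90540482,
  W  = 183.95093092,
  Hg = 201.97064340
)

# Abundance ratio of the isotope one nominal mass unit above the
# principal isotope, relative to the principal isotope (NIST isotopic
# compositions).  Elements whose next isotope sits at +2 Da (Cl, Br, Zn,
# ...) contribute nothing to the M+1 peak and are zero here.
ISOTOPE_M1_RATIO <- c(
  C  = 0.0107    / 0.9893,    # 13C / 12C
  H  = 0.000115  / 0.999885,  # 2H  / 1H
  N  = 0.00364   / 0.99636,   # 15N / 14N
  O  = 0.00038   / 0.99757,   # 17O / 16O
  S  = 0.0075    / 0.9499,    # 33S / 32S
  Si = 0.04685   / 0.92223,   # 29Si/ 28Si
  Mg = 0.1000    / 0.7899,    # 25Mg/ 24Mg
  Fe = 0.02119   / 0.91754,   # 57Fe/ 56Fe
  K  = 0.000117  / 0.932581   # 40K / 39K
)

#' Physical constants used in ion mass arithmetic
#'
#' `ELECTRON_MASS` is the CODATA electron rest mass in Da; `PROTON_MASS`
#' is the 1H monoisotopic mass minus the electron mass, i.e. the mass a
#' molecule gains on protonation.  `C13_SPACING` is the 13C-12C mass
#' difference used as the representative M to M+1 spacing.
#'
#' @name ion-constants
#' @export
ELECTRON_MASS <- 0.000548579909

#' @rdname ion-constants
#' @export
PROTON_MASS <- MONOISOTOPIC_MASS[["H"]] - ELECTRON_MASS  # 1.00727645...

#' @rdname ion-constants
#' @export
C13_SPACING <- 1.0033548378
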