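# Physical constants for peptide mass arithmetic. Monoisotopic residue
# masses follow the Unimod/IUPAC values; precision matters because panel
# precursor m/z are compared at 4 decimals.

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) of the 20 canonical amino-acid
#' residues (i.e., the mass of the residue inside a peptide chain, without
#' the terminal water).
#'
#' @format Named numeric vector, one entry per one-letter residue code.
#' @export
AA_MONO_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Mass constants
#'
#' Monoisotopic mass of water (added once per peptide) and of the proton
#' (added once per charge during ionisation), in Da.
#'
#' @name mass-constants
#' @export
WATER_MONO <- 18.0105646

#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.00727646

#' Heavy-label mass deltas
#'
#' Mass shifts (Da) of the stable-isotope labels carried by the C-terminal
#' residue of a heavy spike-in peptide: 13C6 15N2 lysine (+8.014199) and
#' 13C6 15N4 arginine (+10.008269). These reproduce the nominal "+8"/"+10"
#' mass difference between heavy and light peptide pairs.
#'
#' @format Named numeric vector with entries `K` and `R`.
#' @export
HEAVY_LABEL_DELTA <- c(K = 8.014199, R = 10.008269)

#' Supported post-translational modification deltas
#'
#' Monoisotopic mass deltas (Da) of the three modifications the assay-design
#' stage tolerates: carbamidomethylation of cysteine, oxidation of
#' methionine, and N-terminal acetylation. At most three modifications per
#' peptide are allowed.
#'
#' @format Named numeric vector.
#' @export
MOD_DELTA <- c(
  "carbamidomethyl-C" = 57.021464,
  "oxidation-M"       = 15.994915,
  "acetyl-Nterm"      = 42.010565
)

#' @keywords internal
MAX_MODS_PER_PEPTIDE <- 3L

# round half away from zero, matching the print convention of the panel
round_half_up <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
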