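# Monoisotopic mass tables and physical constants.
# Residue masses are the standard monoisotopic values for the 20 canonical
# amino acids; all masses in Dalton.

#' @keywords internal
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276466
WATER_MASS <- 18.010565
# neutral loss of phosphoric acid (H3PO4), the nominal "-98 Da" loss
PHOSPHO_NEUTRAL_LOSS <- 97.976896

# UniMod tags understood in modified-sequence notation
UNIMOD_TABLE <- tibble::tibble(
  tag = c("UniMod:4", "UniMod:21", "UniMod:35"),
  name = c("Carbamidomethyl", "Phospho", "Oxidation"),
  mass_delta = c(57.021464, 79.966331, 15.994915)
)

#' Amino-acid residue masses
#'
#' Monoisotopic residue masses (Da) for the 20 canonical amino acids, as used
#' by all mass computations in the package.
#'
#' @return A named numeric vector keyed by one-letter residue code.
#' @export
residue_masses <- function() AA_MONO

#' Modification table
#'
#' The UniMod modifications recognised in modified-sequence notation, with
#' their monoisotopic mass deltas.
#'
#' @return A tibble with columns `tag`, `name`, `mass_delta`.
#' @export
modification_table <- function() UNIMOD_TABLE
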