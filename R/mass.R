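#' Monoisotopic neutral mass of a glycan
#'
#' Sum of residue masses plus one water, with heavy-isotope label shifts.
#' Deterministic to 1e-4 Da.
#'
#' @param g glycan.
#' @return numeric, Da.
#' @examples
#' neutral_mass(parse_glycan("Glcb"))        # 180.0634
#' neutral_mass(parse_glycan("Manb1-2Manb")) # 342.1162
#' @export
neutral_mass <- function(g) {
  comp_mass(glycan_comp(g))
}

.adduct_masses <- c(Na = 22.98976928)

#' Precursor m/z of a singly charged adduct
#'
#' Monoisotopic m/z = neutral mass + adduct mass - electron mass; nominal
#' m/z is the nearest integer (the unit-resolution ion-trap convention in
#' which all diagnostic values such as 245/275/305 are quoted).
#'
#' @param g glycan.
#' @param adduct charge carrier token; only \code{"Na"} is supported.
#' @return list with \code{mz_monoisotopic} and \code{mz_nominal}.
#' @examples
#' precursor_mz(parse_glycan("GlcNAcb1-2Man"))$mz_nominal  # 406
#' @export
precursor_mz <- function(g, adduct = g$adduct) {
  if (!adduct %in% names(.adduct_masses)) stop("unsupported adduct: ", adduct)
  mono <- neutral_mass(g) + .adduct_masses[[adduct]] - element_masses[["electron"]]
  list(mz_monoisotopic = mono, mz_nominal = as.integer(round(mono)))
}

# m/z of a cationized fragment composition (already includes Na if present)
.comp_mz <- function(x, adduct = "Na") {
  comp_mass(x) + .adduct_masses[[adduct]] - element_masses[["electron"]]
}

#' Mass of a neutral loss composition
#'
#' @param atoms composition vector (see [comp()]), possibly containing
#'   \code{O18}.
#' @return list with \code{monoisotopic} (Da) and \code{nominal} (integer).
#' @examples
#' loss_mass(comp(C = 2, H = 4, O = 2))$nominal   # 60
#' loss_mass(comp(C = 1, H = 2, O18 = 1))$nominal # 32
#' @export
loss_mass <- function(atoms) {
  m <- comp_mass(atoms)
  list(monoisotopic = m, nominal = as.integer(round(m)))
}
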