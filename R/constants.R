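#' Physical and isotopic constants
#'
#' Monoisotopic masses and natural isotopic abundances used throughout the
#' package. Isotope masses and abundances follow the IUPAC/CIAAW 2013
#' recommended values, truncated to six decimal places; the same table is
#' shipped as a machine-readable TSV in `inst/extdata/isotopes.tsv`.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{proton}{mass of a proton, Da (1.007276)}
#'   \item{hydrogen_atom}{mass of a hydrogen atom, Da (1.007825)}
#'   \item{water}{monoisotopic mass of H2O, Da (18.010565)}
#'   \item{ammonia}{monoisotopic mass of NH3, Da (17.026549)}
#'   \item{z_ion}{mass added to a C-terminal residue sum to give the ECD
#'     z-radical ion neutral mass, Da (1.991841)}
#' }
#' @export
physical_constants <- list(
  proton        = 1.007276,
  hydrogen_atom = 1.007825,
  water         = 18.010565,
  ammonia       = 17.026549,
  z_ion         = 1.991841
)

# Isotope table: per element, masses (Da) and natural abundances (fraction),
# ordered by nucleon number; entry 1 is the lightest (monoisotopic) isotope.
# IUPAC/CIAAW 2013, six decimals.
.isotopes <- list(
  C = list(mass = c(12.000000, 13.003355),
           abundance = c(0.989300, 0.010700)),
  H = list(mass = c(1.007825, 2.014102),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.003074, 15.000109),
           abundance = c(0.996360, 0.003640)),
  O = list(mass = c(15.994915, 16.999132, 17.999160),
           abundance = c(0.997570, 0.000380, 0.002050)),
  S = list(mass = c(31.972071, 32.971459, 33.967867, 35.967081),
           abundance = c(0.949900, 0.007500, 0.042500, 0.000100))
)

#' Supported chemical elements
#'
#' @return Character vector of element symbols with isotope data.
#' @export
supported_elements <- function() names(.isotopes)

#' Isotope table
#'
#' The isotopic masses and abundances used by [isotope_distribution()] and
#' [monoisotopic_mass()], as a data frame.
#'
#' @return A data.frame with columns `element`, `nucleons` (offset from the
#'   lightest isotope), `mass` (Da) and `abundance` (fraction).
#' @export
isotope_table <- function() {
  do.call(rbind, lapply(names(.isotopes), function(e) {
    iso <- .isotopes[[e]]
    nuc <- round(iso$mass - iso$mass[1])
    data.frame(element = e, nucleons = nuc, mass = iso$mass,
               abundance = iso$abundance)
  }))
}

# Amino-acid residue compositions (residue = amino acid minus water).
.aa_residues <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

#' Amino-acid residue composition table
#'
#' Elemental compositions of the 20 standard amino-acid residues (the amino
#' acid minus one water). Also shipped as `inst/extdata/amino_acids.tsv`.
#'
#' @return A data.frame with one row per residue and one column per element.
#' @export
amino_acid_table <- function() {
  m <- do.call(rbind, .aa_residues)
  data.frame(residue = rownames(m), m, row.names = NULL)
}
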