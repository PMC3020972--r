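#' Elemental compositions
#'
#' An elemental composition is a map from element symbol to a non-negative
#' atom count. Compositions add and subtract element-wise; subtraction that
#' would drive any count negative is an error, so signed deltas (losses such
#' as -H2O) are carried by [modification()] objects, not by compositions.
#'
#' @param ... Named integer atom counts, e.g. `composition(C = 2, H = 5,
#'   N = 1, O = 2)`. Unnamed single argument may be a named numeric vector.
#' @return An object of class `elemental_composition` (named integer vector
#'   over [supported_elements()]).
#' @examples
#' composition(C = 2, H = 5, N = 1, O = 2)  # glycine as a free amino acid
#' @export
composition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    args <- as.list(args[[1]])
  counts <- stats::setNames(numeric(length(supported_elements())),
                            supported_elements())
  if (length(args)) {
    nm <- names(args)
    if (is.null(nm) || any(nm == ""))
      stop("composition() arguments must be named by element symbol")
    bad <- setdiff(nm, supported_elements())
    if (length(bad))
      stop("unsupported element(s): ", paste(bad, collapse = ", "))
    for (e in nm) counts[e] <- counts[e] + args[[e]]
  }
  if (any(counts < 0)) stop("atom counts must be non-negative")
  if (any(counts != round(counts))) stop("atom counts must be integers")
  structure(counts, class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  f <- if (length(nz)) paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = "")
       else "(empty)"
  cat("<elemental composition> ", f, "  (",
      format(monoisotopic_mass(x), nsmall = 6), " Da monoisotopic)\n",
      sep = "")
  invisible(x)
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  structure(unclass(e1) + unclass(e2), class = "elemental_composition")
}

#' @export
`-.elemental_composition` <- function(e1, e2) {
  out <- unclass(e1) - unclass(e2)
  if (any(out < 0))
    stop("composition subtraction would give negative count for: ",
         paste(names(out)[out < 0], collapse = ", "))
  structure(out, class = "elemental_composition")
}

#' @export
`*.elemental_composition` <- function(e1, e2) {
  if (is.numeric(e2)) structure(unclass(e1) * e2, class = "elemental_composition")
  else structure(unclass(e2) * e1, class = "elemental_composition")
}

#' Composition of a water molecule
#' @return H2O as an `elemental_composition`.
#' @export
water_composition <- function() composition(H = 2, O = 1)

#' Elemental composition of a peptide or protein sequence
#'
#' Sums the residue compositions of a one-letter amino-acid string and adds
#' one water for the free termini. The empty sequence therefore returns the
#' composition of water alone.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @return An `elemental_composition`.
#' @examples
#' composition_from_sequence("G")  # C2H5NO2, 75.03203 Da
#' @export
composition_from_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!(res %in% names(.aa_residues)))
  if (length(bad))
    stop("unknown residue code '", res[bad[1]], "' at position ", bad[1])
  counts <- stats::setNames(numeric(length(supported_elements())),
                            supported_elements())
  for (r in res) {
    rc <- .aa_residues[[r]]
    counts[names(rc)] <- counts[names(rc)] + rc
  }
  structure(counts, class = "elemental_composition") + water_composition()
}

#' Monoisotopic mass of a composition
#'
#' Sum over elements of atom count times the mass of the element's lightest
#' isotope. Additive: `monoisotopic_mass(a + b)` equals
#' `monoisotopic_mass(a) + monoisotopic_mass(b)`.
#'
#' @param comp An `elemental_composition`.
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  sum(vapply(names(.isotopes),
             function(e) comp[[e]] * .isotopes[[e]]$mass[1], numeric(1)))
}

#' m/z of a positive ion
#'
#' `(neutral_mass + charge * proton) / charge` for protonated species.
#' [neutral_from_mz()] is the exact inverse.
#'
#' @param neutral_mass Neutral monoisotopic (or isotopologue) mass, Da.
#' @param charge Positive integer charge state.
#' @return m/z in Th.
#' @export
mz <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  (neutral_mass + charge * physical_constants$proton) / charge
}

#' @rdname mz
#' @param x Observed m/z.
#' @export
neutral_from_mz <- function(x, charge) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  x * charge - charge * physical_constants$proton
}
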