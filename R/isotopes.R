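# Aggregated isotopologue distributions.
#
# A distribution is carried internally as a data.frame with columns
#   offset : nucleon offset from the monoisotopic peak (integer, >= 0)
#   ab     : summed abundance of all isotopologues at that offset
#   am     : abundance-weighted mass sum (so mass = am / ab)
# Convolution of two species adds offsets and masses and multiplies
# abundances; aggregation by offset keeps the representation linear in the
# atom count.

# exact polynomial convolution of two (ab, am) ladders on the offset grid;
# direct O(n*m) sums rather than FFT so entries near the abundance floor
# keep full relative precision
.iso_convolve <- function(a, b) {
  na <- length(a$ab); nb <- length(b$ab)
  ab <- numeric(na + nb - 1L)
  am <- numeric(na + nb - 1L)
  for (i in seq_len(na)) {
    idx <- i:(i + nb - 1L)
    ab[idx] <- ab[idx] + a$ab[i] * b$ab
    am[idx] <- am[idx] + a$ab[i] * b$am + a$am[i] * b$ab
  }
  keep <- which(ab > 0)
  keep <- seq_len(max(keep))
  list(ab = ab[keep], am = am[keep])
}

# n-fold self-convolution by exponentiation by squaring
.iso_power <- function(single, n) {
  result <- list(ab = 1, am = 0)
  base <- single
  while (n > 0) {
    if (n %% 2 == 1) result <- .iso_convolve(result, base)
    n <- n %/% 2
    if (n > 0) base <- .iso_convolve(base, base)
  }
  result
}

#' Aggregated isotope distribution of a composition
#'
#' Computes the isotopologue ladder of an elemental composition, aggregated
#' by nucleon offset from the monoisotopic peak. Each element's n-atom
#' distribution is obtained by exact self-convolution of its single-atom
#' isotope distribution; elements are then convolved together. The exact
#' mass reported for each offset class is the abundance-weighted mean mass
#' of the isotopologues in the class. Entries below `prune_threshold`
#' (absolute abundance fraction) are dropped from the final result only,
#' so retained abundances are exact to floating-point precision.
#'
#' @param comp An `elemental_composition`.
#' @param prune_threshold Drop final entries with abundance below this
#'   fraction. Default 1e-10.
#' @return An object of class `isotope_pattern`: data.frame with columns
#'   `offset` (integer nucleon offset, entry 0 = monoisotopic), `mass`
#'   (abundance-weighted exact mass, Da) and `abundance` (fraction; sums to
#'   1 minus pruning losses). Masses are strictly increasing with offset.
#' @examples
#' isotope_distribution(composition(C = 100))
#' @export
isotope_distribution <- function(comp, prune_threshold = 1e-10) {
  stopifnot(inherits(comp, "elemental_composition"))
  if (!(prune_threshold > 0 && prune_threshold < 1))
    stop("prune_threshold must be in (0, 1)")
  dist <- list(ab = 1, am = 0)
  for (e in names(.isotopes)) {
    n <- comp[[e]]
    if (n == 0) next
    iso <- .isotopes[[e]]
    off <- round(iso$mass - iso$mass[1])
    ab <- numeric(max(off) + 1L)
    am <- numeric(max(off) + 1L)
    ab[off + 1L] <- iso$abundance
    am[off + 1L] <- iso$abundance * iso$mass
    dist <- .iso_convolve(dist, .iso_power(list(ab = ab, am = am), n))
  }
  offset <- seq_along(dist$ab) - 1L
  keep <- dist$ab >= prune_threshold
  out <- data.frame(offset = offset[keep],
                    mass = dist$am[keep] / dist$ab[keep],
                    abundance = dist$ab[keep])
  structure(out, class = c("isotope_pattern", "data.frame"))
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope pattern> ", nrow(x), " offsets, abundance sum ",
      format(sum(x$abundance), digits = 10), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 12), ...)
  if (nrow(x) > 12) cat("... ", nrow(x) - 12, " more rows\n", sep = "")
  invisible(x)
}

#' Most abundant isotopologue of a pattern
#'
#' @param pattern An `isotope_pattern`.
#' @return The row (offset, mass, abundance) with maximal abundance.
#' @export
most_abundant_isotopologue <- function(pattern) {
  stopifnot(inherits(pattern, "isotope_pattern"))
  pattern[which.max(pattern$abundance), , drop = FALSE]
}
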