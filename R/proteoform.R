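#' Modification definitions
#'
#' A modification is a named, signed elemental delta plus a site rule saying
#' which residues (or terminus) it may occupy. Built-in modifications:
#'
#' * `methyl` (+CH2, +14.015650 Da; K/R side chains)
#' * `acetyl` (+C2H2O, +42.010565 Da; K side chains)
#' * `nterm_acetyl` (+C2H2O at residue 1, the protein alpha-amine)
#' * `water_loss` (-H2O, -18.010565 Da; any residue, typically unlocalized)
#'
#' @param name Modification name (one of the built-ins, or a new label when
#'   `gain`/`loss` are given).
#' @param gain,loss `elemental_composition` gained / lost.
#' @param site_rule Character: residue one-letter codes the modification may
#'   occupy (e.g. `"KR"`), `"nterm"` (residue 1 only), or `"*"` (any).
#' @return An object of class `modification` with fields `name`, `gain`,
#'   `loss`, `site_rule` and `delta_mass` (Da).
#' @export
modification <- function(name, gain = composition(), loss = composition(),
                         site_rule = "*") {
  if (missing(gain) && missing(loss) && name %in% names(.builtin_mods))
    return(.builtin_mods[[name]])
  structure(list(name = name, gain = gain, loss = loss,
                 site_rule = site_rule,
                 delta_mass = monoisotopic_mass(gain) - monoisotopic_mass(loss)),
            class = "modification")
}

.make_mod <- function(name, gain, loss, site_rule)
  structure(list(name = name, gain = gain, loss = loss, site_rule = site_rule,
                 delta_mass = monoisotopic_mass(gain) - monoisotopic_mass(loss)),
            class = "modification")

.builtin_mods <- list(
  methyl       = NULL, acetyl = NULL, nterm_acetyl = NULL, water_loss = NULL
)

# deferred so composition() exists at build time
.init_builtin_mods <- function() {
  .builtin_mods$methyl <<- .make_mod("methyl", composition(C = 1, H = 2),
                                     composition(), "KR")
  .builtin_mods$acetyl <<- .make_mod("acetyl", composition(C = 2, H = 2, O = 1),
                                     composition(), "K")
  .builtin_mods$nterm_acetyl <<- .make_mod("nterm_acetyl",
                                           composition(C = 2, H = 2, O = 1),
                                           composition(), "nterm")
  .builtin_mods$water_loss <<- .make_mod("water_loss", composition(),
                                         composition(H = 2, O = 1), "*")
  invisible(NULL)
}
.init_builtin_mods()

#' @export
print.modification <- function(x, ...) {
  cat("<modification> ", x$name, sprintf(" (%+.6f Da, sites: %s)\n",
      x$delta_mass, x$site_rule), sep = "")
  invisible(x)
}

#' Proteoforms
#'
#' A proteoform is a base sequence plus a multiset of modifications, each
#' optionally localized to a 1-based residue index on the mature sequence
#' (for histone H2B, residue 1 is the mature N-terminal serine).
#'
#' @param sequence One-letter amino-acid string of the mature protein.
#' @param modifications List of modification entries; each entry is a list
#'   with fields `mod` (a [modification()] or built-in name), `count`
#'   (default 1) and optional `site` (1-based residue index; `NA` =
#'   unlocalized).
#' @param label Display label; defaults to an auto-generated one.
#' @return An object of class `proteoform`.
#' @examples
#' proteoform("SAKAEK", modifications = list(
#'   list(mod = "methyl", count = 2, site = 3)))
#' @export
proteoform <- function(sequence, modifications = list(), label = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  mods <- lapply(modifications, function(m) {
    if (inherits(m, "modification")) m <- list(mod = m)
    if (is.character(m$mod)) m$mod <- modification(m$mod)
    if (is.null(m$count)) m$count <- 1L
    if (is.null(m$site)) m$site <- NA_integer_
    if (!is.na(m$site) && (m$site < 1 || m$site > n))
      stop("modification site ", m$site, " outside [1, ", n, "]")
    m
  })
  if (is.null(label)) label <- .proteoform_label(mods)
  structure(list(sequence = sequence, modifications = mods, label = label),
            class = "proteoform")
}

.proteoform_label <- function(mods) {
  if (!length(mods)) return("unmodified")
  paste(vapply(mods, function(m) {
    s <- if (!is.na(m$site)) paste0("@", m$site) else ""
    if (m$count == 1) paste0(m$mod$name, s) else
      paste0(m$count, "x", m$mod$name, s)
  }, character(1)), collapse = "+")
}

#' @export
print.proteoform <- function(x, ...) {
  cat("<proteoform> ", x$label, " (", nchar(x$sequence), " aa, ",
      sprintf("%.4f", proteoform_mass(x)), " Da neutral monoisotopic)\n",
      sep = "")
  invisible(x)
}

#' Elemental composition of a proteoform
#'
#' Base sequence composition plus all modification gains, minus all losses.
#' When a modification is localized, its site rule is checked against the
#' residue at that index (`check_sites = TRUE`, the default); unlocalized
#' modifications are never site-checked at this level.
#'
#' @param p A `proteoform`.
#' @param check_sites Validate localized sites against each modification's
#'   site rule.
#' @return An `elemental_composition`.
#' @export
apply_modifications <- function(p, check_sites = TRUE) {
  stopifnot(inherits(p, "proteoform"))
  comp <- composition_from_sequence(p$sequence)
  for (m in p$modifications) {
    if (check_sites && !is.na(m$site)) .check_site(m, p$sequence)
    for (k in seq_len(m$count)) comp <- comp + m$mod$gain - m$mod$loss
  }
  comp
}

.check_site <- function(m, sequence) {
  rule <- m$mod$site_rule
  if (rule == "*") return(invisible(TRUE))
  if (rule == "nterm") {
    if (m$site != 1L)
      stop("modification '", m$mod$name, "' is N-terminal only (site ",
           m$site, " given)")
    return(invisible(TRUE))
  }
  res <- substr(sequence, m$site, m$site)
  if (!grepl(res, rule, fixed = TRUE))
    stop("modification '", m$mod$name, "' not allowed on residue ", res,
         " at site ", m$site, " (allowed: ", rule, ")")
  invisible(TRUE)
}

#' Neutral monoisotopic mass of a proteoform
#' @inheritParams apply_modifications
#' @return Mass in Da.
#' @export
proteoform_mass <- function(p, check_sites = FALSE)
  monoisotopic_mass(apply_modifications(p, check_sites = check_sites))

#' Resolve the adduct convention of a printed reference mass
#'
#' Literature monoisotopic masses for intact proteins are sometimes printed
#' as neutral masses and sometimes as proton adducts, and the labelling is
#' not always reliable. This computes both the neutral and the \[M+H\]+
#' monoisotopic mass of a sequence and returns whichever agrees with the
#' printed reference within `tol_ppm`. The returned convention should then
#' be applied pipeline-wide at I/O boundaries (internally all masses are
#' neutral).
#'
#' @param sequence Mature protein sequence.
#' @param printed_reference The literature mass, Da.
#' @param tol_ppm Agreement tolerance, ppm (default 1).
#' @return A list with `convention` (`"neutral"` or `"proton_adduct"`), the
#'   matched mass, its ppm error, and both candidate masses.
#' @export
calibrate_mass_convention <- function(sequence, printed_reference,
                                      tol_ppm = 1) {
  m_neutral <- monoisotopic_mass(composition_from_sequence(sequence))
  m_adduct <- m_neutral + physical_constants$proton
  err_n <- ppm_error(printed_reference, m_neutral)
  err_a <- ppm_error(printed_reference, m_adduct)
  if (abs(err_n) <= tol_ppm && abs(err_a) > tol_ppm)
    conv <- "neutral"
  else if (abs(err_a) <= tol_ppm && abs(err_n) > tol_ppm)
    conv <- "proton_adduct"
  else if (abs(err_n) <= tol_ppm && abs(err_a) <= tol_ppm)
    conv <- if (abs(err_n) <= abs(err_a)) "neutral" else "proton_adduct"
  else
    stop(sprintf(paste0(
      "printed reference %.4f Da matches neither the neutral monoisotopic ",
      "mass (%.4f Da, %.2f ppm) nor the proton adduct (%.4f Da, %.2f ppm) ",
      "within %g ppm"),
      printed_reference, m_neutral, err_n, m_adduct, err_a, tol_ppm))
  matched <- if (conv == "neutral") m_neutral else m_adduct
  list(convention = conv, matched_mass = matched,
       error_ppm = ppm_error(printed_reference, matched),
       neutral_mass = m_neutral, adduct_mass = m_adduct)
}

#' Read a single-record protein FASTA
#'
#' @param path Path to a FASTA file with one record.
#' @return A list with `id` (first token of the description line) and
#'   `sequence`.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 1L)
    stop("expected a single-record FASTA, found ", length(set), " records")
  list(id = strsplit(names(set)[1], "\\s+")[[1]][1],
       sequence = as.character(set[[1]]))
}

#' Mature yeast histone H2B sequence
#'
#' Reads the bundled H2B precursor fixture (RefSeq NP_010510.1, transcribed
#' into `inst/extdata/`) and removes the initiator methionine, so that
#' residue 1 is the mature N-terminal serine and lysine 37 is the K37 of
#' the histone literature.
#'
#' @return The 130-residue mature sequence string.
#' @export
h2b_mature_sequence <- function() {
  path <- system.file("extdata", "H2B_NP_010510.1.fasta",
                      package = "topdownptm", mustWork = TRUE)
  seq <- read_protein_fasta(path)$sequence
  if (substr(seq, 1, 1) != "M")
    stop("H2B fixture does not start with an initiator methionine")
  substr(seq, 2, nchar(seq))
}
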