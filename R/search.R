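#' Signed relative mass error in parts per million
#'
#' @param observed Observed mass, Da.
#' @param theoretical Theoretical mass, Da (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`, signed.
#' @examples
#' ppm_error(14113.6028, 14113.6056)  # about -0.198 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be > 0")
  (observed - theoretical) / theoretical * 1e6
}

#' Candidate PTM search space
#'
#' Defines the combinatorial space of modification compositions considered
#' when matching an intact mass: up to `max_methyl` methyls and `max_acetyl`
#' internal acetyls (jointly capped at `max_total` marks), optionally with
#' N-terminal acetylation and/or a water loss. The defaults generate a
#' superset of the nine proteoform classes observed for yeast H2B.
#'
#' @param max_methyl,max_acetyl Per-type caps on modification units.
#' @param max_total Combined cap on methyl + acetyl units.
#' @param allow_nterm_acetyl,allow_water_loss Include these binary marks.
#' @return An object of class `candidate_space`.
#' @export
candidate_space <- function(max_methyl = 4, max_acetyl = 4, max_total = 4,
                            allow_nterm_acetyl = TRUE,
                            allow_water_loss = TRUE) {
  stopifnot(max_methyl >= 0, max_acetyl >= 0, max_total >= 0)
  structure(list(max_methyl = max_methyl, max_acetyl = max_acetyl,
                 max_total = max_total,
                 allow_nterm_acetyl = allow_nterm_acetyl,
                 allow_water_loss = allow_water_loss),
            class = "candidate_space")
}

#' Enumerate candidate proteoforms
#'
#' Deterministic, duplicate-free enumeration of all modification
#' combinations allowed by a [candidate_space()] applied to a base
#' proteoform, ordered by total delta mass. Candidates carry composition
#' classes only (no sites): site localization is the fragment-ladder
#' module's job.
#'
#' @param space A `candidate_space`.
#' @param base A `proteoform` (typically unmodified).
#' @return A data.frame with columns `label`, `n_methyl`, `n_acetyl`,
#'   `nterm_acetyl`, `water_loss`, `delta_mass`, `neutral_mass`, and a
#'   `proteoform` list-column.
#' @export
enumerate_candidates <- function(space, base) {
  stopifnot(inherits(space, "candidate_space"), inherits(base, "proteoform"))
  base_mass <- proteoform_mass(base)
  grid <- expand.grid(
    n_methyl = 0:space$max_methyl,
    n_acetyl = 0:space$max_acetyl,
    nterm_acetyl = if (space$allow_nterm_acetyl) c(FALSE, TRUE) else FALSE,
    water_loss = if (space$allow_water_loss) c(FALSE, TRUE) else FALSE,
    KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$n_methyl + grid$n_acetyl <= space$max_total, ,
               drop = FALSE]
  mods_of <- function(r) {
    mods <- list()
    if (r$n_methyl > 0)
      mods <- c(mods, list(list(mod = "methyl", count = r$n_methyl)))
    if (r$n_acetyl > 0)
      mods <- c(mods, list(list(mod = "acetyl", count = r$n_acetyl)))
    if (r$nterm_acetyl)
      mods <- c(mods, list(list(mod = "nterm_acetyl", count = 1L)))
    if (r$water_loss)
      mods <- c(mods, list(list(mod = "water_loss", count = 1L)))
    mods
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid[i, ]
    p <- proteoform(base$sequence, mods_of(r), label = .class_label(r))
    delta <- proteoform_mass(p) - base_mass
    data.frame(label = p$label, n_methyl = r$n_methyl, n_acetyl = r$n_acetyl,
               nterm_acetyl = r$nterm_acetyl, water_loss = r$water_loss,
               delta_mass = delta, neutral_mass = base_mass + delta)
  })
  out <- do.call(rbind, rows)
  out$proteoform <- lapply(seq_len(nrow(grid)), function(i)
    proteoform(base$sequence, mods_of(grid[i, ]),
               label = .class_label(grid[i, ])))
  out <- out[order(out$delta_mass, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Table-1-style class labels: "Ac-aS1+2Me", "Me2", "H2B-H2O", ...
.class_label <- function(r) {
  parts <- character(0)
  if (r$nterm_acetyl) parts <- c(parts, "Ac-aS1")
  marks <- character(0)
  if (r$n_methyl > 0)
    marks <- c(marks, if (r$n_methyl == 1) "Me" else paste0(r$n_methyl, "Me"))
  if (r$n_acetyl > 0)
    marks <- c(marks, if (r$n_acetyl == 1) "Ac" else paste0(r$n_acetyl, "Ac"))
  if (length(marks)) parts <- c(parts, paste(marks, collapse = "+"))
  lab <- paste(parts, collapse = "+")
  if (lab == "") lab <- "unmodified"
  if (r$water_loss) lab <- if (lab == "unmodified") "-H2O"
                           else paste0(lab, "-H2O")
  lab
}

#' Match an observed intact mass against candidate proteoforms
#'
#' Returns all candidates whose theoretical neutral mass lies within
#' `tol_ppm` of the observed mass, ranked by absolute ppm error, then by
#' parsimony (fewer total modification units), then label.
#'
#' @param observed Observed neutral monoisotopic mass, Da.
#' @param candidates Candidate table from [enumerate_candidates()].
#' @param tol_ppm Matching tolerance, ppm (default 1, the usual FTICR
#'   intact-mass tolerance).
#' @return A data.frame of matches with columns `rank`, `label`,
#'   `observed_mass`, `theoretical_mass`, `error_ppm`, `n_units`; empty
#'   (zero rows) if nothing matches.
#' @export
match_mass <- function(observed, candidates, tol_ppm = 1) {
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  err <- ppm_error(observed, candidates$neutral_mass)
  units <- candidates$n_methyl + candidates$n_acetyl +
    candidates$nterm_acetyl + candidates$water_loss
  keep <- which(abs(err) <= tol_ppm)
  out <- data.frame(label = candidates$label[keep],
                    observed_mass = rep(observed, length(keep)),
                    theoretical_mass = candidates$neutral_mass[keep],
                    error_ppm = err[keep], n_units = units[keep])
  out <- out[order(abs(out$error_ppm), out$n_units, out$label), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "label", "observed_mass", "theoretical_mass",
          "error_ppm", "n_units")]
}

#' Build a proteoform report table
#'
#' Combines mass matches with relative abundances into one report row per
#' observed proteoform class. When several candidates lie within tolerance
#' of the same observed mass (e.g. trimethyl vs acetyl, 0.0364 Da apart),
#' the row carries a joint label (`"3Me/Ac"` style) with all errors listed
#' and is flagged ambiguous. Classes with no site evidence are marked
#' unlocalized.
#'
#' @param matches A list of match tables (one per observed mass, as
#'   returned by [match_mass()]).
#' @param abundances Numeric vector of relative abundances (percent),
#'   parallel to `matches`; `NA` allowed.
#' @param localized_sites Optional character vector of site annotations
#'   parallel to `matches` (e.g. `"K37"`), `NA` = not localized.
#' @return A data.frame with columns `label`, `abundance_percent`,
#'   `observed_mass`, `theoretical_mass`, `error_ppm`, `localized_sites`,
#'   `ambiguity_flag`.
#' @export
build_ptm_table <- function(matches, abundances = NULL,
                            localized_sites = NULL) {
  stopifnot(is.list(matches))
  n <- length(matches)
  if (is.null(abundances)) abundances <- rep(NA_real_, n)
  if (is.null(localized_sites)) localized_sites <- rep(NA_character_, n)
  rows <- lapply(seq_len(n), function(i) {
    m <- matches[[i]]
    if (!nrow(m)) return(NULL)
    joint <- nrow(m) > 1
    data.frame(
      label = paste(m$label, collapse = "/"),
      abundance_percent = abundances[i],
      observed_mass = m$observed_mass[1],
      theoretical_mass = m$theoretical_mass[1],
      error_ppm = paste(sprintf("%.3f", m$error_ppm), collapse = "/"),
      localized_sites = if (is.na(localized_sites[i])) "unassigned"
                        else localized_sites[i],
      ambiguity_flag = joint)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = character(0), abundance_percent = numeric(0),
                      observed_mass = numeric(0),
                      theoretical_mass = numeric(0),
                      error_ppm = character(0),
                      localized_sites = character(0),
                      ambiguity_flag = logical(0))
  rownames(out) <- NULL
  out
}

#' Write a proteoform report as TSV
#' @param table Report from [build_ptm_table()] (or an abundance table).
#' @param path Output path.
#' @export
write_report_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
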