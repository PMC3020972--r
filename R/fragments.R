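# ECD c / z-radical fragment ladders and breakpoint localization.

# cumulative residue masses, with localized modification deltas applied at
# their residue index; unlocalized mods are an error (callers iterate sites)
.residue_masses <- function(p) {
  res <- strsplit(p$sequence, "")[[1]]
  m <- vapply(res, function(r) {
    rc <- .aa_residues[[r]]
    sum(rc * vapply(names(rc), function(e) .isotopes[[e]]$mass[1],
                    numeric(1)))
  }, numeric(1))
  for (mod in p$modifications) {
    if (is.na(mod$site))
      stop("fragment ladders require localized modifications; '",
           mod$mod$name, "' has no site (iterate candidate sites instead)")
    m[mod$site] <- m[mod$site] + mod$count * mod$mod$delta_mass
  }
  unname(m)
}

#' ECD c / z-radical fragment ladders
#'
#' Generates the theoretical c and z-radical ion ladders of a proteoform
#' with fully localized modifications, at charges `1..max_charge`. The
#' adopted chemistry is `c_i = sum(residues 1..i) + NH3` (17.026549 Da) and
#' `z_j = sum(residues n-j+1..n) + 1.991841` Da, which satisfies the
#' complementarity identity `c_i + z_(n-i) = M_neutral + 1.007825 Da` at
#' every cleavage site.
#'
#' @param p A `proteoform`; every modification must carry a site.
#' @param types Ion types to emit, subset of `c("c", "z")`.
#' @param max_charge Fragment charges 1..`max_charge` are emitted.
#' @return A data.frame of fragment ions: `type`, `index` (residues from
#'   the respective terminus, 1-based, up to n-1), `charge`,
#'   `neutral_mass`, `mz`.
#' @export
fragment_ladder <- function(p, types = c("c", "z"), max_charge = 1) {
  stopifnot(inherits(p, "proteoform"))
  n <- nchar(p$sequence)
  if (n < 2) stop("sequence must have length >= 2")
  types <- match.arg(types, c("c", "z"), several.ok = TRUE)
  rm <- .residue_masses(p)
  idx <- seq_len(n - 1L)
  rows <- list()
  if ("c" %in% types) {
    neutral <- cumsum(rm)[idx] + physical_constants$ammonia
    rows$c <- data.frame(type = "c", index = idx, neutral_mass = neutral)
  }
  if ("z" %in% types) {
    neutral <- cumsum(rev(rm))[idx] + physical_constants$z_ion
    rows$z <- data.frame(type = "z", index = idx, neutral_mass = neutral)
  }
  base <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(seq_len(max_charge), function(z)
    cbind(base, charge = z, mz = mz(base$neutral_mass, z))))
  rownames(out) <- NULL
  out[, c("type", "index", "charge", "neutral_mass", "mz")]
}

#' Paired shifted / unshifted ladders for localization
#'
#' Builds the c/z ladders of the unmodified hypothesis and of the
#' mass-shifted hypothesis (every fragment shifted by the full delta mass),
#' tagged with a `variant` column. Matching observed MS/MS peaks against
#' this combined set classifies each ladder index as shifted, unshifted or
#' unobserved — the input [localize()] needs.
#'
#' @param base A `proteoform` carrying the modifications shared by both
#'   hypotheses (fully localized).
#' @param delta An `elemental_composition` gained by the shifted form (e.g.
#'   2 methyls, C2H4).
#' @param max_charge Fragment charges 1..`max_charge`.
#' @param types Ion types.
#' @return A fragment table as in [fragment_ladder()] plus a `variant`
#'   column (`"unshifted"` / `"shifted"`).
#' @export
localization_ladders <- function(base, delta, max_charge = 1,
                                 types = c("c", "z")) {
  dm <- monoisotopic_mass(delta)
  un <- fragment_ladder(base, types, max_charge)
  sh <- un
  sh$neutral_mass <- sh$neutral_mass + dm
  sh$mz <- mz(sh$neutral_mass, sh$charge)
  un$variant <- "unshifted"
  sh$variant <- "shifted"
  rbind(un, sh)
}

#' Match observed MS/MS peaks to theoretical fragments
#'
#' Each observed centroid is assigned to at most one theoretical fragment
#' (the one with smallest absolute ppm error within `tol_ppm`); peaks
#' matching nothing are reported separately, never an error.
#'
#' @param observed A centroid `mass_spectrum`.
#' @param ladder Fragment table from [fragment_ladder()] or
#'   [localization_ladders()].
#' @param tol_ppm Matching tolerance, ppm (default 10, a typical
#'   fragment-ion tolerance).
#' @param min_intensity Peaks below this intensity are not matched and go
#'   to the unassigned list (default 0, i.e. off).
#' @return A list with `assignments` (the ladder rows matched, plus
#'   `mz_observed`, `intensity`, `error_ppm`, and `ambiguous_match`, TRUE
#'   when more than one theoretical fragment lay within tolerance of the
#'   peak) and `unassigned` (data.frame of unmatched peaks).
#' @export
match_fragments <- function(observed, ladder, tol_ppm = 10,
                            min_intensity = 0) {
  stopifnot(inherits(observed, "mass_spectrum"),
            observed$mode == "centroid")
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  empty <- ladder[0, , drop = FALSE]
  empty$mz_observed <- numeric(0); empty$intensity <- numeric(0)
  empty$error_ppm <- numeric(0); empty$ambiguous_match <- logical(0)
  if (!length(observed$mz) || !nrow(ladder))
    return(list(assignments = empty,
                unassigned = data.frame(mz = observed$mz,
                                        intensity = observed$intensity)))
  ord <- order(ladder$mz)
  lad <- ladder[ord, , drop = FALSE]
  rows <- list()
  unmatched <- logical(length(observed$mz))
  for (i in seq_along(observed$mz)) {
    o <- observed$mz[i]
    if (observed$intensity[i] < min_intensity) { unmatched[i] <- TRUE; next }
    # every ladder entry within tolerance: the closest is the assignment,
    # additional ones make the assignment ambiguous
    win <- o * tol_ppm * 1e-6
    j1 <- findInterval(o - win, lad$mz) + 1L
    j2 <- findInterval(o + win, lad$mz)
    if (j2 < j1) { unmatched[i] <- TRUE; next }
    cand <- j1:j2
    err <- ppm_error(o, lad$mz[cand])
    best <- which.min(abs(err))
    r <- lad[cand[best], , drop = FALSE]
    r$mz_observed <- o
    r$intensity <- observed$intensity[i]
    r$error_ppm <- err[best]
    # entries at (near-)identical theoretical m/z are one fragment species,
    # not an ambiguity
    distinct <- unique(round(lad$mz[cand], 6))
    r$ambiguous_match <- length(distinct) > 1L
    rows[[length(rows) + 1L]] <- r
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(assignments) <- NULL
  list(assignments = assignments,
       unassigned = data.frame(mz = observed$mz[unmatched],
                               intensity = observed$intensity[unmatched]))
}

#' Localize a mass delta by fragment-ladder breakpoint analysis
#'
#' Given fragment assignments against the paired shifted/unshifted ladders,
#' brackets the modified residue: an unshifted c_i places the site after
#' residue i, a shifted c_i places it at or before residue i, and z ions
#' contribute the mirror-image constraints from the C terminus. The
#' reported interval is the tightest residue range consistent with all
#' matched ions; the site call is unique only when the interval collapses
#' to a single residue. An optional residue-type filter (e.g. `"K"` for
#' methylation chemistry) may narrow the candidate set and is always
#' flagged in the result, never applied silently.
#'
#' @param delta The `elemental_composition` being localized.
#' @param assignments Assignment table from [match_fragments()] run against
#'   [localization_ladders()] output (must carry the `variant` column).
#' @param sequence The protein sequence.
#' @param residue_filter Optional string of allowed residue letters.
#' @return An object of class `localization_result`: list with
#'   `delta_mass`, `interval` (c(start, end) or NULL when no shifted ion
#'   matched), `site_call` (residue index or `"ambiguous"`),
#'   `candidate_sites`, `n_supporting_c`, `n_supporting_z`, `filtered`.
#' @export
localize <- function(delta, assignments, sequence, residue_filter = NULL) {
  if (is.null(assignments$variant))
    stop("assignments must come from localization_ladders() matching")
  n <- nchar(sequence)
  a <- assignments
  # peaks compatible with more than one theoretical fragment are not
  # site-determining evidence
  if (!is.null(a$ambiguous_match)) a <- a[!a$ambiguous_match, , drop = FALSE]
  # an index observed both shifted and unshifted (same ion type) is
  # self-contradictory evidence
  for (tp in c("c", "z")) {
    both <- intersect(a$index[a$type == tp & a$variant == "shifted"],
                      a$index[a$type == tp & a$variant == "unshifted"])
    if (length(both))
      stop("contradictory evidence: ", tp, " ion index ", both[1],
           " matched both shifted and unshifted within tolerance")
  }
  c_sh <- a$index[a$type == "c" & a$variant == "shifted"]
  c_un <- a$index[a$type == "c" & a$variant == "unshifted"]
  z_sh <- a$index[a$type == "z" & a$variant == "shifted"]
  z_un <- a$index[a$type == "z" & a$variant == "unshifted"]
  n_c <- length(unique(c_sh)); n_z <- length(unique(z_sh))
  res <- list(delta_mass = monoisotopic_mass(delta),
              n_supporting_c = n_c, n_supporting_z = n_z,
              filtered = !is.null(residue_filter))
  if (n_c + n_z == 0) {
    res$interval <- NULL
    res$candidate_sites <- integer(0)
    res$site_call <- "ambiguous"
    class(res) <- "localization_result"
    return(res)
  }
  lower <- max(1L, if (length(c_un)) max(c_un) + 1L else 1L,
               if (length(z_sh)) n - min(z_sh) + 1L else 1L)
  upper <- min(n, if (length(c_sh)) min(c_sh) else n,
               if (length(z_un)) n - max(z_un) else n)
  if (lower > upper)
    stop("contradictory evidence: shifted/unshifted ions bracket an empty ",
         "interval [", lower, ", ", upper, "]")
  sites <- lower:upper
  if (!is.null(residue_filter)) {
    res_letters <- strsplit(sequence, "")[[1]][sites]
    sites <- sites[res_letters %in% strsplit(residue_filter, "")[[1]]]
  }
  res$interval <- c(lower, upper)
  res$candidate_sites <- sites
  res$site_call <- if (length(sites) == 1L) sites else "ambiguous"
  class(res) <- "localization_result"
  res
}

#' @export
print.localization_result <- function(x, ...) {
  cat("<localization> delta ", sprintf("%+.4f", x$delta_mass), " Da; ",
      if (is.null(x$interval)) "no shifted ions matched"
      else paste0("interval [", x$interval[1], ", ", x$interval[2], "]"),
      "; site call: ", as.character(x$site_call),
      " (", x$n_supporting_c, " c / ", x$n_supporting_z, " z ions",
      if (x$filtered) ", residue-filtered", ")\n", sep = "")
  invisible(x)
}

#' Write a localization report as TSV
#' @param result A `localization_result` (or list of them).
#' @param path Output path.
#' @export
write_localization_tsv <- function(result, path) {
  if (inherits(result, "localization_result")) result <- list(result)
  rows <- lapply(result, function(x) data.frame(
    delta_mass = x$delta_mass,
    interval_start = if (is.null(x$interval)) NA_integer_ else x$interval[1],
    interval_end = if (is.null(x$interval)) NA_integer_ else x$interval[2],
    site_call = as.character(x$site_call),
    n_supporting_c = x$n_supporting_c,
    n_supporting_z = x$n_supporting_z,
    filtered_flag = x$filtered))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(delta_mass = numeric(0), interval_start = integer(0),
                      interval_end = integer(0), site_call = character(0),
                      n_supporting_c = integer(0),
                      n_supporting_z = integer(0), filtered_flag = logical(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
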