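#' Mass spectra
#'
#' A minimal spectrum container: ascending m/z values with non-negative
#' intensities, in either `profile` (continuum) or `centroid` (peak list)
#' mode, plus free-form metadata (resolution setting, charge range, ...).
#'
#' @param mz Numeric m/z values, strictly increasing.
#' @param intensity Non-negative intensities, same length.
#' @param mode `"profile"` or `"centroid"`.
#' @param metadata Named list of acquisition metadata.
#' @return An object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, mode = c("centroid", "profile"),
                          metadata = list()) {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("m/z values must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 mode = mode, metadata = metadata),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass spectrum> ", x$mode, ", ", length(x$mz), " points",
      if (length(x$mz)) sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)),
      "\n", sep = "")
  invisible(x)
}

#' Read / write two-column peak lists
#'
#' Whitespace-separated `m/z intensity` text with `#` comment lines, the
#' interchange format used for MS1 spectra throughout the package.
#'
#' @param path File path.
#' @param mode Spectrum mode to tag the result with.
#' @return A `mass_spectrum` (reader) or `path`, invisibly (writer).
#' @export
read_peaklist <- function(path, mode = "centroid") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(mass_spectrum(numeric(0), numeric(0), mode))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  ord <- order(m[, 1])
  mass_spectrum(m[ord, 1], m[ord, 2], mode)
}

#' @rdname read_peaklist
#' @param spec A `mass_spectrum`.
#' @param header Optional comment lines written at the top (without `#`).
#' @export
write_peaklist <- function(spec, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  writeLines(sprintf("%.6f %.6f", spec$mz, spec$intensity), con)
  invisible(path)
}

#' Read / write MGF peak lists
#'
#' A minimal Mascot Generic Format dialect (BEGIN IONS / END IONS blocks
#' with TITLE, PEPMASS and CHARGE headers) used for MS/MS spectra.
#'
#' @param path File path.
#' @return A list of `mass_spectrum` objects, one per IONS block, each with
#'   the block headers in its metadata.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1):(ends[i] - 1)]
    hdr <- grep("=", block, value = TRUE)
    meta <- list()
    for (h in hdr) {
      kv <- strsplit(h, "=", fixed = TRUE)[[1]]
      meta[[tolower(kv[1])]] <- paste(kv[-1], collapse = "=")
    }
    pk <- block[!grepl("=", block) & nzchar(trimws(block))]
    if (!length(pk))
      return(mass_spectrum(numeric(0), numeric(0), "centroid", meta))
    m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), as.numeric))
    ord <- order(m[, 1])
    mass_spectrum(m[ord, 1], m[ord, 2], "centroid", meta)
  })
}

#' @rdname read_mgf
#' @param spectra A `mass_spectrum` or list of them.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "mass_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    for (k in names(s$metadata))
      if (is.character(s$metadata[[k]]) || is.numeric(s$metadata[[k]]))
        writeLines(paste0(toupper(k), "=", s$metadata[[k]]), con)
    writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Centroid a profile spectrum
#'
#' Finds local maxima above a signal-to-noise threshold and refines each
#' apex by three-point parabolic interpolation. The noise level is taken as
#' the median of the positive profile intensities unless given explicitly.
#'
#' @param profile A profile-mode `mass_spectrum`.
#' @param snr_threshold Keep maxima with intensity >= `snr_threshold *
#'   noise_level`.
#' @param noise_level Noise intensity estimate; default `median(intensity
#'   > 0)`.
#' @return A centroid `mass_spectrum`.
#' @export
pick_peaks <- function(profile, snr_threshold = 3, noise_level = NULL) {
  stopifnot(inherits(profile, "mass_spectrum"))
  if (profile$mode != "profile")
    stop("pick_peaks() requires a profile-mode spectrum")
  x <- profile$mz; y <- profile$intensity
  n <- length(y)
  if (n < 3) return(mass_spectrum(numeric(0), numeric(0), "centroid",
                                  profile$metadata))
  if (is.null(noise_level)) {
    pos <- y[y > 0]
    noise_level <- if (length(pos)) stats::median(pos) else 0
  }
  thr <- snr_threshold * noise_level
  i <- 2:(n - 1)
  apex <- i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] > thr & y[i] > 0]
  if (!length(apex)) return(mass_spectrum(numeric(0), numeric(0), "centroid",
                                          profile$metadata))
  # parabola through (x[-1], y[-1]), (x0, y0), (x[+1], y[+1]) on an
  # approximately uniform local grid
  yl <- y[apex - 1]; y0 <- y[apex]; yr <- y[apex + 1]
  denom <- yl - 2 * y0 + yr
  delta <- ifelse(denom == 0, 0, 0.5 * (yl - yr) / denom)
  dx <- (x[apex + 1] - x[apex - 1]) / 2
  cmz <- x[apex] + delta * dx
  cint <- y0 - 0.25 * (yl - yr) * delta
  ord <- order(cmz)
  mass_spectrum(cmz[ord], cint[ord], "centroid", profile$metadata)
}

#' Expected isotopic peak spacing for a charge state
#'
#' Validation utility: adjacent isotopologue peaks of a z-charged envelope
#' are separated by about 1.00235/z Th (the average nucleon mass
#' difference over charge). Useful for sanity-checking a hypothesized
#' charge against observed spacing; the pipeline itself assigns charge by
#' candidate-driven matching, not by spacing inference.
#'
#' @param charge Charge state.
#' @return Expected spacing in Th.
#' @export
isotope_spacing <- function(charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  1.00235 / charge
}
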