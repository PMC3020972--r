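# Seeded simulator of microESI-FTICR MS1 and ECD MS/MS spectra.

#' Simulator configuration
#'
#' Instrument and noise parameters for the FTICR spectrum simulator.
#' Resolution follows the FTICR scaling `R(m) = R0 * (400 / m)`; the
#' default `R0` of 580,000 at m/z 400 matches a 12 T instrument operated in
#' broadband mode. Default MS1 charge states 9/10/11 with weights
#' 0.3/0.4/0.3 place the main envelope of a ~14 kDa protein near m/z 1400.
#'
#' @param resolution Resolving power at the reference m/z.
#' @param reference_mz Reference m/z for the resolution setting (400).
#' @param charges MS1 charge states emitted.
#' @param charge_weights Relative intensity of each charge state.
#' @param n_noise_peaks Uniform-random noise peaks added per spectrum.
#' @param noise_intensity Noise peak intensity scale, as a fraction of the
#'   simulated base peak.
#' @param jitter_sigma Multiplicative log-normal intensity jitter applied
#'   per theoretical peak (0.02 = about 2 percent RSD).
#' @param fragment_detection_prob Probability that an emitted ECD fragment
#'   ion is detected (partial ladder coverage).
#' @param fragment_ppm_sigma Gaussian m/z error of detected fragments, ppm.
#' @param seed Integer seed; fully determines the simulator output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(resolution = 580000, reference_mz = 400,
                       charges = c(9L, 10L, 11L),
                       charge_weights = c(0.3, 0.4, 0.3),
                       n_noise_peaks = 200, noise_intensity = 0.005,
                       jitter_sigma = 0.02,
                       fragment_detection_prob = 0.5,
                       fragment_ppm_sigma = 2, seed = 1L) {
  stopifnot(resolution > 0, length(charges) == length(charge_weights),
            all(charge_weights >= 0))
  structure(list(resolution = resolution, reference_mz = reference_mz,
                 charges = as.integer(charges),
                 charge_weights = charge_weights / sum(charge_weights),
                 n_noise_peaks = n_noise_peaks,
                 noise_intensity = noise_intensity,
                 jitter_sigma = jitter_sigma,
                 fragment_detection_prob = fragment_detection_prob,
                 fragment_ppm_sigma = fragment_ppm_sigma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# FWHM of a profile peak at m/z m: m / R(m), R(m) = R0 * ref / m
.fwhm_at <- function(m, cfg) m^2 / (cfg$resolution * cfg$reference_mz)

#' Simulate an MS1 spectrum of a proteoform mixture
#'
#' Draws every (proteoform, charge) isotopic envelope as Gaussian profile
#' peaks with m/z-dependent FTICR width, peak heights proportional to
#' mixture abundance x charge weight x isotopologue abundance, perturbed by
#' per-peak multiplicative jitter, plus uniform-random noise peaks. The
#' output is fully reproducible from the config seed.
#'
#' @param mixture A data.frame with a `proteoform` list-column and an
#'   `abundance` column (fractions summing to 1), e.g. from
#'   [table1_fixture()]; or a list of `list(proteoform =, abundance =)`.
#' @param cfg A [sim_config()].
#' @param mz_margin m/z padding around the theoretical peak range.
#' @param grid_step Profile grid spacing; default one fifth of the
#'   narrowest peak FWHM.
#' @return A profile `mass_spectrum` with the config recorded in its
#'   metadata.
#' @export
simulate_ms1 <- function(mixture, cfg = sim_config(), mz_margin = 2,
                         grid_step = NULL) {
  if (is.list(mixture) && !is.data.frame(mixture))
    mixture <- data.frame(abundance = vapply(mixture, `[[`, numeric(1),
                                             "abundance")) |>
      (\(d) {d$proteoform <- lapply(mixture, `[[`, "proteoform"); d})()
  ab <- mixture$abundance
  if (abs(sum(ab) - 1) > 1e-6)
    stop("mixture abundances must sum to 1 (got ", sum(ab), ")")
  set.seed(cfg$seed)
  peaks <- list()
  for (i in seq_len(nrow(mixture))) {
    p <- mixture$proteoform[[i]]
    pat <- isotope_distribution(apply_modifications(p, check_sites = FALSE))
    pat <- pat[pat$abundance >= 1e-4 * max(pat$abundance), ]
    for (k in seq_along(cfg$charges)) {
      z <- cfg$charges[k]
      h <- ab[i] * cfg$charge_weights[k] * pat$abundance
      if (cfg$jitter_sigma > 0)
        h <- h * exp(stats::rnorm(length(h), 0, cfg$jitter_sigma))
      peaks[[length(peaks) + 1L]] <-
        data.frame(mz = mz(pat$mass, z), height = h)
    }
  }
  peaks <- do.call(rbind, peaks)
  base_peak <- max(peaks$height)
  if (cfg$n_noise_peaks > 0) {
    lo <- min(peaks$mz) - mz_margin; hi <- max(peaks$mz) + mz_margin
    noise <- data.frame(
      mz = stats::runif(cfg$n_noise_peaks, lo, hi),
      height = stats::runif(cfg$n_noise_peaks, 0,
                            cfg$noise_intensity * base_peak))
    peaks <- rbind(peaks, noise)
  }
  lo <- min(peaks$mz) - mz_margin; hi <- max(peaks$mz) + mz_margin
  if (is.null(grid_step)) grid_step <- .fwhm_at(lo, cfg) / 5
  grid <- seq(lo, hi, by = grid_step)
  intensity <- numeric(length(grid))
  sigma <- .fwhm_at(peaks$mz, cfg) / (2 * sqrt(2 * log(2)))
  for (j in seq_len(nrow(peaks))) {
    s <- sigma[j]
    i1 <- max(1L, ceiling((peaks$mz[j] - 5 * s - lo) / grid_step) + 1L)
    i2 <- min(length(grid), floor((peaks$mz[j] + 5 * s - lo) / grid_step) + 1L)
    if (i1 > i2) next
    idx <- i1:i2
    intensity[idx] <- intensity[idx] +
      peaks$height[j] * exp(-(grid[idx] - peaks$mz[j])^2 / (2 * s^2))
  }
  mass_spectrum(grid, intensity, "profile",
                metadata = list(simulated = TRUE, seed = cfg$seed,
                                resolution = cfg$resolution,
                                charges = cfg$charges))
}

#' Simulate an ECD MS/MS spectrum
#'
#' Emits the c/z fragment ladders of a fully localized proteoform at
#' charges `1..precursor_charge - 1`, retains each ion with the configured
#' detection probability, perturbs m/z by Gaussian error
#' (`fragment_ppm_sigma`), and adds uniform noise peaks. Output is a
#' centroid spectrum, seeded.
#'
#' @param p A `proteoform` with all modifications localized.
#' @param precursor_charge Precursor charge state.
#' @param cfg A [sim_config()].
#' @return A centroid `mass_spectrum`.
#' @export
simulate_ecd <- function(p, precursor_charge, cfg = sim_config()) {
  stopifnot(inherits(p, "proteoform"), precursor_charge >= 2)
  set.seed(cfg$seed + 1L)
  lad <- fragment_ladder(p, c("c", "z"), max_charge = precursor_charge - 1L)
  keep <- stats::runif(nrow(lad)) < cfg$fragment_detection_prob
  lad <- lad[keep, , drop = FALSE]
  obs_mz <- lad$mz * (1 + stats::rnorm(nrow(lad), 0,
                                       cfg$fragment_ppm_sigma * 1e-6))
  obs_int <- exp(stats::rnorm(nrow(lad), 0, 0.5))
  if (cfg$n_noise_peaks > 0 && nrow(lad) > 0) {
    lo <- min(obs_mz); hi <- max(obs_mz)
    obs_mz <- c(obs_mz, stats::runif(cfg$n_noise_peaks, lo, hi))
    # electronic noise sits far below the fragment-ion intensities
    obs_int <- c(obs_int, stats::runif(cfg$n_noise_peaks, 0,
                                       cfg$noise_intensity * max(obs_int)))
  }
  if (!length(obs_mz))
    return(mass_spectrum(numeric(0), numeric(0), "centroid",
                         metadata = list(simulated = TRUE, seed = cfg$seed,
                                         precursor_charge = precursor_charge)))
  ord <- order(obs_mz)
  obs_mz <- obs_mz[ord]; obs_int <- obs_int[ord]
  dup <- c(FALSE, diff(obs_mz) <= 0)
  mass_spectrum(obs_mz[!dup], obs_int[!dup], "centroid",
                metadata = list(simulated = TRUE, seed = cfg$seed,
                                precursor_charge = precursor_charge))
}

#' The nine-class H2B proteoform mixture
#'
#' Returns the nine proteoform classes observed for yeast histone H2B with
#' their literature relative abundances (7.0, 12.8, 5.5, 25.7, 29.9, 7.3,
#' 4.7, 4.6, 2.4 percent, which sum to 99.9 before renormalization to
#' fractions). Classes whose sites are known carry them (N-terminal acetyl
#' at Ser1; dimethyl at Lys37); composition-only classes are represented by
#' one concrete localized proteoform so they can also drive the MS/MS
#' simulator (methyls placed at Lys37 by convention; the "3Me/Ac" and
#' "4Me/Ac" degeneracy classes by their all-methyl member).
#'
#' @param sequence Protein sequence to build the classes on; defaults to
#'   the mature H2B fixture. Any 120-140 aa sequence with a lysine at
#'   position 37 works for quantification tests.
#' @return A data.frame with columns `label`, `abundance_percent`,
#'   `abundance` (renormalized fraction) and a `proteoform` list-column.
#' @export
table1_fixture <- function(sequence = h2b_mature_sequence()) {
  me <- function(count) list(mod = "methyl", count = count, site = 37L)
  ac_nt <- list(mod = "nterm_acetyl", count = 1L, site = 1L)
  classes <- list(
    list(label = "-H2O", pct = 7.0,
         mods = list(list(mod = "water_loss", count = 1L, site = 1L))),
    list(label = "unmodified", pct = 12.8, mods = list()),
    list(label = "Me", pct = 5.5, mods = list(me(1))),
    list(label = "2Me", pct = 25.7, mods = list(me(2))),
    list(label = "Ac-aS1", pct = 29.9, mods = list(ac_nt)),
    list(label = "Ac-aS1+Me", pct = 7.3, mods = list(ac_nt, me(1))),
    list(label = "Ac-aS1+2Me", pct = 4.7, mods = list(ac_nt, me(2))),
    list(label = "Ac-aS1+3Me/Ac", pct = 4.6, mods = list(ac_nt, me(3))),
    list(label = "Ac-aS1+4Me/Ac", pct = 2.4, mods = list(ac_nt, me(4))))
  pct <- vapply(classes, `[[`, numeric(1), "pct")
  out <- data.frame(label = vapply(classes, `[[`, character(1), "label"),
                    abundance_percent = pct,
                    abundance = pct / sum(pct))
  out$proteoform <- lapply(classes, function(cl)
    proteoform(sequence, cl$mods, label = cl$label))
  out
}
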