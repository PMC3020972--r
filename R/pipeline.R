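# End-to-end orchestration: simulate -> assign -> quantify -> localize ->
# report, plus a flat key=value run-configuration format.

#' Run configuration
#'
#' All pipeline tunables in one object: the sequence fixture, candidate
#' caps, tolerances, quantification parameters, the simulator block, and
#' the output directory. Round-trips losslessly through the flat
#' `section.key=value` text format of [read_run_config()] /
#' [write_run_config()].
#'
#' @param sequence_file Path to the single-record protein FASTA; default
#'   the bundled H2B fixture.
#' @param clip_initiator_met Remove a leading initiator methionine so
#'   numbering is mature (residue 1 = Ser1 for H2B).
#' @param space A [candidate_space()].
#' @param tol_ms1_ppm,tol_msms_ppm Matching tolerances (defaults 1 and 10).
#' @param top_k,n_charge Quantification parameters (defaults 4 and 3).
#' @param reference_mass Printed literature mass used to calibrate the
#'   adduct convention (default 14113.6056, the H2B theoretical
#'   monoisotopic value).
#' @param sim A [sim_config()].
#' @param out_dir Output directory for reports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sequence_file = system.file(
                         "extdata", "H2B_NP_010510.1.fasta",
                         package = "topdownptm"),
                       clip_initiator_met = TRUE,
                       space = candidate_space(),
                       tol_ms1_ppm = 1, tol_msms_ppm = 10,
                       top_k = 4, n_charge = 3,
                       reference_mass = 14113.6056,
                       sim = sim_config(), out_dir = ".") {
  stopifnot(tol_ms1_ppm > 0, tol_msms_ppm > 0)
  structure(list(sequence_file = sequence_file,
                 clip_initiator_met = clip_initiator_met, space = space,
                 tol_ms1_ppm = tol_ms1_ppm, tol_msms_ppm = tol_msms_ppm,
                 top_k = top_k, n_charge = n_charge,
                 reference_mass = reference_mass, sim = sim,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read / write run configurations
#'
#' Flat `section.key=value` text, `#` comments; values are scalars or
#' comma-separated vectors. `write_run_config()` then `read_run_config()`
#' reproduces the configuration exactly.
#'
#' @param path File path.
#' @return A `run_config` (reader) or `path`, invisibly (writer).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (l in lines) {
    parts <- strsplit(l, "=", fixed = TRUE)[[1]]
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  num <- function(key, default) {
    v <- kv[[key]]
    if (is.null(v)) default else as.numeric(strsplit(v, ",")[[1]])
  }
  str_ <- function(key, default) if (is.null(kv[[key]])) default else kv[[key]]
  flag <- function(key, default)
    if (is.null(kv[[key]])) default else kv[[key]] == "TRUE"
  run_config(
    sequence_file = str_("run.sequence_file",
                         system.file("extdata", "H2B_NP_010510.1.fasta",
                                     package = "topdownptm")),
    clip_initiator_met = flag("run.clip_initiator_met", TRUE),
    space = candidate_space(
      max_methyl = num("space.max_methyl", 4),
      max_acetyl = num("space.max_acetyl", 4),
      max_total = num("space.max_total", 4),
      allow_nterm_acetyl = flag("space.allow_nterm_acetyl", TRUE),
      allow_water_loss = flag("space.allow_water_loss", TRUE)),
    tol_ms1_ppm = num("run.tol_ms1_ppm", 1),
    tol_msms_ppm = num("run.tol_msms_ppm", 10),
    top_k = num("run.top_k", 4), n_charge = num("run.n_charge", 3),
    reference_mass = num("run.reference_mass", 14113.6056),
    sim = sim_config(
      resolution = num("sim.resolution", 580000),
      reference_mz = num("sim.reference_mz", 400),
      charges = num("sim.charges", c(9, 10, 11)),
      charge_weights = num("sim.charge_weights", c(0.3, 0.4, 0.3)),
      n_noise_peaks = num("sim.n_noise_peaks", 200),
      noise_intensity = num("sim.noise_intensity", 0.005),
      jitter_sigma = num("sim.jitter_sigma", 0.02),
      fragment_detection_prob = num("sim.fragment_detection_prob", 0.5),
      fragment_ppm_sigma = num("sim.fragment_ppm_sigma", 2),
      seed = num("sim.seed", 1)),
    out_dir = str_("run.out_dir", "."))
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  fmt <- function(x) paste(format(x, scientific = FALSE, trim = TRUE,
                                  digits = 15), collapse = ",")
  lines <- c(
    paste0("run.sequence_file=", cfg$sequence_file),
    paste0("run.clip_initiator_met=", cfg$clip_initiator_met),
    paste0("run.tol_ms1_ppm=", fmt(cfg$tol_ms1_ppm)),
    paste0("run.tol_msms_ppm=", fmt(cfg$tol_msms_ppm)),
    paste0("run.top_k=", fmt(cfg$top_k)),
    paste0("run.n_charge=", fmt(cfg$n_charge)),
    paste0("run.reference_mass=", fmt(cfg$reference_mass)),
    paste0("run.out_dir=", cfg$out_dir),
    paste0("space.max_methyl=", fmt(cfg$space$max_methyl)),
    paste0("space.max_acetyl=", fmt(cfg$space$max_acetyl)),
    paste0("space.max_total=", fmt(cfg$space$max_total)),
    paste0("space.allow_nterm_acetyl=", cfg$space$allow_nterm_acetyl),
    paste0("space.allow_water_loss=", cfg$space$allow_water_loss),
    paste0("sim.resolution=", fmt(cfg$sim$resolution)),
    paste0("sim.reference_mz=", fmt(cfg$sim$reference_mz)),
    paste0("sim.charges=", fmt(cfg$sim$charges)),
    paste0("sim.charge_weights=", fmt(cfg$sim$charge_weights)),
    paste0("sim.n_noise_peaks=", fmt(cfg$sim$n_noise_peaks)),
    paste0("sim.noise_intensity=", fmt(cfg$sim$noise_intensity)),
    paste0("sim.jitter_sigma=", fmt(cfg$sim$jitter_sigma)),
    paste0("sim.fragment_detection_prob=",
           fmt(cfg$sim$fragment_detection_prob)),
    paste0("sim.fragment_ppm_sigma=", fmt(cfg$sim$fragment_ppm_sigma)),
    paste0("sim.seed=", fmt(cfg$sim$seed)))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full top-down pipeline
#'
#' Orchestrates the stages end to end: load (or default) the sequence
#' fixture, calibrate the printed-mass adduct convention, centroid and
#' assign the MS1 spectrum against the enumerated candidate space, quantify
#' proteoform classes by envelope integration, localize the dimethyl delta
#' from each MS/MS spectrum by ladder breakpoint analysis, and write the
#' TSV reports plus a run log. With `ms1 = NULL` the MS1 spectrum is
#' simulated from the nine-class H2B mixture; with `msms = NULL` one ECD
#' spectrum of the dimethylated form is simulated.
#'
#' @param cfg A [run_config()].
#' @param ms1 A profile or centroid `mass_spectrum`, a peak-list file path,
#'   or NULL to simulate.
#' @param msms A list of centroid `mass_spectrum` objects, an MGF file
#'   path, NULL to simulate, or `list()` to skip localization.
#' @param log Connection or path for the run log (default `stderr()`).
#' @return A list with `proteoform_table`, `abundance`, `localizations`,
#'   `calibration`, and the paths of the written reports.
#' @export
run_pipeline <- function(cfg = run_config(), ms1 = NULL, msms = NULL,
                         log = stderr()) {
  logf <- function(...) {
    msg <- sprintf(...)
    if (inherits(log, "connection")) writeLines(msg, log)
    else cat(msg, "\n", file = log, append = TRUE, sep = "")
  }
  seq <- read_protein_fasta(cfg$sequence_file)$sequence
  if (cfg$clip_initiator_met && substr(seq, 1, 1) == "M")
    seq <- substr(seq, 2, nchar(seq))
  logf("sequence: %d aa from %s", nchar(seq), cfg$sequence_file)

  cal <- calibrate_mass_convention(seq, cfg$reference_mass)
  logf("mass convention: %s (reference %.4f Da matched at %.3f ppm)",
       cal$convention, cfg$reference_mass, cal$error_ppm)

  base <- proteoform(seq)
  candidates <- enumerate_candidates(cfg$space, base)
  logf("candidate space: %d compositions", nrow(candidates))

  mixture <- NULL
  if (is.null(ms1)) {
    mixture <- table1_fixture(seq)
    ms1 <- simulate_ms1(mixture, cfg$sim)
    logf("simulated MS1 (seed %d, %d classes)", cfg$sim$seed, nrow(mixture))
  } else if (is.character(ms1)) {
    ms1 <- read_peaklist(ms1, mode = "profile")
  }
  centroids <- if (ms1$mode == "profile") pick_peaks(ms1) else ms1
  logf("MS1: %d centroids", length(centroids$mz))

  envelopes <- assign_envelopes(centroids, candidates, cfg$sim$charges,
                                tol_ppm = cfg$tol_ms1_ppm)
  logf("assigned %d envelopes", length(envelopes))
  abundance <- relative_abundance(envelopes, top_k = cfg$top_k,
                                  n_charge = cfg$n_charge)

  # observed neutral mass per quantified class: intensity-weighted readout
  # of the matched monoisotopic position across its envelopes
  env_labels <- vapply(envelopes, `[[`, character(1), "label")
  matches <- lapply(abundance$label, function(lab) {
    grp <- envelopes[env_labels == lab]
    obs <- stats::weighted.mean(
      vapply(grp, function(e)
        neutral_from_mz(e$peaks$mz_observed[1], e$charge) -
          e$peaks$offset[1] * 1.00235, numeric(1)),
      vapply(grp, `[[`, numeric(1), "intensity"))
    match_mass(obs, candidates, tol_ppm = cfg$tol_ms1_ppm)
  })

  if (is.null(msms)) {
    me2 <- proteoform(seq, list(list(mod = "methyl", count = 2, site = 37L)),
                      label = "2Me")
    msms <- list(simulate_ecd(me2, precursor_charge = 10L, cfg$sim))
    logf("simulated ECD MS/MS of the dimethyl form (seed %d)", cfg$sim$seed)
  } else if (is.character(msms)) {
    msms <- read_mgf(msms)
  }

  delta <- composition(C = 2, H = 4)  # the dimethyl delta under study
  locs <- list()
  for (s in msms) {
    if (!length(s$mz)) next
    zprec <- s$metadata$precursor_charge %||% s$metadata$charge %||% 10L
    zprec <- as.integer(sub("\\+$", "", as.character(zprec)))
    zmax <- max(1L, zprec - 1L)
    lad <- localization_ladders(base, delta, max_charge = zmax)
    asn <- match_fragments(s, lad, tol_ppm = cfg$tol_msms_ppm,
                           min_intensity = 0.02 * max(s$intensity))
    locs[[length(locs) + 1L]] <-
      localize(delta, asn$assignments, seq)
  }
  if (!length(locs)) logf("no MS/MS spectra: localization report empty")
  for (l in locs)
    logf("localization: interval [%s], site call %s",
         if (is.null(l$interval)) "-" else paste(l$interval, collapse = ", "),
         as.character(l$site_call))

  site_by_label <- vapply(abundance$label, function(lab) {
    if (lab %in% c("2Me") && length(locs) &&
        !identical(locs[[1]]$site_call, "ambiguous"))
      paste0("K", locs[[1]]$site_call) else NA_character_
  }, character(1))
  ptm_table <- build_ptm_table(matches, abundance$abundance_percent,
                               site_by_label)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(cfg$out_dir, "proteoform_table.tsv")
  p2 <- file.path(cfg$out_dir, "localization.tsv")
  write_report_tsv(ptm_table, p1)
  write_localization_tsv(locs, p2)
  logf("reports: %s, %s", p1, p2)

  list(proteoform_table = ptm_table, abundance = abundance,
       localizations = locs, calibration = cal, mixture = mixture,
       paths = c(proteoform_table = p1, localization = p2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
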