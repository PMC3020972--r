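test_that("c and z ladders satisfy the complementarity identity", {
  set.seed(5)
  aa <- strsplit("GASPVTLINDQKEMHFRYWC", "")[[1]]
  for (rep in 1:10) {
    seq <- paste(sample(aa, sample(5:40, 1), replace = TRUE),
                 collapse = "")
    p <- proteoform(seq)
    lad <- fragment_ladder(p, max_charge = 1)
    M <- proteoform_mass(p)
    n <- nchar(seq)
    for (i in seq_len(n - 1)) {
      ci <- lad$neutral_mass[lad$type == "c" & lad$index == i]
      zi <- lad$neutral_mass[lad$type == "z" & lad$index == n - i]
      expect_equal(ci + zi - M, 1.007825, tolerance = 1e-6)
    }
  }
})

test_that("a dipeptide has exactly one c and one z index", {
  lad <- fragment_ladder(proteoform("GG"), max_charge = 1)
  expect_equal(nrow(lad), 2)
  expect_equal(lad$index, c(1L, 1L))
  # c1 of GG: one glycine residue plus NH3
  expect_equal(lad$neutral_mass[lad$type == "c"],
               57.021464 + 17.026549, tolerance = 1e-5)
})

test_that("a localized dimethyl shifts exactly the spanning fragments", {
  seq <- h2b_mature_sequence()
  un <- fragment_ladder(proteoform(seq), max_charge = 1)
  me2 <- fragment_ladder(
    proteoform(seq, list(list(mod = "methyl", count = 2, site = 37L))),
    max_charge = 1)
  dc <- me2$neutral_mass[me2$type == "c"] - un$neutral_mass[un$type == "c"]
  expect_equal(dc[1:36], rep(0, 36))
  expect_equal(dc[37:129], rep(28.0313, 93), tolerance = 1e-4)
  # z ions mirror from the C terminus: z_j spans the site for j >= n-36
  dz <- me2$neutral_mass[me2$type == "z"] - un$neutral_mass[un$type == "z"]
  expect_equal(dz[1:93], rep(0, 93))
  expect_equal(dz[94:129], rep(28.0313, 36), tolerance = 1e-4)

  # ladders demand localized modifications
  expect_error(fragment_ladder(
    proteoform(seq, list(list(mod = "methyl", count = 2)))), "localized")
})

test_that("fragment matching assigns every true ion and no distant noise", {
  seq <- test_sequence()
  me2 <- proteoform(seq, list(list(mod = "methyl", count = 2, site = 12L)))
  cfg <- sim_config(seed = 6, fragment_detection_prob = 1,
                    n_noise_peaks = 0, fragment_ppm_sigma = 0)
  ecd <- simulate_ecd(me2, 4L, cfg)
  lad <- fragment_ladder(me2, max_charge = 3)
  asn <- match_fragments(ecd, lad, tol_ppm = 10)
  expect_equal(nrow(asn$assignments), length(ecd$mz))
  expect_equal(nrow(asn$unassigned), 0)
  expect_lt(max(abs(asn$assignments$error_ppm)), 0.1)

  # empty spectrum: zero assignments, not an error
  empty <- match_fragments(mass_spectrum(numeric(0), numeric(0),
                                         "centroid"), lad)
  expect_equal(nrow(empty$assignments), 0)

  # noise planted at least 20 ppm from every fragment stays unassigned
  set.seed(8)
  noise_mz <- sort(lad$mz + lad$mz * stats::runif(nrow(lad), 40e-6, 80e-6))
  noise_mz <- noise_mz[1:50]
  spec <- mass_spectrum(noise_mz, rep(1, 50), "centroid")
  asn2 <- match_fragments(spec, lad, tol_ppm = 10)
  expect_equal(nrow(asn2$unassigned), 50)
})

test_that("breakpoint localization pins a fully covered site", {
  seq <- h2b_mature_sequence()
  base <- proteoform(seq)
  delta <- composition(C = 2, H = 4)
  me2 <- proteoform(seq, list(list(mod = "methyl", count = 2, site = 37L)))
  cfg <- sim_config(seed = 10, fragment_detection_prob = 1,
                    n_noise_peaks = 0, fragment_ppm_sigma = 0)
  ecd <- simulate_ecd(me2, 10L, cfg)
  lad <- localization_ladders(base, delta, max_charge = 9)
  asn <- match_fragments(ecd, lad, tol_ppm = 10)
  loc <- localize(delta, asn$assignments, seq)
  expect_equal(loc$interval, c(37, 37))
  expect_equal(loc$site_call, 37)
  expect_gt(loc$n_supporting_c, 0)
  expect_gt(loc$n_supporting_z, 0)
})

test_that("localization handles gaps, absences and contradictions", {
  seq <- h2b_mature_sequence()
  delta <- composition(C = 2, H = 4)

  # no shifted ions: empty interval, ambiguous, zero support
  none <- data.frame(type = "c", index = c(10L, 20L),
                     variant = "unshifted")
  loc0 <- localize(delta, none, seq)
  expect_null(loc0$interval)
  expect_equal(loc0$site_call, "ambiguous")
  expect_equal(loc0$n_supporting_c + loc0$n_supporting_z, 0)

  # coverage gap: unshifted c30, shifted c40 -> interval [31, 40];
  # the K-only filter narrows to the lysines in that window
  gap <- data.frame(type = "c", index = c(30L, 40L),
                    variant = c("unshifted", "shifted"))
  locg <- localize(delta, gap, seq)
  expect_equal(locg$interval, c(31, 40))
  expect_equal(locg$site_call, "ambiguous")
  lock <- localize(delta, gap, seq, residue_filter = "K")
  expect_equal(lock$candidate_sites, c(31L, 34L, 37L))
  expect_true(lock$filtered)

  # same index matched both shifted and unshifted: hard ambiguity error
  contra <- data.frame(type = "c", index = c(40L, 40L),
                       variant = c("unshifted", "shifted"))
  expect_error(localize(delta, contra, seq), "index 40")
})

test_that("the interval never excludes the true site and only tightens", {
  seq <- h2b_mature_sequence()
  n <- nchar(seq)
  delta <- composition(C = 2, H = 4)
  truth <- 37L
  variant_c <- function(i) ifelse(i >= truth, "shifted", "unshifted")
  variant_z <- function(j) ifelse(j >= n - truth + 1L, "shifted",
                                  "unshifted")
  set.seed(12)
  for (rep in 1:20) {
    ci <- sort(sample(seq_len(n - 1), sample(3:40, 1)))
    zi <- sort(sample(seq_len(n - 1), sample(3:40, 1)))
    asn <- rbind(
      data.frame(type = "c", index = ci, variant = variant_c(ci)),
      data.frame(type = "z", index = zi, variant = variant_z(zi)))
    loc <- localize(delta, asn, seq)
    if (!is.null(loc$interval))
      expect_true(loc$interval[1] <= truth && truth <= loc$interval[2])
  }

  # growing the coverage mask never widens the interval
  full_c <- data.frame(type = "c", index = seq_len(n - 1),
                       variant = variant_c(seq_len(n - 1)))
  set.seed(13)
  mask <- sample(seq_len(n - 1), 10)
  widths <- numeric(0)
  for (k in c(10, 30, 60, 90, n - 1)) {
    mask <- union(mask, sample(seq_len(n - 1), k))
    loc <- localize(delta, full_c[full_c$index %in% mask, , drop = FALSE],
                    seq)
    if (!is.null(loc$interval))
      widths <- c(widths, loc$interval[2] - loc$interval[1])
  }
  expect_true(all(diff(widths) <= 0))
})

test_that("noisy partial-coverage spectra still bracket lysine 37", {
  seq <- h2b_mature_sequence()
  base <- proteoform(seq)
  delta <- composition(C = 2, H = 4)
  me2 <- proteoform(seq, list(list(mod = "methyl", count = 2, site = 37L)))
  lad <- localization_ladders(base, delta, max_charge = 9)
  errs <- c()
  for (s in 1:20) {
    cfg <- sim_config(seed = s, fragment_detection_prob = 0.6)
    ecd <- simulate_ecd(me2, 10L, cfg)
    asn <- match_fragments(ecd, lad, tol_ppm = 10,
                           min_intensity = 0.02 * max(ecd$intensity))
    loc <- localize(delta, asn$assignments, seq)
    expect_true(loc$interval[1] <= 37 && 37 <= loc$interval[2])
    errs <- c(errs, asn$assignments$error_ppm[!asn$assignments$ambiguous_match])
  }
  # the simulator's m/z errors carry no systematic bias
  expect_lt(abs(mean(errs)), 0.3)
})
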