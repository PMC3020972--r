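test_that("sequence compositions follow residue-sum-plus-water chemistry", {
  g <- composition_from_sequence("G")
  expect_equal(unclass(g)[c("C", "H", "N", "O", "S")],
               c(C = 2, H = 5, N = 1, O = 2, S = 0))
  expect_equal(monoisotopic_mass(g), 75.03203, tolerance = 1e-7)

  # zero residues: the termini water remains
  expect_equal(unclass(composition_from_sequence("")),
               unclass(water_composition()))
  expect_equal(monoisotopic_mass(water_composition()), 18.010565,
               tolerance = 1e-9)

  expect_error(composition_from_sequence("GAXQ"), "position 3")
})

test_that("the mature H2B fixture reproduces the literature intact mass", {
  seq <- h2b_mature_sequence()
  expect_equal(nchar(seq), 130)
  expect_equal(substr(seq, 1, 1), "S")   # mature N-terminal serine
  expect_equal(substr(seq, 37, 37), "K") # the dimethylation site

  cal <- calibrate_mass_convention(seq, 14113.6056)
  expect_equal(cal$convention, "proton_adduct")
  expect_lt(abs(cal$error_ppm), 1)
  expect_equal(cal$adduct_mass, cal$neutral_mass + physical_constants$proton)
})

test_that("mass convention calibration is empirical, not assumed", {
  # a sequence checked against its own computed neutral mass
  m <- monoisotopic_mass(composition_from_sequence(test_sequence()))
  cal <- calibrate_mass_convention(test_sequence(), m)
  expect_equal(cal$convention, "neutral")
  expect_equal(cal$error_ppm, 0, tolerance = 1e-9)

  # a reference off by 100 ppm matches neither convention
  expect_error(calibrate_mass_convention(test_sequence(), m * (1 + 1e-4)),
               "matches neither")
})

test_that("monoisotopic mass is additive over compositions", {
  set.seed(42)
  for (i in 1:20) {
    a <- composition(C = sample(0:50, 1), H = sample(0:80, 1),
                     N = sample(0:20, 1), O = sample(0:20, 1),
                     S = sample(0:3, 1))
    b <- composition(C = sample(0:50, 1), H = sample(0:80, 1),
                     N = sample(0:20, 1), O = sample(0:20, 1),
                     S = sample(0:3, 1))
    expect_equal(monoisotopic_mass(a + b),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-12)
  }
  expect_error(composition(C = 1) - composition(C = 2), "negative")
})

test_that("modification deltas match their defining chemistry", {
  expect_equal(modification("methyl")$delta_mass, 14.015650,
               tolerance = 1e-9)
  expect_equal(modification("acetyl")$delta_mass, 42.010565,
               tolerance = 1e-9)
  expect_equal(modification("water_loss")$delta_mass, -18.010565,
               tolerance = 1e-9)

  base <- proteoform(test_sequence())
  me2 <- proteoform(test_sequence(),
                    list(list(mod = "methyl", count = 2, site = 12L)))
  expect_equal(proteoform_mass(me2) - proteoform_mass(base), 28.031300,
               tolerance = 1e-9)

  # zero modifications: identity
  expect_equal(unclass(apply_modifications(base)),
               unclass(composition_from_sequence(test_sequence())))

  wl <- proteoform(test_sequence(), list(list(mod = "water_loss")))
  expect_equal(proteoform_mass(wl) - proteoform_mass(base), -18.010565,
               tolerance = 1e-9)

  # site rules: methyl on glycine is rejected when sites are checked
  bad <- proteoform(test_sequence(),
                    list(list(mod = "methyl", count = 1, site = 1L)))
  expect_error(apply_modifications(bad, check_sites = TRUE),
               "not allowed on residue G")
  expect_error(proteoform(test_sequence(),
                          list(list(mod = "methyl", site = 99L))),
               "outside")
})

test_that("H2 isotope pattern matches the binomial closed form", {
  p <- 0.000115  # deuterium natural abundance
  pat <- isotope_distribution(composition(H = 2), prune_threshold = 1e-12)
  expect_equal(pat$offset, c(0L, 1L, 2L))
  expect_equal(pat$abundance, c((1 - p)^2, 2 * p * (1 - p), p^2),
               tolerance = 1e-12)
  expect_equal(pat$mass[1], 2 * 1.007825, tolerance = 1e-9)
})

test_that("C100 pattern is binomial and matches the per-atom oracle", {
  pat <- isotope_distribution(composition(C = 100), prune_threshold = 1e-12)
  p13 <- 0.010700
  binom <- stats::dbinom(pat$offset, 100, p13)
  expect_equal(pat$abundance, binom, tolerance = 1e-9)

  oracle <- oracle_isotope_distribution(c(C = 100))
  m <- merge(as.data.frame(pat), oracle, by = "offset")
  expect_gt(nrow(m), 5)
  expect_lt(max(abs(m$abundance.x - m$abundance.y) / m$abundance.y), 1e-9)
  expect_lt(max(abs(m$mass.x - m$mass.y)), 1e-9)
})

test_that("isotope patterns equal the exhaustive convolution oracle", {
  set.seed(7)
  for (i in 1:5) {
    counts <- c(C = sample(0:200, 1), H = sample(0:200, 1),
                N = sample(0:40, 1), O = sample(0:30, 1),
                S = sample(0:4, 1))
    if (sum(counts) == 0) counts["C"] <- 10
    pat <- isotope_distribution(do.call(composition, as.list(counts)),
                                prune_threshold = 1e-14)
    oracle <- oracle_isotope_distribution(counts)
    m <- merge(as.data.frame(pat), oracle, by = "offset")
    keep <- m$abundance.y >= 1e-12
    expect_lt(max(abs(m$abundance.x[keep] - m$abundance.y[keep]) /
                    m$abundance.y[keep]), 1e-9)
    expect_lt(max(abs(m$mass.x[keep] - m$mass.y[keep])), 1e-8)
  }
})

test_that("isotope pattern invariants hold for a protein-sized composition", {
  pat <- isotope_distribution(
    apply_modifications(proteoform(h2b_mature_sequence())),
    prune_threshold = 1e-10)
  expect_lt(abs(sum(pat$abundance) - 1), 10 * 1e-10)
  expect_true(all(diff(pat$mass) > 0))
  expect_equal(pat$offset[1], 0L)
  expect_equal(pat$mass[1],
               monoisotopic_mass(composition_from_sequence(
                 h2b_mature_sequence())), tolerance = 1e-6)
})

test_that("m/z and neutral mass round-trip exactly", {
  expect_equal(mz(1000, 1), 1001.007276, tolerance = 1e-9)
  expect_equal(mz(1000, 10), 101.007276, tolerance = 1e-9)
  set.seed(11)
  for (z in 1:30) {
    M <- stats::runif(1, 100, 20000)
    expect_equal(neutral_from_mz(mz(M, z), z), M, tolerance = 1e-9)
  }
  expect_error(mz(1000, 0), "positive")
  expect_error(neutral_from_mz(500, -1), "positive")
})

test_that("shipped constant tables agree with the in-code tables", {
  iso <- read.delim(system.file("extdata", "isotopes.tsv",
                                package = "topdownptm"))
  expect_equal(iso$mass, isotope_table()$mass)
  expect_equal(iso$abundance, isotope_table()$abundance)
  aa <- read.delim(system.file("extdata", "amino_acids.tsv",
                               package = "topdownptm"))
  tab <- amino_acid_table()
  expect_equal(aa[order(aa$residue), ], tab[order(tab$residue), ],
               ignore_attr = TRUE)
})
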