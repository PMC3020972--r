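---
title: "Top-down proteoform characterization: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Top-down proteoform characterization: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topdownptm)
```

## The scientific problem

Intact-protein ("top-down") mass spectrometry characterizes proteoforms —
the specific molecular forms of a protein carrying a particular set of
post-translational modifications (PTMs) — without digestion. Three
inferences make up the core workflow this package implements, using yeast
histone H2B and its dimethylation at lysine 37 as the reference system:

1. **Intact-mass matching.** A deconvolved monoisotopic mass is compared
   against the theoretical masses of a combinatorial space of candidate
   modification compositions, at parts-per-million tolerance. A dimethyl
   form, for example, sits +28.0313 Da (2 × CH~2~) above the unmodified
   protein.
2. **Fragment-ladder PTM localization.** Electron capture dissociation
   (ECD) cleaves the backbone N–Cα bond, producing N-terminal c ions and
   C-terminal z-radical ions. Fragments that span the modified residue
   carry the mass shift; fragments that do not, do not. The index at which
   the ladder switches from unshifted to shifted brackets the site.
3. **Isotopic-envelope quantification.** The relative abundance of each
   proteoform class is the normalized sum of its most intense isotopic
   peaks across its most intense charge states.

## Mass conventions and the chemistry core

All masses are stored internally as **neutral monoisotopic** values.
Adduct conventions enter only at I/O boundaries, because published intact
masses are variously printed as neutral or as proton-adduct ([M+H]⁺)
values and the labelling is not always internally consistent.
`calibrate_mass_convention()` resolves the question empirically: it
computes both candidate masses from the sequence and accepts whichever
agrees with the printed reference within tolerance (default 1 ppm),
failing loudly when neither does. For the bundled H2B fixture (RefSeq
NP_010510.1 with the initiator methionine removed, so residue 1 is the
mature N-terminal serine), the 130-residue sequence gives a neutral
monoisotopic mass of 14112.5983 Da and a proton adduct of 14113.6056 Da;
the reference value is recognized as a proton adduct.

```{r calibration}
cal <- calibrate_mass_convention(h2b_mature_sequence(), 14113.6056)
cal$convention
cal$error_ppm
```

Isotopic masses and abundances follow the IUPAC/CIAAW 2013 recommended
values at six-decimal precision (shipped as `inst/extdata/isotopes.tsv`);
at 2,000 atoms the truncation error is below 0.01 ppm, an order of
magnitude under the 1 ppm matching tolerance. Only C, H, N, O and S are
enabled, which covers unmodified proteins and the modifications treated
here (methyl +CH~2~, acetyl +C~2~H~2~O, water loss −H~2~O); the element
table is a single structure and extensible.

### Isotope distributions

`isotope_distribution()` computes the aggregated isotopologue ladder: all
isotopologues with the same nucleon count are pooled into one entry whose
exact mass is their abundance-weighted mean — the quantity a
high-resolution (but not fine-structure-resolving) FTICR measurement
reports. The algorithm convolves each element's single-atom distribution
to its atom-count power by exponentiation-by-squaring, then convolves
across elements. Two numerical choices matter:

* Convolutions are computed by direct polynomial multiplication rather
  than FFT, so entries ten orders of magnitude below the base peak retain
  full relative precision (the test suite checks agreement with an
  exhaustive per-atom convolution oracle to 1e−9 relative error).
* No pruning is applied during intermediate convolutions — only exact
  floating-point underflow truncates the tails — and the user-facing
  `prune_threshold` (default 1e−10) is applied once, to the final ladder.
  Retained abundances are therefore exact, and the ladder sums to 1 minus
  the pruned tail mass.

## Candidate enumeration and intact-mass matching

The candidate space caps methyl and acetyl counts (default 4 each, joint
cap 4) and toggles N-terminal acetylation and water loss, generating 60
compositions for the defaults. Matching tolerance defaults to 1 ppm, the
customary FTICR intact-mass figure. Ties are broken by absolute ppm error,
then parsimony (fewer modification units), then label — output order is
fully deterministic.

Two degeneracies deserve note. Trimethylation and acetylation differ by
0.036385 Da (≈2.6 ppm at 14.1 kDa): resolvable at 1 ppm, unresolvable at
5 ppm, in which case the report renders a joint `3Me/Ac` label with an
ambiguity flag. N-terminal and internal (lysine) acetylation are *exactly*
mass-degenerate; envelope assignment collapses such candidates into one
joint-labelled class, because MS1 composition matching cannot, even in
principle, distinguish them — site assignment belongs exclusively to the
fragment-localization stage.

## Envelope assignment and quantification

MS1 profile spectra are centroided by local-maximum detection with
three-point parabolic apex interpolation. Envelope assignment is
**candidate-driven**: for each (candidate, charge) pair the theoretical
isotopologue positions are matched greedily (best |ppm| first) against the
centroids, each centroid is consumed by at most one envelope, and
envelopes with fewer than 3 matched isotopologues are discarded as noise
matches. A spacing-based charge checker (`isotope_spacing()`, ≈1.00235/z)
is provided as a validation utility, but de novo charge deconvolution of
unknown proteins is out of scope.

Quantification follows the top-4 / three-charge-state rule: per class, sum
the four most intense matched isotopic peaks in each of its three most
intense charge-state envelopes, then normalize class sums to 100%.
"Integration" is implemented as summed centroid intensities rather than
profile areas — centroid sums are resolution-independent, and the choice
is isolated in one function should a profile-area variant ever be needed.
The three charge states are chosen by envelope intensity. Classes observed
in fewer than the required charge states are flagged in the report, never
silently dropped. The normalization denominator is the set of assigned
classes; unassigned peaks are excluded.

## Fragment ladders and breakpoint localization

The adopted ECD fragment chemistry is

* c~i~ = Σ residues 1..i + NH~3~ (17.026549 Da),
* z~j~• = Σ residues n−j+1..n + 1.991841 Da,

which yields the testable complementarity identity
c~i~ + z~(n−i)~• = M + 1.007825 Da at every cleavage index (z+1 "z-prime"
species are out of scope). Localized modifications contribute their delta
to every fragment spanning their residue.

Localization is **interval-based, not probabilistic**: an unshifted c~i~
proves the site lies after residue i; a shifted c~i~ proves it lies at or
before i; z ions mirror these constraints from the C terminus. The
reported interval is the tightest range consistent with all
site-determining ions, which is honest about coverage gaps — partial
ladders (e.g. shifted ions starting only at c~37~ through c~49~) produce a
wider interval rather than a guessed point call. A residue-type filter
(e.g. lysines only, for methylation chemistry) can narrow the candidate
set but is off by default and always flagged in the result: the site call
should rest on the ladder, with residue chemistry as corroboration only.

Three safeguards make the breakpoint argument robust on realistic spectra,
where the combined shifted + unshifted c/z ladder at fragment charges
1..9 contains ~4,600 theoretical positions:

* a peak lying within tolerance of **more than one** theoretical fragment
  is flagged `ambiguous_match` and excluded from site evidence (the
  standard "site-determining ion" criterion);
* the pipeline applies an intensity floor (2% of the MS/MS base peak) so
  low-level electronic noise cannot enter the evidence set;
* an index genuinely matched both shifted and unshifted by unambiguous
  peaks raises a hard contradiction error naming the index, as does an
  empty bracketing interval.

Fragment matching tolerance defaults to 10 ppm (fragments are lighter and
less precisely measured than the precursor, which keeps 1 ppm); fragment
charges default to 1..(precursor charge − 1).

## The simulator: what it emulates, and what it does not

`simulate_ms1()` and `simulate_ecd()` generate the data the analysis
stages expect, with every random draw governed by one integer seed
(identical config + seed gives bit-identical spectra).

* **Resolution model.** Gaussian peaks with FWHM = m/z ÷ R(m/z) and
  R(m) = R0 · (400/m), the FTICR scaling; R0 defaults to 580,000 at m/z
  400, a 12 T broadband setting. At m/z 1415 this gives ≈6 ppm FWHM, so
  1 ppm centroid matching is comfortable for isolated peaks.
* **Charge envelope.** MS1 charge states default to {9, 10, 11} with
  weights 0.3/0.4/0.3, consistent with a ~14 kDa histone observed around
  a 10+ precursor; the true instrument envelope is not critical because
  quantification normalizes across classes that share it.
* **Intensity noise.** Per-peak multiplicative log-normal jitter with
  σ = 0.02 (≈2% RSD) plus 200 uniform-random noise peaks at up to 0.5% of
  the base peak. Under these defaults the nine-class mixture is recovered
  with per-class RSD ≤ 1% for classes above 5%, matching the replicate
  precision reported for this kind of measurement.
* **ECD model.** Each theoretical c/z ion at charges 1..(precursor−1) is
  detected with probability 0.5 (chosen so partial ladders of the
  c~37~–c~49~ style are typical), with 2 ppm Gaussian m/z error;
  electronic noise is drawn far below fragment intensity, as on a real
  FTICR transient.

Not emulated: isotopic fine structure, space-charge frequency shifts,
baseline drift, chromatographic time, internal fragments, and co-isolation
chimera spectra. Passing tests on simulated data therefore demonstrate the
*inference logic* — mass arithmetic, envelope bookkeeping, breakpoint
bracketing, normalization — not robustness to every artifact of real
spectra.

## Problem sizes used by the test suite

The bundled checks run the full 130-residue H2B system: nine proteoform
classes at three charge states on a ~216,000-point profile grid, ten
seeded noisy replicates for the quantification recovery and repeatability
checks, twenty seeded replicates for localization soundness, and
oracle-vs-implementation isotope comparisons up to a few hundred atoms.
These sizes exercise every code path at the full protein scale while
keeping the whole suite in the minutes range on one core.

## Known limitations

* Compositions are limited to C/H/N/O/S; phospho- or metal-adducted forms
  would need an element-table extension.
* The candidate space enumerates methyl/acetyl/N-terminal-acetyl/water
  loss only; open (blind) delta-mass search is explicitly out of scope.
* One delta composition is localized per MS/MS spectrum; simultaneous
  localization of several distinct deltas is not attempted.
* Quantification assumes the charge-weight profile is shared across
  classes (true when classes co-elute and ionize alike, as for histone
  proteoforms differing by small marks; not guaranteed for chemically
  dissimilar species).
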