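---
title: "Marker ion correlations for combinatorial PTM isomers"
author: "pcovms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker ion correlations for combinatorial PTM isomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcovms)
```

## The problem

Combinatorial isomers are peptides with the same sequence and the same
number of identical modifications, placed on different subsets of the
eligible sites.  The canonical hard case is the tryptic histone H4 tail
peptide 4--17, `GKGGKGLGKGGAKR`, carrying two acetyl groups on two of its
four lysines (protein positions K5, K8, K12, K16).  All six diacetyl
forms — conventionally P1 = K5/K16, P2 = K8/K12, P3 = K5/K12,
P4 = K8/K16, P5 = K5/K8, P6 = K12/K16 — have *exactly* the same
elemental composition, coelute, and are co-isolated and co-fragmented in
tandem MS.

Standard MS/MS identifies an isomer in such a cofragmented mixture only
if it produces a *marker ion*: a fragment m/z no other isomer in the
mixture can produce.  This degeneracy is exact (degenerate fragments
share elemental composition), so no instrument resolution can break it.
Within the mixture P1--P4, the K8/K16 isomer P4 produces **no** marker
ion at all, terminal or internal: every one of its fragments is also
made by P1, P2 or P3.  For example the acetylated y~5~
(`GGAK(ac)R`, m/z 530.30) is shared with P1 and the acetylated internal
b-type ion spanning residues 3--8 (`GGK(ac)GLG`, m/z 512.28) is shared
with P2.

The way out is *correlation*: although no single fragment is unique to
P4, the **pair** (512.28, 530.30) can only be produced together, from a
single precursor ion, by P4.  Two-dimensional partial covariance mass
spectrometry measures exactly this: over an ensemble of thousands of
repeated MS/MS microscans, fragments born in the same dissociation event
co-fluctuate, and the covariance of their intensity channels reveals the
connection.

```{r markers}
iso <- h4_diacetyl_isomers(c("P1", "P2", "P3", "P4"))
find_unique_markers(iso, "1d", kinds = c("b", "y", "internal_b"))$summary
find_unique_markers(iso, "2d")$summary
```

## Fragment enumeration and uniqueness

`chem` functions enumerate the complete backbone fragment space:
terminal `b`/`y` ions and internal ions from two backbone cleavages
(b-type internals carry neither terminal group; a-type additionally lose
CO).  Spans are inclusive 1-based peptide coordinates; protein numbering
is used only for display labels.  Neutral losses, immonium ions and
isotopologues are deliberately out of scope: the degeneracy argument and
the marker analysis concern backbone fragments.

Correlation signatures pair fragments with *disjoint residue spans* —
the combinations that can coexist in one dissociation outcome: b×y
pairs (including complementary ones) and terminal×internal pairs.
Internal×internal pairs are not enumerated.

Uniqueness is assessed at two tolerances, deliberately distinct:

* **exact** (`1e-6` Th): combinatorial degeneracy is exact, so the
  in-silico analysis asks whether masses are identical, not close;
* **instrument** (`0.3` Th default): when theoretical markers are
  matched against unit-resolution experimental peaks, a marker is only
  useful if no other isomer has a pair within the *match* tolerance.
  Near-degenerate pairs that are distinct at the exact tolerance but
  closer than 0.3 Th would otherwise masquerade as evidence, and pairs
  whose two coordinates coincide (two distinct fragments of equal mass)
  are dropped because they fall inside the map's autocorrelation
  exclusion band.

An instructive genuine degeneracy: in `GKGGKGLGKGGAKR` the internal
spans (3,8) `GGKGLG` and (6,11) `GLGKGG` have identical residue
multisets, so the acetylated m/z 512.28 ion is produced by three of the
four panel isomers at the m/z level even though only two produce the
*species* `GGK(ac)GLG`.  The uniqueness engine works purely at the m/z
level, which is what an instrument sees.

## The partial covariance map

For microscan intensities \(X_x\) and total ion current \(T\), the
classical TIC partial covariance is

\[
\mathrm{pCov}(x,y) \;=\; \mathrm{Cov}(X_x, X_y)
  \;-\; \frac{\mathrm{Cov}(X_x, T)\,\mathrm{Cov}(T, X_y)}
             {\mathrm{Var}(T)} ,
\]

which removes the spurious all-against-all correlation driven by
scan-to-scan fluctuations of the precursor fill.  Both this estimator
and the package default annihilate a pure common-mode ensemble to
numerical zero.

**Why a self-correcting default.**  Because the examined channels
contribute to \(T\) themselves, the classical estimator subtracts part
of the genuine Poisson co-fluctuation of a correlated pair as if it were
confound.  In the regime this package simulates — countable ions per
scan, many fragmentation channels, coincidence rates well below total
channel intensity — that bias is *systematically negative* at true
coincidence coordinates and can exceed the coincidence signal
(analytically, the spurious term scales like
\(E[f]\,s_x s_y / R\) with \(s\) the channel intensities and \(R\) the
total rate, while the signal scales with the shared-channel rate alone).
The package therefore defaults to a self-corrected estimator that
regresses each pair on \(T - X_x - X_y\), i.e. excludes the examined
channels from their own confound regressor; it is computed in closed
form from the same second moments, costs the same \(O(n_\text{bins}^2)\),
and reduces to the classical formula when the pair's share of the TIC is
negligible.  The classical (`"tic"`) and uncorrected (`"plain"`)
estimators remain selectable everywhere.

## Peak detection and jackknife scoring

Candidate peaks are 8-neighbourhood local maxima in the upper triangle,
above `5 × MAD` of the map by default, with a 3-bin band around the
autocorrelation diagonal excluded.  Each peak's volume integrates the
map over a square window (half-width 2 bins).

Significance is the ratio \(V/\sigma_{JK}\): the scans are split into
`g = 100` contiguous blocks, the window volume is recomputed with each
block deleted, and \(\sigma_{JK}\) is the jackknife standard deviation
of those recomputations.  The window volume collapses to scalar
sufficient statistics (per-block sums of the window-row and
window-column traces, their products, and the TIC moments), so all
\(g\) leave-one-out volumes cost \(O(1)\) each.  A volume that is
perfectly stable under resampling (\(\sigma_{JK}=0\)) is reported as an
`Inf` score with a warning, never as a silent division.

**Composite marker scores.**  A single weak marker correlation can fail
to separate from map noise when both of its coordinates are shared with
other cofragmented species (the coincidence correlation is diluted by
roughly \(1/\sqrt{m_x m_y}\), with \(m\) the number of channels feeding
each coordinate).  `composite_marker_score()` therefore sums the volumes
of *all* of an isomer's marker pairs and jackknifes the sum: signal adds
linearly while resampling noise adds in quadrature, and for an absent
isomer the composite behaves like a single approximately standard-normal
deviate instead of the maximum of many.  `identify_isomers()` makes its
presence calls from the composite; the per-marker matches are retained
for reporting and quantification.  The default presence threshold of 5
is a conservative five-sigma-like requirement on that composite; there
is no universal printed value and it is exposed as a parameter.

Relative abundances follow from the proportionality of a correlation
peak's volume to its precursor's concentration; with markers of
comparable fragmentation efficiency, normalised marker volumes estimate
mixture fractions directly.

## The synthetic microscan generator

The simulator exists to make the whole chain testable without
instrument data, by reproducing the *statistical structure* that the
partial covariance correction assumes:

* per scan, a common-mode factor \(f \sim \mathrm{LogNormal}(0,
  \sigma_\text{TIC})\) models electrospray/fill fluctuations — the
  confound;
* each fragmentation channel's precursor count is
  \(\mathrm{Poisson}(f \lambda p)\) (Poisson thinning over branching
  ratios), and every count deposits **all** of the channel's products at
  once — the correlation source;
* products land as narrow Gaussian peaks on a uniform m/z grid, with
  additive detector noise and non-negative clipping; the reported TIC is
  the full-spectrum deposited current, including products outside the
  acquired map window.

Default choices, with reasons:

* **grid 0.2 Th bins, peak width 0.05 Th**: one product occupies at most
  ±1 bin, so the same-peak correlation footprint stays inside the 3-bin
  diagonal exclusion;
* **TIC fluctuation 0.3 (log-SD)**: a strong but realistic infusion
  instability, large enough that confound suppression is a meaningful
  test;
* **uniform branching over every complementary b/y channel plus every
  disjoint (terminal, internal) channel, total 0.9**: a deliberately
  agnostic synthetic choice — real CID branching is peptide-specific and
  concentrated, which makes real marker correlations *stronger* than
  these simulations;
* **`lambda_total = 200` precursors per scan** (50 per isomer in a
  four-component mixture): reproduces the strong-fragment regime of
  unit-resolution CID spectra.  Much smaller fills leave single channels
  with too few coincidences per 10^4 scans for stable scoring; much
  larger fills grow the common-mode estimation noise of the covariance
  (\(\propto \lambda^2\)) faster than the coincidence signal
  (\(\propto \lambda\)).  Scores are non-monotone in fill, a real
  operating characteristic of covariance MS.

What the generator does **not** emulate: ion-trap space charge,
isotope envelopes, chromatographic elution, charge states above 1+, and
realistic (non-uniform) branching ratios.  Passing tests therefore
demonstrate the estimator, scoring and identification logic under the
assumed statistical model — not instrument-grade realism.

## Problem sizes used in the validation suite

The shipped tests run the in-silico uniqueness analysis on ~110 random
peptides (length 8--20, 2--5 lysines, diacetyl) with a brute-force
cross-product oracle on the length-≤8 subset; estimator and scoring
studies use 10^4-microscan ensembles (20 seeded replicates for the
true-pair-vs-200-nulls ranking); quantification uses a five-point
precursor-rate grid and 70:30 / 50:50 two-component mixtures; and the
end-to-end study simulates mixtures of two, three and four of P1--P4 on
a 280--660 Th map with presence calls for all six P isomers.  These
sizes were chosen as the smallest that exercise each claim with
comfortable statistical margin.

## Known limitations

* The uniqueness survey treats digestion-consistent isomers at a fixed
  missed-cleavage budget; semi-tryptic and non-specific cleavage are out
  of scope.
* Quantification assumes comparable fragmentation efficiency of the
  interrogated marker channels; across isomers with structurally
  different markers this introduces bias (visible as mild super-linearity
  of volume with rate in the simulations).
* The self-corrected estimator removes the examined pair from its
  confound regressor but partner products of shared channels still
  contribute; at extreme fills residual bias reappears.
* `count_identifiable()` exposes the enumeration universe (enzyme,
  missed cleavages, length bounds, multiplicities, charge states) as
  parameters rather than fixing a canonical survey.
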