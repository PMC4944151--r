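---
title: "Deconvoluting iduronate ring-pucker populations from NMR couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting iduronate ring-pucker populations from NMR couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puckerfit)
```

## The model

The pyranose ring of L-iduronic acid (IdoA) and its 2-*O*-sulphated form
(IdoA2S) in heparan sulphate interconverts between three forms: the
\(^1C_4\) chair, the \(^2S_O\) skew-boat and, less often, the \(^4C_1\)
chair. Ring flipping is fast on the chemical-shift and J-coupling timescale
(the underlying kinetics are microsecond-scale), so each measured vicinal
coupling of the ring is a time average. Writing \(J_k^{(c)}\) for the mean
value of coupling \(k \in \{J_{12}, J_{23}, J_{34}, J_{45}\}\) in pure
conformer \(c\), the observable is the population-weighted mixture

\[
J_k^{\mathrm{obs}} \;=\; \sum_{c} p_c \, J_k^{(c)},
\qquad p_c \ge 0,\; \sum_c p_c = 1 .
\]

This linearity is exact whenever per-frame couplings average
arithmetically: the mean over an ensemble that spends a fraction \(p_c\) of
frames in conformer \(c\) equals the \(p\)-mixture of the per-conformer
means, regardless of the within-conformer fluctuations. That identity (it
is asserted numerically in the test suite) is why a basis of three
*reference coupling vectors* is a faithful stand-in for averaging over
hundreds of thousands of simulation snapshots, and it is the package's
canonical internal representation.

Populations are recovered by minimising the residual sum of squares

\[
\mathrm{RSS}(p) = \sum_{k}\bigl(J_k^{\mathrm{obs}} - \textstyle\sum_c p_c J_k^{(c)}\bigr)^2
\]

over the probability simplex. Two fitters share this objective:

* `fit_populations_continuous()` — the exact solution. The equality
  constraint is eliminated by substitution, the reduced normal equations
  are solved on every support subset of the three conformers, and the best
  feasible (componentwise nonnegative) solution wins. With three basis
  vectors this active-set enumeration *is* exhaustive, so the result is the
  global constrained minimiser, not an approximation. Components that the
  unconstrained solution would drive negative come back clamped to zero —
  which is exactly how the two-state rows of the bundled table arise.
* `fit_populations_grid()` — an exhaustive lattice search at a resolution
  of 1% (configurable to 0.5% or 0.1%). It exists as a transparent,
  assumption-free cross-check; exact ties between lattice points resolve
  deterministically to higher \(^1C_4\), then higher \(^2S_O\).

The two agree to grid resolution. A caution from measuring this on the
bundled table: the lattice *optimiser* is not always the lattice point
nearest the continuous optimum — at 1% resolution the worst componentwise
gap across the eight records is 1.21 grid steps. Consequently a 1% grid can
round a reported percentage one point away from the exact solution on
near-flat objectives, and the package therefore treats the continuous fit
as the reporting convention.

## Reporting conventions

`report_table()` mirrors the layout in which such analyses are published,
and every number it prints traces to a documented rule (also carried in the
report's `conventions` attribute):

* **Populations** are the continuous-fit fractions rendered as integer
  percents, rounding half up. Conformers below 0.5% print as a dash.
* **Calculated couplings** (the parenthetical column) are the unrounded
  mixture at the fitted populations, rounded half-up to one decimal.
* **RSS** is reported in the *printed convention*: the squared deviation of
  the measured couplings from the one-decimal-*rounded* back-calculation,
  to two decimals. The optimisation objective itself always uses unrounded
  values; both numbers are kept on the fit object (`rss_unrounded`,
  `rss_printed_convention`).

The rounded-RSS convention is not a whim: back-calculating at the printed
integer percents cannot reproduce the published table (records sharing
printed populations carry different parenthetical couplings, so the
original back-calculations were made from unrounded fits), whereas the
continuous fit reproduces the population, parenthetical and RSS columns of
all eight records cell for cell. Whether the original optimiser minimised
the rounded or the unrounded objective is unknowable from the table; this
package standardises on the unrounded objective and reports both RSS
flavours.

```{r}
rep <- report_table(table1_measurements(), builtin_reference_set())
format_report(rep)
```

## The reference basis

The built-in reference set (`builtin_reference_set()`) holds the mean
couplings of the pure \(^1C_4\), \(^2S_O\) and \(^4C_1\) forms of the
iduronate ring, as obtained from microsecond conformer-restrained
molecular-dynamics ensembles of the same hexasaccharides (units Hz):

```{r}
builtin_reference_set()
```

`derive_reference_set()` rebuilds such a basis from labelled trajectories
by Karplus back-calculation. Two caveats are deliberate:

* The package's Karplus parameterisation (`A = 7.76`, `B = -1.10`,
  `C = 1.40` Hz, with an optional additive substituent correction) is the
  classic three-term proton relation. It is *not* the force-field-specific
  procedure behind the built-in numbers, so a derived basis is expected to
  differ from the built-in one numerically; reproduction of the published
  table always uses the built-in basis.
* Karplus coefficients are never fitted here; they are inputs.

## Geometry layer

`cremer_pople()` implements the standard puckering analysis: out-of-plane
displacements \(z_j\) relative to the mean plane give an amplitude \(Q\)
and spherical angles \((\theta, \varphi)\). Conventions that the package
fixes (the literature leaves several free):

* Ring atoms are indexed O5, C1, C2, C3, C4, C5 with O5 first.
* \(\theta = 0\) is the \(^4C_1\) chair, \(\theta = 180^\circ\) the
  \(^1C_4\) chair.
* On the equator, \(\varphi = 150^\circ\) is assigned to \(^2S_O\): at that
  azimuth the displacement pattern has C2 above and O5 below the plane.
  The full constant table lives in `CANONICAL_PUCKER`.
* `classify_conformer()` accepts \(\theta\) within 35° of a pole and, for
  the skew-boat, \(|\theta - 90^\circ| \le 35^\circ\) with \(\varphi\)
  within 30° of the canonical azimuth — half the spacing between canonical
  forms. Everything else, and any ring with \(Q < 0.1\) Å, is `OTHER`.
  \(\varphi\) is undefined at the poles and flagged as such rather than
  given an arbitrary value.

`build_ideal_ring()` inverts the transform: atoms are placed on a circle
with the prescribed displacements, the radius chosen by least squares over
the six bond-length targets (C–C 1.52 Å, C–O 1.43 Å), and ring protons
added tetrahedrally at 1.10 Å. The proton side pattern is the idealised
L-iduronate configuration, fixed once by three requirements: all four
H–C–C–H torsions gauche in \(^1C_4\) (small couplings), H1–H4
trans-diaxial in \(^4C_1\) (large couplings), and the short trans-ring
H2–H5 contact in \(^2S_O\).

Default amplitudes are per form — 0.57 Å for the chairs and 0.76 Å for the
skew-boat — because twist forms of pyranoses pucker with characteristically
larger amplitude; a single shared amplitude cannot reproduce the ~2.6 Å
H2–H5 skew-boat contact that makes the NOE assay work. With these defaults
the idealised rings give H2–H5 of 2.63 Å (\(^2S_O\)) versus 4.08 Å in both
chairs. A knowable limitation: the idealised chairs are exact mirror
images, so their H2–H5 distances coincide; the ~0.2 Å asymmetry between
real \(^1C_4\) (≈4.0 Å) and \(^4C_1\) (≈4.2 Å) rings comes from exocyclic
substituents the six-atom-plus-protons model does not carry. Both values
sit inside the published bands, but the strict three-way distance ordering
is asserted in tests only as \(^2S_O < {}^1C_4 \le {}^4C_1\).

Hydrogen bonds (`detect_hbonds()`) are geometric: donor–acceptor distance
≤ 3.5 Å and D–H⋯A angle ≥ 135°, common molecular-dynamics practice; the
criteria object makes both thresholds and the atom selectors explicit, and
detection degrades to distance-only when the donor proton is absent.

## NOE ratio prediction

The \(^2S_O\) diagnostic is the ratio of the H2–H5 to the H4–H5 NOE
cross-peak. Two predictors are provided: linear mixing of the
pure-conformer ratios (0.05, 0.53, 0.03 for \(^1C_4\), \(^2S_O\),
\(^4C_1\)), and isotropic two-spin \(r^{-6}\) intensity averaging

\[
\mathrm{ratio}(p) = \frac{\sum_c p_c\, r_{25,c}^{-6}}{\sum_c p_c\, r_{45,c}^{-6}} .
\]

H2–H5 distances default to 4.0, 2.6 and 4.2 Å. The H4–H5 distances are not
independently known; the defaults (2.43, 2.34, 2.35 Å) are *derived
constants*, back-solved so that each pure-state \(r^{-6}\) limit reproduces
the pure ratio exactly — making the two predictors consistent at the
corners of the simplex. Both are strictly increasing in \(p_{2S_O}\), which
is all they are used for: oligosaccharides tumble anisotropically, so
two-spin quantitative distances are not defensible and measured ratios are
never fitted. `ratio_trend()` reports Kendall concordance only.

## The synthetic-data generator

`flip_model()` / `simulate_flip_trajectory()` / `states_to_frames()` /
`synth_observed_couplings()` emulate the statistical structure the analysis
assumes, so the whole pipeline can be validated end to end with no external
data:

* **Kinetics.** A discrete-time Markov chain with the requested stationary
  distribution. Only the timescale ("slow, microsecond") is known, not the
  rates, so the chain is parameterised by one dwell number: the expected
  dwell of the most populated state (default 50 frames), with minor states
  dwelling proportionally shorter (\(d_i \propto \pi_i\)). This is the
  unique reversible chain with the requested stationary law and equal jump
  flow between populated states — and proportional dwell is not merely
  convenient: a chain in which *every* state keeps the same dwell is
  infeasible whenever one state's outflow exceeds the others' combined
  (e.g. stationary 68/32).
* **Geometry.** Each state maps to its idealised ring plus isotropic
  Gaussian jitter (default used in validation: 0.05 Å), a stand-in for
  thermal fluctuation within a conformer well. Real within-well motion is
  correlated and anharmonic; passing tests therefore show correctness of
  the averaging/fitting machinery, not force-field realism.
* **Measurement noise.** Independent Gaussian noise per coupling, default
  0.1 Hz — about the one-decimal resolution at which couplings are
  tabulated; no published error model exists.

All stochastic functions take explicit integer seeds and restore the
caller's RNG state; seeded runs are bit-reproducible.

Validation sizes used by the tests and the bundled analysis scripts: the
end-to-end recovery property runs 100,000 frames at 0.05 Å jitter and
recovers stationary populations within 3 percentage points; the shrinking-
error property uses 3 seeds × sizes 1,000/5,000/25,000; the noisy-coupling
recovery property uses 500 seeded replicates. These sizes were chosen so
that Monte-Carlo error sits comfortably below the asserted tolerances.

## Degenerate and edge inputs

* Reference sets with two indistinguishable basis vectors are rejected at
  construction and re-checked in both fitters (the deconvolution is
  ill-posed).
* A planar ring has \(Q = 0\) and undefined \(\theta, \varphi\); collinear
  ring atoms and collinear torsion atoms raise geometry errors rather than
  returning angles.
* Population vectors renormalise only within an explicit tolerance;
  negative components always error.
* Row-level fit failures in `report_table()` are collected per record and
  do not abort the remaining rows.
* Rounding anywhere in the reporting path is half-up (`round_half_up()`),
  matching how printed tables are rounded, never banker's rounding.

## Known limitations

* The package deconvolutes *populations*; it estimates no kinetics from
  data and no error bars on populations (none are published for the
  measurement table; the couplings' digital resolution is unknown, so the
  record type deliberately carries no uncertainty field).
* The idealised geometry builder supports the three canonical iduronate
  forms only; it is not a general sugar builder, and its chairs are mirror
  images (see above).
* NOE predictions are directional diagnostics, not quantities to compare
  with measured ratios numerically.
* The built-in reference couplings are inputs taken from restrained-
  ensemble calculations; reproducing them from first principles is outside
  scope.
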