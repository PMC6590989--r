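---
title: "raftCRAC: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{raftCRAC: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftCRAC)
```

raftCRAC asks two linked questions about a membrane ion channel: does it
partition into cholesterol-rich microdomains (lipid rafts), and does its
sequence carry motifs through which cholesterol could bind it directly?
The package implements the five quantitative procedures that answer these
questions — motif scanning, conservation analysis, gradient partitioning,
TIRF co-movement colocalization and Hill dose-response comparison —
together with ground-truthed simulators that make each procedure testable
end to end.  This vignette records the models, their assumptions, the
parameters that matter, and the design decisions taken where the problem
was genuinely open.

## CRAC motif scanning

The CRAC (Cholesterol Recognition/interaction Amino acid Consensus) motif
is a linear, directional pattern read from the N- to the C-terminus: a
branched apolar residue (L/V), then 1–5 arbitrary residues, an aromatic
residue (Y canonically; Y/F/W in the extended definition), another 1–5
arbitrary residues, and a basic residue (K/R).  Both presets are available
from `cracPattern()`.

Design decisions:

* **Gap semantics.**  "X~1–5~" counts residues *strictly between* two
  anchors, from 1 to 5 inclusive.  This convention reproduces the known
  TM2/TM4 motif inventory of mouse TRPA1 exactly (e.g. V780→F786 spans a
  gap of 5, Y788→K790 a gap of 1) and is asserted in the test suite.
* **All overlapping matches are reported.**  Distinct anchor triples are
  distinct motifs even when they share residues: each triple is an
  independent candidate binding configuration, and the three overlapping
  TM2 motifs of mouse TRPA1 are counted separately for the same reason.
* **Window rule.**  `scanTM()` expands each transmembrane segment by a
  configurable flank (default 5 residues, the juxtamembrane stretch at the
  lipid–water interface, where the basic anchor typically sits) and
  requires *all three* anchors to lie inside the flanked window — the
  strictest containment reading that still yields the known motifs.
  Overlapping windows are never merged; a match in two windows is reported
  under each segment id.
* **Coordinates.**  1-based inclusive residue numbers throughout, with a
  per-record `offset` so that fragments keep full-length numbering
  (e.g. V780 in an 11-residue fragment).  `'X'` (unknown residue) matches
  no anchor set but may occupy gap positions.
* **TM2 boundaries.**  Two published conventions exist for the mouse TRPA1
  TM2 segment (766–793 and 765–793); both are kept as presets in
  `trpa1Topology()` rather than silently choosing one.

The scanner is validated against an independent brute-force enumeration of
all (i, j, k) triples on 1,000 random sequences (length ≤ 60), and its
count monotonicity, offset covariance and directionality are
property-tested.

## Conservation scoring

Conservation of an ortholog alignment is scored with a transparent
property-class scheme rather than a re-implementation of any particular
alignment viewer's score: the displayed flags are what carries the
biological claim, and those are reproduced exactly as defined.  A column
gets the identity flag (`*`) when all rows are identical with no gaps, and
the property flag (`+`) when all rows share at least one class of a
configurable residue-property table (default: hydrophobic, aromatic,
positive, negative, polar, small, and a proline/glycine special class).
The numeric score is the number of classes shared by every residue divided
by the number of classes, set to 1 for strict identity.  Gaps always break
both flags, are excluded from consensus denominators, and count as
non-conserving in anchor-conservation fractions — the conservative choice,
stated explicitly because displayed-alignment conventions are silent on it.
Consensus ties break alphabetically and carry an ambiguity flag, for
determinism.

`anchorConservation()` maps each match anchor from reference-row numbering
through the alignment and reports the fraction of species whose residue at
that column belongs to the anchor's class (apolar {L,V}, aromatic {Y,F,W},
basic {K,R}) — class-preserving substitutions still count as conserved,
which is the biologically relevant notion for a motif defined over residue
classes.

## Density-gradient partitioning

Fraction profiles (default 6 fractions, tube top first) are summarized by
their normalized profile, peak fraction, intensity-weighted centroid
`sum(i * I_i) / sum(I_i)`, and the share of signal in a designated raft
fraction set (default fractions {3, 4}, where flotation gradients
concentrate raft markers such as flotillin-2).  The depletion statistic is
the shift of these summaries between control and treated profiles,
positive toward denser fractions.  The headline "fraction shift" is the
peak shift — the coarse statistic matching how such shifts are reported —
with the centroid shift alongside as its continuous counterpart; replicate
summaries average per-pair shifts and report the s.e.m.  Peak ties resolve
to the lowest index with an explicit tie flag.  All statistics are
invariant to overall profile scaling.  Densitometry itself (extracting
band intensities from blot images) is out of scope; profiles enter as
tables.

## TIRF co-movement colocalization

The dynamic colocalization score operationalizes "moving together": a red
track is colocalized when some green track stays within `rPair` pixels on
at least `minConsecutive` consecutive shared frames.  The
three-consecutive-frame rule (at the standard 500 ms frame interval)
exists to reject chance coincidences of independently moving structures;
the test suite verifies that planted 2-frame coincidences are rejected.

Upstream of the rule:

* **Detection** is a difference-of-Gaussians band-pass (kernels σ/√2 and
  σ√2, a constant-bandwidth pair centred on the spot scale σ, default
  1.5 px ≈ the PSF), local maxima above the band-pass median + k·MAD
  (k = 5), non-maximum suppression within 2 px (one detection per
  resolvable spot), and sub-pixel refinement by local centroid.
* **Tracking** is greedy frame-to-frame nearest-neighbour linking with a
  hard radius `rLink` (default 4 px, about four times the expected
  frame-to-frame displacement at the default simulated mobility) and no
  gap closing: the consecutive-frame rule presumes unbroken observation,
  so a lost detection deliberately ends a track.

Open choices resolved here: the percentage's denominator is the red
(channel-of-interest) tracks at least `minConsecutive` frames long, since
the scientific claim is about the channel's structures; green and union
denominators are available.  "Staying together" is centre-to-centre
distance ≤ `rPair` (default 3 px), as no published distance threshold
exists.  Sequential two-channel excitation can be compensated with an
optional integer frame offset on the green channel (default 0).

## Confocal membrane fraction

The membrane ROI comes from the membrane-dye channel: global Otsu
threshold, morphological closing (5 px disc), largest connected component.
Filling the ring gives the whole-cell mask.  Background is the median
reporter intensity outside the cell mask — the estimator is a package
choice, as the underlying exclusion rule ("below background excluded") does
not specify one — and reporter pixels at or below it are excluded from all
sums.  The membrane fraction is the ring sum over the whole-cell sum, both
background-excluded; it is invariant to reporter gain and bounded by [0, 1]
because the ring is a subset of the cell mask by construction.  A
clustering index — the coefficient of variation of ring intensity over 36
angular bins around the cell centroid — is reported alongside to give
"clustered membrane localization" a number; it is an addition of this
package, not a reproduction of any published quantity.  One cell per image
is assumed; multi-cell fields should be cropped upstream.

## Hill dose-response analysis

The response model is ΔCa²⁺(c) = Max·c^H / (c^H + EC50^H), evaluated in
log space as Max / (1 + exp(H·(log EC50 − log c))) for stability at
extreme concentrations.  `fitHill()` pools all cells into one nonlinear
least-squares fit (per-concentration means are available as an option) —
pooling matches the convention of fitting one curve to all cells from
several transfections and reporting a fitting error.  Positivity of all
three parameters is enforced by fitting on the log scale; the Hill
coefficient is bounded to [0.3, 10]; initialization takes Max from the
largest per-concentration mean and EC50 from log-interpolating the
half-maximal concentration.  Standard errors are asymptotic, delta-method
transformed from the log scale.  Non-convergence is returned as a flagged
result with the optimizer message, never silently.

`compareConditions()` reports the EC50 fold change and Max ratio
(treated/control) with percentile bootstrap intervals: cells are resampled
within each condition, stratified by concentration so every dose stays
represented, and both fits are repeated (default B = 200).  A resampling
interval is the minimal defensible uncertainty for a ratio of fitted
parameters.  `classifyMcdSensitivity()` calls a condition pair "sensitive"
when the fold-change interval excludes 1 — mirroring the
wild-type-sensitive versus CRAC-mutant-insensitive dichotomy.

## Synthetic data: what it emulates, and what it does not

Every generator takes a mandatory seed, is bit-reproducible, and returns
its ground truth alongside the data; recovery tests never re-derive truth
from the data.  Gaussian read noise is added to an ideal noise-free image
(no Poisson shot noise, no camera gain model — the noiseless ideal keeps
recovery tests analytically tractable), and intensity budgets are
conserved exactly before noise injection.

* `simOrthologSet()` emulates a 24-species mammalian ortholog panel with
  no indels (the alignment is the identity — conservation analysis
  operates on an existing alignment, so indel handling belongs to the gap
  policy, not the generator).  Anchor sites of planted motifs are retained
  with probability `anchorFidelity` (default 0.9) and otherwise mutated
  *out of* their class; other sites mutate uniformly at
  `substitutionRate` (default 0.1).  The first row is the unmutated
  reference.
* `simTirfMovie()` emulates two-channel TIRF at 500 ms intervals:
  reflected Gaussian random walks, co-moving pairs sharing one base
  trajectory with independent per-channel jitter (0.3 px), isotropic
  Gaussian spots (σ 1.5 px) on constant background.  Defaults — 192×192 px
  (≈12 µm at the 65 nm/px scale of a 100× TIRF system), 13 structures,
  diffusion 1.0 px/frame per axis (D ≈ 0.005 µm²/s, a mobile
  membrane-proximal vesicle), amplitude/noise 200/5 — were chosen to match
  that instrument scale and the sparse vesicle fields in which
  co-movement scoring is well-posed; the generator warns when the mean
  nearest-neighbour distance falls below twice the pairing radius.  It
  does not model vesicle fusion, directed transport, photobleaching or
  evanescent-field depth.
* `simConfocalCell()` draws a circular cell: membrane-dye annulus
  (radius 30 px, thickness 3 px), nuclear disk, and a reporter channel
  splitting a fixed photon budget exactly as `fMembrane` on the annulus
  versus the interior, optionally clustered along the perimeter with a von
  Mises profile.  Real cells are neither circular nor single — passing
  recovery tests shows the quantification is correct on its stated model,
  not that segmentation is robust to arbitrary morphology.
* `simGradientProfile()` mixes two discretized Gaussian components — a
  raft component (centre fraction 3) and a non-raft component (centre 6) —
  with weight `raftWeight`; width 0 collapses a component to a delta.
  `expectedGradientProfile()` gives the noiseless mixture, from which the
  analytic expectation of centroids and shifts follows for tests.
* `simDoseResponse()` draws per-cell responses as Hill(c) + N(0, σ).
  Defaults are the wild-type conditions (EC50 11.8 µM, Max 0.79 µM); the
  Hill coefficient is not a published value, so it stays a free parameter
  with default 2.

## Problem sizes and numerical notes

The shipped test-suite and acceptance computations use: 1,000 random
sequences (length ≤ 60) for scanner-oracle equivalence; 24-species panels
for conservation recovery; movies of 40 frames at 192×192 px with 13
structures for co-movement recovery (recovered within ±10 percentage
points of the planted fraction); 96×96 px cells for membrane-fraction
recovery (±0.05); 50 cells per concentration over six doses, 20 replicate
seeds, for noisy Hill recovery; and B = 100–200 bootstrap resamples for
condition comparison.  All tolerances are asserted in
`tests/testthat/` at these sizes.

Determinism: generators call `set.seed()` internally with their mandatory
seed; `runPipeline()` embeds a config hash (FNV-1a over the canonical JSON)
and the seed in every report and contains no timestamps, so identical
config + seed gives byte-identical output.

## Known limitations

* Real-data values from the original imaging experiments (the 89% dynamic
  colocalization score, the ~75% membrane-amplitude reduction after
  cholesterol depletion) depend on unavailable raw images and are
  emulated, not reproduced.
* The scanner covers CRAC only — not the inverted CARC motif nor
  sterol-sensing domains.
* Tracking has no gap closing or motion model; heavily crowded fields are
  out of its design envelope (the generator's density warning marks the
  boundary).
* The gradient module consumes densitometry tables; it does not extract
  band intensities from blot images, and it does not calibrate gradient
  densities.
* Hill fitting assumes a saturating single-site response; biphasic
  dose-response curves will fit poorly and should be caught by the
  residual summary.
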