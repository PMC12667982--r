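---
title: "Methods: circumferential MAP lattice wrapping and motor gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circumferential MAP lattice wrapping and motor gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrapmap)
```

## The scientific problem

Most structural microtubule-associated proteins (MAPs) — tau, MAP2, MAP4,
MAP7 — bind along a single protofilament. MAP9 is different: its
microtubule-binding domain (MTBD) is a single long α-helix carrying five
degenerate tubulin-binding pseudo-repeats of the form **ΦXXWXXXK** (a
hydrophobic Φ, an invariant tryptophan at Φ+3, an invariant lysine at Φ+7),
spaced so that consecutive repeats land on *adjacent protofilaments*. The
helix therefore wraps circumferentially around the microtubule, stapling
protofilaments laterally — which suppresses catastrophe and slows
depolymerization — and its position on the lattice selectively gates which
kinesin motors can walk past it.

`wrapmap` implements the quantitative analyses that support this picture,
each paired with a seeded synthetic-data generator so the full pipeline is
testable without any deposited data:

1. **Motif scanning** (`scanPseudoRepeats`): detect ΦXXWXXXK repeats and
   their spacers on a protein sequence.
2. **Wrap geometry** (`wrapRepeats` and friends): how many protofilaments
   a repeat-bearing helix spans, and how many MAPs tile the circumference.
3. **MD inter-protein correlation and contacts** (`correlationMap`,
   `filterPairs`, `classifyContacts`, `interactionSummary`): the
   three-step correlation method over Cα coordinates, followed by
   residue-level interaction classification with occupancy fractions.
4. **Single-molecule motility** (`runFrequency`, `runStats`,
   `fitLangmuir`): run frequency, run length, velocity, and equilibrium
   binding (Langmuir isotherm, K~D~).
5. **Dynamic instability** (`segmentPhases`, `growthRate`,
   `catastropheFrequency`, `depolymerizationRate`): tip-trace phase
   segmentation and kinetic metrics.

## Motif scanning

A candidate repeat is any window with Φ at position *i*, W at *i*+3 and K
at *i*+7. W and K are strict: the corresponding alanine and
charge-reversal substitutions abolish lattice binding, so a window without
them is not a repeat. The Φ class is a genuine modeling decision: the
canonical repeats use tyrosine or phenylalanine, but one repeat uses
valine at the Φ position, so the default class is
{F, Y, W, L, I, V, M} with full score for F/Y (1.0), 0.8 for W and 0.6
for the aliphatic hydrophobics. The default `minScore = 0.5` admits the
valine repeat while letting users restrict to aromatic-only scans.

Overlapping candidates are resolved greedily — highest score first, ties
to the left-most — and surviving repeats are grouped into *chains*
whenever the spacer (residues strictly between one repeat's K and the
next repeat's Φ) falls inside `spacerRange`. The default range of 30–45
residues brackets the observed 35/36-residue spacers loosely enough for
orthologs. All positions are reported in the input's own author
numbering.

The human MAP9 MTBD anchors used throughout the tests are
Φ = 429, 473, 516, 560, 603 (identities Y, F, F, V, Y), giving spacers
36/35/36/35 and Φ-to-Φ periods 44/43/44/43 (mean 43.5):

```{r motifs}
seq <- implantMotifs(length = 700, seed = 1)
tb <- scanPseudoRepeats(seq)
tb
```

## Wrap geometry

The lattice is modeled as a cylinder of `nProtofilaments` identical
binding sites (the seam is ignored because the repeats bind β-tubulin,
which presents the same epitope on every protofilament). Three numbers
control everything:

* **rise per residue**: 1.5 Å, the canonical α-helix rise; a 200-residue
  MTBD is exactly a 300 Å helix under this value.
* **dimer axial repeat**: 82 Å (length of an αβ-tubulin dimer).
* **binding radius**: the one free parameter. No radius is measured
  directly, so the default is chosen for self-consistency: the arc
  between adjacent protofilament sites (`2πr/n`) equals the mean repeat
  period stretched along the helix (43.5 residues × 1.5 Å = 65.25 Å),
  giving r ≈ 145.4 Å for 14 protofilaments. The 5-protofilament span is
  therefore model-dependent and should be read as a geometric
  consistency statement, not an independent measurement.

The span is `min(nRepeats, floor(contour/spacing) + 1)` — the starting
protofilament counts — and the number of MAPs tiling the circumference is
`ceiling(n/span)`. With the MAP9 defaults: a 300 Å helix, span 5,
3 MAPs per 14-protofilament circumference. `wrapRepeats` also reports
each repeat's *arc mismatch* (preceding period × rise − site arc
spacing), a per-repeat strain indicator that stays within ±2.2 Å for the
43/44-residue periods.

## MD correlation and contact classification

The three-step method:

1. **Covariance.** The configuration vector R holds the Cα coordinates of
   the two analysis groups (e.g. the MAP helix and a kinesin motor
   domain); the covariance C = ⟨(R−⟨R⟩)(R−⟨R⟩)ᵀ⟩ is computed about the
   trajectory mean over all runs concatenated. The per-residue-pair
   scalar is the displacement-vector inner-product normalization (the
   dynamic cross-correlation convention):
   c_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩), bounded in [−1, 1].
   Residues with zero displacement variance (e.g. restrained atoms) are
   flagged degenerate and reported as 0 rather than NaN. No superposition
   is applied by default — the tubulin Cα restraints of the source
   simulations fix the frame — and coordinates are never rescaled, so
   rigid translations and rotations of whole frames leave the map
   unchanged.
2. **Distance filter.** A residue pair is kept iff its minimum
   inter-residue heavy-atom distance is within `contactFilterCutoff`
   (default 12 Å, the widest classifier criterion) in at least
   `contactFilterMinFraction` (default 0.10) of frames. The source
   method states no threshold, so both are exposed in `contactRules()`.
3. **Classification.** Per frame and per pair: *salt bridge* — any basic
   nitrogen (Lys NZ; Arg NE/NH1/NH2; His optional, off by default since
   protonation is unknown) within 6 Å of an acidic oxygen (Asp OD1/OD2,
   Glu OE1/OE2, C-terminal OXT); *hydrogen bond* — donor–acceptor
   distance ≤ 3.5 Å with the D–H···A arrangement within 30° of linearity
   (the angle criterion is read as deviation from linearity: a literal
   D-Ĥ-A angle ≤ 30° is geometrically impossible at 3.5 Å); when the
   input has no hydrogens the test falls back to distance-only and the
   records carry a `distance_only` flag; *hydrophobic* — any side-chain
   carbon pair ≤ 8 Å (side-chain carbons are all carbons except backbone
   C and CA, so glycine contributes none); *repulsive* — any like-charged
   pair (basic-N/basic-N or acidic-O/acidic-O) ≤ 12 Å. The repulsive
   class is a distance criterion; the signed correlation is carried
   alongside rather than being required to be negative.

Occupancy — the fraction of frames satisfying a criterion — is reported
per run and pooled over the concatenated runs, matching how multi-run
production simulations are analyzed (for the lattice-only system, eight
125-ns runs totalling 1 μs; see `mdRunTable()`). `interactionSummary()`
reports mean ± SD of per-run occupancies using the *population* SD
convention (recorded in the output attribute), so two runs at 0.16 and
0.26 report 0.21 ± 0.05.

A labeled alternative worth noting: the narrative description of the
method speaks of correlations of inter-residue *distances* while the
formal definition is a coordinate covariance. These are different
statistics; the package implements the covariance definition, and the
distance-correlation variant is deliberately not conflated with it.

## Motility statistics and binding

Run frequency is the number of processive runs on a microtubule divided
by its length and the observation time (events µm⁻¹ min⁻¹), summarized as
mean ± SD across microtubules (the unit of replication in the source
figures). "Processive" is operationalized as displacement ≥ 0.5 µm and
duration ≥ 0.6 s (three frames at 200 ms) — manual kymograph scoring has
no published threshold, so these are explicit, configurable defaults.
Run length is the absolute displacement of a scored track and velocity is
run length over duration.

Equilibrium binding fits the single-site Langmuir isotherm
I(c) = I~max~·c/(K~D~+c) by Levenberg–Marquardt least squares over all
replicate intensity measurements, with K~D~ bounded positive,
initialized at I~max~ = largest per-concentration mean and K~D~ = the
concentration nearest half-max. The reported K~D~ ± SE uses the fit's
parameter covariance (a bootstrap is easy to layer on top but is not the
default, matching the common fit-SE reporting convention). The fit is
scale-equivariant: rescaling all intensities rescales I~max~ and leaves
K~D~ unchanged. Note that a "recovered within 1 fit SE" check of such a
fit has ~68% nominal coverage even for a perfect estimator; the package's
own parameter-recovery property instead bounds the *median relative bias*
across 200 simulated curves (< 5% at 15% multiplicative noise).

## Dynamic instability

Tip traces (time, tip position) are segmented by a centered
sliding-window least-squares velocity classified against two thresholds:
growth above +0.2 µm/min, shrinkage below −3 µm/min, pause in between.
The defaults separate the two regimes by roughly an order of magnitude on
each side (growth is of order 1 µm/min; shrinkage is of order
0.3 µm/s = 18 µm/min). Adjacent same-type samples merge into phases;
phases shorter than `minDuration` (3 samples) are absorbed into their
longer neighbor; each final phase is refit by ordinary least squares for
its slope and slope SE. Segmentation is invariant to position offsets and
time-origin shifts, and on noise-free piecewise-linear traces recovers
slopes exactly and transitions to one sample.

Derived metrics: growth rate is the per-trace time-weighted mean growth
slope (µm/min), summarized across traces; depolymerization rate is the
per-trace time-weighted |slope| of shrinkage phases (µm/s); catastrophe
frequency is transitions into shrinkage (from growth *or* pause) divided
by total growth time — the per-growth-time convention is a choice, since
the observable is also reported per total time in parts of the
literature, and it is recorded in the output.

### The synthetic two-state process, and what the tests do and do not show

`simulateDynamicInstability()` draws a continuous-time two-state process:
growth at v~g~ switching with hazard k~cat~, shrinkage at v~s~ switching
back with hazard k~res~, length floored at the seed (hitting zero forces
regrowth), sampled at the frame interval with additive Gaussian
localization noise. Defaults emulate the in vitro imaging conditions of
the motivating experiments: 5-s frames, 0.05 µm localization noise,
v~g~ = 1.5 µm/min, v~s~ = 0.3 µm/s, k~cat~ = 0.5 min⁻¹, k~res~ = 0. The
exact event log is returned so estimators can be scored against the
realization that generated the data.

Problem sizes used in the shipped checks (chosen for sub-minute suite
runtimes while keeping hundreds of events per estimate): recovery of the
depolymerization speed uses 50 shrinkage-only traces of 30 s at 0.2-s
sampling with 0.1 µm noise; estimator-consistency checks use 25/100/400
traces of 300 s.

Two honest limitations:

* **Sub-resolution events.** Phase durations are exponential, so some
  shrink excursions are shorter than any detector's resolution floor
  (about 0.5–1 s here). A threshold segmenter therefore *cannot* be
  exactly unbiased for the generative k~cat~; at 0.2-s sampling with low
  noise the missed fraction is ~5%, and in seed-regrowth regimes where
  catastrophes strike immediately after regrowth it can reach ~15%. The
  consistency tests therefore score the estimator against the
  realization's event log (agreement within the detection floor) and
  against the generative hazard with that floor acknowledged — the same
  limitation applies to manual kymograph scoring of real movies.
  Consistency runs use a rescue-dominated regime (k~res~ = 3 min⁻¹,
  0.2-s sampling, 0.01 µm noise, 15-sample window) so the floor stays
  small.
* **What the generators do not emulate.** No photophysics (blinking,
  bleaching), no tip-structure effects on localization, no
  length-dependent or age-dependent catastrophe, no MT-MT crossings, and
  the motility generator uses constant velocity within a run. Passing
  tests demonstrate that the estimators recover the parameters of these
  idealized processes at realistic noise — not that they are robust to
  every artifact of real microscopy data.

## Numerical and interface conventions

* Coordinates in Å; positions along MTs in µm; times in s (rates in the
  units stated per function); residue numbering 1-based as authored,
  0-based only internally.
* All generators hang off one top-level seed fanned out through fixed
  per-generator labels (`subSeed`), so adding a generator never perturbs
  another's stream; identical seeds give byte-identical serialized
  outputs.
* Degenerate inputs are first-class: zero-variance residues are flagged
  rather than propagating NaN; empty track sets and repeat-free
  sequences return empty results rather than errors; malformed
  multi-model PDBs are rejected naming the offending model.
* The command-line surface is a thin wrapper (`inst/scripts/wrapmap.R`)
  over `runPipeline()`, which writes TSV/JSON results plus a
  `run_info.json` embedding the package version, seed and full
  configuration of every run.
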