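---
title: "Crosslink-restrained coarse-grained modeling of receptor-tethered flexible proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosslink-restrained coarse-grained modeling of receptor-tethered flexible proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlwalk)
```

## The modeling problem

Many regulatory proteins dock onto large, rigid assemblies through short
structured elements while the rest of the chain remains flexible.  A
prominent example is the spindle-pole-body receptor Spc110p, whose
N-terminal coiled-coil binds the γ-tubulin small complex (γTuSC) while its
first ~160 residues lack stable structure.  Crosslinking mass spectrometry
(XL-MS) is often the only source of positional information for such
regions: each confidently identified crosslink bounds the Cα–Cα distance
between two residues by the span of the crosslinker arm.

`xlwalk` implements the standard integrative-modeling treatment of this
situation:

1. **Evidence filtering.**  Crosslink identifications are kept when the
   peptide-level q-value is ≤ 0.01 and the residue pair is supported by at
   least two peptide-spectrum matches (PSMs), after merging A–B / B–A
   duplicates of the same unordered pair.
2. **Hybrid representation.**  Resolved regions become rigid bodies of Cα
   particles taken from deposited coordinates; unresolved regions become
   flexible strings of beads, one bead per `per_bead` residues with the
   volume-equivalent radius `r(n) = (3 n v_res / 4π)^{1/3}` (v_res =
   132.3 Å³ per residue; r(1) ≈ 3.17 Å).
3. **Scoring.**  Models are scored against (i) crosslinks, as flat-bottom
   upper harmonics on the *ambiguity minimum* distance (the minimum over
   all chain-copy combinations, so a link satisfied by either copy of a
   dimer counts once), (ii) soft-sphere excluded volume and (iii) sequence
   connectivity.
4. **Sampling.**  Seeded Metropolis Monte Carlo with simulated annealing
   over single-bead, collective segment, tail-pivot and rigid-body moves.
5. **Analysis.**  Good-scoring models are pooled across independent runs,
   clustered by structural similarity, and summarized as localization
   probability densities (MRC maps) contoured relative to each map's own
   maximum.

A second, independent toolbox quantifies differences between
conformational states of the rigid assembly itself: Kabsch superposition,
center-of-mass displacements, screw (twist/rise) and helical-pitch
parameters of filaments, Shrake–Rupley solvent-accessible surface areas
and buried interface areas, and displacement of ring subunits from an
ideal lattice register.

## Restraint forms and their parameters

**Crosslinks.**  For a link with threshold `L` (defaults: DSS 35 Å,
EDC 25 Å, Cα–Cα) and ambiguity-minimum distance `d`, the penalty is

```
score = k · min( max(0, d − L), δ_max )²,    k = 1 (score/Å²), δ_max = 10 Å
```

The flat bottom means any geometry satisfying the link is equally good —
the data only cap the distance.  The truncation at `δ_max` makes the
restraint *robust*: identification tables at 1% FDR contain false
positives whose endpoints can sit 50–100 Å apart, and an unbounded
quadratic would let a single such outlier (≈2000 score units at 80 Å)
outweigh dozens of satisfied links and drag true neighbors off their
sites.  With the truncation an outlier contributes a bounded penalty
(k·δ_max² = 100) and exerts no force once beyond `L + δ_max`.  The
thresholds themselves are the usual linker-arm plus side-chain allowances;
both are per-run configurable, as is the ambiguity scope (all copies, or
paired copies only).

**Excluded volume.**  `k_ev · max(0, r_i + r_j − d_ij)²` over all particle
pairs, exempting pairs inside one rigid body and sequence-adjacent pairs
(the chain term below already governs those).

**Connectivity.**  Consecutive particles spanning `g` residues are held
below `U = r_i + r_j + c·g` with `c = 3.8` Å/residue (the Cα–Cα virtual
bond) by an upper harmonic.  Pairs inside one rigid body are exempt:
their distances are fixed by construction, so the term would only add a
constant — and for pseudo-atom test receptors whose residue numbering
does not follow a physical chain it would add a large, meaningless one.

**Known anchors.**  When a segment's binding site is known independently
(e.g. a docked crystal structure of the coiled-coil), the restraint set
accepts `anchors`: distance restraints with the same flat-bottom form that
are excluded from crosslink satisfaction statistics, since they are prior
knowledge rather than XL-MS evidence.

## Sampling design

A `sampler_config()` *step* is one sweep: one attempted move per mobile
entity, so the per-particle move budget is independent of system size.
The move mix for flexible chains is 50% single-bead translations
(σ = 2 Å), 25% rigid translations of a random 2–16 bead window, and 25%
pivots of a chain tail about a random bead; mobile rigid bodies get
combined rotation (σ = 5°) + translation (σ = 1 Å) moves.  All proposals
are symmetric, so plain Metropolis acceptance is valid.  The collective
moves matter: single-bead diffusion alone decorrelates a 150-bead coil far
too slowly to equilibrate within a 20,000-sweep run.

Annealing is geometric over 10 equal stages from T = 20 down to T = 0.5.
The hot end melts mis-threaded topologies (a chain segment trapped on the
wrong side of a subunit must transiently break several links to cross);
the cold end matters because a flat-bottom landscape pushes satisfied
links against their thresholds entropically, and at T = 1 thermal kicks
carry them over often enough that the instantaneous satisfied fraction
hovers near the good-scoring cut.  At T = 0.5 satisfied links stay
satisfied.

Each run derives its random stream from `(master seed, run index)` and
re-initializes the flexible chains on a fresh surface-hugging
self-avoiding walk, so runs are independent in both their noise and their
starting topology.  Identical seed + config + inputs reproduce the
trajectory bit for bit (the compiled sampling core draws exclusively from
R's RNG).

**Good-scoring criteria.**  A model is good-scoring when its satisfied
crosslink fraction is ≥ 0.9 and its excluded-volume and connectivity
scores are each below 1.0 score unit per mobile particle — about twice
the thermal expectation of one active quadratic constraint per particle
at the final temperature, i.e. a cap that rejects genuinely strained
models without rejecting ordinary thermal fluctuation.

## Ensemble analysis

Pairwise model similarity is RMSD over a particle selection in the fixed
receptor frame (no superposition — the receptor defines the frame).
Clustering is deterministic greedy centroid clustering: the model with the
largest neighborhood seeds cluster 1, its members are removed, repeat;
ties break toward the lowest model index.

The cluster radius defaults to `"auto"`: the estimated *sampling
precision*, taken as the median RMSD between models from different runs.
This is the field's standard protocol for coarse-grained ensembles — a
fixed radius chosen a priori is either meaninglessly tight (fragmenting a
unimodal ensemble whose true spread under 35 Å flat-bottom restraints is
tens of Å) or meaninglessly loose.  For a unimodal posterior the auto
threshold lands at the ensemble's own spread and yields one dominant
cluster; for well-separated modes the median inter-run RMSD sits at the
within-mode scale and the modes stay separate.  Any numeric radius can be
passed instead.

Localization densities rasterize each selected particle as a solid sphere
of its radius on a 3 Å voxel grid (1 Å for atomic Gaussian
rasterization, σ = resolution/2.355); raw occupancy counts are stored and
per-model normalization is a writer option.  Maps are written as MRC2014
mode-2 (float32) with correct cell and origin metadata.  Contour levels
are fractions of each map's own maximum (default 2.5%).  Difference maps
subtract after a least-squares amplitude fit of the model map to the
experimental map; sharpening and filtering are out of scope.

## The synthetic study

Because the real study's inputs are external depositions, the package
ships a generator that emulates the geometry of the problem end to end:

* **Receptor:** two rigid pseudo-Cα blocks (3 × 3 × 14 grid at 5 Å
  spacing, 0.5 Å jitter) related by a screw of 54.5° twist and 21.2 Å
  rise about the z axis at a 40 Å offset — an open-state-like helical
  segment of two elongated, GCP-sized subunits.  The elongation matters:
  XL-MS restraints are informative only when the assembly extent
  (~100 Å here) is large relative to the linker arm (35 Å).
* **Ground truth:** a 150-residue self-avoiding path with 3.8 Å steps
  that stays 6.4–10 Å from receptor atoms (surface-hugging, with enough
  clearance that the coarse-grained model can occupy the same positions),
  anchored near a designated receptor site.
* **Crosslinks:** 30 true links sampled among ligand–receptor and
  ligand–ligand pairs with ground-truth distance ≤ 0.8 × threshold,
  weighted by an empirical span prior (Gaussian around 17 ± 5 Å for DSS,
  10 ± 4 Å for EDC) so simulated link lengths resemble real
  identifications instead of piling up at the margin cap; plus 2 decoys
  drawn beyond 1.5 × threshold, so truth and decoy labels are unambiguous.
  All rows carry q-values ≤ 0.01 and PSM counts ≥ 2; filter-violating
  rows can be injected to exercise the evidence filter.
* **Plumbing:** the toy travels through the same PDB and CSV readers as
  real data.

The default study (`run_toy_pipeline()`) runs 4 independent runs of
20,000 sweeps, records a snapshot every 50 sweeps, filters to
good-scoring models, clusters at the sampling precision, and evaluates
the top cluster: its occupancy, its ensemble crosslink satisfaction, and
the fraction of ground-truth path points inside the 2.5% contour of its
localization density.  These sizes keep the full study at roughly two
minutes on a single core.

What passing does and does not show: the generator reproduces the
*geometry* of the inference problem (rigid receptor, tethered flexible
chain, distance caps with a controlled false-positive rate) but not mass
spectra, peptide detectability, compositional ambiguity, or density-map
restraints.  Success on the toy demonstrates that the pipeline's
machinery — filtering, representation, scoring, annealing, clustering,
densities — is internally consistent and recovers a planted truth under
realistic restraint density; it does not by itself validate conclusions
about any particular real complex.

## State-comparison conventions

* `superpose()` returns the proper rotation + translation mapping the
  second coordinate set onto the first (Kabsch, SVD with reflection
  guard); fewer than 3 points or collinear selections are errors.
* `screw_parameters()` requires a rotation above 10⁻³ degrees (a pure
  translation has no screw axis); the axis sign is chosen so the rise is
  non-negative, the axis point is the closest point of the axis to the
  origin, and `screw_transform()` reconstructs the transform to 10⁻⁶ Å.
* `helical_pitch(twist, rise)` = `rise · 360 / twist` Å per turn; with the
  open-state values 54.5° and 21.2 Å this gives 140 Å/turn.
* Center-of-mass displacements superpose on an alignment selection first
  and are unweighted over Cα by default (mass weighting is a flag).
* SASA uses Shrake–Rupley sampling with a 1.4 Å probe and 960
  golden-spiral points per atom (rotation-variance ≤ 1%), Bondi-style
  heavy-atom radii, hydrogens ignored.  Against NACCESS-derived numbers,
  agreement within ±10% should be expected (different radii sets and
  sampling).  Buried area is reported both-sides
  (`SASA(A) + SASA(B) − SASA(AB)`) with per-side halves alongside, since
  published totals rarely state the convention.
* Lattice-register displacement superposes ring subunit positions onto
  reference sites using only designated alignment pairs (≥ 3 pairs:
  Kabsch; exactly 2: centroid match plus minimal rotation aligning the
  pair axis) and reports per-subunit offsets and their maximum.

## Numerical and degenerate-input choices

* Argmin ties in ambiguous distances break toward the lowest copy, then
  the lowest model index; clustering ties toward the lowest model index —
  all outputs are deterministic given inputs and seeds.
* The sampler's compiled core maintains a dynamic cell list for the
  short-ranged overlap term; it changes nothing about the score, only the
  cost of evaluating it.  Score deltas exclude intra-move-set pairs,
  which rigid subset moves preserve exactly.
* Snapshot score breakdowns are recomputed from scratch in R rather than
  accumulated from deltas, so reported scores cannot drift.
* Crosslinks whose endpoints are entirely unrepresented are reported
  `unmappable` and leave the satisfied-fraction denominator.
* All-zero density grids refuse to produce a contour level; a contour
  fraction of 0 warns.  Grids read back from MRC must be mode 2 with
  x,y,z axis order.

## Known limitations

* The crosslink restraint is a truncated flat-bottom cap, not a Bayesian
  likelihood with nuisance parameters; the Bayesian form is the natural
  extension point.
* No density-map cross-correlation restraint: maps enter only for
  rasterization, difference maps and visual comparison.
* Rigid bodies have no internal flexibility, and sampling has no replica
  exchange or gradient path.
* The attainable precision for a 150-residue chain under 35 Å caps is
  tens of Ångströms; localization densities, not per-residue coordinates,
  are the meaningful output.
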