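---
title: "Methods: hairpin handedness and three-helix bundle foldability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hairpin handedness and three-helix bundle foldability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlefold)
```

## The model

`bundlefold` treats a single-chain three-helix bundle as two
αα-hairpins sharing a middle helix. The analysis rests on three layers:

1. **Torsion space.** A backbone conformation is a list of per-residue
   (φ, ψ, ω) dihedrals. Chains are built from internal coordinates by
   sequential NeRF placement with fixed ideal covalent geometry
   (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; bond angles 111.2°,
   117.2°, 121.7°; O at 1.231 Å, 120.1°, trans to the following N).
   ω(i) is the torsion of the peptide bond *preceding* residue i
   (CA(i−1)–C(i−1)–N(i)–CA(i)); this must be stated because the cis
   label depends on it. With the ideal helix dihedrals (−57, −47, 180)
   this geometry yields a right-handed α-helix with ≈1.5 Å rise and
   ≈3.63 residues per turn — the periodicity the whole foldability
   argument depends on.

2. **ABEGO coarse-graining.** Each residue's torsions map to one of
   five letters. We adopt the Rosetta bin boundaries: O if |ω| < 90°;
   otherwise for φ < 0, A if −75° ≤ ψ < 50° and B elsewhere; for
   φ ≥ 0, G if −100° < ψ ≤ 100° and E elsewhere. The four trans bins
   tile the Ramachandran plane completely (verified by a 1° raster in
   the tests). The exact boundary placement is a convention; all
   downstream statistics only require that it is applied consistently.

3. **Hairpin geometry.** For a helix-loop-helix fragment, **v**_N and
   **v**_C are the axis directions of the final/first single turn
   (4 Cα) of the flanking helices, both taken N→C along the chain;
   **v**_L joins the last Cα of the N-helix to the first Cα of the
   C-helix. The crossing angle is *antiparallel-referenced*,
   θ_HH = arccos(**v**_N · (−**v**_C)), so ideal hairpin packing gives
   θ_HH = 0° and the hairpin filter keeps θ_HH < 60° (strict). φ_HH is
   the torsion of the vector triple (**v**_N, **v**_L, **v**_C),
   signed so that the left-handed packing of the recurrent GB loop is
   negative; handedness is L iff φ_HH < 0. Mirroring a fragment
   negates φ_HH exactly, which pins the label convention to a single
   calibration (GB → L) and makes the L/R statistics meaningful.

### Helix axes

The per-turn axis is estimated by the bisector construction: at each
interior Cα the bisector of the bonds to its neighbours points at the
local axis, and the cross product of successive bisectors is parallel
to it; window-averaged directions plus an algebraic circle fit of the
projected Cα positions give an axis line that is exact for an ideal
helix. On a minimal 4-residue window with 5° torsion noise the
direction is good to ~10° on average (Monte-Carlo checked in the test
suite); worst-case single draws can deviate by ~20°, which is why
handedness statistics are computed over fragment populations, not
single noisy fragments.

## Reference bundles (Crick parameterization)

Ideal decoys are generated analytically: a minor helix (radius
2.26 Å, 1.51 Å rise per residue, 3.62 residues per minor turn) wound
on a superhelix of radius R and pitch P, with the superhelical phase
advancing by d/√(R² + (P/2π)²) per residue so that arc length grows by
the rise. Defaults follow the standard settings used throughout:
oligomer state 3, base radius 9.0 Å with the variant series
{×0.75, ×0.90, ×1.00, ×1.10, ×1.25} = {6.75, 8.1, 9.0, 9.9, 11.25} Å,
pitch 300 Å, interface angle 20° entering as the minor-helix phase of
every chain. A parallel trimer is re-sorted to a single up-down-up
chain by reversing the residue order of chain 2 (coordinates
untouched), and the CW/CCW enantiomer pair is produced by mirroring
(x → −x). Chirality is classified from the signed area of the
projected helix-centroid triangle viewed from the N-terminal end of
helix 1; the absolute CW/CCW naming is a convention, fixed once, and
every measurement only relies on mirroring flipping it.

Measurements close the loop on the generator: the minor helix is
averaged out with a boxcar spanning exactly one minor period
(fractional end weights), leaving samples of the superhelical axis
curve; the mean perpendicular distance of those samples from the
fitted bundle axis recovers R to well within 0.1 Å on 20-residue
helices, and a cylinder-fit refinement of the axis direction followed
by a linear fit of axial travel against unwrapped phase recovers P to
within a few Å on a 200-residue generation (tolerance 15 Å). The
cylinder refinement matters: a plain principal-component axis is
tilted by a few degrees on a one-turn arc, which biases the fitted
pitch by ~20%.

## TM-score and register freedom

The folded criterion is the standard TM-score,
TM = (1/L_ref) Σ 1/(1 + (d_i/d0)²) with
d0 = max(0.5, 1.24·(L_ref − 15)^⅓ − 1.8), maximized over rigid
superpositions by a deterministic seed-fragment extension: seed
windows of lengths {L, L/2, L/4, L/8} at stride 3, iterative
re-selection of pairs within a cutoff (d0, d0 + 1.5, d0 + 3 Å;
escalated when fewer than 4 pairs qualify), best score kept. The tests
check it against an exhaustive rigid-body oracle (rotation-grid
multi-start refinement of the same objective) on pairs up to 40
residues, to 0.01. The oracle comparison is confined to structurally
related pairs: for unrelated structures with d0 at its 0.5 Å floor the
mathematical optimum of the TM objective degenerates to a 2-atom
coincidence that no fragment-extension heuristic (including the
published one) represents, and that regime carries no information
here.

Because the structures compared are equal-topology by construction,
no alignment search is needed — with one exception. A fixed
residue-to-residue correspondence cannot absorb *helical register*:
offsetting a helix by one residue rotates its Cα spiral by ~100°,
which a sequence-independent structure alignment would absorb and a
fixed map turns into ~2–4 Å of systematic distance. The scan therefore
scores through `tm_score_registered()`, which maximizes the TM-score
over integer per-helix register shifts (±3) of the correspondence,
pre-screening shift combinations by rigid-fit RMSD and fully scoring
the best few. Loop residues are excluded from the correspondence
throughout: the references have no loops.

## Blueprint building and the loop torsion tables

A blueprint assigns each residue H or L plus an ABEGO letter. Helix
positions receive the ideal helix dihedrals; loop positions receive
torsions from a shipped table. Two levels are shipped:

* **Per-motif conformers** for GB, GBB, BAAB and BAB, one per
  handedness. Each was fixed once, at design time, by sampling inside
  the motif's ABEGO bins under hairpin constraints (θ_HH below the
  cut, unambiguous φ_HH sign, no Cα clash). A single per-letter table
  cannot do this job: a joint random search over letter values found
  no combination that realizes GB → L, GBB → R and BAAB → L
  simultaneously with usable margins, which reflects the real
  stereochemistry — the same letter takes different torsions in
  different motifs. The GB majority (L) conformer was additionally
  chosen, by constrained optimization inside its bins, to make the
  two-hairpin bundle geometry as consistent as possible with the ideal
  reference decoys for *both* chiralities across the H scan; this is
  what lets the foldability scan express the helix-periodicity signal
  rather than builder idiosyncrasy. BAB deliberately ships both an L
  and an R conformer of comparable quality — that two-sidedness *is*
  the motif's documented ambiguity.
* **Per-letter fallback** at bin centres, for loop strings with no
  motif entry.

Sampled mode adds Gaussian torsion noise and redraws until every
residue still classifies to its blueprint letter, so blueprints are
honoured by construction at any noise level. Representative mode is
fully deterministic.

Sterics are handled by a Cα proxy: a conformation clashes when any
pair with |i − j| ≥ 3 lies closer than 3.5 Å. There is no energy
model and no minimization; this is a deliberate simplification that
keeps the scan a pure statement about backbone geometry.

## The second-helix scan

For each H in 5..20 a helix(14)–loop–helix(H)–loop–helix(14) blueprint
is built and scored against CW and CCW references with matching helix
lengths (the CCW reference is the exact mirror of the CW one, so
mirrored builds swap the two columns bitwise — a suite invariant).
Fractions use the strict TM > 0.55 rule with all attempted
trajectories in the denominator, including clashed ones.

The scan's reference radius variant defaults to ×0.75 (6.75 Å): of the
standard variant series, it is the scale closest to the inter-helix
packing distances the torsion-space builder actually produces
(≈9–12 Å between axes; the ×1.00 scale implies 15.6 Å axis separation,
which no 2-residue loop can span). The generator-closure measurements
are independent of this choice and are made at ×1.00 and ×0.75 as
printed.

What the defaults produce (recomputed by the acceptance suite, not
asserted here): all-clash rows recur every 3–4 residues of H — the
α-helix period — and the significant best-TM peaks of the CW and CCW
columns interleave, with at least one folded combination crossing
TM = 0.55. Mixed GB+GBB blueprints, whose two hairpins prefer opposite
handedness, stay below 0.55 for every H. Quantitative folded-fraction
magnitudes from large fragment-assembly campaigns are *not*
reproduction targets of this package: a single representative
conformer per loop cannot emulate an ensemble of picked fragments, and
the bar heights depend on that ensemble.

## The synthetic generator

`generate_fragment_dataset()` emulates the statistical structure the
motif analysis assumes about natural helix-loop-helix fragments: a few
dominant short loop types, each with strongly biased handedness, plus
one ambiguous motif. The default engineered spec ships GB (10:1 L),
BAB (1.2:1), GBB (8:1 R) and BAAB (7:1 L) at 100 fragments each with
σ = 5° loop noise — sizes chosen so the ratio-5 selection rule is
exercised with comfortable margins in under a minute of CPU.
Minority-handedness fragments are built from the opposite-handedness
conformer of the *same* ABEGO string, with rejection sampling on both
the letters and the φ_HH sign, so every truth label is exact and the
engineered ratios are realized to the fragment. (Mirroring, the
obvious alternative, flips the sign of every torsion and therefore
changes the loop's ABEGO letters — a mirrored GB loop reads as
starting with A and would be pruned — so it cannot populate the same
motif class.)

What the generator does *not* emulate: amino-acid sequences and their
redundancy structure, helix length and loop length distributions of
real domains, bent or irregular helices, and fragments whose loops
contain cis peptides. Passing the recovery tests therefore shows the
pipeline's logic is sound, not that its thresholds are optimal for
real structural databases.

## Numerical conventions and degenerate inputs

* Angles live in (−180°, 180°]; torsions follow the IUPAC sign
  convention (cross-checked against bio3d on built chains).
* Strict inequalities everywhere a threshold is quoted: θ_HH < 60°,
  TM > 0.55, ratio > 5.0.
* A handedness ratio with a zero denominator is +∞ and passes any
  ratio cut: a motif of exclusively one handedness is maximally
  biased.
* The median of φ_HH within a motif class is the ordinary median on
  (−180, 180] without circular wrapping; selected motifs are unimodal
  and far from the branch cut, and bimodal classes are excluded by the
  ratio rule. Representative selection breaks ties by lowest fragment
  id.
* Collinear atoms make a torsion undefined (error, not NA); fragments
  with missing backbone atoms are rejected with a diagnostic; an
  empty input to the pipeline yields empty tables, not an error.
* All randomness flows through R's session RNG; fixed seeds give
  bit-identical datasets, builds and output files.

## Problem sizes

The shipped tests and the acceptance script run at desk scale:
20-residue helices for radius closures, one 200-residue chain for the
pitch fit, 100 fragments per motif for recovery, single-trajectory
representative-mode scans over H = 5..20, and TM oracle pairs of at
most 40 residues. These sizes were chosen so the full suite completes
in a few minutes while every statistical margin tested (ratio rule,
recovery rate, peak structure) remains far from its threshold.

## Known limitations

* One conformer per (motif, handedness) — loop flexibility within a
  bin is represented only by Gaussian jitter, not by the true density.
* No energetics: clash filtering plus ideal torsions stand in for a
  force field; folded fractions are geometric statements.
* The fallback secondary-structure assignment (runs of ≥5 'A') detects
  helices only; strand-containing chains need an external DSSP track.
* `measure_pitch()` needs ≥150 residues (a substantial fraction of a
  superhelical turn); shorter traces are refused rather than
  extrapolated.
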