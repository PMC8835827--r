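---
title: "Methods: trajectory post-analysis of a multidomain kinase"
author: "kitdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory post-analysis of a multidomain kinase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The cytoplasmic region of the receptor tyrosine kinase KIT couples a rigid,
bilobed tyrosine-kinase (TK) core to several intrinsically disordered or
multi-state appendages: the transmembrane (TM) helix, the juxtamembrane
region (JMR, with functional sub-segments JM-P/JM-B/JM-S/JM-Z), the kinase
insert domain (KID) that interrupts the TK domain between its N- and
C-lobes, the activation loop, and the phosphorylatable C-terminal tail.
Characterizing that disorder from molecular-dynamics trajectories requires
a battery of ensemble analyses rather than any single observable.  `kitdyn`
implements that battery end to end: superposition-normalized deviation
metrics, inter-domain centroid geometry, secondary-structure time maps,
interaction networks, ensemble clustering, coupled-motion analysis and
free-energy landscapes, plus a synthetic-trajectory generator that provides
planted ground truth for every stage.

## Normalization

Every analysis begins by least-squares fitting each conformation onto a
reference (the initial model) over a declared fit selection.  We use the
Kabsch algorithm: SVD of the coordinate cross-covariance with a determinant
correction so a reflection is never applied.  Fewer than three fit atoms,
or collinear fit atoms, leave the rotation under-determined and raise an
error rather than returning an arbitrary frame.  The default fit selection
is the Cα of the rigid TK core, residues 582–688 plus 769–931 — the TK
domain minus the flexible KID — so that domain-level analyses measure
internal motion relative to a stationary core.  The KID residue range
(689–768) is defined as the complement of that fit selection inside the TK
domain (582–931); explicit KID boundaries are rarely printed and this
definition is self-consistent with the fit.

## Deviation metrics

RMSD series, per-atom RMSF (deviation from each atom's time-mean position
after per-frame fitting) and the mass-weighted radius of gyration follow
their textbook definitions; masses come from a bundled standard atomic
weight table keyed by element.  Rg is computed over a configurable
selection (all atoms by default); whether heavy atoms only or all atoms
enter Rg is exposed as a choice (`selection(elements = ...)`) because
conventions differ between analysis packages and the difference is well
below the effects studied here.

## Inter-domain geometry

Domain positions are summarized by centroids (mass-weighted by default) and
the six pairwise distances of a labelled four-node tetrahedron.  Segment
("hint") vectors — representative axes of structurally stable elements such
as the TM helix (P524–C537), β1 (T594–A597), αC (L637–G648), αH1
(A701–N705), αE (S771–L783) and β9 (V824–K826) — are computed as the first
principal axis of the segment's Cα coordinates, sign-fixed to point from
the N-terminal toward the C-terminal half.  A principal-axis fit was chosen
over endpoint differences because it is insensitive to terminal fraying;
for an ideal helix it reproduces the cylinder axis to well under 5 degrees.

Bending angles between two hint vectors use
`Θ = arccos(v₁·v₂/(‖v₁‖‖v₂‖))`, reported in degrees.  The TM kink angle at
the V530 hinge is the angle between the two half-helix principal axes, each
anchored at the hinge Cα and oriented *away* from it.  Under this
convention a perfectly straight helix scores 180° and a right-angle kink
90°; the alternative convention (both vectors N→C, straight = 0°) is
equally defensible from the verbal definition, so the choice is documented
here and fixed.

## Secondary structure

The per-frame assignment implements the Kabsch–Sander rules directly: a
backbone H-bond exists when the electrostatic energy
`E = 0.084·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)·332 kcal/mol` is below
−0.5 kcal/mol; two consecutive n-turns make a helix (G/H/I for n = 3/4/5),
bridge patterns make parallel/antiparallel bridges and ladders (B/E),
remaining turn residues are T, Cα bends above 70° are S, and overlaps are
resolved in the order H, B, E, G, I, T, S.  Amide hydrogens are
reconstructed geometrically (bisector of C(i−1)–N and Cα–N at 1.01 Å) when
absent, so heavy-atom-only trajectories are assignable; prolines and chain
N-termini never donate.  Residues missing a backbone heavy atom are
labelled coil with a warning.  π-helices are folded into H at the reporting
layer; the parallel/antiparallel strand distinction is kept internally.
β-bulge linking of ladders is not implemented; on the idealized and
moderately noisy structures used for validation this does not register, and
whole-chain agreement with an independent reference implementation (mdtraj's
DSSP, used only as a test oracle) is 100% on ideal helices/sheets and ≈96%
on noisy 431-residue frames.

## Interaction networks

H-bonds are detected geometrically: donors and acceptors are N/O/S,
d(D–A) ≤ 3.6 Å and D–H···A ≥ 120°, with every (D,H,A) triple reported so
bifurcated bonds count as separate events; intra-residue pairs are
excluded.  Hydrophobic contacts pair residues from
{Ala, Val, Leu, Ile, Pro, Phe, Met, Trp} whose side-chain heavy atoms
approach within 4 Å.  Candidate pairs are pruned with a uniform spatial
grid (cell = cutoff) whose result is required — and tested — to equal an
exhaustive all-pairs scan exactly.

Occurrence patterns count, per residue pair, the fraction of sampled frames
with at least one event.  The inter-domain pattern is obtained by
exclusion: backbone–backbone bonds between residues co-assigned (by modal
label over the sampled frames) to the same helix at sequence separation
≤ 5, or both assigned to strand, are removed, as are backbone–backbone
pairs wholly inside one named domain.  Side-chain-mediated bonds always
survive, which is what preserves the biologically interesting contacts of
type "JMR tyrosine side chain to αC-helix glutamate".  The published
procedure describes this exclusion qualitatively; the same-helix /
same-ladder / same-domain backbone rule is this package's concrete
interpretation and is deliberately conservative.  Bonds involving a
chain-terminal residue are flagged as potential construct-terminus
artefacts but never removed.

## Ensemble clustering

The reference-picking algorithm: draw a random frame from the remaining
ensemble as a reference, discard everything within RMSD r of it, repeat
until the ensemble is exhausted (references end up pairwise > r apart),
then assign every frame to its nearest reference, ties to the lowest
reference index.  The random draw makes a seed part of the method's
signature, so the seed is an explicit argument and is recorded in all
outputs.  Two RMSD modes are exposed: "context" (frames fitted once to the
initial conformation on a global selection, so a fragment keeps its
position in the whole protein) and "intrinsic" (fitted on the fragment
itself).  The cutoff sweep covers 2.0–5.0 Å in 0.5 Å steps by default (a
narrower 3–5 Å sweep is a supported subset) and reports, per cutoff, the
cluster count and the cumulative population of clusters holding ≥ 1% of
frames — the aid for choosing a cutoff whose major clusters cover > 95% of
the ensemble.  "Major cluster" is not formally defined in the source
procedure; the ≥ 1% rule is our documented resolution.

## Coupled motions

The dynamical cross-correlation map is the normalized displacement
covariance `C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)` over Cα, computed
from raw (unfiltered) deviations from time means; atoms with zero variance
get correlation 0 and an explicit flag.  PCA diagonalizes the backbone
coordinate covariance after fitting on the average conformation (mean of a
first-pass fit, then refit); with more coordinates than frames the
spectrum truncates at n−1 modes, and full-mode reconstruction reproduces
the fitted coordinates exactly, which is asserted in the tests.

Elastic-network modes are built on Cα with two parameterized Hookean
rules: a cutoff network (uniform k within 13 Å — a standard
anisotropic-network choice) and an inverse-square distance weighting.
Consecutive beads are additionally treated as covalently chained
(`chain_springs`), the usual Cα force-field convention; this also keeps
networks with sparse regions connected.  These rules are this package's
elastic-network force fields; they are deliberately simple, and acceptance
of this component is structural — symmetry, exactly six near-zero modes for
a connected (non-collinear) network, equality with an independent
finite-difference Hessian and with a covariance computed by a projection +
solve route — not numerical identity with any third-party parameterization.
A collinear network (e.g. two beads) has five rigid-body modes, the one
physically meaningful special case.

## Free-energy landscapes

`ΔG(R1,R2) = −k_B T ln(P(R1,R2)/Pmax)` with `k_B = 0.0019872 kcal/(mol·K)`
and T = 310 K by default (the simulation temperature).  P is the raw joint
histogram — no smoothing by default, matching the plain Boltzmann-inversion
definition; a Gaussian-kernel option exists but is labelled an extension.
The default grid is 100×100 bins (the source procedure does not state a
bin count; 100 bins resolves the planted well separations used in testing
by an order of magnitude).  The most-populated bin sits at exactly ΔG = 0
and empty bins carry +∞.  Wells are user-declared rectangles, mirroring the
manual square-around-the-minimum procedure; their population is the
fraction of frames falling inside (not a bin integral, so partition
populations sum to exactly 1).  An automatic flood-fill well finder is
provided for convenience and labelled as such.  Basin free-energy
differences are computed from basin populations,
`ΔΔG = −k_B T ln(p₁/p₂)`; the difference of single-bin minima estimates the
same quantity but inherits the upward noise of a per-bin extreme statistic,
which is why populations are the primary route.

Per-domain landscapes treat each domain as a dependent part of the whole:
frames are fitted once on the global TK-core selection, then the domain's
Cα RMSD (to frame 1) and Rg serve as reaction coordinates.

## The synthetic generator

No trajectory of the real system is archived, so the test surface is a
generator that emulates the features the pipeline must detect, with the
ground truth emitted alongside:

- a chain of named segments built from canonical backbone torsions
  (α: φ=−57°, ψ=−47°; 3₁₀: −49°, −26°; β: −119°, 113°; coil: randomized)
  with ideal bond geometry (N–Cα 1.458, Cα–C 1.525, C–N 1.329 Å) and a
  pseudo-side-chain CB per residue;
- appendage segments hopping between discrete rigid anchor poses under a
  dwell process with geometric segment lengths whose per-state frame
  quotas equal the declared occupancy weights exactly (up to rounding) —
  the declared weights *are* the ground truth each analysis is scored
  against, so the generator realizes them rather than sampling them;
- helix/coil folding schedules per segment; planted H-bonds realized by
  placing the acceptor carbonyl oxygen collinear with the donor N–H at
  2.9 Å in exactly the scheduled fraction of frames;
- harmonic positional jitter (0.05–0.3 Å sd) standing in for thermal
  fluctuation.

The canonical benchmark plants two mirror-symmetric appendage poses
(±25° about the same axis) so the two metastable states are geometrically
equivalent and differ only in occupancy — the cleanest possible test of
occupancy recovery.  The KIT-like fixture spans I516–R946 (431 residues,
reduced backbone, 2,000 frames of 10 ps): rigid TM + TK segments, coil
JMR/C-tail, a two-state KID (70/30) and a two-anchor C-tail (60/40).

What the generator does **not** emulate: force-field energetics, solvent,
realistic kinetics and barrier heights, side-chain rotamers, or compact
tertiary packing (segments sprawl; block-rotation states break covalent
continuity at appendage junctions, which is why chain springs exist in the
ENM).  Passing tests therefore demonstrate that the analysis machinery
recovers planted signals of realistic magnitude from realistic noise — not
that it reproduces any published trajectory-derived number, which would
require the unarchived 2-µs ensembles.

## Numerical choices and degenerate inputs

- Superposition refuses < 3 or collinear fit atoms; clustering refuses
  non-positive cutoffs; Rg refuses empty selections and non-positive
  masses; a constant reaction coordinate is an error with guidance rather
  than a single-bin landscape.
- Assignment ties in clustering go to the lowest reference index; PCA and
  ENM mode signs are fixed (first nonzero component positive) so runs are
  comparable.
- The DCD writer emits single-precision CHARMM format (≈10⁻⁵ Å round-trip
  error, far below thermal jitter); PDB coordinates carry three decimals.
- Analysis strides are expressed in frames; with the 10 ps frame spacing
  used throughout, the defaults correspond to analyzing every 10 ps and
  clustering every 100 ps.

## Problem sizes used in the test-suite

Oracle-equivalence checks run on ≥100 random instances of up to 300 atoms;
parameter-recovery benchmarks use 10,000 frames (landscapes), 100×300
frames (clustering across seeds) and 2,000 frames (planted H-bond and the
KIT-like fixture).  These sizes were chosen so the full battery runs on a
single CPU in minutes while keeping counting error well inside the
recovery tolerances (±0.02 for occupancies at n = 10,000).

## Known limitations

- The secondary-structure module omits β-bulges and DSSP's
  solvent-accessibility output.
- The exclusion rule for "intra-domain framework" H-bonds is an
  interpretation of a qualitative procedure; alternative readings (e.g.
  whole-sheet exclusion) would remove slightly different sets.
- Elastic-network force constants are not calibrated to any all-atom
  force field; spectra are meaningful up to an overall scale.
- The pivot-cone (apex-angle) analysis of TM-helix precession is out of
  scope: it is a qualitative result requiring the real membrane system.
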