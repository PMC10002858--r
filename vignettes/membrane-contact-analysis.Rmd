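---
title: "Methods: protein-lipid contacts and membrane topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein-lipid contacts and membrane topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membcontacts)
```

This vignette is the package's own account of the methods it implements:
the definitions, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## The analysis model

The object of study is a peripheral membrane-binding domain (the motivating
system is a C1b-type zinc-finger domain of PKC-δ with a bound activating
ligand) inserted into one leaflet of a heterogeneous bilayer, observed as a
coordinate trajectory. All analyses reduce to a small set of primitives:

**Distances.** All inter-atomic distances are minimum-image distances in an
orthorhombic box: each displacement component is reduced by
`d - L*round(d/L)`. Triclinic boxes are out of scope and rejected by
validation. Whether published distance-based analyses of this kind wrapped
periodic images is rarely stated; we wrap by default and expose
`periodic = FALSE` for comparison. For points inside the box the wrapped
distance equals the minimum over the 27 neighbouring images, which is the
oracle the test suite checks against.

**Contacts and occupancy.** A probe group (e.g. the side-chain amine
nitrogen of a lysine) is *bound* to a lipid molecule in a frame when the
minimum distance between the probe's tracked atoms and the lipid's tracked
atoms is `<= cutoff`. The cutoff defaults to 6 Å — the conventional
ionic-interaction distance for headgroup contacts — and the boundary is
inclusive. Where a residue's tracked set is ambiguous in chemical language
("side-chain oxygen *or* amide nitrogen" of a serine), we track the set and
take the minimum distance; this resolves the ambiguity conservatively and
is configurable in the selection file. Class-level occupancy uses union
semantics — any molecule of the class counts — because residue-by-class
occupancy is the quantity reported in this literature; per-molecule tables
are emitted alongside.

**Lifetimes.** Bound segments are maximal runs of bound frames; a segment's
duration is its frame count times the frame spacing `dt`. An unbound gap of
at most `gap_tolerance_frames` flanked by bound frames can be bridged into
one segment. The default is 0 (no bridging): bridging interacts with the
analysis stride, so it is a deliberate user decision. With a coarse stride,
brief unbinding events vanish below the frame spacing and lifetimes
lengthen; users comparing lifetime distributions across trajectories should
fix the stride first. The transient/stable rule — transient iff the longest
continuous segment is < 10 ns *or* total bound time is < 50 ns — is the
field's operational definition and both thresholds are arguments of
`classify_interaction()`.

**Insertion depth.** Depth is the signed z-displacement of a reference atom
(default: Cα of the binding-loop glycine, residue 253) from the mean z of
the PS phosphate atoms of the protein-containing leaflet, positive toward
the membrane midplane. Two interpretation choices are deliberate:

* only the protein-containing (lower) leaflet's PS phosphates define the
  plane — depth against the opposite leaflet would be meaningless;
* the sign convention is anchored on the midplane, computed as the mean z
  of all lipid headgroup atoms, so depth is invariant to global
  translation and to which leaflet the protein occupies.

Depth values are emitted signed (an atom outside the phosphate plane is
negative), not as magnitudes.

**Tilt.** The protein long axis runs from the centroid of the bottom-third
marker residues' Cα atoms (233, 246, 263, 276) to the centroid of the
upper-third markers (239, 241, 253, 255). Tilt is the angle between this
axis and the membrane normal (z), folded to [0°, 90°]: 0° is upright. A
literal reading of "angle with a line perpendicular to the membrane normal"
would give the complementary angle, but the accompanying usage (larger
angle described as more tilted, deeper-inserted complexes reported near 48°
versus 38° for shallower ones) is only consistent with the
normal-referenced convention; `convention = "in_plane"` emits the
complement for anyone wanting the literal reading.

**Leaflets.** A lipid belongs to the lower leaflet iff the mean z of its
headgroup atoms is below the midplane. Assignment is recomputed every frame
rather than cached, so lipid flips are tracked correctly (and the synthetic
flip tests stay honest).

**Superposition RMSD.** The QC RMSD trace uses the Kabsch algorithm (SVD of
the covariance matrix with reflection correction, proper rotation enforced)
on Cα atoms by default, matching standard backbone usage; the atom subset
is configurable. Degenerate (collinear) point sets are rejected: the
optimal rotation is not unique there. The determinant sign is corrected via
the smallest singular vector, and the test suite cross-checks the result
against a direct numeric minimization over rotations to 1e-6 Å.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `cutoff` | 6 | Å | conventional ionic/hydrogen-bond contact distance for headgroup engagement |
| `gap_tolerance_frames` | 0 | frames | no bridging unless the user opts in; stride-dependent |
| `continuous_min_ns`, `total_min_ns` | 10, 50 | ns | the transient/stable rule |
| depth/tilt histogram bins | 0.5 Å × 2° | | unstated in the source literature; fine enough to resolve the reported 3 Å / 10° contrasts |
| heatmap `bin_width` | 1 | Å | sub-lipid-diameter lateral resolution |
| `qc_window_ns`, `qc_tolerance` | 100, 0.01 | ns, Å/ns | a drift that accumulates ≥ 1 Å over the trailing 100 ns window is flagged |
| `stride` | 1 | frames | lifetime estimates are stride-sensitive; see above |

## The synthetic generator

`simulate_trajectory()` emulates exactly the statistical structure the
analyses consume, nothing more:

* **Bilayer**: one headgroup pseudo-atom per lipid, on two planes at
  ±20 Å (half-thickness default, consistent with the ~8 Å depth scale of
  the real system), per-leaflet class counts from a
  `membrane_composition` (defaults to the published 66/59-lipid
  phorbol-system table), lateral Gaussian random walk (default 1 Å/frame)
  with periodic wrap, per-frame z jitter (0.3 Å).
* **Protein**: a rigid pseudo-Cα scaffold of residues 231–280 carrying
  probe pseudo-atoms named so the shipped selections resolve. The
  upper/lower marker quartets have their centroids exactly on the body
  axis, so the planted tilt is recovered exactly by the centroid
  construction; the depth reference Cα is placed exactly at the planted
  depth each frame. Planted defaults 8 ± 1 Å and 48° ± 5° follow the
  deeper-inserted complex of the motivating study.
* **Contacts**: each plan entry drives a two-state Markov chain with
  q_off = dt/τ and q_on = q_off·p/(1−p), whose stationary occupancy is
  exactly p and whose bound-run lengths are geometric with mean dt/q_off
  = τ exactly — the discrete-time analogue of exponential lifetimes, and
  the value the recovery tests compare against (avoiding discretization
  bias). On bound frames the designated lipid sits uniformly in a
  2–5.5 Å shell of its probe (within the centroid of several probes for
  a bridged multivalent entry); on unbound frames it is kept ≥ 8 Å from
  every probe atom. The analyzed bound series therefore reproduces the
  chain exactly, which the tests assert frame-for-frame.
* `mean_lifetime_ns = Inf` gives the absorbing always-bound limit.

What it does **not** emulate — and hence what passing tests do and do not
show about real data: no excluded volume (free lipids may wander through
the protein footprint, adding incidental contacts on top of planted ones),
no acyl chains or membrane elasticity, no protein internal dynamics (the
QC RMSD of a synthetic run is identically zero), no curvature or
undulation, and no force field of any kind. Estimator-recovery results
validate the *analysis code* under known kinetics; they say nothing about
the convergence of 500 ns all-atom simulations, whose per-replicate
occupancies scatter widely (as the real study's error bars show).

One interaction worth knowing: a planted PS contact pulls that PS lipid
out of its leaflet plane, which shifts the PS phosphate plane used by the
depth estimator by a few tenths of an Å (7 PS lipids in the lower leaflet
of the default composition). Depth-recovery checks therefore run without a
contact plan; with one, the small shallow bias is real, not a bug.

## Numerical choices and degenerate inputs

* Largest-remainder allocation turns target class fractions into integer
  per-leaflet counts that sum exactly to the leaflet totals; ties break
  deterministically by class order. Allocating the published percentage
  targets onto the published leaflet totals reproduces the published
  counts exactly — with one caveat: the upper-leaflet PC entry of the
  second (bryostatin-system) table prints 20% where the count, 15 of 73,
  is 20.55% and rounds to 21. Every other of the 28 table cells matches
  nearest-integer rounding; we report the arithmetic value and document
  the discrepancy rather than resolving it. Relatedly, the overall
  "25% cholesterol" description circulating for this composition does not
  match the per-leaflet tables (21–24%); the tables are authoritative
  here.
* Histogram values outside the bin range are clamped into the edge bins
  (with a message), never silently dropped, so count conservation holds.
* Heatmap positions are wrapped into the primary box image before
  binning; with recentering enabled, positions are taken relative to the
  protein's lateral centroid and wrapped into a centred box, which makes
  the map invariant to lateral drift. Recentering is off by default (the
  lab frame is what published maps show).
* Empty selections, missing residues, atom-count mismatches between a
  frame file and its system, non-monotonic frame times, non-positive
  boxes, and infeasible generator plans (p outside (0,1), τ ≤ dt, a box
  too small to hold the composition at ≥ 5 Å spacing) all fail loudly
  with the offending group/frame/row named.
* The GRO reader interprets a bare `t=` value as picoseconds (the format's
  convention) and an explicit `ns` suffix as nanoseconds; coordinates are
  converted nm → Å on read. PDB is the canonical fixture format; its
  1e-3 Å coordinate precision bounds round-trip accuracy.

## Problem sizes used in the tests

The estimator-recovery suites run at desk scale, chosen to put three
standard errors well inside the effect sizes of interest: occupancy
recovery uses 5 replicates × 5000 frames (0.1 ns spacing) per planted p,
with the standard error computed from the chain's effective sample size
n_eff = n·(1−ρ)/(1+ρ), ρ = 1 − q_on − q_off; lifetime recovery uses
15 × 2500 ns replicates of a lean 32-lipid bilayer (lifetime statistics do
not depend on bilayer size) so that ~180 completed segments keep the
sample-mean comparison well-behaved against the exact discrete-chain mean;
depth/tilt recovery pools 5 × 500 frames. The acceptance script
(`scripts/acceptance.R`) reports the same quantities with 15 occupancy
replicates per p for a tighter pooled estimate.

## Known limitations

* Orthorhombic boxes only; no triclinic support.
* No neighbour-list optimization: distance evaluation is exact and
  exhaustive over tracked atom pairs, which is the right trade-off for
  probe-set analyses (tens of atoms), not for all-atom contact maps.
* No angle-based hydrogen-bond criterion: the contact definition is
  distance-only, so "hydrogen bonding" in the chemical sense is inferred,
  not verified, and no attempt is made to distinguish interaction
  chemistry within the 6 Å criterion.
* Compressed trajectory formats (XTC/DCD) are not read natively; convert
  to multi-model PDB or concatenated GRO, or plug a reader producing an
  `md_trajectory`.
* The lateral heatmap reports raw counts (or frequencies); smoothing is
  left to plotting.
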