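# membcontacts

Protein–lipid contact and membrane-topology analysis for molecular dynamics
trajectories of peripheral membrane proteins in heterogeneous bilayers.

The package is written for the common situation in membrane biophysics where
a small membrane-binding module — the motivating system is a PKC-δ C1b-type
zinc-finger domain bound to an activating ligand and embedded in a
plasma-membrane mimic of seven lipid classes (CHOL, PC, PE, PS, PA, PIP,
CER) — is simulated for hundreds of nanoseconds and one needs to quantify,
reproducibly, *which residues engage which lipids, for how long, and at what
membrane depth and orientation*.

## What it computes

For tracked atom groups (e.g. lysine side-chain NZ, the L250 backbone amide
N, the cholesterol hydroxyl O3, lipid phosphate oxygens), all under periodic
minimum-image distances in an orthorhombic box:

* **Occupancy** — a probe group is *occupied* by a lipid class in a frame
  when any molecule of that class has min-distance ≤ the cutoff (default
  6 Å, inclusive). Occupancy fraction = occupied frames / total frames.
* **Interaction lifetimes** — durations of maximal runs of bound frames per
  (probe, lipid molecule) pair, with optional bridging of short unbound
  gaps. An interaction is *transient* if its longest continuous segment is
  < 10 ns **or** its total bound time is < 50 ns, otherwise *stable*
  (thresholds configurable).
* **Multivalency** — per frame, how many probes engage one lipid molecule
  and how many lipid molecules engage one probe.
* **Insertion depth** — signed z-displacement of a reference atom (Cα of
  the binding-loop glycine G253 by default) from the mean plane of the
  protein-leaflet PS phosphates; positive = toward the membrane midplane.
* **Tilt angle** — angle between the membrane normal and the protein long
  axis (centroid of upper-third marker Cα atoms minus centroid of
  bottom-third markers), folded to [0°, 90°]; 0° = upright.
* **Topology histograms** — pooled 2D depth × tilt histograms across
  replicate simulations.
* **Lateral heatmaps** — per-leaflet (x, y) localization counts of tracked
  lipid atoms, with mean protein Cα positions as overlay points.
* **Equilibration QC** — area per lipid (lateral box area / leaflet lipid
  count), Kabsch-superposition RMSD versus time, and a linear-drift
  stability check on any QC series.

A **synthetic trajectory generator** (`simulate_trajectory()`) builds a
two-leaflet bilayer with a chosen composition (the two published
plasma-membrane-mimic tables ship as `reference_composition()`), lateral
lipid diffusion, a rigid pseudo-Cα protein scaffold at a planted insertion
depth/tilt, and planted two-state Markov binding episodes with prescribed
stationary occupancy p and mean lifetime τ (per-frame switch probabilities
q_off = dt/τ, q_on = q_off·p/(1−p)). Every analysis stage is therefore
testable against known ground truth.

## Worked example

Simulate 500 ns (1000 frames) with a planted K271–PS contact
(p = 0.6, τ = 50 ns) and analyze it:

```r
library(membcontacts)

p <- synthetic_params(
  n_frames = 1000, dt = 0.5, seed = 42,
  contact_plan = data.frame(groups = "K271_NZ", lipid_class = "PS",
                            occupancy = 0.6, mean_lifetime_ns = 50))
sim  <- simulate_trajectory(p)
traj <- sim$trajectory

sel <- read_selection_spec(default_selection_path("synthetic"))
rec <- contact_records(traj, sel, cutoff = 6, lipid_classes = "PS")
subset(occupancy(rec), occupancy_fraction > 0)
#>   protein_group lipid_class occupancy_fraction n_frames replicate_id
#> 1       K256_NZ          PS              0.741     1000            1
#> 3       K271_NZ          PS              0.917     1000            1
#> 4       K275_NZ          PS              0.760     1000            1
#> ...
```

K271 is occupied 92% of the time: the planted episode (realized chain
occupancy 0.89 for this seed — a 500 ns run of a τ = 50 ns chain has few
independent episodes, so the realized fraction scatters widely around 0.6)
plus incidental approaches of free PS lipids. Neighbouring probes (K256,
K275) also read high because the planted lipid parks within the cutoff of
several clustered lysines at once — the multivalent engagement that
`multivalency()` quantifies. The longest bound segments:

```r
lt <- lifetime_table(rec)
head(lt[order(-lt$duration_ns), ], 3)
#>  protein_group lipid_class duration_ns total_bound_ns max_continuous_ns classification
#>        K271_NZ          PS       370.5            445             370.5          stable
#>        K271_NZ          PS        47.0            445             370.5          stable
#>        K271_NZ          PS        27.5            445             370.5          stable
```

Membrane topology:

```r
res <- resolve_selection(traj$system, sel)
dep <- insertion_depth(traj, res$G253_CA, res$PS, res$headgroups)
til <- tilt_angle(traj)
topology_histogram(dep$depth, til$tilt)
#> <topology_histogram> 1000 frames pooled; mean depth 7.505 A, mean tilt 48.03 deg
```

The planted depth is 8 Å; the estimate reads slightly shallow here because
the PS phosphate plane includes the bound PS lipid that the contact plan
pulls up toward the protein.

The whole pipeline (occupancy/lifetime/multivalency CSVs, depth/tilt series,
topology histogram, per-class heatmaps, QC table, JSON manifest) runs from a
single config via `run_pipeline()`, or from a shell via
`inst/scripts/membcontacts-cli.R`.

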