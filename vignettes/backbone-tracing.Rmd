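---
title: "Tracing protein backbones and finding ligands in cryoEM density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing protein backbones and finding ligands in cryoEM density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captrace)
```

## The problem

A near-atomic resolution (~2-5 Å) cryoEM density map of a protein shows a
continuous tube of density following the backbone, but no annotated atoms.
De novo model building asks: given only the map, a density threshold at
which the chain connectivity is visible, and the expected number of
residues, where does the Cα chain run?

`captrace` treats this as a geometric optimization problem. The density
above threshold is reduced to exactly `nres` representative points
("pseudoatoms", one per expected residue), and the chain is the minimum-
length open path visiting every pseudoatom once — a traveling-salesperson
problem (TSP). Consecutive Cα atoms sit ~3.8 Å apart, so the shortest
Hamiltonian path through well-placed pseudoatoms is an excellent fold
hypothesis, without using sequence or template information at all. The
sequence enters only at the end, when it is threaded onto the finished path.

The same pseudoatom machinery, run on the density *left over* after masking
a finished protein model, locates waters, ions and ligands (see "Residual
density" below).

## Pipeline

1. **Filtration.** Optionally low-pass filter the map to 4.5 Å. The filter
   is a Fourier-space Gaussian with transfer `H(s) = exp(-(R*s)^2)`
   (`R` = resolution, `s` in 1/Å), i.e. a real-space kernel of sd
   `R/(pi*sqrt(2))` — the same width convention the simulator uses, so the
   attenuation of any planted sinusoid is analytic. Filtering matters
   beyond denoising: on a smooth density tube, k-means behaves like a
   uniform one-dimensional quantizer along the chain, which keeps the
   pseudoatoms in register with the residues.
2. **Seeding.** Above-threshold voxel centers, weighted by their density
   values, are clustered into exactly `nres` groups (`kmeans`, `sc`
   spectral, `ac` Ward, `ms` mean shift, or `gmm`); the pseudoatoms are
   density-weighted cluster centroids. k-means runs 20 restarts and keeps
   the lowest quantization objective — register errors (two centroids
   sharing a residue, none on its neighbor) are exactly the local optima
   that restarts remove. Mean shift and Ward need not produce the requested
   count naturally; the count is reconciled by 2-means splits of the
   heaviest clusters or merges of the closest pair, because the downstream
   TSP needs exactly `nres` nodes.
3. **Path identification.** Pairwise Euclidean distances (optionally
   stretched by `1 + 2*max(0, 1 - rho_min/tau)` where `rho_min` is the
   minimum density sampled every 0.5 Å along the segment — segments through
   empty map are penalized). `solve_cycle()` is exact (Held-Karp) up to 12
   nodes and a deterministic nearest-neighbor + 2-opt + Or-opt heuristic
   beyond, capped at `or_time` (default 30 s; small instances finish in
   milliseconds). The pipeline solves the *open-path* problem via a
   zero-weight dummy node (`solve_open()`). This deviates from cutting the
   heaviest edge of the plain cycle, deliberately: on any elongated chain
   the minimum cycle is a "ladder" (up one side, down the other on i±3
   rungs) that is shorter than chain-plus-closure, so no edge deletion can
   recover the fold, whereas the dummy node makes the open path itself the
   optimization target. `open_path()` still provides the cut-heaviest-edge
   conversion for cycles solved without a dummy.
4. **Refinement.** `refine_path()` alternates, over rounds with weights
   1, 2, 4 ("increasing physical constraints"), a relaxation of every
   pseudoatom — restoring 3.8 Å adjacent spacing, opening chain angles
   below ~85°, pushing apart non-consecutive clashes under 3.3 Å, and
   climbing the local density gradient — with a TSP re-solve. A new
   ordering is adopted only when clearly shorter (0.1% hysteresis), so
   hairline ties after strong relaxation do not churn a settled topology;
   a round that fails to improve the mean bond-length deviation is
   discarded and refinement stops, making the geometry contract monotone.
5. **Threading.** The 1-letter sequence maps 1:1 onto path positions.
   With `reverse`, both orientations are scored by the correlation between
   per-residue heavy-atom counts and the density mass within 3 Å of each
   node — big residues should sit in heavy density; ties go forward. The
   unpublished reference scoring is replaced by this explicit, documented
   one. `build_all_atom()` then places N, C, O (and Cβ for non-glycines)
   from Cα triplets with ideal bond lengths; chain breaks above 4.5 Å get
   no bridging atoms. No chemistry refinement is attempted — that belongs
   to external real-space refinement tools.

## Probabilistic models

Because one trace takes seconds, many can be afforded. `generate_decoys()`
re-seeds over a threshold bracket (default: the working threshold ±1 map
sigma, three values) and perturbs positions over a noise schedule (default:
20 values, 0-5 Å), one decoy path per (threshold, noise) pair — 60 decoys
by default, 100 with a 5-value bracket. All decoys share the map's frame,
so correspondence is a renumbering: each decoy is matched to the zero-noise,
central-threshold reference by the Hungarian assignment minimizing total
squared distance. Per-node averages form the average model; its path is
solved with the same TSP contract.

Each node then receives a connectivity probability: with `A(i)` the node's
unordered neighbor set in the average path and `B_d(i)` the corresponded
decoy neighbors, the per-decoy score is `|A n B| / max(|A|, |B|)` and the
probability is 100 times the decoy mean. The score is direction-agnostic
(both chain neighbors count, one of two matched = 0.5). The symmetric
normalization is a deliberate choice: normalizing by `|A(i)|` alone lets a
terminus (one neighbor) score full marks whenever its single neighbor
appears anywhere next to it, which *inflates* terminal confidence — the
opposite of what decoy ensembles actually show, namely that chain ends are
where connectivity wanders. Under the symmetric rule a terminus is fully
confident only in decoys that also end there, identical ensembles still
score 100 everywhere, and a node whose neighbors are entirely replaced in
half the decoys scores exactly 50. Probabilities are written to the PDB
B-factor column; the conventional coloring reads 100% blue, 75% white, and
50% or below red.

## Residual density: waters, ions, ligands

`run_pw_ligands()` masks the map within 2 Å of the protein model (the paper
leaves this radius unstated; 2 Å removes a bond-length shell while keeping
adjacent ligand density — the separate 5 Å `model_dist` is the outer
limit), then places one candidate point per remaining above-threshold voxel
— the candidate count is data-driven, never user-specified. Candidates are
filtered by distance to the model (≤ `model_dist`, default 5 Å) and, when
half-maps exist, by half-map consistency: voxels where the half-maps differ
by ≥ `half_thresh` (default 0.5) map sigmas are discarded as irreproducible
density. Survivors are clustered by weighted Gaussian mean shift with
bandwidth `bandwidth_weight * min(voxel)/10` Å (default weight 10 = one
voxel); modes whose member sets approach within one bandwidth are merged,
so a contiguous elongated ligand ridge becomes one cluster instead of a
string of fragments. Clusters are classified by size and shape: extent
≤ 2.5 Å (boundary inclusive) is a water/ion, anything larger a ligand. A
member-count cap exists as a sanity bound but defaults loose (60): with
per-voxel seeding the member count of a genuine water scales with voxel
volume, so extent is the scale-free criterion. Waters and ions are not
distinguished. The output is exactly two coordinate files and two masked
maps (ligand set, water set); `score_template_fit()` scores a posed
template by Pearson correlation between its simulated density and the map
within 3 Å of the template.

## The synthetic world

Every test runs on generated systems, never downloads. `make_ca_trace()`
produces Cα chains with exact 3.8 ± 0.01 Å spacing and ≥ 3.0 Å
self-avoidance: ideal helices (1.5 Å rise, 100° twist), extended strands,
a helix-turn-helix (two ~10 Å-separated antiparallel helical arms joined by
an arc, built by resampling a wobbled centerline at exact 3.8 Å chords),
and persistent self-avoiding random walks. `simulate_map()` places one
isotropic Gaussian per residue, sd `resolution/(pi*sqrt(2))`, optionally
weighted by residue heavy-atom counts when a sequence is given — simulating
the size contrast threading relies on. Half-maps add independent Gaussian
voxel noise. `plant_nonprotein()` adds an elongated 12-point ligand in the
3-5 Å surface band, isolated waters ≥ 2.5 Å from everything (but within
the model-distance filter's reach), and optionally an "inconsistent" blob:
full amplitude in half-map 1 only, half amplitude in the full map (so the
full map remains the half-map average), which the consistency filter must
reject.

What a green test establishes — and what it does not: the fixtures have
uniform, isotropic resolution, no B-factor falloff, no CTF artifacts, no
solvent noise floor, and side chains reduced to per-residue kernel weights.
Fold-recovery rates on these maps (≥ 90% of true adjacent pairs, 20-60
residues, pooled over seeds) show the geometry engine is sound, not that
real 4 Å maps with anisotropy and disorder will trace as cleanly. One known
hard case is deliberately documented rather than hidden: a long *isolated*
ideal helix invites cross-turn (i, i±3) shortcuts whenever seeding slips
register, the same local-connectivity swaps that dominate decoy
disagreement in practice; the compact helix-turn-helix fixtures used for
acceptance are the more protein-like world.

## Numerical choices

- Axis order is normalized on read (`MAPC/R/S` honored), world coordinates
  always in Å; voxel membership in every mask is decided by voxel-center
  distance; sigma always means the sd over all voxels of the full map.
- The "<50% voxel value difference" prose and the 0.5-sigma tabulated
  default are reconciled in favor of the sigma-unit definition.
- Positional noise is interpreted in Å (sd of displacement per axis); the
  source material says "sigma" without defining a length unit.
- Seeding caps candidates at 2e5 voxels by density-weighted subsampling;
  spectral/Ward cluster a subsample (1200/3000) and assign the rest to the
  nearest centroid.
- TSP determinism: greedy start at node 1, best-improvement scans with
  fixed tie-breaks, no randomness; `or_time` is a ceiling, not a target.
- Decoy ensembles perform no outlier rejection before averaging.
- `tsp = "ortools"` and `"lkh"` are accepted for interface compatibility;
  both route to the internal solver.

## Limitations

Nucleic acids are not modeled; no real-space chemical refinement, map
sharpening, FSC computation or symmetry handling; ligand chemical identity
is not assigned (clusters are located and shaped, not named); very long
isolated helices may trace with local i±3 swaps, which the probabilistic
model flags as sub-100% connectivity rather than repairs.
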