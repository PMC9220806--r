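Package: captrace
Title: De Novo Backbone Tracing and Ligand Detection in CryoEM Density Maps
Version: 0.1.0
Authors@R: person("captrace", "developers", role = c("aut", "cre"),
    email = "captrace@example.org")
Description: Tools for de novo protein model building in near-atomic
    resolution cryoEM density maps. Reduces above-threshold density to a
    fixed number of pseudoatoms (Calpha surrogates), traces the backbone by
    solving a traveling-salesperson problem over the pseudoatoms, refines
    the path against simple protein-geometry constraints, and threads an
    amino-acid sequence onto the trace. Decoy path ensembles generated over
    density-threshold brackets and positional-noise schedules yield a
    probabilistic model with per-residue connectivity probabilities encoded
    in the PDB B-factor column. A companion residual-density tool masks the
    protein, seeds and filters candidate points (model distance, half-map
    consistency), clusters them by mean shift, and classifies clusters as
    waters/ions or ligands. Includes MRC/CCP4 map I/O, minimal PDB I/O, and
    a synthetic ground-truth generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, clue, FNN
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
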