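Package: lipasetk
Title: Virtual-Screening Triage and Trajectory Binding Analysis for Lipases
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for structure-based selection of serine-hydrolase lipases
    and for analysing substrate diffusion in molecular-dynamics trajectories.
    Builds catalytic-triad-centred docking boxes, applies a two-stage triage
    of docking results (negative affinity and catalytic distance prefilter,
    then dual affinity/distance cutoffs on focus ligands), detects
    per-molecule binding events under a pocket-entry distance criterion with
    entry counts, residence times and ternary-complex overlap windows,
    computes per-residue flexibility (RMSF after rigid superposition),
    channel geometric descriptors (dihedrals, angles, distances) and
    per-residue substrate contact frequencies, and quantifies phospholipid
    products from fatty-acid methyl-ester (FAME) tables. A synthetic-data
    module generates toy structures, docking tables with planted triage
    outcomes, trajectories with planted binding schedules, and FAME tables so
    the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports: jsonlite, optparse, stats, tools, utils, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
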