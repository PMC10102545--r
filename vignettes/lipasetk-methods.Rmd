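---
title: "Methods: screening triage, binding kinetics and pocket descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening triage, binding kinetics and pocket descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipasetk)
```

# The scientific problem

Serine-hydrolase lipases (EC 3.1.1.3) catalyse transesterification through a
Ser-His-Asp/Glu catalytic triad: the Ser O&gamma; attacks the substrate's acyl
carbon. Selecting a lipase for a given acyl exchange — here, moving
docosahexaenoic acid (DHA) from a triacylglycerol donor (DHA-TAG) onto a
phosphatidylcholine (PC) acceptor in a solvent-free oil system — involves
two computational stages that this package implements as reusable,
format-agnostic operations:

1. **Structure-based triage** of docking results over a panel of candidate
   lipase structures, using the predicted affinity and the *catalytic
   distance* (Ser O&gamma; to acyl carbon) as the joint selection criterion.
2. **Trajectory analysis** of molecular-dynamics simulations of the selected
   enzyme surrounded by substrate molecules: when and for how long each
   substrate enters the active pocket, whether acceptor and donor are bound
   *simultaneously* (the ternary complex that makes transesterification
   possible), which surface regions are flexible, how the substrate channels
   breathe, and which residues the substrates touch.

A third, small stage quantifies the reaction products from gas-chromatography
FAME (fatty-acid methyl ester) tables.

The package never runs a docking engine or an MD engine. It consumes their
tabular and trajectory outputs, and ships a synthetic-data module that
generates all of these inputs with planted, exactly-known ground truth.

# Screening model

For each candidate structure the docking search volume is a cube centred on
the **geometric centre of the catalytic triad** (the unweighted mean over all
atoms of the three triad residues), with a default edge of 22.5 Å — large
enough to accommodate a triacylglycerol in any orientation around the triad.

Triage is two-stage, and the inequality conventions deliberately differ:

* **Prefilter** (loose): a structure is kept when its ligand records have
  catalytic distance strictly `< 8` Å and strictly negative affinity. Both
  bounds are strict because that is how loose "plausibility" cuts are
  conventionally stated ("distance below 8 Å", "negative affinity").
  Whether *every* ligand of a structure must pass or *any one* suffices is a
  documented ambiguity of this kind of panel screen; the scope is a
  configuration knob (`scope = "all"` default), and the synthetic generator
  plants tables whose outcome is identical under both scopes.
* **Main screen** (dual cutoff, inclusive): a structure passes when, for
  every *focus ligand* (default DHA-TAG and DUPC — the donor and the
  representative di-unsaturated PC), its best pose satisfies affinity
  `<= -5.0` kcal/mol **and** distance `<= 4.0` Å. Inclusive bounds follow
  the usual "Affinity ≤ −5.0" phrasing of screening figure captions. A
  4.5 Å alternative distance cutoff is expressible through
  `screen_criteria()` because both values circulate for this kind of screen.

When several poses exist per (structure, ligand) pair the best pose is the
one with the lowest affinity, ties broken by the smaller catalytic distance —
the standard triage convention. Output is sorted by the best focus-ligand
affinity, ties broken lexicographically by structure id, so reports are
reproducible byte-for-byte.

# Binding kinetics model

A substrate molecule is **in the active pocket** in frame $t$ when

$$ d_t = \lVert \mathrm{centroid}(\text{molecule}, t) -
   \mathrm{centre}(\text{triad}, t) \rVert < c $$

with entry cutoff $c = 15$ Å by default. The cutoff is deliberately
generous: bulky triacylglycerols never approach the triad itself, so pocket
entry is scored on the whole-molecule centroid (configurable to a named
atom such as the acyl carbon). The comparison is strict (`< c`).

Frames are 0-based and binding events are **half-open intervals**
$[s, e)$, so durations add without off-by-one corrections:
$\text{duration} = (e - s)\,\Delta t$ with $\Delta t$ the frame spacing in
ns. $\Delta t$ is a required user input because trajectory files do not
reliably carry it.

Per batch (independent simulation replicate) the module reports, per
substrate class:

* **entering count** — distinct molecules with at least one event (episode
  counts are reported alongside, since a molecule can re-enter);
* **total binding time** — summed bound frames × $\Delta t$ over all
  molecules of the class;
* cross-batch arithmetic means of both.

**Ternary windows** are maximal intervals during which *every* required
class (default PC and DHA-TAG) has at least one bound molecule — the
geometric signature of the enzyme–acceptor–donor complex. The total ternary
time is necessarily bounded by each class's own union bound time.

An optional **debounce** filter removes bound runs shorter than $k$ frames
and then bridges unbound gaps shorter than $k$ (in that order, so blips are
removed before gaps are bridged). Runs touching the first or last frame are
never merged: the observation window truncates them, so their true length is
unknown. `debounce = 0` (default) is the identity.

# Pocket dynamics descriptors

* **Superposition**: each frame is rigidly fitted (least-squares Kabsch
  rotation + translation, proper rotation enforced) onto frame 1 using the
  protein backbone.
* **Flexibility**: per residue, the root-mean-square fluctuation (RMSF) of
  its representative atom (default C&alpha;) about its time-average position
  after superposition. A common alternative phrasing, "per-residue RMSD from
  the backbone", is ambiguous; RMSF about the time mean is the standard,
  well-defined choice and is what this package computes. The flexible-region
  caller returns maximal runs of consecutive residues strictly above a
  cutoff (default 0.025 Å). That default is unusually small for solvated
  proteins; it is appropriate for the nearly rigid, (micro-)anhydrous
  systems this workflow targets and should be treated as data, not dogma.
* **Channel descriptors**: time series of a torsion over four C&alpha;
  anchors (signed, degrees in (−180, 180], standard IUPAC convention),
  a vertex angle over three anchors (degrees in [0, 180]), and an anchor
  distance (Å). Undefined geometries (collinear torsion axes, coincident
  points) yield `NA` rather than an arbitrary number. Anchors are given as
  `"chain:resnum[:resname]"` keys; the anchor atom is configurable because
  channel descriptors are residue-level.
* **Contact frequencies**: per residue and substrate class, the number of
  frames in which *any* residue atom is strictly within 8 Å of *any* atom
  of *any* molecule of the class. Contact is binary per (residue, class,
  frame) so frequencies are bounded by the frame count and cross-batch
  averaging is meaningful. Residues reaching the highlight count (default
  70) are flagged as strong interactors.

All descriptors are invariant under global rigid motion of each frame;
torsions flip sign under mirror reflection (angles and distances do not).
These invariances are enforced by property tests.

# Lipid quantification

Methylation stoichiometry converts band FAME totals to product moles:
1 mol PC releases 2 mol FAME (two acyl chains), 1 mol LPC releases 1 mol.
Hence $\text{moles(PC)} = \Sigma\,\text{FAME}/2$,
$\text{moles(LPC)} = \Sigma\,\text{FAME}/1$, and yield is moles over initial
moles × 100. "DHA incorporation" is DHA's share of the band's fatty-acid
profile in percent — computed from amounts in whatever consistent unit the
GC workflow produced (mol or normalized area); the package does not convert
between the two.

# The synthetic world

The generators state a fixed world rather than tunable knobs:

* `gen_docking_table(158, 85, 24)` is the canonical fixture: 158 structures
  × 8 ligands (DHA-TAG/DAG/MAG, DHA, C18:2, C16:0, DPPC, DUPC), with
  exactly 85 structures planted to pass the prefilter and 24 of those to
  pass the dual screen. Every drawn value keeps a margin of at least 0.1
  (kcal/mol or Å) from every cutoff, so the planted truth is insensitive to
  tie-breaking and to the prefilter scope.
* `gen_trajectory()` places single-atom substrate "centroids" at 5 Å
  (bound) or 40 Å (unbound) from the triad centre plus uniform-in-ball
  noise (default 1 Å). Noise is uniform in a ball — not Gaussian — so the
  precondition "noise never crosses the 15 Å cutoff" is checkable exactly,
  which is what makes frame-exact planted-truth tests possible. Presets
  encode the solvent contrast as per-molecule entry probabilities: PC 0.025
  (anhydrous) vs 0.125 (micro-water) over 20 PC molecules — expected 0.5 vs
  2.5 distinct entries per batch, a 5× design — and DHA-TAG 0.05 over 200
  molecules (~10 per batch) in both. These rates reproduce the *scale and
  contrast* of the observed entry statistics; they do not reproduce any
  real trajectory, force field, or diffusion physics.
* `gen_fame_table()` realizes a stated fatty-acid composition at a random
  positive scale (profiles are scale-invariant by construction).

What a green test therefore establishes: the analysis stages recover planted
truth exactly, obey their invariants, and reproduce published summary
arithmetic. What it does not establish: anything about real docking scores,
real MD behaviour, water models, or thermodynamics.

# Numerical choices and edge cases

* Strict vs inclusive inequalities are per-stage as described above; the
  boundary cases (distance exactly 8.0/4.0 Å, affinity exactly −5.0,
  distance exactly 15 Å) are covered by tests.
* The entry cutoff comparison at exactly the cutoff value is unbound
  (strict `<`).
* Torsions return values in (−180, 180]; the −180 representation is mapped
  to +180.
* The Kabsch fit enforces a proper rotation (determinant +1), so mirror
  solutions are never produced.
* Degenerate geometry yields `NA` values, never silent zeros.
* Reading never reorders atoms or frames; all readers raise named error
  conditions (`ltk_missing_file`, `ltk_no_atoms`, `ltk_frame_mismatch`,
  `ltk_duplicate_key`, ...) so callers can distinguish failure modes.
* Outputs are written atomically (temp file + rename), and re-running a
  subcommand with the same seed and config is byte-identical.

# Design decisions that were genuinely open

* **Pocket reference point**: no standard exists for "distance between
  enzyme and substrate"; the triad-centre-to-centroid distance is the least
  arbitrary default and the reference is exposed (`reference = "centroid"`
  or an atom name).
* **Entering count semantics**: distinct molecules, not episodes — the
  published per-batch maxima are plausible as distinct-molecule counts for
  200 donors — but episode counts are always emitted alongside.
* **Trajectory carriers**: multi-model PDB and a plain-text XYZ dialect
  whose comment line holds the frame time and whose atom-name token encodes
  `chain.resname.resnum.atom`. Binary formats (DCD/XTC) are out of scope:
  desk-scale testability beats throughput here.
* **Config format**: YAML and JSON are both accepted; JSON is the
  round-trip reference format.
* **Debounce boundary rule**: window-edge runs are exempt from merging (see
  above).

# Known limitations

* The trajectory reader loads everything into memory; fine for desk-scale
  and test systems, not for production 240 ns runs with explicit water.
* Contact frequencies use a dense all-pairs distance scan per frame;
  adequate below ~10^3 atoms, no spatial indexing.
* `prefilter()`/`screen()` treat the ligand panel as given; they do not
  model pose ensembles beyond best-pose selection.
* The synthetic presets model entry counts, not residence-time
  distributions; planted event lengths are convenient, not physical.
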