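---
title: "Methods and conventions in tailscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions in tailscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailscope)
```

`tailscope` analyses conformational ensembles of the histone H3
N-terminal tail — secondary-structure content, conformational clusters,
the tail's maximum reach — and places the results in the context of the
nucleosome (docking-pose ranking, contact classes) and of compact
chromatin (quartile reach shells on a tetranucleosome). This vignette
records the scientific conventions the package commits to, why each was
chosen, and what its synthetic data do and do not establish.

## The tail and its isoforms

The working object is the free N-terminal tail of histone H3, taken as
the first 43 residues of the H3 chain so that the peptide ends at P43 —
the residue used as the anchoring reference for all reach calculations.
(The tail is sometimes delimited at residue 38; the package exposes
`n_residues` in `extract_tail()` so either convention can be used, with
43 as the default.) PTM isoforms are represented at the metadata level:
`apply_ptm_pattern()` rewrites residue names (LYS→ALY for acetylation,
LYS→MLY/M3L for di-/trimethylation, SER→SEP for phosphorylation) and
validates chemical compatibility, but builds no modified side-chain
atoms. No analysis in the package reads side-chain geometry beyond the
Cβ stub, so constructing modified rotamers would add atoms nothing
consumes; workflows that need them should prepare structures upstream.

## Secondary structure

Hydrogen bonds between backbone amide (N–H) and carbonyl (C=O) groups
are scored with the Kabsch–Sander electrostatic model,

$$E \;=\; q_1 q_2 \, f \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}}
  - \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right),$$

with $q_1 q_2 = 0.084\,e^2$ and $f = 332$ kcal·Å/(mol·e²); a bond is
called when $E < -0.5$ kcal/mol. These three constants are exposed in
`ss_params()` but there is rarely a reason to change them — they are the
standard published values, and the −0.5 kcal/mol cutoff deliberately
tolerates ~0.5 Å / ~20° of distortion from ideal bond geometry.

Conventions worth knowing:

* **Amide hydrogens** are reconstructed geometrically when absent
  (H on N, 1.01 Å along the preceding C=O direction) — energy-minimised
  or backbone-only inputs usually lack them. Explicit `H`/`HN` atoms are
  used when present. Prolines and residue 1 never donate.
* **Assignment rules** follow DSSP: two consecutive $i \to i+4$ turns
  open an α-helix (code `H`, covering residues $i..i+3$ per turn pair),
  two consecutive $i \to i+3$ turns a 3₁₀ helix (`G`), with priority
  `H > G` where the patterns overlap. Bridge patterns (parallel and
  antiparallel) give strands (`E`) when bridges extend to a neighbouring
  residue pair and isolated bridges (`B`) otherwise; remaining residues
  inside a 3- or 4-turn are `T`; everything else is coil `C`. π-helices,
  bends and PP-II are deliberately outside the alphabet — the six
  classes are the ones the downstream occupancy profiles distinguish.
* **Chain termini**: the first and last residues lack the turn partners
  required for `H`, so they can never be assigned helix. This is a
  property of the rules, not an error.
* The assignment layer was written against an independent brute-force
  oracle (literal pair enumeration plus literal pattern rules) and the
  two are required to agree exactly on every test fixture.

`ss_matrix()` applies the assignment per frame; `occupancy()` reduces
the frame × residue grid to per-residue class fractions, which sum to 1
by construction.

## Clustering

Pairwise distances are Cα RMSD *after* least-squares (Kabsch)
superposition — rotation and translation only, never reflection. For a
free peptide, unfitted RMSD would mostly measure diffusion, which
carries no conformational information, so fitted RMSD is the only
convention the package offers. Degenerate (collinear) point sets give a
conditioning warning, not an error.

`single_linkage()` merges frames whenever any cross-pair distance is at
most the cutoff; this equals the connected components of the threshold
graph, and is computed through single-linkage agglomeration cut at the
cutoff height. The default cutoff is 13 Å (the value used for full
43-residue tails); tip re-clustering uses the same cutoff on the Cα of
residues 1–15 (`rmsd_matrix(traj, selection = 1:15)`). Determinism is
guaranteed by fixed tie-breaks: clusters are ranked by population with
ties to the lowest member frame index, and the representative of a
cluster is its **medoid** (minimum summed RMSD to the cluster, ties
again to the lowest frame). Coordinate averaging is never used — the
average of divergent conformers is not a conformer.

## Reach

For each frame, `max_reach_frame()` takes the distance from the anchor
Cα (P43 by default) to every Cα strictly N-terminal of it and keeps the
maximum. The anchor itself is excluded; "N-terminal" means lower residue
number. The statistic is invariant under rigid motion of the frame.

`summarize_reach()` reports Q1/median/Q3 using linear interpolation
between order statistics (`stats::quantile` type 7, the R default).
This convention is fixed and documented because the chromatin reach
shells inherit their radii from it — changing the quantile type would
silently move the shells. Whiskers follow Tukey's 1.5 IQR rule by
default, with `whiskers = "minmax"` available since box plots of reach
data are drawn under both conventions in practice.

Isoform comparisons use the unpaired Welch test (unequal variances,
two-sided, 95% CI) via `stats::t.test`. Two degenerate conventions: two
constant equal samples give $t = 0, p = 1$; two constant *different*
samples are an error, since $t$ is undefined. A single comparison is
reported, so no multiple-testing correction is applied.

## Docking poses and contacts

The docking bookkeeping assumes a grid campaign: the receptor's xy
bounding box is divided into `rows × cols` cells (3 × 3 by default,
labelled row-major A1…C3), each spanning the full z extent, and each
expanded by `overlap_frac` (default 0.25) of its width on interior
edges. The exact overlap of the original campaign's cells is not
recorded anywhere, so it is a parameter; any value ≥ 0 preserves the
property that every receptor atom lies in at least one cell. z-overlap
is not modelled — cells already span z.

Binding energies follow the **positive-is-favourable** sign convention;
`read_pose_table(autodock_sign = TRUE)` negates Autodock-convention
input on the way in. `best_pose()` takes the maximum energy per
structure, ties broken by cell label order. The package ships the
reference tip docking-energy table (`h3_docking_energies()`: six tip
structures × nine cells) as a worked input for the ranking logic.

`find_contacts()` applies one distance cutoff (default 5 Å) to all
three contact classes — total, hydrogen bond, hydrophobic. The source
analyses state the 5 Å window explicitly only for hydrogen bonds; the
package applies it to every class as the simplest uniform reading, and
the cutoff is a parameter. Within the window:

* a **hydrogen bond** is an N/O–N/O pair within 3.5 Å, additionally
  requiring a donor–H–acceptor angle ≥ 135° when an explicit amide H is
  present (distance-only otherwise). This geometric criterion is a
  documented operationalisation, not a published constant of the
  original analysis, and is the most deviation-prone convention in the
  package.
* a **hydrophobic contact** is a carbon–carbon pair in which neither
  carbon has a covalent N/O neighbour (< 1.8 Å) in its own structure —
  the simplest reproducible definition of "apolar carbon".

Receptor atoms are tagged `DNA` (nucleotide residue codes) or
`histone_<chain>`; `contact_summary()` tallies per component.

## The tetranucleosome reach model

`build_shells()` centres a spherical annulus on each H3 anchor with
inner radius Q1 and outer radius Q3 of a reach distribution: the region
where the central half of the observed tip positions lie. A site is
**reachable** when the *nearest* of its points falls inside the annulus
(`all_points = TRUE` gives the stricter convention) — a tail tip need
only touch part of a binding surface. Sites are classified against
explicit stack topology metadata (`nucleosome_id`, `stack_id`), never
inferred from geometry. `transplant_site()` moves site or pose
coordinates between nucleosomes through the Kabsch superposition of
their common core atoms, which makes site annotation on an assembled
stack a rigid-motion-exact operation.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every stage has a fully specified input
with known ground truth:

* `gen_peptide_trajectory()` builds an ideal-geometry backbone (N, Cα,
  C, O and Cβ stubs; bond lengths 1.458 / 1.525 / 1.329 Å, the standard
  backbone angles) from per-residue dihedrals. Planted segments switch
  between canonical helix dihedrals (α: φ = −57°, ψ = −47°; 3₁₀:
  φ = −49°, ψ = −26°) and coil *independently per frame* at the
  segment's persistence probability. The default spec plants the two
  helices observed in unmodified-tail ensembles — tip (3–12) at
  persistence 0.8 and middle (20–29) at 0.4, mirroring the reported
  greater stability of the tip helix. Coil residues draw jittered
  dihedrals from an extended basin (φ₀ = −120°, ψ₀ = 130°) or, for
  compact chains, from a mixture of α/αL/β basins.
* `gen_active_inactive_pair()` emulates the compact active vs extended
  inactive contrast: the active analogue is a compact mixed-basin coil,
  the inactive an extended coil with a planted α-helix at residues
  20–27 at persistence 0.65 (the reported 60–70% persistence of the
  helix between L20 and K27). The reach margin between the two is a
  consequence of the basin choice, and is deliberately large so that
  the Welch comparison is decisively powered at 2000 frames.
* `gen_toy_nucleosome()` / `gen_tetranucleosome()` build pseudo-atom
  assemblies: a 147-point DNA superhelix (1.65 turns, 42 Å radius), an
  octamer shell over eight chains, two P43 anchors, and annotated
  tip-binding and acidic-patch sites. The tetranucleosome stacks
  2 × 2 nucleosomes (50 Å rise within a stack, 110 Å between stacks).
  The geometry is *designed*, not fitted: parental tip sites sit
  ~31.5 Å from their anchors, same-stack neighbour sites ~50 Å,
  acidic patches ~24 Å, adjacent-stack sites beyond 95 Å, so that a
  short (28–40 Å) shell spans only the parental site and a long
  (29–52 Å) shell adds exactly the same-stack neighbour — the
  qualitative contact pattern of the compact-chromatin model.
* `gen_pose_table()` plants a strictly maximal best cell per structure
  under seeded noise.

All generators are pure functions of their spec and seed, restore the
caller's RNG state, and reproduce bit-identically.

What passing tests on these inputs show: the analysis chain recovers
planted truth exactly or within stated statistical bounds, every
convention above is implemented as documented, and the pipeline is
deterministic. What they do not show: anything about real MD ensembles.
The generators have no force field, no solvent, no excluded volume and
no correlated dynamics (frames are independent draws, so occupancy error
bounds are binomial); their conformers are not physical. Quantitative
results on real tails — absolute reach distributions, cluster counts,
docking energies — require real trajectories and a docking engine, both
out of scope here. The package's claims about real data are therefore
qualitative: the statistics it implements are the ones under which the
reported contrasts (longer inactive reach, stack-limited contact
patterns) are expressible and testable.

## Problem sizes and numerical choices

The test-suite and acceptance computations use 2000-frame ensembles for
the statistical recoveries (persistence within ±0.05 of {0.2, 0.5,
0.8}; Welch detection of the planted reach margin at p < 0.001) and
100–500-frame ensembles for structural and pipeline checks — sizes at
which the binomial bounds above hold with comfortable margin and a full
run stays interactive on a single CPU. Superposition uses SVD with a
determinant correction (no reflections); RMSD symmetry is enforced to
1e−6; PDB coordinates round-trip at the format's three-decimal
precision. JSON summaries contain no timestamps, so identical
config + seed reproduces them byte for byte.

## Known limitations

* Secondary-structure assignment is this package's Kabsch–Sander/DSSP
  implementation; ensembles assigned with other tools (e.g. YASARA's
  internal algorithm) may differ in edge cases, so cross-tool
  comparisons should be made at the level of occupancy profiles, not
  per-frame labels.
* The hydrogen-bond geometric criterion (3.5 Å / 135°) is a documented
  choice; absolute H-bond counts are sensitive to it.
* mmCIF and binary trajectory formats (XTC/DCD) are not read; convert
  to multi-MODEL PDB upstream.
* PTMs are metadata-only (see above); hydrogen placement and energy
  minimisation are out of scope.
* The toy nucleosome is a pseudo-atom disc for geometry and contact
  bookkeeping, not a structural model of the particle.
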