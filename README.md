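# tailscope

Analysis of histone H3 N-terminal tail conformational ensembles and their
interactions with the nucleosome.

The N-terminal tail of histone H3 is the longest and most heavily modified
of the core histone tails. Although usually described as disordered, long
molecular-dynamics ensembles of the free 43-residue tail show transient
α-helices whose stability depends on the post-translational modification
(PTM) pattern carried by the tail, and the tail's *reach* — how far its
tip can sweep from its anchoring point on the nucleosome — differs between
the euchromatin-associated ("active": K4me3 + K36me3, K9ac + K14ac) and
heterochromatin-associated ("inactive": K9me2 + K27me2, S10ph + S28ph)
isoforms. That difference decides which binding sites the tail can touch
inside compact chromatin.

`tailscope` implements the complete analysis chain for this problem as a
tidyverse-native R package, for structural bioinformaticians who have tail
ensembles (or want fully synthetic stand-ins) and need the downstream
statistics:

* **Structure/trajectory I/O** — multi-MODEL PDB in and out, tail
  extraction (`extract_tail()`, e.g. the first 43 residues of chain A),
  and metadata-level PTM isoform annotation (`apply_ptm_pattern()`,
  Table-style patterns via `ptm_pattern()`).
* **Secondary structure** — per-frame assignment from the Kabsch–Sander
  electrostatic hydrogen-bond energy

  ```
  E = q1 q2 · f · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN),   q1 q2 = 0.084 e², f = 332 kcal·Å/(mol·e²)
  ```

  with a bond called at E < −0.5 kcal/mol, reduced by the DSSP pattern
  rules to the 6-class alphabet {H, G, E, B, T, C}
  (`assign_ss()`, `ss_matrix()`, `occupancy()`).
* **Conformational clustering** — all-vs-all Cα RMSD after Kabsch
  superposition, single-linkage clustering at a 13 Å cutoff (connected
  components of the threshold graph), medoid "median structures", and
  15-residue tip re-clustering (`kabsch_rmsd()`, `rmsd_matrix()`,
  `single_linkage()`, `representative()`).
* **Reach statistic** — per frame, the maximum distance from the P43 Cα
  anchor to any Cα on its N-terminal side; quartile summaries and the
  Welch (unequal-variance) t comparison between isoforms
  (`reach_series()`, `summarize_reach()`, `welch_test()`).
* **Docking-pose analysis** — 3 × 3 overlapping grid cells over the
  nucleosome (`make_grid()`), best-pose selection per tip structure in
  the positive-is-favourable energy convention (`best_pose()`,
  `rank_poses()`, with the reference tip docking-energy table shipped as
  `h3_docking_energies()`), and contact classification within 5 Å —
  total, hydrogen-bond and hydrophobic, tagged DNA vs histone chain
  (`find_contacts()`, `contact_summary()`).
* **Tetranucleosome reach model** — a spherical annulus (Q1–Q3 of the
  reach distribution) around each H3 anchor of a stacked
  tetranucleosome; annotated sites are classified as intranucleosomal,
  internucleosomal within the stack, or adjacent-stack
  (`build_shells()`, `classify_reachable_sites()`, `transplant_site()`).
* **Synthetic data** — seeded generators for backbone ensembles with
  planted helices of tunable persistence, compact/extended isoform
  pairs, toy nucleosome and tetranucleosome pseudo-atom assemblies, and
  pose tables with planted best cells (`gen_peptide_trajectory()`,
  `gen_active_inactive_pair()`, `gen_toy_nucleosome()`,
  `gen_tetranucleosome()`, `gen_pose_table()`), so every stage is
  testable without MD or docking runs.
* **Orchestration** — `run_pipeline()` runs every stage on a config
  (`pipeline_config()` or YAML), writing per-stage CSV/PDB reports and a
  deterministic `summary.json`.

## Worked example

```r
library(tailscope)
library(dplyr)

# A 500-frame synthetic ensemble of the unmodified 43-residue H3 tail,
# with its two planted helices: tip (residues 3-12, persistence 0.8)
# and middle (20-29, persistence 0.4).
traj <- gen_peptide_trajectory(peptide_spec(n_frames = 500), seed = 42)
occ  <- occupancy(ss_matrix(traj))
occ |> filter(code == "H", res_seq %in% c(5, 8, 24, 40))
#> # A tibble: 4 × 3
#>   res_seq code  fraction
#>     <int> <chr>    <dbl>
#> 1       5 H        0.776
#> 2       8 H        0.776
#> 3      24 H        0.396
#> 4      40 H        0
```

Residues inside the tip helix recover its 0.8 persistence, the middle
helix its 0.4, and residues outside the planted segments show no helix.

```r
# Reach comparison between compact ("active-like") and extended
# ("inactive-like") synthetic isoforms:
pair <- gen_active_inactive_pair(n_frames = 500, seed = 42)
welch_test(reach_series(pair$inactive), reach_series(pair$active))
#> # A tibble: 1 × 10
#>   estimate     t    df p_value conf_low conf_high mean_a mean_b   n_a   n_b
#>      <dbl> <dbl> <dbl>   <dbl>    <dbl>     <dbl>  <dbl>  <dbl> <int> <int>
#> 1     66.7  66.8  779.       0     64.8      68.7   103.   36.5   500   500
```

The extended isoform reaches ~67 Å farther on average; the Welch test
declares the difference overwhelmingly significant.

```r
# Best docking pose of the first unmodified tip cluster, from the
# shipped grid-cell energy table (kcal/mol, positive = favourable):
best_pose(h3_docking_energies(), "unmodified_i")
#> # A tibble: 1 × 3
#>   structure_label cell  energy
#>   <chr>           <chr>  <dbl>
#> 1 unmodified_i    C3      8.49

# Which sites can a long-reach tail touch in a stacked tetranucleosome?
tetra <- gen_tetranucleosome()
cls <- classify_reachable_sites(tetra, build_shells(tetra, q1 = 29, q3 = 52))
cls |> filter(reachable) |> count(relation, kind)
#> # A tibble: 2 × 3
#>   relation                    kind                 n
#>   <chr>                       <chr>            <int>
#> 1 internucleosomal_same_stack tip_binding_site     4
#> 2 intranucleosomal            tip_binding_site     8
```

With a long (inactive-like) shell every anchor reaches the tip binding
site of its own nucleosome, four anchors additionally reach the site of
the nucleosome above/below in the same stack, and no anchor reaches the
adjacent stack or the H2A/H2B acidic patch.

Each result type has a plot: `autoplot()` on a secondary-structure
matrix or a clustering, `plot_occupancy()`, `plot_reach_compare()`,
`plot_reachability()`.

## Vignette

`vignettes/tailscope-methods.Rmd` describes the models and conventions in
detail: the hydrogen-bond energy and assignment rules, the clustering and
quantile conventions, the reach-shell construction, what the synthetic
generators do and do not emulate, and the package's known limitations.
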