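Package: tailscope
Title: Conformational and Docking Analysis of Histone Tail Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for conformational ensembles of histone
    N-terminal tails and their interactions with the nucleosome. Assigns
    per-frame secondary structure from backbone hydrogen-bond energies,
    clusters trajectory frames by superposed alpha-carbon RMSD
    (single linkage), computes the anchor-referenced maximum tail reach
    statistic and its Welch comparison between modification isoforms,
    ranks grid-cell docking poses and classifies tip-nucleosome contacts,
    and evaluates quartile-shell accessibility of binding sites on a
    tetranucleosome model. Includes seeded generators for synthetic
    peptide trajectories with planted helices, toy nucleosome and
    tetranucleosome assemblies, and docking pose tables, so the full
    pipeline is testable without molecular dynamics or docking runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
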