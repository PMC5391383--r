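test_that("read_structure parses a hand-written two-residue file", {
  f <- write_two_residue_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- read_structure(f)
  expect_equal(nrow(s), 8)
  expect_equal(sort(unique(s$res_seq)), c(1, 2))
  expect_equal(s$res_name[s$res_seq == 2][1], "GLY")
  expect_equal(s$x[1], 0)
  expect_equal(s$x[2], 1.458)
})

test_that("degenerate and malformed PDB inputs raise named parse errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(), empty)
  expect_error(read_structure(empty), "no ATOM")

  trunc <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1      0.0"), trunc)
  expect_error(read_structure(trunc), "line 1")

  expect_error(read_structure(withr::local_tempfile()), "not found")
})

test_that("model selection picks the requested MODEL and flags missing ones", {
  # three models with distinct z
  spec <- peptide_spec(
    n_res = 4, segments = empty_segments(),
    n_frames = 3, coil_dihedral_jitter = 10
  )
  traj <- gen_peptide_trajectory(spec, seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  s2 <- read_structure(f, model_index = 2)
  expect_equal(
    structure_coords(s2),
    round(traj$coords[2, , ], 3),
    ignore_attr = TRUE
  )
  expect_error(read_structure(f, model_index = 4), "model 4 not found")
})

test_that("trajectories round-trip through multi-MODEL PDB at file precision", {
  spec <- peptide_spec(n_res = 6, segments = empty_segments(), n_frames = 5)
  traj <- gen_peptide_trajectory(spec, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  back <- read_trajectory(f, dt = 25)
  expect_equal(n_frames(back), 5)
  expect_equal(back$dt, 25)
  expect_lt(max(abs(back$coords - traj$coords)), 5e-4 + 1e-9)
  expect_equal(back$topology$name, traj$topology$name)

  single <- withr::local_tempfile(fileext = ".pdb")
  write_structure(frame_structure(traj, 1), single)
  expect_equal(n_frames(read_trajectory(single, dt = 25)), 1)
})

test_that("non-congruent models are rejected", {
  spec <- peptide_spec(n_res = 4, segments = empty_segments(), n_frames = 3)
  traj <- gen_peptide_trajectory(spec, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  lines <- readLines(f)
  # drop one ATOM line from the last model
  atom_lines <- grep("^ATOM", lines)
  lines <- lines[-atom_lines[length(atom_lines)]]
  writeLines(lines, f)
  expect_error(read_trajectory(f, dt = 25), "not congruent")
})

test_that("extract_tail selects the first n residues of a chain", {
  # two-chain structure: chain A 5 residues, chain B 2 residues
  mk <- function(chain, n, offset) {
    tibble::tibble(
      name = "CA", element = "C", res_seq = seq_len(n),
      res_name = "ALA", chain_id = chain,
      x = offset + seq_len(n), y = 0, z = 0
    )
  }
  s <- as_structure(dplyr::bind_rows(mk("A", 5, 0), mk("B", 2, 100)))
  t3 <- extract_tail(s, "A", 3)
  expect_equal(unique(t3$chain_id), "A")
  expect_equal(sort(unique(t3$res_seq)), 1:3)

  t1 <- extract_tail(s, "A", 1)
  expect_equal(unique(t1$res_seq), 1)

  expect_error(extract_tail(s, "B", 3), "only 2 residues")
  expect_error(extract_tail(s, "Z", 1), "not present")
})

test_that("extract_tail is idempotent and the 43-residue H3 cut ends at P43", {
  spec <- peptide_spec(n_frames = 1)
  tail43 <- frame_structure(gen_peptide_trajectory(spec, seed = 1), 1)
  cut <- extract_tail(tail43, "A", 43)
  expect_equal(max(cut$res_seq), 43)
  expect_equal(cut$res_name[cut$res_seq == 43][1], "PRO")
  again <- extract_tail(cut, "A", 43)
  expect_equal(
    as.data.frame(again[, names(again)]),
    as.data.frame(cut[, names(cut)]),
    ignore_attr = TRUE
  )
})

test_that("PTM patterns rewrite residue names without touching geometry", {
  spec <- peptide_spec(n_frames = 1)
  tail43 <- frame_structure(gen_peptide_trajectory(spec, seed = 1), 1)

  act <- apply_ptm_pattern(tail43, ptm_pattern("active"))
  expect_equal(unique(act$res_name[act$res_seq %in% c(4, 36)]), "M3L")
  expect_equal(unique(act$res_name[act$res_seq %in% c(9, 14)]), "ALY")
  expect_equal(structure_coords(act), structure_coords(tail43))
  expect_equal(nrow(act), nrow(tail43))

  ina <- apply_ptm_pattern(tail43, ptm_pattern("inactive"))
  expect_equal(unique(ina$res_name[ina$res_seq %in% c(9, 27)]), "MLY")
  expect_equal(unique(ina$res_name[ina$res_seq %in% c(10, 28)]), "SEP")

  hyp <- apply_ptm_pattern(tail43, ptm_pattern("hyperacetylated"))
  lys_pos <- c(4, 9, 14, 18, 23, 27, 36, 37)
  expect_equal(unique(hyp$res_name[hyp$res_seq %in% lys_pos]), "ALY")
  expect_false(any(hyp$res_name == "LYS"))

  unm <- apply_ptm_pattern(tail43, ptm_pattern("unmodified"))
  expect_equal(unm$res_name, tail43$res_name)

  ala <- apply_ptm_pattern(tail43, ptm_pattern("ala_ctrl"))
  expect_equal(unique(ala$res_name), "ALA")
  gly <- apply_ptm_pattern(tail43, ptm_pattern("gly_ctrl"))
  expect_equal(unique(gly$res_name), "GLY")
})

test_that("incompatible PTM targets are rejected", {
  spec <- peptide_spec(n_frames = 1)
  tail43 <- frame_structure(gen_peptide_trajectory(spec, seed = 1), 1)
  bad <- tibble::tibble(res_seq = 10L, mod = "ac") # S10 is a serine
  expect_error(apply_ptm_pattern(tail43, bad), "lysine required")
  bad2 <- tibble::tibble(res_seq = 4L, mod = "ph") # K4 is a lysine
  expect_error(apply_ptm_pattern(tail43, bad2), "serine/threonine")
})

test_that("PTM patterns load from a YAML config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "active:",
    "  - K4:me3",
    "  - K36:me3",
    "  - K9:ac",
    "  - K14:ac",
    "hyper:",
    "  - all:ac"
  ), f)
  pats <- read_ptm_patterns(f)
  expect_named(pats, c("active", "hyper"))
  expect_equal(sort(pats$active$res_seq), c(4, 9, 14, 36))
  expect_equal(attr(pats$hyper, "scope"), "all_lys_ac")
})

test_that("frame_count converts simulation length to saved frames", {
  expect_identical(frame_count(500, 25), 20000L)
  expect_identical(frame_count(1, 1000), 1L)
  expect_identical(frame_count(10, 25), 400L)
  expect_error(frame_count(-1, 25), "positive")
  expect_error(frame_count(10, 0), "positive")
})
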