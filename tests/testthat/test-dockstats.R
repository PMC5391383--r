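toy_receptor <- function() gen_toy_nucleosome()$structures[[1]]

test_that("a 1 x 1 grid is the bounding box itself", {
  rec <- toy_receptor()
  g <- make_grid(rec, rows = 1, cols = 1, overlap_frac = 0.3)
  expect_equal(nrow(g), 1)
  expect_equal(g$cell, "A1")
  expect_equal(c(g$xmin, g$xmax), range(rec$x))
  expect_equal(c(g$ymin, g$ymax), range(rec$y))
})

test_that("a 3 x 3 grid at zero overlap tiles the box exactly", {
  rec <- toy_receptor()
  g <- make_grid(rec, overlap_frac = 0)
  expect_equal(g$cell, c("A1", "A2", "A3", "B1", "B2", "B3", "C1", "C2", "C3"))
  expect_equal(unique(round(g$xmax - g$xmin, 9)), round(diff(range(rec$x)) / 3, 9))
  # adjacent cells share exactly their boundary
  a1 <- g[g$cell == "A1", ]
  a2 <- g[g$cell == "A2", ]
  expect_equal(a1$xmax, a2$xmin)
})

test_that("overlap widens interior edges and coverage is complete", {
  rec <- toy_receptor()
  g <- make_grid(rec, overlap_frac = 0.25)
  wx <- diff(range(rec$x)) / 3
  mid <- g[g$cell == "B2", ]
  expect_equal(mid$xmax - mid$xmin, wx * 1.5)
  edge <- g[g$cell == "A1", ]
  expect_equal(edge$xmax - edge$xmin, wx * 1.25)

  # Monte-Carlo membership oracle: every random point of the box lies in
  # >= 1 cell; interior points near boundaries lie in >= 2.
  set.seed(10)
  px <- runif(500, min(rec$x), max(rec$x))
  py <- runif(500, min(rec$y), max(rec$y))
  n_cells <- sapply(seq_along(px), function(i) {
    sum(px[i] >= g$xmin & px[i] <= g$xmax & py[i] >= g$ymin & py[i] <= g$ymax)
  })
  expect_true(all(n_cells >= 1))
  expect_gt(sum(n_cells >= 2), 0)

  # every receptor atom is covered
  in_any <- sapply(seq_len(nrow(rec)), function(i) {
    any(rec$x[i] >= g$xmin & rec$x[i] <= g$xmax &
      rec$y[i] >= g$ymin & rec$y[i] <= g$ymax)
  })
  expect_true(all(in_any))
  expect_error(make_grid(rec, rows = 0), ">= 1")
})

test_that("expected_pose_total multiplies cells by poses per cell", {
  rec <- toy_receptor()
  expect_identical(expected_pose_total(make_grid(rec), 400), 3600L)
  expect_identical(expected_pose_total(make_grid(rec, 1, 1), 400), 400L)
  expect_identical(expected_pose_total(make_grid(rec, 2, 3), 10), 60L)
})

test_that("best_pose recovers the highlighted cells of the reference table", {
  t2 <- h3_docking_energies()
  expect_equal(nrow(t2), 54)
  cases <- list(
    unmodified_i = list(cell = "C3", energy = 8.49),
    hyperacetylated_i = list(cell = "C3", energy = 0.28),
    active_i = list(cell = "B3", energy = 1.93),
    inactive_i = list(cell = "C1", energy = 1.48)
  )
  for (lab in names(cases)) {
    bp <- best_pose(t2, lab)
    expect_equal(bp$cell, cases[[lab]]$cell)
    expect_equal(bp$energy, cases[[lab]]$energy)
  }
  expect_error(best_pose(t2, "nope"), "no poses")
})

test_that("best_pose breaks ties by cell label order", {
  t <- tibble::tibble(
    structure_label = "x",
    cell = c("C3", "B2", "A2"),
    energy = c(1.5, 1.5, 1.0)
  )
  expect_equal(best_pose(t, "x")$cell, "B2")
  single <- tibble::tibble(structure_label = "y", cell = "B1", energy = -2)
  expect_equal(best_pose(single, "y")$energy, -2)
})

test_that("rank_poses orders structures by their best energies", {
  t2 <- h3_docking_energies()
  rk <- rank_poses(t2)
  expect_equal(nrow(rk), 6)
  expect_equal(rk$structure_label[1], "unmodified_iii") # 9.33 in A3
  expect_true(all(diff(rk$energy) <= 0))
  # unmodified clusters outrank all modified isoforms
  unmod <- grepl("^unmodified", rk$structure_label)
  expect_true(all(which(unmod) < which(!unmod)))
})

test_that("pose tables round-trip through CSV with the sign flag", {
  t <- tibble::tibble(
    structure_label = "x", cell = c("A1", "A2"), energy = c(-1.2, -3.4)
  )
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(t, f, row.names = FALSE)
  got <- read_pose_table(f, autodock_sign = TRUE)
  expect_equal(got$energy, c(1.2, 3.4))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(t[, 1:2], bad, row.names = FALSE)
  expect_error(read_pose_table(bad), "missing column")
})

test_that("contact detection respects the distance cutoff exactly", {
  one_atom <- function(x, el = "C", name = "CB", chain = "A") {
    tibble::tibble(
      name = name, element = el, res_seq = 1L, res_name = "ALA",
      chain_id = chain, x = x, y = 0, z = 0
    )
  }
  near <- find_contacts(one_atom(0), one_atom(4.9, chain = "B"), cutoff = 5)
  expect_equal(nrow(near), 1)
  expect_equal(near$distance, 4.9)
  far <- find_contacts(one_atom(0), one_atom(5.1, chain = "B"), cutoff = 5)
  expect_equal(nrow(far), 0)
})

test_that("contact pairs match the all-pairs oracle and are symmetric", {
  spec <- peptide_spec(n_res = 6, segments = empty_segments(), n_frames = 1)
  tip <- frame_structure(gen_peptide_trajectory(spec, seed = 21), 1)
  rec <- toy_receptor()
  # park the tip close to the octamer surface
  tip$x <- tip$x + 28
  tip$z <- tip$z - 6
  ct <- find_contacts(tip, rec, cutoff = 5)
  want <- oracle_contact_pairs(tip, rec, 5)
  expect_equal(nrow(ct), nrow(want))
  got_pairs <- paste(match(ct$tip_atom, tip$name), ct$receptor_res)
  expect_gt(nrow(ct), 0)

  # symmetry: swapping tip and receptor yields the same pair count
  ct_swap <- find_contacts(rec, tip, cutoff = 5)
  expect_equal(nrow(ct_swap), nrow(ct))
  expect_equal(sort(ct$distance), sort(ct_swap$distance))
})

test_that("hydrogen-bond and hydrophobic classes are classified correctly", {
  mk <- function(name, el, x, res = 1L, chain = "A", resname = "ALA") {
    tibble::tibble(
      name = name, element = el, res_seq = res, res_name = resname,
      chain_id = chain, x = x, y = 0, z = 0
    )
  }
  # polar N (tip) vs DNA O at 3.0 A -> hydrogen bond to DNA
  tip_n <- mk("N", "N", 0)
  rec_o <- mk("OP", "O", 3.0, chain = "I", resname = "DA")
  hb <- find_contacts(tip_n, rec_o, cutoff = 5)
  expect_true(hb$is_hbond)
  expect_equal(hb$component, "DNA")
  expect_false(hb$is_hydrophobic)

  # same pair at 4 A: a contact but too long for a hydrogen bond
  far_o <- mk("OP", "O", 4.0, chain = "I", resname = "DA")
  hb2 <- find_contacts(tip_n, far_o, cutoff = 5)
  expect_false(hb2$is_hbond)

  # apolar C vs apolar C -> hydrophobic
  tip_c <- mk("CB", "C", 0)
  rec_c <- mk("CB", "C", 4.0, chain = "D")
  ph <- find_contacts(tip_c, rec_c, cutoff = 5)
  expect_true(ph$is_hydrophobic)
  expect_equal(ph$component, "histone_D")

  # carbon bonded to an O (carbonyl-like) is polar -> not hydrophobic
  tip_co <- dplyr::bind_rows(mk("C", "C", 0), mk("O", "O", 1.23))
  ph2 <- find_contacts(tip_co, rec_c, cutoff = 5)
  expect_false(any(ph2$is_hydrophobic[ph2$tip_atom == "C"]))
})

test_that("contact_summary tallies classes per receptor component", {
  mk <- function(name, el, x, y = 0, res = 1L, chain = "A", resname = "ALA") {
    tibble::tibble(
      name = name, element = el, res_seq = res, res_name = resname,
      chain_id = chain, x = x, y = y, z = 0
    )
  }
  tip <- dplyr::bind_rows(
    mk("N", "N", 0, res = 1L),
    mk("CB", "C", 0, y = 20, res = 2L)
  )
  rec <- dplyr::bind_rows(
    mk("OP", "O", 3, res = 1L, chain = "I", resname = "DA"),
    mk("OP", "O", 3.2, y = 1, res = 2L, chain = "I", resname = "DA"),
    mk("CB", "C", 2, y = 20, res = 3L, chain = "B"),
    mk("CB", "C", 3, y = 21, res = 4L, chain = "B"),
    mk("CB", "C", 1, y = 19, res = 5L, chain = "B")
  )
  sm <- contact_summary(find_contacts(tip, rec, cutoff = 5))
  total <- sm[sm$component == "total", ]
  dna <- sm[sm$component == "DNA", ]
  hb <- sm[sm$component == "histone_B", ]
  expect_equal(dna$n_hbond, 2)
  expect_equal(hb$n_hydrophobic, 3)
  expect_equal(total$n_total, 5)
  expect_true(all(sm$n_hbond <= sm$n_total))
  expect_true(all(sm$n_hydrophobic <= sm$n_total))

  empty <- contact_summary(find_contacts(
    mk("N", "N", 0), mk("OP", "O", 50, chain = "I"), 5
  ))
  expect_equal(empty$n_total, 0)
})

test_that("planted pose tables recover their best cells", {
  g <- make_grid(toy_receptor())
  pt <- gen_pose_table(g, c("s1", "s2"), c(s1 = "C3", s2 = "A1"), seed = 5)
  expect_equal(best_pose(pt, "s1")$cell, "C3")
  expect_equal(best_pose(pt, "s2")$cell, "A1")
  expect_identical(
    gen_pose_table(g, "s1", c(s1 = "B2"), seed = 9),
    gen_pose_table(g, "s1", c(s1 = "B2"), seed = 9)
  )
  expect_error(gen_pose_table(g, "s1", c(s1 = "Z9"), seed = 1), "not in grid")
  expect_error(gen_pose_table(g, "s1", c(other = "A1"), seed = 1), "no planted cell")
})
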