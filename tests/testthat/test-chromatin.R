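# Fixture shell radii for the reachability tests: chosen against the toy
# tetranucleosome geometry (parental tip site at ~31.5 A, same-stack
# neighbour tip at ~49.9 A, acidic patches at ~23.7 / ~55.3 A, adjacent
# stack beyond 95 A) so the short shell spans only the parental site and
# the long shell spans parental + same-stack sites.
active_like <- list(q1 = 28, q3 = 40)
inactive_like <- list(q1 = 29, q3 = 52)

test_that("build_shells produces one annulus per anchor with quartile radii", {
  tetra <- gen_tetranucleosome()
  sh <- build_shells(tetra, q1 = 30, q3 = 50)
  expect_equal(nrow(sh), 8)
  expect_equal(unique(sh$r_inner), 30)
  expect_equal(unique(sh$r_outer), 50)

  single <- gen_toy_nucleosome()
  expect_equal(nrow(build_shells(single, q1 = 1, q3 = 2)), 2)

  # radii can come straight from a reach summary
  sm <- summarize_reach(tibble::tibble(reach = c(10, 20, 30, 40)))
  sh2 <- build_shells(single, summary = sm)
  expect_equal(unique(sh2$r_inner), sm$q1)
  expect_equal(unique(sh2$r_outer), sm$q3)

  # degenerate zero-thickness shells are allowed
  sh3 <- build_shells(single, q1 = 5, q3 = 5)
  expect_equal(sh3$r_inner, sh3$r_outer)
  expect_error(build_shells(single, q1 = 9, q3 = 2))
})

test_that("site_reachable implements the annulus and point conventions", {
  shell <- list(x = 0, y = 0, z = 0, r_inner = 10, r_outer = 20)
  expect_false(site_reachable(shell, cbind(0, 0, 0))) # at the centre
  expect_true(site_reachable(shell, cbind(15, 0, 0))) # mid-annulus
  expect_false(site_reachable(shell, cbind(25, 0, 0))) # beyond the shell

  # multi-point site straddling the annulus: nearest point decides,
  # checked against a per-point scan
  pts <- rbind(c(5, 0, 0), c(15, 0, 0), c(30, 0, 0))
  d <- sqrt(rowSums(pts^2))
  expect_equal(
    site_reachable(shell, pts),
    min(d) >= 10 && min(d) <= 20
  )
  # nearest point is *inside* the inner sphere here -> not reachable
  expect_false(site_reachable(shell, pts))
  outer_pts <- rbind(c(12, 0, 0), c(30, 0, 0))
  expect_true(site_reachable(shell, outer_pts))
  expect_false(site_reachable(shell, outer_pts, all_points = TRUE))
  expect_true(site_reachable(shell, rbind(c(12, 0, 0), c(18, 0, 0)),
    all_points = TRUE
  ))
  expect_error(site_reachable(shell, matrix(0, 0, 3)), "no points")
})

test_that("zero-radius shells reach nothing", {
  tetra <- gen_tetranucleosome()
  sh <- build_shells(tetra, q1 = 0, q3 = 0)
  cls <- classify_reachable_sites(tetra, sh)
  expect_false(any(cls$reachable))
})

test_that("the short 'active-like' shell reaches only parental tip sites", {
  tetra <- gen_tetranucleosome()
  sh <- build_shells(tetra, q1 = active_like$q1, q3 = active_like$q3)
  cls <- classify_reachable_sites(tetra, sh)
  reached <- cls[cls$reachable, ]
  expect_gt(nrow(reached), 0)
  expect_equal(unique(reached$relation), "intranucleosomal")
  expect_equal(unique(reached$kind), "tip_binding_site")
  # every anchor reaches its own parental site
  expect_equal(sort(unique(reached$anchor_id)), sort(sh$anchor_id))
})

test_that("the long 'inactive-like' shell adds same-stack sites but never
          the adjacent stack or the acidic patch", {
  tetra <- gen_tetranucleosome()
  sh <- build_shells(tetra, q1 = inactive_like$q1, q3 = inactive_like$q3)
  cls <- classify_reachable_sites(tetra, sh)
  reached <- cls[cls$reachable, ]
  expect_setequal(
    unique(reached$relation),
    c("intranucleosomal", "internucleosomal_same_stack")
  )
  expect_false(any(reached$relation == "internucleosomal_adjacent_stack"))
  expect_false(any(reached$kind == "acidic_patch"))
  # every anchor keeps its parental site
  intra <- reached[reached$relation == "intranucleosomal", ]
  expect_equal(sort(unique(intra$anchor_id)), sort(sh$anchor_id))
  # at least one anchor gains a neighbour site in its own stack
  same <- reached[reached$relation == "internucleosomal_same_stack", ]
  expect_gt(nrow(same), 0)
  expect_equal(unique(same$kind), "tip_binding_site")
})

test_that("reachable sets are monotone in the shell radii", {
  tetra <- gen_tetranucleosome()
  base <- classify_reachable_sites(tetra, build_shells(tetra, q1 = 29, q3 = 45))
  wider <- classify_reachable_sites(tetra, build_shells(tetra, q1 = 29, q3 = 60))
  narrower_inner <- classify_reachable_sites(
    tetra, build_shells(tetra, q1 = 20, q3 = 45)
  )
  key <- function(d) paste(d$anchor_id, d$site_id)[d$reachable]
  expect_true(all(key(base) %in% key(wider)))
  expect_true(all(key(base) %in% key(narrower_inner)))
})

test_that("classification distances agree with direct geometry", {
  tetra <- gen_tetranucleosome()
  sh <- build_shells(tetra, q1 = 10, q3 = 20)
  cls <- classify_reachable_sites(tetra, sh)
  expect_equal(nrow(cls), nrow(sh) * nrow(tetra$sites))
  row <- cls[cls$anchor_id == sh$anchor_id[1] &
    cls$site_id == tetra$sites$site_id[1], ]
  pts <- tetra$site_points[tetra$site_points$site_id == row$site_id, ]
  d <- min(sqrt((pts$x - sh$x[1])^2 + (pts$y - sh$y[1])^2 + (pts$z - sh$z[1])^2))
  expect_equal(row$distance, d)
})

test_that("transplant_site is the identity on its own nucleosome", {
  asm <- gen_toy_nucleosome()
  ncp <- asm$structures[[1]]
  pose <- cbind(c(10, 12), c(0, 1), c(5, 5))
  moved <- transplant_site(pose, ncp, ncp)
  expect_equal(moved, pose, tolerance = 1e-9)
})

test_that("transplant_site follows rigid motions exactly", {
  asm <- gen_toy_nucleosome()
  ncp <- asm$structures[[1]]
  moved_ncp <- ncp
  xyz <- random_rigid_motion(structure_coords(ncp), seed = 12)
  moved_ncp$x <- xyz[, 1]
  moved_ncp$y <- xyz[, 2]
  moved_ncp$z <- xyz[, 3]
  pose <- cbind(c(38, 35), c(0, 2), c(-10, -8))
  got <- transplant_site(pose, ncp, moved_ncp)
  want <- random_rigid_motion(pose, seed = 12)
  # the same rigid transform applies (note: random_rigid_motion is a pure
  # function of its seed, so applying it to the pose is the ground truth)
  expect_equal(got, want, tolerance = 1e-6)

  # structure input keeps metadata and moves coordinates
  tip <- frame_structure(
    gen_peptide_trajectory(
      peptide_spec(n_res = 4, segments = empty_segments(), n_frames = 1),
      seed = 2
    ), 1
  )
  moved_tip <- transplant_site(tip, ncp, moved_ncp)
  expect_equal(moved_tip$name, tip$name)
  expect_equal(
    structure_coords(moved_tip),
    random_rigid_motion(structure_coords(tip), seed = 12),
    tolerance = 1e-6, ignore_attr = TRUE
  )
  expect_error(
    transplant_site(pose, ncp, tip),
    "no usable core"
  )
})

test_that("transplant_site commutes with rigid motions of the target", {
  asm <- gen_toy_nucleosome()
  ncp <- asm$structures[[1]]
  pose <- cbind(c(20, 25, 30), c(1, 2, 3), c(0, -5, 5))
  # target A: translated copy; target B: A moved rigidly again
  a <- ncp
  a$x <- a$x + 40
  b <- a
  xyz <- random_rigid_motion(structure_coords(a), seed = 33)
  b$x <- xyz[, 1]
  b$y <- xyz[, 2]
  b$z <- xyz[, 3]
  direct <- transplant_site(pose, ncp, b)
  via_a <- transplant_site(transplant_site(pose, ncp, a), a, b)
  expect_equal(direct, via_a, tolerance = 1e-6)
})

test_that("assembly validation catches inconsistent metadata", {
  expect_error(
    nucleosome_assembly(
      nucleosomes = tibble::tibble(nucleosome_id = "N1", stack_id = 1L),
      anchors = tibble::tibble(
        anchor_id = "a", nucleosome_id = "N2", x = 0, y = 0, z = 0
      ),
      sites = tibble::tibble(
        site_id = "s", nucleosome_id = "N1", kind = "tip_binding_site"
      ),
      site_points = tibble::tibble(site_id = "s", x = 0, y = 0, z = 0)
    ),
    "unknown nucleosome_id"
  )
  expect_error(
    nucleosome_assembly(
      nucleosomes = tibble::tibble(nucleosome_id = "N1", stack_id = 1L),
      anchors = tibble::tibble(
        anchor_id = "a", nucleosome_id = "N1", x = 0, y = 0, z = 0
      ),
      sites = tibble::tibble(
        site_id = "s", nucleosome_id = "N1", kind = "tip_binding_site"
      ),
      site_points = tibble::tibble(site_id = "t", x = 0, y = 0, z = 0)
    ),
    "unknown site"
  )
})
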