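# Seeded synthetic-data generators. These stand in for the inputs the
# analysis stages normally consume -- long MD ensembles of the H3 tail,
# nucleosome / tetranucleosome coordinates, and docking pose tables -- so
# every stage of the pipeline has a fully specified, reproducible input
# whose ground truth (planted helices, planted best cells, planted reach
# margins) is known by construction.

# Ideal backbone internal coordinates (Angstrom / degrees).
bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

# Canonical helix dihedrals.
ss_dihedrals <- list(
  alpha = c(phi = -57, psi = -47),
  three_ten = c(phi = -49, psi = -26)
)

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, globalenv())
      } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Specification for a synthetic peptide ensemble
#'
#' Describes a backbone-only peptide trajectory with planted secondary
#' structure: each segment switches between its ideal helix dihedrals and
#' coil, independently per frame, with probability `persistence` of being
#' helical -- a minimal emulation of a partially stable helix in a long MD
#' ensemble.
#'
#' @param n_res Number of residues (default 43, the H3 N-terminal tail).
#' @param segments Data frame with columns `start_res`, `end_res`,
#'   `ss_class` (`"alpha"` or `"three_ten"`), `persistence` (0-1). Segments
#'   must lie within the peptide and not overlap. The default plants the two
#'   helices observed in the unmodified tail ensemble: a tip helix at
#'   residues 3-12 (persistence 0.8) and a weaker middle helix at residues
#'   20-29 (persistence 0.4).
#' @param n_frames Number of frames.
#' @param dt Frame spacing, ps.
#' @param coil_dihedral_jitter SD of the Gaussian jitter on coil dihedrals,
#'   degrees.
#' @param coil_basin `"extended"` (beta/PPII-like coil, long chains) or
#'   `"compact"` (mixed-basin coil producing collapsed chains).
#' @param sequence Character vector of one-letter residue codes (defaults to
#'   the H3 tail for 43 residues, polyalanine otherwise).
#' @return A list of class `peptide_spec`.
#' @export
peptide_spec <- function(n_res = 43,
                         segments = tibble::tibble(
                           start_res = c(3L, 20L),
                           end_res = c(12L, 29L),
                           ss_class = "alpha",
                           persistence = c(0.8, 0.4)
                         ),
                         n_frames = 200, dt = 25,
                         coil_dihedral_jitter = 20,
                         coil_basin = c("extended", "compact"),
                         sequence = NULL) {
  coil_basin <- match.arg(coil_basin)
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) > 0) {
    stopifnot(
      all(segments$start_res >= 1), all(segments$end_res <= n_res),
      all(segments$start_res <= segments$end_res),
      all(segments$persistence >= 0), all(segments$persistence <= 1),
      all(segments$ss_class %in% names(ss_dihedrals))
    )
    covered <- unlist(Map(seq, segments$start_res, segments$end_res))
    if (anyDuplicated(covered)) {
      stop("planted segments overlap", call. = FALSE)
    }
  }
  if (is.null(sequence)) {
    sequence <- if (n_res == 43) h3_tail_sequence() else rep("A", n_res)
  }
  stopifnot(length(sequence) == n_res)
  structure(
    list(
      n_res = n_res, segments = segments, n_frames = n_frames, dt = dt,
      coil_dihedral_jitter = coil_dihedral_jitter, coil_basin = coil_basin,
      sequence = sequence
    ),
    class = "peptide_spec"
  )
}

# Build backbone coordinates for all frames at once from per-frame phi/psi
# matrices (n_frames x n_res). Atom order per residue is N, CA, C, O plus a
# CB stub for non-glycine residues (the only side-chain atom carried; it
# feeds the hydrophobic-contact class and nothing else).
build_backbone <- function(phi, psi, sequence) {
  nf <- nrow(phi)
  nr <- ncol(phi)
  g <- bb_geom
  N <- CA <- C <- O <- CB <- vector("list", nr)
  rep_row <- function(v) matrix(v, nf, 3, byrow = TRUE)
  N[[1]] <- rep_row(c(0, 0, 0))
  CA[[1]] <- rep_row(c(g$n_ca, 0, 0))
  th <- g$ang_n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + g$ca_c * rep_row(c(cos(pi - th), sin(pi - th), 0))
  has_cb <- sequence != "G"
  for (i in seq_len(nr)) {
    if (i > 1) {
      N[[i]] <- place_atom(
        N[[i - 1]], CA[[i - 1]], C[[i - 1]],
        g$c_n, g$ang_ca_c_n, psi[, i - 1]
      )
      CA[[i]] <- place_atom(
        CA[[i - 1]], C[[i - 1]], N[[i]],
        g$n_ca, g$ang_c_n_ca, g$omega
      )
      C[[i]] <- place_atom(
        C[[i - 1]], N[[i]], CA[[i]],
        g$ca_c, g$ang_n_ca_c, phi[, i]
      )
    }
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o, psi[, i] + 180)
    if (has_cb[i]) {
      # Idealised tetrahedral CB from the local N, CA, C frame.
      b <- CA[[i]] - N[[i]]
      cc <- C[[i]] - CA[[i]]
      a <- row_cross(b, cc)
      CB[[i]] <- CA[[i]] - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
    }
  }
  atoms_per_res <- 4L + as.integer(has_cb)
  coords <- array(0, dim = c(nf, sum(atoms_per_res), 3))
  at <- 0L
  for (i in seq_len(nr)) {
    coords[, at + 1L, ] <- N[[i]]
    coords[, at + 2L, ] <- CA[[i]]
    coords[, at + 3L, ] <- C[[i]]
    coords[, at + 4L, ] <- O[[i]]
    if (has_cb[i]) coords[, at + 5L, ] <- CB[[i]]
    at <- at + atoms_per_res[i]
  }
  coords
}

peptide_topology <- function(spec) {
  nr <- spec$n_res
  res_names <- unname(aa_three[spec$sequence])
  has_cb <- spec$sequence != "G"
  rows <- lapply(seq_len(nr), function(i) {
    nm <- c("N", "CA", "C", "O", if (has_cb[i]) "CB")
    el <- c("N", "C", "C", "O", if (has_cb[i]) "C")
    tibble::tibble(
      name = nm, element = el, res_seq = i, res_name = res_names[i],
      chain_id = "A", x = 0, y = 0, z = 0
    )
  })
  as_structure(dplyr::bind_rows(rows), label = "synthetic peptide")
}

coil_dihedrals <- function(nf, nr, jitter, basin) {
  if (basin == "extended") {
    phi0 <- matrix(-120, nf, nr)
    psi0 <- matrix(130, nf, nr)
  } else {
    # Mixture of backbone basins gives collapsed random-walk chains.
    basins <- matrix(
      sample(1:3, nf * nr, replace = TRUE, prob = c(0.45, 0.25, 0.3)),
      nf, nr
    )
    phi0 <- matrix(c(-65, 60, -120)[basins], nf, nr)
    psi0 <- matrix(c(-45, 45, 130)[basins], nf, nr)
  }
  list(
    phi = phi0 + matrix(stats::rnorm(nf * nr, sd = jitter), nf, nr),
    psi = psi0 + matrix(stats::rnorm(nf * nr, sd = jitter), nf, nr)
  )
}

#' Generate a synthetic peptide trajectory with planted helices
#'
#' Builds an ideal-geometry backbone (N, CA, C, O) for every frame from
#' per-residue dihedrals: planted segments use canonical helix dihedrals
#' when "on" (an independent Bernoulli draw per segment and frame at the
#' segment's persistence) and coil dihedrals otherwise. The same seed
#' always reproduces the identical trajectory.
#'
#' @param spec A [peptide_spec()].
#' @param seed Integer seed (required; generators are pure functions of
#'   spec + seed).
#' @return A `tail_trajectory` whose `planted` attribute records the
#'   per-frame on/off state of every segment.
#' @export
gen_peptide_trajectory <- function(spec = peptide_spec(), seed) {
  stopifnot(inherits(spec, "peptide_spec"), !missing(seed))
  with_seed(seed, {
    nf <- spec$n_frames
    nr <- spec$n_res
    cd <- coil_dihedrals(nf, nr, spec$coil_dihedral_jitter, spec$coil_basin)
    phi <- cd$phi
    psi <- cd$psi
    on_states <- matrix(FALSE, nf, max(1, nrow(spec$segments)))
    if (nrow(spec$segments) > 0) {
      for (k in seq_len(nrow(spec$segments))) {
        seg <- spec$segments[k, ]
        on <- stats::runif(nf) < seg$persistence
        on_states[, k] <- on
        ideal <- ss_dihedrals[[seg$ss_class]]
        cols <- seg$start_res:seg$end_res
        phi[on, cols] <- ideal[["phi"]]
        psi[on, cols] <- ideal[["psi"]]
      }
    }
    coords <- build_backbone(phi, psi, spec$sequence)
    traj <- trajectory(peptide_topology(spec), coords, dt = spec$dt)
    attr(traj, "planted") <- on_states
    traj
  })
}

#' Generate a compact ("active-like") and extended ("inactive-like") pair
#'
#' Returns two 43-residue tail trajectories with a planted reach margin:
#' the first uses a compact mixed-basin coil (emulating the collapsed,
#' loop-dominated active isoform), the second an extended coil with a
#' planted alpha-helix at residues 20-27 at persistence 0.65 (emulating the
#' inactive isoform, whose middle helix persists for 60-70% of the
#' ensemble and whose reach is substantially longer).
#'
#' @param n_frames Frames per trajectory (>= 100).
#' @param seed Integer seed.
#' @return A named list with elements `active` and `inactive`.
#' @export
gen_active_inactive_pair <- function(n_frames = 2000, seed) {
  stopifnot(n_frames >= 100, !missing(seed))
  active_spec <- peptide_spec(
    n_res = 43,
    segments = tibble::tibble(
      start_res = integer(), end_res = integer(),
      ss_class = character(), persistence = numeric()
    ),
    n_frames = n_frames, coil_basin = "compact",
    coil_dihedral_jitter = 25
  )
  inactive_spec <- peptide_spec(
    n_res = 43,
    segments = tibble::tibble(
      start_res = 20L, end_res = 27L,
      ss_class = "alpha", persistence = 0.65
    ),
    n_frames = n_frames, coil_basin = "extended",
    coil_dihedral_jitter = 15
  )
  list(
    active = gen_peptide_trajectory(active_spec, seed = seed),
    inactive = gen_peptide_trajectory(inactive_spec, seed = seed + 1L)
  )
}

# -- Toy nucleosomes --------------------------------------------------------

#' Specification for a toy nucleosome
#'
#' A pseudo-atom nucleosome disc: the DNA path is a superhelix of one
#' pseudo-atom per base pair (147 bp spooled in ~1.65 turns at the
#' canonical ~42 A superhelix radius), the octamer a cylindrical shell of
#' CA pseudo-atoms distributed over the eight histone chains. Two H3
#' anchor points mark the P43 positions where the tails leave the core,
#' and annotated sites mark the tail-tip binding position (placed between
#' the H3/H2B exit side, below the disc mid-plane) and the H2A/H2B acidic
#' patch (near the disc axis).
#'
#' @param dna_radius DNA superhelix radius, Angstrom.
#' @param dna_turns Superhelical turns of the DNA path.
#' @param pitch Superhelix rise per turn, Angstrom.
#' @param n_bp Number of DNA pseudo-atoms (one per bp).
#' @param octamer_radius Radius of the octamer pseudo-atom shell, Angstrom.
#' @param anchor_radius Radial position of the two H3 P43 anchors, Angstrom.
#' @param anchor_angle Angular position (+/-) of the anchors, radians.
#' @param site_radius Radial position of the tip binding site, Angstrom.
#' @param site_z Height of the tip binding site, Angstrom.
#' @return A list of class `nucleosome_spec`.
#' @export
nucleosome_spec <- function(dna_radius = 42, dna_turns = 1.65, pitch = 24,
                            n_bp = 147, octamer_radius = 30,
                            anchor_radius = 26, anchor_angle = 0.9,
                            site_radius = 38, site_z = -10) {
  stopifnot(
    dna_radius > 0, pitch > 0, n_bp > 1, octamer_radius > 0,
    anchor_radius > 0, site_radius > 0
  )
  structure(
    list(
      dna_radius = dna_radius, dna_turns = dna_turns, pitch = pitch,
      n_bp = n_bp, octamer_radius = octamer_radius,
      anchor_radius = anchor_radius, anchor_angle = anchor_angle,
      site_radius = site_radius, site_z = site_z
    ),
    class = "nucleosome_spec"
  )
}

toy_nucleosome_structure <- function(spec) {
  # DNA superhelix, centred on the origin.
  t <- seq(-spec$dna_turns * pi, spec$dna_turns * pi, length.out = spec$n_bp)
  dna <- tibble::tibble(
    # alternate phosphate / backbone-oxygen pseudo-atoms so the DNA path
    # offers hydrogen-bond acceptors
    name = rep_len(c("P", "OP"), spec$n_bp),
    element = rep_len(c("P", "O"), spec$n_bp),
    res_seq = seq_len(spec$n_bp), res_name = "DA", chain_id = "I",
    x = spec$dna_radius * cos(t),
    y = spec$dna_radius * sin(t),
    z = spec$pitch * t / (2 * pi)
  )
  # Octamer shell: three rings of CA pseudo-atoms over chains A-H
  # (A/E = H3, B/F = H4, C/G = H2A, D/H = H2B).
  ring <- function(z, n, offset) {
    a <- offset + 2 * pi * seq_len(n) / n
    tibble::tibble(
      x = spec$octamer_radius * cos(a),
      y = spec$octamer_radius * sin(a), z = z
    )
  }
  oct_xyz <- dplyr::bind_rows(ring(-12, 24, 0), ring(0, 24, 0.13), ring(12, 24, 0.26))
  oct <- tibble::tibble(
    # surface pseudo-atoms cycle apolar carbon / amide N / carbonyl O
    name = rep_len(c("CB", "CB", "N", "O"), nrow(oct_xyz)),
    element = rep_len(c("C", "C", "N", "O"), nrow(oct_xyz)),
    res_seq = seq_len(nrow(oct_xyz)),
    res_name = "ALA",
    chain_id = rep_len(LETTERS[1:8], nrow(oct_xyz)),
    x = oct_xyz$x, y = oct_xyz$y, z = oct_xyz$z
  )
  as_structure(dplyr::bind_rows(dna, oct), label = "toy nucleosome")
}

toy_anchors <- function(spec) {
  a <- spec$anchor_angle
  tibble::tibble(
    anchor = c("H3_A", "H3_E"),
    x = spec$anchor_radius * cos(c(a, -a)),
    y = spec$anchor_radius * sin(c(a, -a)),
    z = c(0, 0)
  )
}

toy_sites <- function(spec) {
  tip <- tibble::tibble(
    site_id = "tip_site", kind = "tip_binding_site",
    x = spec$site_radius, y = 0, z = spec$site_z
  )
  patch <- tibble::tibble(
    site_id = "acidic_patch", kind = "acidic_patch",
    x = c(0, 0, 3), y = c(0, 3, 0), z = 0
  )
  dplyr::bind_rows(tip, patch)
}

#' Generate a single toy nucleosome assembly
#'
#' @param spec A [nucleosome_spec()].
#' @return A `nucleosome_assembly` (see [nucleosome_assembly()]) with one
#'   nucleosome, two H3 anchors and annotated tip-binding and acidic-patch
#'   sites.
#' @export
gen_toy_nucleosome <- function(spec = nucleosome_spec()) {
  s <- toy_nucleosome_structure(spec)
  anchors <- toy_anchors(spec)
  sites <- toy_sites(spec)
  nucleosome_assembly(
    nucleosomes = tibble::tibble(nucleosome_id = "N1", stack_id = 1L),
    structures = list(N1 = s),
    anchors = tibble::tibble(
      anchor_id = paste0("N1_", anchors$anchor),
      nucleosome_id = "N1",
      x = anchors$x, y = anchors$y, z = anchors$z
    ),
    sites = tibble::tibble(
      site_id = paste0("N1_", unique(sites$site_id)),
      nucleosome_id = "N1",
      kind = sites$kind[!duplicated(sites$site_id)]
    ),
    site_points = tibble::tibble(
      site_id = paste0("N1_", sites$site_id),
      x = sites$x, y = sites$y, z = sites$z
    )
  )
}

#' Generate a toy tetranucleosome assembly
#'
#' Two stacks of two nucleosomes each (the zig-zag tetranucleosome
#' arrangement): nucleosomes within a stack are separated along the stack
#' axis, the stacks by a larger lateral separation. Anchors and annotated
#' sites are populated by rigid transplantation ([transplant_site()]) of
#' the template nucleosome's sites onto every placed copy.
#'
#' @param spec A [nucleosome_spec()] for the template nucleosome.
#' @param stack_separation Distance between the two stack axes, Angstrom.
#' @param nucleosome_spacing Rise between stacked nucleosomes, Angstrom.
#' @return A `nucleosome_assembly` with 4 nucleosomes, 8 anchors, 4
#'   tip-binding sites and 4 acidic-patch sites.
#' @export
gen_tetranucleosome <- function(spec = nucleosome_spec(),
                                stack_separation = 110,
                                nucleosome_spacing = 50) {
  stopifnot(stack_separation > 0, nucleosome_spacing > 0)
  template <- toy_nucleosome_structure(spec)
  anchors0 <- toy_anchors(spec)
  sites0 <- toy_sites(spec)
  placements <- tibble::tibble(
    nucleosome_id = c("S1N1", "S1N2", "S2N1", "S2N2"),
    stack_id = c(1L, 1L, 2L, 2L),
    dx = c(0, 0, stack_separation, stack_separation),
    dz = c(0, nucleosome_spacing, 0, nucleosome_spacing)
  )
  structures <- list()
  anchors <- list()
  sites <- list()
  site_points <- list()
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    moved <- template
    moved$x <- moved$x + p$dx
    moved$z <- moved$z + p$dz
    structures[[p$nucleosome_id]] <- as_structure(moved, label = p$nucleosome_id)
    # Transplant anchors and sites from the template through the rigid
    # core superposition onto the placed copy.
    anchor_xyz <- transplant_site(
      as.matrix(anchors0[, c("x", "y", "z")]), template, moved
    )
    anchors[[i]] <- tibble::tibble(
      anchor_id = paste0(p$nucleosome_id, "_", anchors0$anchor),
      nucleosome_id = p$nucleosome_id,
      x = anchor_xyz[, 1], y = anchor_xyz[, 2], z = anchor_xyz[, 3]
    )
    site_xyz <- transplant_site(
      as.matrix(sites0[, c("x", "y", "z")]), template, moved
    )
    sites[[i]] <- tibble::tibble(
      site_id = paste0(p$nucleosome_id, "_", unique(sites0$site_id)),
      nucleosome_id = p$nucleosome_id,
      kind = sites0$kind[!duplicated(sites0$site_id)]
    )
    site_points[[i]] <- tibble::tibble(
      site_id = paste0(p$nucleosome_id, "_", sites0$site_id),
      x = site_xyz[, 1], y = site_xyz[, 2], z = site_xyz[, 3]
    )
  }
  nucleosome_assembly(
    nucleosomes = placements[, c("nucleosome_id", "stack_id")],
    structures = structures,
    anchors = dplyr::bind_rows(anchors),
    sites = dplyr::bind_rows(sites),
    site_points = dplyr::bind_rows(site_points)
  )
}

# -- Pose tables ------------------------------------------------------------

#' Generate a synthetic docking pose table with planted best cells
#'
#' One energy per (structure label, grid cell); the planted cell of each
#' label is strictly maximal (most favourable, in the positive-is-favorable
#' sign convention), all other energies are seeded noise below it.
#'
#' @param grid A grid tibble from [make_grid()].
#' @param structures Character vector of structure labels.
#' @param planted_best Named character vector or list mapping each label to
#'   its planted best cell.
#' @param seed Integer seed.
#' @return A pose-table tibble with columns `structure_label`, `cell`,
#'   `energy`.
#' @export
gen_pose_table <- function(grid, structures, planted_best, seed) {
  stopifnot(!missing(seed))
  planted_best <- unlist(planted_best)
  missing_lab <- setdiff(structures, names(planted_best))
  if (length(missing_lab) > 0) {
    stop("no planted cell for label(s): ", paste(missing_lab, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unname(planted_best[structures]), grid$cell)
  if (length(bad) > 0) {
    stop("planted cell(s) not in grid: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  with_seed(seed, {
    rows <- lapply(structures, function(lab) {
      e <- stats::runif(nrow(grid), min = -4, max = 6)
      best <- which(grid$cell == planted_best[[lab]])
      e[best] <- max(e[-best]) + stats::runif(1, 0.5, 2)
      tibble::tibble(structure_label = lab, cell = grid$cell, energy = round(e, 2))
    })
    dplyr::bind_rows(rows)
  })
}
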