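# Secondary-structure assignment from backbone geometry.
#
# Hydrogen bonds are detected with the Kabsch-Sander electrostatic model:
# the backbone amide (N-H) and carbonyl (C=O) groups carry partial charges
# whose interaction energy is
#
#   E = q1q2 * f * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)   [kcal/mol]
#
# with q1q2 = 0.084 e^2 and f = 332 kcal*A/(mol*e^2); a bond is called when
# E < -0.5 kcal/mol. Assignments then follow the DSSP pattern rules reduced
# to the 6-class alphabet H (alpha-helix), G (3-10 helix), E (beta-strand),
# B (isolated beta-bridge), T (hydrogen-bonded turn), C (coil/other).

#' Secondary-structure assignment parameters
#'
#' @param q1q2_factor Product of the partial charges on the H-bonding groups
#'   (e^2).
#' @param f_dimensional Dimensional factor (kcal*A/(mol*e^2)).
#' @param e_cutoff Energy threshold below which a hydrogen bond is called
#'   (kcal/mol, must be negative).
#' @param min_helix_run Number of consecutive turns required to open a
#'   helix (2 in the standard rules).
#' @return A list of parameters for [assign_ss()] and friends.
#' @export
ss_params <- function(q1q2_factor = 0.084, f_dimensional = 332,
                      e_cutoff = -0.5, min_helix_run = 2) {
  stopifnot(e_cutoff < 0, min_helix_run >= 1)
  list(
    q1q2_factor = q1q2_factor, f_dimensional = f_dimensional,
    e_cutoff = e_cutoff, min_helix_run = min_helix_run
  )
}

# Backbone coordinate bundle for one frame: per-residue N, CA, C, O matrices
# plus a reconstructed amide H. Residue 1 and prolines have no amide H.
backbone_frame <- function(coords, topology) {
  res <- sort(unique(topology$res_seq))
  n <- length(res)
  get_atoms <- function(atom_name) {
    m <- matrix(NA_real_, n, 3)
    idx <- which(topology$name == atom_name)
    pos <- match(topology$res_seq[idx], res)
    m[pos, ] <- coords[idx, , drop = FALSE]
    m
  }
  N <- get_atoms("N")
  CA <- get_atoms("CA")
  C <- get_atoms("C")
  O <- get_atoms("O")
  for (nm in c("N", "CA", "C", "O")) {
    m <- switch(nm, N = N, CA = CA, C = C, O = O)
    if (anyNA(m)) {
      stop("missing backbone ", nm, " atom for residue ",
        res[which(rowSums(is.na(m)) > 0)[1]],
        call. = FALSE
      )
    }
  }
  # Amide H: on N, 1.01 A along the direction of the preceding C=O bond
  # (O -> C), the standard geometric reconstruction when H is absent.
  H <- matrix(NA_real_, n, 3)
  idxH <- which(topology$name %in% c("H", "HN"))
  if (length(idxH) > 0) {
    pos <- match(topology$res_seq[idxH], res)
    H[pos, ] <- coords[idxH, , drop = FALSE]
  }
  need <- which(rowSums(is.na(H)) > 0)
  need <- need[need > 1]
  if (length(need) > 0) {
    dir <- row_unit(C[need - 1, , drop = FALSE] - O[need - 1, , drop = FALSE])
    H[need, ] <- N[need, , drop = FALSE] + 1.01 * dir
  }
  is_pro <- tapply(topology$res_name, topology$res_seq, function(v) v[1])[as.character(res)] == "PRO"
  list(res = res, n = n, N = N, CA = CA, C = C, O = O, H = H, is_pro = unname(is_pro))
}

#' Backbone hydrogen bonds of one frame
#'
#' Evaluates the Kabsch-Sander electrostatic energy for every
#' donor (amide) / acceptor (carbonyl) residue pair with `|i - j| >= 2` and
#' returns the pairs whose energy falls below the cutoff. The first residue
#' and prolines cannot donate.
#'
#' @param coords n_atoms x 3 coordinate matrix for one frame.
#' @param topology Atom tibble describing the atoms (must contain backbone
#'   N, CA, C, O; amide H is reconstructed geometrically when absent).
#' @param params See [ss_params()].
#' @return A tibble with columns `donor_res`, `acceptor_res`, `energy`
#'   (kcal/mol).
#' @export
backbone_hbonds <- function(coords, topology, params = ss_params()) {
  bb <- backbone_frame(coords, topology)
  hb <- hbond_set(bb, params)
  tibble::tibble(
    donor_res = bb$res[hb$donor],
    acceptor_res = bb$res[hb$acceptor],
    energy = hb$energy
  )
}

# Internal: H-bond pairs by residue *position* (1..n). Returns donor,
# acceptor index vectors and energies, plus the n x n bond matrix
# bond[acceptor, donor].
hbond_set <- function(bb, params) {
  n <- bb$n
  pd <- function(a, b) {
    # distance between acceptor-group atom rows (a) and donor-group rows (b)
    dx <- outer(a[, 1], b[, 1], `-`)
    dy <- outer(a[, 2], b[, 2], `-`)
    dz <- outer(a[, 3], b[, 3], `-`)
    sqrt(dx^2 + dy^2 + dz^2)
  }
  q <- params$q1q2_factor * params$f_dimensional
  # E[i, j]: carbonyl of residue i (acceptor side) with amide of residue j
  E <- q * (1 / pd(bb$O, bb$N) + 1 / pd(bb$C, bb$H) -
    1 / pd(bb$O, bb$H) - 1 / pd(bb$C, bb$N))
  E[is.na(E)] <- 0 # donors without H (residue 1, prolines)
  E[, bb$is_pro] <- 0
  E[, 1] <- 0
  near <- abs(outer(seq_len(n), seq_len(n), `-`)) < 2
  E[near] <- 0
  bond <- E < params$e_cutoff
  idx <- which(bond, arr.ind = TRUE)
  list(
    acceptor = idx[, 1], donor = idx[, 2],
    energy = E[idx], bond = bond
  )
}

#' Assign secondary structure to one frame
#'
#' DSSP pattern rules on the Kabsch-Sander bond set: two consecutive
#' i -> i+4 turns open an alpha-helix (H), two consecutive i -> i+3 turns a
#' 3-10 helix (G, where not already H), bridge patterns give ladders (E) or
#' isolated bridges (B), remaining turn residues T, everything else C.
#' Pi-helix patterns are not assigned (they fall through to T/C).
#'
#' @inheritParams backbone_hbonds
#' @return Character vector of codes in `{H,G,E,B,T,C}`, one per residue,
#'   named by residue number.
#' @export
assign_ss <- function(coords, topology, params = ss_params()) {
  bb <- backbone_frame(coords, topology)
  hb <- hbond_set(bb, params)
  codes <- ss_reduce(hb$bond, bb$n, params$min_helix_run)
  names(codes) <- bb$res
  codes
}

# Internal: reduce a bond matrix (bond[acceptor, donor] = TRUE) to codes.
ss_reduce <- function(bond, n, min_helix_run = 2) {
  has_turn <- function(k) {
    # n-turn at i: CO(i) accepts from NH(i + k)
    t <- rep(FALSE, n)
    if (n > k) {
      i <- seq_len(n - k)
      t[i] <- bond[cbind(i, i + k)]
    }
    t
  }
  turn3 <- has_turn(3)
  turn4 <- has_turn(4)
  codes <- rep("C", n)

  # Bridges: parallel (i-1 -> j and j -> i+1, or j-1 -> i and i -> j+1),
  # antiparallel (i -> j and j -> i, or i-1 -> j+1 and j-1 -> i+1).
  hb <- function(a, d) {
    ok <- a >= 1 & a <= n & d >= 1 & d <= n
    out <- rep(FALSE, length(a))
    out[ok] <- bond[cbind(a[ok], d[ok])]
    out
  }
  bridge <- matrix(FALSE, n, n)
  ij <- which(
    abs(outer(seq_len(n), seq_len(n), `-`)) > 2,
    arr.ind = TRUE
  )
  i <- ij[, 1]
  j <- ij[, 2]
  par <- (hb(i - 1, j) & hb(j, i + 1)) | (hb(j - 1, i) & hb(i, j + 1))
  anti <- (hb(i, j) & hb(j, i)) | (hb(i - 1, j + 1) & hb(j - 1, i + 1))
  bridge[ij] <- par | anti

  is_bridge <- rowSums(bridge) > 0
  # Ladder: bridge residues with a bridge neighbour at i +/- 1 sharing a
  # partner neighbourhood; simplified to: consecutive bridge residues form
  # strands (E), isolated ones are B.
  strand <- rep(FALSE, n)
  for (k in which(is_bridge)) {
    partners <- which(bridge[k, ])
    ext <- any(vapply(partners, function(p) {
      (k > 1 && any(bridge[k - 1, ][pmax(1, p - 1):pmin(n, p + 1)])) ||
        (k < n && any(bridge[k + 1, ][pmax(1, p - 1):pmin(n, p + 1)]))
    }, logical(1)))
    strand[k] <- ext
  }

  # Helices: runs of >= min_helix_run consecutive n-turns; a turn run
  # starting at i marks residues i .. i + k - 1.
  mark_helix <- function(turn, k, code, codes, blocked) {
    run <- rep(TRUE, n)
    for (s in seq_len(min_helix_run) - 1) {
      run <- run & c(rep(FALSE, s), turn)[seq_len(n)]
    }
    for (i in which(run)) {
      span <- i:min(n, i + k - 1)
      span <- span[!blocked[span]]
      codes[span] <- code
    }
    codes
  }
  blocked <- rep(FALSE, n)
  codes <- mark_helix(turn4, 4, "H", codes, blocked)
  blocked <- codes == "H" # DSSP priority H > G
  codes <- mark_helix(turn3, 3, "G", codes, blocked)

  free <- !(codes %in% c("H", "G"))
  codes[free & strand] <- "E"
  codes[free & !strand & is_bridge] <- "B"

  # Turns: residues i+1 .. i+k-1 of an n-turn at i, where still unassigned.
  free <- codes == "C"
  for (k in c(3, 4)) {
    turn <- if (k == 3) turn3 else turn4
    for (i in which(turn)) {
      span <- (i + 1):(i + k - 1)
      span <- span[span <= n]
      codes[span][codes[span] == "C"] <- "T"
    }
  }
  codes
}

#' Per-frame secondary-structure matrix of a trajectory
#'
#' Runs [assign_ss()] on every frame, producing the frame x residue label
#' grid from which occupancy profiles and evolution plots are derived.
#'
#' @param traj A `tail_trajectory`.
#' @param params See [ss_params()].
#' @return An object of class `ss_matrix`: list with `labels` (frame x
#'   residue character matrix), `res_seq`, and `times_ps`.
#' @export
ss_matrix <- function(traj, params = ss_params()) {
  nf <- n_frames(traj)
  if (nf < 1) stop("trajectory has no frames", call. = FALSE)
  rows <- lapply(seq_len(nf), function(i) {
    assign_ss(frame_coords(traj, i), traj$topology, params)
  })
  labels <- do.call(rbind, rows)
  res <- sort(unique(traj$topology$res_seq))
  dimnames(labels) <- list(NULL, res)
  structure(
    list(
      labels = labels, res_seq = res,
      times_ps = (seq_len(nf) - 1) * traj$dt
    ),
    class = "ss_matrix"
  )
}

#' @export
print.ss_matrix <- function(x, ...) {
  cat(
    "<ss_matrix> ", nrow(x$labels), " frames x ", length(x$res_seq),
    " residues\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a secondary-structure matrix into long form
#'
#' @param x An `ss_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `time_ps`, `res_seq`, `code`.
#' @method tidy ss_matrix
#' @export
tidy.ss_matrix <- function(x, ...) {
  nf <- nrow(x$labels)
  nr <- length(x$res_seq)
  tibble::tibble(
    frame = rep(seq_len(nf), times = nr),
    time_ps = rep(x$times_ps, times = nr),
    res_seq = rep(x$res_seq, each = nf),
    code = as.vector(x$labels)
  )
}

ss_codes <- c("H", "G", "E", "B", "T", "C")

#' Per-residue secondary-structure occupancy
#'
#' The fraction of frames each residue spends in each of the six classes --
#' the "percentage of simulation time" profile of an ensemble.
#'
#' @param m An `ss_matrix`.
#' @return A tibble with columns `res_seq`, `code`, `fraction`; fractions
#'   for a residue sum to 1.
#' @export
occupancy <- function(m) {
  stopifnot(inherits(m, "ss_matrix"))
  nf <- nrow(m$labels)
  if (nf < 1) stop("empty secondary-structure matrix", call. = FALSE)
  counts <- apply(m$labels, 2, function(col) {
    table(factor(col, levels = ss_codes))
  })
  tibble::tibble(
    res_seq = rep(m$res_seq, each = length(ss_codes)),
    code = rep(ss_codes, times = length(m$res_seq)),
    fraction = as.vector(counts) / nf
  )
}
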