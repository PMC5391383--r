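# Docking-pose bookkeeping: the overlapping grid-cell scheme over the
# nucleosome, best-pose selection per tip structure, and contact
# classification (total / hydrogen bond / hydrophobic) between a docked
# tip and the nucleosome.

#' Overlapping grid cells over a receptor
#'
#' Divides the receptor's xy bounding box into `rows` x `cols` axis-aligned
#' cells (each spanning the full z extent), expands every cell by
#' `overlap_frac` of its width on interior edges, and labels the cells
#' row-major `A1, A2, ..., B1, ...` -- the scheme used to split the
#' nucleosome surface into 9 overlapping docking cells.
#'
#' @param receptor An atom tibble.
#' @param rows,cols Grid shape (default 3 x 3).
#' @param overlap_frac Linear overlap between adjacent cells as a fraction
#'   of cell width, in `[0, 0.5]`.
#' @return A tibble with one row per cell: `cell`, `row`, `col`, `xmin`,
#'   `xmax`, `ymin`, `ymax`, `zmin`, `zmax`.
#' @export
make_grid <- function(receptor, rows = 3, cols = 3, overlap_frac = 0.25) {
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1", call. = FALSE)
  stopifnot(overlap_frac >= 0, overlap_frac <= 0.5, nrow(receptor) > 0)
  xr <- range(receptor$x)
  yr <- range(receptor$y)
  zr <- range(receptor$z)
  wx <- diff(xr) / cols
  wy <- diff(yr) / rows
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  tibble::tibble(
    cell = paste0(LETTERS[grid$row], grid$col),
    row = grid$row,
    col = grid$col,
    xmin = xr[1] + (grid$col - 1) * wx - ifelse(grid$col > 1, overlap_frac * wx, 0),
    xmax = xr[1] + grid$col * wx + ifelse(grid$col < cols, overlap_frac * wx, 0),
    ymin = yr[1] + (grid$row - 1) * wy - ifelse(grid$row > 1, overlap_frac * wy, 0),
    ymax = yr[1] + grid$row * wy + ifelse(grid$row < rows, overlap_frac * wy, 0),
    zmin = zr[1],
    zmax = zr[2]
  )
}

#' Total pose count of a grid campaign
#'
#' @param grid A grid tibble from [make_grid()].
#' @param per_cell Poses generated per cell (>= 1); 400 poses over a 3 x 3
#'   grid gives the canonical 3600 poses per docked structure.
#' @return Integer total number of poses.
#' @export
expected_pose_total <- function(grid, per_cell = 400) {
  stopifnot(per_cell >= 1)
  as.integer(nrow(grid) * per_cell)
}

#' Read a docking pose table from CSV
#'
#' @param path CSV with columns `structure_label`, `cell`, `energy` (and
#'   optionally more).
#' @param autodock_sign If `TRUE`, energies follow the Autodock convention
#'   (negative = favourable) and are negated on input; the package works in
#'   the positive-is-favourable convention throughout.
#' @return A pose-table tibble.
#' @export
read_pose_table <- function(path, autodock_sign = FALSE) {
  t <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("structure_label", "cell", "energy")
  missing_cols <- setdiff(need, names(t))
  if (length(missing_cols) > 0) {
    stop("pose table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(is.finite(t$energy))) stop("non-finite pose energies", call. = FALSE)
  if (autodock_sign) t$energy <- -t$energy
  t
}

#' The reference H3 tail-tip docking energy table
#'
#' The grid-cell binding energies (kcal/mol, positive = favourable) of the
#' six clustered H3 tail-tip structures docked over the 3 x 3 cell scheme
#' covering the nucleosome core particle: three clusters of the unmodified
#' tail plus the hyperacetylated, active and inactive isoform clusters.
#'
#' @return A pose-table tibble (54 rows).
#' @export
h3_docking_energies <- function() {
  read_pose_table(system.file("extdata", "h3_tip_docking_energies.csv",
    package = "tailscope", mustWork = TRUE
  ))
}

#' Best docking pose of a structure
#'
#' Selects the grid cell with the maximum binding energy for one structure
#' label (larger = more favourable in the positive sign convention); ties
#' are broken by cell label order (A1 before A2 before ... C3).
#'
#' @param pose_table A pose-table tibble.
#' @param structure_label Label to rank.
#' @return A one-row tibble with `structure_label`, `cell`, `energy`.
#' @export
best_pose <- function(pose_table, structure_label) {
  rows <- pose_table[pose_table$structure_label == structure_label, ]
  if (nrow(rows) == 0) {
    stop("no poses for structure '", structure_label, "'", call. = FALSE)
  }
  rows <- rows[order(-rows$energy, rows$cell), ]
  rows[1, c("structure_label", "cell", "energy")]
}

#' Rank the best pose of every structure in a table
#'
#' @param pose_table A pose-table tibble.
#' @return A tibble with one row per structure label (in first-appearance
#'   order), ranked by descending best energy.
#' @export
rank_poses <- function(pose_table) {
  labs <- unique(pose_table$structure_label)
  out <- dplyr::bind_rows(lapply(labs, function(l) best_pose(pose_table, l)))
  out[order(-out$energy), ]
}

# -- Contact analysis -------------------------------------------------------

receptor_component <- function(receptor) {
  dna_res <- c("DA", "DT", "DG", "DC", "DU", "A", "T", "G", "C", "U")
  ifelse(receptor$res_name %in% dna_res, "DNA",
    paste0("histone_", receptor$chain_id)
  )
}

# Carbon atoms with no covalently bonded N/O neighbour (< 1.8 A) in their
# own structure are treated as apolar.
apolar_carbons <- function(s) {
  xyz <- structure_coords(s)
  is_c <- s$element == "C"
  is_no <- s$element %in% c("N", "O")
  out <- rep(FALSE, nrow(s))
  if (!any(is_c)) {
    return(out)
  }
  if (!any(is_no)) {
    out[is_c] <- TRUE
    return(out)
  }
  dc <- xyz[is_c, , drop = FALSE]
  dn <- xyz[is_no, , drop = FALSE]
  d2 <- outer(rowSums(dc^2), rowSums(dn^2), `+`) - 2 * dc %*% t(dn)
  out[is_c] <- apply(d2, 1, min) > 1.8^2
  out
}

#' Contacts between a docked tip and a receptor
#'
#' Enumerates all inter-structure atom pairs within `cutoff` (total
#' contacts) and classifies two subsets: hydrogen bonds -- N/O donor /
#' acceptor pairs within 3.5 A, additionally requiring a donor-H-acceptor
#' angle of at least 135 degrees when explicit hydrogens are present -- and
#' hydrophobic contacts, carbon-carbon pairs within the cutoff where
#' neither carbon has a covalent N/O neighbour. Receptor atoms are tagged
#' DNA or by histone chain.
#'
#' @param tip,receptor Atom tibbles.
#' @param cutoff Contact distance cutoff, Angstrom (default 5).
#' @param hbond_dist Donor-acceptor distance cutoff for hydrogen bonds.
#' @param hbond_angle Minimum donor-H-acceptor angle (degrees) when an
#'   explicit H is present on the donor.
#' @return A tibble with one row per contact pair: `tip_atom`, `tip_res`,
#'   `receptor_atom`, `receptor_res`, `receptor_chain`, `component`,
#'   `distance`, `is_hbond`, `is_hydrophobic`.
#' @export
find_contacts <- function(tip, receptor, cutoff = 5,
                          hbond_dist = 3.5, hbond_angle = 135) {
  tip <- as_structure(tip)
  receptor <- as_structure(receptor)
  tx <- structure_coords(tip)
  rx <- structure_coords(receptor)
  d2 <- outer(rowSums(tx^2), rowSums(rx^2), `+`) - 2 * tx %*% t(rx)
  d2[d2 < 0] <- 0
  idx <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(
      tip_atom = character(), tip_res = integer(),
      receptor_atom = character(), receptor_res = integer(),
      receptor_chain = character(), component = character(),
      distance = numeric(), is_hbond = logical(), is_hydrophobic = logical()
    ))
  }
  i <- idx[, 1]
  j <- idx[, 2]
  dist <- sqrt(d2[idx])
  polar_t <- tip$element[i] %in% c("N", "O")
  polar_r <- receptor$element[j] %in% c("N", "O")
  is_hb <- polar_t & polar_r & dist <= hbond_dist
  # Angle screen where the tip partner carries an explicit amide H.
  if (any(is_hb)) {
    hset <- which(is_hb)
    for (k in hset) {
      if (tip$element[i[k]] != "N") next
      hrow <- which(tip$res_seq == tip$res_seq[i[k]] &
        tip$name %in% c("H", "HN"))
      if (length(hrow) == 0) next
      v1 <- tx[i[k], ] - tx[hrow[1], ]
      v2 <- rx[j[k], ] - tx[hrow[1], ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang < hbond_angle) is_hb[k] <- FALSE
    }
  }
  apolar_t <- apolar_carbons(tip)
  apolar_r <- apolar_carbons(receptor)
  is_phob <- apolar_t[i] & apolar_r[j]
  comp <- receptor_component(receptor)
  tibble::tibble(
    tip_atom = tip$name[i], tip_res = tip$res_seq[i],
    receptor_atom = receptor$name[j], receptor_res = receptor$res_seq[j],
    receptor_chain = receptor$chain_id[j], component = comp[j],
    distance = dist, is_hbond = is_hb, is_hydrophobic = is_phob
  )
}

#' Tally a contact report by class and receptor component
#'
#' @param contacts A contact tibble from [find_contacts()].
#' @return A tibble with one row per receptor component (`DNA`,
#'   `histone_A`, ...) plus a `total` row, and columns `n_total`,
#'   `n_hbond`, `n_hydrophobic`.
#' @export
contact_summary <- function(contacts) {
  tally <- function(d, label) {
    tibble::tibble(
      component = label,
      n_total = nrow(d),
      n_hbond = sum(d$is_hbond),
      n_hydrophobic = sum(d$is_hydrophobic)
    )
  }
  comps <- sort(unique(contacts$component))
  dplyr::bind_rows(
    tally(contacts, "total"),
    dplyr::bind_rows(lapply(comps, function(cp) {
      tally(contacts[contacts$component == cp, ], cp)
    }))
  )
}
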